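## Genome model: chromosome specification, founders, individuals, markers
## and genotype readout.

#' Read a genome specification
#'
#' A genome specification lists the chromosomes of the model organism: five
#' autosomes (I-V), one X and the mitochondrial genome (MT), each with a
#' length in base pairs.  Comment lines starting with `#` are ignored.
#'
#' @param path CSV file with columns `chromosome,length,kind`, kinds in
#'   `autosome`, `sex_chromosome`, `mitochondrial`.
#' @return data frame of class `genome_spec`.
#' @export
read_genome_spec <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    fill = FALSE, strip.white = TRUE),
    error = function(e) stop_format(sprintf("cannot parse genome spec '%s': %s",
                                            path, conditionMessage(e)))
  )
  need <- c("chromosome", "length", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_format(sprintf("genome spec is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  df <- df[need]
  df$length <- as.numeric(df$length)
  if (any(is.na(df$length)) || any(df$length <= 0)) {
    stop_format("genome spec lengths must be positive numbers")
  }
  kinds <- c("autosome", "sex_chromosome", "mitochondrial")
  if (any(!df$kind %in% kinds)) {
    stop_format(sprintf("genome spec kind must be one of: %s",
                        paste(kinds, collapse = ", ")))
  }
  if (sum(df$kind == "autosome") != 5L) {
    stop_format("genome spec must contain exactly five autosomes")
  }
  if (sum(df$kind == "sex_chromosome") != 1L) {
    stop_format("genome spec must contain exactly one X (sex) chromosome")
  }
  if (anyDuplicated(df$chromosome)) {
    stop_format("genome spec chromosome names must be unique")
  }
  class(df) <- c("genome_spec", "data.frame")
  df
}

#' Default genome specification
#'
#' Approximate chromosome sizes bundled with the package (editable copy
#' under `inst/extdata/genome_spec.csv`); only relative marker placement
#' matters for the statistics.
#'
#' @return data frame of class `genome_spec`.
#' @export
default_genome_spec <- function() {
  read_genome_spec(pkg_extdata("genome_spec.csv"))
}

genome_autosomes <- function(genome) {
  genome$chromosome[genome$kind == "autosome"]
}

genome_x <- function(genome) {
  genome$chromosome[genome$kind == "sex_chromosome"]
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosome)
  if (is.na(i)) stop_validation(sprintf("unknown chromosome '%s'", chrom))
  genome$length[i]
}

chrom_kind <- function(genome, chrom) {
  i <- match(chrom, genome$chromosome)
  if (is.na(i)) stop_validation(sprintf("unknown chromosome '%s'", chrom))
  genome$kind[i]
}

## ---- marker panel ---------------------------------------------------------

#' Read a marker panel
#'
#' @param path CSV with columns `name,chromosome,position,assay` (assay in
#'   `AFLP`, `RFLP`); `#` comment lines ignored.
#' @param genome genome specification used to range-check positions.
#' @return data frame of class `marker_panel`.
#' @export
read_marker_panel <- function(path, genome = default_genome_spec()) {
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    fill = FALSE, strip.white = TRUE),
    error = function(e) stop_format(sprintf("cannot parse marker panel '%s': %s",
                                            path, conditionMessage(e)))
  )
  need <- c("name", "chromosome", "position", "assay")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_format(sprintf("marker panel is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  df <- df[need]
  df$position <- suppressWarnings(as.numeric(df$position))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$chromosome %in% genome$chromosome) {
      stop_format(sprintf("marker panel row %d ('%s'): unknown chromosome '%s'",
                          i, row$name, row$chromosome))
    }
    if (is.na(row$position) || row$position < 0 ||
        row$position >= chrom_length(genome, row$chromosome)) {
      stop_format(sprintf(
        "marker panel row %d ('%s'): position must lie in [0, %s) on %s",
        i, row$name, chrom_length(genome, row$chromosome), row$chromosome))
    }
    if (!row$assay %in% c("AFLP", "RFLP")) {
      stop_format(sprintf("marker panel row %d ('%s'): assay must be AFLP or RFLP",
                          i, row$name))
    }
  }
  if (anyDuplicated(df$name)) {
    stop_format(sprintf("duplicate marker name(s): %s",
                        paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  }
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Default marker panel
#'
#' The bundled eleven-marker AF16/HK104 genotyping panel: nine AFLP indel
#' markers on four autosomes (none on chromosome I) plus three on the X,
#' the mitochondrial RFLP cb18178 and the X RFLP cb51757 at 12.0 Mbp.
#' Positions without a published anchor are editable placeholders (see the
#' comments in `inst/extdata/marker_panel.csv`).
#'
#' @param genome genome specification used to range-check positions.
#' @return data frame of class `marker_panel`.
#' @examples
#' p <- default_marker_panel()
#' p[p$chromosome == "X", ]
#' @export
default_marker_panel <- function(genome = default_genome_spec()) {
  read_marker_panel(pkg_extdata("marker_panel.csv"), genome)
}

nuclear_markers <- function(panel) panel[panel$chromosome != "MT", , drop = FALSE]

## Markers ordered by concatenated-genome coordinate (chromosome order as in
## the genome spec, MT last, position within chromosome).
order_markers <- function(panel, genome = default_genome_spec()) {
  chrom_rank <- match(panel$chromosome, c(genome$chromosome[genome$kind != "mitochondrial"], "MT"))
  panel[order(chrom_rank, panel$position), , drop = FALSE]
}

marker_row <- function(panel, name) {
  i <- match(name, panel$name)
  if (is.na(i)) stop_usage(sprintf("marker '%s' is not in the panel", name))
  as.list(panel[i, ])
}

## ---- individuals ----------------------------------------------------------

new_individual <- function(sex, autosomes, x, mitotype) {
  structure(list(sex = sex, autosomes = autosomes, x = x, mitotype = mitotype),
            class = "individual")
}

#' Create a homozygous founder individual
#'
#' Founders come from wild populations that propagate by selfing, so their
#' nuclear genomes are completely homozygous: every haplotype is a single
#' segment of the founder's own ancestry, and the mitotype equals the
#' population label.  Hermaphrodites carry two X copies; males are X0 and
#' carry one.
#'
#' @param population founder label, `"AF16"` or `"HK104"`.
#' @param sex `"hermaphrodite"` or `"male"`.
#' @param genome genome specification.
#' @return an `individual`.
#' @examples
#' founder("AF16", "hermaphrodite")
#' @export
founder <- function(population, sex = c("hermaphrodite", "male"),
                    genome = default_genome_spec()) {
  assert_pop(population)
  sex <- match.arg(sex)
  pure <- function(chrom) list(b = c(0, chrom_length(genome, chrom)), a = population)
  aut_names <- genome_autosomes(genome)
  autosomes <- lapply(aut_names, function(ch) {
    h <- pure(ch)
    list(h, h)
  })
  names(autosomes) <- aut_names
  xh <- pure(genome_x(genome))
  x <- if (sex == "hermaphrodite") list(xh, xh) else list(xh)
  new_individual(sex, autosomes, x, population)
}

#' Genotype an individual at a marker
#'
#' Reads the ancestry of each haplotype at the marker position and encodes
#' it as a two-letter call (`A` = AF16 allele, `H` = HK104 allele):
#' `"AA"`, `"HH"` or `"AH"`.  A mitochondrial marker reads the mitotype
#' (doubled, e.g. `"HH"` for an HK104 mitotype).  For an X marker in an X0
#' male the single hemizygous allele is doubled for table storage and the
#' result carries attribute `hemizygous = TRUE`.
#'
#' @param ind an `individual`.
#' @param marker one row of a marker panel (or a list with `name`,
#'   `chromosome`, `position`).
#' @return a call string, possibly with attribute `hemizygous`.
#' @export
genotype_at <- function(ind, marker) {
  marker <- as.list(marker)
  chrom <- marker$chromosome
  if (chrom == "MT") return(hom_call(ind$mitotype))
  haps <- if (is.null(ind$autosomes[[chrom]])) ind$x else ind$autosomes[[chrom]]
  if (is.null(haps) || length(haps) == 0L) {
    stop_validation(sprintf("individual carries no chromosome '%s'", chrom))
  }
  L <- hap_length(haps[[1L]])
  if (marker$position < 0 || marker$position >= L) {
    stop_usage(sprintf("marker '%s' position %s outside chromosome %s [0, %s)",
                       marker$name, marker$position, chrom, L))
  }
  anc <- vapply(haps, function(h) h$a[findInterval(marker$position, h$b)], "")
  if (length(anc) == 1L) {
    call <- hom_call(anc)
    attr(call, "hemizygous") <- TRUE
    return(call)
  }
  if (anc[1L] == anc[2L]) hom_call(anc[1L]) else "AH"
}

is_homozygous_genome <- function(ind) {
  for (pair in ind$autosomes) {
    if (!identical(pair[[1L]], pair[[2L]])) return(FALSE)
  }
  if (length(ind$x) == 2L && !identical(ind$x[[1L]], ind$x[[2L]])) return(FALSE)
  TRUE
}

#' @export
print.individual <- function(x, ...) {
  nseg <- sum(vapply(x$autosomes, function(p) length(p[[1]]$a) + length(p[[2]]$a), 0L)) +
    sum(vapply(x$x, function(h) length(h$a), 0L))
  cat(sprintf("<individual> %s, mitotype %s, %d X cop%s, %d ancestry segments\n",
              x$sex, x$mitotype, length(x$x), if (length(x$x) == 1) "y" else "ies", nseg))
  invisible(x)
}

## ---- genotype tables ------------------------------------------------------

#' Construct a genotype table
#'
#' A genotype table is the interchange object between the simulator, the
#' fixture generator and the statistics: one row per hybrid line with
#' metadata columns `line_id`, `design`, `male_pop`, `herm_pop`, `mitotype`
#' followed by one column per marker holding ancestry calls in
#' `AA`/`HH`/`AH`/`NA`.
#'
#' @param df data frame with the metadata columns followed by marker columns.
#' @return `df` validated, of class `genotype_table`.
#' @export
genotype_table <- function(df) {
  miss <- setdiff(TABLE_META_COLS, names(df))
  if (length(miss)) {
    stop_format(sprintf("genotype table is missing metadata column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  df <- df[c(TABLE_META_COLS, setdiff(names(df), TABLE_META_COLS))]
  for (col in c("design", "male_pop", "herm_pop", "mitotype")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$line_id <- as.character(df$line_id)
  bad_pop <- !df$male_pop %in% POPULATIONS | !df$herm_pop %in% POPULATIONS |
    !df$mitotype %in% POPULATIONS
  if (any(bad_pop)) {
    stop_format(sprintf("genotype table row %d: unknown population label",
                        which(bad_pop)[1L]))
  }
  for (m in table_markers(df)) {
    calls <- as.character(df[[m]])
    ok <- is.na(calls) | calls %in% CALL_TOKENS
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop_format(sprintf(
        "genotype table row %d, column '%s': invalid call token '%s' (expected AA/HH/AH/NA)",
        i, m, calls[i]))
    }
    df[[m]] <- calls
  }
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Marker column names of a genotype table
#' @param table a genotype table.
#' @return character vector of marker names.
#' @export
table_markers <- function(table) setdiff(names(table), TABLE_META_COLS)

## The single (male_pop, herm_pop) direction of a table; errors if mixed.
table_direction <- function(table) {
  dirs <- unique(table[, c("male_pop", "herm_pop")])
  if (nrow(dirs) != 1L) {
    stop_usage("genotype table mixes cross directions; split by direction first")
  }
  list(male_pop = dirs$male_pop[1L], herm_pop = dirs$herm_pop[1L])
}

#' Read / write genotype tables
#'
#' Plain-text CSV (or TSV, chosen by file extension) with a header row
#' naming the metadata columns and markers.  `write_genotype_table()` and
#' [read_genotype_table()] round-trip exactly.
#'
#' @param path file path; `.tsv`/`.txt` are tab-separated, anything else
#'   comma-separated.
#' @return a `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = "NA",
                      fill = FALSE, check.names = FALSE),
    error = function(e) stop_format(sprintf("cannot parse genotype table '%s': %s",
                                            path, conditionMessage(e)))
  )
  genotype_table(df)
}

#' @param table a `genotype_table`.
#' @rdname read_genotype_table
#' @export
write_genotype_table <- function(table, path) {
  table <- genotype_table(as.data.frame(table))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d lines x %d markers (%s)\n",
              nrow(x), length(table_markers(x)),
              paste(unique(paste0(x$male_pop, "x", x$herm_pop)), collapse = ", ")))
  NextMethod()
}
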