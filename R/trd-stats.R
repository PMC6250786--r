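## Transmission ratio distortion statistics: allele fractions, design-
## specific null expectations, chi-square tests with Bonferroni correction,
## drift probabilities, linkage disequilibrium and reciprocal-cross
## asymmetry.

## Focal-allele and total counts at a marker.  Each homozygous line
## contributes two alleles, each heterozygous line one of each; missing
## calls are excluded entirely.
allele_counts <- function(calls, focal_pop) {
  calls <- calls[!is.na(calls)]
  hom_focal <- sum(calls == hom_call(focal_pop))
  het <- sum(calls == "AH")
  list(focal = 2L * hom_focal + het,
       total = 2L * length(calls),
       n_informative = length(calls))
}

#' Allele-fraction (TRD) estimate at a marker
#'
#' Transmission ratio distortion is measured as the ratio of the number of
#' focal-population alleles to the total number of alleles scored across
#' replicate lines; for a diploid the total is twice the number of lines
#' (minus missing calls).  Heterozygous lines contribute one allele to each
#' count (set `drop_unfixed = TRUE` to exclude them instead).
#'
#' @param table a [genotype_table()] of lines from a single design and
#'   cross direction.
#' @param marker marker (column) name.
#' @param focal_pop population whose allele fraction is reported
#'   (default `"HK104"`).
#' @param drop_unfixed exclude heterozygous lines rather than counting one
#'   allele of each.
#' @return list of class `trd_result` with fields `marker`, `design`,
#'   `male_pop`, `herm_pop`, `n_lines`, `focal`, `total`, `trd`.
#' @examples
#' tab <- make_table(fixture_spec(9, counts = c(cb51757 = 4), seed = 1))
#' trd_fraction(tab, "cb51757")$trd  # 8/18
#' @export
trd_fraction <- function(table, marker, focal_pop = "HK104",
                         drop_unfixed = FALSE) {
  assert_pop(focal_pop, "focal population")
  if (!marker %in% table_markers(table)) {
    stop_usage(sprintf("marker '%s' is not genotyped in this table", marker))
  }
  if (length(unique(table$design)) != 1L) {
    stop_usage("genotype table mixes designs; split by design first")
  }
  dir <- table_direction(table)
  calls <- table[[marker]]
  if (drop_unfixed) calls[calls == "AH"] <- NA
  cnt <- allele_counts(calls, focal_pop)
  if (cnt$total == 0L) {
    stop_usage(sprintf("no informative lines at marker '%s'", marker))
  }
  structure(list(marker = marker, design = table$design[1L],
                 male_pop = dir$male_pop, herm_pop = dir$herm_pop,
                 n_lines = cnt$n_informative,
                 focal_pop = focal_pop,
                 focal = cnt$focal, total = cnt$total,
                 trd = cnt$focal / cnt$total),
            class = "trd_result")
}

#' Null allele-retention expectation for a marker
#'
#' Under neutrality half of the replicate-line alleles at an autosomal
#' marker come from each founder.  X-linked expectations depend on cross
#' direction, because hermaphrodites carry two X copies and males one:
#' the maternal X allele is expected at two-thirds and the paternal at
#' one-third.  Mitochondrial loci are uniparentally inherited and have no
#' null TRD test here.
#'
#' @param chromosome chromosome name of the marker.
#' @param male_pop,herm_pop cross direction (male and hermaphrodite founder).
#' @param focal_pop population whose expected fraction is returned.
#' @param genome genome specification (classifies the chromosome).
#' @return expected focal-allele fraction.
#' @examples
#' null_expectation("X", male_pop = "AF16", herm_pop = "HK104") # 2/3
#' null_expectation("III", male_pop = "AF16", herm_pop = "HK104") # 0.5
#' @export
null_expectation <- function(chromosome, male_pop, herm_pop,
                             focal_pop = "HK104",
                             genome = default_genome_spec()) {
  assert_pop(male_pop); assert_pop(herm_pop); assert_pop(focal_pop)
  if (male_pop == herm_pop) stop_usage("cross direction needs two distinct founders")
  if (!focal_pop %in% c(male_pop, herm_pop)) {
    stop_usage("focal population must be one of the two founders")
  }
  kind <- chrom_kind(genome, chromosome)
  switch(kind,
         mitochondrial = stop_usage(
           "mitochondrial loci are uniparentally inherited: no null TRD expectation"),
         autosome = 0.5,
         sex_chromosome = if (focal_pop == herm_pop) 2 / 3 else 1 / 3)
}

#' Pearson chi-square test of an allele fraction against its null
#'
#' One-degree-of-freedom Pearson goodness-of-fit test, no continuity
#' correction: the statistic is the sum of `(O - E)^2 / E` over the two
#' allele classes, with the p-value from the chi-square survival function.
#' When either expected count falls below 1 the result is flagged
#' `unreliable` rather than switched to an exact test, preserving
#' comparability across markers.
#'
#' @param focal_count observed focal-allele count.
#' @param total_count total alleles scored (positive).
#' @param expected_fraction null focal fraction, strictly inside `(0, 1)`.
#' @return list with `statistic`, `p`, `unreliable`.
#' @examples
#' chisq_trd(0, 40, 1/3)   # statistic 20
#' @export
chisq_trd <- function(focal_count, total_count, expected_fraction) {
  if (total_count <= 0) stop_usage("total allele count must be positive")
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop_usage("expected fraction must lie strictly between 0 and 1")
  }
  if (focal_count < 0 || focal_count > total_count) {
    stop_usage("focal count must lie between 0 and the total count")
  }
  e <- total_count * c(expected_fraction, 1 - expected_fraction)
  o <- c(focal_count, total_count - focal_count)
  stat <- sum((o - e)^2 / e)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       unreliable = any(e < 1))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in `(0, 1)`.
#' @param n_tests number of tests in the family (>= 1).
#' @return per-test p-value threshold `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 20)  # 0.0025
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_usage("alpha must lie strictly between 0 and 1")
  }
  if (n_tests < 1) stop_usage("n_tests must be at least 1")
  alpha / n_tests
}

#' Probability that drift alone fixes the same allele in every line
#'
#' All replicate lines share a genotype only at the fully heterozygous F1
#' generation, so absent selection each line independently fixes either
#' founder allele with equal probability; the chance that all `n_lines`
#' fix the same specified allele is `per_line_prob ^ n_lines`.
#'
#' @param n_lines number of replicate lines (>= 0).
#' @param per_line_prob per-line fixation probability of the specified
#'   allele (default 0.5).
#' @return the drift probability.
#' @examples
#' drift_probability(20)  # 9.5e-7
#' drift_probability(5)   # 3.1%
#' @export
drift_probability <- function(n_lines, per_line_prob = 0.5) {
  if (any(n_lines < 0) || any(n_lines != floor(n_lines))) {
    stop_usage("n_lines must be non-negative integers")
  }
  if (any(per_line_prob < 0 | per_line_prob > 1)) {
    stop_usage("per_line_prob must lie in [0, 1]")
  }
  per_line_prob^n_lines
}

## ---- linkage disequilibrium -----------------------------------------------

## 0/1 focal-allele indicator per line at a (fixed) locus; NA for
## heterozygous or missing calls.  `locus` may be a marker name or
## "MT"/"mitotype" for the mitochondrial haplotype.
line_allele_indicator <- function(table, locus, focal_pop) {
  if (locus %in% c("MT", "mitotype")) {
    return(as.integer(table$mitotype == focal_pop))
  }
  if (!locus %in% table_markers(table)) {
    stop_usage(sprintf("locus '%s' is not genotyped in this table", locus))
  }
  calls <- table[[locus]]
  out <- rep(NA_integer_, length(calls))
  out[!is.na(calls) & calls == hom_call(focal_pop)] <- 1L
  out[!is.na(calls) & calls == hom_call(other_pop(focal_pop))] <- 0L
  out
}

#' Linkage disequilibrium between two loci across lines
#'
#' Computes D, D' and r-squared from line-level fixed alleles: lines
#' heterozygous or missing at either locus are excluded (and counted in
#' `n_excluded`).  The mitotype may stand in for either locus
#' (`"MT"`), which is how inter-genomic (mito-nuclear) LD is measured.
#' A locus with no variation among the informative lines leaves LD
#' undefined (`monomorphic = TRUE`, statistics `NA`).
#'
#' @param table a [genotype_table()].
#' @param locus_a,locus_b marker names, or `"MT"` for the mitotype.
#' @param focal_pop population coded 1 in the allele indicators.
#' @return list of class `ld_result` with `D`, `D_prime`, `r2`, `complete`
#'   (r-squared within 1e-9 of 1), `monomorphic`, allele frequencies and
#'   line counts.
#' @export
ld_pair <- function(table, locus_a, locus_b, focal_pop = "HK104") {
  x <- line_allele_indicator(table, locus_a, focal_pop)
  y <- line_allele_indicator(table, locus_b, focal_pop)
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 2L) {
    stop_usage("fewer than two lines informative at both loci: LD undefined")
  }
  x <- x[keep]; y <- y[keep]
  pA <- mean(x); pB <- mean(y)
  pAB <- mean(x == 1L & y == 1L)
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  if (mono) {
    res <- list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                complete = FALSE, monomorphic = TRUE)
  } else {
    D <- pAB - pA * pB
    d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    res <- list(D = D, D_prime = if (d_max > 0) D / d_max else NA_real_,
                r2 = r2, complete = abs(r2 - 1) < 1e-9, monomorphic = FALSE)
  }
  structure(c(list(locus_a = locus_a, locus_b = locus_b, focal_pop = focal_pop,
                   n_lines = n, n_excluded = sum(!keep),
                   pA = pA, pB = pB, pAB = pAB),
              res),
            class = "ld_result")
}

## ---- reciprocal asymmetry -------------------------------------------------

#' Reciprocal-cross asymmetry of TRD at a marker
#'
#' Compares TRD between the two reciprocal cross directions with each
#' direction's fraction measured relative to its own maternal
#' (hermaphrodite-founder) allele, so that a mito-X pattern that tracks the
#' maternal side in both directions registers as symmetric (delta = 0).
#' Allele counts are compared across directions with a 2x2 Pearson
#' chi-square homogeneity test.
#'
#' @param table_dir1,table_dir2 genotype tables from the two reciprocal
#'   directions.
#' @param marker marker name genotyped in both tables.
#' @return list with `delta_trd` (maternal-relative difference,
#'   direction 1 minus direction 2), per-direction maternal fractions,
#'   `statistic` and `p`.
#' @export
reciprocal_asymmetry <- function(table_dir1, table_dir2, marker) {
  d1 <- table_direction(table_dir1)
  d2 <- table_direction(table_dir2)
  if (!(d1$male_pop == d2$herm_pop && d1$herm_pop == d2$male_pop)) {
    stop_usage("the two tables must come from reciprocal cross directions")
  }
  t1 <- trd_fraction(table_dir1, marker, focal_pop = d1$herm_pop)
  t2 <- trd_fraction(table_dir2, marker, focal_pop = d2$herm_pop)
  counts <- matrix(c(t1$focal, t1$total - t1$focal,
                     t2$focal, t2$total - t2$focal),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(direction = c(
                     paste0(d1$male_pop, "x", d1$herm_pop),
                     paste0(d2$male_pop, "x", d2$herm_pop)),
                     allele = c("maternal", "paternal")))
  if (any(colSums(counts) == 0L)) {
    ## both directions entirely maternal (or paternal): trivially homogeneous
    stat <- 0; p <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(marker = marker,
       delta_trd = t1$trd - t2$trd,
       maternal_trd_dir1 = t1$trd, maternal_trd_dir2 = t2$trd,
       counts = counts, statistic = stat, p = p,
       symmetric = abs(t1$trd - t2$trd) < sqrt(.Machine$double.eps))
}

## ---- report ---------------------------------------------------------------

#' Marker-by-marker TRD report across tables
#'
#' One row per (nuclear marker, table): observed focal-allele fraction,
#' design-specific null expectation, Pearson chi-square statistic and
#' p-value, and significance flags after Bonferroni correction
#' (`significant`) and at the nominal alpha (`significant_nominal`).
#' Markers are ordered by their coordinate after concatenating all
#' chromosome sequences.  `n_tests = "auto"` counts the rows of the report
#' (markers x directions), matching a correction family of "markers times
#' cross directions".
#'
#' @param tables a genotype table or list of genotype tables, each from a
#'   single design and direction.
#' @param panel marker panel supplying chromosome assignments.
#' @param alpha family-wise significance level.
#' @param n_tests `"auto"` or an explicit family size.
#' @param focal_pop population whose allele fraction is reported.
#' @param genome genome specification.
#' @return data frame of class `trd_report` with attribute `threshold`.
#' @export
trd_report <- function(tables, panel = default_marker_panel(), alpha = 0.05,
                       n_tests = "auto", focal_pop = "HK104",
                       genome = default_genome_spec()) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  if (length(tables) == 0L) stop_usage("at least one genotype table is required")
  panel <- order_markers(panel, genome)
  nuclear <- nuclear_markers(panel)
  rows <- list()
  for (tab in tables) {
    dir <- table_direction(tab)
    present <- nuclear[nuclear$name %in% table_markers(tab), , drop = FALSE]
    unknown <- setdiff(table_markers(tab),
                       c(panel$name))
    if (length(unknown)) {
      stop_usage(sprintf("marker '%s' in table is absent from the panel", unknown[1L]))
    }
    for (i in seq_len(nrow(present))) {
      m <- present[i, ]
      tr <- trd_fraction(tab, m$name, focal_pop)
      exp_frac <- null_expectation(m$chromosome, dir$male_pop, dir$herm_pop,
                                   focal_pop, genome)
      ct <- chisq_trd(tr$focal, tr$total, exp_frac)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m$name, chrom = m$chromosome, position = m$position,
        design = tr$design,
        direction = paste0(dir$male_pop, "x", dir$herm_pop),
        n_lines = tr$n_lines, focal_count = tr$focal, total = tr$total,
        trd = tr$trd, expected = exp_frac,
        chisq = ct$statistic, p = ct$p, unreliable = ct$unreliable,
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else data.frame(
    marker = character(), chrom = character(), position = numeric(),
    design = character(), direction = character(), n_lines = integer(),
    focal_count = integer(), total = integer(), trd = numeric(),
    expected = numeric(), chisq = numeric(), p = numeric(),
    unreliable = logical(), stringsAsFactors = FALSE)
  n_eff <- if (identical(n_tests, "auto")) max(nrow(rep_df), 1L) else n_tests
  thr <- bonferroni_threshold(alpha, n_eff)
  rep_df$significant <- rep_df$p < thr
  rep_df$significant_nominal <- rep_df$p < alpha
  attr(rep_df, "threshold") <- thr
  attr(rep_df, "alpha") <- alpha
  attr(rep_df, "n_tests") <- n_eff
  class(rep_df) <- c("trd_report", "data.frame")
  rep_df
}

#' @export
print.trd_report <- function(x, ...) {
  cat(sprintf("TRD report: %d tests, Bonferroni threshold p < %g (alpha %g)\n",
              attr(x, "n_tests"), attr(x, "threshold"), attr(x, "alpha")))
  y <- as.data.frame(x)
  y$trd <- sprintf("%.2f", round_half_up(y$trd, 2))
  y$expected <- sprintf("%.2f", round_half_up(y$expected, 2))
  print(y, ...)
  invisible(x)
}
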