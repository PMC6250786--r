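## Forward-in-time simulation of the two RIL breeding designs: meiosis with
## a single obligate crossover per bivalent, X0 sex determination, maternal
## mitochondrial inheritance, and viability selection under a configurable
## two-locus (mito-nuclear or nuclear-nuclear) incompatibility model.

#' Crossover model
#'
#' Strong crossover interference in *Caenorhabditis* makes a single
#' chiasma per bivalent the expectation, so the default places exactly one
#' breakpoint per bivalent at a uniformly drawn position.  A Poisson mode
#' (crossover count drawn per bivalent, positions uniform) is provided for
#' sensitivity analysis.
#'
#' @param mode `"obligate_single"` (default) or `"poisson"`.
#' @param rate expected crossovers per bivalent (Poisson mode only).
#' @return an object of class `crossover_model`.
#' @export
crossover_model <- function(mode = c("obligate_single", "poisson"), rate = 1) {
  mode <- match.arg(mode)
  if (mode == "poisson" && (!is.numeric(rate) || rate < 0)) {
    stop_validation("poisson crossover rate must be non-negative")
  }
  structure(list(mode = mode, rate = rate), class = "crossover_model")
}

## Integer breakpoints in (0, L); exactly one in the default mode.
draw_breakpoints <- function(cx, L) {
  if (cx$mode == "obligate_single") {
    1 + floor(runif(1) * (L - 1))
  } else {
    n <- rpois(1L, cx$rate)
    if (n == 0L) return(numeric())
    sort(sample.int(L - 1L, min(n, L - 1L)))
  }
}

## One meiotic product of a bivalent.  A homozygous pair is transmitted
## as-is (recombination between identical haplotypes is invisible).
meiose <- function(h1, h2, cx) {
  if (identical(h1, h2)) return(h1)
  if (cx$mode == "obligate_single") {
    L <- h1$b[length(h1$b)]
    x <- 1 + floor(runif(1) * (L - 1))
    if (runif(1) < 0.5) meiose_single(h1, h2, x) else meiose_single(h2, h1, x)
  } else {
    recombine_pair(h1, h2, draw_breakpoints(cx, hap_length(h1)),
                   runif(1) < 0.5)
  }
}

## Fast path for the obligate single crossover: hA contributes [0, x), hB
## contributes [x, L), with the junction merged when ancestries agree.
## Both inputs are canonical, so the junction is the only mergeable pair.
meiose_single <- function(hA, hB, x) {
  i <- sum(hA$b < x)
  nB <- length(hB$a)
  j <- sum(hB$b <= x)
  iA <- seq_len(i)
  if (hA$a[i] == hB$a[j]) {
    list(b = c(hA$b[iA], hB$b[(j + 1L):(nB + 1L)]),
         a = c(hA$a[iA], if (j < nB) hB$a[(j + 1L):nB]))
  } else {
    list(b = c(hA$b[iA], x, hB$b[(j + 1L):(nB + 1L)]),
         a = c(hA$a[iA], hB$a[j:nB]))
  }
}

#' Draw one gamete from a parent
#'
#' Every autosome recombines as a bivalent under the crossover model.  A
#' hermaphrodite's X pair recombines likewise, so her gametes always carry
#' an X; a male's single X cannot recombine and is transmitted intact in
#' half of his gametes (the other half are nullo-X and sire X0 sons).
#' Gametes carry no mitotype: mitochondria are inherited maternally at
#' fertilization.
#'
#' @param parent an `individual`.
#' @param crossover a [crossover_model()].
#' @return list with `autosomes` (list of 5 haplotypes) and `x` (a
#'   haplotype, or `NULL` for a nullo-X sperm).
#' @export
gamete <- function(parent, crossover = crossover_model()) {
  aut <- parent$autosomes
  g <- vector("list", length(aut))
  for (i in seq_along(aut)) {
    pair <- aut[[i]]
    g[[i]] <- meiose(pair[[1L]], pair[[2L]], crossover)
  }
  names(g) <- names(aut)
  gx <- if (parent$sex == "hermaphrodite") {
    meiose(parent$x[[1L]], parent$x[[2L]], crossover)
  } else if (runif(1) < 0.5) {
    parent$x[[1L]]
  } else {
    NULL
  }
  list(autosomes = g, x = gx)
}

## Fuse an egg and a sperm; sex is decided by whether the sperm carries an X.
zygote <- function(egg, sperm, mitotype) {
  aut <- vector("list", length(egg$autosomes))
  for (i in seq_along(aut)) {
    aut[[i]] <- list(egg$autosomes[[i]], sperm$autosomes[[i]])
  }
  names(aut) <- names(egg$autosomes)
  if (is.null(sperm$x)) {
    new_individual("male", aut, list(egg$x), mitotype)
  } else {
    new_individual("hermaphrodite", aut, list(egg$x, sperm$x), mitotype)
  }
}

#' Mate a male to a (pseudofemale) hermaphrodite
#'
#' Each offspring fuses two independent gametes.  All offspring inherit the
#' hermaphrodite's mitotype (maternal mitochondrial inheritance); offspring
#' receiving an X-bearing sperm are XX hermaphrodites, the rest X0 males.
#'
#' @param male,herm parent `individual`s with the stated sexes.
#' @param n_offspring brood size.
#' @param crossover a [crossover_model()].
#' @return list of offspring `individual`s.
#' @export
cross <- function(male, herm, n_offspring, crossover = crossover_model()) {
  if (male$sex != "male" || herm$sex != "hermaphrodite") {
    stop_usage("cross() requires a male and a hermaphrodite, in that order")
  }
  lapply(seq_len(n_offspring), function(i) {
    zygote(gamete(herm, crossover), gamete(male, crossover), herm$mitotype)
  })
}

#' Self-fertilize a hermaphrodite
#'
#' Both gametes are drawn independently from the same parent; all selfed
#' offspring are XX hermaphrodites (the rare X-nondisjunction males of real
#' *Caenorhabditis* broods are ignored) and keep the parental mitotype.
#'
#' @param herm a hermaphrodite `individual`.
#' @param n_offspring brood size.
#' @param crossover a [crossover_model()].
#' @return list of offspring `individual`s.
#' @export
self_fertilize <- function(herm, n_offspring, crossover = crossover_model()) {
  if (herm$sex != "hermaphrodite") {
    stop_usage("self_fertilize() requires a hermaphrodite")
  }
  lapply(seq_len(n_offspring), function(i) {
    zygote(gamete(herm, crossover), gamete(herm, crossover), herm$mitotype)
  })
}

## ---- incompatibility (DMI) model ------------------------------------------

#' Define a two-locus incompatibility term
#'
#' A Dobzhansky-Muller incompatibility term couples an allele at one locus
#' with an allele at another (either may be the mitochondrial genome) and
#' reduces fitness by `s` when both sides match.  Under the `recessive`
#' trigger a nuclear side matches only when the individual is homozygous
#' (or hemizygous, for the male X) for the allele; under `dominant`, any
#' copy suffices.  The mitochondrial side matches when the mitotype equals
#' the allele.
#'
#' @param chrom_a,chrom_b chromosome names (or `"MT"`; at most one side).
#' @param pos_a,pos_b base-pair positions (ignored for MT).
#' @param allele_a,allele_b founder-population labels.
#' @param s selection coefficient in `[0, 1]`; `s = 1` is lethal.
#' @param trigger `"recessive"` (default) or `"dominant"`.
#' @return an object of class `dmi_term`.
#' @export
dmi_term <- function(chrom_a, pos_a = NA, allele_a,
                     chrom_b, pos_b = NA, allele_b,
                     s, trigger = c("recessive", "dominant")) {
  trigger <- match.arg(trigger)
  assert_pop(allele_a, "allele")
  assert_pop(allele_b, "allele")
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    stop_validation("selection coefficient s must be a single number in [0, 1]")
  }
  if (chrom_a == "MT" && chrom_b == "MT") {
    stop_validation("at most one side of an incompatibility term may be mitochondrial")
  }
  for (side in list(list(chrom_a, pos_a), list(chrom_b, pos_b))) {
    if (side[[1]] != "MT" && (is.na(side[[2]]) || side[[2]] < 0)) {
      stop_validation("nuclear incompatibility loci need a non-negative position")
    }
  }
  structure(list(chrom_a = chrom_a, pos_a = pos_a, allele_a = allele_a,
                 chrom_b = chrom_b, pos_b = pos_b, allele_b = allele_b,
                 s = s, trigger = trigger),
            class = "dmi_term")
}

#' Compose incompatibility terms into a fitness model
#'
#' Terms combine multiplicatively: fitness is the product of `(1 - s)` over
#' all triggered terms, so it always lies in `[0, 1]`.  An empty model is
#' neutral.
#'
#' @param ... `dmi_term` objects.
#' @return an object of class `dmi_model`.
#' @export
dmi_model <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1L]]) &&
      !inherits(terms[[1L]], "dmi_term")) {
    terms <- terms[[1L]]
  }
  for (t in terms) {
    if (!inherits(t, "dmi_term")) stop_validation("dmi_model() accepts dmi_term objects")
  }
  structure(list(terms = terms), class = "dmi_model")
}

#' Lethal mito-X incompatibility shorthand
#'
#' Convenience constructor for the recessive incompatibility between a
#' nuclear X allele and the opposite population's mitotype.
#'
#' @param x_pos position of the X locus (default: the cb-m127 placement of
#'   the bundled panel).
#' @param x_allele X-linked allele participating in the incompatibility.
#' @param mito_allele mitotype participating in the incompatibility.
#' @param s selection coefficient (default lethal).
#' @return a `dmi_model` with a single term.
#' @export
dmi_mito_x <- function(x_pos = 16800000, x_allele = "AF16",
                       mito_allele = "HK104", s = 1) {
  dmi_model(dmi_term("X", x_pos, x_allele, "MT", NA, mito_allele, s = s,
                     trigger = "recessive"))
}

term_side_matches <- function(ind, chrom, pos, allele, trigger) {
  if (chrom == "MT") return(ind$mitotype == allele)
  haps <- if (is.null(ind$autosomes[[chrom]])) ind$x else ind$autosomes[[chrom]]
  if (is.null(haps) || length(haps) == 0L) {
    stop_validation(sprintf("incompatibility locus on unknown chromosome '%s'", chrom))
  }
  if (pos < 0 || pos >= hap_length(haps[[1L]])) {
    stop_validation(sprintf("incompatibility locus %s:%s outside chromosome", chrom, pos))
  }
  anc <- vapply(haps, function(h) h$a[findInterval(pos, h$b)], "")
  if (trigger == "recessive") all(anc == allele) else any(anc == allele)
}

#' Viability of an individual under an incompatibility model
#'
#' @param ind an `individual`.
#' @param dmi a [dmi_model()].
#' @return fitness in `[0, 1]`: the product of `(1 - s)` over triggered terms.
#' @export
viability <- function(ind, dmi) {
  w <- 1
  for (t in dmi$terms) {
    if (term_side_matches(ind, t$chrom_a, t$pos_a, t$allele_a, t$trigger) &&
        term_side_matches(ind, t$chrom_b, t$pos_b, t$allele_b, t$trigger)) {
      w <- w * (1 - t$s)
    }
  }
  w
}

## Bernoulli survival of each offspring with probability equal to fitness.
survivors <- function(offspring, dmi) {
  if (length(dmi$terms) == 0L) return(offspring)
  w <- vapply(offspring, viability, 0, dmi = dmi)
  keep <- runif(length(offspring)) < w
  offspring[keep]
}

## ---- cross designs --------------------------------------------------------

#' Describe a RIL breeding design
#'
#' The AI-RIL schedule follows the founder cross with seven generations of
#' sibling mating (three mated hermaphrodites per generation) and then ten
#' generations of single-hermaphrodite selfing; the F2 RIL schedule uses a
#' single founding sib-mated hermaphrodite, one additional sib-mating
#' generation (two rounds total) and the same ten selfing generations.
#' `cross_design()` exposes every knob; [ai_ril_design()] and
#' [f2_ril_design()] fill in the published defaults.
#'
#' @param male_pop,herm_pop founder populations of the P0 male and
#'   (pseudofemale) hermaphrodite; must differ.
#' @param design `"AI-RIL"` or `"F2RIL"`.
#' @param replicates number of replicate lines.
#' @param sib_mating_generations rounds of sibling mating after the founder
#'   cross.
#' @param selfing_generations rounds of single-hermaphrodite selfing.
#' @param hermaphrodites_per_generation mated hermaphrodites (each paired
#'   with a sibling male) founding each sib-mating generation.
#' @param brood_size offspring per mated (or selfing) hermaphrodite.
#' @param self_to_fixation keep selfing past the scheduled generations until
#'   the line is homozygous genome-wide.
#' @return an object of class `cross_design`.
#' @examples
#' ai_ril_design("AF16", "HK104", replicates = 19)
#' @export
cross_design <- function(male_pop, herm_pop, design = c("AI-RIL", "F2RIL"),
                         replicates = 20,
                         sib_mating_generations = NULL,
                         selfing_generations = 10,
                         hermaphrodites_per_generation = NULL,
                         brood_size = 10,
                         self_to_fixation = FALSE) {
  design <- match.arg(design)
  assert_pop(male_pop)
  assert_pop(herm_pop)
  if (male_pop == herm_pop) {
    stop_validation("male and hermaphrodite founders must come from different populations")
  }
  if (is.null(sib_mating_generations)) {
    sib_mating_generations <- if (design == "AI-RIL") 7L else 2L
  }
  if (is.null(hermaphrodites_per_generation)) {
    hermaphrodites_per_generation <- if (design == "AI-RIL") 3L else 1L
  }
  counts <- c(replicates = replicates,
              sib_mating_generations = sib_mating_generations,
              selfing_generations = selfing_generations,
              hermaphrodites_per_generation = hermaphrodites_per_generation,
              brood_size = brood_size)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts))) {
    stop_validation("design counts must all be positive integers")
  }
  structure(list(male_pop = male_pop, herm_pop = herm_pop, design = design,
                 replicates = as.integer(replicates),
                 sib_mating_generations = as.integer(sib_mating_generations),
                 selfing_generations = as.integer(selfing_generations),
                 hermaphrodites_per_generation = as.integer(hermaphrodites_per_generation),
                 brood_size = as.integer(brood_size),
                 self_to_fixation = isTRUE(self_to_fixation)),
            class = "cross_design")
}

#' @rdname cross_design
#' @param ... passed on to [cross_design()].
#' @export
ai_ril_design <- function(male_pop, herm_pop, ...) {
  cross_design(male_pop, herm_pop, design = "AI-RIL", ...)
}

#' @rdname cross_design
#' @export
f2_ril_design <- function(male_pop, herm_pop, ...) {
  cross_design(male_pop, herm_pop, design = "F2RIL", ...)
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf(
    "<cross_design> %s  %s male x %s hermaphrodite\n  %d replicates; %d sib-mating + %d selfing generations; %d herm/gen, brood %d%s\n",
    x$design, x$male_pop, x$herm_pop, x$replicates, x$sib_mating_generations,
    x$selfing_generations, x$hermaphrodites_per_generation, x$brood_size,
    if (x$self_to_fixation) "; self to fixation" else ""))
  invisible(x)
}

## ---- running a design -----------------------------------------------------

## One attempt at a replicate line.  Returns the final hermaphrodite, or
## NULL on extinction (viability selection leaving too few survivors of the
## needed sexes).  `extra` records selfing generations beyond the schedule
## used to reach genome-wide homozygosity under self_to_fixation.
simulate_replicate <- function(design, dmi, genome, cx) {
  male <- founder(design$male_pop, "male", genome)
  herm <- founder(design$herm_pop, "hermaphrodite", genome)
  pool <- survivors(cross(male, herm, design$brood_size, cx), dmi)
  n_h <- design$hermaphrodites_per_generation
  for (g in seq_len(design$sib_mating_generations)) {
    sexes <- vapply(pool, function(i) i$sex, "")
    herms <- which(sexes == "hermaphrodite")
    males <- which(sexes == "male")
    if (length(herms) < n_h || length(males) < n_h) return(NULL)
    moms <- herms[sample.int(length(herms), n_h)]
    dads <- males[sample.int(length(males), n_h)]
    pool <- survivors(
      unlist(lapply(seq_len(n_h), function(k) {
        cross(pool[[dads[k]]], pool[[moms[k]]], design$brood_size, cx)
      }), recursive = FALSE),
      dmi)
  }
  sexes <- vapply(pool, function(i) i$sex, "")
  herms <- which(sexes == "hermaphrodite")
  if (length(herms) == 0L) return(NULL)
  cur <- pool[[herms[sample.int(length(herms), 1L)]]]
  extra <- 0L
  g <- 0L
  max_extra <- 300L
  repeat {
    g <- g + 1L
    if (g > design$selfing_generations) {
      if (!design$self_to_fixation || is_homozygous_genome(cur)) break
      extra <- extra + 1L
      if (extra > max_extra) return(NULL)
    }
    brood <- survivors(self_fertilize(cur, design$brood_size, cx), dmi)
    if (length(brood) == 0L) return(NULL)
    cur <- brood[[sample.int(length(brood), 1L)]]
  }
  list(line = cur, extra_selfing = extra)
}

#' Run a breeding design and genotype the resulting lines
#'
#' Simulates `design$replicates` independent replicate lines: founder cross,
#' sibling-mating generations with viability sampling under the
#' incompatibility model, then single-hermaphrodite selfing, finishing with
#' the final hermaphrodite genotyped at the marker panel.  Replicates that
#' go extinct (selection leaving no viable parents of the required sexes)
#' are restarted on a fresh random substream and counted in the run log,
#' mirroring studies that report only completed lines.  The master seed
#' fully determines the output: replicate `r`, attempt `a` uses a substream
#' derived from `(seed, r, a)`, and the caller's RNG state is left intact.
#'
#' @param design a [cross_design()].
#' @param dmi a [dmi_model()] (default: neutral).
#' @param panel marker panel used to genotype the final lines.
#' @param genome genome specification.
#' @param crossover a [crossover_model()].
#' @param seed master integer seed.
#' @param max_restarts abort (with a diagnostic) once a single replicate has
#'   failed this many consecutive attempts, indicating the incompatibility
#'   model is effectively lethal for the design.
#' @return object of class `ril_run`: a list with `table` (the
#'   [genotype_table()] of final lines), `log` (per-replicate data frame of
#'   restarts and extra selfing generations) and the call parameters.
#' @examples
#' \donttest{
#' run <- run_design(ai_ril_design("AF16", "HK104", replicates = 5), seed = 1)
#' run$table
#' }
#' @export
run_design <- function(design, dmi = dmi_model(), panel = default_marker_panel(),
                       genome = default_genome_spec(),
                       crossover = crossover_model(), seed = 1L,
                       max_restarts = 100L) {
  if (!inherits(design, "cross_design")) stop_usage("design must be a cross_design")
  if (!inherits(dmi, "dmi_model")) stop_usage("dmi must be a dmi_model")
  ## validate DMI loci against the genome up front
  for (t in dmi$terms) {
    for (side in list(c(t$chrom_a, t$pos_a), c(t$chrom_b, t$pos_b))) {
      if (side[1] != "MT") {
        L <- chrom_length(genome, side[1])
        if (as.numeric(side[2]) >= L) {
          stop_validation(sprintf("incompatibility locus %s:%s outside chromosome",
                                  side[1], side[2]))
        }
      }
    }
  }
  rows <- vector("list", design$replicates)
  log_rows <- vector("list", design$replicates)
  dir_tag <- paste0(design$male_pop, "x", design$herm_pop)
  for (r in seq_len(design$replicates)) {
    attempt <- 0L
    res <- NULL
    while (is.null(res)) {
      attempt <- attempt + 1L
      if (attempt > max_restarts) {
        stop_runtime(sprintf(
          "replicate %d went extinct %d times in a row: the incompatibility model is effectively lethal for this design",
          r, max_restarts))
      }
      res <- with_seed(mix_seed(seed, r, attempt),
                       simulate_replicate(design, dmi, genome, crossover))
    }
    calls <- vapply(seq_len(nrow(panel)), function(i) {
      as.character(genotype_at(res$line, panel[i, ]))
    }, "")
    row <- c(list(line_id = sprintf("%s_%s_L%02d", design$design, dir_tag, r),
                  design = design$design,
                  male_pop = design$male_pop,
                  herm_pop = design$herm_pop,
                  mitotype = res$line$mitotype),
             stats::setNames(as.list(calls), panel$name))
    rows[[r]] <- as.data.frame(row, check.names = FALSE,
                               stringsAsFactors = FALSE)
    log_rows[[r]] <- data.frame(replicate = r, restarts = attempt - 1L,
                                extra_selfing = res$extra_selfing,
                                final_generation = design$sib_mating_generations +
                                  design$selfing_generations + res$extra_selfing + 1L)
  }
  structure(list(table = genotype_table(do.call(rbind, rows)),
                 log = do.call(rbind, log_rows),
                 design = design, dmi = dmi, seed = as.integer(seed)),
            class = "ril_run")
}

#' @export
print.ril_run <- function(x, ...) {
  cat(sprintf("<ril_run> %s %sx%s, %d lines (%d restarts), seed %d\n",
              x$design$design, x$design$male_pop, x$design$herm_pop,
              nrow(x$table), sum(x$log$restarts), x$seed))
  invisible(x)
}
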