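---
title: "Simulating RIL breeding designs and testing transmission ratio distortion"
author: "rilTRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating RIL breeding designs and testing transmission ratio distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two diverged populations of a selfing nematode such as *Caenorhabditis
briggsae* are hybridized and bred into recombinant inbred lines (RIL),
selection during line production eliminates allele combinations that reduce
fitness — in particular Dobzhansky–Muller incompatibilities (DMIs) between
the maternally inherited mitochondrial genome and nuclear loci.  Surviving
lines therefore over-retain co-adapted alleles, which is detectable as
transmission ratio distortion (TRD): a marker's allele fraction across
replicate lines deviating from its neutral expectation.

rilTRD provides both halves of this analysis:

* a forward-in-time simulator of the two breeding designs (advanced-intercross
  AI-RIL and F2 RIL) in a hermaphrodite/X0-male species, with maternal
  mitochondrial inheritance and configurable two-locus incompatibility
  selection, and
* the statistics used on genotyped lines: allele fractions against
  design-specific nulls, chi-square tests with Bonferroni correction, drift
  fixation probabilities, linkage disequilibrium (including mitotype–nuclear
  pairs) and reciprocal-cross asymmetry.

## The genome and meiosis model

A genome is five autosomes (I–V), one X and a mitochondrial genome, with
approximate *C. briggsae* lengths bundled as an editable CSV.  A haplotype
is an ordered list of ancestry segments (founder labels AF16/HK104) in
0-based half-open base-pair coordinates, kept in canonical form: contiguous,
fully tiling `[0, length)`, no zero-width segments, adjacent segments of
different ancestry.  Only ancestry is tracked — sequence-level variation is
out of scope.

Meiosis places **exactly one obligate crossover per bivalent** at a uniform
integer position.  This reflects the strong crossover interference of
*Caenorhabditis* chromosomes, where a single chiasma per bivalent is the
expectation; a Poisson-count mode is available for sensitivity analysis
(`crossover_model("poisson", rate = )`).  A male's single X has no pairing
partner: it is transmitted intact in half of his sperm, and nullo-X sperm
sire X0 males.  Hermaphrodite self-sperm always carry an X, so selfed broods
are entirely hermaphrodite; the ~0.1% X-nondisjunction males of real broods
are ignored as negligible at simulated scales.

Mitotype is a single maternal label per individual.  Heteroplasmy is
unrepresentable by construction, matching the empirical observation that
hybrid-line mitotypes are uniformly maternal.

## Breeding designs

```{r}
library(rilTRD)
ai <- ai_ril_design("AF16", "HK104", replicates = 19)
f2 <- f2_ril_design("HK104", "AF16", replicates = 12)
```

Defaults (all overridable through `cross_design()`):

| parameter | AI-RIL | F2 RIL | rationale |
|---|---|---|---|
| sib-mating generations | 7 | 2 | seven generations of sibling mating (F1–F7) vs. one founding sib-mated hermaphrodite plus one additional generation |
| mated hermaphrodites per generation | 3 | 1 | three sibling-mated hermaphrodites found each AI-RIL generation; one for F2 RIL |
| selfing generations | 10 | 10 | ten generations of single-hermaphrodite selfing, halving heterozygosity each generation to ~0.1% |
| brood size | 10 | 10 | true brood sizes and within-plate competition are unreported; 10 keeps sex sampling and viability selection meaningful without inflating run time |

Each sib-mating round pools the broods of the current mated hermaphrodites,
applies viability selection, then samples the next generation's
hermaphrodites and an equal number of sibling males uniformly from the
survivors.  The selfing phase descends through a single hermaphrodite per
generation.  With `self_to_fixation = TRUE` selfing continues past the
schedule until the genome is homozygous everywhere (rarely more than a
couple of extra generations after ten rounds).

Replicates that go extinct — selection leaving no viable parents of the
required sexes — are **restarted on a fresh random substream** and counted
in the run log, mirroring studies that report only completed lines; the log
makes any conditioning bias measurable.  A replicate failing 100 consecutive
attempts aborts the run with a diagnostic, since the incompatibility model
is then effectively lethal for the design.  Reproducibility contract: one
master seed; replicate `r`, attempt `a` uses a substream mixed from
`(seed, r, a)` with a Lehmer-style generator, so runs are bit-identical per
seed and replicates are individually reproducible.

## Incompatibility selection

A `dmi_term()` couples an allele at one locus with an allele at another
(either side may be the mitochondrial genome) and multiplies fitness by
`1 - s` when both sides match.  The `recessive` trigger requires
homozygosity — or hemizygosity on the male X — at a nuclear side; `dominant`
fires on any copy.  Selection acts as viability: each offspring survives a
Bernoulli draw with probability equal to its fitness, before parents of the
next generation are sampled.  The underlying biology (developmental-delay
competition, fecundity loss, embryonic lethality) is not quantified in the
source data, so `s` is a free model parameter; `s = 1` with
`dmi_mito_x()` reproduces the absolute mito-X distortion pattern:

```{r}
run <- run_design(
  ai_ril_design("AF16", "HK104", replicates = 19, self_to_fixation = TRUE),
  dmi = dmi_mito_x(x_pos = 16800000, x_allele = "AF16", mito_allele = "HK104"),
  seed = 1)
trd_fraction(run$table, "cb-m127")$trd  # 1: every line fixed HK104 on the X
```

## Null expectations and the statistics

TRD at a marker is the fraction of focal-population alleles among all
alleles scored: two per homozygous line, one per heterozygous line, missing
calls excluded.  Null expectations: autosomes 0.5; the X depends on cross
direction because hermaphrodites carry two X copies and males one — at line
founding the maternal X allele is at frequency 2/3 and the paternal at 1/3,
and under neutrality the fixation probability equals that initial frequency.
Mitochondrial loci are uniparentally inherited and have no TRD test.
(A fine point: the reproductive-value-weighted X frequency is the conserved
quantity, while the frequency *within hermaphrodites* oscillates as
`p_f' = (p_f + p_m)/2`, `p_m' = p_f` from `(1/2, 1)`; because lines descend
from a single selfed hermaphrodite after seven sib-mating rounds, the exact
design expectation is 171/256 ≈ 0.668, imperceptibly above 2/3 at realistic
replicate counts.  The 2/3 null is used throughout, as published.)

Observed fractions are tested with a Pearson chi-square (df = 1, no
continuity correction) against the null, Bonferroni-corrected: with ten
markers and two cross directions the family is twenty tests and
`bonferroni_threshold(0.05, 20)` gives the per-test threshold 0.0025.
Expected counts below 1 flag the result `unreliable` rather than switching
to an exact test, preserving comparability across markers.
`drift_probability(n)` gives the chance that drift alone fixes the same
allele in all `n` lines (`0.5^20 ≈ 9.5e-7`; `0.5^5 ≈ 3.1%`), the argument
separating selection from drift.  Linkage disequilibrium (`ld_pair()`) is
computed on line-level fixed alleles — heterozygous/missing lines excluded —
with the mitotype usable as a locus, so inter-genomic mito-X LD is measured
the same way as nuclear-nuclear LD.

```{r}
suite <- study_fixture_suite()
report <- trd_report(suite, n_tests = 20)
exp1 <- genotype_table(rbind(as.data.frame(suite$ai_ril_hk104_mito),
                             as.data.frame(suite$ai_ril_af16_mito)))
ld_pair(exp1, "MT", "cb-m127")  # complete mito-X LD across directions
```

### A calibration note on counting units

For fully inbred lines the two alleles a line contributes are identical, so
the allele-based chi-square statistic is exactly twice the statistic
computed on line counts.  Under pure line-level drift its type-I error at
alpha = 0.05 and n = 19 lines is therefore not 0.05 but 0.158 — computable
exactly by enumerating Binomial line-fixation counts — while the same test
on line counts sits near nominal (0.057, the residual being chi-square
discreteness).  The package implements the allele-based convention because
it is the published definition, and the test suite verifies the simulated
pipeline against both enumerated rates.  Users comparing borderline p-values
to the threshold should be aware the allele-based test is anticonservative;
the absolute distortions the design targets (fractions 0 or 1 across 19–20
lines) are unaffected by the distinction.

### Reciprocal asymmetry

`reciprocal_asymmetry()` measures each direction's TRD relative to its own
maternal allele, so a mito-X pattern that tracks the maternal side in both
directions (HK104 fractions 1.00 and 0.00) registers as symmetric
(delta = 0); the allele counts are additionally compared across directions
with a 2×2 Pearson homogeneity test.  Degenerate tables in which both
directions are entirely maternal are reported as trivially homogeneous
(statistic 0, p = 1) rather than NaN.

## The synthetic-data generator

`make_table()` builds exact-count fixture tables: requested focal-line
counts are met exactly, line assignment is randomized by seed, coupled
marker sets co-segregate line-for-line, and every line's mitotype is the
maternal population.  `study_fixture_suite()` reproduces the structure of
the study's four line sets — replicate counts 19/20/9/12, X fractions
1.00/0.00/0.44/0.08, chromosome III co-fixing with the absolute-bias X
markers.  Two values in that suite are documented assumptions, not
published numbers: autosomal markers in the HK104-mitotype AI-RIL table are
fixed for HK104 in 15 of 19 lines (~80%, standing in for a bias reported
only graphically), and the third X marker is set to 17 of 19 (significant
but not absolute).  `neutral_fixture()` draws per-line fixation directly
from the null Bernoulli parameters (0.5 autosomal, 2/3 maternal-X) for
calibration work.

What the generators do **not** emulate: linkage between markers on the same
chromosome (fixture markers are independent unless explicitly coupled),
residual heterozygosity, genotyping error or missingness, and any selection
acting during line production.  Passing fixture-based tests therefore
validates the statistics' arithmetic, not the simulator; simulator-based
tests cover the population genetics.

## Numerical choices

* Coordinates are 0-based half-open base pairs throughout; crossover
  breakpoints are integers in `(0, L)`, so zero-width segments cannot arise
  from meiosis.
* Haplotype normalization (zero-width removal, merging equal-ancestry
  neighbours) runs on every constructed haplotype; the single-crossover
  splice needs only a junction merge because its inputs are canonical.
* "Complete LD" is `|r² - 1| < 1e-9`; a locus monomorphic among informative
  lines leaves LD undefined (`NA`, flagged) rather than 0/0.
* Human-readable fractions round half away from zero to two decimals
  (`round_half_up()`); machine outputs keep full precision.
* Chi-square p-values come from `stats::pchisq`; the suite cross-checks
  statistics and p-values against `stats::chisq.test` over all small-count
  instances.

## Problem sizes used by the checks

The simulation-based checks use 2,000 replicates per direction for neutral
null recovery (Monte Carlo standard error ≈ 0.01 on a fraction, tested at
±0.02 with marker averaging), 19–20 replicates for the lethal mito-X runs
(matching the study's line counts), 6,000 selfing lineages for the
heterozygosity-decay law `(1/2)^g` through generation 10, and 600 neutral
fixture datasets for type-I calibration.  These sizes put every stochastic
check at three Monte Carlo standard errors or better while keeping the
whole suite in the minutes range on a single core.

## Known limitations

* Selection is viability-only; fecundity or gametic selection models are
  not implemented.
* Temperature-dependent effects are not modeled.
* Brood size and within-plate competition intensity are simplifications;
  absolute extinction/restart rates should not be over-interpreted, though
  the run log exposes them.
* The obligate-single crossover model ignores the small fraction of
  bivalents with zero or multiple chiasmata; the Poisson mode brackets the
  consequences.
* Marker positions without a published anchor are placeholders in the
  bundled panel file; statistics depending only on marker identity and
  chromosome assignment are unaffected, but within-chromosome LD decay in
  simulated tables depends on those placements.
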