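test_that("trd_fraction reproduces worked allele fractions", {
  nine <- make_table(fixture_spec(9, counts = c(cb51757 = 4L), seed = 1))
  r9 <- trd_fraction(nine, "cb51757")
  expect_equal(r9$focal, 8L)
  expect_equal(r9$total, 18L)
  expect_equal(round_half_up(r9$trd, 2), 0.44)
  twelve <- make_table(fixture_spec(12, male_pop = "HK104", herm_pop = "AF16",
                                    counts = c(cb51757 = 1L), seed = 1))
  expect_equal(round_half_up(trd_fraction(twelve, "cb51757")$trd, 2), 0.08)
  twenty <- make_table(fixture_spec(20, design = "AI-RIL", male_pop = "HK104",
                                    herm_pop = "AF16",
                                    counts = c("cb-m127" = 0L), seed = 1))
  expect_equal(trd_fraction(twenty, "cb-m127")$trd, 0)
  ## heterozygous lines contribute one allele of each
  expect_equal(trd_fraction(all_het_table(6), "cb51757")$trd, 0.5)
  ## dropping unfixed lines can leave nothing informative
  expect_error(trd_fraction(all_het_table(6), "cb51757", drop_unfixed = TRUE),
               class = "rilTRD_usage_error")
})

test_that("focal and mirror fractions sum to one at every marker", {
  suite <- study_fixture_suite(seed = 2)
  for (tab in suite) {
    for (m in setdiff(table_markers(tab), "cb18178")) {
      expect_equal(trd_fraction(tab, m, "HK104")$trd +
                     trd_fraction(tab, m, "AF16")$trd, 1)
    }
  }
})

test_that("null expectations follow chromosome kind and cross direction", {
  expect_equal(null_expectation("X", "HK104", "AF16", focal_pop = "HK104"), 1 / 3)
  expect_equal(null_expectation("X", "AF16", "HK104", focal_pop = "HK104"), 2 / 3)
  expect_equal(null_expectation("III", "AF16", "HK104", focal_pop = "HK104"), 0.5)
  expect_equal(null_expectation("III", "HK104", "AF16", focal_pop = "HK104"), 0.5)
  expect_error(null_expectation("MT", "AF16", "HK104"), class = "rilTRD_usage_error")
})

test_that("chisq_trd matches the closed form and the stats oracle", {
  r <- chisq_trd(0, 40, 1 / 3)
  expect_equal(r$statistic, 20)
  expect_equal(r$p, 7.744216e-06, tolerance = 1e-6)
  r0 <- chisq_trd(20, 40, 0.5)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r19 <- chisq_trd(38, 38, 2 / 3)
  expect_equal(r19$statistic, 19)
  expect_equal(r19$p, stats::pchisq(19, 1, lower.tail = FALSE))
  ## grid agreement with the independent chisq.test implementation
  for (total in c(6L, 20L, 40L, 60L)) {
    for (e in c(1 / 3, 0.5, 2 / 3)) {
      for (focal in 0:total) {
        got <- chisq_trd(focal, total, e)
        want <- suppressWarnings(
          stats::chisq.test(c(focal, total - focal), p = c(e, 1 - e),
                            correct = FALSE))
        expect_equal(got$statistic, unname(want$statistic))
        expect_equal(got$p, want$p.value)
      }
    }
  }
  ## chi-square and binomial-exact p-values order identically along one tail
  total <- 40L; e <- 1 / 3
  upper <- ceiling(total * e):total
  p_chi <- vapply(upper, function(f) chisq_trd(f, total, e)$p, 0)
  p_bin <- vapply(upper, function(f) stats::binom.test(f, total, e)$p.value, 0)
  expect_identical(order(p_chi), order(p_bin))
  ## unreliable flag when an expected count drops below one
  expect_true(chisq_trd(0, 2, 1 / 3)$unreliable)
  expect_false(chisq_trd(0, 40, 1 / 3)$unreliable)
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0.001, 0.2)
    n <- sample(1:50, 1)
    expect_equal(bonferroni_threshold(a, n) * n, a)
  }
  ## significance count is monotone non-increasing in the family size
  suite <- study_fixture_suite(seed = 4)
  tabs <- list(suite$ai_ril_hk104_mito, suite$ai_ril_af16_mito)
  n_sig <- vapply(c(1, 5, 20, 100, 1000),
                  function(n) sum(trd_report(tabs, n_tests = n)$significant), 0)
  expect_true(all(diff(n_sig) <= 0))
})

test_that("drift probabilities match the closed form", {
  expect_equal(signif(drift_probability(20), 2), 9.5e-07)
  expect_equal(drift_probability(5), 0.03125)
  expect_equal(signif(100 * drift_probability(5), 2), 3.1)
  expect_equal(drift_probability(0), 1)
  set.seed(42)
  for (i in 1:10) {
    p <- runif(1, 0.05, 0.95)
    probs <- drift_probability(0:25, p) # vectorized over n via ^
    expect_true(all(diff(probs) < 0))
  }
})

test_that("ld_pair measures complete mito-X disequilibrium and independence", {
  suite <- study_fixture_suite(seed = 5)
  exp1 <- genotype_table(rbind(as.data.frame(suite$ai_ril_hk104_mito),
                               as.data.frame(suite$ai_ril_af16_mito)))
  mito_x <- ld_pair(exp1, "MT", "cb-m127")
  expect_true(mito_x$complete)
  expect_equal(mito_x$r2, 1)
  expect_gt(mito_x$D, 0)
  expect_equal(mito_x$D_prime, 1)
  ## independent loci in a large table show essentially no LD
  set.seed(43)
  n <- 4000
  df <- data.frame(line_id = sprintf("L%04d", 1:n), design = "AI-RIL",
                   male_pop = "AF16", herm_pop = "HK104", mitotype = "HK104",
                   m1 = sample(c("AA", "HH"), n, replace = TRUE),
                   m2 = sample(c("AA", "HH"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  ## m1/m2 stand in for unlinked markers; register them via genotype_table
  tab <- genotype_table(df)
  expect_lt(ld_pair(tab, "m1", "m2")$r2, 0.005)
})

test_that("ld_pair reproduces a hand-enumerated four-line table", {
  ## lines: {AB, AB, ab, aB} with A/B the focal alleles at the two loci
  df <- data.frame(line_id = paste0("L", 1:4), design = "F2RIL",
                   male_pop = "AF16", herm_pop = "HK104", mitotype = "HK104",
                   mA = c("HH", "HH", "AA", "AA"),
                   mB = c("HH", "HH", "AA", "HH"),
                   stringsAsFactors = FALSE)
  r <- ld_pair(genotype_table(df), "mA", "mB")
  expect_equal(r$pA, 0.5)
  expect_equal(r$pB, 0.75)
  expect_equal(r$D, 0.125)
  expect_equal(r$r2, 1 / 3)
  expect_false(r$complete)
})

test_that("ld_pair r-squared equals the squared correlation of line indicators", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- sample(c(0, 1), n, replace = TRUE)
    y <- ifelse(runif(n) < 0.7, x, sample(c(0, 1), n, replace = TRUE))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    df <- data.frame(line_id = paste0("L", 1:n), design = "F2RIL",
                     male_pop = "AF16", herm_pop = "HK104", mitotype = "HK104",
                     mA = ifelse(x == 1, "HH", "AA"),
                     mB = ifelse(y == 1, "HH", "AA"),
                     stringsAsFactors = FALSE)
    r <- ld_pair(genotype_table(df), "mA", "mB")
    expect_equal(r$r2, stats::cor(x, y)^2)
  }
})

test_that("ld_pair flags monomorphic loci and refuses tiny inputs", {
  mono <- make_table(fixture_spec(10, design = "AI-RIL",
                                  counts = c("cb-m127" = 10L, "cb-m26" = 5L),
                                  seed = 6))
  r <- ld_pair(mono, "cb-m127", "cb-m26")
  expect_true(r$monomorphic)
  expect_true(is.na(r$r2))
  expect_false(r$complete)
  one <- make_table(fixture_spec(1, counts = c(cb51757 = 1L), seed = 1))
  expect_error(ld_pair(one, "cb51757", "MT"), class = "rilTRD_usage_error")
  ## heterozygous/missing lines are excluded and reported
  het <- as.data.frame(make_table(fixture_spec(10, counts = c(cb51757 = 5L),
                                               seed = 7)))
  het$cb51757[1] <- "AH"
  r2 <- ld_pair(genotype_table(het), "cb51757", "MT")
  expect_equal(r2$n_excluded, 1L)
  expect_equal(r2$n_lines, 9L)
})

test_that("reciprocal asymmetry is measured maternal-relative", {
  suite <- study_fixture_suite(seed = 8)
  ## absolute maternal bias in both directions registers as symmetric
  ra <- reciprocal_asymmetry(suite$ai_ril_hk104_mito, suite$ai_ril_af16_mito,
                             "cb-m127")
  expect_equal(ra$delta_trd, 0)
  expect_true(ra$symmetric)
  expect_equal(ra$p, 1)
  expect_equal(ra$maternal_trd_dir1, 1)
  expect_equal(ra$maternal_trd_dir2, 1)
  ## a genuinely one-sided bias is flagged by the 2x2 homogeneity test
  biased <- make_table(fixture_spec(20, design = "AI-RIL", male_pop = "AF16",
                                    herm_pop = "HK104",
                                    counts = c("cb-m127" = 19L), seed = 9))
  null_t <- make_table(fixture_spec(20, design = "AI-RIL", male_pop = "HK104",
                                    herm_pop = "AF16",
                                    counts = c("cb-m127" = 10L), seed = 10))
  ra2 <- reciprocal_asymmetry(biased, null_t, "cb-m127")
  ## maternal fractions: 38/40 vs 20/40
  expect_equal(ra2$maternal_trd_dir1, 38 / 40)
  expect_equal(ra2$maternal_trd_dir2, 20 / 40)
  expect_equal(ra2$delta_trd, 18 / 40)
  ## hand-computed 2x2 Pearson statistic on the same counts
  o <- matrix(c(38, 2, 20, 20), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(ra2$statistic, sum((o - e)^2 / e))
  expect_lt(ra2$p, 0.0025)
  expect_error(reciprocal_asymmetry(biased, biased, "cb-m127"),
               class = "rilTRD_usage_error")
})

test_that("trd_report orders markers genomically and reproduces table fractions", {
  suite <- study_fixture_suite(seed = 12)
  rep_all <- trd_report(suite, n_tests = 20)
  expect_equal(attr(rep_all, "threshold"), 0.0025)
  ai1 <- rep_all[rep_all$direction == "AF16xHK104" & rep_all$design == "AI-RIL", ]
  expect_equal(ai1$trd[ai1$marker == "cb-m127"], 1)
  ai2 <- rep_all[rep_all$direction == "HK104xAF16" & rep_all$design == "AI-RIL", ]
  expect_equal(ai2$trd[ai2$marker == "cb-m127"], 0)
  f2 <- rep_all[rep_all$design == "F2RIL", ]
  expect_equal(round_half_up(sort(f2$trd), 2), c(0.08, 0.44))
  ## within a table block, markers run in concatenated-genome order
  panel <- default_marker_panel()
  want <- panel$name[order(match(panel$chromosome, c("I","II","III","IV","V","X")),
                           panel$position)]
  want <- want[want %in% ai1$marker]
  expect_equal(ai1$marker, want)
  ## the absolute X rows are Bonferroni-significant, the F2 0.44 row is not
  expect_true(all(rep_all$significant[rep_all$marker == "cb-m127" &
                                        rep_all$design == "AI-RIL"]))
  expect_false(rep_all$significant[rep_all$marker == "cb51757" &
                                     rep_all$direction == "AF16xHK104"])
  ## the 0.08 row: nominally significant, not after Bonferroni
  row008 <- rep_all[rep_all$marker == "cb51757" &
                      rep_all$direction == "HK104xAF16", ]
  expect_true(row008$significant_nominal)
  expect_false(row008$significant)
})

test_that("trd_report handles neutral tables and empty marker sets", {
  neutral <- lapply(1:2, function(i) {
    neutral_fixture(19, seed = 100 + i,
                    male_pop = c("AF16", "HK104")[i],
                    herm_pop = c("HK104", "AF16")[i])
  })
  rep_n <- trd_report(neutral, n_tests = "auto")
  expect_equal(attr(rep_n, "n_tests"), 20L)
  expect_false(any(rep_n$significant))
  ## a table with no nuclear marker columns yields an empty report
  df <- as.data.frame(neutral[[1]])[, c(rilTRD:::TABLE_META_COLS, "cb18178")]
  empty <- trd_report(genotype_table(df))
  expect_equal(nrow(empty), 0L)
})
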