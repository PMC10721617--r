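test_that("Wilson interval contains the point estimate and stays in [0, 1]", {
  for (n in c(1, 2, 5, 17, 50, 200)) {
    for (k in unique(round(seq(0, n, length.out = 7)))) {
      ci <- wilson_interval(k, n)
      expect_gte(ci[["low"]], 0)
      expect_lte(ci[["high"]], 1)
      expect_lte(ci[["low"]], k / n + 1e-12)
      expect_gte(ci[["high"]], k / n - 1e-12)
    }
  }
  expect_equal(wilson_interval(10, 10)[["high"]], 1)
  expect_error(wilson_interval(5, 0), "positive")
  expect_error(wilson_interval(7, 5), "\\[0, n\\]")
})

test_that("exact McNemar matches the binomial form and is symmetric", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(2, 2), 1)
  # exhaustive symmetry and validity over a grid
  for (b in 0:12) {
    for (cc in 0:12) {
      p <- mcnemar_exact(b, cc)
      expect_equal(p, mcnemar_exact(cc, b))
      expect_gte(p, 0)
      expect_lte(p, 1)
      # oracle: direct two-sided binomial tail
      expect_equal(p, min(1, 2 * pbinom(min(b, cc), b + cc, 0.5)))
    }
  }
  expect_lt(mcnemar_exact(30, 2), 1e-4)
})

test_that("Cohen's kappa reproduces hand-computed values and invariances", {
  # collapsed device-by-HRA table of the printed fixture
  collapsed <- matrix(c(41, 4, 32, 27), 2, 2)
  expect_equal(round(cohens_kappa(collapsed), 2), 0.34)
  expect_equal(cohens_kappa(diag(c(10, 5))), 1)
  expect_equal(cohens_kappa(matrix(1, 2, 2)), 0)
  # rater swap = transpose invariance
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(4, 10) + 1, 2, 2)
    expect_equal(cohens_kappa(m), cohens_kappa(t(m)))
  }
  expect_error(cohens_kappa(matrix(0, 2, 2)), "positive")
})

test_that("ROC AUC equals the exhaustive Mann-Whitney count", {
  # perfectly separated and all-tied edge cases
  expect_equal(roc_analysis(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(rep(0.5, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)

  mann_whitney <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    s <- 0
    for (p in pos) for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
    s / (length(pos) * length(neg))
  }
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, mann_whitney(scores, labels))
    expect_true(all(diff(r$sensitivities) >= 0))
    expect_gte(r$pr_auc, 0); expect_lte(r$pr_auc, 1)
  }
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(40)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.3, 0.7))
  ours <- roc_analysis(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("matched operating point maximizes specificity at target sensitivity", {
  sep <- roc_analysis(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))
  at1 <- matched_operating_point(sep, 1.0)
  expect_equal(at1$sensitivity, 1)
  expect_equal(at1$specificity, 1)
  expect_lte(at1$threshold, 11)
  at0 <- matched_operating_point(sep, 0)
  expect_equal(at0$specificity, 1)

  # constructed cohort where 20 of 22 positives exceed the cutoff
  scores <- c(runif(82, 0.0, 0.35), runif(20, 0.45, 1), c(0.1, 0.2))
  labels <- c(rep(FALSE, 82), rep(TRUE, 22))
  op <- matched_operating_point(roc_analysis(scores, labels), 20 / 22)
  expect_equal(op$sensitivity, 20 / 22)
  expect_true(op$attained)
})

test_that("two-proportion chi-square matches the Pearson formula", {
  expect_equal(two_proportion_chisq(5, 10, 5, 10), 1)
  expect_equal(two_proportion_chisq(71, 82, 30, 50),
               two_proportion_chisq(30, 50, 71, 82))
  # brute-force Pearson 2x2 oracle, no continuity correction
  pearson_p <- function(k1, n1, k2, n2) {
    o <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  expect_equal(two_proportion_chisq(71, 82, 30, 50), pearson_p(71, 82, 30, 50))
  expect_equal(two_proportion_chisq(3, 20, 15, 25), pearson_p(3, 20, 15, 25))
  expect_error(two_proportion_chisq(0, 10, 0, 5), "degenerate")
})

test_that("QC accounting, Weber fraction and noise floor follow definitions", {
  expect_equal(qc_failure_fraction(109, 104)$percent, 4.6)
  expect_equal(qc_failure_fraction(100, 100)$percent, 0)
  expect_equal(qc_failure_fraction(10, 7)$percent, 30)
  expect_error(qc_failure_fraction(0, 0), "positive")

  img <- matrix(1.0, 10, 10) / 10
  fg <- matrix(FALSE, 10, 10); fg[1:5, ] <- TRUE
  bg <- !fg
  img[fg] <- 0.83; img[bg] <- 0.10
  expect_equal(weber_fraction(img, fg, bg), 7.3)
  img[fg] <- 0.27
  expect_equal(weber_fraction(img, fg, bg), 1.7)
  img[fg] <- 0.10
  expect_equal(weber_fraction(img, fg, bg), 0)
  expect_error(weber_fraction(img, fg, fg), "disjoint")

  expect_equal(noise_floor(matrix(0.4, 5, 5)), 0)
  set.seed(15)
  blank <- matrix(pmin(pmax(rnorm(256^2, 0.5, 0.03), 0), 1), 256, 256)
  expect_equal(noise_floor(blank), 0.03, tolerance = 0.05)
})

test_that("diagnostics from the printed table reproduce the published values", {
  d <- diagnostics_from_table(printed_agreement_fixture())
  expect_equal(round(d$device_sensitivity, 2), 0.91)   # 20/22
  expect_equal(d$sensitivity_k[["device"]], 20)
  expect_equal(round(d$device_specificity, 2), 0.87)   # 71/82
  expect_equal(round(d$hra_sensitivity, 2), 0.91)
  expect_equal(d$hra_specificity, 43 / 82)
  expect_equal(d$agreement_count, 68)
  expect_equal(round(d$kappa, 2), 0.34)
  expect_equal(round(100 * d$prevalence), 21)
  expect_equal(d$discordant_count, 36)
  expect_equal(round(100 * d$discordant_ain1_share), 78)  # 28/36
  expect_equal(d$mcnemar_sensitivity_p, 1.0)
  expect_lt(d$mcnemar_specificity_p, 1e-4)

  # perfect agreement: everything 1
  perfect <- array(0, c(2, 2, 3))
  perfect[1, 1, 1:2] <- c(10, 60)
  perfect[2, 2, 3] <- 20
  dp <- diagnostics_from_table(agreement_table(perfect))
  expect_equal(dp$device_sensitivity, 1)
  expect_equal(dp$device_specificity, 1)
  expect_equal(dp$kappa, 1)

  empty_pos <- array(0, c(2, 2, 3)); empty_pos[1, 1, 1] <- 5
  expect_error(diagnostics_from_table(agreement_table(empty_pos)),
               "sensitivity")
})

test_that("cohort-derived tables recover programmed call patterns exactly", {
  spec <- cohort_spec(
    class_counts = c(benign = 10L, AIN1 = 30L, `AIN2+` = 15L),
    score_distributions = list(
      benign = list(type = "degenerate", value = 0.1),
      AIN1 = list(type = "degenerate", value = 0.2),
      `AIN2+` = list(type = "degenerate", value = 0.9)
    ),
    hra_confusion = c(benign = 0, AIN1 = 0, `AIN2+` = 1),
    qc_fail_probability = 0
  )
  ch <- generate_site_cohort(spec, seed = 9)
  d <- diagnostics_from_table(agreement_from_cohort(ch, cutoff = 0.4))
  expect_equal(d$device_sensitivity, 1)
  expect_equal(d$device_specificity, 1)
  expect_equal(d$hra_sensitivity, 1)
  expect_equal(d$hra_specificity, 1)
  expect_equal(d$kappa, 1)

  # programmed device-negative positives: sensitivity 0 at the 0.4 cutoff
  spec2 <- spec
  spec2$score_distributions$`AIN2+` <- list(type = "degenerate", value = 0.3)
  d2 <- diagnostics_from_table(
    agreement_from_cohort(generate_site_cohort(spec2, seed = 9))
  )
  expect_equal(d2$device_sensitivity, 0)
  expect_equal(d2$device_specificity, 1)
})
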