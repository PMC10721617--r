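#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: with `z` the normal quantile for the level and
#' `p = k/n`, the interval is
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`,
#' always inside \[0, 1\] and always containing `k/n`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("`k` must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact binomial test: with `b` and `c` the two discordant-pair
#' counts, `p = min(1, 2 * P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`; `p = 1` when there is no discordance. The
#' exact form (rather than the chi-square approximation) is what makes the
#' balanced 2-vs-2 discordance comparison return exactly 1.
#'
#' @param b,c Discordant counts (>= 0).
#' @return Two-sided p-value.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) stop("discordant counts must be >= 0", call. = FALSE)
  if (b + c == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}

#' Cohen's kappa for a 2 x 2 rater agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' diagonal fraction and expected agreement `p_e` from the marginal products.
#' Returns 1 directly when both observed and expected agreement are 1
#' (single-category degenerate case).
#'
#' @param cross_table 2 x 2 numeric matrix of counts, rows = rater 1 calls,
#'   columns = rater 2 calls (same category order).
#' @return Kappa.
#' @export
cohens_kappa <- function(cross_table) {
  cross_table <- as.matrix(cross_table)
  stopifnot(all(dim(cross_table) == c(2, 2)))
  n <- sum(cross_table)
  if (n <= 0) stop("table total must be positive", call. = FALSE)
  po <- sum(diag(cross_table)) / n
  pe <- sum(rowSums(cross_table) * colSums(cross_table)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("expected agreement is 1 with imperfect observed agreement",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic summary from a stratified agreement table
#'
#' Computes every agreement statistic the stratified 2 x 2 x 3 table
#' determines, treating AIN 2+ as the positive class and benign/AIN 1 as
#' negative:
#' device sensitivity (device-positive AIN 2+ / all AIN 2+), device
#' specificity (device-negative non-AIN 2+ / all non-AIN 2+), the same
#' margins for HRA impression, raw agreement (cells where the two calls
#' match), Cohen's kappa on the collapsed 2 x 2 device-by-HRA table,
#' prevalence, Wilson confidence intervals for the device margins, exact
#' McNemar comparisons of device vs HRA sensitivity (discordance within the
#' positive stratum) and specificity (discordance within the negative
#' strata), and the share of discordant sites that are AIN 1 sites called
#' negative by the device but positive by HRA.
#'
#' @param table An [agreement_table()].
#' @param ci_level Confidence level for the Wilson intervals.
#' @return An object of class `diagnostic_summary`; proportions are stored
#'   as exact fractions, and `print()` reports them rounded to two decimals
#'   alongside the counts.
#' @export
diagnostics_from_table <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "agreement_table"))
  ct <- table$counts
  n <- sum(ct)
  if (n <= 0) stop("agreement table is empty", call. = FALSE)
  pos <- ct[, , "AIN2+"]
  neg <- ct[, , "benign"] + ct[, , "AIN1"]
  n_pos <- sum(pos); n_neg <- sum(neg)
  if (n_pos == 0) stop("undefined statistic: sensitivity (no positive-class sites)",
                       call. = FALSE)
  if (n_neg == 0) stop("undefined statistic: specificity (no negative-class sites)",
                       call. = FALSE)
  dev_tp <- sum(pos["+", ]); dev_tn <- sum(neg["-", ])
  hra_tp <- sum(pos[, "+"]); hra_tn <- sum(neg[, "-"])
  collapsed <- apply(ct, c(1, 2), sum)
  agree <- sum(diag(collapsed))
  # discordance between paired raters, per stratum
  sens_b <- sum(pos["-", "+"]); sens_c <- sum(pos["+", "-"])
  spec_b <- sum(neg["-", "+"]); spec_c <- sum(neg["+", "-"])
  discordant <- sum(collapsed["-", "+"], collapsed["+", "-"])
  disc_ain1 <- ct["-", "+", "AIN1"]
  structure(
    list(
      n_sites = n,
      device_sensitivity = dev_tp / n_pos,
      device_specificity = dev_tn / n_neg,
      hra_sensitivity = hra_tp / n_pos,
      hra_specificity = hra_tn / n_neg,
      sensitivity_k = c(device = dev_tp, hra = hra_tp, n = n_pos),
      specificity_k = c(device = dev_tn, hra = hra_tn, n = n_neg),
      sensitivity_ci = wilson_interval(dev_tp, n_pos, ci_level),
      specificity_ci = wilson_interval(dev_tn, n_neg, ci_level),
      agreement_count = agree,
      agreement_fraction = agree / n,
      kappa = cohens_kappa(collapsed),
      prevalence = n_pos / n,
      mcnemar_sensitivity_p = mcnemar_exact(sens_b, sens_c),
      mcnemar_specificity_p = mcnemar_exact(spec_b, spec_c),
      discordant_count = discordant,
      discordant_ain1_share = if (discordant > 0) disc_ain1 / discordant else NA_real_,
      ci_level = ci_level
    ),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  f2 <- function(v) sprintf("%.2f", v)
  cat("<diagnostic_summary>\n")
  cat(sprintf("  device: sensitivity %s (%d/%d, %d%% CI %s-%s), specificity %s (%d/%d, CI %s-%s)\n",
              f2(x$device_sensitivity), x$sensitivity_k["device"],
              x$sensitivity_k["n"], round(100 * x$ci_level),
              f2(x$sensitivity_ci[1]), f2(x$sensitivity_ci[2]),
              f2(x$device_specificity), x$specificity_k["device"],
              x$specificity_k["n"],
              f2(x$specificity_ci[1]), f2(x$specificity_ci[2])))
  cat(sprintf("  HRA:    sensitivity %s, specificity %s\n",
              f2(x$hra_sensitivity), f2(x$hra_specificity)))
  cat(sprintf("  agreement %d/%d (%d%%), kappa %s, prevalence %d%%\n",
              x$agreement_count, x$n_sites,
              round(100 * x$agreement_fraction), f2(x$kappa),
              round(100 * x$prevalence)))
  cat(sprintf("  McNemar: sensitivity p = %.4g, specificity p = %.4g\n",
              x$mcnemar_sensitivity_p, x$mcnemar_specificity_p))
  invisible(x)
}

#' ROC and precision-recall analysis of per-site scores
#'
#' Sweeps the unique score values as inclusive (score >= threshold)
#' positivity thresholds, computes sensitivity/specificity at each, and
#' integrates the ROC by the trapezoid rule — which, with ties receiving a
#' sloped segment, makes the AUC identical to the Mann-Whitney statistic
#' with half credit for tied pairs. The precision-recall curve is integrated
#' as a step function (precision at each threshold times the recall
#' increment), the average-precision convention.
#'
#' @param scores Numeric per-site scores.
#' @param labels Logical (or 0/1): `TRUE` for positive-class (AIN 2+) sites.
#' @return An object of class `roc_result` with fields `thresholds`,
#'   `sensitivities`, `specificities`, `auc`, `pr_auc`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  np <- sum(labels); nn <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores[labels] >= t) / np, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!labels] < t) / nn, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  prec <- vapply(thr, function(t) {
    called <- sum(scores >= t)
    if (called == 0) 1 else sum(scores[labels] >= t) / called
  }, numeric(1))
  pr_auc <- sum(diff(sens) * utils::tail(prec, -1))
  structure(
    list(thresholds = thr, sensitivities = sens, specificities = spec,
         auc = auc, pr_auc = pr_auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, PR-AUC %.3f over %d thresholds\n",
              x$auc, x$pr_auc, length(x$thresholds)))
  invisible(x)
}

#' Operating point matched to a target sensitivity
#'
#' Among thresholds whose sensitivity is at least the target, returns the
#' one with maximal specificity (ties broken toward the higher threshold) —
#' the rule used to compare the device to the clinical comparator at equal
#' sensitivity. If no threshold attains the target, the maximum-sensitivity
#' point is returned with `attained = FALSE`.
#'
#' @param roc A `roc_result`.
#' @param target_sensitivity Target in \[0, 1\].
#' @return List with `threshold`, `sensitivity`, `specificity`, `attained`.
#' @export
matched_operating_point <- function(roc, target_sensitivity) {
  stopifnot(inherits(roc, "roc_result"))
  if (target_sensitivity < 0 || target_sensitivity > 1) {
    stop("`target_sensitivity` must lie in [0, 1]", call. = FALSE)
  }
  ok <- roc$sensitivities >= target_sensitivity
  if (!any(ok)) {
    i <- which.max(roc$sensitivities)
    return(list(threshold = roc$thresholds[i],
                sensitivity = roc$sensitivities[i],
                specificity = roc$specificities[i], attained = FALSE))
  }
  cand <- which(ok)
  best_spec <- max(roc$specificities[cand])
  cand <- cand[roc$specificities[cand] == best_spec]
  i <- cand[which.max(roc$thresholds[cand])]
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivities[i],
       specificity = roc$specificities[i], attained = TRUE)
}

#' Two-proportion chi-square test
#'
#' Pearson chi-square on the pooled 2 x 2 table with 1 degree of freedom,
#' without continuity correction by default (set `correct = TRUE` for the
#' Yates-corrected variant). Used to compare specificities of two devices at
#' matched sensitivity.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply continuity correction (default `FALSE`).
#' @return Two-sided p-value.
#' @export
two_proportion_chisq <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    stop("undefined statistic: pooled proportion is degenerate", call. = FALSE)
  }
  suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = correct)$p.value
  )
}

#' Quality-control failure accounting
#'
#' @param n_imaged Sites imaged (> 0).
#' @param n_passed Sites passing QC (0 <= n_passed <= n_imaged).
#' @return List with `n_imaged`, `n_passed`, `n_failed`, `fraction`, and
#'   `percent` (the failure fraction as a percentage rounded to 1 decimal,
#'   e.g. 109 imaged / 104 passed -> 4.6).
#' @export
qc_failure_fraction <- function(n_imaged, n_passed) {
  if (n_imaged <= 0) stop("`n_imaged` must be positive", call. = FALSE)
  if (n_passed < 0 || n_passed > n_imaged) {
    stop("`n_passed` must lie in [0, n_imaged]", call. = FALSE)
  }
  frac <- (n_imaged - n_passed) / n_imaged
  list(n_imaged = n_imaged, n_passed = n_passed,
       n_failed = n_imaged - n_passed,
       fraction = frac, percent = round(100 * frac, 1))
}

#' Weber contrast of a target image
#'
#' `(mean foreground - mean background) / mean background` over the two
#' disjoint masks — the contrast measure used on a bar-resolution target.
#'
#' @param image An `hrme_frame` or numeric matrix.
#' @param fg_mask,bg_mask Logical masks, disjoint and nonempty.
#' @return The Weber fraction.
#' @export
weber_fraction <- function(image, fg_mask, bg_mask) {
  px <- if (inherits(image, "hrme_frame")) image$pixels else image
  stopifnot(is.matrix(px), identical(dim(px), dim(fg_mask)),
            identical(dim(px), dim(bg_mask)))
  if (!any(fg_mask) || !any(bg_mask)) {
    stop("masks must be nonempty", call. = FALSE)
  }
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint", call. = FALSE)
  mb <- mean(px[bg_mask])
  if (mb == 0) stop("undefined statistic: zero background mean", call. = FALSE)
  (mean(px[fg_mask]) - mb) / mb
}

#' Noise floor of a blank-target image
#'
#' The standard deviation of the pixel intensities of a blank frame — the
#' operational noise-floor measurement.
#'
#' @param blank An `hrme_frame` or numeric matrix.
#' @return Standard deviation (0 for a constant frame).
#' @export
noise_floor <- function(blank) {
  px <- if (inherits(blank, "hrme_frame")) blank$pixels else blank
  stopifnot(is.matrix(px), length(px) > 0L)
  if (length(px) == 1L) return(0)
  stats::sd(as.numeric(px))
}
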