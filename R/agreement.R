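#' Device-by-comparator agreement table stratified by histopathology
#'
#' A 2 x 2 x 3 count array indexed by device call (`-`, `+`), HRA call
#' (`-`, `+`) and severity tier (`benign`, `AIN1`, `AIN2+`). This is the
#' central data structure of the diagnostic evaluation: every headline
#' agreement statistic is a deterministic function of its 12 cells.
#'
#' @param counts Numeric array of dimension `c(2, 2, 3)`, or a named list of
#'   per-tier 2 x 2 matrices; all counts must be non-negative.
#' @return An object of class `agreement_table`.
#' @export
agreement_table <- function(counts) {
  if (is.list(counts)) {
    counts <- array(unlist(counts[severity_levels]), dim = c(2, 2, 3))
  }
  stopifnot(is.array(counts), all(dim(counts) == c(2, 2, 3)))
  if (any(counts < 0)) stop("agreement counts must be >= 0", call. = FALSE)
  dimnames(counts) <- list(device = c("-", "+"), hra = c("-", "+"),
                           class = severity_levels)
  structure(list(counts = counts), class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table> device x HRA x histopathology counts\n")
  for (cl in severity_levels) {
    cat(sprintf("  %s (n = %d):\n", cl, sum(x$counts[, , cl])))
    print(x$counts[, , cl])
  }
  invisible(x)
}

#' Grand total and per-tier totals
#' @param x An `agreement_table`.
#' @return `table_total`: grand total; `class_totals`: named per-tier sums.
#' @export
table_total <- function(x) sum(x$counts)

#' @rdname table_total
#' @export
class_totals <- function(x) apply(x$counts, 3, sum)

#' The printed 104-site agreement table
#'
#' Returns the published per-site agreement between the high-frame-rate
#' device call and HRA impression, stratified by histopathologic tier
#' (columns benign n = 11, AIN 1 n = 71, AIN 2+ n = 22):
#'
#' | device, HRA | benign | AIN 1 | AIN 2+ |
#' |-------------|--------|-------|--------|
#' | `- -`       | 7      | 34    | 0      |
#' | `- +`       | 2      | 28    | 2      |
#' | `+ -`       | 0      | 2     | 2      |
#' | `+ +`       | 2      | 7     | 18     |
#'
#' Every published agreement statistic (sensitivity 0.91, specificity 0.87,
#' agreement 68/104, kappa 0.34, prevalence 21%) is recomputable from these
#' twelve cells via [diagnostics_from_table()].
#'
#' @return An [agreement_table()].
#' @export
printed_agreement_fixture <- function() {
  counts <- array(0, dim = c(2, 2, 3))
  # cells[device, hra, class]
  counts[1, 1, ] <- c(7, 34, 0)
  counts[1, 2, ] <- c(2, 28, 2)
  counts[2, 1, ] <- c(0, 2, 2)
  counts[2, 2, ] <- c(2, 7, 18)
  agreement_table(counts)
}

#' Build an agreement table from a site cohort
#'
#' Applies the positivity cutoff to the device scores, pairs the resulting
#' calls with the recorded HRA impressions, and tabulates by severity tier.
#' Sites failing QC are excluded, mirroring the analysis-set rule.
#'
#' @param cohort A cohort data frame (see [generate_site_cohort()]).
#' @param cutoff Device positivity cutoff; a site is device-positive iff
#'   `device_score >= cutoff`.
#' @param qc_only If `TRUE` (default), drop sites with `qc_pass == FALSE`.
#' @return An [agreement_table()].
#' @export
agreement_from_cohort <- function(cohort, cutoff = 0.4, qc_only = TRUE) {
  if (qc_only) cohort <- cohort[cohort$qc_pass, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("no sites left after QC filtering", call. = FALSE)
  dev <- ifelse(cohort$device_score >= cutoff, "+", "-")
  hra <- ifelse(cohort$hra_impression == "HSIL", "+", "-")
  counts <- array(0, dim = c(2, 2, 3))
  for (k in seq_along(severity_levels)) {
    sel <- cohort$severity_class == severity_levels[k]
    counts[, , k] <- table(factor(dev[sel], levels = c("-", "+")),
                           factor(hra[sel], levels = c("-", "+")))
  }
  agreement_table(counts)
}
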