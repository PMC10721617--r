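#' Map a histopathologic diagnosis to its severity tier
#'
#' The analysis groups the six histopathologic categories into three tiers:
#' benign; AIN 1 (with condyloma acuminatum grouped into this non-precancer
#' tier and flagged in metadata); and AIN 2+ (AIN 2, AIN 3 or cancer), the
#' positive class.
#'
#' @param histopathology Character vector with values among
#'   `"benign"`, `"AIN1"`, `"condyloma"`, `"AIN2"`, `"AIN3"`, `"cancer"`.
#' @return Character vector with values in `c("benign", "AIN1", "AIN2+")`.
#' @export
severity_class <- function(histopathology) {
  map <- c(benign = "benign", AIN1 = "AIN1", condyloma = "AIN1",
           AIN2 = "AIN2+", AIN3 = "AIN2+", cancer = "AIN2+")
  bad <- setdiff(unique(histopathology), names(map))
  if (length(bad)) {
    stop("unknown histopathology value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[histopathology])
}

severity_levels <- c("benign", "AIN1", "AIN2+")

#' Cohort specification for synthetic site generation
#'
#' Describes the marginal structure of a clinical site cohort: fixed per-tier
#' site counts, per-tier device-score distributions on \[0, 1\], per-tier
#' probabilities that the clinical comparator (HRA impression) calls HSIL,
#' and a quality-control failure probability.
#'
#' The defaults emulate the 104-site analysis-set structure: counts 11
#' benign / 71 AIN 1 / 22 AIN 2+, Beta score distributions with class means
#' ordered benign < AIN 1 < AIN 2+, and HRA HSIL rates taken from the
#' printed per-tier agreement margins (4/11, 35/71, 20/22).
#'
#' @param class_counts Named integer vector over
#'   `c("benign", "AIN1", "AIN2+")`; missing tiers count 0.
#' @param score_distributions Named list per tier; each element either
#'   `list(type = "beta", shape1 =, shape2 =)` or
#'   `list(type = "degenerate", value =)`.
#' @param hra_confusion Named probability vector per tier: P(HRA calls HSIL).
#' @param qc_fail_probability Probability a site's image fails QC.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(class_counts = c(benign = 11L, AIN1 = 71L, `AIN2+` = 22L),
                        score_distributions = default_score_distributions(),
                        hra_confusion = c(benign = 4 / 11, AIN1 = 35 / 71,
                                          `AIN2+` = 20 / 22),
                        qc_fail_probability = 0.046) {
  counts <- integer(3); names(counts) <- severity_levels
  counts[names(class_counts)] <- as.integer(class_counts)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0L) stop("at least one class count must be > 0", call. = FALSE)
  if (any(hra_confusion < 0 | hra_confusion > 1) ||
      qc_fail_probability < 0 || qc_fail_probability > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (cl in names(counts[counts > 0])) {
    d <- score_distributions[[cl]]
    if (is.null(d)) stop("missing score distribution for class ", cl, call. = FALSE)
    if (identical(d$type, "degenerate") &&
        (d$value < 0 || d$value > 1)) {
      stop("degenerate score must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(class_counts = counts, score_distributions = score_distributions,
         hra_confusion = hra_confusion,
         qc_fail_probability = qc_fail_probability),
    class = "cohort_spec"
  )
}

#' Default per-tier device-score distributions
#'
#' Beta distributions on \[0, 1\] with means ordered benign (0.15) <
#' AIN 1 (0.25) < AIN 2+ (0.65). The clinical per-tier score distributions
#' are not published, so these are illustrative study conditions, not a
#' calibration.
#'
#' @return Named list of distribution descriptors.
#' @export
default_score_distributions <- function() {
  list(
    benign  = list(type = "beta", shape1 = 1.5, shape2 = 8.5),
    AIN1    = list(type = "beta", shape1 = 2.0, shape2 = 6.0),
    `AIN2+` = list(type = "beta", shape1 = 6.5, shape2 = 3.5)
  )
}

draw_score <- function(dist, n) {
  switch(dist$type,
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    degenerate = rep(dist$value, n),
    # two-point mixture: `hi` with probability p_positive, else `lo`;
    # useful for programming an exact expected sensitivity/specificity
    two_point = ifelse(stats::runif(n) < dist$p_positive, dist$hi, dist$lo),
    stop("unknown score distribution type: ", dist$type, call. = FALSE)
  )
}

#' Generate a synthetic site cohort
#'
#' Produces one record per site with exact per-tier counts (counts are fixed
#' design margins, not sampled), device scores drawn from the per-tier
#' distributions, HRA impressions drawn from the per-tier HSIL probability,
#' and QC flags. Site `i` uses the deterministic substream `seed + i`, so
#' two runs with the same spec and seed are identical, and different seeds
#' change scores but never the class counts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A data frame with columns `site_id`, `patient_id`,
#'   `histopathology`, `severity_class`, `hra_impression` (`"HSIL"` /
#'   `"non-HSIL"`), `device_score` and `qc_pass`.
#' @export
generate_site_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  histo_pool <- list(
    benign = c(benign = 1),
    AIN1 = c(AIN1 = 0.9, condyloma = 0.1),
    `AIN2+` = c(AIN2 = 0.6, AIN3 = 0.35, cancer = 0.05)
  )
  classes <- rep(severity_levels, times = spec$class_counts)
  n <- length(classes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    withr_seed(seed + i, {
      histo <- sample(names(histo_pool[[cl]]), 1L, prob = histo_pool[[cl]])
      score <- draw_score(spec$score_distributions[[cl]], 1L)
      hra <- stats::runif(1) < spec$hra_confusion[[cl]]
      qc <- stats::runif(1) >= spec$qc_fail_probability
    })
    out[[i]] <- data.frame(
      site_id = sprintf("S%03d", i),
      patient_id = sprintf("P%03d", (i - 1L) %/% 3L + 1L),
      histopathology = histo,
      severity_class = cl,
      hra_impression = if (hra) "HSIL" else "non-HSIL",
      device_score = score,
      qc_pass = qc,
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  cohort
}

#' Write / read a site cohort CSV
#'
#' Plain-CSV serialization with the fixed header
#' `site_id,patient_id,histopathology,severity_class,hra_impression,device_score,qc_pass`.
#'
#' @param cohort A cohort data frame from [generate_site_cohort()].
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  ch <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "patient_id", "histopathology", "severity_class",
            "hra_impression", "device_score", "qc_pass")
  miss <- setdiff(need, names(ch))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ch$qc_pass <- as.logical(ch$qc_pass)
  ch
}
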