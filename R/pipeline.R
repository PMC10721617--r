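#' Per-severity phantom rendering parameters
#'
#' The synthetic study conditions tying histopathologic severity to nuclear
#' morphology: neoplastic epithelium shows crowded, enlarged nuclei, so
#' nucleus density and radius increase across benign < AIN 1 < AIN 2+.
#' These are the generator defaults used by [run_pipeline()] and the
#' end-to-end tests.
#'
#' @return Named list per severity tier with `density` (nuclei/mm^2) and
#'   `radius_range` (um).
#' @export
severity_phantom_params <- function() {
  list(
    benign  = list(density = 200, radius_range = c(3.0, 4.5)),
    AIN1    = list(density = 350, radius_range = c(3.5, 5.5)),
    `AIN2+` = list(density = 700, radius_range = c(4.5, 7.0))
  )
}

#' Render a frame sequence for a site of a given severity tier
#'
#' Convenience wrapper: generates a phantom with the tier's nuclear
#' morphology (see [severity_phantom_params()]) and renders a short burst
#' under probe translation.
#'
#' @param severity One of `"benign"`, `"AIN1"`, `"AIN2+"`.
#' @param params [acquisition_params()]; default [hf_hrme_params()].
#' @param n_frames Frames in the burst.
#' @param speed Probe speed, mm/s.
#' @param size_px Raster side in pixels.
#' @param seed Integer seed.
#' @return An `hrme_sequence`.
#' @export
render_site_sequence <- function(severity,
                                 params = hf_hrme_params(),
                                 n_frames = 6L,
                                 speed = 0.5,
                                 size_px = 128L,
                                 seed = 1L) {
  sp <- severity_phantom_params()[[severity]]
  if (is.null(sp)) stop("unknown severity tier: ", severity, call. = FALSE)
  margin <- speed * (n_frames / params$frame_rate) * 1000 + 40
  extent <- size_px * params$pixel_pitch + 2 * margin
  phantom <- generate_phantom(extent, sp$density,
                              nucleus_radius_range = sp$radius_range,
                              seed = seed)
  render_sequence(phantom, trajectory_spec(speed), params, n_frames,
                  seed = seed + 1000L, size_px = size_px)
}

#' Score a frame end to end
#'
#' Probe detection, optional resampling to the reference pitch, quadrant
#' split and classifier aggregation in one call.
#'
#' @param frame An `hrme_frame`.
#' @param ref_pitch Reference pitch for resampling (um/px); `NULL` skips
#'   resampling.
#' @param classifier Per-quadrant classifier.
#' @param cutoff Positivity cutoff.
#' @param site_id Optional identifier.
#' @return A `site_score`.
#' @export
score_frame <- function(frame, ref_pitch = 0.78,
                        classifier = baseline_quadrant_probability,
                        cutoff = 0.4, site_id = NA_character_) {
  if (!is.null(ref_pitch) && ref_pitch != frame$params$pixel_pitch) {
    frame <- resample_to_reference(frame, ref_pitch = ref_pitch)
  }
  region <- detect_probe_region(frame)
  quads <- split_quadrants(frame, region)
  score_site(quads, classifier, cutoff, site_id)
}

#' Pipeline run configuration
#'
#' A single structured configuration for [run_pipeline()]: synthetic cohort
#' sizes, acquisition constants, degradation method, classifier cutoff,
#' divergence estimator, confidence level, master seed and output directory.
#'
#' @param sites_per_class Named counts of image sites rendered per tier.
#' @param method Degradation method id (1-6) or `"custom"`.
#' @param degradation A [degradation_config()] used when `method = "custom"`;
#'   otherwise overrides for [degradation_method_config()].
#' @param cutoff Positivity cutoff.
#' @param kl_estimator `"gaussian-per-dim"` or `"knn"`.
#' @param ci_level Confidence level.
#' @param master_seed Integer master seed.
#' @param n_frames,speed,size_px Rendering controls per site.
#' @param cohort A [cohort_spec()] for the tabular cohort stage.
#' @param output_dir Directory for stage outputs and the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sites_per_class = c(benign = 4L, AIN1 = 4L, `AIN2+` = 4L),
                       method = 2L,
                       degradation = NULL,
                       cutoff = 0.4,
                       kl_estimator = "gaussian-per-dim",
                       ci_level = 0.95,
                       master_seed = 1L,
                       n_frames = 6L,
                       speed = 0.5,
                       size_px = 96L,
                       cohort = cohort_spec(),
                       output_dir = tempfile("hrmesim_run_")) {
  if (!(identical(method, "custom") || method %in% 1:6)) {
    stop("`method` must be 1..6 or \"custom\"", call. = FALSE)
  }
  if (identical(method, "custom") && is.null(degradation)) {
    stop("`method = \"custom\"` needs an explicit `degradation` config",
         call. = FALSE)
  }
  if (cutoff < 0 || cutoff > 1) stop("`cutoff` must lie in [0, 1]", call. = FALSE)
  structure(
    list(sites_per_class = sites_per_class, method = method,
         degradation = degradation, cutoff = cutoff,
         kl_estimator = kl_estimator, ci_level = ci_level,
         master_seed = as.integer(master_seed), n_frames = as.integer(n_frames),
         speed = speed, size_px = as.integer(size_px), cohort = cohort,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> degrade -> score -> shift -> evaluate on synthetic
#' data: renders a burst per site with severity-dependent nuclear
#' morphology, degrades each burst with the configured method, scores the
#' original and degraded selected frames, extracts per-quadrant features
#' from both arms and estimates their average K-L divergence, builds the
#' tabular cohort and its diagnostic summary, and writes a JSON manifest
#' (per-stage seeds, outputs, checksums) plus the cohort CSV, feature CSVs
#' and a results JSON into the output directory. Deterministic stages are
#' bit-identical across reruns with the same config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `scores` (per-site data frame), `kl`
#'   (a `divergence_estimate`), `diagnostics` (a `diagnostic_summary`),
#'   `manifest` and `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  deg_cfg <- if (identical(config$method, "custom")) {
    config$degradation
  } else {
    do.call(degradation_method_config,
            c(list(method = config$method), config$degradation))
  }

  classes <- rep(names(config$sites_per_class), times = config$sites_per_class)
  rows <- vector("list", length(classes))
  feats_orig <- list(); feats_deg <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    seq_i <- render_site_sequence(cl, n_frames = config$n_frames,
                                  speed = config$speed,
                                  size_px = config$size_px,
                                  seed = seed + 10L * i)
    deg_i <- apply_method(seq_i, deg_cfg, seed = seed + 10L * i + 5L)
    sc_o <- score_frame(selected_frame(seq_i), cutoff = config$cutoff,
                        site_id = sprintf("S%03d", i))
    sc_d <- score_frame(deg_i, cutoff = config$cutoff,
                        site_id = sprintf("S%03d", i))
    qo <- split_quadrants(selected_frame(seq_i),
                          detect_probe_region(selected_frame(seq_i)))
    qd <- split_quadrants(deg_i, detect_probe_region(deg_i))
    feats_orig[[i]] <- t(vapply(qo$quadrants, extract_features,
                                numeric(64), pixel_pitch = qo$pixel_pitch))
    feats_deg[[i]] <- t(vapply(qd$quadrants, extract_features,
                               numeric(64), pixel_pitch = qd$pixel_pitch))
    rows[[i]] <- data.frame(
      site_id = sprintf("S%03d", i), severity_class = cl,
      score_original = sc_o$score, call_original = sc_o$call,
      score_degraded = sc_d$score, call_degraded = sc_d$call,
      stringsAsFactors = FALSE
    )
  }
  scores <- do.call(rbind, rows)
  fs_orig <- feature_set(do.call(rbind, feats_orig), "original")
  fs_deg <- feature_set(do.call(rbind, feats_deg), "degraded")
  kl <- estimate_kl(fs_deg, fs_orig, estimator = config$kl_estimator)

  cohort <- generate_site_cohort(config$cohort, seed = seed)
  tab <- agreement_from_cohort(cohort, cutoff = config$cutoff)
  diag <- diagnostics_from_table(tab, ci_level = config$ci_level)

  paths <- list(
    cohort = file.path(config$output_dir, "cohort.csv"),
    scores = file.path(config$output_dir, "scores.csv"),
    features_original = file.path(config$output_dir, "features_original.csv"),
    features_degraded = file.path(config$output_dir, "features_degraded.csv"),
    results = file.path(config$output_dir, "results.json")
  )
  write_cohort_csv(cohort, paths$cohort)
  utils::write.csv(scores, paths$scores, row.names = FALSE, quote = FALSE)
  write_feature_csv(fs_orig, paths$features_original)
  write_feature_csv(fs_deg, paths$features_degraded)
  results <- list(
    kl_divergence = kl$value, kl_estimator = kl$estimator,
    device_sensitivity = diag$device_sensitivity,
    device_specificity = diag$device_specificity,
    agreement_count = diag$agreement_count, kappa = diag$kappa,
    prevalence = diag$prevalence
  )
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    stages = c("simulate", "degrade", "score", "shift", "evaluate"),
    master_seed = seed,
    method = config$method,
    n_sites = length(classes),
    outputs = lapply(paths, normalizePath),
    checksums = as.list(unname(tools::md5sum(unlist(paths)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$checksums) <- names(paths)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, kl = kl, diagnostics = diag,
                 manifest = manifest, output_dir = config$output_dir))
}

#' Replay every statistic the printed tables determine
#'
#' Self-contained end-to-end check: loads the printed 104-site agreement
#' table and the imaging counts (109 imaged, 104 analyzed), recomputes all
#' derived agreement statistics, the Wilson intervals, the exact McNemar
#' p-values, the QC failure fraction, and the degradation-design arithmetic
#' identities (frame averaging 70 fps / 5 -> 14 fps and 5 x 1.4 ms -> 7 ms,
#' computed on an actually rendered burst; resampling 1.24/0.78 um -> 1.6x),
#' and compares each against its published value.
#'
#' @return A data frame with columns `statistic`, `computed`, `printed` and
#'   `pass`; attribute `ok` is `TRUE` iff every row passes. Confidence
#'   bounds are compared at the published two-decimal precision (truncation
#'   convention, under which all four bounds reproduce exactly).
#' @export
replay_printed_results <- function() {
  trunc2 <- function(x) floor(100 * x) / 100
  d <- diagnostics_from_table(printed_agreement_fixture())
  qc <- qc_failure_fraction(109, 104)

  seqn <- render_site_sequence("AIN1", params = hf_hrme_params(),
                               n_frames = 5L, speed = 1, size_px = 24L,
                               seed = 7L)
  avg <- average_frames(seqn, 5L)

  rows <- list(
    c("device_sensitivity", round(d$device_sensitivity, 2), 0.91),
    c("device_specificity", round(d$device_specificity, 2), 0.87),
    c("hra_sensitivity", round(d$hra_sensitivity, 2), 0.91),
    c("agreement_count", d$agreement_count, 68),
    c("n_sites", d$n_sites, 104),
    c("agreement_percent", round(100 * d$agreement_fraction), 65),
    c("kappa", round(d$kappa, 2), 0.34),
    c("prevalence_percent", round(100 * d$prevalence), 21),
    c("discordant_ain1_share_percent", round(100 * d$discordant_ain1_share), 78),
    c("sensitivity_ci_low", trunc2(d$sensitivity_ci[1]), 0.72),
    c("sensitivity_ci_high", trunc2(d$sensitivity_ci[2]), 0.97),
    c("specificity_ci_low", trunc2(d$specificity_ci[1]), 0.77),
    c("specificity_ci_high", trunc2(d$specificity_ci[2]), 0.92),
    c("mcnemar_sensitivity_p", d$mcnemar_sensitivity_p, 1.0),
    c("mcnemar_specificity_p_below_1e4",
      as.numeric(d$mcnemar_specificity_p < 1e-4), 1),
    c("qc_failure_percent", qc$percent, 4.6),
    c("equivalent_frame_rate_fps", avg$equivalent_frame_rate, 14),
    c("composite_exposure_ms", avg$composite_exposure, 7),
    c("resize_factor", resize_factor(1.24, 0.78), 1.6)
  )
  report <- data.frame(
    statistic = vapply(rows, `[[`, character(1), 1),
    computed = as.numeric(vapply(rows, `[[`, character(1), 2)),
    printed = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  report$pass <- abs(report$computed - report$printed) < 1e-9
  attr(report, "ok") <- all(report$pass)
  report
}
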