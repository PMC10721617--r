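#' Extract a 64-element feature vector from a quadrant
#'
#' The deployed deep model summarizes each quadrant as a 64-element embedding
#' before classification; the baseline extractor here produces a fixed-length
#' stand-in from interpretable descriptors: intensity moments, a 16-bin
#' intensity histogram, nine deciles, gradient statistics, local-contrast
#' texture summaries and the nuclear morphometry block (count density, area
#' mean/sd, equivalent radius, area fraction, foreground/background ratio),
#' zero-padded to exactly 64 elements. Custom extractors plug in behind the
#' same contract: a deterministic, all-finite, length-64 numeric vector.
#'
#' @param quadrant Numeric matrix (one quadrant).
#' @param pixel_pitch Micrometers per pixel.
#' @param extractor Optional function `(quadrant, pixel_pitch) -> numeric(64)`
#'   overriding the baseline.
#' @return Numeric vector of length 64.
#' @export
extract_features <- function(quadrant, pixel_pitch = 0.78, extractor = NULL) {
  stopifnot(is.matrix(quadrant), length(quadrant) > 0L)
  if (!is.null(extractor)) {
    v <- extractor(quadrant, pixel_pitch)
    if (length(v) != 64L || !is.numeric(v) || !all(is.finite(v))) {
      stop("extractor contract violation: need 64 finite numeric values",
           call. = FALSE)
    }
    return(as.numeric(v))
  }
  v <- as.numeric(quadrant)
  mo <- quadrant_morphometry(quadrant, pixel_pitch)
  gx <- quadrant[, -1, drop = FALSE] - quadrant[, -ncol(quadrant), drop = FALSE]
  gy <- quadrant[-1, , drop = FALSE] - quadrant[-nrow(quadrant), , drop = FALSE]
  grad <- c(abs(gx), abs(gy))
  hist16 <- graphics::hist(v, breaks = seq(0, 1, length.out = 17),
                           plot = FALSE)$density / 16
  feats <- c(
    mean(v), stats::sd(v), mean((v - mean(v))^3), stats::quantile(v, c(0.05, 0.95)),
    hist16,
    stats::quantile(v, seq(0.1, 0.9, by = 0.1)),
    mean(grad), stats::sd(grad), stats::quantile(grad, c(0.5, 0.9)),
    mo$density / 1000, mo$mean_area_um2 / 100, mo$sd_area_um2 / 100,
    mo$mean_radius_um / 10, mo$area_fraction, mo$intensity_ratio / 5,
    mo$count / 100
  )
  feats[!is.finite(feats)] <- 0
  out <- numeric(64L)
  out[seq_along(feats)] <- feats
  out
}

#' Labeled collection of feature vectors
#'
#' @param vectors Numeric matrix, one row per vector (64 columns for the
#'   baseline extractor; any fixed width is accepted).
#' @param label Dataset name.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(vectors, label = "dataset") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L) stop("feature set must be nonempty", call. = FALSE)
  if (!all(is.finite(vectors))) stop("feature values must be finite", call. = FALSE)
  structure(list(vectors = vectors, label = label), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> '%s': %d vectors x %d dims\n",
              x$label, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Feature sets to/from CSV
#'
#' One row per vector: columns `f1..fD` plus a `label` column.
#'
#' @param set A `feature_set`.
#' @param path File path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   a `feature_set`.
#' @export
write_feature_csv <- function(set, path) {
  stopifnot(inherits(set, "feature_set"))
  df <- as.data.frame(set$vectors)
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  df$label <- set$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lab <- if ("label" %in% names(df)) df$label[1] else "dataset"
  df$label <- NULL
  feature_set(as.matrix(df), lab)
}

#' Average Kullback-Leibler divergence between two feature sets
#'
#' The default `"gaussian-per-dim"` estimator fits a univariate Gaussian to
#' each feature dimension of each set, evaluates the closed-form divergence
#' `KL(a_d || b_d) = log(s_b/s_a) + (s_a^2 + (m_a - m_b)^2) / (2 s_b^2) - 1/2`
#' per dimension, and returns the mean over dimensions — an "average K-L
#' divergence" across the embedding. The direction is KL(a || b)
#' (asymmetric). Zero-variance dimensions are regularized with a variance
#' floor rather than raised as errors. A nonparametric `"knn"`
#' (Kozachenko-Leonenko style, k = 1) estimator on the full vectors is
#' available; it can return slightly negative values at small samples.
#'
#' @param a,b `feature_set`s with >= 2 vectors each and equal width.
#' @param estimator `"gaussian-per-dim"` (default) or `"knn"`.
#' @param eps Variance floor for degenerate dimensions.
#' @param standardize Standardize both sets by `b`'s per-dimension
#'   location/scale before estimation (off by default).
#' @return An object of class `divergence_estimate` with fields `value`
#'   (nats), `estimator` and (for the Gaussian estimator) `per_dimension`.
#' @export
estimate_kl <- function(a, b, estimator = c("gaussian-per-dim", "knn"),
                        eps = 1e-8, standardize = FALSE) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  estimator <- match.arg(estimator)
  A <- a$vectors; B <- b$vectors
  if (ncol(A) != ncol(B)) stop("feature sets differ in width", call. = FALSE)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("each feature set needs at least 2 vectors", call. = FALSE)
  }
  if (standardize) {
    mu <- colMeans(B)
    sg <- pmax(apply(B, 2, stats::sd), sqrt(eps))
    A <- sweep(sweep(A, 2, mu), 2, sg, `/`)
    B <- sweep(sweep(B, 2, mu), 2, sg, `/`)
  }
  if (estimator == "gaussian-per-dim") {
    ma <- colMeans(A); mb <- colMeans(B)
    va <- pmax(apply(A, 2, stats::var), eps)
    vb <- pmax(apply(B, 2, stats::var), eps)
    per_dim <- 0.5 * log(vb / va) + (va + (ma - mb)^2) / (2 * vb) - 0.5
    structure(list(value = mean(per_dim), estimator = estimator,
                   per_dimension = per_dim),
              class = "divergence_estimate")
  } else {
    structure(list(value = kl_knn(A, B), estimator = estimator,
                   per_dimension = NULL),
              class = "divergence_estimate")
  }
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> %.4f nats (%s)\n", x$value, x$estimator))
  invisible(x)
}

# Kozachenko-Leonenko style 1-NN KL estimator:
# (d/n) sum log(nu_i / rho_i) + log(m / (n - 1))
kl_knn <- function(A, B) {
  n <- nrow(A); m <- nrow(B); d <- ncol(A)
  dAA <- as.matrix(stats::dist(A))
  diag(dAA) <- Inf
  rho <- apply(dAA, 1, min)
  cross <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  nu <- sqrt(pmax(apply(cross, 1, min), 0))
  floorv <- 1e-12
  d / n * sum(log(pmax(nu, floorv) / pmax(rho, floorv))) + log(m / (n - 1))
}

#' Two-dimensional embedding of feature sets for visualization
#'
#' Runs t-distributed stochastic neighbor embedding (exact, non-Barnes-Hut;
#' implemented in the package) on the pooled vectors of one or more feature
#' sets and returns labeled 2-D coordinates for plotting. The embedding is
#' visualization-only: reproducible for a fixed seed, but its geometry
#' carries no quantitative meaning and no statistic in the package depends
#' on it.
#'
#' @param sets List of `feature_set`s (or a single one).
#' @param perplexity t-SNE perplexity; total vector count must exceed
#'   `3 * perplexity`.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return Data frame with columns `x`, `y`, `label`.
#' @export
embed_2d <- function(sets, perplexity = 10, seed = 1L, max_iter = 300L) {
  if (inherits(sets, "feature_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "feature_set")))
  X <- do.call(rbind, lapply(sets, `[[`, "vectors"))
  labels <- unlist(lapply(sets, function(s) rep(s$label, nrow(s$vectors))))
  if (nrow(X) <= 3 * perplexity) {
    stop("too few vectors for the requested perplexity", call. = FALSE)
  }
  Y <- withr_seed(seed, tsne_exact(X, perplexity = perplexity,
                                   max_iter = max_iter))
  data.frame(x = Y[, 1], y = Y[, 2], label = labels,
             stringsAsFactors = FALSE)
}
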