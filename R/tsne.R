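# Exact (dense) t-SNE, used by embed_2d(). Standard formulation: per-point
# Gaussian bandwidths calibrated to the target perplexity by bisection on
# the conditional-distribution entropy, symmetrized affinities, Student-t
# low-dimensional kernel, gradient descent with momentum and early
# exaggeration. O(n^2) memory/time — intended for the modest sample sizes a
# visual check uses, not large datasets. Caller seeds the RNG.

tsne_exact <- function(X, perplexity = 10, max_iter = 300L,
                       eta = 100, momentum = 0.5, final_momentum = 0.8,
                       exaggeration = 4, exaggeration_iter = 80L) {
  X <- as.matrix(X)
  n <- nrow(X)
  # squared Euclidean distances
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, `+`) - 2 * tcrossprod(X), 0)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= exaggeration_iter) Pex else P
    sy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sy, sy, `+`) - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter < 20L) momentum else final_momentum
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
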