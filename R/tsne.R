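# Exact t-SNE (no tree approximation) for small contig sets.
# Standard formulation: Gaussian input affinities with per-point bandwidth
# calibrated to the target perplexity by bisection, symmetrized; Student-t
# output kernel; gradient descent with momentum and early exaggeration.

tsne_exact <- function(X, perplexity = 30, seed = 0, n_components = 2,
                       max_iter = 500, eta = 200, exaggeration = 12) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { beta <- beta / 2; next }
      H <- log(sump) + beta * sum(di * p) / sump
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.eps)
  Y <- with_seed(seed, matrix(stats::rnorm(n * n_components, sd = 1e-4),
                              n, n_components))
  dY <- matrix(0, n, n_components)
  gains <- matrix(1, n, n_components)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= 100) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
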