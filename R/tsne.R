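# A compact t-distributed stochastic neighbour embedding operating on a
# precomputed distance matrix. Standard recipe: per-point bandwidths fitted
# to the target perplexity by bisection, symmetrised input affinities,
# Student-t low-dimensional kernel, gradient descent with momentum, early
# exaggeration and adaptive gains.

# conditional affinities p_{j|i} for one row of squared distances at
# precision beta; returns list(H = Shannon entropy, p = affinities)
.hbeta <- function(d2, beta) {
  p <- exp(-d2 * beta)
  sp <- sum(p)
  if (sp == 0) {
    return(list(H = 0, p = d2 * 0))
  }
  H <- log(sp) + beta * sum(d2 * p) / sp
  list(H = H, p = p / sp)
}

tsne_input_probs <- function(D, perplexity, tol = 1e-5) {
  n <- nrow(D)
  D2 <- D^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf
    betamax <- Inf
    d2 <- D2[i, -i]
    hb <- .hbeta(d2, beta)
    tries <- 0
    while (abs(hb$H - logU) > tol && tries < 50) {
      if (hb$H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      hb <- .hbeta(d2, beta)
      tries <- tries + 1
    }
    P[i, -i] <- hb$p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional t-SNE from a distance matrix
#'
#' @param D symmetric distance matrix.
#' @param seed seed for the random initialisation.
#' @param perplexity target perplexity, clamped to `(n - 1) / 3`.
#' @param n_iter iterations.
#' @return n x 2 coordinate matrix.
#' @keywords internal
tsne_embed <- function(D, seed = 1, perplexity = 30, n_iter = 500) {
  n <- nrow(D)
  perplexity <- max(2, min(perplexity, floor((n - 1) / 3)))
  P <- tsne_input_probs(D, perplexity)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 200
  exaggeration <- 12
  for (iter in seq_len(n_iter)) {
    Pm <- if (iter <= 100) P * exaggeration else P
    momentum <- if (iter <= 250) 0.5 else 0.8
    # Student-t affinities in the embedding
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pm - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
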