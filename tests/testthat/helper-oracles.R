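# Independent brute-force oracles used by the tests. These deliberately use
# explicit per-neuron / per-message loops, not the package's vectorized
# code paths.

# forward pass of a dense ReLU chain (linear final layer) by explicit loops
naive_dense_forward <- function(Ws, bs, x) {
  a <- x
  for (l in seq_along(Ws)) {
    z <- numeric(nrow(Ws[[l]]))
    for (j in seq_len(nrow(Ws[[l]]))) {
      s <- bs[[l]][j]
      for (i in seq_along(a)) s <- s + a[i] * Ws[[l]][j, i]
      z[j] <- s
    }
    a <- if (l < length(Ws)) pmax(z, 0) else z
  }
  a
}

# per-message alpha-beta relevance propagation on a dense ReLU chain:
# messages R_{i<-j} = q_ij / sum_i q_ij * R_j accumulated by explicit loops
naive_dense_lrp <- function(Ws, bs, x, target, alpha = 1, beta = 0,
                            eps = 1e-9) {
  acts <- list(x)
  a <- x
  for (l in seq_along(Ws)) {
    z <- as.vector(Ws[[l]] %*% a + bs[[l]])
    a <- if (l < length(Ws)) pmax(z, 0) else z
    acts[[l + 1]] <- a
  }
  R <- numeric(length(a))
  R[target] <- a[target]
  for (l in rev(seq_along(Ws))) {
    a_in <- acts[[l]]
    W <- Ws[[l]]
    Rlow <- numeric(length(a_in))
    for (j in seq_len(nrow(W))) {
      contrib <- a_in * W[j, ]
      zp <- sum(pmax(contrib, 0))
      zn <- sum(pmin(contrib, 0))
      for (i in seq_along(a_in)) {
        Rlow[i] <- Rlow[i] +
          (alpha * max(contrib[i], 0) / (zp + eps) -
           beta * min(contrib[i], 0) / (zn - eps)) * R[j]
      }
    }
    R <- Rlow
  }
  R
}

# brute-force 2-D convolution (stride 1, zero padding) by explicit loops
brute_conv <- function(a, W, b, k, pad) {
  h <- dim(a)[1]; w <- dim(a)[2]; cc <- dim(a)[3]; f <- ncol(W)
  ap <- array(0, c(h + 2 * pad, w + 2 * pad, cc))
  ap[pad + seq_len(h), pad + seq_len(w), ] <- a
  oh <- h + 2 * pad - k + 1
  ow <- w + 2 * pad - k + 1
  out <- array(0, c(oh, ow, f))
  for (ff in seq_len(f)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    s <- b[ff]
    for (ch in seq_len(cc)) for (di in seq_len(k)) for (dj in seq_len(k)) {
      wi <- (ch - 1) * k * k + (dj - 1) * k + di
      s <- s + ap[i + di - 1, j + dj - 1, ch] * W[wi, ff]
    }
    out[i, j, ff] <- s
  }
  out
}

# express a (pad = 0) conv layer as an equivalent dense weight matrix
# mapping vec(input) to vec(output), so the dense per-message LRP oracle
# applies to convolutional layers too
conv_as_dense <- function(layer) {
  geom <- layer$geom
  stopifnot(geom$p == 0)
  np <- nrow(geom$idx)
  f <- layer$spec$filters
  in_len <- geom$h * geom$w * geom$c
  D <- matrix(0, np * f, in_len)
  for (ff in seq_len(f)) {
    for (p in seq_len(np)) {
      D[p + (ff - 1) * np, geom$idx[p, ]] <- layer$W[, ff]
    }
  }
  D
}

# build a random dense ReLU chain model plus its raw weight lists
rand_dense_model <- function(dims, seed) {
  set.seed(seed)
  Ws <- list(); bs <- list()
  nl <- length(dims) - 1
  layers <- list()
  for (l in seq_len(nl)) {
    Ws[[l]] <- matrix(stats::rnorm(dims[l + 1] * dims[l]), dims[l + 1], dims[l])
    bs[[l]] <- stats::rnorm(dims[l + 1]) * 0.1
    layers <- c(layers, list(layer_dense(dims[l + 1])))
    if (l < nl) layers <- c(layers, list(layer_relu()))
  }
  m <- build_network(dims[1], layers, seq_len(dims[nl + 1]), seed = seed)
  j <- 1
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$kind == "dense") {
      m$layers[[i]]$W <- Ws[[j]]
      m$layers[[i]]$b <- bs[[j]]
      j <- j + 1
    }
  }
  list(model = m, Ws = Ws, bs = bs)
}

# a deterministic hand-built sample with a known rectangular mask
rect_sample <- function(canvas = 20, rows = 5:12, cols = 7:14, age = 3L) {
  mask <- matrix(FALSE, canvas, canvas)
  mask[rows, cols] <- TRUE
  img <- matrix(0, canvas, canvas)
  img[mask] <- 0.7
  structure(
    list(image = img, mask = mask, age = age, variant = "baseline",
         params = NULL, sample_id = "rect"),
    class = "otolith_sample"
  )
}

# pool-window index matrix for an h x w plane with non-overlapping 2x2
# windows, rows in column-major pooled order (independent of the package's
# internal construction)
build_im2col_test <- function(h, w, size = 2) {
  ph <- h %/% size
  pw <- w %/% size
  idx <- matrix(0L, ph * pw, size * size)
  r <- 0
  for (j in seq_len(pw)) {
    for (i in seq_len(ph)) {
      r <- r + 1
      top <- (i - 1) * size + 1
      left <- (j - 1) * size + 1
      cells <- as.vector(outer(top:(top + size - 1),
                               (left:(left + size - 1) - 1) * h, `+`))
      idx[r, ] <- cells
    }
  }
  idx
}
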