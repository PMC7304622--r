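# Spectral relevance analysis: descriptor preprocessing, affinity graph,
# spectral clustering, F1 scoring and the t-SNE embedding.

test_that("contour cropping keeps the mask bounding box and its mass", {
  scores <- matrix(0, 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[10:20, 5:15] <- TRUE
  scores[12:18, 7:13] <- 1 # relevance wholly inside the mask
  cr <- crop_to_contour(scores, mask)
  expect_identical(dim(cr), c(11L, 11L))
  expect_equal(sum(cr), sum(scores))
  # full mask is an identity crop
  expect_identical(crop_to_contour(scores, matrix(TRUE, 30, 30)), scores)
  expect_error(crop_to_contour(scores, matrix(FALSE, 30, 30)), "empty")
})

test_that("sum-downsampling pools blocks and conserves total mass", {
  expect_equal(downsample_sum(matrix(1, 4, 4), 2), matrix(4, 2, 2))
  m <- matrix(runif(112 * 112), 112)
  d <- downsample_sum(m, 56)
  expect_equal(d[1, 1], sum(m[1:2, 1:2]))
  expect_equal(sum(d), sum(m), tolerance = 1e-6)
  expect_error(downsample_sum(matrix(1, 4, 4), 8), "larger")
})

test_that("mass is conserved through the full descriptor chain", {
  set.seed(11)
  total_err <- 0
  for (i in 1:20) {
    h <- sample(20:60, 1); w <- sample(20:60, 1)
    m <- matrix(runif(h * w), h, w)
    rz <- resize_map(m, 112)
    expect_equal(sum(rz), sum(m), tolerance = 1e-9)
    d <- downsample_sum(rz, 56)
    total_err <- max(total_err, abs(sum(d) - sum(m)) / sum(m))
  }
  expect_lt(total_err, 1e-6)
})

test_that("descriptors carry metadata and conserve in-mask relevance", {
  set.seed(12)
  maps <- list(matrix(runif(400), 20), matrix(runif(400), 20),
               matrix(runif(400), 20))
  masks <- replicate(3, matrix(TRUE, 20, 20), simplify = FALSE)
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         predicted_age = c(2L, 3L, 5L),
                         variant = "baseline")
  d <- make_descriptors(maps, masks, meta, out_size = 28)
  expect_identical(dim(d$mat), c(3L, 784L))
  expect_equal(rowSums(d$mat), vapply(maps, sum, 0), tolerance = 1e-6)
})

test_that("the affinity graph uses k = ceiling(ln n), symmetrised by union", {
  set.seed(13)
  x <- matrix(rnorm(100 * 5), 100)
  g <- build_affinity(x)
  expect_identical(g$k, 5L) # ceiling(ln 100)
  expect_identical(g$matrix, t(g$matrix))
  expect_true(all(diag(g$matrix) == 0))
  expect_true(all(rowSums(g$matrix > 0) >= g$k - 1))

  # three near-identical points plus a far outlier, k = 1: the outlier links
  # to its single nearest neighbour and the matrix stays symmetric
  y <- rbind(c(0, 0), c(0, 1e-3), c(1e-3, 0), c(100, 100))
  D <- as.matrix(dist(y)) # brute-force distance table
  g1 <- build_affinity(y, k = 1)
  nn_out <- which.min(D[4, -4])
  expect_equal(g1$matrix[4, nn_out], 1)
  expect_identical(g1$matrix, t(g1$matrix))
  expect_error(build_affinity(y[1:2, ]), "at least 3")
})

test_that("spectral clustering separates disconnected cliques exactly", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  g <- structure(list(matrix = A, k = 3, n = 8), class = "affinity_graph")
  labs <- spectral_cluster(g, 2, seed = 1)
  expect_length(unique(labs[1:4]), 1)
  expect_length(unique(labs[5:8]), 1)
  expect_false(labs[1] == labs[5])

  # more components than clusters: warn but proceed
  B <- matrix(0, 9, 9)
  B[1:3, 1:3] <- 1; B[4:6, 4:6] <- 1; B[7:9, 7:9] <- 1
  diag(B) <- 0
  gb <- structure(list(matrix = B, k = 2, n = 9), class = "affinity_graph")
  expect_warning(spectral_cluster(gb, 2, seed = 1), "components")
})

test_that("well-separated descriptor clouds are recovered with F1 = 1", {
  set.seed(14)
  cloud <- rbind(
    matrix(rnorm(50 * 10, mean = 0, sd = 1), 50),
    matrix(rnorm(50 * 10, mean = 20, sd = 1), 50)
  )
  groups <- rep(c("g1", "g2"), each = 50)
  g <- build_affinity(cloud)
  labs <- spectral_cluster(g, 2, seed = 3)
  expect_equal(clustering_f1(labs, groups), 1.0)

  # permutation invariance of the partition (up to label swap)
  perm <- sample(100)
  g2 <- build_affinity(cloud[perm, ])
  labs2 <- spectral_cluster(g2, 2, seed = 3)
  agree <- mean(labs2 == labs[perm])
  expect_true(agree %in% c(0, 1))
})

test_that("spectral clustering agrees with an independently built oracle", {
  # naive oracle: loop-built normalized Laplacian, eigenvectors of the two
  # smallest eigenvalues, row-normalised, exhaustive best 2-partition by
  # minimising within-cluster spread
  set.seed(15)
  for (rep in 1:5) {
    pts <- rbind(matrix(rnorm(8, 0, 0.3), 4), matrix(rnorm(8, 5, 0.3), 4))
    g <- build_affinity(pts, k = 2)
    A <- g$matrix
    n <- nrow(A)
    L <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      di <- sum(A[i, ]); dj <- sum(A[j, ])
      L[i, j] <- (i == j) - A[i, j] / sqrt(max(di, 1e-12) * max(dj, 1e-12))
    }
    ev <- eigen(L, symmetric = TRUE)
    U <- ev$vectors[, c(n - 1, n)]
    U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
    best <- NULL; best_val <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      asg <- as.integer(intToBits(code))[1:n]
      if (length(unique(asg)) < 2) next
      val <- sum(vapply(0:1, function(cl) {
        rows <- U[asg == cl, , drop = FALSE]
        sum(sweep(rows, 2, colMeans(rows))^2)
      }, 0))
      if (val < best_val) { best_val <- val; best <- asg }
    }
    got <- spectral_cluster(g, 2, seed = 5)
    expect_true(all(got == best) || all(got == 1 - best))
  }
})

test_that("F1 is matching- and order-invariant with the expected null level", {
  g <- rep(c("a", "b"), each = 10)
  perfect <- rep(c(0, 1), each = 10)
  expect_equal(clustering_f1(perfect, g), 1.0)
  expect_equal(clustering_f1(1 - perfect, g), 1.0)
  perm <- sample(20)
  expect_equal(clustering_f1(perfect[perm], g[perm]), 1.0)
  expect_error(clustering_f1(c(0, 1), c("a", "b", "a")), "equal length")

  set.seed(16)
  null_f1 <- replicate(50, clustering_f1(sample(rep(0:1, 100)),
                                         rep(c("a", "b"), each = 100)))
  expect_lt(abs(mean(null_f1) - 0.5), 0.1)
})

test_that("the t-SNE embedding is seeded, shaped, and keeps duplicates close", {
  set.seed(17)
  x <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4, 6), 30))
  x <- rbind(x, x[1, , drop = FALSE]) # duplicated descriptor
  g <- build_affinity(x)
  e1 <- embed_tsne(g, seed = 9, perplexity = 10)
  e2 <- embed_tsne(g, seed = 9, perplexity = 10)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$y, e2$y)
  expect_identical(dim(as.matrix(e1[, c("x", "y")])), c(61L, 2L))

  co <- as.matrix(e1[, c("x", "y")])
  dup_dist <- sqrt(sum((co[1, ] - co[61, ])^2))
  expect_lt(dup_dist, median(dist(co)))

  small <- structure(list(matrix = matrix(0, 3, 3), k = 1, n = 3),
                     class = "affinity_graph")
  expect_error(embed_tsne(small), "at least 5")
})
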