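# Relevance propagation: rule validation, hand-computed redistribution
# examples, oracle equivalence, conservation, non-negativity, and linearity.

test_that("rule parameters enforce alpha - beta = 1 with beta >= 0", {
  expect_error(rule_params(2, 0.5), "alpha - beta")
  expect_error(rule_params(0.5, -0.5), "alpha - beta")
  expect_error(rule_params(1, 0, stabilizer = -1), "stabilizer")
  p <- rule_params(2, 1)
  expect_equal(p$alpha, 2)
  expect_equal(p$beta, 1)
})

test_that("output relevance is the target logit and nothing else", {
  m <- rand_dense_model(c(4, 3, 2), seed = 1)$model
  tr <- forward(m, array(c(1, -1, 0.5, 2), 4))
  r <- init_relevance(tr, 2, m$class_labels)
  expect_equal(r, c(0, tr$logits[2]))
  expect_error(init_relevance(tr, 99, m$class_labels), "target class")
  # zero logit propagates an all-zero map
  m$layers[[3]]$W[] <- 0
  m$layers[[3]]$b[] <- 0
  map0 <- compute_relevance_map(m, array(c(1, -1, 0.5, 2), 4), target_class = 1)
  expect_true(all(map0$scores == 0))
})

test_that("dense redistribution matches hand-computed examples", {
  # two inputs with positive contributions 2:3 under one output neuron
  ly <- list(kind = "dense", W = matrix(c(2, 3), 1, 2), b = 0)
  r <- propagate_alphabeta(ly, c(1, 1), 1.0)
  expect_equal(r, c(0.4, 0.6), tolerance = 1e-6)

  # a = (1, 2), w = (0.5, 0.25): contributions (0.5, 0.5) -> split evenly
  ly2 <- list(kind = "dense", W = matrix(c(0.5, 0.25), 1, 2), b = 0)
  expect_equal(propagate_alphabeta(ly2, c(1, 2), 1.0), c(0.5, 0.5),
               tolerance = 1e-6)

  # all contributions negative with beta = 0: nothing to propagate
  ly3 <- list(kind = "dense", W = matrix(c(-1, -2), 1, 2), b = 0)
  expect_equal(propagate_alphabeta(ly3, c(1, 1), 1.0), c(0, 0))

  expect_error(propagate_alphabeta(list(kind = "relu"), 1, 1), "dense and conv")
})

test_that("pooling propagates winner-take-all with equal tie splitting", {
  ly <- list(kind = "maxpool", spec = layer_maxpool(2),
             pool_idx = build_im2col_test(4, 4))
  a <- array(0, c(4, 4, 1))
  a[1, 1, 1] <- 5 # unique max in the top-left window
  a[3:4, 3:4, 1] <- 2 # tied window
  r_up <- array(1, c(2, 2, 1))
  r_low <- propagate_pool(ly, a, r_up)
  expect_equal(r_low[1, 1, 1], 1)
  expect_equal(sum(r_low), sum(r_up))
  expect_equal(as.vector(r_low[3:4, 3:4, 1]), rep(0.25, 4))

  # flatten is a bijective pass-through
  lyf <- list(kind = "flatten")
  a2 <- array(runif(8), c(2, 2, 2))
  rf <- propagate_pool(lyf, a2, seq_len(8))
  expect_equal(as.vector(rf), as.numeric(1:8))
})

test_that("vectorized propagation equals the per-message oracle on tiny nets", {
  maxdiff <- 0
  for (rep in 1:20) {
    set.seed(rep + 300)
    dims <- c(sample(4:10, 1), sample(3:10, 1), sample(3:10, 1), sample(2:6, 1))
    rd <- rand_dense_model(dims, seed = rep + 400)
    x <- rnorm(dims[1])
    tgt <- sample(dims[length(dims)], 1)
    ab <- if (rep %% 2 == 0) c(2, 1) else c(1, 0)
    got <- compute_relevance_map(rd$model, array(x, dims[1]),
                                 target_class = tgt,
                                 params = rule_params(ab[1], ab[2]))
    want <- naive_dense_lrp(rd$Ws, rd$bs, x, tgt, ab[1], ab[2])
    maxdiff <- max(maxdiff, max(abs(as.vector(got$scores) - want)))
  }
  expect_lt(maxdiff, 1e-9)
})

test_that("conv propagation equals the oracle via the dense equivalent", {
  for (rep in 1:5) {
    set.seed(rep + 500)
    m <- build_network(
      c(4, 4, 1),
      list(layer_conv(2, kernel = 2, pad = 0), layer_relu(),
           layer_flatten(), layer_dense(3)),
      class_labels = 1:3, seed = rep + 600
    )
    m$layers[[1]]$b[] <- 0
    m$layers[[4]]$b[] <- 0
    x <- array(rnorm(16), c(4, 4, 1))
    tgt <- sample(3, 1)
    got <- compute_relevance_map(m, x, target_class = tgt)
    Wd <- conv_as_dense(m$layers[[1]])
    want <- naive_dense_lrp(list(Wd, m$layers[[4]]$W),
                            list(rep(0, nrow(Wd)), m$layers[[4]]$b),
                            as.vector(x), tgt)
    expect_lt(max(abs(as.vector(got$scores) - want)), 1e-9)
  }
})

test_that("relevance is conserved exactly for bias-free activating networks", {
  for (rep in 1:5) {
    set.seed(rep + 700)
    m <- build_network(
      c(6, 6, 1),
      list(layer_conv(3), layer_relu(), layer_maxpool(2),
           layer_flatten(), layer_dense(4)),
      class_labels = 1:4, seed = rep
    )
    m$layers[[1]]$W <- abs(m$layers[[1]]$W)
    m$layers[[1]]$b[] <- 0
    m$layers[[5]]$W <- abs(m$layers[[5]]$W)
    m$layers[[5]]$b[] <- 0
    x <- array(runif(36), c(6, 6, 1))
    map <- compute_relevance_map(m, x, target_class = 2)
    rep_c <- audit_conservation(map)
    expect_lt(rep_c$max_rel_deviation, 1e-6)
    expect_equal(sum(map$scores), map$logit, tolerance = 1e-6)
  }
})

test_that("biased networks leak relevance into a report, not an error", {
  set.seed(801)
  m <- rand_dense_model(c(5, 4, 3), seed = 801)$model
  map <- compute_relevance_map(m, array(runif(5), 5), target_class = 1)
  expect_s3_class(audit_conservation(map), "conservation_report")
  # all-zero map with zero logit has deviation 0
  m$layers[[3]]$W[] <- 0
  m$layers[[3]]$b[] <- 0
  map0 <- compute_relevance_map(m, array(runif(5), 5), target_class = 1)
  expect_equal(audit_conservation(map0)$max_rel_deviation, 0)
})

test_that("activating-only maps are non-negative on ReLU nets", {
  set.seed(802)
  m <- default_architecture(c(20, 20, 1), 1:4, conv_filters = 4,
                            dense_units = 6, seed = 802)
  for (i in 1:10) {
    x <- matrix(runif(400), 20, 20)
    map <- compute_relevance_map(m, x)
    if (map$logit >= 0) expect_gte(min(map$scores), 0)
  }
})

test_that("propagation is linear in the initial relevance", {
  set.seed(803)
  rd <- rand_dense_model(c(5, 4, 3), seed = 803)
  x <- rnorm(5)
  tr <- forward(rd$model, array(x, 5))
  r1 <- init_relevance(tr, 2, rd$model$class_labels)
  prop <- function(r) {
    for (i in rev(seq_along(rd$model$layers))) {
      ly <- rd$model$layers[[i]]
      a_in <- if (i == 1) tr$input else tr$acts[[i - 1]]
      r <- if (ly$kind %in% c("dense", "conv")) {
        propagate_alphabeta(ly, a_in, r)
      } else {
        r
      }
    }
    r
  }
  expect_equal(prop(3 * r1), 3 * prop(r1), tolerance = 1e-12)
})
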