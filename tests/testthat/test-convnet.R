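# Forward pass exactness, augmentation, normalisation, training and
# prediction of the miniature convolutional classifier.

test_that("forward pass matches a per-neuron loop oracle on tiny dense nets", {
  for (rep in 1:10) {
    set.seed(rep)
    dims <- c(sample(4:10, 1), sample(3:10, 1), sample(3:10, 1), sample(2:6, 1))
    rd <- rand_dense_model(dims, seed = rep + 100)
    x <- rnorm(dims[1])
    tr <- forward(rd$model, array(x, dims[1]))
    expect_lt(max(abs(tr$logits - naive_dense_forward(rd$Ws, rd$bs, x))), 1e-9)
  }
})

test_that("an all-ones 2x2 kernel on an all-ones 3x3 input yields 4 everywhere", {
  m <- build_network(c(3, 3, 1),
                     list(layer_conv(1, kernel = 2, pad = 0),
                          layer_flatten(), layer_dense(1)),
                     class_labels = 1, seed = 1)
  m$layers[[1]]$W[] <- 1
  m$layers[[1]]$b[] <- 0
  out <- forward(m, matrix(1, 3, 3))$acts[[1]]
  expect_equal(as.vector(out), rep(4, 4))
})

test_that("forward conv/pool stack matches the brute-force conv oracle", {
  set.seed(3)
  m <- build_network(
    c(6, 6, 2),
    list(layer_conv(3, kernel = 3, pad = 1), layer_relu(),
         layer_maxpool(2), layer_flatten(), layer_dense(4)),
    class_labels = 1:4, seed = 3
  )
  x <- array(runif(72), c(6, 6, 2))
  tr <- forward(m, x)
  bf <- brute_conv(x, m$layers[[1]]$W, m$layers[[1]]$b, 3, 1)
  expect_lt(max(abs(tr$acts[[1]] - bf)), 1e-12)
  # ReLU zeroes negatives
  expect_true(all(tr$acts[[2]] >= 0))
  expect_equal(tr$acts[[2]], pmax(tr$acts[[1]], 0))
  # max-pool picks window maxima
  expect_equal(tr$acts[[3]][1, 1, 1], max(tr$acts[[2]][1:2, 1:2, 1]))
})

test_that("dense identity layer reproduces its input as logits", {
  m <- build_network(3, list(layer_dense(3)), class_labels = 1:3, seed = 1)
  m$layers[[1]]$W <- diag(3)
  m$layers[[1]]$b[] <- 0
  v <- c(0.3, -1.2, 2.5)
  expect_equal(forward(m, array(v, 3))$logits, v)
  expect_error(forward(m, array(1, 4)), "shape")
})

test_that("augmentation respects the identity, zero and range contracts", {
  set.seed(4)
  img <- render_baseline(sample_shape_params(5, 56), 56, "x")$image
  expect_identical(augment(img, angle = 0, flip_h = FALSE, flip_v = FALSE,
                           shift = 0), img)
  z <- matrix(0, 56, 56)
  for (i in 1:5) {
    set.seed(i)
    expect_identical(augment(z), z)
  }
  expect_identical(
    augment(img, angle = 360, flip_h = FALSE, flip_v = FALSE, shift = 0,
            filter = "none"),
    img
  )
  set.seed(5)
  a <- augment(img)
  expect_identical(dim(a), dim(img))
  expect_true(all(a >= 0 & a <= 1))
  # flips and shift are exact index operations
  expect_identical(augment(img, 0, TRUE, FALSE, 0), img[, 56:1])
  expect_identical(augment(img, 0, FALSE, TRUE, 0), img[56:1, ])
  expect_identical(augment(img, 0, FALSE, FALSE, 3)[4:56, ], img[1:53, ])
})

test_that("quarter-turn rotation matches the exact array rotation", {
  set.seed(6)
  img <- matrix(runif(16 * 16), 16, 16)
  r90 <- augment(img, angle = 90, flip_h = FALSE, flip_v = FALSE, shift = 0,
                 filter = "none")
  # independent oracle: a quarter turn is a transpose plus a flip
  ok <- isTRUE(all.equal(r90, t(img)[, 16:1], tolerance = 1e-12)) ||
    isTRUE(all.equal(r90, t(img[, 16:1]), tolerance = 1e-12))
  expect_true(ok)
})

test_that("normalisation uses training statistics and flags degenerate channels", {
  set.seed(7)
  samples <- generate_dataset(3, ages = 1:3, canvas_size = 40, seed = 3)$train
  st <- normalization_stats(samples)
  px <- unlist(lapply(samples, function(s) as.vector(apply_normalization(s$image, st))))
  expect_lt(abs(mean(px)), 1e-6)
  expect_lt(abs(sd(px) - 1), 1e-6)
  # constant image at the mean maps to zero
  expect_equal(apply_normalization(matrix(st$mean, 4, 4), st),
               matrix(0, 4, 4))
  flat <- samples[1]
  flat[[1]]$image[] <- 0.5
  expect_error(normalization_stats(flat), "degenerate")
  expect_error(apply_normalization(matrix(1, 2, 2), list(mean = 0, sd = 0)),
               "degenerate")
})

test_that("prediction takes the argmax with lowest-age tie-break", {
  m <- build_network(3, list(layer_dense(5)), class_labels = 3:7, seed = 1)
  m$layers[[1]]$W[] <- 0
  m$layers[[1]]$b <- c(0, 2, 2, 1, 0) # tie between classes 4 and 5
  expect_identical(predict_age(m, array(0, 3))$age, 4L)
  # untrained random model predicts within the label range
  set.seed(8)
  m2 <- default_architecture(c(40, 40, 1), 1:26, conv_filters = c(4, 8),
                             dense_units = 8, seed = 8)
  p <- predict_age(m2, matrix(runif(1600), 40, 40))
  expect_true(p$age %in% 1:26)
  expect_length(p$logits, 26)
})

test_that("training separates a linearly separable two-class toy problem", {
  # class 1: bright left half; class 2: bright right half
  set.seed(9)
  mk <- function(cls, id) {
    img <- matrix(0.1, 8, 8) + matrix(rnorm(64, 0, 0.01), 8, 8)
    if (cls == 1) img[, 1:4] <- img[, 1:4] + 0.7 else img[, 5:8] <- img[, 5:8] + 0.7
    structure(list(image = pmin(pmax(img, 0), 1),
                   mask = matrix(TRUE, 8, 8), age = as.integer(cls),
                   variant = "baseline", params = NULL,
                   sample_id = paste0("t", id)),
              class = "otolith_sample")
  }
  samples <- c(lapply(1:10, function(i) mk(1, i)),
               lapply(11:20, function(i) mk(2, i)))
  m <- build_network(c(8, 8, 1),
                     list(layer_flatten(), layer_dense(2)),
                     class_labels = 1:2, seed = 9)
  m <- train_network(m, samples,
                     train_config(epochs = 20, learning_rate = 0.01,
                                  seed = 9, augment = FALSE))
  preds <- vapply(samples, function(s) predict_age(m, s$image)$age, 0L)
  expect_identical(preds, vapply(samples, `[[`, 0L, "age"))
  expect_lt(m$train_log$loss[20], m$train_log$loss[1])
})

test_that("training is reproducible and frozen at zero learning rate", {
  ds <- generate_dataset(3, ages = 1:2, canvas_size = 40, seed = 10)
  arch <- function() default_architecture(c(40, 40, 1), 1:2,
                                          conv_filters = 4, dense_units = 8,
                                          seed = 10)
  cfg <- train_config(epochs = 2, seed = 11, augment = TRUE)
  m1 <- train_network(arch(), ds, cfg)
  m2 <- train_network(arch(), ds, cfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$train_log, m2$train_log)

  m0 <- arch()
  mz <- train_network(m0, ds, train_config(epochs = 1, learning_rate = 0,
                                           seed = 12, augment = FALSE))
  for (i in seq_along(m0$layers)) {
    expect_identical(mz$layers[[i]]$W, m0$layers[[i]]$W)
    expect_identical(mz$layers[[i]]$b, m0$layers[[i]]$b)
  }
  expect_error(train_network(arch(), list(), cfg), "empty")
})

test_that("the trained default model clearly beats chance on the easy regime", {
  rep <- cached_default_report()
  pr <- rep$predictions
  te <- pr[pr$variant == "baseline" & pr$split == "test", ]
  acc <- mean(te$read_age == te$predicted_age)
  n_classes <- length(unique(pr$read_age))
  expect_gte(acc, 5 / n_classes)
  # and the training loss decreased
  lg <- rep$train_log[rep$train_log$variant == "baseline", ]
  expect_lt(lg$loss[nrow(lg)], lg$loss[1])
})
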