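# Augmentation, normalisation, and gradient training of the miniature
# convolutional classifier.

#' Augment one image
#'
#' Applies the on-the-fly training augmentation: rotation uniform in
#' [0, 360) degrees, independent horizontal and vertical flips each with
#' probability 0.5, and a vertical shift uniform over the integers in
#' [-10, 10] pixels. Missing arguments are drawn from the current RNG
#' stream; passing them explicitly makes the transform deterministic.
#' Output has the same shape, values clamped to [0, 1]; exposed pixels are
#' filled with zero.
#'
#' @param image matrix in [0,1].
#' @param angle rotation in degrees (counter-clockwise).
#' @param flip_h,flip_v logical flips across the vertical / horizontal axis.
#' @param shift integer vertical shift in pixels (positive = down).
#' @param filter interpolation for the rotation, `"bilinear"` or `"none"`.
#' @return matrix of the same dimensions.
#' @export
augment <- function(image, angle = NULL, flip_h = NULL, flip_v = NULL,
                    shift = NULL, filter = "bilinear") {
  if (is.null(angle)) angle <- stats::runif(1, 0, 360)
  if (is.null(flip_h)) flip_h <- stats::runif(1) < 0.5
  if (is.null(flip_v)) flip_v <- stats::runif(1) < 0.5
  if (is.null(shift)) shift <- sample(-10:10, 1)
  d <- dim(image)
  out <- image
  if (angle %% 360 != 0) {
    out <- EBImage::rotate(out, angle, filter = filter,
                           output.dim = d, bg.col = 0)
    out <- matrix(out, d[1], d[2])
  }
  if (flip_h) out <- out[, rev(seq_len(d[2]))]
  if (flip_v) out <- out[rev(seq_len(d[1])), ]
  if (shift != 0) {
    shifted <- matrix(0, d[1], d[2])
    src <- seq_len(d[1]) - shift
    ok <- src >= 1 & src <= d[1]
    shifted[which(ok), ] <- out[src[ok], ]
    out <- shifted
  }
  clamp01(out)
}

#' Channel normalisation statistics from training images
#'
#' @param samples list of `otolith_sample` (the training set).
#' @return list with `mean` and `sd` of all training pixels.
#' @export
normalization_stats <- function(samples) {
  px <- unlist(lapply(samples, function(s) as.vector(s$image)))
  s <- stats::sd(px)
  if (s == 0) stop("degenerate channel: zero standard deviation", call. = FALSE)
  list(mean = mean(px), sd = s)
}

#' Apply channel normalisation
#'
#' Subtracts the training-set mean and divides by the training-set standard
#' deviation. The same statistics are applied to train and test images.
#'
#' @param image matrix.
#' @param stats list with `mean` and `sd` (from [normalization_stats()]).
#' @export
apply_normalization <- function(image, stats) {
  if (stats$sd == 0) stop("degenerate channel: zero standard deviation", call. = FALSE)
  (image - stats$mean) / stats$sd
}

#' Training configuration
#'
#' The recipe: adaptive-moment (Adam) optimiser over the softmax
#' cross-entropy loss, batch size 8, learning rate 4e-4, augmentation on
#' the fly. Epoch count is problem-dependent and set by the caller.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param epochs passes over the training set.
#' @param seed seed governing shuffling, augmentation draws.
#' @param augment whether to augment each image on the fly.
#' @export
train_config <- function(batch_size = 8, learning_rate = 4e-4, epochs = 10,
                         seed = 1, augment = TRUE) {
  stopifnot(batch_size >= 1, learning_rate >= 0)
  list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
       epochs = as.integer(epochs), seed = as.integer(seed),
       augment = isTRUE(augment))
}

# backward pass: gradient of the loss w.r.t. every parameter, given the
# trace and the gradient at the logits
backward <- function(model, trace, g) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    a_in <- layer_input(trace, i)
    if (ly$kind == "dense") {
      grads[[i]] <- list(W = g %o% a_in, b = g)
      g <- as.vector(crossprod(ly$W, g))
    } else if (ly$kind == "relu") {
      g <- g * (a_in > 0)
    } else if (ly$kind == "flatten") {
      dim(g) <- trace$extras[[i]]$in_dim
    } else if (ly$kind == "maxpool") {
      ex <- trace$extras[[i]]
      d <- ex$in_dim
      gout <- matrix(g, nrow(ly$pool_idx), d[3])
      gin <- array(0, d)
      plane_len <- d[1] * d[2]
      for (ch in seq_len(d[3])) {
        lin <- ly$pool_idx[cbind(seq_len(nrow(ly$pool_idx)), ex$amax[, ch])]
        gin[lin + (ch - 1L) * plane_len] <- gout[, ch]
      }
      g <- gin
    } else if (ly$kind == "conv") {
      G <- matrix(g, nrow(trace$extras[[i]]$P), ly$spec$filters)
      grads[[i]] <- list(W = crossprod(trace$extras[[i]]$P, G),
                         b = colSums(G))
      g <- col2im(G %*% t(ly$W), ly$geom)
    }
  }
  grads
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train the network
#'
#' Mini-batch Adam on the softmax cross-entropy loss with on-the-fly
#' augmentation. Normalisation statistics are computed from the training
#' set and stored on the model so prediction normalises identically. Fully
#' seeded: the same `(model, dataset, config)` yields identical weights.
#'
#' @param model a `network_model` from [build_network()].
#' @param ds a `dataset_split` (only `ds$train` is used) or list of
#'   `otolith_sample`.
#' @param config a [train_config()].
#' @return the trained `network_model`, with a `train_log` tibble
#'   (`epoch`, `loss`, `accuracy`) attached.
#' @export
train_network <- function(model, ds, config = train_config()) {
  samples <- if (inherits(ds, "dataset_split")) ds$train else ds
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  labels <- match(vapply(samples, `[[`, 0L, "age"), model$class_labels)
  if (anyNA(labels)) stop("sample age not among model class labels", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  model$norm_stats <- normalization_stats(samples)

  # Adam state
  mstate <- lapply(model$layers, function(l) {
    if (is.null(l$W)) NULL else list(mW = 0 * l$W, vW = 0 * l$W,
                                     mb = 0 * l$b, vb = 0 * l$b)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  n <- length(samples)
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    total_loss <- 0
    n_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, n)]
      acc <- NULL
      for (j in batch) {
        img <- samples[[j]]$image
        if (config$augment) img <- augment(img)
        img <- apply_normalization(img, model$norm_stats)
        tr <- forward(model, img)
        p <- softmax(tr$logits)
        y <- labels[j]
        total_loss <- total_loss - log(max(p[y], 1e-12))
        n_correct <- n_correct + (which.max(tr$logits) == y)
        gl <- p
        gl[y] <- gl[y] - 1
        gr <- backward(model, tr, gl)
        if (is.null(acc)) {
          acc <- gr
        } else {
          for (i in seq_along(gr)) {
            if (!is.null(gr[[i]])) {
              acc[[i]]$W <- acc[[i]]$W + gr[[i]]$W
              acc[[i]]$b <- acc[[i]]$b + gr[[i]]$b
            }
          }
        }
      }
      nb <- length(batch)
      t_step <- t_step + 1
      for (i in seq_along(model$layers)) {
        if (is.null(acc[[i]])) next
        gW <- acc[[i]]$W / nb
        gb <- acc[[i]]$b / nb
        st <- mstate[[i]]
        st$mW <- beta1 * st$mW + (1 - beta1) * gW
        st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
        st$mb <- beta1 * st$mb + (1 - beta1) * gb
        st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
        mhatW <- st$mW / (1 - beta1^t_step)
        vhatW <- st$vW / (1 - beta2^t_step)
        mhatb <- st$mb / (1 - beta1^t_step)
        vhatb <- st$vb / (1 - beta2^t_step)
        model$layers[[i]]$W <- model$layers[[i]]$W -
          config$learning_rate * mhatW / (sqrt(vhatW) + eps)
        model$layers[[i]]$b <- model$layers[[i]]$b -
          config$learning_rate * mhatb / (sqrt(vhatb) + eps)
        mstate[[i]] <- st
      }
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, loss = total_loss / n,
                                   accuracy = n_correct / n)
  }
  model$train_log <- dplyr::bind_rows(log)
  model
}
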