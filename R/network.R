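#' Layer specifications
#'
#' Constructors for the five layer kinds of the miniature convolutional
#' classifier: `conv` (2-D convolution, zero padding), `relu`, `maxpool`
#' (non-overlapping), `flatten` and `dense`. A network is an ordered stack
#' of these; the final layer must be dense with one unit per age class.
#'
#' @param filters number of convolution filters.
#' @param kernel odd kernel side length.
#' @param pad zero-padding width (default keeps spatial size for stride 1).
#' @param size pooling window (and stride).
#' @param units dense output units.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv <- function(filters, kernel = 3, pad = (kernel - 1) / 2) {
  structure(list(kind = "conv", filters = as.integer(filters),
                 kernel = as.integer(kernel), pad = as.integer(pad)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_relu <- function() structure(list(kind = "relu"), class = "layer_spec")

#' @rdname layer_spec
#' @export
layer_maxpool <- function(size = 2) {
  structure(list(kind = "maxpool", size = as.integer(size)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_flatten <- function() structure(list(kind = "flatten"), class = "layer_spec")

#' @rdname layer_spec
#' @export
layer_dense <- function(units) {
  structure(list(kind = "dense", units = as.integer(units)),
            class = "layer_spec")
}

# --- im2col machinery -------------------------------------------------------
# For a conv layer on an (H, W, C) input with kernel k and zero padding p,
# precompute the linear indices into the zero-padded array that extract the
# (out_h*out_w) x (k*k*C) patch matrix. Stride is 1.
build_im2col <- function(h, w, c, k, p) {
  hp <- h + 2L * p
  wp <- w + 2L * p
  out_h <- hp - k + 1L
  out_w <- wp - k + 1L
  # patch top-left corners, column-major over (out_h, out_w)
  or_ <- rep(seq_len(out_h), times = out_w)
  oc_ <- rep(seq_len(out_w), each = out_h)
  # offsets within a patch: (k, k, c) column-major
  dr <- rep(seq_len(k) - 1L, times = k * c)
  dc <- rep(rep(seq_len(k) - 1L, each = k), times = c)
  dch <- rep(seq_len(c) - 1L, each = k * k)
  idx <- matrix(0L, out_h * out_w, k * k * c)
  for (j in seq_len(k * k * c)) {
    idx[, j] <- (or_ + dr[j]) + (oc_ + dc[j] - 1L) * hp + dch[j] * hp * wp
  }
  list(idx = idx, hp = hp, wp = wp, out_h = out_h, out_w = out_w,
       h = h, w = w, c = c, k = k, p = p)
}

pad_array <- function(a, p) {
  if (p == 0) return(a)
  d <- dim(a)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- a
  out
}

unpad_array <- function(a, p, h, w) {
  if (p == 0) return(a)
  a[p + seq_len(h), p + seq_len(w), , drop = FALSE]
}

im2col <- function(a, geom) {
  ap <- pad_array(a, geom$p)
  m <- ap[geom$idx]
  dim(m) <- dim(geom$idx)
  m
}

# scatter-add a patch-shaped matrix back onto the (padded) input grid
col2im <- function(m, geom) {
  acc <- numeric(geom$hp * geom$wp * geom$c)
  s <- rowsum(as.vector(m), group = as.vector(geom$idx))
  acc[as.integer(rownames(s))] <- s
  a <- array(acc, c(geom$hp, geom$wp, geom$c))
  unpad_array(a, geom$p, geom$h, geom$w)
}

# --- network construction ---------------------------------------------------

#' Build a network model
#'
#' Assembles an introspectable feed-forward network from layer specs,
#' computing every intermediate shape and initialising weights (He-scaled
#' Gaussian) and zero biases from the current RNG stream. Convolution
#' patch-extraction indices are precomputed per layer, so the input shape is
#' fixed at build time.
#'
#' @param input_shape `c(h, w, channels)` of the input image.
#' @param layers list of [layer_spec] objects; the last must be `dense`.
#' @param class_labels integer vector of age labels, one per output unit of
#'   the final dense layer.
#' @param seed integer seed for weight initialisation.
#' @return a `network_model`: list of layers, each holding its spec, shapes,
#'   and (for conv/dense) weights `W` and biases `b`; plus `class_labels`
#'   and, after [train_network()], `norm_stats` and `train_log`.
#' @export
build_network <- function(input_shape, layers, class_labels, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  shape <- input_shape # c(h, w, c) or scalar length after flatten
  built <- list()
  for (i in seq_along(layers)) {
    sp <- layers[[i]]
    ly <- list(kind = sp$kind, spec = sp, in_shape = shape)
    if (sp$kind == "conv") {
      stopifnot(length(shape) == 3)
      geom <- build_im2col(shape[1], shape[2], shape[3], sp$kernel, sp$pad)
      fan_in <- sp$kernel^2 * shape[3]
      ly$W <- matrix(stats::rnorm(fan_in * sp$filters, 0, sqrt(2 / fan_in)),
                     fan_in, sp$filters)
      ly$b <- numeric(sp$filters)
      ly$geom <- geom
      shape <- c(geom$out_h, geom$out_w, sp$filters)
    } else if (sp$kind == "relu") {
      # shape unchanged
    } else if (sp$kind == "maxpool") {
      stopifnot(length(shape) == 3)
      if (shape[1] %% sp$size != 0 || shape[2] %% sp$size != 0) {
        stop("maxpool input not divisible by pool size", call. = FALSE)
      }
      ly$geom <- build_im2col(shape[1], shape[2], 1L, sp$size, 0L)
      # pooling uses stride = size: subset the stride-1 patches
      keep_r <- seq(1L, shape[1] - sp$size + 1L, by = sp$size)
      keep_c <- seq(1L, shape[2] - sp$size + 1L, by = sp$size)
      sel <- as.vector(outer(keep_r, (keep_c - 1L) * ly$geom$out_h, `+`))
      ly$pool_idx <- ly$geom$idx[sel, , drop = FALSE]
      ly$out_hw <- c(shape[1] %/% sp$size, shape[2] %/% sp$size)
      shape <- c(ly$out_hw, shape[3])
    } else if (sp$kind == "flatten") {
      shape <- prod(shape)
    } else if (sp$kind == "dense") {
      stopifnot(length(shape) == 1)
      ly$W <- matrix(stats::rnorm(sp$units * shape, 0, sqrt(2 / shape)),
                     sp$units, shape)
      ly$b <- numeric(sp$units)
      shape <- sp$units
    } else {
      stop("unsupported layer kind: ", sp$kind, call. = FALSE)
    }
    ly$out_shape <- shape
    built[[i]] <- ly
  }
  last <- built[[length(built)]]
  if (last$kind != "dense" || last$out_shape != length(class_labels)) {
    stop("final layer must be dense with one unit per class", call. = FALSE)
  }
  structure(
    list(layers = built, class_labels = as.integer(class_labels),
         input_shape = input_shape, norm_stats = NULL, train_log = NULL),
    class = "network_model"
  )
}

#' Default miniature VGG-style architecture
#'
#' Stacks conv(3x3)+relu+maxpool(2) blocks followed by a hidden dense+relu
#' layer and the classification head. Input height/width must be divisible
#' by `2^length(conv_filters)`.
#'
#' @param input_shape `c(h, w, c)`.
#' @param class_labels age labels for the output units.
#' @param conv_filters filters per block.
#' @param dense_units hidden dense width.
#' @param seed seed for initialisation.
#' @export
default_architecture <- function(input_shape, class_labels,
                                 conv_filters = c(8, 16), dense_units = 32,
                                 seed = 1) {
  layers <- list()
  for (f in conv_filters) {
    layers <- c(layers, list(layer_conv(f), layer_relu(), layer_maxpool(2)))
  }
  layers <- c(layers, list(layer_flatten(), layer_dense(dense_units),
                           layer_relu(), layer_dense(length(class_labels))))
  build_network(input_shape, layers, class_labels, seed = seed)
}

#' @export
print.network_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("<network_model> %d layers, %d classes, %d parameters%s\n",
              length(x$layers), length(x$class_labels), np,
              if (is.null(x$train_log)) " (untrained)" else ""))
  for (l in x$layers) {
    cat(sprintf("  %-8s %s -> %s\n", l$kind,
                paste(l$in_shape, collapse = "x"),
                paste(l$out_shape, collapse = "x")))
  }
  invisible(x)
}

# --- forward pass -----------------------------------------------------------

#' Forward pass with full activation trace
#'
#' Runs the network on one image and records the input and output
#' activations of every layer, plus conv patch matrices and maxpool argmax
#' structure, so that backpropagation and relevance propagation can replay
#' the pass exactly. Deterministic.
#'
#' @param model a `network_model`.
#' @param image matrix (h x w) or array (h x w x c) matching the model input.
#' @return an `activation_trace`: list with `input`, per-layer `acts`
#'   (output of each layer), `extras` (cached patches / pool indices) and
#'   `logits`.
#' @export
forward <- function(model, image) {
  a <- as_input_array(model, image)
  acts <- vector("list", length(model$layers))
  extras <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "conv") {
      P <- im2col(a, ly$geom)
      Z <- P %*% ly$W
      Z <- sweep(Z, 2, ly$b, `+`)
      a <- array(Z, c(ly$geom$out_h, ly$geom$out_w, ly$spec$filters))
      extras[[i]] <- list(P = P)
    } else if (ly$kind == "relu") {
      a <- pmax(a, 0)
    } else if (ly$kind == "maxpool") {
      d <- dim(a)
      np <- nrow(ly$pool_idx)
      out <- array(0, c(ly$out_hw, d[3]))
      amax <- matrix(0L, np, d[3]) # argmax linear index per window/channel
      for (ch in seq_len(d[3])) {
        plane <- a[, , ch]
        Pm <- plane[ly$pool_idx]
        dim(Pm) <- dim(ly$pool_idx)
        mx <- do.call(pmax, as.data.frame(Pm))
        out[, , ch] <- mx
        amax[, ch] <- max.col(Pm, ties.method = "first")
      }
      extras[[i]] <- list(in_dim = d, amax = amax)
      a <- out
    } else if (ly$kind == "flatten") {
      extras[[i]] <- list(in_dim = dim(a))
      a <- as.vector(a)
    } else if (ly$kind == "dense") {
      a <- as.vector(ly$W %*% a + ly$b)
    }
    acts[[i]] <- a
  }
  structure(
    list(input = as_input_array(model, image), acts = acts, extras = extras,
         logits = acts[[length(acts)]]),
    class = "activation_trace"
  )
}

as_input_array <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!all(dim(image) == model$input_shape)) {
    stop("image shape does not match model input shape", call. = FALSE)
  }
  image
}

# activation feeding layer i (the model input for i = 1)
layer_input <- function(trace, i) {
  if (i == 1) trace$input else trace$acts[[i - 1]]
}

#' Predict the age of one otolith image
#'
#' Runs a forward pass and returns the argmax class label; ties are broken
#' toward the lowest age so predictions are deterministic. If the model
#' carries normalisation statistics they are applied first.
#'
#' @param model a trained or untrained `network_model`.
#' @param image input image matrix in [0,1] (un-normalised).
#' @return list with `age` (integer label) and `logits` (named numeric).
#' @export
predict_age <- function(model, image) {
  if (!is.null(model$norm_stats)) {
    image <- apply_normalization(image, model$norm_stats)
  }
  tr <- forward(model, image)
  logits <- stats::setNames(tr$logits, model$class_labels)
  list(age = model$class_labels[which.max(tr$logits)], logits = logits)
}

#' Predict ages for a whole dataset split
#'
#' @param model a `network_model`.
#' @param ds a `dataset_split` (or list of `otolith_sample`).
#' @return tibble with `sample_id`, `read_age`, `predicted_age`, `variant`,
#'   `split`.
#' @export
predict_dataset <- function(model, ds) {
  one <- function(samples, split) {
    if (length(samples) == 0) return(tibble::tibble())
    tibble::tibble(
      sample_id = vapply(samples, `[[`, "", "sample_id"),
      read_age = vapply(samples, `[[`, 0L, "age"),
      predicted_age = vapply(samples, function(s) {
        as.integer(predict_age(model, s$image)$age)
      }, 0L),
      variant = vapply(samples, `[[`, "", "variant"),
      split = split
    )
  }
  if (inherits(ds, "dataset_split")) {
    dplyr::bind_rows(one(ds$train, "train"), one(ds$test, "test"))
  } else {
    one(ds, "train")
  }
}
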