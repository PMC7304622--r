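# Layer-wise relevance propagation: generic message passing, the
# alpha-beta rule, and its alpha=1/beta=0 special case.

#' Relevance-rule parameters
#'
#' Parameters of the alpha-beta redistribution rule. `alpha` scales the
#' positive (activating) contributions and `beta` the negative (inhibiting)
#' ones, constrained to `alpha - beta = 1` with `beta >= 0`; `beta = 0`
#' gives the rule that propagates activating evidence only. A small
#' stabilizer guards denominators that would otherwise be zero.
#'
#' @param alpha,beta rule scalars with `alpha - beta = 1`, `beta >= 0`.
#' @param stabilizer small positive value added to denominators.
#' @export
rule_params <- function(alpha = 1, beta = 0, stabilizer = 1e-9) {
  if (abs(alpha - beta - 1) > 1e-12 || beta < 0) {
    stop("rule parameters must satisfy alpha - beta = 1 and beta >= 0",
         call. = FALSE)
  }
  if (stabilizer < 0) stop("stabilizer must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, stabilizer = stabilizer),
            class = "rule_params")
}

#' Initialise output-layer relevance
#'
#' The relevance propagated into the network is the pre-softmax logit of
#' the target class: a vector that equals that logit at the target class
#' position and zero elsewhere.
#'
#' @param trace an `activation_trace` from [forward()].
#' @param target_class age label whose evidence is propagated.
#' @param class_labels the model's class labels.
#' @return numeric relevance vector over the output units.
#' @export
init_relevance <- function(trace, target_class, class_labels) {
  k <- match(target_class, class_labels)
  if (is.na(k)) stop("target class not among model classes", call. = FALSE)
  r <- numeric(length(trace$logits))
  r[k] <- trace$logits[k]
  r
}

# positive / negative parts of sums of elementwise products:
# sum_i (a_i w_i)^+ = a^+ . w^+ + a^- . w^-  (same-sign products)
# sum_i (a_i w_i)^- = a^+ . w^- + a^- . w^+

#' Propagate relevance through a dense or convolutional layer
#'
#' Applies the alpha-beta rule: each upper-layer unit's relevance is split
#' among its inputs in proportion to the positive parts (and, weighted by
#' `-beta`, the negative parts) of the contributions `a_i * w_ij`, each
#' normalised by the corresponding layer-wise sum. Bias terms take no
#' relevance. With `beta = 0` this reduces to redistribution over
#' activating contributions only.
#'
#' @param layer one element of `model$layers` (kind `dense` or `conv`).
#' @param a_in the layer's input activations from the same forward pass.
#' @param r_up relevance of the layer's output units (vector or array).
#' @param params a [rule_params()].
#' @return relevance of the layer's input units, same shape as `a_in`.
#' @export
propagate_alphabeta <- function(layer, a_in, r_up, params = rule_params()) {
  eps <- params$stabilizer
  if (layer$kind == "dense") {
    a <- as.vector(a_in)
    ap <- pmax(a, 0); an <- pmin(a, 0)
    Wp <- pmax(layer$W, 0); Wn <- pmin(layer$W, 0)
    zp <- as.vector(Wp %*% ap + Wn %*% an) # sum_i (a w)^+ per output
    rp <- r_up / (zp + eps)
    r_low <- params$alpha * (ap * as.vector(crossprod(Wp, rp)) +
                             an * as.vector(crossprod(Wn, rp)))
    if (params$beta > 0) {
      zn <- as.vector(Wn %*% ap + Wp %*% an) # sum_i (a w)^- (<= 0)
      rn <- r_up / (zn - eps)
      r_low <- r_low - params$beta *
        (ap * as.vector(crossprod(Wn, rn)) +
         an * as.vector(crossprod(Wp, rn)))
    }
    r_low
  } else if (layer$kind == "conv") {
    P <- im2col(a_in, layer$geom)
    Pp <- pmax(P, 0); Pn <- pmin(P, 0)
    Wp <- pmax(layer$W, 0); Wn <- pmin(layer$W, 0)
    Zp <- Pp %*% Wp + Pn %*% Wn # (patches x filters)
    R <- matrix(r_up, nrow(P), layer$spec$filters)
    Ratio <- R / (Zp + eps)
    M <- params$alpha * (Pp * (Ratio %*% t(Wp)) + Pn * (Ratio %*% t(Wn)))
    if (params$beta > 0) {
      Zn <- Pp %*% Wn + Pn %*% Wp
      Ration <- R / (Zn - eps)
      M <- M - params$beta *
        (Pp * (Ration %*% t(Wn)) + Pn * (Ration %*% t(Wp)))
    }
    col2im(M, layer$geom)
  } else {
    stop("propagate_alphabeta handles dense and conv layers only",
         call. = FALSE)
  }
}

#' Propagate relevance through pooling and reshaping layers
#'
#' Max-pooling redistributes each pooled unit's relevance entirely onto the
#' input position attaining the window maximum (winner-take-all); windows
#' with tied maxima split the relevance equally among the tied positions.
#' Flatten passes relevance through index-wise. Both preserve the relevance
#' total exactly.
#'
#' @param layer a `maxpool` or `flatten` layer.
#' @param a_in the layer's input activations.
#' @param r_up relevance of the layer's outputs.
#' @return relevance of the layer's inputs.
#' @export
propagate_pool <- function(layer, a_in, r_up) {
  if (layer$kind == "flatten") {
    dim(r_up) <- dim(a_in)
    return(r_up)
  }
  if (layer$kind != "maxpool") {
    stop("propagate_pool handles maxpool and flatten layers only", call. = FALSE)
  }
  d <- dim(a_in)
  np <- nrow(layer$pool_idx)
  rout <- matrix(r_up, np, d[3])
  rin <- array(0, d)
  plane_len <- d[1] * d[2]
  for (ch in seq_len(d[3])) {
    plane <- a_in[, , ch]
    Pm <- plane[layer$pool_idx]
    dim(Pm) <- dim(layer$pool_idx)
    mx <- do.call(pmax, as.data.frame(Pm))
    tie <- Pm == mx
    share <- rout[, ch] / rowSums(tie)
    Msg <- tie * share
    rin[(ch - 1L) * plane_len + as.vector(layer$pool_idx)] <-
      rin[(ch - 1L) * plane_len + as.vector(layer$pool_idx)] + as.vector(Msg)
  }
  rin
}

#' Compute a per-pixel relevance map
#'
#' Runs a forward pass, initialises the output relevance from the target
#' class logit, and back-propagates it through every layer in reverse:
#' alpha-beta redistribution through dense and conv layers, identity
#' through ReLU (relevance attaches to the post-activation unit),
#' winner-take-all through max-pooling, index pass-through for flatten.
#' Records the relevance total at every layer boundary.
#'
#' @param model a `network_model`.
#' @param image input image (matrix), already in the model's input domain;
#'   set `normalize = TRUE` to apply the model's stored normalisation first.
#' @param target_class age label to explain; default the predicted class.
#' @param params a [rule_params()].
#' @param normalize apply `model$norm_stats` to the image first.
#' @return a `relevance_map`: list with `scores` (h x w matrix, channels
#'   summed), `target_class`, `rule`, `logit` (the initialised relevance
#'   total R_f) and `per_layer_sums` (output to input).
#' @export
compute_relevance_map <- function(model, image, target_class = NULL,
                                  params = rule_params(), normalize = FALSE) {
  if (normalize) {
    if (is.null(model$norm_stats)) stop("model has no normalisation stats", call. = FALSE)
    image <- apply_normalization(image, model$norm_stats)
  }
  tr <- forward(model, image)
  if (is.null(target_class)) {
    target_class <- model$class_labels[which.max(tr$logits)]
  }
  r <- init_relevance(tr, target_class, model$class_labels)
  rf <- sum(r)
  sums <- numeric(length(model$layers) + 1)
  sums[1] <- rf
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    a_in <- layer_input(tr, i)
    r <- switch(ly$kind,
      dense = propagate_alphabeta(ly, a_in, r, params),
      conv = propagate_alphabeta(ly, a_in, r, params),
      relu = r,
      maxpool = propagate_pool(ly, a_in, r),
      flatten = propagate_pool(ly, a_in, r),
      stop("unsupported layer kind: ", ly$kind, call. = FALSE)
    )
    sums[length(model$layers) - i + 2] <- sum(r)
  }
  d <- dim(tr$input)
  scores <- if (length(d) == 3) {
    apply(array(r, d), c(1, 2), sum)
  } else {
    array(r, d)
  }
  structure(
    list(scores = scores, target_class = target_class,
         rule = params, logit = rf, per_layer_sums = sums),
    class = "relevance_map"
  )
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> class %s (R_f = %.4f), %dx%d, total %.4f, rule alpha=%g beta=%g\n",
    x$target_class, x$logit, nrow(x$scores), ncol(x$scores),
    sum(x$scores), x$rule$alpha, x$rule$beta
  ))
  invisible(x)
}

#' Audit layer-wise relevance conservation
#'
#' Reports the relevance total at each layer boundary (from the output
#' down to the pixels) and its relative deviation from the initialised
#' relevance R_f. Exact conservation is expected for bias-free networks
#' with no inhibiting contributions; biases and the stabilizer leak
#' relevance, which is reported rather than treated as an error.
#'
#' @param map a `relevance_map`.
#' @return a `conservation_report`: list with `per_layer` tibble
#'   (`boundary`, `total`, `rel_deviation`) and `max_rel_deviation`.
#' @export
audit_conservation <- function(map) {
  stopifnot(inherits(map, "relevance_map"))
  rf <- map$logit
  denom <- max(abs(rf), .Machine$double.eps)
  dev <- abs(map$per_layer_sums - rf) / denom
  if (rf == 0 && all(map$per_layer_sums == 0)) dev <- rep(0, length(dev))
  structure(
    list(
      per_layer = tibble::tibble(
        boundary = seq_along(map$per_layer_sums) - 1L,
        total = map$per_layer_sums,
        rel_deviation = dev
      ),
      max_rel_deviation = max(dev)
    ),
    class = "conservation_report"
  )
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> max relative deviation %.3g over %d boundaries\n",
              x$max_rel_deviation, nrow(x$per_layer)))
  invisible(x)
}
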