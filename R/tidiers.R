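# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained network's training log
#'
#' @param x a `network_model`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `accuracy` (empty if untrained).
#' @method tidy network_model
#' @export
tidy.network_model <- function(x, ...) {
  if (is.null(x$train_log)) {
    return(tibble::tibble(epoch = integer(0), loss = numeric(0),
                          accuracy = numeric(0)))
  }
  x$train_log
}

#' One-row summary of a network model
#'
#' @param x a `network_model`.
#' @param ... unused.
#' @method glance network_model
#' @export
glance.network_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  lg <- x$train_log
  tibble::tibble(
    n_layers = length(x$layers),
    n_classes = length(x$class_labels),
    n_params = np,
    epochs_trained = if (is.null(lg)) 0L else max(lg$epoch),
    final_loss = if (is.null(lg)) NA_real_ else lg$loss[nrow(lg)],
    final_accuracy = if (is.null(lg)) NA_real_ else lg$accuracy[nrow(lg)]
  )
}

#' Tidy a relevance map into long (row, col, relevance) form
#'
#' @param x a `relevance_map`.
#' @param ... unused.
#' @method tidy relevance_map
#' @export
tidy.relevance_map <- function(x, ...) {
  s <- x$scores
  tibble::tibble(
    row = rep(seq_len(nrow(s)), times = ncol(s)),
    col = rep(seq_len(ncol(s)), each = nrow(s)),
    relevance = as.vector(s)
  )
}

#' One-row summary of a relevance map
#'
#' @param x a `relevance_map`.
#' @param ... unused.
#' @method glance relevance_map
#' @export
glance.relevance_map <- function(x, ...) {
  tibble::tibble(
    target_class = x$target_class,
    logit = x$logit,
    total_relevance = sum(x$scores),
    negative_fraction = mean(x$scores < 0),
    alpha = x$rule$alpha,
    beta = x$rule$beta
  )
}

#' Per-sample tidy view of a clustering result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- tibble::tibble(cluster = x$labels, group = x$group_labels)
  if (!is.null(x$meta)) out <- dplyr::bind_cols(x$meta, out)
  out
}

#' One-row summary of a clustering result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, f1 = x$f1)
}

#' Tidy an average relevance map
#'
#' @param x an `average_map`.
#' @param ... unused.
#' @method tidy average_map
#' @export
tidy.average_map <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    row = rep(seq_len(nrow(g)), times = ncol(g)),
    col = rep(seq_len(ncol(g)), each = nrow(g)),
    relevance = as.vector(g),
    predicted_age = x$predicted_age,
    n_samples = x$n_samples
  )
}
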