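# Spectral relevance analysis over collections of relevance maps:
# preprocessing to 56x56 sum-pooled descriptors, k-NN affinity graph,
# spectral clustering, t-SNE embedding, and F1 cluster-recovery scoring.

#' Crop a relevance map tightly to the otolith contour
#'
#' Returns the sub-grid of the tight bounding box of the foreground mask;
#' relevance outside the box (background noise contributions) is discarded.
#'
#' @param scores relevance matrix (or a `relevance_map`).
#' @param mask logical foreground mask of the same dimensions.
#' @return the cropped relevance matrix.
#' @export
crop_to_contour <- function(scores, mask) {
  if (inherits(scores, "relevance_map")) scores <- scores$scores
  stopifnot(all(dim(scores) == dim(mask)))
  bb <- mask_bbox(mask)
  scores[bb$row[1]:bb$row[2], bb$col[1]:bb$col[2], drop = FALSE]
}

#' Resize a relevance map, conserving total mass
#'
#' Bilinear resize to a square intermediate size, then rescale so the total
#' relevance equals the input total (interpolation alone does not conserve
#' mass).
#'
#' @param scores relevance matrix.
#' @param size output side length.
#' @export
resize_map <- function(scores, size = 112) {
  tot <- sum(scores)
  out <- resize_bilinear(scores, size, size)
  s <- sum(out)
  if (tot != 0 && s != 0) out <- out * (tot / s)
  out
}

#' Sum-downsample a relevance map over a regular grid
#'
#' Each output cell is the sum of the pixels of its grid cell, so the total
#' relevance is conserved exactly. Input dimensions must be multiples of
#' `out_size`.
#'
#' @param scores relevance matrix.
#' @param out_size output side length (default 56).
#' @return `out_size` x `out_size` matrix.
#' @export
downsample_sum <- function(scores, out_size = 56) {
  if (nrow(scores) < out_size || ncol(scores) < out_size) {
    stop("out_size larger than input map", call. = FALSE)
  }
  block_sum(scores, out_size)
}

#' Build heatmap descriptors from relevance maps
#'
#' The SpRAy preprocessing chain for each map: crop tightly along the
#' otolith contour, bilinearly resize to a common intermediate size
#' (mass-renormalised), then sum-downsample over a regular grid to
#' `out_size` x `out_size`.
#'
#' @param maps list of `relevance_map` (or matrices).
#' @param masks list of logical masks matching the maps.
#' @param meta tibble with one row per map; must contain `sample_id`,
#'   `predicted_age`, `variant` (extra columns are kept).
#' @param intermediate_size common resize target before sum-pooling.
#' @param out_size descriptor side length.
#' @return a `spray_descriptors`: list with `mat` (n x out_size^2 matrix,
#'   one flattened descriptor per row) and `meta`.
#' @export
make_descriptors <- function(maps, masks, meta, intermediate_size = 112,
                             out_size = 56) {
  stopifnot(length(maps) == length(masks), nrow(meta) == length(maps))
  mat <- t(vapply(seq_along(maps), function(i) {
    m <- crop_to_contour(maps[[i]], masks[[i]])
    m <- resize_map(m, intermediate_size)
    as.vector(downsample_sum(m, out_size))
  }, numeric(out_size^2)))
  structure(list(mat = mat, meta = tibble::as_tibble(meta),
                 out_size = out_size),
            class = "spray_descriptors")
}

#' @export
print.spray_descriptors <- function(x, ...) {
  cat(sprintf("<spray_descriptors> %d maps, %dx%d grid\n",
              nrow(x$mat), x$out_size, x$out_size))
  invisible(x)
}

#' k-nearest-neighbour affinity graph over descriptors
#'
#' Flattens the descriptors, links each one to its `k` Euclidean nearest
#' neighbours with unit weight (`k = ceiling(ln n)` by default, the
#' standard heuristic for spectral clustering on k-NN graphs), and
#' symmetrises the adjacency by union. Diagonal is zero.
#'
#' @param x a `spray_descriptors` or an n x p numeric matrix.
#' @param k neighbour count; default `ceiling(log(n))`.
#' @return an `affinity_graph`: list with `matrix` (n x n symmetric 0/1),
#'   `k`, `n`.
#' @export
build_affinity <- function(x, k = NULL) {
  mat <- if (inherits(x, "spray_descriptors")) x$mat else as.matrix(x)
  n <- nrow(mat)
  if (n < 3) stop("need at least 3 descriptors", call. = FALSE)
  if (is.null(k)) k <- ceiling(log(n))
  k <- max(1L, min(as.integer(k), n - 1L))
  D <- as.matrix(stats::dist(mat))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  structure(list(matrix = A, k = k, n = n), class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> n = %d, k = %d, %d edges\n",
              x$n, x$k, sum(x$matrix) / 2))
  invisible(x)
}

#' Spectral clustering on the normalized Laplacian
#'
#' Forms the symmetric normalized Laplacian of the affinity graph, takes
#' the eigenvectors of its `n_clusters` smallest eigenvalues, row-normalises
#' them, and partitions the rows with seeded k-means. Graphs with more
#' connected components than clusters trigger a warning but are still
#' clustered.
#'
#' @param graph an `affinity_graph`.
#' @param n_clusters number of clusters (default 2).
#' @param seed seed for the k-means initialisation.
#' @return integer cluster labels in `0:(n_clusters-1)`.
#' @export
spectral_cluster <- function(graph, n_clusters = 2, seed = 1) {
  A <- graph$matrix
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > n_clusters) {
    warning(sprintf("graph has %d connected components (> %d clusters)",
                    ncomp, n_clusters))
  }
  deg <- rowSums(A)
  dh <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (dh %o% dh) * A
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(n_clusters) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(U, centers = n_clusters, nstart = 10, iter.max = 100)
  as.integer(km$cluster - 1L)
}

#' Best-matching F1 score of a 2-way clustering against group labels
#'
#' Binary F1 computed under whichever of the two possible cluster-to-group
#' assignments maximises it, so the score is invariant to cluster
#' relabelling. The positive class is the second group level.
#'
#' @param labels integer cluster labels (2 distinct values at most).
#' @param group_labels vector of group memberships (2 levels).
#' @return F1 in [0, 1].
#' @export
clustering_f1 <- function(labels, group_labels) {
  if (length(labels) != length(group_labels)) {
    stop("labels and group_labels must have equal length", call. = FALSE)
  }
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  y <- as.integer(g) - 1L # positive class = second level
  lab <- as.integer(factor(labels)) - 1L
  f1_of <- function(pred) {
    tp <- sum(pred == 1 & y == 1)
    fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  max(f1_of(lab), f1_of(1L - lab))
}

#' Run spectral relevance analysis on a descriptor set
#'
#' Convenience wrapper chaining [build_affinity()], [spectral_cluster()]
#' and [clustering_f1()] against the age-group labels in the descriptor
#' metadata.
#'
#' @param desc a `spray_descriptors` whose `meta` has a `group` column
#'   (or `predicted_age`, from which groups are assigned).
#' @param seed clustering seed.
#' @param k neighbour count override.
#' @return a `cluster_result`: list with `labels`, `f1`, `group_labels`,
#'   `graph`, `n`, `k`.
#' @export
spray_cluster <- function(desc, seed = 1, k = NULL) {
  stopifnot(inherits(desc, "spray_descriptors"))
  meta <- desc$meta
  if (!"group" %in% names(meta)) {
    meta$group <- vapply(meta$predicted_age, function(a) assign_age_group(a)$name, "")
  }
  graph <- build_affinity(desc, k = k)
  labels <- spectral_cluster(graph, 2, seed = seed)
  f1 <- clustering_f1(labels, meta$group)
  structure(
    list(labels = labels, f1 = f1, group_labels = meta$group,
         graph = graph, n = graph$n, k = graph$k, meta = meta),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> n = %d, k = %d, F1 = %.3f\n", x$n, x$k, x$f1))
  invisible(x)
}

#' t-SNE embedding of the affinity graph
#'
#' Derives pairwise distances from the affinity graph as unweighted
#' shortest-path lengths (disconnected pairs capped at twice the largest
#' finite distance) and embeds them in two dimensions with a seeded
#' t-distributed stochastic neighbour embedding.
#'
#' @param graph an `affinity_graph`.
#' @param seed embedding seed.
#' @param perplexity t-SNE perplexity (clamped to the sample size).
#' @param n_iter gradient-descent iterations.
#' @return an `embedding2d`: tibble with columns `x`, `y` plus attribute
#'   `seed`.
#' @export
embed_tsne <- function(graph, seed = 1, perplexity = 30, n_iter = 500) {
  n <- graph$n
  if (n < 5) stop("need at least 5 samples to embed", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(graph$matrix > 0, mode = "undirected")
  D <- igraph::distances(g)
  fin <- D[is.finite(D)]
  cap <- if (length(fin) > 0 && max(fin) > 0) 2 * max(fin) else 1
  D[!is.finite(D)] <- cap
  Y <- tsne_embed(D, seed = seed, perplexity = perplexity, n_iter = n_iter)
  out <- tibble::tibble(x = Y[, 1], y = Y[, 2])
  attr(out, "seed") <- seed
  class(out) <- c("embedding2d", class(out))
  out
}
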