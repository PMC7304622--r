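# File interfaces: PNG image datasets with CSV manifests, JSON model
# checkpoints, descriptor archives, and rendered heatmaps.

#' Write / read an otolith dataset as PNG images plus a CSV manifest
#'
#' Images are stored as 8-bit grayscale PNGs (`<sample_id>.png`) with their
#' masks (`<sample_id>_mask.png`), and a `manifest.csv` holding
#' `sample_id`, `age`, `variant`, `split`, `seed`. This is also the entry
#' path for real images: drop PNGs next to a manifest of read ages.
#'
#' @param ds a `dataset_split`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c(ds$train, ds$test)) {
    png::writePNG(clamp01(s$image), file.path(dir, paste0(s$sample_id, ".png")))
    png::writePNG(s$mask * 1, file.path(dir, paste0(s$sample_id, "_mask.png")))
  }
  utils::write.csv(as.data.frame(manifest(ds)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param mask_threshold used to binarise mask PNGs (or, when a sample has
#'   no mask file, to derive a foreground mask from the image itself).
#' @return for `read_dataset`, a `dataset_split`.
#' @export
read_dataset <- function(dir, mask_threshold = 0.5) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    img <- read_image_png(file.path(dir, paste0(man$sample_id[i], ".png")))
    mask_file <- file.path(dir, paste0(man$sample_id[i], "_mask.png"))
    mask <- if (file.exists(mask_file)) {
      read_image_png(mask_file) >= mask_threshold
    } else {
      img > mask_threshold * max(img)
    }
    structure(
      list(image = img, mask = mask, age = as.integer(man$age[i]),
           variant = man$variant[i], params = NULL,
           sample_id = man$sample_id[i]),
      class = "otolith_sample"
    )
  })
  names(samples) <- man$sample_id
  is_test <- man$split == "test"
  structure(
    list(train = samples[!is_test], test = samples[is_test],
         seed = if ("seed" %in% names(man)) man$seed[1] else NA_integer_,
         variant = man$variant[1],
         canvas_size = nrow(samples[[1]]$image)),
    class = "dataset_split"
  )
}

#' Write / read a network checkpoint as JSON
#'
#' One JSON file holding a header (layer specs, class labels, normalisation
#' statistics) and the flattened weight arrays. Round-trips at full double
#' precision.
#'
#' @param model a `network_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  layers <- lapply(model$layers, function(l) {
    out <- list(kind = l$kind, spec = unclass(l$spec),
                in_shape = l$in_shape, out_shape = l$out_shape)
    if (!is.null(l$W)) {
      out$W <- as.vector(l$W)
      out$W_dim <- dim(l$W)
      out$b <- l$b
    }
    out
  })
  obj <- list(
    header = list(
      package = "otolrp",
      input_shape = model$input_shape,
      class_labels = model$class_labels,
      norm_stats = model$norm_stats
    ),
    layers = layers,
    train_log = if (is.null(model$train_log)) NULL else
      as.data.frame(model$train_log)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return for `read_model`, a `network_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(obj$layers)), function(i) {
    sp <- obj$layers$spec[i, , drop = FALSE]
    kind <- obj$layers$kind[i]
    switch(kind,
      conv = layer_conv(sp$filters, sp$kernel, sp$pad),
      relu = layer_relu(),
      maxpool = layer_maxpool(sp$size),
      flatten = layer_flatten(),
      dense = layer_dense(sp$units)
    )
  })
  model <- build_network(unlist(obj$header$input_shape), specs,
                         obj$header$class_labels, seed = 0)
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$W)) {
      model$layers[[i]]$W <- matrix(obj$layers$W[[i]],
                                    obj$layers$W_dim[[i]][1],
                                    obj$layers$W_dim[[i]][2])
      model$layers[[i]]$b <- obj$layers$b[[i]]
    }
  }
  if (!is.null(obj$header$norm_stats)) {
    model$norm_stats <- obj$header$norm_stats
  }
  if (!is.null(obj$train_log)) {
    model$train_log <- tibble::as_tibble(obj$train_log)
  }
  model
}

#' Write / read a descriptor set as a matrix archive plus manifest
#'
#' The n x p descriptor matrix goes to `descriptors.csv` (no header, one
#' row per map) and the metadata to `descriptors_meta.csv`.
#'
#' @param desc a `spray_descriptors`.
#' @param dir output directory.
#' @export
write_descriptors <- function(desc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(desc$mat, file.path(dir, "descriptors.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(as.data.frame(desc$meta),
                   file.path(dir, "descriptors_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_descriptors
#' @return for `read_descriptors`, a `spray_descriptors`.
#' @export
read_descriptors <- function(dir) {
  mat <- as.matrix(utils::read.csv(file.path(dir, "descriptors.csv"),
                                   header = FALSE))
  dimnames(mat) <- NULL
  meta <- tibble::as_tibble(utils::read.csv(
    file.path(dir, "descriptors_meta.csv"), stringsAsFactors = FALSE))
  structure(list(mat = mat, meta = meta,
                 out_size = as.integer(sqrt(ncol(mat)))),
            class = "spray_descriptors")
}

#' Render a relevance grid to a white-to-red PNG heatmap
#'
#' The redder the pixel, the larger its (positive) relevance; negative
#' values are clipped to white.
#'
#' @param x a `relevance_map`, `average_map`, or numeric matrix.
#' @param path PNG output path.
#' @export
write_heatmap_png <- function(x, path) {
  g <- if (inherits(x, "relevance_map")) x$scores
       else if (inherits(x, "average_map")) x$grid
       else x
  mx <- max(g)
  v <- if (mx > 0) pmax(g, 0) / mx else g * 0
  rgb <- array(1, c(nrow(g), ncol(g), 3))
  rgb[, , 2] <- 1 - v
  rgb[, , 3] <- 1 - v
  png::writePNG(rgb, path)
  invisible(path)
}
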