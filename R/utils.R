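# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# EBImage stores images with dim1 = x; our matrices use dim1 = image row
# (vertical, anterior at row 1). The wrappers below keep that convention.
resize_bilinear <- function(m, nr, nc) {
  EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
}

resize_nearest <- function(m, nr, nc) {
  EBImage::resize(m, w = nr, h = nc, filter = "none")
}

gaussian_blur <- function(m, sigma) {
  EBImage::gblur(m, sigma = sigma)
}

#' @keywords internal
mask_bbox <- function(mask) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(row = rows, col = cols)
}

# sum-pool a matrix into blocks of equal size; dims must be divisible
block_sum <- function(m, out_size) {
  fr <- nrow(m) / out_size
  fc <- ncol(m) / out_size
  if (fr != floor(fr) || fc != floor(fc)) {
    stop("matrix dimensions must be multiples of out_size", call. = FALSE)
  }
  r1 <- rowsum(m, rep(seq_len(out_size), each = fr))
  out <- t(rowsum(t(r1), rep(seq_len(out_size), each = fc)))
  dimnames(out) <- NULL
  out
}

# circular angular difference in degrees, result in [0, 180]
ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Derive a reproducible sub-seed from a base seed and a stage tag,
# kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
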