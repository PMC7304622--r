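#' Age-conditional otolith shape parameters
#'
#' Draws the morphological parameters of one synthetic otolith from
#' age-conditional distributions. The morphology follows the growth pattern
#' of Greenland halibut ear stones: juveniles (ages 1-4) are nearly circular
#' with a large nucleus and no anterior fingers; with age the otolith grows
#' mainly in the anterior direction, lobed "fingers" appear and lengthen,
#' and the nucleus shrinks relative to the whole.
#'
#' The nucleus trend is deliberately steep at young ages and flat at old
#' ages, so the inner structure carries most of the age signal for young
#' fish while overall size and contour shape dominate for older fish.
#'
#' @param age integer age in years, 1 to 26.
#' @param canvas_size side length (pixels) of the square canvas the otolith
#'   will be rendered on; radii scale with it.
#' @param contrast separability knob (> 0). Stochastic spread of every
#'   parameter is divided by `contrast`, so larger values give cleaner
#'   between-age morphological contrast and smaller values blur it.
#'   Uses the current RNG stream; seed with [set.seed()] for reproducibility.
#' @return an object of class `shape_params`: a list with fields
#'   `base_radius`, `anterior_elongation`, `n_fingers`, `finger_length`,
#'   `nucleus_relative_radius`, `ring_count`, `noise_amplitude`, `age`.
#' @examples
#' set.seed(1)
#' sample_shape_params(3)
#' @export
sample_shape_params <- function(age, canvas_size = 112, contrast = 1) {
  if (length(age) != 1 || is.na(age) || age != round(age) || age < 1 || age > 26) {
    stop("age must be a single integer in 1..26", call. = FALSE)
  }
  if (contrast <= 0) stop("contrast must be > 0", call. = FALSE)
  age <- as.integer(age)
  frac <- (age - 1) / 25

  # Overall size grows with age but with substantial individual variation
  # (fixed spread, NOT sharpened by `contrast`), so size alone separates
  # broad age groups yet blurs neighbouring ages - especially juveniles,
  # whose ageing cue is the nucleus. Structure and shape spreads shrink
  # with `contrast`.
  base_radius <- min(
    canvas_size * 0.28,
    canvas_size * (0.16 + 0.10 * frac) * exp(stats::rnorm(1, 0, 0.09))
  )
  anterior_elongation <- min(0.7, max(0, 0.65 * frac^1.1 +
    stats::rnorm(1, 0, 0.04 / contrast)))

  if (age <= 4) {
    n_fingers <- 0L
    finger_length <- 0
  } else {
    n_fingers <- max(2L, as.integer(round(2 + 4 * (age - 5) / 21)) +
      sample(c(-1L, 0L, 1L), 1))
    finger_length <- min(
      canvas_size * 0.11,
      canvas_size * (0.035 + 0.06 * (age - 5) / 21) *
        exp(stats::rnorm(1, 0, 0.08 / contrast))
    )
  }

  nucleus_relative_radius <- min(0.75, max(
    0.08,
    0.68 * exp(-0.11 * (age - 1)) + stats::rnorm(1, 0, 0.012 / contrast)
  ))

  structure(
    list(
      base_radius = base_radius,
      anterior_elongation = anterior_elongation,
      n_fingers = n_fingers,
      finger_length = finger_length,
      nucleus_relative_radius = nucleus_relative_radius,
      ring_count = age,
      noise_amplitude = 0.04,
      age = age
    ),
    class = "shape_params"
  )
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf(
    "<shape_params> age %d: radius %.1f px, elongation %.2f, %d fingers (%.1f px), nucleus %.2f, %d rings\n",
    x$age, x$base_radius, x$anterior_elongation, x$n_fingers,
    x$finger_length, x$nucleus_relative_radius, x$ring_count
  ))
  invisible(x)
}

# radial boundary (pixels) of the otolith outline as a function of angle
# theta (degrees, 90 = anterior/up), given shape parameters and the random
# phase/jitter values drawn at render time
boundary_radius <- function(theta, params, finger_angles, finger_widths,
                            harm_amp, harm_phase) {
  anterior <- exp(-(ang_diff(theta, 90) / 55)^2)
  posterior <- 0.15 * exp(-(ang_diff(theta, 270) / 70)^2)
  r <- params$base_radius *
    (1 + params$anterior_elongation * (anterior + posterior))
  if (params$n_fingers > 0) {
    for (i in seq_along(finger_angles)) {
      r <- r + params$finger_length *
        exp(-(ang_diff(theta, finger_angles[i]) / finger_widths[i])^2)
    }
  }
  # smooth low-order irregularity of the outline
  r <- r + params$base_radius * params$noise_amplitude *
    (harm_amp[1] * sin(2 * theta * pi / 180 + harm_phase[1]) +
       harm_amp[2] * sin(3 * theta * pi / 180 + harm_phase[2]))
  r
}

#' Render a baseline synthetic otolith image
#'
#' Draws one grayscale otolith on a square canvas, anterior pointing up.
#' The foreground is a closed blob whose outline is an ellipse-like base
#' deformed anteriorly by the finger profile; the interior holds a brighter
#' nucleus disk, `ring_count` low-contrast concentric growth rings and
#' additive noise, softened by a small Gaussian blur that emulates the loss
#' of fine zone detail at reduced image resolution. Background pixels carry
#' dark noise. All intensities are clamped to [0, 1].
#'
#' @param params a [sample_shape_params()] result.
#' @param canvas_size canvas side length in pixels.
#' @param sample_id identifier stored on the sample.
#' @return an `otolith_sample`: list with `image` (canvas x canvas matrix in
#'   [0,1]), `mask` (logical matrix, TRUE on otolith pixels), `age`,
#'   `variant = "baseline"`, `params`, `sample_id`.
#' @export
render_baseline <- function(params, canvas_size = 112, sample_id = "s1") {
  stopifnot(inherits(params, "shape_params"))
  cy <- 0.62 * canvas_size # centre row; room for anterior growth upward
  cx <- 0.50 * canvas_size

  # per-sample randomness of finger placement and outline irregularity
  if (params$n_fingers > 0) {
    finger_angles <- seq(90 - 48, 90 + 48, length.out = params$n_fingers) +
      stats::rnorm(params$n_fingers, 0, 3)
    finger_widths <- pmax(4, 7 + stats::rnorm(params$n_fingers, 0, 1))
  } else {
    finger_angles <- numeric(0)
    finger_widths <- numeric(0)
  }
  harm_amp <- stats::runif(2, 0.3, 1)
  harm_phase <- stats::runif(2, 0, 2 * pi)

  max_extent <- params$base_radius * (1 + params$anterior_elongation) +
    params$finger_length + params$base_radius * params$noise_amplitude * 2
  if (cy - max_extent < 1 || cx - max_extent / 2 < 1) {
    stop("rendering error: foreground exceeds canvas", call. = FALSE)
  }

  row <- matrix(seq_len(canvas_size), canvas_size, canvas_size)
  col <- matrix(seq_len(canvas_size), canvas_size, canvas_size, byrow = TRUE)
  dy <- cy - row # positive = up (anterior)
  dx <- col - cx
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  rr <- sqrt(dx^2 + dy^2)

  rb <- boundary_radius(theta, params, finger_angles, finger_widths,
                        harm_amp, harm_phase)
  mask <- rr <= rb

  r_nuc <- params$nucleus_relative_radius * params$base_radius
  nucleus <- mask & (rr <= r_nuc)

  img <- matrix(0, canvas_size, canvas_size)
  # dark noisy background
  img[!mask] <- stats::rnorm(sum(!mask), 0.06, 0.4 * params$noise_amplitude)
  # interior: base level plus concentric rings between nucleus and edge
  interior <- mask & !nucleus
  u <- (rr - r_nuc) / pmax(rb - r_nuc, 1e-6)
  ring_term <- if (params$ring_count > 0) {
    0.10 * sin(2 * pi * params$ring_count * u)
  } else {
    0
  }
  img[interior] <- 0.48 + (if (is.matrix(ring_term)) ring_term[interior] else 0)
  img[nucleus] <- 0.85
  if (params$noise_amplitude > 0) {
    img <- img + matrix(stats::rnorm(canvas_size^2, 0, params$noise_amplitude),
                        canvas_size, canvas_size)
  }
  if (params$ring_count > 0 || params$noise_amplitude > 0) {
    img <- gaussian_blur(img, sigma = 0.8)
  }
  img <- clamp01(img)

  structure(
    list(image = img, mask = mask, age = params$age, variant = "baseline",
         params = params, sample_id = sample_id),
    class = "otolith_sample"
  )
}

#' @export
print.otolith_sample <- function(x, ...) {
  cat(sprintf(
    "<otolith_sample> %s: age %d, %s variant, %dx%d, %.0f%% foreground\n",
    x$sample_id, x$age, x$variant, nrow(x$image), ncol(x$image),
    100 * mean(x$mask)
  ))
  invisible(x)
}

#' Binary (silhouette) variant of an otolith sample
#'
#' Sets every otolith pixel to one and every background pixel to zero,
#' removing all inner structure so only size and contour shape remain.
#' Idempotent; refuses standardized input.
#'
#' @param sample a baseline (or already binary) `otolith_sample`.
#' @return the sample with `image` equal to its mask and `variant = "binary"`.
#' @export
make_binary <- function(sample) {
  stopifnot(inherits(sample, "otolith_sample"))
  if (sample$variant == "standardized") {
    stop("make_binary expects a baseline sample", call. = FALSE)
  }
  sample$image <- matrix(as.numeric(sample$mask), nrow(sample$mask))
  sample$variant <- "binary"
  sample
}

#' Size-standardized variant of an otolith sample
#'
#' Zeroes the background, then rescales the foreground (aspect ratio
#' preserved) so the mask's vertical extent equals `target_vertical_extent`
#' and recentres it on the canvas. Inner structure is preserved up to
#' bilinear interpolation; the size attribute is removed while shape and
#' structure are retained.
#'
#' @param sample a baseline `otolith_sample` with non-empty mask.
#' @param target_vertical_extent desired mask height in pixels.
#' @return an `otolith_sample` with `variant = "standardized"`.
#' @export
make_standardized <- function(sample, target_vertical_extent = NULL) {
  stopifnot(inherits(sample, "otolith_sample"))
  if (sample$variant != "baseline") {
    stop("make_standardized expects a baseline sample", call. = FALSE)
  }
  if (!any(sample$mask)) stop("mask is empty", call. = FALSE)
  canvas <- nrow(sample$image)
  if (is.null(target_vertical_extent)) {
    target_vertical_extent <- round(0.62 * canvas)
  }

  bb <- mask_bbox(sample$mask)
  img <- sample$image
  img[!sample$mask] <- 0
  sub_img <- img[bb$row[1]:bb$row[2], bb$col[1]:bb$col[2], drop = FALSE]
  sub_msk <- sample$mask[bb$row[1]:bb$row[2], bb$col[1]:bb$col[2], drop = FALSE]

  h <- nrow(sub_img)
  w <- ncol(sub_img)
  new_h <- as.integer(target_vertical_extent)
  new_w <- max(1L, as.integer(round(w * target_vertical_extent / h)))
  if (new_h > canvas || new_w > canvas) {
    stop("standardized foreground exceeds canvas", call. = FALSE)
  }

  res_img <- resize_bilinear(sub_img, new_h, new_w)
  res_msk <- resize_bilinear(sub_msk * 1, new_h, new_w) >= 0.5

  out_img <- matrix(0, canvas, canvas)
  out_msk <- matrix(FALSE, canvas, canvas)
  r0 <- floor((canvas - new_h) / 2)
  c0 <- floor((canvas - new_w) / 2)
  out_img[r0 + seq_len(new_h), c0 + seq_len(new_w)] <- res_img
  out_msk[r0 + seq_len(new_h), c0 + seq_len(new_w)] <- res_msk
  out_img[!out_msk] <- 0
  out_img <- clamp01(out_img)

  sample$image <- out_img
  sample$mask <- out_msk
  sample$variant <- "standardized"
  sample
}

#' Generate a seeded synthetic otolith dataset
#'
#' Renders `n_per_age` otoliths for every requested age in the requested
#' image variant, and splits them into train and test sets, stratified by
#' age. Fully deterministic given `seed`: the underlying baseline geometry
#' depends only on `(seed, ages, n_per_age, canvas_size, contrast)`, so the
#' three variants of the same `sample_id` share one geometry.
#'
#' @param n_per_age samples per age class (>= 1).
#' @param ages integer vector of ages (subset of 1..26).
#' @param variant one of `"baseline"`, `"binary"`, `"standardized"`.
#' @param canvas_size canvas side in pixels.
#' @param split_fraction fraction of each age assigned to the test set.
#' @param seed integer seed.
#' @param contrast separability knob passed to [sample_shape_params()].
#' @param target_vertical_extent standardized-variant mask height; default
#'   62% of the canvas.
#' @return a `dataset_split`: list with `train` and `test` (lists of
#'   `otolith_sample`), `seed`, `variant`, `canvas_size`.
#' @export
generate_dataset <- function(n_per_age, ages = 1:26, variant = "baseline",
                             canvas_size = 112, split_fraction = 0.2,
                             seed = 1, contrast = 1,
                             target_vertical_extent = NULL) {
  if (n_per_age < 1) stop("n_per_age must be >= 1", call. = FALSE)
  variant <- match.arg(variant, c("baseline", "binary", "standardized"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  samples <- list()
  for (age in ages) {
    for (i in seq_len(n_per_age)) {
      sid <- sprintf("a%02d_s%03d", age, i)
      p <- sample_shape_params(age, canvas_size, contrast)
      s <- render_baseline(p, canvas_size, sid)
      samples[[sid]] <- s
    }
  }
  if (variant == "binary") {
    samples <- lapply(samples, make_binary)
  } else if (variant == "standardized") {
    samples <- lapply(samples, make_standardized,
                      target_vertical_extent = target_vertical_extent)
  }

  # stratified split, deterministic continuation of the same stream
  test_ids <- character(0)
  n_test <- round(n_per_age * split_fraction)
  for (age in ages) {
    ids <- sprintf("a%02d_s%03d", age, seq_len(n_per_age))
    if (n_test > 0) test_ids <- c(test_ids, sample(ids, n_test))
  }
  is_test <- names(samples) %in% test_ids

  structure(
    list(train = samples[!is_test], test = samples[is_test],
         seed = seed, variant = variant, canvas_size = canvas_size),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s variant: %d train / %d test (seed %d)\n",
              x$variant, length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Dataset manifest as a tibble
#'
#' @param ds a `dataset_split`.
#' @return tibble with columns `sample_id`, `age`, `variant`, `split`, `seed`.
#' @export
manifest <- function(ds) {
  stopifnot(inherits(ds, "dataset_split"))
  one <- function(samples, split) {
    tibble::tibble(
      sample_id = vapply(samples, `[[`, "", "sample_id"),
      age = vapply(samples, `[[`, 0L, "age"),
      variant = vapply(samples, `[[`, "", "variant"),
      split = split
    )
  }
  out <- dplyr::bind_rows(one(ds$train, "train"), one(ds$test, "test"))
  out$seed <- ds$seed
  dplyr::arrange(out, .data$sample_id)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
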