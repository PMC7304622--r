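# Model-vs-reader agreement statistics: RMSE, the per-otolith age-reading
# coefficient of variation, 1.5xIQR outlier exclusion, and mean CV per age
# group and data variant.

#' Root mean squared error between predictions and read ages
#'
#' @param pairs tibble/data.frame with columns `read_age` and
#'   `predicted_age` (e.g. from [predict_dataset()]).
#' @return non-negative RMSE in years.
#' @examples
#' rmse(data.frame(read_age = c(5, 5), predicted_age = c(4, 6))) # 1
#' @export
rmse <- function(pairs) {
  if (nrow(pairs) == 0) stop("no age pairs", call. = FALSE)
  sqrt(mean((pairs$read_age - pairs$predicted_age)^2))
}

#' Age-reading coefficient of variation for one otolith
#'
#' The CV of two independent age estimates (human reader and model) of the
#' same otolith: the two-reading sample standard deviation (n - 1
#' denominator, i.e. |a - b| / sqrt(2)) over the two-reading mean, as a
#' percentage. This is the standard between-reader precision statistic in
#' the age-reading literature. Setting `ddof = 0` switches to the
#' population (n denominator) form.
#'
#' @param read_age,predicted_age numeric vectors (recycled pairwise).
#' @param ddof degrees-of-freedom correction: 1 (default, n - 1) or 0.
#' @return CV percentages, >= 0 and symmetric in the two readings.
#' @examples
#' pairwise_cv(8, 10) # 15.713
#' @export
pairwise_cv <- function(read_age, predicted_age, ddof = 1) {
  stopifnot(ddof %in% c(0, 1))
  s <- abs(read_age - predicted_age) / if (ddof == 1) sqrt(2) else 2
  m <- (read_age + predicted_age) / 2
  100 * s / m
}

#' 1.5 x IQR outlier exclusion
#'
#' Excludes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with
#' quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7). Fewer than 4 values: nothing is excluded
#' and a warning is raised. Kept and excluded values partition the input.
#'
#' @param values numeric vector.
#' @return list with `kept`, `excluded`, `kept_idx`, `lower`, `upper`.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))$excluded # 100
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values: no IQR exclusion applied")
    return(list(kept = values, excluded = numeric(0),
                kept_idx = seq_along(values), lower = -Inf, upper = Inf))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  keep <- values >= lower & values <= upper
  list(kept = values[keep], excluded = values[!keep],
       kept_idx = which(keep), lower = lower, upper = upper)
}

#' Mean CV per age group, variant and split
#'
#' For each (variant, split, age group) stratum: per-otolith CVs between
#' read and predicted age, 1.5xIQR outlier exclusion, then the mean of the
#' kept CVs. Group membership is assigned from the human-read age (the
#' grouping is a property of the specimen); set `group_by = "predicted"`
#' to stratify by model-predicted age instead.
#'
#' @param pairs tibble with `read_age`, `predicted_age` and optionally
#'   `variant`, `split`, `sample_id`.
#' @param group_by `"read"` (default) or `"predicted"`.
#' @param ddof passed to [pairwise_cv()].
#' @return a `cv_summary` tibble: one row per stratum with `variant`,
#'   `split`, `group`, `n`, `n_excluded`, `mean_cv` and list-columns
#'   `cvs` (all per-sample CVs) and `excluded_ids`. Empty strata get
#'   `mean_cv = NA` and are flagged by `n = 0`.
#' @export
mean_cv_by_group <- function(pairs, group_by = c("read", "predicted"),
                             ddof = 1) {
  group_by <- match.arg(group_by)
  pairs <- tibble::as_tibble(pairs)
  if (!"variant" %in% names(pairs)) pairs$variant <- "baseline"
  if (!"split" %in% names(pairs)) pairs$split <- "train"
  if (!"sample_id" %in% names(pairs)) {
    pairs$sample_id <- as.character(seq_len(nrow(pairs)))
  }
  key_age <- if (group_by == "read") pairs$read_age else pairs$predicted_age
  pairs$group <- age_group_of(key_age)
  pairs$cv <- pairwise_cv(pairs$read_age, pairs$predicted_age, ddof = ddof)

  out <- pairs |>
    dplyr::group_by(.data$variant, .data$split, .data$group) |>
    dplyr::group_modify(function(d, key) {
      filt <- withCallingHandlers(
        iqr_filter(d$cv),
        warning = function(w) invokeRestart("muffleWarning")
      )
      tibble::tibble(
        n = nrow(d),
        n_excluded = length(filt$excluded),
        mean_cv = if (length(filt$kept) > 0) mean(filt$kept) else NA_real_,
        cvs = list(d$cv),
        excluded_ids = list(d$sample_id[setdiff(seq_len(nrow(d)), filt$kept_idx)])
      )
    }) |>
    dplyr::ungroup()
  out$group <- factor(out$group, levels = .age_groups$name)
  out <- dplyr::arrange(out, .data$variant, .data$split, .data$group)
  class(out) <- c("cv_summary", class(out))
  out
}
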