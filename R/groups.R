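# Age-group assignment and per-predicted-age average relevance maps.

.age_groups <- tibble::tibble(
  name = c("juvenile", "adolescent", "young_adult", "adult"),
  lo = c(1L, 5L, 10L, 14L),
  hi = c(4L, 9L, 13L, 26L)
)

#' Age-group definitions
#'
#' The four morphological age groups of Greenland halibut otoliths:
#' juveniles (1-4, near-circular, large nucleus, no separable fingers),
#' adolescents (5-9, short distinct fingers), young adults (10-13, longer
#' fingers) and adults (14-26, long fingers, strongly asymmetric shape).
#'
#' @return tibble with columns `name`, `lo`, `hi` partitioning ages 1-26.
#' @export
age_groups <- function() .age_groups

#' Assign an age to its group
#'
#' @param age integer age in 1..26.
#' @return list with `name` and `age_range` (inclusive bounds).
#' @examples
#' assign_age_group(4)$name # "juvenile"
#' @export
assign_age_group <- function(age) {
  if (length(age) != 1 || is.na(age) || age < 1 || age > 26 || age != round(age)) {
    stop("age must be a single integer in 1..26", call. = FALSE)
  }
  row <- .age_groups[.age_groups$lo <= age & age <= .age_groups$hi, ]
  list(name = row$name, age_range = c(row$lo, row$hi))
}

#' Vectorised age-group names
#'
#' @param ages integer vector of ages in 1..26.
#' @return character vector of group names.
#' @export
age_group_of <- function(ages) {
  vapply(ages, function(a) assign_age_group(a)$name, "")
}

#' Average relevance map for one predicted age
#'
#' Element-wise mean of the descriptor grids sharing one predicted age and
#' variant, divided by its maximum so the brightest cell is exactly 1.
#' An all-zero mean skips normalisation and is flagged.
#'
#' @param grids list of equal-sized descriptor matrices, or a
#'   `spray_descriptors` restricted to one predicted age.
#' @param predicted_age,variant metadata recorded on the result (taken from
#'   the descriptors when available).
#' @return an `average_map`: list with `grid` (max 1 when non-degenerate),
#'   `predicted_age`, `n_samples`, `variant`, `degenerate`.
#' @export
average_relevance_map <- function(grids, predicted_age = NA, variant = NA) {
  if (inherits(grids, "spray_descriptors")) {
    d <- grids
    if (is.na(predicted_age)) {
      ages <- unique(d$meta$predicted_age)
      if (length(ages) != 1) stop("descriptors span several predicted ages", call. = FALSE)
      predicted_age <- ages
    }
    if (is.na(variant) && "variant" %in% names(d$meta)) {
      variant <- unique(d$meta$variant)[1]
    }
    grids <- lapply(seq_len(nrow(d$mat)), function(i) {
      matrix(d$mat[i, ], d$out_size, d$out_size)
    })
  }
  if (length(grids) == 0) stop("no descriptors to average", call. = FALSE)
  m <- Reduce(`+`, grids) / length(grids)
  mx <- max(m)
  degenerate <- mx <= 0
  if (!degenerate) m <- m / mx
  structure(
    list(grid = m, predicted_age = predicted_age,
         n_samples = length(grids), variant = variant,
         degenerate = degenerate),
    class = "average_map"
  )
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("<average_map> predicted age %s, n = %d, %s%s\n",
              x$predicted_age, x$n_samples, x$variant,
              if (x$degenerate) " (degenerate: all-zero mean)" else ""))
  invisible(x)
}

#' Select the display ages of one group
#'
#' The (at most) four ages of a group with the highest numbers of
#' predictions; ties are broken toward the lower age.
#'
#' @param counts named integer vector (names = predicted ages) or tibble
#'   with columns `predicted_age`, `n`.
#' @param group group name (see [age_groups()]).
#' @param n_max maximum number of ages to display.
#' @return integer vector of selected ages, sorted by descending count.
#' @export
select_display_ages <- function(counts, group, n_max = 4) {
  if (is.data.frame(counts)) {
    tab <- counts
  } else {
    tab <- tibble::tibble(predicted_age = as.integer(names(counts)),
                          n = as.integer(counts))
  }
  row <- .age_groups[.age_groups$name == group, ]
  if (nrow(row) == 0) stop("unknown group: ", group, call. = FALSE)
  tab <- tab[tab$predicted_age >= row$lo & tab$predicted_age <= row$hi, ]
  tab <- tab[order(-tab$n, tab$predicted_age), ]
  utils::head(tab$predicted_age, n_max)
}
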