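# (L, dL) pairs: the fitting substrate. dL = L_(a+1) - L_a is always
# paired with the start-of-interval length L_a, since the law is written
# with L_s, the length before the increment.

#' Increment pairs
#'
#' A data frame of (length, increment) pairs with provenance. Negative
#' observed increments are retained (they are legitimate measurement noise
#' around the fitted line) but flagged in the `negative` column.
#'
#' @param birth_year,age Provenance of each pair (the cohort and the
#'   start-of-interval age).
#' @param length Start-of-interval length \eqn{L_a}.
#' @param increment \eqn{dL = L_{a+1} - L_a} (per elapsed unit when
#'   observation intervals are uneven).
#' @return A data frame of class `increment_set` with columns
#'   `birth_year`, `age`, `length`, `increment`, `negative`.
#' @export
increment_set <- function(birth_year = NA_integer_, age = NA_integer_,
                          length = numeric(), increment = numeric()) {
  n <- max(base::length(length), base::length(increment))
  out <- data.frame(
    birth_year = rep_len(as.integer(birth_year), n),
    age = rep_len(as.integer(age), n),
    length = as.numeric(length), increment = as.numeric(increment)
  )
  out$negative <- out$increment < 0
  class(out) <- c("increment_set", "data.frame")
  out
}

#' Increments of one cohort
#'
#' Compute \eqn{dL = L_{a+1} - L_a} for every pair of consecutive observed
#' ages of one cohort. Age gaps produce no pair. For sub-annual data with
#' uneven sampling, pass observation `times` (same order as the ages, here
#' serving as observation indices); each increment is then divided by the
#' elapsed interval, still paired with the start length.
#'
#' @param series A [cohort_series()] with at least two ages.
#' @param times Optional numeric observation times aligned with the ages.
#' @return An [increment_set()]; empty when no consecutive ages exist.
#' @examples
#' s <- cohort_series(1999, 1:3, c(10, 20, 28))
#' cohort_increments(s)
#' @export
cohort_increments <- function(series, times = NULL) {
  if (!inherits(series, "cohort_series")) stop_unusable("`series` must be a cohort_series")
  if (length(series$ages) < 2L) stop_insufficient("a cohort needs >= 2 ages to yield increments")
  if (!is.null(times) && length(times) != length(series$ages)) {
    stop_unusable("`times` must align with the cohort's ages")
  }
  i <- which(diff(series$ages) == 1L)
  dl <- series$lengths[i + 1L] - series$lengths[i]
  if (!is.null(times)) {
    dt <- times[i + 1L] - times[i]
    if (any(dt <= 0)) stop_unusable("`times` must be strictly increasing")
    dl <- dl / dt
  }
  increment_set(rep(series$birth_year, length(i)), series$ages[i],
                series$lengths[i], dl)
}

#' Pool increments across cohorts
#'
#' Combine the increment pairs of several year-classes. In
#' `"per_age_average"` mode (the average-increment-by-length view of a
#' stock), each age contributes one pair: the unweighted mean of \eqn{L_a}
#' and of \eqn{dL_a} across the cohorts observed at that age. `"pooled"`
#' returns the union of all raw pairs.
#'
#' @param cohorts List of [cohort_series()] (or a single one).
#' @param mode `"per_age_average"` or `"pooled"`.
#' @return An [increment_set()]; in per-age-average mode `birth_year` is
#'   `NA` and `age` identifies the averaged pair.
#' @export
pool_increments <- function(cohorts, mode = c("per_age_average", "pooled")) {
  mode <- match.arg(mode)
  if (inherits(cohorts, "cohort_series")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop_unusable("`cohorts` is empty")
  pairs <- do.call(rbind, lapply(cohorts, cohort_increments))
  class(pairs) <- c("increment_set", "data.frame")
  if (mode == "pooled") return(pairs)
  ages <- sort(unique(pairs$age))
  increment_set(
    rep(NA_integer_, length(ages)), ages,
    vapply(ages, function(a) mean(pairs$length[pairs$age == a]), numeric(1)),
    vapply(ages, function(a) mean(pairs$increment[pairs$age == a]), numeric(1))
  )
}
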