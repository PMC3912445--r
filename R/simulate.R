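# Forward projection under the law with time-varying environmental k,
# plus Fulton weight-length conversion for biomass. Because the law is
# time-free, increments can be summed across all year-classes present in
# the same year, which is what makes stock-level projection a plain sum.

#' Fulton condition factor
#'
#' The constant `c` of the cubic length-weight relation \eqn{W = c L^3}.
#' Units follow the declaration: weight unit per cubed length unit (the
#' classic North Sea cod value 0.0104 maps length in cm to weight in g).
#'
#' @param value Positive constant.
#' @param weight_unit,length_unit Unit tags.
#' @return An object of class `condition_factor`.
#' @export
condition_factor <- function(value, weight_unit = "g", length_unit = "cm") {
  stopifnot_scalar_number(value, "value")
  if (value <= 0) stop_domain("condition factor must be > 0")
  structure(list(value = value, weight_unit = weight_unit,
                 length_unit = length_unit),
            class = "condition_factor")
}

as_condition_factor <- function(cf) {
  if (inherits(cf, "condition_factor")) return(cf)
  condition_factor(cf)
}

#' Length to weight by Fulton's relation
#'
#' \eqn{W = c L^3}.
#'
#' @param length Length(s) `>= 0`, in the factor's length unit.
#' @param cf A [condition_factor()] (or a bare positive number).
#' @return Weight(s) in the factor's weight unit.
#' @examples
#' length_to_weight(10, condition_factor(0.0104)) # 10.4
#' @export
length_to_weight <- function(length, cf) {
  cf <- as_condition_factor(cf)
  if (any(!is.finite(length)) || any(length < 0)) stop_domain("`length` must be >= 0")
  cf$value * length^3
}

#' Weight to length, the exact inverse
#'
#' \eqn{L = (W / c)^{1/3}}.
#'
#' @param weight Weight(s) `>= 0`.
#' @inheritParams length_to_weight
#' @return Length(s).
#' @export
weight_to_length <- function(weight, cf) {
  cf <- as_condition_factor(cf)
  if (any(!is.finite(weight)) || any(weight < 0)) stop_domain("`weight` must be >= 0")
  (weight / cf$value)^(1 / 3)
}

check_k_series <- function(k_series) {
  if (!is.numeric(k_series) || any(!is.finite(k_series))) {
    stop_domain("`k_series` must be finite and numeric")
  }
  if (any(k_series < 0 | k_series > 1)) stop_domain("every k must lie in [0, 1]")
  as.numeric(k_series)
}

#' Project one cohort under time-varying k
#'
#' Apply the law stepwise with a per-step environmental coefficient:
#' \eqn{L_{t+1} = L_t + k_t (L_{max} - L_t)}. With a constant series this
#' reduces exactly to [trajectory_closed_form()].
#'
#' @param l0 Starting length, `<= l_max`.
#' @param params A [growth_params()] (its `k` is ignored; the series
#'   rules).
#' @param k_series Numeric vector of per-step k values in `[0, 1]`, one
#'   per projection step.
#' @return Lengths at steps `0..length(k_series)`.
#' @examples
#' project_cohort(0, growth_params(0.5, 100), c(0.5, 0.25)) # 0 50 62.5
#' @export
project_cohort <- function(l0, params, k_series) {
  check_params(params)
  k_series <- check_k_series(k_series)
  l <- check_length_state(l0, params)
  out <- numeric(length(k_series) + 1L)
  out[1L] <- l
  for (t in seq_along(k_series)) {
    l <- min(l + k_series[t] * (params$l_max - l), params$l_max)
    out[t + 1L] <- l
  }
  out
}

#' State of one cohort in a stock
#'
#' @param birth_step Integer step at which the cohort entered the stock.
#' @param length Current mean length, `<= l_max` of `params`.
#' @param abundance Number of individuals, `>= 0`.
#' @param params The cohort's [growth_params()].
#' @return An object of class `cohort_state`.
#' @export
cohort_state <- function(birth_step, length, abundance, params) {
  check_params(params)
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(abundance, "abundance")
  if (abundance < 0) stop_domain("`abundance` must be >= 0")
  length <- check_length_state(length, params)
  structure(list(birth_step = as.integer(birth_step), length = length,
                 abundance = abundance, params = params),
            class = "cohort_state")
}

#' Stock biomass across year-classes
#'
#' Per-cohort biomass is `abundance * c * L^3`; the stock total is the
#' plain sum over all cohorts present in the same step -- the
#' across-year-class summation a time-indexed growth curve cannot do. All
#' cohorts must share one length unit, which must match the condition
#' factor's.
#'
#' @param states List of [cohort_state()] (may be empty).
#' @param cf A [condition_factor()].
#' @return List with `total` and `per_cohort` (data frame of
#'   `birth_step`, `length`, `abundance`, `biomass`).
#' @export
stock_biomass <- function(states, cf) {
  cf <- as_condition_factor(cf)
  if (inherits(states, "cohort_state")) states <- list(states)
  if (!length(states)) {
    return(list(total = 0, per_cohort = data.frame(
      birth_step = integer(), length = numeric(),
      abundance = numeric(), biomass = numeric())))
  }
  units <- vapply(states, function(s) s$params$unit, character(1))
  if (length(unique(units)) != 1L || units[1] != cf$length_unit) {
    stop_unit_mismatch(sprintf(
      "cohort length units {%s} must all match the condition factor's '%s'",
      paste(unique(units), collapse = ","), cf$length_unit))
  }
  per <- data.frame(
    birth_step = vapply(states, `[[`, integer(1), "birth_step"),
    length = vapply(states, `[[`, numeric(1), "length"),
    abundance = vapply(states, `[[`, numeric(1), "abundance")
  )
  per$biomass <- per$abundance * length_to_weight(per$length, cf)
  list(total = sum(per$biomass), per_cohort = per)
}

#' Project one cohort's length, abundance and biomass forward
#'
#' Step-by-step projection of a single cohort under a k series, with
#' optional exogenous per-step survival multipliers (mortality and
#' recruitment are inputs, not modelled). States at step boundaries do not
#' depend on the within-step ordering of growth and mortality; what does
#' is the length at which removed fish are accounted, so the `order` flag
#' controls the `removed_biomass` column: `"growth_first"` removes fish at
#' their post-growth length, `"mortality_first"` at their pre-growth
#' length.
#'
#' @param state A [cohort_state()].
#' @param k_series Per-step k values in `[0, 1]`.
#' @param survival Optional per-step abundance multipliers (`>= 0`), same
#'   length as `k_series`; an unequal length is an error, never recycled.
#' @param cf A [condition_factor()] for the weight and biomass columns.
#' @param order `"growth_first"` (default) or `"mortality_first"`.
#' @return Data frame with one row per step `0..n`: `step`, `length`,
#'   `weight`, `abundance`, `biomass`, `removed_biomass` (0 at step 0).
#' @export
project_stock <- function(state, k_series, survival = NULL,
                          cf = condition_factor(0.0104),
                          order = c("growth_first", "mortality_first")) {
  order <- match.arg(order)
  if (!inherits(state, "cohort_state")) stop_unusable("`state` must be a cohort_state")
  cf <- as_condition_factor(cf)
  if (state$params$unit != cf$length_unit) {
    stop_unit_mismatch(sprintf("cohort unit '%s' does not match condition factor unit '%s'",
                               state$params$unit, cf$length_unit))
  }
  k_series <- check_k_series(k_series)
  n <- length(k_series)
  if (is.null(survival)) survival <- rep(1, n)
  if (length(survival) != n) {
    stop_unusable("`survival` must have one multiplier per projection step")
  }
  if (any(survival < 0)) stop_domain("survival multipliers must be >= 0")
  lengths <- project_cohort(state$length, state$params, k_series)
  abund <- numeric(n + 1L)
  abund[1L] <- state$abundance
  for (t in seq_len(n)) abund[t + 1L] <- abund[t] * survival[t]
  weight <- length_to_weight(lengths, cf)
  removed <- pmax(abund[-(n + 1L)] - abund[-1L], 0)
  removal_length <- if (order == "growth_first") lengths[-1L] else lengths[-(n + 1L)]
  removed_biomass <- c(0, removed * length_to_weight(removal_length, cf))
  if (n == 0L) removed_biomass <- 0
  data.frame(step = 0:n, length = lengths, weight = weight,
             abundance = abund, biomass = abund * weight,
             removed_biomass = removed_biomass)
}
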