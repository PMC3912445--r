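# Core growth law: dL = k * (Lmax - L).
# The model is time-free: one "step" is whatever interval separates two
# consecutive observations (a year for survey data, a sampling interval for
# lab data). The step tag is carried as metadata only; no internal time
# arithmetic is ever performed.

# Absolute tolerance for floating comparisons against Lmax, in length units.
LMAX_TOL <- 1e-9

#' Growth-law parameters
#'
#' Bundle the two parameters of the length-increment growth law
#' \eqn{dL = k (L_{max} - L_s)}: the dimensionless environmental growth
#' coefficient `k` and the maximal attainable length `l_max`. `k` captures
#' the environment (food availability, temperature) over one step; `l_max`
#' is a fixed maximal length, reached when increments hit zero -- not an
#' asymptote in the von Bertalanffy sense.
#'
#' `k` must lie in `[0, 1]`: negative `k` would shrink the animal and
#' `k > 1` would overshoot `l_max`, both unphysical under the law.
#'
#' @param k Dimensionless growth coefficient per step, in `[0, 1]`.
#' @param l_max Maximal length, in `unit`s; must be positive.
#' @param unit Length-unit tag, e.g. `"mm"` or `"cm"`.
#' @param step Nominal duration tag of one increment step (metadata only).
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(k = 0.3, l_max = 354, unit = "mm")
#' @export
growth_params <- function(k, l_max, unit = "mm", step = "year") {
  stopifnot_scalar_number(k, "k")
  stopifnot_scalar_number(l_max, "l_max")
  if (k < 0) stop_domain("`k` must be >= 0: the animal cannot shrink")
  if (k > 1) stop_domain("`k` must be <= 1: one step cannot overshoot `l_max`")
  if (l_max <= 0) stop_domain("`l_max` must be > 0")
  if (!is.character(unit) || length(unit) != 1L) stop_domain("`unit` must be a single string")
  structure(
    list(k = k, l_max = l_max, unit = unit, step = step),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth-law parameters: k = %g per %s, l_max = %g %s\n",
              x$k, x$step, x$l_max, x$unit))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "growth_params")) {
    stop_domain("`params` must be a `growth_params` object")
  }
  params
}

check_length_state <- function(length, params) {
  if (!is.numeric(length) || any(!is.finite(length))) {
    stop_domain("`length` must be finite and numeric")
  }
  if (any(length < 0)) stop_domain("`length` must be >= 0")
  if (any(length > params$l_max + LMAX_TOL)) {
    stop_domain(sprintf(
      "length %g exceeds l_max = %g: the increment cannot be negative",
      max(length), params$l_max))
  }
  pmin(length, params$l_max)
}

#' Predicted length increment at a given length
#'
#' Evaluate the growth law \eqn{dL = k (L_{max} - L_s)} at the current
#' length. The increment is always non-negative and is zero exactly at
#' `l_max`.
#'
#' @param params A [growth_params()] object.
#' @param length Current length(s), same unit as `params`; must not exceed
#'   `l_max`.
#' @return Predicted increment(s), in length units.
#' @examples
#' p <- growth_params(0.1, 354)
#' predict_increment(p, 300) # 5.4
#' @export
predict_increment <- function(params, length) {
  check_params(params)
  length <- check_length_state(length, params)
  params$k * (params$l_max - length)
}

#' Apply one growth step
#'
#' Advance a length by one application of the law:
#' \eqn{L \leftarrow L + k (L_{max} - L)}. For `k` in `[0, 1]` the result
#' never exceeds `l_max`.
#'
#' @inheritParams predict_increment
#' @return New length(s) after one step.
#' @examples
#' growth_step(growth_params(0.5, 100), 0) # 50
#' @export
growth_step <- function(params, length) {
  length <- check_length_state(length, check_params(params))
  pmin(length + params$k * (params$l_max - length), params$l_max)
}

#' Constant-k growth trajectory in closed form
#'
#' Under constant `k` the recursion solves to geometric decay of the
#' remaining gap: \eqn{L_n = L_{max} - (L_{max} - L_0)(1 - k)^n}. The
#' sequence is non-decreasing and converges to `l_max`.
#'
#' @param l0 Starting length, in `[0, l_max]`.
#' @param params A [growth_params()] object.
#' @param n Number of steps (`n >= 0`); the result has `n + 1` elements,
#'   the first being `l0`.
#' @return Numeric vector of lengths at steps `0..n`.
#' @examples
#' trajectory_closed_form(0, growth_params(0.5, 100), 3) # 0 50 75 87.5
#' @export
trajectory_closed_form <- function(l0, params, n) {
  check_params(params)
  stopifnot_scalar_number(l0, "l0")
  stopifnot_scalar_number(n, "n")
  if (n < 0 || n != round(n)) stop_domain("`n` must be a non-negative integer")
  l0 <- check_length_state(l0, params)
  params$l_max - (params$l_max - l0) * (1 - params$k)^(0:n)
}
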