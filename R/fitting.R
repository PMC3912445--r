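# Least-squares estimation of (k, Lmax) and the linear-vs-quadratic model
# comparison. Rearranged, the law is a straight line in the increment
# plane: dL = -k * L + k * Lmax, so k = -slope and Lmax = -intercept/slope.

as_pairs <- function(pairs) {
  if (inherits(pairs, "cohort_series")) pairs <- cohort_increments(pairs)
  if (!is.data.frame(pairs) || !all(c("length", "increment") %in% names(pairs))) {
    stop_unusable("`pairs` must be an increment_set (columns `length`, `increment`)")
  }
  pairs
}

# Tolerance under which a residual sum of squares counts as an exact fit,
# relative to the scale of the response.
ss_is_zero <- function(ss, scale) ss <= 1e-12 * max(scale, 1)

#' Fit the linear growth law to increment pairs
#'
#' Ordinary least squares of increment on length. When the slope is
#' negative -- the only case in which the law can hold -- the growth
#' parameters are derived as `k = -slope` and `l_max = -intercept/slope`
#' (the intercept equals `k * l_max`); otherwise both are `NA`.
#'
#' @param pairs An [increment_set()] (or anything with `length` and
#'   `increment` columns); at least 3 pairs with 2 distinct lengths.
#' @return A `linear_fit`: slope/intercept with standard errors and
#'   covariance, residual and total sums of squares, `r_squared`, `n`, and
#'   the derived `k` and `l_max`.
#' @examples
#' fit_linear(increment_set(length = c(0, 10, 20), increment = c(10, 8, 6)))
#' @export
fit_linear <- function(pairs) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3L) stop_insufficient("linear fit needs >= 3 increment pairs")
  if (length(unique(pairs$length)) < 2L) {
    stop_degenerate("all lengths identical: slope is unidentifiable")
  }
  fit <- stats::lm(increment ~ length, data = pairs)
  co <- stats::coef(fit)
  # summary.lm warns on numerically perfect fits (noiseless fixtures);
  # the zero variances it returns are exactly what we want
  vc <- suppressWarnings(stats::vcov(fit))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((pairs$increment - mean(pairs$increment))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  slope <- unname(co["length"])
  intercept <- unname(co["(Intercept)"])
  structure(
    list(
      slope = slope, intercept = intercept,
      se_slope = sqrt(vc["length", "length"]),
      se_intercept = sqrt(vc["(Intercept)", "(Intercept)"]),
      cov_slope_intercept = vc["(Intercept)", "length"],
      rss = rss, tss = tss, r_squared = max(0, min(1, r2)), n = n,
      k = if (slope < 0) -slope else NA_real_,
      l_max = if (slope < 0) -intercept / slope else NA_real_,
      df_residual = n - 2L
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear increment fit (n = %d): dL = %.6g %+.6g * L, R^2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  if (is.na(x$k)) {
    cat("  slope >= 0: k and l_max undefined under the law\n")
  } else {
    cat(sprintf("  k = %.6g, l_max = %.6g\n", x$k, x$l_max))
  }
  invisible(x)
}

#' Confidence intervals for k and l_max
#'
#' `k = -slope` inherits the slope's standard error directly; `l_max =
#' -intercept/slope` gets a delta-method standard error from the
#' (intercept, slope) covariance. Both intervals use the t distribution
#' with `n - 2` degrees of freedom.
#'
#' @param fit A `linear_fit` with defined `k` and `l_max`.
#' @param level Confidence level (default 0.95).
#' @return A data frame with rows `k` and `l_max` and columns `estimate`,
#'   `se`, `lower`, `upper`.
#' @export
growth_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "linear_fit")) stop_unusable("`fit` must be a linear_fit")
  if (is.na(fit$k)) stop_domain("k and l_max are undefined (non-negative slope)")
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df_residual)
  se_k <- fit$se_slope
  # l_max = -b0/b1; gradient (-1/b1, b0/b1^2) wrt (b0, b1)
  g <- c(-1 / fit$slope, fit$intercept / fit$slope^2)
  vc <- matrix(c(fit$se_intercept^2, fit$cov_slope_intercept,
                 fit$cov_slope_intercept, fit$se_slope^2), 2)
  se_lmax <- sqrt(drop(t(g) %*% vc %*% g))
  data.frame(
    row.names = c("k", "l_max"),
    estimate = c(fit$k, fit$l_max),
    se = c(se_k, se_lmax),
    lower = c(fit$k - tq * se_k, fit$l_max - tq * se_lmax),
    upper = c(fit$k + tq * se_k, fit$l_max + tq * se_lmax)
  )
}

#' Fit the quadratic alternative to increment pairs
#'
#' Ordinary least squares of increment on (length, length^2). The
#' `orientation` flag records the sign of the quadratic coefficient:
#' `"concave"` (negative, the sigmoid-growth shape) or `"convex"`
#' (positive, the inverted parabola seen in some pelagic stocks).
#'
#' @param pairs At least 4 pairs with 3 distinct lengths.
#' @return A `quadratic_fit`: coefficients `c0`, `c1`, `c2` of
#'   `dL = c2 L^2 + c1 L + c0`, `rss`, `r_squared`, `n`, `orientation`.
#' @export
fit_quadratic <- function(pairs) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  if (n < 4L) stop_insufficient("quadratic fit needs >= 4 increment pairs")
  if (length(unique(pairs$length)) < 3L) {
    stop_degenerate("need >= 3 distinct lengths for a quadratic fit")
  }
  fit <- stats::lm(increment ~ length + I(length^2), data = pairs)
  if (fit$rank < 3L) stop_degenerate("rank-deficient quadratic design")
  co <- unname(stats::coef(fit))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((pairs$increment - mean(pairs$increment))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  structure(
    list(
      c0 = co[1], c1 = co[2], c2 = co[3],
      rss = rss, tss = tss, r_squared = max(0, min(1, r2)), n = n,
      orientation = if (co[3] >= 0) "convex" else "concave"
    ),
    class = "quadratic_fit"
  )
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Quadratic increment fit (n = %d): dL = %.6g %+.6g * L %+.6g * L^2, R^2 = %.4f (%s)\n",
              x$n, x$c0, x$c1, x$c2, x$r_squared, x$orientation))
  invisible(x)
}

#' Compare the linear law against the quadratic alternative
#'
#' Extra-sum-of-squares F-test for the nested pair: \eqn{F = ((SS_{lin} -
#' SS_{quad})/1) / (SS_{quad}/(n-3))} with an upper-tail p-value from
#' F(1, n-3). The quadratic is preferred iff `p < alpha`; exact ties
#' (both models fit perfectly) go to the simpler linear model. A
#' small-sample AICc comparison is reported alongside as an alternative
#' criterion but does not set the verdict unless requested.
#'
#' @param lin A `linear_fit` and @param quad a `quadratic_fit` computed on
#'   the same pairs (`n >= 5` so the denominator has >= 2 df).
#' @param alpha Significance level for the verdict (default 0.05).
#' @param criterion `"f_test"` (default) or `"aicc"`.
#' @return A `model_comparison`: `f`, `df1`, `df2`, `p_value`, `verdict`
#'   (`"linear-preferred"` or `"quadratic-preferred"`), `alpha`,
#'   `aicc_linear`, `aicc_quadratic`.
#' @export
compare_models <- function(lin, quad, alpha = 0.05, criterion = c("f_test", "aicc")) {
  criterion <- match.arg(criterion)
  if (!inherits(lin, "linear_fit") || !inherits(quad, "quadratic_fit")) {
    stop_unusable("`lin` and `quad` must be linear_fit and quadratic_fit objects")
  }
  if (lin$n != quad$n) stop_unusable("fits were not computed on the same pairs")
  n <- lin$n
  if (n < 5L) stop_insufficient("model comparison needs n >= 5 pairs")
  df2 <- n - 3L
  scale <- max(lin$tss, 1)
  if (ss_is_zero(quad$rss, scale)) {
    if (ss_is_zero(lin$rss, scale)) {
      f <- 0; p <- 1 # both exact: simpler model wins the tie
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- max(0, (lin$rss - quad$rss)) / (quad$rss / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  # AICc with parameter counts including the error variance
  aicc <- function(rss, npar) {
    kk <- npar + 1
    n * log(max(rss, 1e-300) / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
  }
  a_lin <- aicc(lin$rss, 2); a_quad <- aicc(quad$rss, 3)
  verdict <- if (criterion == "f_test") {
    if (p < alpha) "quadratic-preferred" else "linear-preferred"
  } else {
    if (a_quad < a_lin) "quadratic-preferred" else "linear-preferred"
  }
  structure(
    list(f = f, df1 = 1L, df2 = df2, p_value = p, alpha = alpha,
         verdict = verdict, criterion = criterion,
         aicc_linear = a_lin, aicc_quadratic = a_quad),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Extra-sum-of-squares F(%d, %d) = %.4g, p = %.4g -> %s (alpha = %g)\n",
              x$df1, x$df2, x$f, x$p_value, x$verdict, x$alpha))
  invisible(x)
}

#' Detect deviating young ages in a cohort
#'
#' Young fish often show lowered increments that fall off the straight
#' line fitted to older ages (read as a lowered environmental `k` early in
#' life). Starting from all increment pairs, the youngest age is dropped
#' while the linear fit on the remainder has `r_squared` below the
#' threshold and at least `min_points` pairs remain. Only a prefix of
#' youngest ages is ever excluded; if no suffix reaches the threshold the
#' full set is returned flagged `threshold_met = FALSE`.
#'
#' @param series A [cohort_series()] yielding at least `min_points` pairs.
#' @param r2_threshold R-squared required of the core fit (default 0.98).
#' @param min_points Minimum number of pairs the core fit may keep
#'   (default 3).
#' @return A list with `core_ages` (pair start ages kept),
#'   `excluded_ages` (youngest pair ages dropped), `fit` (the core
#'   `linear_fit`), and `threshold_met`.
#' @export
detect_deviating_ages <- function(series, r2_threshold = 0.98, min_points = 3L) {
  pairs <- if (is.data.frame(series)) as_pairs(series) else cohort_increments(series)
  pairs <- pairs[order(pairs$age), , drop = FALSE]
  n <- nrow(pairs)
  if (n < min_points) stop_insufficient("fewer increment pairs than `min_points`")
  for (start in seq_len(n - min_points + 1L)) {
    sub <- pairs[start:n, , drop = FALSE]
    fit <- fit_linear(sub)
    if (fit$r_squared >= r2_threshold) {
      return(list(core_ages = sub$age, excluded_ages = pairs$age[seq_len(start - 1L)],
                  fit = fit, threshold_met = TRUE))
    }
  }
  list(core_ages = pairs$age, excluded_ages = integer(),
       fit = fit_linear(pairs), threshold_met = FALSE)
}

#' Per-age growth coefficient against a known maximal length
#'
#' For an age that sits off the cohort's fitted line, its own `k` is the
#' slope of the straight line from its (length, increment) point to
#' (`l_max`, 0): \eqn{k_a = dL_a / (L_{max} - L_a)}. A negative observed
#' increment is clamped to `k = 0` (a single-point ratio has no
#' noise-cancelling context, unlike a regression) and flagged via the
#' `"clamped"` attribute.
#'
#' @param dl Observed increment(s).
#' @param length Start-of-interval length(s), strictly below `l_max`.
#' @param l_max Maximal length.
#' @return Numeric `k` value(s) with a logical `"clamped"` attribute.
#' @examples
#' k_for_age(5.4, 300, 354) # 0.1
#' @export
k_for_age <- function(dl, length, l_max) {
  if (any(!is.finite(dl)) || any(!is.finite(length))) stop_domain("non-finite inputs")
  stopifnot_scalar_number(l_max, "l_max")
  if (any(length >= l_max)) stop_domain("`length` must be strictly below `l_max`")
  clamped <- dl < 0
  k <- pmax(dl, 0) / (l_max - length)
  attr(k, "clamped") <- clamped
  k
}

#' Per-age k across year-classes
#'
#' For every cohort, [detect_deviating_ages()] splits ages into a core
#' that defines the cohort's straight line and a deviating young prefix.
#' Core ages receive the core-fit `k` (source `"on-line"`); deviating ages
#' receive an individual [k_for_age()] against a shared maximal length,
#' the unweighted mean of the per-cohort core `l_max` estimates (source
#' `"off-line"`). Cohorts whose core fit leaves `l_max` undefined are kept
#' as flagged rows, never dropped silently.
#'
#' @param cohorts List of [cohort_series()].
#' @inheritParams detect_deviating_ages
#' @return A list with `shared_l_max` and `estimates`, a data frame with
#'   columns `birth_year`, `age`, `k`, `source`, `flagged`.
#' @export
k_by_yearclass <- function(cohorts, r2_threshold = 0.98, min_points = 3L) {
  if (inherits(cohorts, "cohort_series")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop_unusable("`cohorts` is empty")
  det <- lapply(cohorts, detect_deviating_ages,
                r2_threshold = r2_threshold, min_points = min_points)
  lmaxes <- vapply(det, function(d) d$fit$l_max, numeric(1))
  shared_l_max <- mean(lmaxes[!is.na(lmaxes)])
  rows <- list()
  for (i in seq_along(cohorts)) {
    s <- cohorts[[i]]; d <- det[[i]]
    pairs <- cohort_increments(s)
    undefined <- is.na(d$fit$l_max)
    for (j in seq_len(nrow(pairs))) {
      a <- pairs$age[j]
      if (a %in% d$core_ages) {
        rows[[length(rows) + 1L]] <- data.frame(
          birth_year = s$birth_year, age = a,
          k = if (undefined) NA_real_ else d$fit$k,
          source = "on-line", flagged = undefined)
      } else {
        if (is.finite(shared_l_max) && pairs$length[j] < shared_l_max) {
          kk <- k_for_age(pairs$increment[j], pairs$length[j], shared_l_max)
          rows[[length(rows) + 1L]] <- data.frame(
            birth_year = s$birth_year, age = a, k = as.numeric(kk),
            source = "off-line", flagged = attr(kk, "clamped"))
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            birth_year = s$birth_year, age = a, k = NA_real_,
            source = "off-line", flagged = TRUE)
        }
      }
    }
  }
  list(shared_l_max = shared_l_max, estimates = do.call(rbind, rows))
}
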