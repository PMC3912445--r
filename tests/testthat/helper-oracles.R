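# Independent oracles, deliberately coded from first principles so they
# share no path with the package implementation.

# Simple linear regression via the textbook sums-of-squares formulas.
oracle_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 2)
  list(slope = slope, intercept = intercept, rss = rss,
       r_squared = 1 - rss / tss,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)))
}

# Polynomial least squares by explicit normal equations on the
# Vandermonde design.
oracle_poly <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(coef = drop(beta), rss = sum(resid^2))
}

# Upper-tail F probability by numerical integration of the density.
oracle_f_upper <- function(f, df1, df2) {
  stats::integrate(function(t) stats::df(t, df1, df2), lower = f, upper = Inf,
                   rel.tol = 1e-10)$value
}

# Noiseless cohort series grown directly by the recursion (no package
# code), with optional per-age k.
oracle_cohort <- function(birth_year, ages, l1, k, l_max, k_by_age = NULL) {
  lens <- numeric(length(ages))
  lens[1] <- l1
  for (j in seq_len(length(ages) - 1)) {
    kj <- if (!is.null(k_by_age)) k_by_age[j] else k
    lens[j + 1] <- lens[j] + kj * (l_max - lens[j])
  }
  cohort_series(birth_year, ages, lens)
}
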