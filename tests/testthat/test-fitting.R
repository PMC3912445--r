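pairs_of <- function(L, dL) increment_set(length = L, increment = dL)

test_that("fit_linear recovers an exact line and derives (k, l_max)", {
  fit <- fit_linear(pairs_of(c(0, 10, 20), c(10, 8, 6)))
  expect_equal(fit$slope, -0.2)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$k, 0.2)
  expect_equal(fit$l_max, 50)
  expect_equal(fit$r_squared, 1)
})

test_that("fit_linear matches the hand-computed normal equations on a noisy triple", {
  fit <- fit_linear(pairs_of(c(0, 10, 20), c(10, 8.5, 5.5)))
  expect_equal(fit$slope, -0.225)
  expect_equal(fit$intercept, 10.25)
  expect_equal(fit$k, 0.225)
  expect_equal(fit$l_max, 10.25 / 0.225)
  expect_equal(fit$r_squared, 1 - 0.375 / 10.5)
})

test_that("a non-negative slope leaves the growth parameters undefined", {
  fit <- fit_linear(pairs_of(c(0, 10, 20), c(1, 2, 3)))
  expect_true(is.na(fit$k))
  expect_true(is.na(fit$l_max))
  expect_error(growth_ci(fit), class = "lengthlaw_domain_error")
})

test_that("degenerate and undersized designs are rejected", {
  expect_error(fit_linear(pairs_of(c(5, 5, 5), c(1, 2, 3))),
               class = "lengthlaw_degenerate_design_error")
  expect_error(fit_linear(pairs_of(c(1, 2), c(1, 2))),
               class = "lengthlaw_insufficient_data_error")
  expect_error(fit_quadratic(pairs_of(c(1, 2, 3), c(1, 2, 3))),
               class = "lengthlaw_insufficient_data_error")
  expect_error(fit_quadratic(pairs_of(c(1, 1, 2, 2), c(1, 2, 3, 4))),
               class = "lengthlaw_degenerate_design_error")
})

test_that("fit_quadratic interpolates an exact parabola and flags orientation", {
  x <- c(0, 10, 20, 30)
  y <- -0.0027 * x^2 + 0.078 * x + 0.25
  fit <- fit_quadratic(pairs_of(x, y))
  expect_equal(fit$c0, 0.25, tolerance = 1e-9)
  expect_equal(fit$c1, 0.078, tolerance = 1e-9)
  expect_equal(fit$c2, -0.0027, tolerance = 1e-9)
  expect_equal(fit$orientation, "concave")
  # exact collinear points give a zero quadratic coefficient
  lin <- fit_quadratic(pairs_of(c(0, 5, 10, 15), c(8, 7, 6, 5)))
  expect_equal(lin$c2, 0, tolerance = 1e-10)
  expect_equal(lin$c1, -0.2, tolerance = 1e-10)
  expect_equal(lin$c0, 8, tolerance = 1e-10)
  convex <- fit_quadratic(pairs_of(x, 0.002 * x^2 - 0.3 * x + 9))
  expect_equal(convex$orientation, "convex")
})

test_that("both fits agree with independent normal-equations oracles", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    x <- runif(n, 0, 300)
    y <- runif(1, 5, 40) - runif(1, 0.01, 0.2) * x + rnorm(n, 0, 2)
    fit <- fit_linear(pairs_of(x, y))
    ol <- oracle_line(x, y)
    expect_equal(fit$slope, ol$slope, tolerance = 1e-8)
    expect_equal(fit$intercept, ol$intercept, tolerance = 1e-8)
    expect_equal(fit$rss, ol$rss, tolerance = 1e-8)
    expect_equal(fit$r_squared, ol$r_squared, tolerance = 1e-8)
    expect_equal(fit$se_slope, ol$se_slope, tolerance = 1e-8)
    expect_equal(fit$se_intercept, ol$se_intercept, tolerance = 1e-8)
    quad <- fit_quadratic(pairs_of(x, y))
    oq <- oracle_poly(x, y, 2)
    expect_equal(c(quad$c0, quad$c1, quad$c2), unname(oq$coef), tolerance = 1e-8)
    expect_equal(quad$rss, oq$rss, tolerance = 1e-8)
  }
})

test_that("model comparison breaks exact ties toward the linear law", {
  x <- c(0, 5, 10, 15, 20)
  y <- 10 - 0.3 * x
  cmp <- compare_models(fit_linear(pairs_of(x, y)), fit_quadratic(pairs_of(x, y)))
  expect_equal(cmp$f, 0)
  expect_equal(cmp$verdict, "linear-preferred")
  expect_error(
    compare_models(fit_linear(pairs_of(x[1:4], y[1:4])),
                   fit_quadratic(pairs_of(x[1:4], y[1:4]))),
    class = "lengthlaw_insufficient_data_error")
})

test_that("the F p-value matches numerical integration of the F density", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    x <- runif(n, 0, 200)
    y <- 30 - 0.1 * x + rnorm(n, 0, 1.5)
    cmp <- compare_models(fit_linear(pairs_of(x, y)), fit_quadratic(pairs_of(x, y)))
    expect_equal(cmp$p_value, oracle_f_upper(cmp$f, 1, n - 3), tolerance = 1e-7)
    expect_gte(cmp$f, 0)
    expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  }
})

test_that("AICc is available as an alternative comparison criterion", {
  set.seed(33)
  x <- seq(10, 200, length.out = 12)
  y <- 40 - 0.15 * x + rnorm(12, 0, 1)
  cmp <- compare_models(fit_linear(pairs_of(x, y)), fit_quadratic(pairs_of(x, y)),
                        criterion = "aicc")
  expect_equal(cmp$criterion, "aicc")
  expect_true(cmp$verdict %in% c("linear-preferred", "quadratic-preferred"))
  expect_true(is.finite(cmp$aicc_linear) && is.finite(cmp$aicc_quadratic))
})

test_that("deviating-age detection drops exactly the suppressed young prefix", {
  k <- 0.3; l_max <- 354
  kk <- c(0.15, 0.15, rep(k, 6))
  s <- oracle_cohort(1993, 1:9, 90, k, l_max, k_by_age = kk)
  det <- detect_deviating_ages(s)
  expect_equal(det$excluded_ages, 1:2)
  expect_equal(det$core_ages, 3:8)
  expect_true(det$threshold_met)
  expect_equal(det$fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(det$fit$k, k, tolerance = 1e-9)
  expect_equal(det$fit$l_max, l_max, tolerance = 1e-6)
  # oracle: exhaustive evaluation of every drop-youngest prefix finds the
  # same (largest) suffix
  pairs <- cohort_increments(s)
  ok <- vapply(1:6, function(start) {
    fit_linear(pairs[start:8, ])$r_squared >= 0.98
  }, logical(1))
  expect_equal(min(which(ok)), 3L)
})

test_that("an exact-line cohort is kept whole and detection is idempotent", {
  s <- oracle_cohort(1988, 1:9, 90, 0.3, 354)
  det <- detect_deviating_ages(s)
  expect_equal(det$excluded_ages, integer())
  expect_equal(det$fit$r_squared, 1, tolerance = 1e-9)
  # idempotent: re-running on the core pairs changes nothing
  pairs <- cohort_increments(s)
  again <- detect_deviating_ages(pairs[pairs$age %in% det$core_ages, ])
  expect_equal(again$core_ages, det$core_ages)
  expect_equal(again$excluded_ages, integer())
})

test_that("a minimal cohort below threshold is returned whole, flagged not met", {
  # 3 pairs that no line fits well, and nothing may be dropped
  s <- cohort_series(2000, 1:4, c(10, 30, 31, 60))
  det <- detect_deviating_ages(s, r2_threshold = 0.98, min_points = 3)
  expect_false(det$threshold_met)
  expect_equal(det$core_ages, 1:3)
  expect_equal(det$excluded_ages, integer())
})

test_that("k_for_age is the slope of the line to (l_max, 0)", {
  expect_equal(as.numeric(k_for_age(20, 100, 354)), 20 / 254)
  expect_equal(as.numeric(k_for_age(0, 100, 354)), 0)
  expect_equal(as.numeric(k_for_age(5.4, 300, 354)), 0.1)
  clamped <- k_for_age(-2, 100, 354)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_error(k_for_age(5, 354, 354), class = "lengthlaw_domain_error")
})

test_that("per-year-class k recovers the generating per-age coefficients", {
  k <- 0.3; l_max <- 354
  kk <- c(0.15, 0.15, rep(k, 6))
  cohorts <- lapply(1:4, function(i) {
    oracle_cohort(1984 + i, 1:9, 70 + 10 * i, k, l_max, k_by_age = kk)
  })
  res <- k_by_yearclass(cohorts)
  expect_equal(res$shared_l_max, l_max, tolerance = 1e-6)
  on_line <- res$estimates[res$estimates$source == "on-line", ]
  off_line <- res$estimates[res$estimates$source == "off-line", ]
  expect_equal(sort(unique(off_line$age)), 1:2)
  expect_equal(on_line$k, rep(k, nrow(on_line)), tolerance = 1e-8)
  expect_equal(off_line$k, rep(0.15, nrow(off_line)), tolerance = 1e-6)
  # constant-k cohorts: every estimate is the shared k
  plain <- lapply(1:3, function(i) oracle_cohort(1990 + i, 1:9, 80 + 15 * i, k, l_max))
  res2 <- k_by_yearclass(plain)
  expect_equal(res2$estimates$k, rep(k, nrow(res2$estimates)), tolerance = 1e-9)
  # a single cohort's shared l_max is its own estimate
  res3 <- k_by_yearclass(plain[1])
  expect_equal(res3$shared_l_max, detect_deviating_ages(plain[[1]])$fit$l_max)
})

test_that("fits are scale equivariant: k, R^2, F and p are unit-free", {
  set.seed(34)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    x <- runif(n, 20, 300)
    y <- 35 - 0.12 * x + rnorm(n, 0, 1.5)
    cc <- runif(1, 0.05, 30)
    f1 <- fit_linear(pairs_of(x, y)); f2 <- fit_linear(pairs_of(cc * x, cc * y))
    expect_equal(f2$k, f1$k, tolerance = 1e-9)
    expect_equal(f2$l_max, cc * f1$l_max, tolerance = 1e-8)
    expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
    c1 <- compare_models(f1, fit_quadratic(pairs_of(x, y)))
    c2 <- compare_models(f2, fit_quadratic(pairs_of(cc * x, cc * y)))
    expect_equal(c2$f, c1$f, tolerance = 1e-7)
    expect_equal(c2$p_value, c1$p_value, tolerance = 1e-7)
  }
})
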