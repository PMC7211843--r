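test_that("the asymptotic covariance matches its closed form", {
  v <- asymptotic_cov(0, k = 1)
  expect_equal(unname(v), matrix(c(1, -1, -1, 2), 2, 2))
  v2 <- asymptotic_cov(-0.11, k = 250)
  expect_equal(v2[1, 1], 0.89^2 / 250)
  expect_equal(v2[1, 2], -0.89 / 250)
  expect_equal(v2[2, 2], (1 + 0.89^2) / 250)
  expect_error(asymptotic_cov(-0.5, 10), "-1/2")
})

test_that("the covariance is positive definite for all gamma > -1/2", {
  # det(k V) = (1+g)^2 (1 + (1+g)^2) - (1+g)^2 = (1+g)^4 > 0
  for (g in seq(-0.49, 2, by = 0.07)) {
    v <- asymptotic_cov(g, k = 50)
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_equal(det(v * 50), (1 + g)^4, tolerance = 1e-12)
  }
})

test_that("shape intervals reproduce published-style arithmetic", {
  ci <- shape_ci(-0.11, k = 250)
  expect_equal(round_half_away(ci[["lower"]], 2), -0.22)
  expect_equal(round_half_away(ci[["upper"]], 2), 0.00)
  ci_n <- shape_ci(-0.16, k = 68)
  expect_equal(round_half_away(ci_n[["lower"]], 2), -0.36)
  # interval width shrinks as 1/sqrt(k)
  w <- function(k) diff(shape_ci(-0.1, k = k))
  expect_equal(unname(w(4e6) / w(1e6)), 0.5, tolerance = 1e-12)
  expect_error(shape_ci(-0.11, k = 250, level = 1.2), "level")
})

test_that("endpoint arithmetic follows t - sigma/gamma", {
  expect_equal(gpd_endpoint(10.69, 0.76, -0.11), 10.69 + 0.76 / 0.11)
  expect_equal(round_half_away(gpd_endpoint(10.69, 0.76, -0.11), 2), 17.60)
  expect_equal(gpd_endpoint(0, 1, -1), 1)
  expect_equal(gpd_endpoint(10, 2, -0.5), 14)
  expect_error(gpd_endpoint(10, 2, 0.1), "non-negative")
  fit <- gpd_fit(-0.5, 2, 10, k = 100)
  expect_equal(endpoint_estimate(fit), 14)
  expect_gt(endpoint_estimate(fit), fit$threshold)
})

test_that("the endpoint variance polynomial is 1 at gamma = 0", {
  expect_equal(yieldcap:::endpoint_var_poly(0), 1)
  # positive on the whole validity range
  for (g in seq(-0.49, -0.01, by = 0.02)) {
    expect_gt(yieldcap:::endpoint_var_poly(g), 0)
  }
})

test_that("the endpoint interval truncates at the sample maximum", {
  # engineered to match a full-sample wheat fit: the Gaussian lower bound
  # ~11.48 falls below the observed maximum 14.02 and is raised to it
  fit <- gpd_fit(gamma = -0.11, sigma = 0.76, threshold = 10.69,
                 k = 250, n = 1536, t0 = 14.02)
  ep <- endpoint_ci(fit)
  expect_equal(ep$xhat, 17.599, tolerance = 1e-3)
  expect_equal(ep$xhat - ep$half_width, 11.48, tolerance = 1e-2)
  expect_true(ep$truncated)
  expect_equal(ep$ci_lower, 14.02)
  expect_equal(ep$ci_upper, ep$xhat + ep$half_width)
  expect_gte(ep$ci_lower, ep$t0)

  # a far-off sample maximum leaves the Gaussian bound untouched
  fit2 <- gpd_fit(gamma = -0.11, sigma = 0.76, threshold = 10.69,
                  k = 250, n = 1536, t0 = 11.0)
  ep2 <- endpoint_ci(fit2)
  expect_false(ep2$truncated)
  expect_equal(ep2$ci_lower, ep2$xhat - ep2$half_width)
})

test_that("the truncation rule holds on every synthetic run", {
  set.seed(61)
  for (r in 1:20) {
    y <- make_tail_sample(150, gamma = -0.2, sigma = 1)
    fit <- fit_gpd_ml(select_exceedances(y, 150))
    if (fit$gamma >= 0 || !fit$asymptotics_valid) next
    ep <- endpoint_ci(fit)
    expect_gte(ep$ci_lower, max(y))
    expect_true(ep$ci_lower <= ep$xhat && ep$xhat <= ep$ci_upper)
  }
})

test_that("return levels interpolate from threshold to endpoint", {
  fit <- gpd_fit(gamma = -0.11, sigma = 0.76, threshold = 10.69,
                 k = 250, n = 1536)
  zeta <- 250 / 1536
  # m * zeta = 1 sits exactly at the threshold
  expect_equal(return_level(fit, m = 1 / zeta + 1e-9)$level, 10.69,
               tolerance = 1e-6)
  expect_error(return_level(fit, m = 1 / zeta), "m \\* k/n > 1")
  # monotone in m, approaching the endpoint in the m -> Inf limit
  ms <- c(10, 100, 1e4, 1e8, 1e12)
  levels <- vapply(ms, function(m) return_level(fit, m)$level, numeric(1))
  expect_true(all(diff(levels) > 0))
  expect_true(all(levels < endpoint_estimate(fit)))
  expect_equal(return_level(fit, Inf)$level, endpoint_estimate(fit))
  # with a strongly bounded tail the limit is reached by m = 1e12
  fit_b <- gpd_fit(gamma = -0.5, sigma = 1, threshold = 10, k = 250,
                   n = 1536)
  expect_equal(return_level(fit_b, 1e12)$level, endpoint_estimate(fit_b),
               tolerance = 1e-3)

  # gamma = 0: the exponential quantile of the exceedance law
  fit0 <- gpd_fit(gamma = 0, sigma = 2, threshold = 10, k = 100, n = 1000)
  m <- 500
  expect_equal(return_level(fit0, m)$level,
               10 + gpd_quantile(1 - 1 / (m * 0.1), 0, 2))
})

test_that("profile return-level intervals contain the point estimate and
           reflect what the shape interval says about boundedness", {
  set.seed(29)
  # large sample, strongly negative shape: CI excludes 0, finite upper end
  y_neg <- gpd_sample(1500, gamma = -0.35, sigma = 1)
  fit_neg <- fit_gpd_ml(excess_set(y_neg, 10, n = 6000))
  expect_lt(shape_ci(fit_neg)[["upper"]], 0)
  prof_neg <- profile_ci_return_level(fit_neg, m = 500)
  expect_false(prof_neg$unbounded_upper)
  expect_true(is.finite(prof_neg$upper))
  expect_true(prof_neg$lower < prof_neg$estimate)
  expect_true(prof_neg$estimate < prof_neg$upper)

  # in the m -> Inf limit the level is the endpoint; with a shape CI
  # containing 0 the endpoint profile interval is unbounded above
  set.seed(30)
  repeat { # first draw whose fit has a negative shape with CI spanning 0
    y_mild <- gpd_sample(80, gamma = -0.1, sigma = 1)
    fit_mild <- fit_gpd_ml(excess_set(y_mild, 10, n = 400))
    if (fit_mild$gamma < 0 && shape_ci(fit_mild)[["upper"]] > 0) break
  }
  ci <- shape_ci(fit_mild)
  expect_true(ci[["lower"]] < 0 && ci[["upper"]] > 0)
  prof_mild <- profile_ci_return_level(fit_mild, m = Inf)
  expect_true(prof_mild$unbounded_upper)
  expect_identical(prof_mild$upper, Inf)
  expect_true(prof_mild$lower < prof_mild$estimate)
  expect_equal(prof_mild$estimate, endpoint_estimate(fit_mild))

  # m -> Inf with a CI excluding 0: a finite endpoint interval
  prof_end <- profile_ci_return_level(fit_neg, m = Inf)
  expect_false(prof_end$unbounded_upper)
  expect_true(is.finite(prof_end$upper))
  expect_equal(prof_end$estimate, endpoint_estimate(fit_neg))
})

test_that("identical strata give a null LR statistic", {
  set.seed(55)
  exc <- excess_set(gpd_sample(200, -0.2, 1), 10)
  f <- fit_gpd_ml(exc)
  cmp <- lr_test_strata(list(a = f, b = f))
  expect_lt(abs(cmp$lr_stat), 1e-4)
  expect_equal(cmp$df, 2L)
  expect_gte(cmp$lr_stat, -1e-8)
})

test_that("the LR test has df = 2(G-1) and detects different tails", {
  set.seed(56)
  fits_same <- lapply(1:3, function(i)
    fit_gpd_ml(excess_set(gpd_sample(150, -0.2, 1), 10)))
  cmp_same <- lr_test_strata(fits_same)
  expect_equal(cmp_same$df, 4L)
  expect_gte(cmp_same$lr_stat, -1e-8)

  fits_diff <- list(
    fit_gpd_ml(excess_set(gpd_sample(200, -0.35, 1), 10)),
    fit_gpd_ml(excess_set(gpd_sample(200, 0.25, 1), 10)))
  cmp_diff <- lr_test_strata(fits_diff)
  expect_gt(cmp_diff$lr_stat, cmp_same$lr_stat)
  expect_lt(cmp_diff$p_value, 0.05)

  expect_error(lr_test_strata(list(fits_same[[1]])), "two stratum")
  expect_error(
    lr_test_strata(list(fits_same[[1]], gpd_fit(-0.2, 1, 10, k = 50))),
    "data-carrying")
})

test_that("tidy and glance views expose the fit and test quantities", {
  set.seed(70)
  fit <- fit_gpd_ml(excess_set(gpd_sample(300, -0.2, 1), 10))
  td <- tidy(fit)
  expect_equal(td$term, c("gamma", "sigma"))
  expect_equal(td$estimate, c(fit$gamma, fit$sigma))
  expect_equal(td$std.error, unname(sqrt(diag(fit$cov))))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  cmp <- lr_test_strata(list(a = fit, b = fit))
  expect_equal(nrow(tidy(cmp)), 3L) # two strata + pooled
  expect_equal(glance(cmp)$p.value, cmp$p_value)
})
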