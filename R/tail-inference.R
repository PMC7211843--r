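# Inference downstream of a GPD fit: Gaussian confidence intervals from
# the ML asymptotics, the finite right-endpoint estimator with its
# truncated interval, profile-likelihood return levels, and
# likelihood-ratio comparisons of stratified tail models.

#' Asymptotic covariance of the GPD maximum-likelihood estimator
#'
#' For shape `gamma > -1/2` the ML estimator of `(gamma, sigma/sigma_true)`
#' based on `k` excesses is asymptotically normal with covariance `V / k`,
#' where `V11 = (1 + gamma)^2`, `V12 = V21 = -(1 + gamma)` and
#' `V22 = 1 + (1 + gamma)^2`. `det(V) = (1 + gamma)^4 > 0`, so the matrix
#' is positive definite on the whole validity range.
#'
#' @param gamma Shape parameter; must exceed -1/2.
#' @param k Effective sample size (number of excesses).
#' @return A symmetric 2x2 matrix: the covariance of
#'   `(gamma_hat, sigma_hat / sigma)`.
#' @examples
#' asymptotic_cov(0, k = 1)      # matrix ((1,-1),(-1,2))
#' asymptotic_cov(-0.11, k = 250)
#' @export
asymptotic_cov <- function(gamma, k) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma)) {
    abort("`gamma` must be a single finite number.")
  }
  if (gamma <= -0.5) {
    abort("Asymptotic normality of the ML estimator requires gamma > -1/2.")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("`k` must be a positive integer.")
  }
  g1 <- 1 + gamma
  matrix(c(g1^2, -g1, -g1, 1 + g1^2), 2, 2,
         dimnames = list(c("gamma", "sigma_rel"),
                         c("gamma", "sigma_rel"))) / k
}

# z = 1.96 at the conventional 95% level (matching the printed interval
# formulas); exact normal quantile otherwise.
z_value <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a probability strictly between 0 and 1.")
  }
  if (isTRUE(all.equal(level, 0.95))) 1.96 else qnorm(1 - (1 - level) / 2)
}

#' Gaussian confidence interval for the GPD shape parameter
#'
#' `gamma_hat +/- z * (1 + gamma_hat) / sqrt(k)`, the interval implied by
#' the asymptotic variance `(1 + gamma)^2 / k` of the ML shape estimator;
#' `z = 1.96` at the default 95% level.
#'
#' @param fit Either a `"gpd_fit"` object or a single numeric shape
#'   estimate (in which case `k` must be given).
#' @param k Effective sample size; taken from `fit` when `fit` is a
#'   `"gpd_fit"`.
#' @param level Confidence level in (0, 1).
#' @return A named numeric vector `c(lower, upper)`.
#' @examples
#' shape_ci(-0.11, k = 250) # (-0.22, 0.00) to 2 decimals
#' @export
shape_ci <- function(fit, k = NULL, level = 0.95) {
  if (inherits(fit, "gpd_fit")) {
    gamma <- fit$gamma
    k <- fit$k
  } else {
    gamma <- fit
    if (is.null(k)) abort("Supply `k` alongside a numeric shape estimate.")
  }
  if (gamma <= -0.5) {
    abort("Shape interval undefined: gamma <= -1/2 invalidates the asymptotics.")
  }
  half <- z_value(level) * (1 + gamma) / sqrt(k)
  c(lower = gamma - half, upper = gamma + half)
}

#' Gaussian confidence interval for the GPD scale parameter
#'
#' Symmetric interval `sigma_hat +/- z * sigma_hat * sqrt(1 + (1 +
#' gamma_hat)^2) / sqrt(k)` from the same asymptotic covariance as
#' [shape_ci()]. Reported intervals are labelled with this method since
#' likelihood-based scale intervals would generally be asymmetric.
#'
#' @inheritParams shape_ci
#' @param gamma Shape estimate, when `fit` is a numeric scale estimate.
#' @return A named numeric vector `c(lower, upper)`.
#' @export
scale_ci <- function(fit, gamma = NULL, k = NULL, level = 0.95) {
  if (inherits(fit, "gpd_fit")) {
    sigma <- fit$sigma
    gamma <- fit$gamma
    k <- fit$k
  } else {
    sigma <- fit
    if (is.null(gamma) || is.null(k)) {
      abort("Supply `gamma` and `k` alongside a numeric scale estimate.")
    }
  }
  if (gamma <= -0.5) {
    abort("Scale interval undefined: gamma <= -1/2 invalidates the asymptotics.")
  }
  half <- z_value(level) * sigma * sqrt(1 + (1 + gamma)^2) / sqrt(k)
  c(lower = sigma - half, upper = sigma + half)
}

#' Right-endpoint estimate of a bounded tail
#'
#' For a fitted negative shape, the excess distribution has finite support
#' and the variable a finite right endpoint, estimated by
#' `x_hat = t_k - sigma_hat / gamma_hat`. A non-negative shape estimate
#' implies an unbounded (exponential or heavy) tail and raises an error.
#'
#' `gpd_endpoint()` is the bare arithmetic on supplied numbers;
#' `endpoint_estimate()` reads the components off a `"gpd_fit"`.
#'
#' @param fit A `"gpd_fit"` object.
#' @param threshold,sigma,gamma Threshold, scale and (negative) shape.
#' @return The endpoint estimate, in the units of the data. Always exceeds
#'   the threshold.
#' @examples
#' gpd_endpoint(10.69, 0.76, -0.11) # 17.60 to 2 decimals
#' @export
endpoint_estimate <- function(fit) {
  stopifnot(inherits(fit, "gpd_fit"))
  gpd_endpoint(fit$threshold, fit$sigma, fit$gamma)
}

#' @rdname endpoint_estimate
#' @export
gpd_endpoint <- function(threshold, sigma, gamma) {
  check_gpd_params(gamma, sigma)
  if (gamma >= 0) {
    abort("No finite right endpoint: the estimated shape is non-negative.")
  }
  threshold - sigma / gamma
}

# sqrt-argument polynomial of the endpoint asymptotics, Horner form;
# equals 1 at gamma = 0 and stays positive on (-1/2, 0).
endpoint_var_poly <- function(gamma) {
  1 + gamma * (4 + gamma * (5 + gamma * (2 + 2 * gamma)))
}

#' Truncated confidence interval for the right endpoint
#'
#' The endpoint estimator is asymptotically Gaussian around the true
#' endpoint with standard deviation `(sigma_hat / gamma_hat^2) *
#' sqrt(1 + 4g + 5g^2 + 2g^3 + 2g^4) / sqrt(k)` (writing `g` for the
#' shape), giving a symmetric interval `x_hat +/- z * sd`. Because the
#' true endpoint cannot lie below an observed value, the lower limit is
#' raised to the sample maximum `t0` whenever the Gaussian bound falls
#' below it; this truncation does not affect coverage. The `truncated`
#' flag records whether the constraint was active.
#'
#' @param fit A `"gpd_fit"` with negative shape; its `t0` must be the
#'   sample maximum for truncation to be meaningful.
#' @param level Confidence level; `z = 1.96` at the default 0.95.
#' @return An object of class `"endpoint_estimate"`: a list with `xhat`,
#'   `ci_lower`, `ci_upper`, `t0`, `level`, `truncated` and `half_width`
#'   (the unconstrained Gaussian half-width).
#' @examples
#' fit <- gpd_fit(gamma = -0.11, sigma = 0.76, threshold = 10.69,
#'                k = 250, n = 1536, t0 = 14.02)
#' endpoint_ci(fit) # lower bound truncated at 14.02
#' @export
endpoint_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gpd_fit"))
  xhat <- endpoint_estimate(fit) # errors when gamma >= 0
  poly <- endpoint_var_poly(fit$gamma)
  if (poly < 0) {
    abort("Endpoint variance polynomial negative: shape outside (-1/2, 0).")
  }
  half <- z_value(level) / sqrt(fit$k) * fit$sigma / fit$gamma^2 * sqrt(poly)
  lower_gauss <- xhat - half
  truncated <- lower_gauss < fit$t0
  structure(
    list(xhat = xhat,
         ci_lower = max(fit$t0, lower_gauss),
         ci_upper = xhat + half,
         t0 = fit$t0, level = level,
         truncated = truncated, half_width = half),
    class = "endpoint_estimate"
  )
}

#' @export
print.endpoint_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Right endpoint: %s, %s%% CI (%s, %s)%s\n",
              format(x$xhat, digits = digits), format(100 * x$level),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              if (x$truncated) {
                sprintf(" [lower bound truncated at sample max %s]",
                        format(x$t0, digits = digits))
              } else ""))
  invisible(x)
}

#' Once-in-m return level of the fitted tail
#'
#' The level exceeded on average once every `m` observations:
#' `t_k + (sigma/gamma) * ((m * zeta)^gamma - 1)` with exceedance rate
#' `zeta = k / n` (the exponential form `t_k + sigma * log(m * zeta)` at
#' `gamma = 0`). For a negative shape the return level increases to the
#' right endpoint as `m` grows.
#'
#' @param fit A `"gpd_fit"`.
#' @param m Return period, in observations (years for one observation per
#'   year); must satisfy `m * k / n > 1`.
#' @return An object of class `"return_level"`: a list with `m`, `zeta`,
#'   `level` (the return level) and the fit's threshold.
#' @examples
#' fit <- gpd_fit(-0.11, 0.76, 10.69, k = 250, n = 1536)
#' return_level(fit, m = 100)$level
#' @export
return_level <- function(fit, m) {
  stopifnot(inherits(fit, "gpd_fit"))
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) && m != Inf) {
    abort("`m` must be a single number (possibly Inf for gamma < 0).")
  }
  zeta <- fit$k / fit$n
  if (m * zeta <= 1) {
    abort(sprintf(
      "Return period too short: need m * k/n > 1 (m * zeta = %.3g).",
      m * zeta))
  }
  level <- return_level_value(m, zeta, fit$threshold, fit$gamma, fit$sigma)
  structure(list(m = m, zeta = zeta, level = level,
                 threshold = fit$threshold),
            class = "return_level")
}

return_level_value <- function(m, zeta, threshold, gamma, sigma) {
  if (abs(gamma) < .GPD_GAMMA_EPS) {
    threshold + sigma * log(m * zeta)
  } else if (is.infinite(m)) {
    if (gamma < 0) threshold - sigma / gamma else Inf
  } else {
    threshold + sigma / gamma * expm1(gamma * log(m * zeta))
  }
}

#' @export
print.return_level <- function(x, digits = 4, ...) {
  cat(sprintf("Once-in-%s return level: %s (exceedance rate %.4g)\n",
              format(x$m), format(x$level, digits = digits), x$zeta))
  invisible(x)
}

#' Profile-likelihood confidence interval for a return level
#'
#' Reparameterises the GPD likelihood in terms of the once-in-`m` return
#' level `z` (solving the scale out as a function of `(gamma, z)`),
#' profiles over the shape, and returns the set of `z` whose profile
#' deviance lies under the chi-square(1) cutoff.
#'
#' With `m = Inf` the once-in-`m` level becomes the right endpoint itself
#' and the likelihood is profiled under the endpoint constraint
#' `sigma = -gamma * (z - t_k)` (shape restricted to negative values).
#' In that limit the interval is by construction unbounded to the right
#' whenever the data cannot rule out a shape of 0 or above -- an
#' exponential or heavy tail has no finite endpoint -- which is exactly
#' when the shape confidence interval contains 0. For finite `m` the
#' return level is finite even under a heavy tail, so the interval is
#' typically bounded.
#'
#' The search declares the upper limit unbounded once the profile has
#' not crossed the cutoff anywhere below ten times the point estimate's
#' excess over the threshold.
#'
#' @param fit A `"gpd_fit"` carrying its excesses (i.e. from
#'   [fit_gpd_ml()], not [gpd_fit()]).
#' @param m Return period, as in [return_level()]; `Inf` profiles the
#'   right endpoint (requires a negative fitted shape).
#' @param level Confidence level for the chi-square cutoff.
#' @return A list of class `"profile_ci"`: `estimate` (the return level),
#'   `lower`, `upper` (`Inf` when unbounded), `unbounded_upper` flag, `m`
#'   and `level`.
#' @export
profile_ci_return_level <- function(fit, m, level = 0.95) {
  stopifnot(inherits(fit, "gpd_fit"))
  if (is.null(fit$exceedances)) {
    abort("Profile likelihood needs the fitted excesses; refit with fit_gpd_ml().")
  }
  y <- fit$exceedances$excesses
  zeta <- fit$k / fit$n
  if (m * zeta <= 1) abort("Return period too short: need m * k/n > 1.")
  if (is.infinite(m) && fit$gamma >= 0) {
    abort("m = Inf profiles the endpoint, which needs a negative fitted shape.")
  }
  est <- return_level_value(m, zeta, fit$threshold, fit$gamma, fit$sigma)
  cutoff <- fit$loglik - qchisq(level, df = 1) / 2

  # profile log-likelihood at a candidate level z > threshold: the scale
  # solves out of the constraint -- sigma = gamma*(z - t)/((m zeta)^gamma - 1)
  # for finite m, sigma = -gamma*(z - t) in the endpoint limit
  lmz <- log(m * zeta)
  prof <- function(z) {
    excess_z <- z - fit$threshold
    if (excess_z <= 0) return(-Inf)
    sigma_of <- if (is.infinite(m)) {
      function(g) -g * excess_z
    } else {
      function(g) if (abs(g) < .GPD_GAMMA_EPS) excess_z / lmz
                  else g * excess_z / expm1(g * lmz)
    }
    obj <- function(g) {
      ll <- gpd_loglik(y, g, sigma_of(g))
      if (is.finite(ll)) -ll else .Machine$double.xmax
    }
    upper_g <- if (is.infinite(m)) -1e-12 else 5
    res <- tryCatch(
      optim(min(fit$gamma, upper_g), obj, method = "Brent",
            lower = -5, upper = upper_g),
      error = function(e) NULL
    )
    if (is.null(res) || res$value >= .Machine$double.xmax) -Inf else -res$value
  }

  inside <- function(z) prof(z) >= cutoff
  step <- max(est - fit$threshold, fit$sigma)

  # lower bound: bracket between threshold and the estimate
  lo_out <- fit$threshold + 1e-8 * step
  lower <- if (inside(lo_out)) {
    lo_out
  } else {
    bisect_boundary(inside, lo_out, est, want_inside_right = TRUE)
  }

  # upper bound: march up a geometric grid to 10x the excess scale
  max_z <- fit$threshold + 10 * step
  z_hi <- est
  unbounded <- TRUE
  mult <- 1.25
  probe <- est + 0.05 * step
  while (probe <= max_z) {
    if (!inside(probe)) {
      unbounded <- FALSE
      break
    }
    z_hi <- probe
    probe <- fit$threshold + (probe - fit$threshold) * mult
  }
  upper <- if (unbounded) Inf else {
    bisect_boundary(inside, z_hi, probe, want_inside_right = FALSE)
  }

  structure(list(estimate = est, lower = lower, upper = upper,
                 unbounded_upper = unbounded, m = m, level = level),
            class = "profile_ci")
}

# locate the crossing of a logical boundary by bisection; the bracket has
# inside(right) == want_inside_right
bisect_boundary <- function(inside, left, right, want_inside_right,
                            iter = 60L) {
  for (i in seq_len(iter)) {
    mid <- (left + right) / 2
    if (inside(mid) == want_inside_right) right <- mid else left <- mid
    if (abs(right - left) < 1e-9 * max(1, abs(right))) break
  }
  (left + right) / 2
}

#' @export
print.profile_ci <- function(x, digits = 4, ...) {
  up <- if (x$unbounded_upper) "Inf (unbounded)" else
    format(x$upper, digits = digits)
  cat(sprintf("Once-in-%s return level %s, %s%% profile CI (%s, %s)\n",
              format(x$m), format(x$estimate, digits = digits),
              format(100 * x$level),
              format(x$lower, digits = digits), up))
  invisible(x)
}

#' Likelihood-ratio test for tail differences between strata
#'
#' Compares a pooled GPD tail model -- one `(gamma, sigma)` shared by
#' every stratum's excesses over its own threshold -- against the
#' alternative of stratum-specific parameters, by a classical likelihood
#' ratio test with `2 * (G - 1)` degrees of freedom for `G` strata. A
#' small p-value is evidence that the tail model (and hence the maximum
#' attainable level) genuinely differs between strata.
#'
#' @param fits A list of `"gpd_fit"` objects, one per stratum, each
#'   carrying its excesses; names are used as stratum labels.
#' @return An object of class `"stratum_comparison"`: a list with
#'   `stratum_fits`, `pooled` (`"gpd_fit"` on the union of the excess
#'   sets), `lr_stat`, `df` and `p_value`.
#' @examples
#' set.seed(42)
#' f <- lapply(1:2, function(i)
#'   fit_gpd_ml(excess_set(gpd_sample(150, -0.2, 1), 10)))
#' lr_test_strata(f)
#' @export
lr_test_strata <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L) {
    abort("Need at least two stratum fits.")
  }
  labels <- names(fits) %||% paste0("stratum_", seq_along(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!inherits(f, "gpd_fit") || is.null(f$exceedances)) {
      abort(sprintf(
        "Stratum '%s' is not a data-carrying gpd_fit (use fit_gpd_ml).",
        labels[i]))
    }
  }
  pooled_exc <- excess_set(
    unlist(lapply(fits, function(f) f$exceedances$excesses)),
    threshold = 0,
    n = sum(vapply(fits, function(f) f$n, integer(1)))
  )
  # threshold label is nominal: the pooled likelihood only sees excesses
  pooled <- fit_gpd_ml(pooled_exc)
  ll_strata <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
  lr <- 2 * (ll_strata - pooled$loglik)
  df <- 2L * (length(fits) - 1L)
  structure(
    list(stratum_fits = setNames(fits, labels), pooled = pooled,
         lr_stat = lr, df = df,
         p_value = pchisq(max(lr, 0), df = df, lower.tail = FALSE)),
    class = "stratum_comparison"
  )
}

#' @export
print.stratum_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Likelihood ratio test, %d strata vs pooled GPD tail:\n",
    length(x$stratum_fits)))
  cat(sprintf("  LR = %s on %d df, p = %s\n",
              format(x$lr_stat, digits = digits), x$df,
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}
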