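# Exceedance selection and GPD parameter estimation.

#' Select the top-k exceedances of a yield sample
#'
#' Implements the peaks-over-threshold sample construction: the threshold
#' `t_k` is the (k+1)th highest value and the analysis sample is the `k`
#' highest values expressed as excesses over `t_k`. Values tied with the
#' threshold are not usable (excesses must be strictly positive); if ties
#' at `t_k` make it impossible to keep exactly `k` strictly positive
#' excesses, an error is raised rather than silently changing `k`.
#'
#' @param x A numeric vector of observations, or a data frame holding a
#'   per-farm sample with a `max_yield` (or `yield`) column, as produced
#'   by [dedup_farm_max()].
#' @param k Effective sample size: number of top order statistics to keep;
#'   must satisfy `1 <= k <= length(x) - 1`.
#'
#' @return An object of class `"exceedances"`: a list with elements
#'   `threshold` (`t_k`), `excesses` (the `k` positive excesses, descending),
#'   `k`, `n` (full sample size) and `t0` (the sample maximum).
#'
#' @examples
#' exc <- select_exceedances(c(1:10), k = 3)
#' exc$threshold # 7
#' exc$excesses  # 3 2 1
#' @export
select_exceedances <- function(x, k) {
  x <- as_yield_vector(x)
  n <- length(x)
  if (!is.numeric(k) || length(k) != 1L || k != floor(k)) {
    abort("`k` must be a single integer.")
  }
  if (k < 1 || k > n - 1) {
    abort(sprintf("`k` must satisfy 1 <= k <= n - 1 = %d (got k = %s).",
                  n - 1L, format(k)))
  }
  sorted <- sort(x, decreasing = TRUE)
  threshold <- sorted[k + 1L]
  top <- sorted[seq_len(k)]
  if (any(top <= threshold)) {
    abort(sprintf(paste0(
      "Ties at the threshold t_k = %s: fewer than k = %d observations ",
      "exceed it strictly. Choose a different k."), format(threshold), k))
  }
  structure(
    list(threshold = threshold, excesses = top - threshold,
         k = as.integer(k), n = as.integer(n), t0 = sorted[1L]),
    class = "exceedances"
  )
}

# Accept a bare numeric vector or a prepared sample data frame.
as_yield_vector <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("max_yield", "yield"), names(x))[1]
    if (is.na(col)) {
      abort("Data frame input must have a `max_yield` or `yield` column.")
    }
    x <- x[[col]]
  }
  if (!is.numeric(x) || length(x) < 2L) {
    abort("Need a numeric sample with at least 2 observations.")
  }
  if (any(!is.finite(x))) abort("Sample contains non-finite values.")
  x
}

as_exceedances <- function(x, k = NULL) {
  if (inherits(x, "exceedances")) return(x)
  if (is.null(k)) abort("Supply `k` when `x` is not an exceedance set.")
  select_exceedances(x, k)
}

#' Build an exceedance set from already-computed excesses
#'
#' Wraps a vector of positive excesses over a known threshold into the
#' `"exceedances"` container used by the fitting functions, for workflows
#' (typically simulations) where the excesses are generated directly
#' rather than selected out of a full sample. The sample maximum `t0` is
#' `threshold + max(excesses)` by construction.
#'
#' @param excesses Strictly positive excesses over `threshold`.
#' @param threshold The threshold `t_k`.
#' @param n Total size of the notional full sample; defaults to `2 * k`,
#'   i.e. an exceedance rate of one half. Only the ratio `k / n` matters,
#'   and only for return levels.
#' @return An `"exceedances"` object, as from [select_exceedances()].
#' @examples
#' set.seed(1)
#' excess_set(gpd_sample(100, -0.2, 1), threshold = 10.69)
#' @export
excess_set <- function(excesses, threshold, n = 2L * length(excesses)) {
  if (!is.numeric(excesses) || length(excesses) < 1L ||
      any(!is.finite(excesses)) || any(excesses <= 0)) {
    abort("`excesses` must be strictly positive finite numbers.")
  }
  k <- length(excesses)
  if (n < k + 1L) abort("`n` must exceed the number of excesses.")
  structure(
    list(threshold = threshold,
         excesses = sort(excesses, decreasing = TRUE),
         k = as.integer(k), n = as.integer(n),
         t0 = threshold + max(excesses)),
    class = "exceedances"
  )
}

#' Assemble a GPD fit object from given parameter values
#'
#' Builds a `"gpd_fit"` from externally supplied estimates, e.g. published
#' shape/scale/threshold values, so that the downstream inference
#' functions ([shape_ci()], [endpoint_estimate()], [endpoint_ci()],
#' [return_level()]) can be applied to reported fits whose underlying data
#' are unavailable.
#'
#' @param gamma,sigma Shape and scale estimates; `sigma > 0`.
#' @param threshold Threshold `t_k` the excesses were taken over.
#' @param k Effective sample size behind the estimates.
#' @param n Total sample size; defaults to `2 * k` (only `k / n` matters,
#'   and only for return levels).
#' @param t0 Sample maximum; defaults to the implied endpoint for
#'   `gamma < 0` (no truncation information) and must be supplied for the
#'   truncated endpoint interval to be meaningful.
#' @return A `"gpd_fit"` object with `loglik = NA` and no stored excesses.
#' @examples
#' fit <- gpd_fit(gamma = -0.11, sigma = 0.76, threshold = 10.69,
#'                k = 250, n = 1536, t0 = 14.02)
#' endpoint_estimate(fit)
#' @export
gpd_fit <- function(gamma, sigma, threshold, k, n = 2L * k, t0 = NULL) {
  check_gpd_params(gamma, sigma)
  if (k < 2 || k != floor(k)) abort("`k` must be an integer >= 2.")
  if (n <= k) abort("`n` must exceed `k`.")
  if (is.null(t0)) {
    t0 <- if (gamma < 0) threshold - sigma / gamma else Inf
  }
  valid <- gamma > -0.5
  cov <- if (valid) {
    scale <- diag(c(1, sigma))
    scale %*% asymptotic_cov(gamma, k) %*% scale
  } else {
    matrix(NA_real_, 2, 2)
  }
  dimnames(cov) <- list(c("gamma", "sigma"), c("gamma", "sigma"))
  structure(
    list(gamma = gamma, sigma = sigma, loglik = NA_real_, cov = cov,
         exceedances = NULL, k = as.integer(k), n = as.integer(n),
         threshold = threshold, t0 = t0, converged = NA,
         asymptotics_valid = valid, method = "external"),
    class = "gpd_fit"
  )
}

#' GPD log-likelihood of an excess sample
#'
#' Log-likelihood of shape/scale `(gamma, sigma)` for strictly positive
#' excesses. Parameter points violating the support constraint
#' `1 + gamma * y / sigma > 0` for any excess (or `sigma <= 0`) score
#' `-Inf`, which is how the constraint is enforced during optimisation.
#'
#' @param excesses Numeric vector of positive excesses.
#' @inheritParams gpd_cdf
#' @return A single number (possibly `-Inf`).
#' @export
gpd_loglik <- function(excesses, gamma, sigma) {
  k <- length(excesses)
  if (!is.finite(sigma) || sigma <= 0 || !is.finite(gamma)) return(-Inf)
  if (abs(gamma) < .GPD_GAMMA_EPS) {
    return(-k * log(sigma) - sum(excesses) / sigma)
  }
  z <- 1 + gamma * excesses / sigma
  if (any(z <= 0)) return(-Inf)
  -k * log(sigma) - (1 + 1 / gamma) * sum(log(z))
}

#' Fit the GPD exceedance model by maximum likelihood
#'
#' Maximises the GPD log-likelihood over `(gamma, log sigma)` by
#' Nelder-Mead with multiple starting points (probability-weighted-moment
#' and moment estimates plus a mildly heavy-tailed default), keeping the
#' best converged solution. The likelihood can be irregular near the
#' boundary of the support constraint, hence the multi-start policy and
#' the `-Inf` penalisation outside the support. The asymptotic normality
#' of the ML estimator (and the stored covariance) is only valid for
#' `gamma > -1/2`; fits beyond that boundary are flagged.
#'
#' @param x An `"exceedances"` object from [select_exceedances()], or a
#'   numeric sample / prepared sample data frame together with `k`.
#' @param k Effective sample size, required when `x` is not already an
#'   exceedance set.
#'
#' @return An object of class `"gpd_fit"`: a list with `gamma`, `sigma`,
#'   `loglik`, `cov` (2x2 asymptotic covariance of `(gamma_hat,
#'   sigma_hat)`; `NA` when `gamma <= -1/2`), `exceedances`, `k`, `n`,
#'   `threshold`, `t0`, `converged`, and `asymptotics_valid` (`FALSE` when
#'   `gamma_hat <= -1/2`). Use [tidy()] / [glance()] for tabular views,
#'   [shape_ci()], [endpoint_estimate()], [endpoint_ci()] and
#'   [return_level()] for inference.
#'
#' @examples
#' set.seed(1)
#' exc <- excess_set(gpd_sample(500, gamma = -0.2, sigma = 1),
#'                   threshold = 10.7, n = 1536)
#' fit <- fit_gpd_ml(exc)
#' tidy(fit)
#' @export
fit_gpd_ml <- function(x, k = NULL) {
  exc <- as_exceedances(x, k)
  y <- exc$excesses
  if (length(y) < 2L) abort("Need at least 2 excesses to fit by ML.")
  if (diff(range(y)) == 0) {
    abort("Degenerate excesses (all equal): the GPD likelihood is unbounded.")
  }

  starts <- ml_starting_points(exc)
  negll <- function(par) {
    g <- par[1]
    if (abs(g) > 5) return(.Machine$double.xmax) # box on the shape
    ll <- gpd_loglik(y, g, exp(par[2]))
    if (!is.finite(ll)) .Machine$double.xmax else -ll
  }

  best <- NULL
  diagnostics <- character()
  for (s in starts) {
    res <- tryCatch(
      optim(s, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (!is.finite(res$value) || res$value >= .Machine$double.xmax) {
      diagnostics <- c(diagnostics, sprintf(
        "start (%.3f, %.3f): likelihood not finite", s[1], s[2]))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(paste0("GPD maximum-likelihood fit failed from all starting ",
                 "points. ", paste(diagnostics, collapse = "; ")))
  }

  gamma_hat <- best$par[1]
  sigma_hat <- exp(best$par[2])
  valid <- gamma_hat > -0.5
  if (!valid) {
    warn(sprintf(paste0(
      "Estimated shape %.3f <= -0.5: the ML asymptotic normality (and all ",
      "Gaussian confidence intervals) is invalid for this fit."), gamma_hat))
  }
  cov <- if (valid) {
    v <- asymptotic_cov(gamma_hat, exc$k)
    # rescale the (sigma_hat / sigma) row/column to the sigma_hat scale
    scale <- diag(c(1, sigma_hat))
    scale %*% v %*% scale
  } else {
    matrix(NA_real_, 2, 2)
  }
  dimnames(cov) <- list(c("gamma", "sigma"), c("gamma", "sigma"))

  structure(
    list(gamma = gamma_hat, sigma = sigma_hat,
         loglik = -best$value, cov = cov,
         exceedances = exc, k = exc$k, n = exc$n,
         threshold = exc$threshold, t0 = exc$t0,
         converged = best$convergence == 0,
         asymptotics_valid = valid,
         method = "ml"),
    class = "gpd_fit"
  )
}

# Starting values for the ML search, in (gamma, log sigma).
ml_starting_points <- function(exc) {
  y <- exc$excesses
  starts <- list(c(0.1, log(mean(y))))
  pwm <- tryCatch(fit_gpd_pwm(exc), error = function(e) NULL)
  mom <- tryCatch(fit_gpd_moment(exc), error = function(e) NULL)
  for (est in list(pwm, mom)) {
    if (!is.null(est) && is.finite(est$gamma) && is.finite(est$sigma) &&
        est$sigma > 0) {
      starts <- c(starts, list(c(est$gamma, log(est$sigma))))
    }
  }
  # nudge starts violating the support constraint into the interior
  ymax <- max(y)
  lapply(starts, function(s) {
    if (s[1] < 0 && -exp(s[2]) / s[1] <= ymax) {
      c(s[1], log(1.05 * ymax * abs(s[1])))
    } else s
  })
}

#' Moment and probability-weighted-moment GPD estimators
#'
#' Semi-parametric alternatives to the ML fit, used as robustness checks
#' and as starting values for the likelihood search. `fit_gpd_moment()`
#' is the Dekkers-Einmahl-de Haan moment estimator computed from the
#' log-spacings of the top order statistics (it therefore needs a
#' strictly positive threshold); `fit_gpd_pwm()` is the Hosking-Wallis
#' probability-weighted-moment estimator computed from the excesses, with
#' `b0` the sample mean of the excesses and `b1` the unbiased estimate of
#' `E[Y (1 - F(Y))]`.
#'
#' @inheritParams fit_gpd_ml
#' @return An object of class `"gpd_params"`: a list with elements
#'   `gamma`, `sigma` and `method`.
#' @examples
#' set.seed(1)
#' exc <- excess_set(gpd_sample(2000, gamma = -0.11, sigma = 0.76), 10.69)
#' fit_gpd_pwm(exc)
#' fit_gpd_moment(exc)
#' @export
fit_gpd_pwm <- function(x, k = NULL) {
  exc <- as_exceedances(x, k)
  y <- sort(exc$excesses)
  kk <- length(y)
  if (kk < 4L) abort("PWM estimation needs at least 4 excesses.")
  b0 <- mean(y)
  # unbiased PWM a_1 = E[Y (1 - F(Y))]
  b1 <- sum(y * (kk - seq_len(kk)) / (kk - 1)) / kk
  denom <- b0 - 2 * b1
  if (denom == 0) abort("PWM estimator undefined: b0 = 2*b1.")
  gamma <- 2 - b0 / denom
  sigma <- 2 * b0 * b1 / denom
  new_gpd_params(gamma, sigma, "pwm")
}

#' @rdname fit_gpd_pwm
#' @export
fit_gpd_moment <- function(x, k = NULL) {
  exc <- as_exceedances(x, k)
  if (exc$k < 4L) abort("Moment estimation needs at least 4 excesses.")
  if (exc$threshold <= 0) {
    abort("The moment estimator needs a strictly positive threshold.")
  }
  logs <- log1p(exc$excesses / exc$threshold) # log X_(top) - log t_k
  m1 <- mean(logs)
  m2 <- mean(logs^2)
  if (m2 == 0) abort("Moment estimator undefined: degenerate top order statistics.")
  gamma_neg <- 1 - 0.5 / (1 - m1^2 / m2)
  gamma <- m1 + gamma_neg
  sigma <- exc$threshold * m1 * (1 - gamma_neg)
  new_gpd_params(gamma, sigma, "moment")
}

new_gpd_params <- function(gamma, sigma, method) {
  structure(list(gamma = gamma, sigma = sigma, method = method),
            class = "gpd_params")
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("GPD parameters (%s): gamma = %.4f, sigma = %.4f\n",
              x$method, x$gamma, x$sigma))
  invisible(x)
}

#' @export
print.exceedances <- function(x, ...) {
  cat(sprintf(
    "Exceedance set: k = %d of n = %d, threshold t_k = %.4g, max t0 = %.4g\n",
    x$k, x$n, x$threshold, x$t0))
  invisible(x)
}

#' @export
print.gpd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("GPD exceedance fit (maximum likelihood)\n"))
  cat(sprintf("  k = %d of n = %d, threshold t_k = %s, sample max t0 = %s\n",
              x$k, x$n, format(x$threshold, digits = digits),
              format(x$t0, digits = digits)))
  cat(sprintf("  gamma = %s, sigma = %s, log-likelihood = %s\n",
              format(x$gamma, digits = digits),
              format(x$sigma, digits = digits),
              format(x$loglik, digits = digits)))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  if (!x$asymptotics_valid) {
    cat("  WARNING: gamma <= -0.5, Gaussian asymptotics invalid\n")
  }
  invisible(x)
}
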