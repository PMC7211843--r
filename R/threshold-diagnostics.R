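# Threshold-choice diagnostics: the shape estimate as a function of the
# effective sample size k, and a rolling-stability heuristic for picking
# k out of the trajectory.

#' Shape and endpoint estimates across effective sample sizes
#'
#' Refits the GPD exceedance model for every `k` in `[k_min, k_max]`
#' (clipped to `n - 1`), recording the threshold, the ML shape estimate
#' with its Gaussian interval, and the implied right endpoint where the
#' shape is negative (`NA` otherwise: a non-negative shape implies no
#' finite endpoint). Small `k` gives noisy estimates, large `k` biased
#' ones; the default range 15-400 brackets the region usually worth
#' inspecting for samples of a few hundred to a few thousand farms.
#'
#' @param x A numeric sample or prepared sample data frame (see
#'   [select_exceedances()]).
#' @param k_min,k_max Smallest and largest effective sample size.
#' @param level Confidence level for the shape intervals.
#' @return A tibble of class `"shape_trajectory"` with columns `k`,
#'   `threshold`, `gamma`, `ci_lower`, `ci_upper`, `endpoint`. Rows where
#'   the ML fit failed or sits below shape -1/2 carry `NA` intervals.
#' @examples
#' set.seed(7)
#' y <- c(rnorm(800, 8, 1.5), 10.7 + gpd_sample(60, -0.15, 0.8))
#' traj <- shape_trajectory(y, k_min = 15, k_max = 120)
#' stability_region(traj, window = 20, tol = 0.1)
#' @export
shape_trajectory <- function(x, k_min = 15, k_max = 400, level = 0.95) {
  x <- as_yield_vector(x)
  if (k_min >= k_max) abort("`k_min` must be smaller than `k_max`.")
  if (k_min < 2) abort("`k_min` must be at least 2.")
  n <- length(x)
  if (k_min > n - 1) abort("`k_min` exceeds n - 1: sample too small.")
  ks <- seq.int(k_min, min(k_max, n - 1))
  sorted <- sort(x, decreasing = TRUE)
  rows <- purrr::map(ks, function(k) {
    fit <- tryCatch(
      suppressWarnings(fit_gpd_ml(select_exceedances(x, k))),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(k = k, threshold = sorted[k + 1L],
                            gamma = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, endpoint = NA_real_))
    }
    ci <- if (fit$asymptotics_valid) shape_ci(fit, level = level) else
      c(lower = NA_real_, upper = NA_real_)
    tibble::tibble(
      k = k, threshold = fit$threshold, gamma = fit$gamma,
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      endpoint = if (fit$gamma < 0) endpoint_estimate(fit) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shape_trajectory", class(out))
  out
}

#' Stability-region heuristic for choosing the effective sample size
#'
#' The trajectory of shape estimates typically settles into a stability
#' region: `k` large enough that the estimate has stopped fluctuating,
#' small enough that only genuine extremes enter the fit. This heuristic
#' recommends the largest `k` whose trailing window of `window` estimates
#' has a range at most `tol` shape units. The choice of `k` is ultimately
#' a judgement call made by looking at the trajectory; the full rolling
#' diagnostics are returned so the recommendation can be overridden, and
#' when no window is stable the function warns and recommends nothing
#' rather than failing.
#'
#' @param traj A [shape_trajectory()].
#' @param window Number of consecutive `k` values that must agree.
#' @param tol Maximum spread (max minus min) of the shape estimate over
#'   the window, in shape units.
#' @return A list of class `"stability_region"`: `k` (recommended, or
#'   `NA` with a warning when nothing stabilises), `window`, `tol`, and
#'   `diagnostics`, a tibble with the rolling range ending at each `k`.
#' @export
stability_region <- function(traj, window = 50, tol = 0.05) {
  stopifnot(inherits(traj, "shape_trajectory"))
  if (nrow(traj) < window) {
    abort(sprintf("Trajectory has %d rows; need at least window = %d.",
                  nrow(traj), window))
  }
  g <- traj$gamma
  roll <- rep(NA_real_, length(g))
  for (i in seq(window, length(g))) {
    win <- g[(i - window + 1L):i]
    if (all(is.finite(win))) roll[i] <- max(win) - min(win)
  }
  diagnostics <- tibble::tibble(k = traj$k, gamma = g, rolling_range = roll)
  stable <- which(is.finite(roll) & roll <= tol)
  if (length(stable) == 0L) {
    warn(sprintf(
      paste0("No window of %d consecutive shape estimates stays within ",
             "%.3g; inspect the trajectory and choose k manually."),
      window, tol))
    k_rec <- NA_integer_
  } else {
    k_rec <- traj$k[max(stable)]
  }
  structure(list(k = k_rec, window = window, tol = tol,
                 diagnostics = diagnostics),
            class = "stability_region")
}

#' @export
print.stability_region <- function(x, ...) {
  if (is.na(x$k)) {
    cat(sprintf(
      "No stable k found (window %d, tolerance %.3g); inspect the trajectory.\n",
      x$window, x$tol))
  } else {
    cat(sprintf(
      "Recommended k = %d (largest k with shape range <= %.3g over %d values)\n",
      x$k, x$tol, x$window))
  }
  invisible(x)
}
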