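# broom-style tabular views of fitted objects

#' Tidy a GPD fit
#'
#' One row per parameter with estimate, asymptotic standard error and
#' Gaussian confidence limits (standard errors and limits are `NA` when
#' the shape estimate is at or below -1/2, where the ML asymptotics do
#' not hold).
#'
#' @param x A `"gpd_fit"`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy gpd_fit
#' @export
tidy.gpd_fit <- function(x, conf.level = 0.95, ...) {
  if (x$asymptotics_valid) {
    se <- sqrt(diag(x$cov))
    g_ci <- shape_ci(x, level = conf.level)
    s_ci <- scale_ci(x, level = conf.level)
    tibble::tibble(
      term = c("gamma", "sigma"),
      estimate = c(x$gamma, x$sigma),
      std.error = unname(se),
      conf.low = c(g_ci[["lower"]], s_ci[["lower"]]),
      conf.high = c(g_ci[["upper"]], s_ci[["upper"]])
    )
  } else {
    tibble::tibble(
      term = c("gamma", "sigma"),
      estimate = c(x$gamma, x$sigma),
      std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_
    )
  }
}

#' Glance at a GPD fit
#'
#' @param x A `"gpd_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, `threshold`, `t0`, `logLik`,
#'   `converged`, `asymptotics_valid`.
#' @method glance gpd_fit
#' @export
glance.gpd_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, threshold = x$threshold, t0 = x$t0,
    logLik = x$loglik, converged = x$converged,
    asymptotics_valid = x$asymptotics_valid
  )
}

#' Tidy an endpoint estimate
#'
#' @param x An `"endpoint_estimate"` from [endpoint_ci()].
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `sample_max`, `truncated`, `level`.
#' @method tidy endpoint_estimate
#' @export
tidy.endpoint_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$xhat, conf.low = x$ci_lower, conf.high = x$ci_upper,
    sample_max = x$t0, truncated = x$truncated, level = x$level
  )
}

#' Tidy a stratum comparison
#'
#' @param x A `"stratum_comparison"` from [lr_test_strata()].
#' @param ... Unused.
#' @return A tibble with one row per stratum plus one for the pooled
#'   model: `stratum`, `k`, `gamma`, `sigma`, `logLik`.
#' @method tidy stratum_comparison
#' @export
tidy.stratum_comparison <- function(x, ...) {
  rows <- purrr::imap(x$stratum_fits, function(f, label) {
    tibble::tibble(stratum = label, k = f$k, gamma = f$gamma,
                   sigma = f$sigma, logLik = f$loglik)
  })
  pooled <- tibble::tibble(stratum = "(pooled)", k = x$pooled$k,
                           gamma = x$pooled$gamma, sigma = x$pooled$sigma,
                           logLik = x$pooled$loglik)
  dplyr::bind_rows(c(rows, list(pooled)))
}

#' Glance at a stratum comparison
#'
#' @param x A `"stratum_comparison"`.
#' @param ... Unused.
#' @return A one-row tibble: `n_strata`, `lr_stat`, `df`, `p.value`.
#' @method glance stratum_comparison
#' @export
glance.stratum_comparison <- function(x, ...) {
  tibble::tibble(n_strata = length(x$stratum_fits), lr_stat = x$lr_stat,
                 df = x$df, p.value = x$p_value)
}

#' Tidy an analysis report
#'
#' @param x A `"yield_report"` from [run_analysis()].
#' @param ... Unused.
#' @return The report's full-precision summary table, one row per
#'   analysis block.
#' @method tidy yield_report
#' @export
tidy.yield_report <- function(x, ...) {
  x$table
}

#' Glance at an analysis report
#'
#' @param x A `"yield_report"`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_strata`, `stratify`, `level`, and
#'   the LR statistic and p-value when the analysis is stratified.
#' @method glance yield_report
#' @export
glance.yield_report <- function(x, ...) {
  tibble::tibble(
    n = sum(x$table$n), n_strata = nrow(x$table), stratify = x$stratify,
    level = x$level,
    lr_stat = if (is.null(x$lr)) NA_real_ else x$lr$lr_stat,
    lr_p = if (is.null(x$lr)) NA_real_ else x$lr$p_value
  )
}
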