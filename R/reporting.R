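# End-to-end analysis runner and report serialization: full-sample or
# stratified tail analyses with the standard summary columns
# (n, k, t, shape (CI), scale (CI), endpoint (CI)).

#' Read and write farm-year panels
#'
#' `read_panel()` reads a CSV with the canonical header
#' `farm_id,year,yield,region,fert_cost,cp_cost` and validates the
#' schema: the columns must all be present (extras are an error), the
#' numeric columns numeric, yields finite and non-negative, and
#' `(farm_id, year)` unique -- violations are reported with row numbers.
#' `write_panel()` writes the same schema; a written panel reads back
#' identically.
#'
#' @param path CSV file path.
#' @param panel A panel tibble.
#' @return `read_panel()` a validated panel tibble; `write_panel()` the
#'   input, invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      farm_id = readr::col_character(),
      year = readr::col_integer(),
      yield = readr::col_double(),
      region = readr::col_character(),
      fert_cost = readr::col_double(),
      cp_cost = readr::col_double()
    )
  )
  expected <- c("farm_id", "year", "yield", "region", "fert_cost", "cp_cost")
  extra <- setdiff(names(panel), expected)
  if (length(extra) > 0L) {
    abort(sprintf("Unexpected column(s) in %s: %s.", path,
                  paste(extra, collapse = ", ")))
  }
  problems <- readr::problems(panel)
  if (nrow(problems) > 0L) {
    abort(sprintf("Malformed values in %s at row(s): %s.", path,
                  paste(head(unique(problems$row), 5), collapse = ", ")))
  }
  check_panel(panel)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  readr::write_csv(panel, path)
  invisible(panel)
}

#' Run the full tail analysis of a yield panel
#'
#' The complete pipeline: (optionally) deflate input costs, collapse the
#' panel to one maximum-yield record per farm, stratify, pick the
#' effective sample size `k` for each stratum, fit the GPD exceedance
#' model by maximum likelihood, and report, per stratum, the sample size,
#' `k`, threshold, shape and scale estimates with Gaussian confidence
#' intervals, and the right-endpoint estimate with its truncated
#' interval. When the analysis is stratified, a likelihood-ratio test of
#' stratum-specific versus pooled tail parameters is attached.
#'
#' @param x A farm-year panel tibble, a path to a panel CSV, or a
#'   [synth_config()] (the panel is then generated first).
#' @param stratify `"none"` (full sample), `"region"` (macro-regions) or
#'   `"spend"` (input-spending bands).
#' @param k Effective sample size: `"auto"` resolves `k` per stratum via
#'   [stability_region()] on that stratum's [shape_trajectory()]; a
#'   single number uses that `k` everywhere; a named vector maps stratum
#'   labels to `k`.
#' @param level Confidence level for all intervals.
#' @param index,base_year Optional price index (`year`,`index` data
#'   frame) and base year for [deflate_costs()]; costs are used as-is
#'   when omitted.
#' @param n_groups Number of spending bands when `stratify = "spend"`.
#' @param k_min,k_max Trajectory range used when `k = "auto"`.
#' @param window,tol Stability-heuristic settings passed to
#'   [stability_region()].
#' @return An object of class `"yield_report"`: a list with `table` (one
#'   row per analysis block, full precision), `fits`, `endpoints`, `lr`
#'   (a [lr_test_strata()] result, or `NULL` for a single block),
#'   `cutpoints` (spending stratification only), `level`, `stratify` and
#'   `log` (one line per fit and per decision, for audit). `tidy()`
#'   returns the table; [write_report()] serializes it.
#' @examples
#' report <- run_analysis(synth_config(n_farms = 300, seed = 1), k = 80)
#' tidy(report)
#' @export
run_analysis <- function(x,
                         stratify = c("none", "region", "spend"),
                         k = "auto",
                         level = 0.95,
                         index = NULL, base_year = NULL,
                         n_groups = 3,
                         k_min = 15, k_max = 400,
                         window = 50, tol = 0.05) {
  stratify <- match.arg(stratify)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  panel <- if (inherits(x, "synth_config")) {
    note("generated synthetic panel (seed %d)", x$seed)
    generate_panel(x)
  } else if (is.character(x) && length(x) == 1L) {
    note("read panel from %s", x)
    read_panel(x)
  } else {
    check_panel(x)
  }

  if (!is.null(index)) {
    if (is.null(base_year)) abort("Supply `base_year` with `index`.")
    panel <- deflate_costs(panel, index, base_year)
    note("deflated costs to %s money", base_year)
  }

  sample <- dedup_farm_max(panel)
  note("deduplicated to %d unique farms (from %d farm-years)",
       nrow(sample), nrow(panel))

  cutpoints <- NULL
  sample <- switch(
    stratify,
    none = dplyr::mutate(sample, stratum = factor("all")),
    region = stratify_by_region(sample),
    spend = {
      s <- stratify_by_spend(sample, n_groups = n_groups)
      cutpoints <- spend_cutpoints(s)
      note("spending cut points: %s",
           paste(signif(cutpoints, 6), collapse = ", "))
      s
    }
  )

  strata <- split(sample, sample$stratum)
  k_map <- resolve_k(k, strata, k_min, k_max, window, tol, note)

  fits <- list()
  endpoints <- list()
  rows <- list()
  for (label in names(strata)) {
    yields <- strata[[label]]$max_yield
    kk <- k_map[[label]]
    fit <- tryCatch(
      fit_gpd_ml(select_exceedances(yields, kk)),
      error = function(e) {
        abort(sprintf("Analysis block '%s' failed: %s", label,
                      conditionMessage(e)))
      }
    )
    note("fit '%s': n=%d k=%d t=%.4g gamma=%.4f sigma=%.4f converged=%s",
         label, fit$n, fit$k, fit$threshold, fit$gamma, fit$sigma,
         fit$converged)
    g_ci <- if (fit$asymptotics_valid) shape_ci(fit, level = level) else
      c(lower = NA_real_, upper = NA_real_)
    s_ci <- if (fit$asymptotics_valid) scale_ci(fit, level = level) else
      c(lower = NA_real_, upper = NA_real_)
    ep <- NULL
    if (fit$gamma < 0 && fit$asymptotics_valid) {
      ep <- endpoint_ci(fit, level = level)
      if (ep$truncated) {
        note("fit '%s': endpoint CI lower bound truncated at t0=%.4g",
             label, fit$t0)
      }
    } else {
      note("fit '%s': no finite endpoint reported (gamma=%.4f)",
           label, fit$gamma)
    }
    fits[[label]] <- fit
    endpoints[[label]] <- ep
    rows[[label]] <- tibble::tibble(
      stratum = label,
      n = length(yields), k = fit$k, threshold = fit$threshold,
      gamma = fit$gamma,
      gamma_lower = g_ci[["lower"]], gamma_upper = g_ci[["upper"]],
      sigma = fit$sigma,
      sigma_lower = s_ci[["lower"]], sigma_upper = s_ci[["upper"]],
      endpoint = if (is.null(ep)) NA_real_ else ep$xhat,
      endpoint_lower = if (is.null(ep)) NA_real_ else ep$ci_lower,
      endpoint_upper = if (is.null(ep)) NA_real_ else ep$ci_upper,
      truncated = if (is.null(ep)) NA else ep$truncated
    )
  }

  lr <- NULL
  if (length(fits) > 1L) {
    lr <- lr_test_strata(fits)
    note("LR test strata vs pooled: LR=%.4f df=%d p=%.4g",
         lr$lr_stat, lr$df, lr$p_value)
  }

  structure(
    list(table = dplyr::bind_rows(rows), fits = fits,
         endpoints = endpoints, lr = lr, cutpoints = cutpoints,
         level = level, stratify = stratify, log = log_lines),
    class = "yield_report"
  )
}

# Resolve the k policy ("auto", scalar, or named map) per stratum.
resolve_k <- function(k, strata, k_min, k_max, window, tol, note) {
  out <- list()
  for (label in names(strata)) {
    n <- nrow(strata[[label]])
    kk <- if (identical(k, "auto")) {
      traj <- shape_trajectory(strata[[label]]$max_yield,
                               k_min = k_min, k_max = min(k_max, n - 1))
      reg <- withCallingHandlers(
        stability_region(traj, window = min(window, nrow(traj)), tol = tol),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (is.na(reg$k)) {
        # nothing met the tolerance: take the k with the flattest window
        idx <- which.min(reg$diagnostics$rolling_range)
        note("stratum '%s': no stable window, using flattest k=%d",
             label, reg$diagnostics$k[idx])
        reg$diagnostics$k[idx]
      } else {
        note("stratum '%s': stability heuristic chose k=%d", label, reg$k)
        reg$k
      }
    } else if (is.numeric(k) && length(k) == 1L && is.null(names(k))) {
      k
    } else if (is.numeric(k) && !is.null(names(k))) {
      if (!label %in% names(k)) {
        abort(sprintf("No k supplied for stratum '%s'.", label))
      }
      k[[label]]
    } else {
      abort("`k` must be \"auto\", a single number, or a named numeric vector.")
    }
    if (kk < 2 || kk > n - 1) {
      abort(sprintf("k = %s invalid for stratum '%s' (n = %d).",
                    format(kk), label, n))
    }
    out[[label]] <- as.integer(kk)
  }
  out
}

#' @export
print.yield_report <- function(x, digits = 2, ...) {
  cat(sprintf("Yield tail analysis (%s stratification, %g%% intervals)\n\n",
              x$stratify, 100 * x$level))
  tbl <- x$table
  fmt <- function(v) format(round_half_away(v, digits), nsmall = digits)
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    ep <- if (is.na(r$endpoint)) "no finite endpoint" else
      sprintf("x* = %s (%s, %s)%s", fmt(r$endpoint), fmt(r$endpoint_lower),
              fmt(r$endpoint_upper),
              if (isTRUE(r$truncated)) " [truncated]" else "")
    cat(sprintf(
      "  %-8s n=%4d k=%3d t=%s  gamma %s (%s, %s)  sigma %s (%s, %s)  %s\n",
      r$stratum, r$n, r$k, fmt(r$threshold), fmt(r$gamma),
      fmt(r$gamma_lower), fmt(r$gamma_upper), fmt(r$sigma),
      fmt(r$sigma_lower), fmt(r$sigma_upper), ep))
  }
  if (!is.null(x$lr)) {
    cat(sprintf("\n  LR test (strata vs pooled): LR = %.3f, df = %d, p = %s\n",
                x$lr$lr_stat, x$lr$df, format.pval(x$lr$p_value, digits = 3)))
  }
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes `report.json` (full-precision values plus display strings
#' rounded half-away-from-zero to `digits` decimals, the audit log, and
#' the LR test when present) and `report.csv` (the full-precision table)
#' into `dir`. Rounding is presentation-only: the JSON always carries the
#' unrounded numbers.
#'
#' @param report A `"yield_report"` from [run_analysis()].
#' @param dir Output directory, created if needed.
#' @param digits Decimal places for the display strings.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir, digits = 2) {
  stopifnot(inherits(report, "yield_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tbl <- report$table
  display <- lapply(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    fmt <- function(v) {
      if (is.na(v)) NA_character_ else
        format(round_half_away(v, digits), nsmall = digits, trim = TRUE)
    }
    list(stratum = r$stratum,
         gamma = sprintf("%s (%s, %s)", fmt(r$gamma), fmt(r$gamma_lower),
                         fmt(r$gamma_upper)),
         sigma = sprintf("%s (%s, %s)", fmt(r$sigma), fmt(r$sigma_lower),
                         fmt(r$sigma_upper)),
         endpoint = if (is.na(r$endpoint)) "none (shape >= 0)" else
           sprintf("%s (%s, %s)", fmt(r$endpoint), fmt(r$endpoint_lower),
                   fmt(r$endpoint_upper)))
  })
  payload <- list(
    level = report$level,
    stratification = report$stratify,
    table = tbl,
    display = display,
    cutpoints = report$cutpoints,
    lr_test = if (!is.null(report$lr)) {
      list(lr_stat = report$lr$lr_stat, df = report$lr$df,
           p_value = report$lr$p_value)
    },
    log = report$log
  )
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "report.csv")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  readr::write_csv(tbl, csv_path)
  invisible(c(json = json_path, csv = csv_path))
}
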