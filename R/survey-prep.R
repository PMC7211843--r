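# Turning a raw farm-year panel into the analysis sample: deflate input
# costs against a price index, collapse each farm to its best year, map
# NUTS1 regions to macro-regions, and stratify by region or by spending.

# NUTS1 -> macro-region grouping used for the regional analyses
MACRO_REGIONS <- c(
  "east midlands" = "east",
  "east of england" = "east",
  "london" = "east",
  "south east england" = "east",
  "north east england" = "north",
  "north west england" = "north",
  "yorkshire & humberside" = "north",
  "west midlands" = "west",
  "south west england" = "west",
  "wales" = "west"
)

#' Map NUTS1 regions to analysis macro-regions
#'
#' England-and-Wales NUTS1 regions are grouped into three macro-regions
#' large enough for a tail analysis: `east` (East Midlands, East of
#' England, London, South East England), `north` (North East England,
#' North West England, Yorkshire & Humberside) and `west` (West Midlands,
#' South West England, Wales). Matching is case-insensitive; labels
#' already equal to a macro-region pass through unchanged.
#'
#' @param nuts1 Character vector of NUTS1 region names.
#' @return Character vector of macro-region labels (`east`, `north`,
#'   `west`).
#' @examples
#' assign_macro_region(c("East Midlands", "Wales"))
#' @export
assign_macro_region <- function(nuts1) {
  if (!is.character(nuts1)) abort("`nuts1` must be a character vector.")
  key <- tolower(trimws(nuts1))
  out <- unname(MACRO_REGIONS[key])
  passthrough <- key %in% unique(unname(MACRO_REGIONS))
  out[passthrough] <- key[passthrough]
  if (anyNA(out)) {
    bad <- unique(nuts1[is.na(out)])
    abort(sprintf(
      "Unknown region(s): %s. Accepted NUTS1 names: %s.",
      paste(bad, collapse = ", "),
      paste(names(MACRO_REGIONS), collapse = ", ")))
  }
  out
}

#' Deflate panel costs against a price index
#'
#' Rescales `fert_cost` and `cp_cost` to base-year money:
#' `cost * index[base_year] / index[year]`. Yields are untouched. The
#' operation is a plain ratio adjustment, so re-applying it to
#' already-deflated records rescales them again -- deflate raw records
#' exactly once.
#'
#' @param panel A farm-year panel (tibble with `farm_id`, `year`,
#'   `yield`, `region`, `fert_cost`, `cp_cost`).
#' @param index A data frame with columns `year` and `index` (positive
#'   values), covering every year in the panel and the base year.
#' @param base_year The year whose money the costs are expressed in.
#' @return The panel with deflated `fert_cost` and `cp_cost`.
#' @examples
#' idx <- tibble::tibble(year = 2009:2010, index = c(90, 100))
#' panel <- tibble::tibble(farm_id = "A", year = 2009, yield = 8,
#'                         region = "east", fert_cost = 100, cp_cost = 50)
#' deflate_costs(panel, idx, base_year = 2010)
#' @export
deflate_costs <- function(panel, index, base_year) {
  check_panel(panel)
  if (!is.data.frame(index) || !all(c("year", "index") %in% names(index))) {
    abort("`index` must be a data frame with columns `year` and `index`.")
  }
  if (any(index$index <= 0)) abort("Price index values must be positive.")
  if (!base_year %in% index$year) {
    abort(sprintf("Base year %s missing from the price index.", base_year))
  }
  missing_years <- setdiff(unique(panel$year), index$year)
  if (length(missing_years) > 0L) {
    abort(sprintf("Price index has no entry for year(s): %s.",
                  paste(sort(missing_years), collapse = ", ")))
  }
  base_value <- index$index[match(base_year, index$year)]
  factor <- base_value / index$index[match(panel$year, index$year)]
  dplyr::mutate(panel,
                fert_cost = .data$fert_cost * factor,
                cp_cost = .data$cp_cost * factor)
}

#' Collapse a panel to one record per farm: the maximum-yield year
#'
#' High-yielding farms participate in several survey years; keeping every
#' year would duplicate them in the upper tail. Each farm is therefore
#' represented once, by its maximum yield across the years it appears,
#' with the region and (deflated) input costs of the year achieving that
#' maximum. When two years tie on the maximum the earliest year's
#' covariates are kept, which makes the result independent of row order.
#'
#' @param panel A farm-year panel, non-empty.
#' @return A tibble with one row per farm: `farm_id`, `max_yield`,
#'   `region`, `total_input_cost` (`fert_cost + cp_cost` of the retained
#'   year) and `year` (the retained year).
#' @examples
#' panel <- generate_panel(synth_config(n_farms = 30, seed = 2))
#' dedup_farm_max(panel)
#' @export
dedup_farm_max <- function(panel) {
  check_panel(panel)
  if (nrow(panel) == 0L) abort("Cannot deduplicate an empty panel.")
  panel |>
    dplyr::arrange(.data$farm_id, dplyr::desc(.data$yield), .data$year) |>
    dplyr::distinct(.data$farm_id, .keep_all = TRUE) |>
    dplyr::transmute(
      farm_id = .data$farm_id,
      max_yield = .data$yield,
      region = .data$region,
      total_input_cost = .data$fert_cost + .data$cp_cost,
      year = .data$year
    ) |>
    tibble::as_tibble()
}

#' Stratify a farm sample into spending groups
#'
#' Orders farms by total input spending (fertilizer plus crop protection)
#' and cuts them into `n_groups` contiguous groups of as-equal-as-possible
#' size: sizes differ by at most one, with the larger groups at the
#' low-spend end. Ties in spending are broken by `farm_id` (stable), so
#' equal-size groups are reproducible even with duplicated spend values.
#' The cut points reported are the spending levels at the group
#' boundaries (maximum spend of each lower group).
#'
#' @param sample A per-farm sample from [dedup_farm_max()].
#' @param n_groups Number of spending bands (default 3: low/medium/high).
#' @return The sample with an added ordered factor column `stratum`
#'   (`spend_1` = lowest spenders, ... ; labelled `low`/`medium`/`high`
#'   when `n_groups = 3`), carrying the boundary spends in
#'   `attr(, "cutpoints")` (see [spend_cutpoints()]).
#' @examples
#' sample <- dedup_farm_max(generate_panel(synth_config(seed = 3)))
#' strat <- stratify_by_spend(sample)
#' table(strat$stratum)
#' spend_cutpoints(strat)
#' @export
stratify_by_spend <- function(sample, n_groups = 3) {
  check_sample(sample)
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 2 ||
      n_groups != floor(n_groups)) {
    abort("`n_groups` must be a single integer >= 2.")
  }
  n <- nrow(sample)
  if (n < n_groups) {
    abort(sprintf("Cannot split %d farms into %d groups.", n, n_groups))
  }
  labels <- if (n_groups == 3) c("low", "medium", "high") else
    paste0("spend_", seq_len(n_groups))
  # larger groups at the low-spend end when n is not divisible
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(sample$total_input_cost, sample$farm_id)
  group_of <- integer(n)
  group_of[ord] <- rep(seq_len(n_groups), times = sizes)
  out <- dplyr::mutate(
    sample,
    stratum = factor(labels[group_of], levels = labels, ordered = TRUE))
  boundary_idx <- cumsum(sizes)[-n_groups]
  attr(out, "cutpoints") <- sample$total_input_cost[ord][boundary_idx]
  out
}

#' @rdname stratify_by_spend
#' @param x A sample returned by [stratify_by_spend()].
#' @export
spend_cutpoints <- function(x) {
  cp <- attr(x, "cutpoints")
  if (is.null(cp)) abort("`x` carries no spending cut points.")
  cp
}

#' Stratify a farm sample by macro-region
#'
#' Labels every farm with its macro-region stratum (mapping NUTS1 names
#' via [assign_macro_region()] where needed). The strata partition the
#' sample: every farm belongs to exactly one.
#'
#' @param sample A per-farm sample from [dedup_farm_max()].
#' @return The sample with an added factor column `stratum`.
#' @examples
#' sample <- dedup_farm_max(generate_panel(synth_config(seed = 3)))
#' table(stratify_by_region(sample)$stratum)
#' @export
stratify_by_region <- function(sample) {
  check_sample(sample)
  macro <- assign_macro_region(as.character(sample$region))
  dplyr::mutate(sample, stratum = factor(macro))
}

# ---- schema checks ----

check_panel <- function(panel) {
  required <- c("farm_id", "year", "yield", "region", "fert_cost", "cp_cost")
  if (!is.data.frame(panel)) abort("The panel must be a data frame.")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0L) {
    abort(sprintf("Panel is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (col in c("year", "yield", "fert_cost", "cp_cost")) {
    if (!is.numeric(panel[[col]])) {
      abort(sprintf("Panel column `%s` must be numeric.", col))
    }
  }
  if (nrow(panel) > 0L) {
    if (any(!is.finite(panel$yield)) || any(panel$yield < 0)) {
      bad <- which(!is.finite(panel$yield) | panel$yield < 0)
      abort(sprintf("Non-finite or negative yield at row(s): %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
    dup <- duplicated(panel[c("farm_id", "year")])
    if (any(dup)) {
      first <- which(dup)[1]
      abort(sprintf(
        "Duplicate (farm_id, year) pair: ('%s', %s) at row %d.",
        panel$farm_id[first], panel$year[first], first))
    }
  }
  invisible(panel)
}

check_sample <- function(sample) {
  required <- c("farm_id", "max_yield", "region", "total_input_cost")
  if (!is.data.frame(sample)) abort("The sample must be a data frame.")
  missing <- setdiff(required, names(sample))
  if (length(missing) > 0L) {
    abort(sprintf("Sample is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sample$farm_id)) {
    abort("Sample has duplicated farm_id values; run dedup_farm_max() first.")
  }
  invisible(sample)
}
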