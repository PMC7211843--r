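# Independent oracles used across the suite. These deliberately avoid the
# package's optimisation and selection code paths: the grid search scans
# the likelihood surface exhaustively, the group-by oracle uses base R
# loops, and the quadrature oracle integrates the density numerically.

# exhaustive (gamma, log sigma) grid search of the GPD log-likelihood;
# returns the best grid point and its log-likelihood
grid_search_gpd <- function(excesses, n_grid = 200,
                            gamma_range = c(-0.95, 1.5)) {
  log_sigma_range <- log(mean(excesses)) + c(-2, 2)
  gammas <- seq(gamma_range[1], gamma_range[2], length.out = n_grid)
  log_sigmas <- seq(log_sigma_range[1], log_sigma_range[2],
                    length.out = n_grid)
  k <- length(excesses)
  best <- list(loglik = -Inf, gamma = NA, sigma = NA)
  for (g in gammas) {
    sig <- exp(log_sigmas)
    ll <- if (abs(g) < 1e-6) {
      -k * log(sig) - sum(excesses) / sig
    } else {
      # vectorised over sigma: k x n_grid matrix of 1 + g*y/sigma
      z <- 1 + outer(excesses, sig, function(y, s) g * y / s)
      ok <- colSums(z <= 0) == 0
      out <- rep(-Inf, length(sig))
      if (any(ok)) {
        out[ok] <- -k * log(sig[ok]) -
          (1 + 1 / g) * colSums(log(z[, ok, drop = FALSE]))
      }
      out
    }
    i <- which.max(ll)
    if (ll[i] > best$loglik) {
      best <- list(loglik = ll[i], gamma = g, sigma = sig[i])
    }
  }
  best
}

# base-R per-farm maximum oracle: loop over farms, no dplyr
dedup_oracle <- function(panel) {
  ids <- sort(unique(panel$farm_id))
  rows <- lapply(ids, function(id) {
    sub <- panel[panel$farm_id == id, , drop = FALSE]
    best <- max(sub$yield)
    cand <- sub[sub$yield == best, , drop = FALSE]
    cand <- cand[order(cand$year), , drop = FALSE][1, , drop = FALSE]
    data.frame(farm_id = id, max_yield = best, region = cand$region,
               total_input_cost = cand$fert_cost + cand$cp_cost,
               year = cand$year, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# a small panel with hand-controllable yields
make_panel <- function(farm_id, year, yield, region = "east",
                       fert_cost = 100, cp_cost = 50) {
  tibble::tibble(farm_id = farm_id, year = year, yield = yield,
                 region = region, fert_cost = fert_cost, cp_cost = cp_cost)
}

# yields with a clean GPD tail: bulk strictly below u, k excesses above
make_tail_sample <- function(k, gamma, sigma, u = 10.69, n_bulk = NULL) {
  n_bulk <- n_bulk %||% (4 * k)
  c(runif(n_bulk, 0.5 * u, u - 1e-3), u + gpd_sample(k, gamma, sigma))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
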