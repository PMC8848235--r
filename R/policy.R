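#' Inventory cost configuration
#'
#' Unit costs for the total-cost objective: a locally produced platelet
#' unit costs about US$350, and a unit bought in an emergency costs
#' almost double — rounded up to US$700 to also penalize the transfusion
#' delay that an external purchase implies.
#'
#' @param unit_cost Cost of a wasted (produced) unit, currency/unit.
#' @param emergency_cost Cost of an emergency-purchased unit.
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(unit_cost = 350, emergency_cost = 700) {
  if (emergency_cost < unit_cost) {
    abort("`emergency_cost` must be at least `unit_cost`.")
  }
  structure(list(unit_cost = unit_cost, emergency_cost = emergency_cost),
            class = "cost_config")
}

#' Total cost of a simulated horizon
#'
#' \deqn{c = \mathrm{unit\_cost} \cdot \sum w_i +
#'   \mathrm{emergency\_cost} \cdot \sum b_i,}
#' i.e. every wasted unit costs its production price and every emergency
#' purchase its (doubled) external price.
#'
#' @param ledger A `platelet_ledger` from [run_simulation()].
#' @param config A [cost_config()].
#' @return Total cost over the post-warmup horizon (currency).
#' @export
total_cost <- function(ledger, config = cost_config()) {
  s <- attr(ledger, "summary")
  if (is.null(s)) abort("`ledger` must be a `platelet_ledger`.")
  config$unit_cost * s$total_wasted + config$emergency_cost * s$total_purchased
}

#' Exhaustive grid search over the policy parameters
#'
#' Simulates the inventory for every (alpha, beta, gamma) combination in
#' the given ranges and returns the cost-minimizing triple together with
#' the full cost surface. Ties are broken by the smallest `alpha`, then
#' `beta`, then `gamma`. The surface is deterministic given the demand
#' and forecast series.
#'
#' @param demand Daily tibble with `date`, `demand`.
#' @param forecasts Tibble with `date`, `p2`, `p4` covering the horizon.
#' @param alpha_range,beta_range,gamma_range Integer vectors of candidate
#'   values (default 0:30 each).
#' @param cost A [cost_config()].
#' @param warmup Days excluded from totals.
#' @return A list: `best` ([policy_params()]), `best_cost`, and `surface`
#'   (tibble `alpha`, `beta`, `gamma`, `cost`, `waste_rate`,
#'   `shortage_rate`).
#' @export
grid_search_policy <- function(demand, forecasts,
                               alpha_range = 0:30, beta_range = 0:30,
                               gamma_range = 0:30, cost = cost_config(),
                               warmup = 14) {
  if (!length(alpha_range) || !length(beta_range) || !length(gamma_range)) {
    abort("parameter ranges must be non-empty.")
  }
  sim <- dplyr::inner_join(forecasts[c("date", "p2", "p4")],
                           demand[c("date", "demand")], by = "date")
  if (nrow(sim) != nrow(forecasts)) {
    abort("`demand` does not cover every forecast date.")
  }
  check_contiguous_dates(sim$date, "simulation span")
  wd <- as.integer(weekday_index(sim$date))
  u <- as.integer(sim$demand)
  p2 <- as.numeric(sim$p2)
  p4 <- as.numeric(sim$p4)
  warm <- as.integer(min(warmup, nrow(sim) - 1L))

  grid <- expand.grid(gamma = as.integer(gamma_range),
                      beta = as.integer(beta_range),
                      alpha = as.integer(alpha_range))
  res <- vapply(seq_len(nrow(grid)), function(k) {
    tot <- simulate_totals_cpp(u, p2, p4, wd, grid$alpha[k], grid$beta[k],
                               grid$gamma[k], warm)
    used <- tot[["total_used"]]
    c(cost = cost$unit_cost * tot[["total_wasted"]] +
        cost$emergency_cost * tot[["total_purchased"]],
      waste_rate = if (used > 0) tot[["total_wasted"]] / used else 0,
      shortage_rate = if (used > 0) tot[["total_purchased"]] / used else 0)
  }, numeric(3))

  surface <- tibble::tibble(
    alpha = grid$alpha, beta = grid$beta, gamma = grid$gamma,
    cost = unname(res["cost", ]), waste_rate = unname(res["waste_rate", ]),
    shortage_rate = unname(res["shortage_rate", ])
  ) |>
    dplyr::arrange(.data$alpha, .data$beta, .data$gamma)

  best_row <- surface |>
    dplyr::arrange(.data$cost, .data$alpha, .data$beta, .data$gamma) |>
    dplyr::slice(1)
  list(
    best = policy_params(best_row$alpha, best_row$beta, best_row$gamma),
    best_cost = best_row$cost,
    surface = surface
  )
}
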