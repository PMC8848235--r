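#' Inventory policy parameters
#'
#' The three integer control parameters of the ordering and purchasing
#' policy: `alpha`, the target end-of-day stock the production order aims
#' to restore; `beta`, the post-consumption stock level at or below which
#' an emergency purchase is triggered; and `gamma`, the stock level
#' restored after such a purchase.
#'
#' @param alpha,beta,gamma Integer units.
#' @return A list of class `policy_params`.
#' @export
policy_params <- function(alpha = 0, beta = 0, gamma = 0) {
  for (v in list(alpha = alpha, beta = beta, gamma = gamma)) {
    if (length(v) != 1 || !is.finite(v)) abort("policy parameters must be single finite numbers.")
  }
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta),
                 gamma = as.integer(gamma)),
            class = "policy_params")
}

#' @export
print.policy_params <- function(x, ...) {
  cat(sprintf("<policy_params> alpha = %d, beta = %d, gamma = %d\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Shelf-life-stratified inventory state
#'
#' Stock is held in four age classes by remaining shelf life: `r0` expires
#' at the end of the current day, `r3` has the full four remaining days a
#' platelet unit gets after quality control. `order_minus_1` and
#' `order_minus_2` are the production orders placed one and two days ago;
#' the latter arrives (at age class `r3`) during the next day's step.
#' Between days, `r0` is always 0 (expired units are discarded within the
#' step).
#'
#' @param r0,r1,r2,r3 Non-negative integer units by remaining shelf life.
#' @param order_minus_1,order_minus_2 Units ordered on the previous two
#'   days.
#' @return A list of class `inventory_state`.
#' @export
inventory_state <- function(r0 = 0, r1 = 0, r2 = 0, r3 = 0,
                            order_minus_1 = 0, order_minus_2 = 0) {
  vals <- c(r0 = r0, r1 = r1, r2 = r2, r3 = r3,
            order_minus_1 = order_minus_1, order_minus_2 = order_minus_2)
  if (any(vals < 0) || any(!is.finite(vals))) {
    abort("all inventory-state fields must be non-negative finite integers.")
  }
  structure(as.list(stats::setNames(as.integer(vals), names(vals))),
            class = "inventory_state")
}

#' @export
print.inventory_state <- function(x, ...) {
  cat(sprintf("<inventory_state> r0..r3 = %d %d %d %d; o[-1] = %d, o[-2] = %d (stock %d)\n",
              x$r0, x$r1, x$r2, x$r3, x$order_minus_1, x$order_minus_2,
              x$r1 + x$r2 + x$r3))
  invisible(x)
}

#' Production order for the day
#'
#' End-of-day ordering rule. An order placed on day i arrives on day
#' i + 2, so it must cover predicted demand until the next arrival:
#' `p2` (the 2-day-ahead demand forecast) on Sunday through Wednesday, and
#' `p4` (the 4-day-ahead forecast) on Thursday, because no orders can be
#' placed on Fridays and Saturdays and the Thursday order is the last to
#' arrive before the weekend gap. The order tops stock up to the target:
#' \deqn{o_i = \max(0,\; P + \alpha - s_i - o_{i-1})}
#' with `P` the applicable forecast, `s_i` current end-of-day stock and
#' `o_{i-1}` yesterday's order (already in the pipeline, arriving
#' tomorrow). The result is rounded half-up to whole units.
#'
#' @param state An [inventory_state()] at the end of day i.
#' @param p2,p4 Non-negative demand forecasts (real units).
#' @param alpha Target end-of-day stock (integer units).
#' @param weekday Integer 0 (Sunday) .. 6 (Saturday).
#' @return Integer units to order.
#' @export
order_quantity <- function(state, p2, p4, alpha, weekday) {
  stopifnot(inherits(state, "inventory_state"))
  if (!weekday %in% 0:6) abort("`weekday` must be an integer in 0..6 (Sunday = 0).")
  if (p2 < 0 || p4 < 0 || alpha < 0) abort("`p2`, `p4` and `alpha` must be non-negative.")
  if (weekday %in% c(5L, 6L)) return(0L)
  P <- if (weekday == 4L) p4 else p2
  s <- state$r1 + state$r2 + state$r3
  as.integer(round_half_up(max(0, P + alpha - s - state$order_minus_1)))
}

#' One day of the blood-bank inventory model
#'
#' Advances the inventory by one day: (a) *init* — stock ages one day
#' (r0 <- r1, r1 <- r2, r2 <- r3) and the order placed two days ago
#' arrives at the freshest age class (r3); (b) the day's demand `u` is
#' consumed oldest-first through r0..r3, tracking the running balances
#' t1..t4 (t4 = total stock - u, possibly negative); (c) if t4 is at or
#' below `beta`, an emergency purchase of `gamma - t4` units is made —
#' purchased units first cover any deficit, the remainder enters stock at
#' r3; (d) any unconsumed r0 units expire and count as waste; (e)
#' end-of-day stock is s = r1 + r2 + r3.
#'
#' @param state An [inventory_state()] from the end of the previous day.
#' @param u Demand (units transfused) on the day, non-negative integer.
#' @param beta Purchase trigger threshold (may be `-Inf` to disable
#'   purchases).
#' @param gamma Post-purchase stock target.
#' @return A list: `state` (next [inventory_state()]; its order fields
#'   are shifted, with `order_minus_1` left at 0 for the caller to fill
#'   after ordering) and `entry`, a one-row tibble with `demand`,
#'   `arrival`, `purchase`, `waste`, `stock` and the balance `t4`.
#' @export
step_day <- function(state, u, beta, gamma) {
  stopifnot(inherits(state, "inventory_state"))
  if (u < 0) abort("`u` must be non-negative.")
  u <- as.integer(u)

  # (a) init: age stock, receive the order placed two days ago.
  r0 <- state$r1
  r1 <- state$r2
  r2 <- state$r3
  r3 <- state$order_minus_2
  arrival <- state$order_minus_2
  b <- 0L
  w <- 0L

  # (b) consume oldest-first; t-values are cumulative stock balances, so
  # t4 = total stock - u (negative when demand exceeds stock). The
  # post-consumption content of each age class is its balance clamped to
  # [0, class size].
  t1 <- r0 - u
  t2 <- r1 + t1
  t3 <- r2 + t2
  t4 <- r3 + t3
  r0 <- max(t1, 0L)
  r1 <- min(max(t2, 0L), r1)
  r2 <- min(max(t3, 0L), r2)
  r3 <- min(max(t4, 0L), r3)

  # (c) emergency purchase if the balance fell to or below beta.
  if (t4 <= beta) {
    b <- max(0L, as.integer(gamma - t4))
    surplus <- b - max(0L, -t4)  # units not used to cover the deficit
    if (surplus > 0L) r3 <- r3 + surplus
  }

  # (d) unconsumed age-0 units expire.
  w <- r0
  r0 <- 0L

  s <- r1 + r2 + r3
  new_state <- inventory_state(
    r0 = 0L, r1 = r1, r2 = r2, r3 = r3,
    order_minus_1 = 0L, order_minus_2 = state$order_minus_1
  )
  list(
    state = new_state,
    entry = tibble::tibble(demand = u, arrival = arrival, purchase = b,
                           waste = w, stock = s, t4 = t4)
  )
}

#' Simulate the blood-bank inventory over a demand horizon
#'
#' Runs the daily inventory model over the simulation span: each day the
#' realized demand is consumed ([step_day()]), then the production order
#' for the day is placed ([order_quantity()]) using that day's demand
#' forecasts. Orders arrive after two days; since no orders are placed on
#' Fridays and Saturdays, no stock arrives on Sundays or Mondays. The
#' simulation starts from empty stock, and the first `warmup` days are
#' excluded from the reported totals to remove initialization artifacts.
#'
#' @param demand A daily tibble with `date` and `demand` (realized
#'   transfusions).
#' @param forecasts A tibble with `date`, `p2`, `p4` covering every
#'   simulated day (the simulation runs over the forecast dates).
#' @param params A [policy_params()].
#' @param warmup Days excluded from totals (default 14).
#' @param cost A [cost_config()] used for the ledger's total cost.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference loop over
#'   [step_day()] / [order_quantity()]); both produce identical ledgers.
#' @param fixed_order Optional constant production order: when given, every
#'   ordering day (Sunday-Thursday) places exactly this many units,
#'   ignoring forecasts and stock — the naive constant-order baseline.
#' @return A `platelet_ledger`: a tibble with one row per day (`date`,
#'   `weekday`, `demand`, `order`, `arrival`, `purchase`, `waste`,
#'   `stock`, `t4`) and a summary attribute; see [glance.platelet_ledger()].
#' @export
run_simulation <- function(demand, forecasts, params = policy_params(),
                           warmup = 14, cost = cost_config(),
                           engine = c("cpp", "r"), fixed_order = NULL) {
  engine <- match.arg(engine)
  fixed <- if (is.null(fixed_order)) -1L else as.integer(fixed_order)
  if (fixed < -1L) abort("`fixed_order` must be non-negative.")
  stopifnot(inherits(params, "policy_params"))
  if (!all(c("date", "demand") %in% names(demand))) {
    abort("`demand` must have `date` and `demand` columns.")
  }
  if (!all(c("date", "p2", "p4") %in% names(forecasts))) {
    abort("`forecasts` must have `date`, `p2`, `p4` columns.")
  }
  sim <- dplyr::inner_join(forecasts[c("date", "p2", "p4")],
                           demand[c("date", "demand")], by = "date")
  if (nrow(sim) != nrow(forecasts)) {
    abort("`demand` does not cover every forecast date; the series are misaligned.")
  }
  check_contiguous_dates(sim$date, "simulation span")
  if (any(sim$p2 < 0 | sim$p4 < 0)) abort("forecasts must be non-negative.")
  n <- nrow(sim)
  wd <- weekday_index(sim$date)

  if (engine == "cpp") {
    res <- simulate_inventory_cpp(
      as.integer(sim$demand), as.numeric(sim$p2), as.numeric(sim$p4),
      as.integer(wd), params$alpha, params$beta, params$gamma, fixed
    )
  } else {
    state <- inventory_state()
    res <- list(order = integer(n), arrival = integer(n), purchase = integer(n),
                waste = integer(n), stock = integer(n), t4 = integer(n))
    for (i in seq_len(n)) {
      o_prev <- state$order_minus_1  # placed yesterday, arrives tomorrow
      stepped <- step_day(state, sim$demand[i], params$beta, params$gamma)
      ord_state <- stepped$state
      ord_state$order_minus_1 <- o_prev
      o <- if (fixed >= 0L) {
        if (wd[i] <= 4L) fixed else 0L
      } else {
        order_quantity(ord_state, sim$p2[i], sim$p4[i], params$alpha, wd[i])
      }
      state <- stepped$state
      state$order_minus_1 <- o
      res$order[i] <- o
      res$arrival[i] <- stepped$entry$arrival
      res$purchase[i] <- stepped$entry$purchase
      res$waste[i] <- stepped$entry$waste
      res$stock[i] <- stepped$entry$stock
      res$t4[i] <- stepped$entry$t4
    }
  }

  ledger <- tibble::tibble(
    date = sim$date, weekday = as.integer(wd), demand = as.integer(sim$demand),
    order = as.integer(res$order), arrival = as.integer(res$arrival),
    purchase = as.integer(res$purchase), waste = as.integer(res$waste),
    stock = as.integer(res$stock), t4 = as.integer(res$t4)
  )
  post <- ledger[-seq_len(min(warmup, n - 1L)), , drop = FALSE]
  totals <- list(
    total_used = sum(post$demand), total_ordered = sum(post$order),
    total_purchased = sum(post$purchase), total_wasted = sum(post$waste)
  )
  totals$waste_rate <- if (totals$total_used > 0) totals$total_wasted / totals$total_used else 0
  totals$shortage_rate <- if (totals$total_used > 0) totals$total_purchased / totals$total_used else 0
  totals$cost <- cost$unit_cost * totals$total_wasted +
    cost$emergency_cost * totals$total_purchased
  attr(ledger, "summary") <- c(
    totals,
    list(params = params, warmup = warmup, cost_config = cost,
         n_days = n, engine = engine, fixed_order = fixed_order)
  )
  class(ledger) <- c("platelet_ledger", class(ledger))
  ledger
}

#' @export
print.platelet_ledger <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<platelet_ledger> %d days (warmup %d), alpha/beta/gamma = %d/%d/%d\n",
    s$n_days, s$warmup, s$params$alpha, s$params$beta, s$params$gamma
  ))
  cat(sprintf(
    "  used %d | ordered %d | purchased %d | wasted %d | waste %.2f%% | shortage %.2f%% | cost %.0f\n",
    s$total_used, s$total_ordered, s$total_purchased, s$total_wasted,
    100 * s$waste_rate, 100 * s$shortage_rate, s$cost
  ))
  NextMethod()
}

#' One-row summary of a simulation ledger
#'
#' @param x A `platelet_ledger`.
#' @param ... Unused.
#' @return A one-row tibble with totals, waste/shortage rates (relative to
#'   transfusions) and total cost over the post-warmup horizon.
#' @export
glance.platelet_ledger <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    n_days = s$n_days, warmup = s$warmup,
    alpha = s$params$alpha, beta = s$params$beta, gamma = s$params$gamma,
    total_used = s$total_used, total_ordered = s$total_ordered,
    total_purchased = s$total_purchased, total_wasted = s$total_wasted,
    waste_rate = s$waste_rate, shortage_rate = s$shortage_rate,
    cost = s$cost
  )
}

#' @export
tidy.platelet_ledger <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "platelet_ledger")
  attr(out, "summary") <- NULL
  out
}
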