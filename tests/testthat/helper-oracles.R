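# Independent oracles and fixture builders shared across tests.

# Unit-level FIFO oracle: every platelet unit is tracked individually by
# the day at whose end it expires. Arrivals (ordered two days earlier) and
# emergency purchases enter with 4 usable days; consumption is oldest
# first. Entirely independent of the package's age-class bookkeeping.
fifo_reference <- function(dates, u, p2, p4, alpha, beta, gamma,
                           fixed_order = NULL) {
  n <- length(u)
  wd <- as.POSIXlt(dates)$wday
  expiry <- integer(0)
  out <- tibble::tibble(order = integer(n), arrival = integer(n),
                        purchase = integer(n), waste = integer(n),
                        stock = integer(n), t4 = integer(n))
  o1 <- 0L; o2 <- 0L
  for (i in seq_len(n)) {
    if (o2 > 0L) expiry <- c(expiry, rep(i + 3L, o2))
    out$arrival[i] <- o2
    expiry <- sort(expiry)
    t4 <- length(expiry) - u[i]
    k <- min(u[i], length(expiry))
    if (k > 0L) expiry <- expiry[-seq_len(k)]
    b <- 0L
    if (t4 <= beta) {
      b <- max(0L, as.integer(gamma - t4))
      surplus <- b - max(0L, -t4)
      if (surplus > 0L) expiry <- c(expiry, rep(i + 3L, surplus))
    }
    w <- sum(expiry == i)
    expiry <- expiry[expiry != i]
    s <- length(expiry)
    o <- 0L
    if (wd[i] <= 4L) {
      if (!is.null(fixed_order)) {
        o <- as.integer(fixed_order)
      } else {
        P <- if (wd[i] == 4L) p4[i] else p2[i]
        raw <- P + alpha - s - o1
        o <- if (raw > 0) as.integer(floor(raw + 0.5)) else 0L
      }
    }
    out$order[i] <- o; out$purchase[i] <- b; out$waste[i] <- as.integer(w)
    out$stock[i] <- s; out$t4[i] <- as.integer(t4)
    o2 <- o1; o1 <- o
  }
  out
}

# Random inventory instance: demand, rough forecasts and a date span.
random_instance <- function(n_days, seed, start = as.Date("2015-03-02")) {
  withr::with_seed(seed, {
    dates <- start + seq_len(n_days) - 1L
    u <- rpois(n_days, 12)
    demand <- tibble::tibble(date = dates, demand = as.integer(u))
    forecasts <- tibble::tibble(
      date = dates,
      p2 = pmax(0, 2 * 12 + rnorm(n_days, 0, 4)),
      p4 = pmax(0, 4 * 12 + rnorm(n_days, 0, 6))
    )
    list(demand = demand, forecasts = forecasts)
  })
}

# Small raw daily table for feature-pipeline tests.
make_raw <- function(n_days = 60, seed = 1, ...) {
  simulate_platelet_series(generator_config(n_days = n_days, seed = seed, ...))
}

# Shared calibrated fixtures for the heavier model tests (built once per
# test run, reused across files).
fixture_cache <- new.env(parent = emptyenv())

calibrated_fixture <- function(n_days, seed = 20080101) {
  key <- paste0("fx_", n_days, "_", seed)
  if (is.null(fixture_cache[[key]])) {
    raw <- simulate_platelet_series(generator_config(n_days = n_days, seed = seed))
    fixture_cache[[key]] <- list(
      config = generator_config(n_days = n_days, seed = seed),
      raw = raw
    )
  }
  fixture_cache[[key]]
}
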