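test_that("the worked emergency-purchase example is exact", {
  # stock 2, unexpected need for 4 units, beta = gamma = 0
  out <- step_day(inventory_state(r2 = 2), u = 4, beta = 0, gamma = 0)
  expect_identical(out$entry$t4, -2L)
  expect_identical(out$entry$purchase, 2L)
  expect_identical(out$entry$stock, 0L)
  expect_identical(out$entry$waste, 0L)
})

test_that("unconsumed age-0 units expire as waste", {
  # r0 = 3 after the init shift, no demand, purchases disabled
  out <- step_day(inventory_state(r1 = 3), u = 0, beta = -Inf, gamma = 0)
  expect_identical(out$entry$waste, 3L)
  expect_identical(out$entry$stock, 0L)
  expect_identical(out$entry$purchase, 0L)
})

test_that("consumption is oldest-first", {
  # after init: r0 = 1, r1 = 2; demand 2 eats all of r0 and one of r1
  out <- step_day(inventory_state(r1 = 1, r2 = 2), u = 2, beta = -Inf, gamma = 0)
  expect_identical(out$entry$waste, 0L)
  expect_identical(out$entry$stock, 1L)
  expect_identical(out$state$r1, 1L)
  expect_identical(out$state$r2, 0L)
})

test_that("orders follow the weekday-dependent order-up-to rule", {
  st <- function(stock, o1) inventory_state(r3 = stock, order_minus_1 = o1)
  # no orders on Fridays and Saturdays
  expect_identical(order_quantity(st(10, 5), 20, 40, 13, 5), 0L)
  expect_identical(order_quantity(st(10, 5), 20, 40, 13, 6), 0L)
  # midweek: alpha + p2 - s - o_prev
  expect_identical(order_quantity(st(10, 5), 20, 40, 13, 2), 18L)
  # Thursday uses the 4-day forecast
  expect_identical(order_quantity(st(10, 5), 20, 40, 13, 4), 38L)
  # clamped at zero when stock is ample
  expect_identical(order_quantity(st(40, 0), 20, 10, 0, 4), 0L)
  # fractional forecasts round half-up
  expect_identical(order_quantity(st(0, 0), 2.5, 0, 0, 1), 3L)
  expect_error(order_quantity(st(1, 0), -1, 0, 0, 1), "non-negative")
  expect_error(order_quantity(st(1, 0), 1, 1, 0, 7), "weekday")
})

test_that("an empty system with zero demand stays empty", {
  inst <- random_instance(60, seed = 1)
  inst$demand$demand <- 0L
  zero_fc <- dplyr::mutate(inst$forecasts, p2 = 0, p4 = 0)
  led <- glance(run_simulation(inst$demand, zero_fc, policy_params(0, 0, 0)))
  expect_identical(led$total_ordered, 0L)
  expect_identical(led$total_purchased, 0L)
  expect_identical(led$total_wasted, 0L)
})

test_that("zero forecasts with alpha 0 push all demand to emergency purchase", {
  inst <- random_instance(100, seed = 2)
  zero_fc <- dplyr::mutate(inst$forecasts, p2 = 0, p4 = 0)
  led <- glance(run_simulation(inst$demand, zero_fc, policy_params(0, 0, 0)))
  expect_equal(led$shortage_rate, 1)
  expect_equal(led$waste_rate, 0)
})

test_that("with beta = gamma = 0 purchases equal the deficit exactly", {
  inst <- random_instance(150, seed = 3)
  led <- run_simulation(inst$demand, inst$forecasts, policy_params(8, 0, 0))
  expect_identical(led$purchase, pmax(0L, -led$t4))
})

test_that("every unit is conserved over the full horizon", {
  for (s in 1:5) {
    inst <- random_instance(200, seed = 10 + s)
    led <- run_simulation(inst$demand, inst$forecasts,
                          policy_params(10, 2, 4), warmup = 0)
    consumed_from_stock <- sum(led$demand) - sum(pmax(0L, -led$t4))
    expect_identical(
      sum(led$arrival) + sum(led$purchase) - sum(pmax(0L, -led$t4)) -
        consumed_from_stock - sum(led$waste),
      led$stock[nrow(led)]
    )
  }
})

test_that("the compiled and reference engines produce identical ledgers", {
  for (s in 1:6) {
    inst <- random_instance(100, seed = 20 + s)
    pars <- withr::with_seed(s, policy_params(sample(0:20, 1), sample(0:5, 1),
                                              sample(0:5, 1)))
    a <- run_simulation(inst$demand, inst$forecasts, pars, engine = "cpp")
    b <- run_simulation(inst$demand, inst$forecasts, pars, engine = "r")
    expect_identical(tidy(a), tidy(b))
  }
  # and in fixed-order baseline mode
  inst <- random_instance(80, seed = 31)
  a <- run_simulation(inst$demand, inst$forecasts, policy_params(0, 0, 0),
                      engine = "cpp", fixed_order = 17)
  b <- run_simulation(inst$demand, inst$forecasts, policy_params(0, 0, 0),
                      engine = "r", fixed_order = 17)
  expect_identical(tidy(a), tidy(b))
})

test_that("the unit-level FIFO oracle reproduces the ledger", {
  for (s in 1:5) {
    inst <- random_instance(100, seed = 40 + s)
    pars <- withr::with_seed(100 + s,
                             policy_params(sample(0:15, 1), sample(0:4, 1),
                                           sample(0:4, 1)))
    led <- run_simulation(inst$demand, inst$forecasts, pars)
    oracle <- fifo_reference(inst$demand$date, inst$demand$demand,
                             inst$forecasts$p2, inst$forecasts$p4,
                             pars$alpha, pars$beta, pars$gamma)
    expect_identical(tidy(led)[names(oracle)], oracle)
  }
})

test_that("no unit outlives its four usable days", {
  # with purchases disabled and zero orders after day k, stock drains to 0
  # within 4 days (shelf-life bound by construction)
  inst <- random_instance(40, seed = 60)
  inst$demand$demand[21:40] <- 0L  # no consumption in the tail
  fc <- dplyr::mutate(inst$forecasts,
                      p2 = dplyr::if_else(dplyr::row_number() > 16, 0, p2),
                      p4 = dplyr::if_else(dplyr::row_number() > 16, 0, p4))
  led <- run_simulation(inst$demand, fc, policy_params(0, -1000, 0), warmup = 0)
  # last possible arrival is day 18 (+2 lead); all stock must be gone by day 22
  expect_true(all(led$stock[23:40] == 0))
  expect_equal(sum(led$waste[21:40]), sum(led$stock[20]) + sum(led$arrival[21:40]))
})

test_that("the system is homogeneous of degree one in integer scalings", {
  inst <- random_instance(120, seed = 70)
  fc_int <- dplyr::mutate(inst$forecasts, p2 = round(p2), p4 = round(p4))
  k <- 3L
  base <- run_simulation(inst$demand, fc_int, policy_params(6, 2, 4), warmup = 0)
  scaled_demand <- dplyr::mutate(inst$demand, demand = demand * k)
  scaled_fc <- dplyr::mutate(fc_int, p2 = p2 * k, p4 = p4 * k)
  scaled <- run_simulation(scaled_demand, scaled_fc,
                           policy_params(6 * k, 2 * k, 4 * k), warmup = 0)
  expect_identical(scaled$order, base$order * k)
  expect_identical(scaled$purchase, base$purchase * k)
  expect_identical(scaled$waste, base$waste * k)
  expect_identical(scaled$stock, base$stock * k)
})

test_that("misaligned forecast and demand series are rejected", {
  inst <- random_instance(30, seed = 80)
  expect_error(
    run_simulation(inst$demand[-5, ], inst$forecasts, policy_params(1, 0, 0)),
    "misaligned"
  )
})
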