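test_that("total cost weighs waste at 350 and purchases at 700", {
  inst <- random_instance(60, seed = 5)
  led <- run_simulation(inst$demand, inst$forecasts, policy_params(5, 0, 0))
  g <- glance(led)
  expect_equal(total_cost(led), 350 * g$total_wasted + 700 * g$total_purchased)
  expect_equal(g$cost, total_cost(led))
  # an empty horizon costs nothing
  inst0 <- random_instance(30, seed = 6)
  inst0$demand$demand <- 0L
  fc0 <- dplyr::mutate(inst0$forecasts, p2 = 0, p4 = 0)
  expect_equal(total_cost(run_simulation(inst0$demand, fc0, policy_params(0, 0, 0))), 0)
  expect_error(cost_config(emergency_cost = 100), "at least")
})

test_that("the cost reconstruction sits at the magnitude of a decade-scale service", {
  # historical-scale totals: ~4654 wasted and ~2988 purchased units over a
  # decade should price in the low millions, same order as a simulated
  # optimized policy on that scale
  c_hist <- 350 * 4654 + 700 * 2988
  expect_identical(floor(log10(c_hist)), 6)
})

test_that("a singleton grid returns that triple with its simulated cost", {
  inst <- random_instance(80, seed = 7)
  gs <- grid_search_policy(inst$demand, inst$forecasts,
                           alpha_range = 9, beta_range = 1, gamma_range = 2)
  expect_identical(unclass(gs$best)[c("alpha", "beta", "gamma")],
                   list(alpha = 9L, beta = 1L, gamma = 2L))
  led <- run_simulation(inst$demand, inst$forecasts, policy_params(9, 1, 2))
  expect_equal(gs$best_cost, glance(led)$cost)
  expect_identical(nrow(gs$surface), 1L)
})

test_that("the grid search equals an independently coded brute-force loop", {
  inst <- random_instance(100, seed = 8)
  gs <- grid_search_policy(inst$demand, inst$forecasts,
                           alpha_range = 0:3, beta_range = 0:3, gamma_range = 0:3)
  best_cost <- Inf
  best <- NULL
  for (a in 0:3) for (b in 0:3) for (g in 0:3) {
    led <- run_simulation(inst$demand, inst$forecasts, policy_params(a, b, g),
                          engine = "r")
    cc <- glance(led)$cost
    if (cc < best_cost) {
      best_cost <- cc
      best <- c(a, b, g)
    }
  }
  expect_equal(gs$best_cost, best_cost)
  expect_identical(c(gs$best$alpha, gs$best$beta, gs$best$gamma), as.integer(best))
  # returned cost is the minimum of the surface, and the surface is complete
  expect_equal(gs$best_cost, min(gs$surface$cost))
  expect_identical(nrow(gs$surface), 64L)
})

test_that("the optimum is reproducible and ties break lexicographically", {
  inst <- random_instance(90, seed = 9)
  g1 <- grid_search_policy(inst$demand, inst$forecasts, 0:5, 0:2, 0:2)
  g2 <- grid_search_policy(inst$demand, inst$forecasts, 0:5, 0:2, 0:2)
  expect_identical(g1$surface, g2$surface)
  expect_identical(unclass(g1$best), unclass(g2$best))
  ties <- g1$surface[g1$surface$cost == g1$best_cost, ]
  first <- ties[order(ties$alpha, ties$beta, ties$gamma), ][1, ]
  expect_identical(c(g1$best$alpha, g1$best$beta, g1$best$gamma),
                   c(first$alpha, first$beta, first$gamma))
})

test_that("costly emergencies push the optimal alpha above zero", {
  chosen <- vapply(1:3, function(s) {
    inst <- random_instance(150, seed = 200 + s)
    # high-variance demand, forecasts deliberately coarse
    inst$demand$demand <- withr::with_seed(s, as.integer(rnbinom(150, mu = 12, size = 2)))
    gs <- grid_search_policy(inst$demand, inst$forecasts,
                             alpha_range = 0:20, beta_range = 0, gamma_range = 0,
                             cost = cost_config(unit_cost = 350, emergency_cost = 3500))
    gs$best$alpha
  }, integer(1))
  expect_true(all(chosen > 0))
})

test_that("empty ranges are rejected", {
  inst <- random_instance(30, seed = 10)
  expect_error(grid_search_policy(inst$demand, inst$forecasts,
                                  alpha_range = integer(0)), "non-empty")
})
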