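make_table <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  tibble::tibble(date = as.Date("2020-01-05") + seq_len(n) - 1L, !!!cols)
}

test_that("zero imputation replaces exactly the missing cells", {
  tbl <- make_table(demand = c(3L, NA, 5L, 2L),
                    census_a = c(NA, 1L, NA, 4L))
  out <- impute_zeros(tbl)
  expect_identical(out$demand, c(3L, 0L, 5L, 2L))
  expect_identical(out$census_a, c(0L, 1L, 0L, 4L))
  # brute-force count of replacements
  expect_identical(sum(is.na(tbl)) - sum(is.na(out)), 3L)
  # a complete table is untouched
  expect_identical(impute_zeros(out), out)
})

test_that("a calendar gap is a hard error", {
  tbl <- make_table(demand = 1:4)
  tbl$date[3] <- tbl$date[3] + 5
  expect_error(impute_zeros(tbl), "gap")
})

test_that("the sparsity filter applies the nonzero-count threshold inclusively", {
  n <- 500
  tbl <- make_table(
    demand = rep(1L, n),
    almost = c(rep(1L, 399), rep(0L, n - 399)),
    enough = c(rep(1L, 400), rep(0L, n - 400)),
    silent = rep(0L, n)
  )
  out <- filter_sparse_features(tbl, min_nonzero = 400)
  expect_named(out, c("date", "demand", "enough"))
  # threshold 0 keeps everything
  expect_identical(filter_sparse_features(tbl, min_nonzero = 0), tbl)
})

test_that("discontinued covariates (long zero runs) are dropped", {
  n <- 800
  tbl <- make_table(
    demand = rep(2L, n),
    gone = c(rep(3L, 100), rep(0L, 400), rep(3L, 300)),
    alive = rep_len(c(0L, 2L), n)
  )
  out <- drop_discontinued_features(tbl, max_zero_run = 365)
  expect_named(out, c("date", "demand", "alive"))
})

test_that("the correlation screen is sign-agnostic and matches the textbook formula", {
  tbl <- make_table(
    demand = c(1L, 2L, 3L, 4L, 5L),
    doubled = c(2L, 4L, 6L, 8L, 10L),
    reversed = c(5L, 4L, 3L, 2L, 1L),
    flat = rep(7L, 5)
  )
  out <- correlation_screen(tbl, r2_threshold = 0.2)
  expect_true(all(c("doubled", "reversed") %in% names(out)))
  expect_false("flat" %in% names(out))

  # seeded noisy features: retention decisions match a hand-rolled Pearson r2
  withr::with_seed(7, {
    n <- 300
    noisy <- make_table(
      demand = as.integer(rpois(n, 10)),
      f1 = as.integer(rpois(n, 5)), f2 = as.integer(rpois(n, 5)),
      f3 = as.integer(rpois(n, 5))
    )
    noisy$f2 <- as.integer(noisy$demand + rpois(n, 3))
  })
  hand_r2 <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  }
  kept <- names(correlation_screen(noisy, 0.2))
  for (nm in c("f1", "f2", "f3")) {
    expect_identical(nm %in% kept,
                     hand_r2(as.numeric(noisy[[nm]]), as.numeric(noisy$demand)) >= 0.2)
  }
})

test_that("PL7 is the mean of the strictly previous window", {
  tbl <- make_table(demand = rep(5L, 12))
  out <- add_rolling_mean(tbl)
  expect_identical(nrow(out), 5L)
  expect_true(all(out$pl7 == 5))

  tbl2 <- make_table(demand = 1:8)
  out2 <- add_rolling_mean(tbl2)
  expect_identical(out2$pl7, 4)  # mean(1..7)

  # brute-force loop oracle on a seeded series
  u <- withr::with_seed(3, as.integer(rpois(40, 9)))
  tbl3 <- make_table(demand = u)
  out3 <- add_rolling_mean(tbl3)
  brute <- vapply(8:40, function(i) mean(u[(i - 7):(i - 1)]), numeric(1))
  expect_equal(out3$pl7, brute)

  expect_error(add_rolling_mean(make_table(demand = 1:7)), "at least")
})

test_that("weekday dummies use Sunday as reference and count the calendar", {
  tbl <- make_table(demand = rep(1L, 14))  # starts on a Sunday
  out <- add_weekday_dummies(tbl)
  dums <- out[grepl("^wd_", names(out))]
  expect_identical(ncol(dums), 6L)
  expect_true(all(rowSums(dums) <= 1))
  expect_true(all(dums[1, ] == 0))                 # Sunday row
  expect_identical(out$wd_sat[7], 1L)              # Saturday row
  expect_true(all(colSums(dums) == 2))             # 14 consecutive days
})

test_that("targets are the forward 2- and 4-day demand sums", {
  tbl <- make_table(demand = rep(3L, 10))
  out <- build_targets(tbl)
  expect_true(all(out$y2 == 6) && all(out$y4 == 12))

  tbl2 <- make_table(demand = 1:6)
  out2 <- build_targets(tbl2)
  expect_identical(out2$y2[1], 5)    # 2 + 3
  expect_identical(out2$y4[1], 14)   # 2 + 3 + 4 + 5

  u <- withr::with_seed(11, as.integer(rpois(30, 8)))
  out3 <- build_targets(make_table(demand = u))
  for (i in seq_len(nrow(out3))) {
    expect_equal(out3$y2[i], sum(u[(i + 1):(i + 2)]))
    expect_equal(out3$y4[i], sum(u[(i + 1):(i + 4)]))
  }
  expect_error(build_targets(make_table(demand = 1:4)), "at least 5")
})

test_that("the assembled design matrix keeps demand, is complete, and y4 >= y2", {
  raw <- make_raw(120, seed = 8)
  raw$census_sig1[c(5, 40)] <- NA
  dm <- build_design_matrix(raw, min_nonzero = 50)
  expect_true("demand" %in% names(dm))
  expect_false(anyNA(dm))
  expect_true(all(dm$y4 >= dm$y2))
  expect_identical(nrow(dm), nrow(raw) - 7L - 4L)
  # cleaning stages are idempotent
  clean <- impute_zeros(raw) |> filter_sparse_features(50) |> correlation_screen()
  expect_identical(correlation_screen(filter_sparse_features(impute_zeros(clean), 50)),
                   clean)
})
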