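# Rolling-origin-recalibration evaluation.
#
# A forecaster is a function(data, train_idx, test_idx, target, seed) that
# fits on the training rows and returns list(predictions = <numeric over
# test rows>, model = <fitted object or NULL>). Factories below wrap the
# package's models into this contract.

#' Forecaster factories for the rolling-origin protocol
#'
#' * `lasso_forecaster()` — the L1-penalized linear model,
#'   [fit_demand_lasso()].
#' * `lstm_forecaster()` — the LSTM network, [fit_demand_lstm()]; test-row
#'   sequences use the rows preceding each test day (available history at
#'   prediction time).
#' * `mean_forecaster()` — predicts the training mean of the target; a
#'   protocol-audit stub.
#' * `pl7_forecaster()` — the naive baseline scaling the trailing 7-day
#'   demand mean: 2 x PL7 for the 2-day target, 4 x PL7 for the 4-day.
#'
#' @param cv_folds Blocked CV folds for the LASSO penalty search.
#' @param config An [lstm_config()] for the LSTM.
#' @name forecasters
#' @return A forecaster function usable with [rolling_origin_forecast()].
NULL

#' @rdname forecasters
#' @export
lasso_forecaster <- function(cv_folds = 5) {
  function(data, train_idx, test_idx, target, seed) {
    model <- fit_demand_lasso(data[train_idx, , drop = FALSE], target,
                              cv_folds = cv_folds)
    list(predictions = predict(model, data[test_idx, , drop = FALSE]),
         model = model, kind = "lasso")
  }
}

#' @rdname forecasters
#' @export
lstm_forecaster <- function(config = lstm_config()) {
  function(data, train_idx, test_idx, target, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    model <- fit_demand_lstm(data[train_idx, , drop = FALSE], target, cfg)
    list(predictions = predict(model, data, rows = test_idx),
         model = model, kind = "lstm")
  }
}

#' @rdname forecasters
#' @export
mean_forecaster <- function() {
  function(data, train_idx, test_idx, target, seed) {
    mu <- mean(data[[target]][train_idx])
    list(predictions = rep(mu, length(test_idx)), model = NULL, kind = "mean")
  }
}

#' @rdname forecasters
#' @export
pl7_forecaster <- function() {
  function(data, train_idx, test_idx, target, seed) {
    mult <- if (target == "y2") 2 else 4
    list(predictions = mult * data$pl7[test_idx], model = NULL, kind = "pl7")
  }
}

#' Rolling-origin-recalibration forecasts
#'
#' Evaluates a forecaster under the expanding-window protocol: iteration j
#' trains on rows 1 .. `initial_train` + j x `step` and predicts the next
#' `step` rows; all hyperparameters are recalibrated at every iteration.
#' Concatenated predictions cover every evaluation row (row
#' `initial_train` + 1 onward) exactly once and every training span ends
#' strictly before its evaluation rows, so there is no look-ahead. Both
#' the 2- and 4-day-ahead models are maintained.
#'
#' Unless `screen = "none"`, the correlation screen on the raw covariates
#' is recomputed on each training span (PL7 and weekday indicators are
#' always retained), so no test-day information leaks into feature
#' selection. `screen = "global"` screens once on the full table,
#' reproducing a single global screen.
#'
#' @param data A design-matrix tibble from [build_design_matrix()].
#' @param forecaster A forecaster function or factory output, see
#'   [forecasters].
#' @param initial_train Rows in the first training span (default 500).
#' @param step Retraining interval in days (default 28).
#' @param screen `"per_iteration"` (default), `"global"` or `"none"`.
#' @param screen_r2 r-squared retention threshold for the screen.
#' @param seed Integer seed; each iteration gets a derived sub-seed.
#' @return A tibble (`date`, `p2`, `p4`, `model`) over the evaluation
#'   rows, with the per-iteration fitted models in
#'   `attr(, "models")$y2` / `$y4` and the iteration bounds in
#'   `attr(, "iterations")`.
#' @export
rolling_origin_forecast <- function(data, forecaster, initial_train = 500,
                                    step = 28, screen = c("per_iteration", "global", "none"),
                                    screen_r2 = 0.2, seed = 1L) {
  screen <- match.arg(screen)
  n <- nrow(data)
  if (n <= initial_train + 1) abort("`data` must be longer than `initial_train` + 1 rows.")
  always_keep <- c("pl7", grep("^wd_", names(data), value = TRUE))
  screenable <- setdiff(feature_cols(data), always_keep)

  if (screen == "global") {
    r2 <- feature_r2(data, screenable)
    global_drop <- names(r2)[r2 < screen_r2]
  }

  starts <- seq(initial_train, n - 1, by = step)
  p2 <- rep(NA_real_, n)
  p4 <- rep(NA_real_, n)
  models <- list(y2 = vector("list", length(starts)),
                 y4 = vector("list", length(starts)))
  iterations <- vector("list", length(starts))
  kind <- "forecast"

  for (j in seq_along(starts)) {
    train_idx <- seq_len(starts[j])
    test_idx <- (starts[j] + 1):min(starts[j] + step, n)
    drop_cols <- switch(screen,
      per_iteration = {
        r2 <- feature_r2(data[train_idx, , drop = FALSE], screenable)
        names(r2)[r2 < screen_r2]
      },
      global = global_drop,
      none = character()
    )
    dat_j <- data[setdiff(names(data), drop_cols)]
    for (target in c("y2", "y4")) {
      res <- forecaster(dat_j, train_idx, test_idx, target,
                        seed = derive_seed(seed + j, "rolling"))
      pred <- pmax(0, as.numeric(res$predictions))
      if (length(pred) != length(test_idx)) {
        abort("forecaster returned the wrong number of predictions.")
      }
      if (target == "y2") p2[test_idx] <- pred else p4[test_idx] <- pred
      models[[target]][[j]] <- res$model
      kind <- res$kind %||% kind
    }
    iterations[[j]] <- tibble::tibble(
      iteration = j, train_end = starts[j],
      test_start = test_idx[1], test_end = test_idx[length(test_idx)]
    )
  }

  eval_idx <- (initial_train + 1):n
  out <- tibble::tibble(
    date = data$date[eval_idx],
    p2 = p2[eval_idx], p4 = p4[eval_idx],
    model = kind
  )
  attr(out, "models") <- models
  attr(out, "iterations") <- dplyr::bind_rows(iterations)
  out
}
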