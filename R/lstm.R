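# A compact LSTM regression network for daily-demand forecasting.
#
# Architecture: LSTM layer (returning the full hidden-state sequence, with
# input dropout and L1-L2 kernel regularization) -> flatten -> elementwise
# activation (ReLU or linear) -> dense layer with a single linear neuron.
# Trained with minibatch Adam on mean squared error, with early stopping on
# a validation set. Everything is deterministic under a seed.

# --- hyperparameter search space -------------------------------------------

lstm_space <- function() {
  list(
    batch_size = c(50, 100),
    units = c(10, 50),
    dropout = seq(0, 0.5, by = 0.05),
    l1 = 10^c(-9, -7, -5, -3),
    l2 = 10^c(-9, -7, -5, -3),
    activation = c("relu", "linear")
  )
}

#' Configuration for the LSTM demand model
#'
#' Bundles the randomized-search budget and training controls for
#' [fit_demand_lstm()]. Hyperparameters (batch size, LSTM units, dropout
#' rate, L1/L2 regularization, flatten activation) are drawn uniformly
#' from a fixed search space:
#' batch size {50, 100}; units {10, 50}; dropout 0 to 0.5 in steps of
#' 0.05; L1 and L2 each in {1e-9, 1e-7, 1e-5, 1e-3}; activation
#' {ReLU, linear}.
#'
#' @param lookback_days Length of the input sequence fed to the LSTM, in
#'   days (default 7, one weekly cycle).
#' @param n_random_draws Number of random hyperparameter draws evaluated
#'   by blocked CV (default 20).
#' @param epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience on validation MSE (default 20).
#' @param cv_folds Blocked CV folds for hyperparameter selection.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling draws, initialization, dropout and
#'   shuffling.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(lookback_days = 7, n_random_draws = 20, epochs = 200,
                        patience = 20, cv_folds = 5, learning_rate = 1e-3,
                        seed = 1L) {
  stopifnot(lookback_days >= 1, n_random_draws >= 1, epochs >= 1, cv_folds >= 2)
  structure(
    list(lookback_days = as.integer(lookback_days),
         n_random_draws = as.integer(n_random_draws),
         epochs = as.integer(epochs), patience = as.integer(patience),
         cv_folds = as.integer(cv_folds), learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "lstm_config"
  )
}

check_in_space <- function(value, name) {
  space <- lstm_space()[[name]]
  ok <- if (is.character(space)) value %in% space else
    any(abs(space - value) < 1e-12)
  if (!ok) {
    abort(sprintf("`%s` = %s is outside the search space {%s}.",
                  name, format(value), paste(format(space), collapse = ", ")))
  }
  invisible(value)
}

draw_hyper <- function() {
  sp <- lstm_space()
  list(
    batch_size = sample(sp$batch_size, 1),
    units = sample(sp$units, 1),
    dropout = sample(sp$dropout, 1),
    l1 = sample(sp$l1, 1),
    l2 = sample(sp$l2, 1),
    activation = sample(sp$activation, 1)
  )
}

# --- network construction ---------------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained LSTM demand network
#'
#' Initializes the network weights (Glorot-uniform kernels, zero biases
#' with the forget-gate bias set to 1) for the given hyperparameters.
#' Every hyperparameter must come from the fixed search space, see
#' [lstm_config()].
#'
#' @param n_features Number of input features per day.
#' @param units LSTM units (10 or 50).
#' @param dropout Input dropout rate.
#' @param l1,l2 Kernel regularization weights.
#' @param activation Activation applied after flattening: `"relu"` or
#'   `"linear"`.
#' @param batch_size Minibatch size used when the network is trained.
#' @param lookback Input sequence length in days.
#' @param seed Seed for weight initialization.
#' @return An object of class `demand_lstm` (untrained).
#' @export
build_lstm <- function(n_features, units = 10, dropout = 0, l1 = 1e-9,
                       l2 = 1e-9, activation = "relu", batch_size = 50,
                       lookback = 7, seed = 1L) {
  check_in_space(units, "units")
  check_in_space(dropout, "dropout")
  check_in_space(l1, "l1")
  check_in_space(l2, "l2")
  check_in_space(activation, "activation")
  check_in_space(batch_size, "batch_size")
  H <- as.integer(units)
  Fn <- as.integer(n_features)
  Tn <- as.integer(lookback)
  weights <- withr::with_seed(as.integer(seed), {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    list(
      W = glorot(Fn, 4 * H), U = glorot(H, 4 * H), b = b,
      Wd = glorot(Tn * H, 1), bd = 0
    )
  })
  structure(
    list(kind = "lstm", weights = weights,
         hyper = list(units = H, dropout = dropout, l1 = l1, l2 = l2,
                      activation = activation, batch_size = as.integer(batch_size)),
         n_features = Fn, lookback = Tn, trained = FALSE,
         features = NULL, target = NULL,
         norm = NULL, seed = as.integer(seed)),
    class = "demand_lstm"
  )
}

#' Number of trainable parameters of an LSTM demand network
#'
#' @param model A `demand_lstm`.
#' @return Integer parameter count:
#'   `4 * (units * (n_features + units) + units)` for the LSTM layer plus
#'   `lookback * units + 1` for the dense head.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "demand_lstm"))
  w <- model$weights
  length(w$W) + length(w$U) + length(w$b) + length(w$Wd) + 1L
}

# Regularization penalty of the current kernel weights.
lstm_reg_loss <- function(model) {
  w <- model$weights$W
  model$hyper$l1 * sum(abs(w)) + model$hyper$l2 * sum(w^2)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass. X: array (B, T, F), already standardized and (in training)
# dropout-masked. Returns yhat and, if `cache`, the per-step activations.
lstm_forward <- function(weights, X, activation, cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- length(weights$b) / 4
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  Hcat <- matrix(0, B, Tn * H)
  steps <- if (cache) vector("list", Tn) else NULL
  bmat <- matrix(weights$b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, dim(X)[3])
    Z <- xt %*% weights$W + h %*% weights$U + bmat
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cs + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (cache) {
      steps[[t]] <- list(x = xt, h_prev = h, c_prev = cs, i = i, f = f,
                         g = g, o = o, c = c_new, tc = tc)
    }
    h <- h_new; cs <- c_new
    Hcat[, ((t - 1) * H + 1):(t * H)] <- h
  }
  act <- if (activation == "relu") pmax(Hcat, 0) else Hcat
  yhat <- drop(act %*% weights$Wd) + weights$bd
  list(yhat = yhat, Hcat = Hcat, act = act, steps = steps)
}

# Backward pass (gradients of mean squared error + kernel penalty).
lstm_backward <- function(weights, fwd, X, y, activation, l1, l2) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; Fn <- dim(X)[3]
  H <- length(weights$b) / 4
  dy <- matrix(2 * (fwd$yhat - y) / B, B, 1)
  dWd <- crossprod(fwd$act, dy)
  dbd <- sum(dy)
  da <- dy %*% t(weights$Wd)
  dHcat <- if (activation == "relu") da * (fwd$Hcat > 0) else da
  dW <- matrix(0, Fn, 4 * H); dU <- matrix(0, H, 4 * H); db <- rep(0, 4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in Tn:1) {
    s <- fwd$steps[[t]]
    dh <- dHcat[, ((t - 1) * H + 1):(t * H), drop = FALSE] + dh_next
    do_ <- dh * s$tc
    dc <- dh * s$o * (1 - s$tc^2) + dc_next
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dZ <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do_ * s$o * (1 - s$o))
    dW <- dW + crossprod(s$x, dZ)
    dU <- dU + crossprod(s$h_prev, dZ)
    db <- db + colSums(dZ)
    dh_next <- dZ %*% t(weights$U)
    dc_next <- dc * s$f
  }
  dW <- dW + l1 * sign(weights$W) + 2 * l2 * weights$W
  list(W = dW, U = dU, b = db, Wd = dWd, bd = dbd)
}

adam_init <- function(weights) {
  lapply(weights, function(w) list(m = w * 0, v = w * 0))
}

adam_update <- function(weights, grads, state, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^step)
    vhat <- state[[nm]]$v / (1 - beta2^step)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# Train weights in place; X/y standardized, Xval/yval for early stopping.
lstm_train <- function(model, X, y, Xval, yval, epochs, patience, lr, seed) {
  weights <- model$weights
  hp <- model$hyper
  n <- dim(X)[1]
  state <- adam_init(weights)
  step <- 0L
  best <- list(weights = weights, val = Inf, wait = 0L)
  diverged <- FALSE
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + hp$batch_size - 1, n)]
        Xb <- X[idx, , , drop = FALSE]
        if (hp$dropout > 0) {
          mask <- matrix(
            (runif(length(idx) * dim(X)[3]) >= hp$dropout) / (1 - hp$dropout),
            length(idx), dim(X)[3]
          )
          for (t in seq_len(dim(X)[2])) Xb[, t, ] <- Xb[, t, ] * mask
        }
        fwd <- lstm_forward(weights, Xb, hp$activation, cache = TRUE)
        if (!all(is.finite(fwd$yhat))) {
          diverged <- TRUE
          break
        }
        gr <- lstm_backward(weights, fwd, Xb, y[idx], hp$activation, hp$l1, hp$l2)
        step <- step + 1L
        upd <- adam_update(weights, gr, state, step, lr)
        weights <- upd$weights
        state <- upd$state
      }
      if (diverged) break
      val_pred <- lstm_forward(weights, Xval, hp$activation)$yhat
      val_mse <- mean((val_pred - yval)^2)
      if (!is.finite(val_mse)) {
        diverged <- TRUE
        break
      }
      if (val_mse < best$val - 1e-9) {
        best$weights <- weights
        best$val <- val_mse
        best$wait <- 0L
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= patience) break
      }
    }
  })
  list(weights = best$weights, val = best$val, diverged = diverged)
}

# Build the (n_usable, T, F) sequence array for anchor rows `rows` of the
# standardized feature matrix; early anchors are padded with the first row.
lstm_sequences <- function(xmat, rows, lookback) {
  n <- length(rows)
  X <- array(0, dim = c(n, lookback, ncol(xmat)))
  for (j in seq_len(n)) {
    idx <- (rows[j] - lookback + 1):rows[j]
    idx[idx < 1] <- 1
    X[j, , ] <- xmat[idx, , drop = FALSE]
  }
  X
}

#' Fit the LSTM demand model with randomized hyperparameter search
#'
#' Draws `n_random_draws` hyperparameter combinations uniformly from the
#' fixed search space, scores each by blocked cross-validated MSE, refits
#' the best combination on the full training span (with a temporal
#' validation tail for early stopping), and returns the fitted network.
#' Draws whose training diverges are discarded with a warning. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param train A design-matrix tibble (predictors plus the target).
#' @param target `"y2"` or `"y4"`.
#' @param config An [lstm_config()].
#' @return A trained `demand_lstm`.
#' @export
fit_demand_lstm <- function(train, target = c("y2", "y4"),
                            config = lstm_config()) {
  target <- match.arg(target)
  stopifnot(inherits(config, "lstm_config"))
  preds <- predictor_cols(train)
  y_raw <- as.numeric(train[[target]])
  xmat <- as.matrix(train[preds])
  storage.mode(xmat) <- "double"
  Tn <- config$lookback_days
  n <- nrow(xmat)
  if (n < Tn + config$cv_folds) abort("training span too short for the lookback window.")

  x_mu <- colMeans(xmat)
  x_sd <- apply(xmat, 2, sd)
  x_sd[x_sd == 0] <- 1
  xs <- sweep(sweep(xmat, 2, x_mu), 2, x_sd, "/")
  y_mu <- mean(y_raw)
  y_sd <- sd(y_raw)
  if (y_sd == 0) y_sd <- 1
  ys <- (y_raw - y_mu) / y_sd

  anchors <- Tn:n  # rows with a full lookback history inside the span
  Xall <- lstm_sequences(xs, anchors, Tn)
  yall <- ys[anchors]
  m <- length(anchors)

  draws <- withr::with_seed(derive_seed(config$seed, "lstm"), {
    lapply(seq_len(config$n_random_draws), function(k) draw_hyper())
  })

  score_draw <- function(hp, draw_seed) {
    folds <- blocked_cv_splits(m, config$cv_folds)
    mses <- vapply(seq_along(folds), function(j) {
      tr <- folds[[j]]$train; va <- folds[[j]]$validation
      net <- build_lstm(length(preds), units = hp$units, dropout = hp$dropout,
                        l1 = hp$l1, l2 = hp$l2, activation = hp$activation,
                        batch_size = hp$batch_size, lookback = Tn,
                        seed = draw_seed + j)
      fit <- lstm_train(net, Xall[tr, , , drop = FALSE], yall[tr],
                        Xall[va, , , drop = FALSE], yall[va],
                        config$epochs, config$patience, config$learning_rate,
                        seed = draw_seed + 100 + j)
      if (isTRUE(fit$diverged)) return(Inf)
      fit$val
    }, numeric(1))
    mean(mses)
  }

  scores <- vapply(seq_along(draws), function(k) {
    s <- score_draw(draws[[k]], derive_seed(config$seed + k, "lstm"))
    if (!is.finite(s)) warn(sprintf("hyperparameter draw %d diverged; discarded.", k))
    s
  }, numeric(1))
  if (all(!is.finite(scores))) abort("all hyperparameter draws diverged.")
  best_hp <- draws[[which.min(scores)]]

  # Final refit on the full span, early-stopping on the temporal tail.
  n_val <- max(1L, floor(0.1 * m))
  tr <- seq_len(m - n_val)
  va <- (m - n_val + 1):m
  net <- build_lstm(length(preds), units = best_hp$units,
                    dropout = best_hp$dropout, l1 = best_hp$l1,
                    l2 = best_hp$l2, activation = best_hp$activation,
                    batch_size = best_hp$batch_size, lookback = Tn,
                    seed = derive_seed(config$seed + 5000L, "lstm"))
  fit <- lstm_train(net, Xall[tr, , , drop = FALSE], yall[tr],
                    Xall[va, , , drop = FALSE], yall[va],
                    config$epochs, config$patience, config$learning_rate,
                    seed = derive_seed(config$seed + 6000L, "lstm"))

  net$weights <- fit$weights
  net$trained <- TRUE
  net$features <- preds
  net$target <- target
  net$norm <- list(x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd)
  net$cv_mse <- min(scores)
  net$n_train <- n
  net
}

#' @export
print.demand_lstm <- function(x, ...) {
  hp <- x$hyper
  cat(sprintf(
    "<demand_lstm> %s; units %d, dropout %.2f, l1 %.0e, l2 %.0e, %s, batch %d, lookback %d, %d params\n",
    if (isTRUE(x$trained)) paste("trained on", x$target) else "untrained",
    hp$units, hp$dropout, hp$l1, hp$l2, hp$activation, hp$batch_size,
    x$lookback, n_parameters(x)
  ))
  invisible(x)
}

#' Predict from a fitted LSTM demand model
#'
#' Builds a lookback sequence ending at each requested row of `newdata`
#' (using the preceding rows of the same table as history) and runs the
#' forward pass. Predictions are de-standardized and clamped at zero.
#'
#' @param object A trained `demand_lstm`.
#' @param newdata A tibble containing the model's feature columns; rows
#'   must be consecutive days.
#' @param rows Integer anchor rows to predict (default: all rows).
#' @param ... Unused.
#' @return Numeric predictions, one per anchor row.
#' @export
predict.demand_lstm <- function(object, newdata, rows = NULL, ...) {
  if (!isTRUE(object$trained)) abort("the network has not been trained.")
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    abort(paste0("`newdata` lacks feature columns: ", paste(missing, collapse = ", ")))
  }
  if (is.null(rows)) rows <- seq_len(nrow(newdata))
  xmat <- as.matrix(newdata[object$features])
  storage.mode(xmat) <- "double"
  xs <- sweep(sweep(xmat, 2, object$norm$x_mu), 2, object$norm$x_sd, "/")
  X <- lstm_sequences(xs, rows, object$lookback)
  yhat <- lstm_forward(object$weights, X, object$hyper$activation)$yhat
  pmax(0, yhat * object$norm$y_sd + object$norm$y_mu)
}

#' @export
glance.demand_lstm <- function(x, ...) {
  tibble::tibble(
    target = x$target %||% NA_character_,
    units = x$hyper$units, dropout = x$hyper$dropout,
    l1 = x$hyper$l1, l2 = x$hyper$l2,
    activation = x$hyper$activation, batch_size = x$hyper$batch_size,
    lookback = x$lookback, n_parameters = n_parameters(x),
    trained = isTRUE(x$trained)
  )
}
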