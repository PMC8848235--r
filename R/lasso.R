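#' Fit the L1-penalized demand model
#'
#' Fits a LASSO linear regression of a forecast target on all predictor
#' columns of a design matrix (covariates, PL7, weekday indicators). The
#' penalty weight is chosen by k-fold *blocked* cross-validation
#' minimizing mean squared error; features are standardized internally and
#' coefficients are reported on the original scale. Predictions are
#' clamped at zero (demand cannot be negative).
#'
#' @param train A design-matrix tibble from [build_design_matrix()], or
#'   any tibble with predictor columns plus the target.
#' @param target `"y2"` (2-day-ahead demand sum) or `"y4"` (4-day-ahead).
#' @param cv_folds Number of blocked CV folds (default 5).
#' @param lambda Optional numeric grid of penalty weights; by default a
#'   100-value log-spaced grid is derived from the data.
#' @return A fitted model of class `demand_lasso`.
#' @export
fit_demand_lasso <- function(train, target = c("y2", "y4"), cv_folds = 5,
                             lambda = NULL) {
  target <- match.arg(target)
  if (!target %in% names(train)) abort(sprintf("`train` lacks target column `%s`.", target))
  preds <- predictor_cols(train)
  if (length(preds) < 1L) abort("`train` has no predictor columns.")
  y <- as.numeric(train[[target]])
  x <- as.matrix(train[preds])
  storage.mode(x) <- "double"

  if (sd(y) == 0) {
    warn("constant target; returning an intercept-only model.")
    fit <- structure(
      list(kind = "lasso", target = target, intercept = y[1],
           coefficients = stats::setNames(rep(0, length(preds)), preds),
           lambda = Inf, n_train = nrow(train), features = preds),
      class = "demand_lasso"
    )
    return(fit)
  }

  foldid <- blocked_foldid(nrow(train), cv_folds)
  cv <- glmnet::cv.glmnet(
    x, y, family = "gaussian", alpha = 1, foldid = foldid,
    lambda = lambda, standardize = TRUE, type.measure = "mse"
  )
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  structure(
    list(kind = "lasso", target = target, intercept = beta[1],
         coefficients = stats::setNames(beta[-1], preds),
         lambda = cv$lambda.min, n_train = nrow(train), features = preds,
         glmnet_cv = cv),
    class = "demand_lasso"
  )
}

#' @export
print.demand_lasso <- function(x, ...) {
  cat(sprintf("<demand_lasso> target %s, lambda %.5g, %d/%d nonzero, n = %d\n",
              x$target, x$lambda, sum(x$coefficients != 0),
              length(x$coefficients), x$n_train))
  invisible(x)
}

#' Predict from a fitted LASSO demand model
#'
#' @param object A `demand_lasso`.
#' @param newdata A tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric predictions clamped at zero.
#' @export
predict.demand_lasso <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    abort(paste0("`newdata` lacks feature columns: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(newdata[object$features])
  storage.mode(x) <- "double"
  pmax(0, drop(x %*% object$coefficients) + object$intercept)
}

#' @export
tidy.demand_lasso <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.demand_lasso <- function(x, ...) {
  tibble::tibble(
    target = x$target, lambda = x$lambda,
    n_nonzero = sum(x$coefficients != 0),
    n_features = length(x$coefficients), n_train = x$n_train
  )
}

#' Summarize coefficients across model iterations
#'
#' Aggregates the fitted LASSO models from the rolling-origin protocol
#' into per-feature mean and SD of the coefficient across iterations
#' (features excluded by the per-iteration screen count as zero), plus the
#' mean and SD of the nonzero-coefficient count.
#'
#' @param models A list of `demand_lasso` objects.
#' @return A tibble (`term`, `mean_weight`, `sd_weight`,
#'   `prop_nonzero`) sorted by absolute mean weight, of class
#'   `coef_report`; use [glance()] for the nonzero-count summary.
#' @export
coefficient_report <- function(models) {
  if (length(models) < 1L) abort("need at least one fitted model.")
  kinds <- vapply(models, function(m) m$kind %||% class(m)[1], "")
  if (!all(kinds == "lasso") || !all(vapply(models, inherits, TRUE, "demand_lasso"))) {
    abort("`coefficient_report()` expects a list of LASSO models only.")
  }
  terms <- sort(unique(unlist(lapply(models, function(m) names(m$coefficients)))))
  W <- vapply(models, function(m) {
    w <- stats::setNames(rep(0, length(terms)), terms)
    w[names(m$coefficients)] <- m$coefficients
    w
  }, numeric(length(terms)))
  W <- matrix(W, nrow = length(terms), dimnames = list(terms, NULL))
  nz <- colSums(W != 0)
  out <- tibble::tibble(
    term = terms,
    mean_weight = unname(rowMeans(W)),
    sd_weight = unname(apply(W, 1, function(r) if (length(models) > 1) sd(r) else 0)),
    prop_nonzero = unname(rowMeans(W != 0))
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$mean_weight)))
  attr(out, "nonzero_mean") <- mean(nz)
  attr(out, "nonzero_sd") <- if (length(models) > 1) sd(nz) else 0
  attr(out, "n_models") <- length(models)
  class(out) <- c("coef_report", class(out))
  out
}

#' @export
glance.coef_report <- function(x, ...) {
  tibble::tibble(
    n_models = attr(x, "n_models"),
    nonzero_mean = attr(x, "nonzero_mean"),
    nonzero_sd = attr(x, "nonzero_sd")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
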