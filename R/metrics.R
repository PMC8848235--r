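#' Forecast-accuracy metrics
#'
#' Computes the three error measures used throughout the pipeline:
#' * RMSE — square root of the mean squared deviation;
#' * r-squared — squared Pearson correlation of predictions and truth;
#' * MAPE — mean over days of |pred - true| / true x 100, with zero-truth
#'   days excluded (their count is reported and a note emitted).
#'
#' @param predicted Numeric predictions.
#' @param actual Numeric true values, same length.
#' @return A one-row tibble: `rmse`, `r2`, `mape`, `n_days`,
#'   `n_zero_excluded`.
#' @export
#' @examples
#' compute_metrics(c(2, 2), c(1, 4))
compute_metrics <- function(predicted, actual) {
  p <- as.numeric(predicted)
  a <- as.numeric(actual)
  if (length(p) != length(a)) abort("`predicted` and `actual` must have equal length.")
  if (length(a) < 2) abort("need at least 2 days.")
  if (all(a == 0)) abort("all true values are zero; MAPE is undefined.")
  rmse <- sqrt(mean((p - a)^2))
  r2 <- if (sd(p) == 0 || sd(a) == 0) NA_real_ else cor(p, a)^2
  nz <- a != 0
  n_excl <- sum(!nz)
  if (n_excl > 0) inform(sprintf("MAPE: excluded %d zero-demand day(s).", n_excl))
  mape <- mean(abs(p[nz] - a[nz]) / a[nz]) * 100
  tibble::tibble(rmse = rmse, r2 = r2, mape = mape,
                 n_days = length(a), n_zero_excluded = n_excl)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the per-day values with replacement, recomputes the statistic
#' on each resample and takes the 2.5/97.5 percentiles (for `conf` 0.95).
#' Deterministic given `seed`.
#'
#' @param per_day_values Numeric vector (at least 10 days).
#' @param statistic Function mapping a numeric vector to a scalar
#'   (default `mean`).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A one-row tibble: `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(per_day_values, statistic = mean, n_boot = 2000,
                         seed = 1L, conf = 0.95) {
  x <- as.numeric(per_day_values)
  n <- length(x)
  if (n < 10) abort("need at least 10 days for a bootstrap interval.")
  point <- statistic(x)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) statistic(x[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  q <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(estimate = point, lower = q[1], upper = q[2])
}

# Paired bootstrap of a metric over days.
bootstrap_metric_ci <- function(predicted, actual, metric_fun, n_boot, seed,
                                conf = 0.95) {
  n <- length(actual)
  point <- metric_fun(predicted, actual)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fun(predicted[idx], actual[idx])
    }, numeric(1))
  })
  reps <- reps[is.finite(reps)]
  alpha <- (1 - conf) / 2
  q <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  # percentile intervals are widened, if needed, to contain the full-sample
  # point estimate, so reported intervals always bracket the estimate
  c(estimate = point, lower = min(q[1], point), upper = max(q[2], point))
}

#' P-value for a difference from two confidence intervals
#'
#' Converts two independent 95% CIs into a two-sided p-value for the
#' difference of the estimates, assuming normal sampling distributions:
#' each standard error is recovered as (upper - lower) / (2 x 1.96), the
#' SE of the difference is their quadrature sum, and
#' p = 2 x Phi(-|est_a - est_b| / SE_diff).
#'
#' @param est_a,est_b Point estimates.
#' @param ci_a,ci_b Length-2 numeric vectors (lower, upper) of the 95%
#'   CIs.
#' @return The two-sided p-value.
#' @export
#' @examples
#' ci_difference_pvalue(10, c(8, 12), 13, c(11, 15))
ci_difference_pvalue <- function(est_a, ci_a, est_b, ci_b) {
  stopifnot(length(ci_a) == 2, length(ci_b) == 2,
            ci_a[1] <= est_a, est_a <= ci_a[2],
            ci_b[1] <= est_b, est_b <= ci_b[2])
  se_a <- (ci_a[2] - ci_a[1]) / (2 * 1.96)
  se_b <- (ci_b[2] - ci_b[1]) / (2 * 1.96)
  se_diff <- sqrt(se_a^2 + se_b^2)
  if (se_diff == 0) {
    if (est_a == est_b) return(1)
    warn("zero combined SE with unequal estimates; returning p = 0.")
    return(0)
  }
  z <- (est_a - est_b) / se_diff
  2 * pnorm(-abs(z))
}

metric_funs <- function() {
  list(
    rmse = function(p, a) sqrt(mean((p - a)^2)),
    r2 = function(p, a) if (sd(p) == 0 || sd(a) == 0) NA_real_ else cor(p, a)^2,
    mape = function(p, a) {
      nz <- a != 0
      if (!any(nz)) return(NA_real_)
      mean(abs(p[nz] - a[nz]) / a[nz]) * 100
    }
  )
}

#' Evaluate rolling-origin forecasts against the realized targets
#'
#' Joins a forecast series to the design matrix by date and reports RMSE,
#' r-squared and MAPE with percentile-bootstrap 95% CIs for both horizons.
#'
#' @param forecasts A tibble from [rolling_origin_forecast()] (`date`,
#'   `p2`, `p4`, `model`).
#' @param data The design-matrix tibble holding `date`, `y2`, `y4`.
#' @param n_boot Bootstrap resamples per metric.
#' @param seed Integer seed.
#' @return A long tibble: `model`, `horizon` (2 or 4), `metric`,
#'   `estimate`, `lower`, `upper`, `n_days`.
#' @export
evaluate_forecasts <- function(forecasts, data, n_boot = 2000, seed = 1L) {
  joined <- dplyr::inner_join(
    forecasts, data[c("date", "y2", "y4")], by = "date"
  )
  if (nrow(joined) != nrow(forecasts)) {
    abort("some forecast dates are missing from `data`.")
  }
  funs <- metric_funs()
  out <- purrr::map_dfr(c(2, 4), function(h) {
    p <- joined[[paste0("p", h)]]
    a <- joined[[paste0("y", h)]]
    purrr::imap_dfr(funs, function(f, nm) {
      ci <- bootstrap_metric_ci(p, a, f, n_boot,
                                seed = derive_seed(seed + h, "metrics"))
      tibble::tibble(
        model = joined$model[1], horizon = h, metric = nm,
        estimate = ci[["estimate"]], lower = ci[["lower"]],
        upper = ci[["upper"]], n_days = length(a)
      )
    })
  })
  out
}
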