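#' Replace missing counts with zeros
#'
#' Missing cells in count columns represent days on which an event simply
#' did not occur in the source system, so they are imputed as zero. Dates
#' are never touched; a gap in the calendar is a hard error because every
#' downstream step assumes contiguous days.
#'
#' @param raw A daily tibble with a `date` column and count columns.
#' @return The same tibble with every missing count replaced by 0.
#' @export
impute_zeros <- function(raw) {
  if (!"date" %in% names(raw)) abort("`raw` must have a `date` column.")
  if (anyNA(raw$date)) abort("`date` must not contain missing values.")
  check_contiguous_dates(raw$date, "`raw`")
  dplyr::mutate(raw, dplyr::across(-"date", ~ tidyr::replace_na(.x, 0L)))
}

#' Drop sparsely observed covariate columns
#'
#' Removes every feature column with fewer than `min_nonzero` nonzero
#' entries; such covariates were typically not recorded over most of the
#' period and carry no usable signal. `demand` is never dropped.
#'
#' @param table An imputed daily tibble.
#' @param min_nonzero Minimum number of nonzero entries a feature column
#'   must have to be kept (default 400).
#' @return The tibble with sparse feature columns removed.
#' @export
filter_sparse_features <- function(table, min_nonzero = 400) {
  keep <- vapply(names(table), function(nm) {
    if (nm %in% reserved_cols()) return(TRUE)
    sum(table[[nm]] != 0) >= min_nonzero
  }, logical(1))
  table[keep]
}

#' Drop covariates that did not exist continuously
#'
#' Operationalizes department turnover: any feature column containing a run
#' of at least `max_zero_run` consecutive zeros is treated as a covariate
#' whose source did not exist for part of the period and is removed.
#'
#' @param table An imputed daily tibble.
#' @param max_zero_run Length of the disqualifying all-zero run (default
#'   365 days).
#' @return The tibble with discontinued feature columns removed.
#' @export
drop_discontinued_features <- function(table, max_zero_run = 365) {
  longest_zero_run <- function(x) {
    r <- rle(x == 0)
    z <- r$lengths[r$values]
    if (length(z)) max(z) else 0L
  }
  keep <- vapply(names(table), function(nm) {
    if (nm %in% reserved_cols()) return(TRUE)
    longest_zero_run(table[[nm]]) < max_zero_run
  }, logical(1))
  table[keep]
}

# Squared Pearson correlation of each feature column with demand; a
# zero-variance column scores 0 rather than erroring.
feature_r2 <- function(table, cols = feature_cols(table)) {
  u <- as.numeric(table$demand)
  vapply(cols, function(nm) {
    x <- as.numeric(table[[nm]])
    if (sd(x) == 0 || sd(u) == 0) return(0)
    cor(x, u)^2
  }, numeric(1))
}

#' Screen covariates by squared correlation with demand
#'
#' Keeps feature columns whose squared Pearson correlation with the
#' `demand` column is at least `r2_threshold`. The screen is sign-agnostic
#' (strong negative correlates are kept) and a constant column is treated
#' as r-squared 0. `date` and `demand` always survive.
#'
#' @param table An imputed, sparsity-filtered daily tibble.
#' @param r2_threshold Retention threshold on r-squared (default 0.2).
#' @return The screened tibble.
#' @export
correlation_screen <- function(table, r2_threshold = 0.2) {
  if (!"demand" %in% names(table)) abort("`table` must have a `demand` column.")
  r2 <- feature_r2(table)
  drop <- names(r2)[r2 < r2_threshold]
  table[setdiff(names(table), drop)]
}

#' Add the trailing 7-day mean of demand (PL7)
#'
#' PL7 on day i is the mean demand over the `window` strictly previous
#' days (i - window .. i - 1); the current day is excluded so the predictor
#' is available before the day's outcome. The first `window` rows, for
#' which PL7 is undefined, are dropped.
#'
#' @param table A daily tibble with `demand`.
#' @param window Trailing window length in days (default 7).
#' @return The tibble with a `pl7` column, `window` rows shorter.
#' @export
add_rolling_mean <- function(table, window = 7) {
  n <- nrow(table)
  if (n < window + 1) {
    abort(sprintf("need at least %d rows for a %d-day trailing mean.", window + 1, window))
  }
  u <- as.numeric(table$demand)
  cu <- cumsum(u)
  idx <- (window + 1):n
  pl7 <- (cu[idx - 1] - c(0, cu)[idx - window]) / window
  out <- table[idx, , drop = FALSE]
  out$pl7 <- pl7
  out
}

#' Add day-of-week indicator columns
#'
#' Adds six 0/1 columns `wd_mon` .. `wd_sat`; Sunday is the reference
#' category (all six indicators zero).
#'
#' @param table A daily tibble with `date`.
#' @return The tibble with six weekday indicator columns appended.
#' @export
add_weekday_dummies <- function(table) {
  wd <- weekday_index(table$date)
  for (k in 1:6) {
    table[[paste0("wd_", weekday_labels[k + 1L])]] <- as.integer(wd == k)
  }
  table
}

#' Build the 2- and 4-day-ahead demand targets
#'
#' For each day i, `y2` is demand summed over days i+1 and i+2 and `y4`
#' over days i+1 .. i+4 — the quantities the ordering policy needs, since
#' an order placed on day i arrives on day i+2. Trailing rows without a
#' full 4-day window are dropped.
#'
#' @param table A daily tibble with `demand`.
#' @return The tibble with `y2` and `y4` appended, 4 rows shorter.
#' @export
build_targets <- function(table) {
  n <- nrow(table)
  if (n < 5) abort("need at least 5 rows to form 4-day-ahead targets.")
  u <- as.numeric(table$demand)
  idx <- 1:(n - 4)
  y2 <- u[idx + 1] + u[idx + 2]
  y4 <- y2 + u[idx + 3] + u[idx + 4]
  out <- table[idx, , drop = FALSE]
  out$y2 <- y2
  out$y4 <- y4
  out
}

#' Build the supervised design matrix from a raw daily table
#'
#' Chains the cleaning and feature-construction steps: zero imputation,
#' removal of discontinued and sparse covariates, optional global
#' correlation screening, the trailing 7-day demand mean (PL7), weekday
#' indicators, and the 2-/4-day-ahead targets.
#'
#' By default no correlation screen is applied here: the rolling-origin
#' evaluator screens on each training span to avoid test-set leakage. Pass
#' `screen_r2` to reproduce a single global screen instead.
#'
#' @param raw A raw daily tibble (`date`, `demand`, covariates).
#' @param min_nonzero Sparsity threshold, see [filter_sparse_features()].
#' @param max_zero_run Continuity threshold, see
#'   [drop_discontinued_features()].
#' @param screen_r2 Optional global r-squared screening threshold; `NULL`
#'   (default) defers screening to the evaluation protocol.
#' @param window PL7 window length.
#' @return A design-matrix tibble: `date`, `demand`, retained covariates,
#'   `pl7`, `wd_mon` .. `wd_sat`, `y2`, `y4`.
#' @export
build_design_matrix <- function(raw, min_nonzero = 400, max_zero_run = 365,
                                screen_r2 = NULL, window = 7) {
  out <- raw |>
    impute_zeros() |>
    drop_discontinued_features(max_zero_run = max_zero_run) |>
    filter_sparse_features(min_nonzero = min_nonzero)
  if (!is.null(screen_r2)) {
    out <- correlation_screen(out, r2_threshold = screen_r2)
  }
  out |>
    add_rolling_mean(window = window) |>
    add_weekday_dummies() |>
    build_targets()
}
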