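# Internal helpers shared across modules.

# Weekday index with the blood-bank convention: Sunday = 0 ... Saturday = 6.
weekday_index <- function(date) {
  as.POSIXlt(date)$wday
}

weekday_labels <- c("sun", "mon", "tue", "wed", "thu", "fri", "sat")

# Round half up: platelet units are discrete, and .5 rounds away from the
# shortage side.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Derive a module-specific seed from a single study seed, keeping the result
# a valid 32-bit integer.
derive_seed <- function(seed, module) {
  offsets <- c(
    synthetic = 101L, features = 211L, lasso = 307L, lstm = 401L,
    rolling = 503L, metrics = 601L, inventory = 701L, policy = 809L,
    study = 907L
  )
  off <- offsets[[module]]
  if (is.null(off)) off <- 997L
  as.integer((as.numeric(seed) * 48271 + off * 2671) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Column names that are never treated as predictors or screened features.
reserved_cols <- function() {
  c("date", "demand", "y2", "y4")
}

# Feature columns of a daily table: everything except date/demand/targets.
feature_cols <- function(data) {
  setdiff(names(data), reserved_cols())
}

# Predictor columns of a design matrix (features + pl7 + weekday dummies).
predictor_cols <- function(data) {
  feature_cols(data)
}

check_contiguous_dates <- function(date, where = "table") {
  if (length(date) == 0L) abort(sprintf("%s has no rows.", where))
  d <- as.integer(diff(as.Date(date)))
  if (length(d) && any(d != 1L)) {
    i <- which(d != 1L)[1L]
    abort(sprintf(
      "%s has a calendar gap between rows %d and %d (%s -> %s); daily tables must be contiguous.",
      where, i, i + 1L, format(date[i]), format(date[i + 1L])
    ))
  }
  invisible(TRUE)
}
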