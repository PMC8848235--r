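#' Read a daily series table from CSV
#'
#' Reads and validates the package's daily CSV schema: a `date` column of
#' ISO-8601 dates followed by non-negative integer count columns (one of
#' them `demand`), one row per consecutive day. Validation failures name
#' the offending column and row.
#'
#' @param path Path to the CSV file.
#' @return A validated daily tibble.
#' @export
read_daily_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"date" %in% names(raw)) abort("CSV must have a `date` column first.")
  date <- as.Date(raw$date)
  if (anyNA(date)) {
    abort(sprintf("column `date`, row %d: unparseable date.", which(is.na(date))[1]))
  }
  raw$date <- date
  check_contiguous_dates(date, basename(path))
  for (nm in setdiff(names(raw), "date")) {
    x <- raw[[nm]]
    if (!is.numeric(x)) abort(sprintf("column `%s` is not numeric.", nm))
    bad <- which(!is.na(x) & (x < 0 | x != floor(x)))
    if (length(bad)) {
      abort(sprintf("column `%s`, row %d: counts must be non-negative integers.",
                    nm, bad[1]))
    }
    raw[[nm]] <- as.integer(x)
  }
  raw
}

#' Write a daily series table to CSV
#'
#' Inverse of [read_daily_csv()]; `read_daily_csv(write_daily_csv(x))`
#' round-trips exactly.
#'
#' @param table A daily tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(table, path) {
  out <- table
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a simulation ledger
#'
#' Writes the per-day ledger as CSV and, alongside it, a JSON summary
#' (`<path>.summary.json`) with totals, rates, cost and the policy
#' parameters.
#'
#' @param ledger A `platelet_ledger`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_csv(tidy(ledger), path, progress = FALSE)
  s <- attr(ledger, "summary")
  js <- list(
    totals = s[c("total_used", "total_ordered", "total_purchased", "total_wasted")],
    waste_rate = s$waste_rate, shortage_rate = s$shortage_rate, cost = s$cost,
    params = unclass(s$params), warmup = s$warmup,
    cost_config = unclass(s$cost_config), n_days = s$n_days
  )
  jsonlite::write_json(js, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
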