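#' Cumulative waste, purchase and cost of a simulation ledger
#'
#' @param object A `platelet_ledger`.
#' @param cost A [cost_config()] for the cumulative-cost panel.
#' @param ... Unused.
#' @return A ggplot with cumulative outdating, emergency purchases and
#'   cost over the simulated horizon.
#' @export
autoplot.platelet_ledger <- function(object, cost = cost_config(), ...) {
  df <- tidy(object) |>
    dplyr::transmute(
      date = .data$date,
      waste = cumsum(.data$waste),
      purchase = cumsum(.data$purchase),
      cost = cumsum(cost$unit_cost * .data$waste +
                      cost$emergency_cost * .data$purchase)
    ) |>
    tidyr::pivot_longer(-"date", names_to = "series", values_to = "cumulative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = "cumulative units / currency",
                  title = "Simulated inventory: cumulative outdating, purchase and cost")
}

#' Plot forecasts against realized demand targets
#'
#' @param forecasts A tibble from [rolling_origin_forecast()].
#' @param data The design matrix holding `date`, `y2`, `y4`.
#' @param horizon 2 or 4.
#' @return A ggplot of predicted vs realized demand sums over time.
#' @export
plot_forecast <- function(forecasts, data, horizon = 2) {
  stopifnot(horizon %in% c(2, 4))
  joined <- dplyr::inner_join(forecasts, data[c("date", "y2", "y4")], by = "date")
  df <- tibble::tibble(
    date = joined$date,
    predicted = joined[[paste0("p", horizon)]],
    realized = joined[[paste0("y", horizon)]]
  ) |>
    tidyr::pivot_longer(-"date", names_to = "series", values_to = "units")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$units,
                                   colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = NULL, y = sprintf("%d-day demand (units)", horizon),
                  colour = NULL,
                  title = sprintf("%d-day-ahead platelet demand: forecast vs realized", horizon))
}

#' Plot the weekday demand profile
#'
#' @param table A daily tibble with `date` and `demand`.
#' @return A ggplot of mean demand by day of week (Sunday first).
#' @export
plot_weekday_profile <- function(table) {
  df <- table |>
    dplyr::mutate(weekday = factor(weekday_labels[weekday_index(.data$date) + 1L],
                                   levels = weekday_labels)) |>
    dplyr::group_by(.data$weekday) |>
    dplyr::summarise(mean_demand = mean(.data$demand), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weekday, y = .data$mean_demand)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean units/day",
                  title = "Mean platelet demand by day of week")
}
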