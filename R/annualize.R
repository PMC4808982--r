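#' Annualize daily monitor series
#'
#' Collapses daily station concentrations to annual means, flagging years
#' whose data capture falls below a completeness threshold. Completeness is
#' the fraction of calendar days (leap-aware) with a non-missing value;
#' years under the threshold get `NA` rather than a biased mean, so
#' missingness stays an explicit state.
#'
#' @param daily Tibble with columns `station_id`, `date` (`Date`), `value`.
#' @param min_completeness Minimum fraction of days observed for a year to
#'   yield a mean; in (0, 1], default 0.75 (a common monitoring-network
#'   data-capture convention).
#' @return A tibble with columns `station_id`, `year`, `value` (annual mean
#'   or `NA`), `n_days`, `completeness`.
#' @examples
#' d <- tibble::tibble(
#'   station_id = "S1",
#'   date = seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day"),
#'   value = 50
#' )
#' annualize(d)
#' @export
annualize <- function(daily, min_completeness = 0.75) {
  if (!is.numeric(min_completeness) || length(min_completeness) != 1L ||
      min_completeness <= 0 || min_completeness > 1) {
    stop_cumulair("min_completeness must lie in (0, 1]",
                  "cumulair_validation_error")
  }
  check_columns(daily, c("station_id", "date", "value"), "daily")
  daily |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(
      n_days = sum(!is.na(.data$value)),
      mean_obs = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      completeness = .data$n_days / days_in_year(.data$year),
      value = dplyr::if_else(.data$completeness >= .env$min_completeness,
                             .data$mean_obs, NA_real_)
    ) |>
    dplyr::select("station_id", "year", "value", "n_days", "completeness")
}
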