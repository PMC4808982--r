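#' Reconstruct unit-level annual means for pre-period years
#'
#' Applies each unit's calibration on its index monitor to station annual
#' levels in the target years: `E_N(y) = exp(a_N + b_N log S_m(y))`. Where
#' a station has an observed annualized mean for a target year it is used
#' directly; otherwise the station level is extrapolated from its fitted
#' temporal trend (`trends` must then be supplied). Extrapolation is
#' refused beyond `max_horizon` years before the first observed station
#' year, since a log-linear trend carried too far back loses credibility.
#'
#' The per-cell `sd_log` column carries the calibration residual standard
#' deviation on the log scale; a multiplicative one-sigma band is
#' `value * exp(±sd_log)`.
#'
#' @param calibration A `"calibration_fit"` from [calibrate_units()].
#' @param station_annual Observed annualized station means (`station_id`,
#'   `year`, `value`).
#' @param target_years Integer years to reconstruct.
#' @param trends Optional `"trend_fit"` for the stations (identifier
#'   `series_id` = station id), used to extrapolate unobserved years.
#' @param max_horizon Maximum number of years before the first observed
#'   station year for which extrapolation is allowed (default 10).
#' @return A tibble of class `"reconstructed_field"`: `unit_id`, `year`,
#'   `value`, `sd_log`, covering exactly `target_years` for every
#'   calibrated unit.
#' @export
backcast <- function(calibration, station_annual, target_years,
                     trends = NULL, max_horizon = 10L) {
  target_years <- as.integer(target_years)
  obs <- dplyr::filter(station_annual, !is.na(.data$value))
  first_year <- min(obs$year)
  if (any(target_years < first_year - max_horizon)) {
    stop_cumulair(
      sprintf("target year(s) %s beyond the %d-year extrapolation horizon (first observed station year %d)",
              paste(target_years[target_years < first_year - max_horizon],
                    collapse = ", "),
              max_horizon, first_year),
      "cumulair_config_error")
  }

  needed <- tidyr::expand_grid(
    station_id = unique(calibration$station_id),
    year = target_years
  )
  have <- dplyr::inner_join(needed, obs, by = c("station_id", "year"))
  missing <- dplyr::anti_join(needed, have, by = c("station_id", "year"))
  if (nrow(missing) > 0L) {
    if (is.null(trends)) {
      stop_cumulair(
        sprintf("no observed station mean for %s in year(s) %s and no trend model supplied",
                paste(unique(missing$station_id), collapse = ", "),
                paste(sort(unique(missing$year)), collapse = ", ")),
        "cumulair_reference_error")
    }
    extr <- predict_trend(trends, target_years) |>
      dplyr::rename(station_id = "series_id") |>
      dplyr::semi_join(missing, by = c("station_id", "year"))
    if (nrow(extr) < nrow(missing)) {
      lost <- dplyr::anti_join(missing, extr, by = c("station_id", "year"))
      stop_cumulair(
        sprintf("no trend model for station(s): %s",
                paste(unique(lost$station_id), collapse = ", ")),
        "cumulair_reference_error")
    }
    have <- dplyr::bind_rows(have, extr)
  }

  out <- calibration |>
    dplyr::select("unit_id", "station_id", "a", "b", "sigma") |>
    dplyr::inner_join(have, by = "station_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(
      unit_id = .data$unit_id, year = .data$year,
      value = exp(.data$a + .data$b * log(.data$value)),
      sd_log = .data$sigma
    ) |>
    dplyr::arrange(.data$unit_id, .data$year)
  new_cumulair_tbl(out, "reconstructed_field")
}

#' Quantify reconstruction error on withheld years
#'
#' Re-runs the whole reconstruction pipeline with a block of observed
#' years withheld: station series and the unit annual field are truncated
#' to the remaining years, the index assignment (unless supplied), station
#' trends and unit calibrations are refitted, the withheld years are
#' backcast through trend extrapolation alone — exactly as a true
#' pre-period year would be — and the estimates are compared with the
#' withheld unit observations.
#'
#' @param bundle An [exposure_bundle()] with `stations` and `daily` tables.
#' @param holdout_years Integer years to withhold; must be observed years
#'   and leave at least `min_fit_years` years for fitting.
#' @param index_map Optional precomputed (`unit_id`, `station_id`) map;
#'   by default clustering and assignment are redone on the truncated data.
#' @param k Cluster count passed to [cluster_profiles()] when the index
#'   map is recomputed.
#' @param min_completeness Completeness threshold for [annualize()].
#' @param min_fit_years Minimum years that must remain for fitting
#'   (default 3).
#' @param max_horizon Extrapolation horizon passed to [backcast()].
#' @return A tibble of class `"holdout_validation"` with one row per unit:
#'   `unit_id`, `n_years`, `bias` (mean estimated minus observed, ug/m3),
#'   `mare` (mean absolute relative error), `rmse`. The `overall`
#'   attribute (also via [glance()]) pools all unit-years.
#' @export
holdout_validate <- function(bundle, holdout_years, index_map = NULL,
                             k = "auto", min_completeness = 0.75,
                             min_fit_years = 3L, max_horizon = 10L) {
  stopifnot(inherits(bundle, "exposure_bundle"))
  holdout_years <- as.integer(holdout_years)
  obs_years <- sort(unique(bundle$annual$year))
  if (!all(holdout_years %in% obs_years)) {
    stop_cumulair("holdout_years must be a subset of the observed years",
                  "cumulair_config_error")
  }
  fit_years <- setdiff(obs_years, holdout_years)
  if (length(fit_years) < min_fit_years) {
    stop_cumulair(
      sprintf("holdout leaves %d fit year(s); at least %d required",
              length(fit_years), min_fit_years),
      "cumulair_config_error")
  }

  unit_fit <- dplyr::filter(bundle$annual, .data$year %in% fit_years)
  station_all <- annualize(bundle$daily, min_completeness)
  station_fit <- dplyr::filter(station_all, .data$year %in% fit_years)

  if (is.null(index_map)) {
    daily_fit <- dplyr::filter(
      bundle$daily,
      as.integer(format(.data$date, "%Y")) %in% fit_years)
    feats <- build_features(unit_fit, daily_fit, min_completeness)
    clustering <- cluster_profiles(feats, k = k)
    index_map <- assign_index(clustering, bundle$units, bundle$stations)
  }

  trends <- fit_trends(
    dplyr::rename(station_fit, series_id = "station_id"))
  calib <- calibrate_units(unit_fit, station_fit, index_map)
  est <- backcast(calib, station_fit, holdout_years, trends = trends,
                  max_horizon = max_horizon)

  cmp <- est |>
    dplyr::inner_join(bundle$annual |>
                        dplyr::select("unit_id", "year", obs = "value"),
                      by = c("unit_id", "year")) |>
    dplyr::filter(!is.na(.data$obs))

  per_unit <- cmp |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      bias = mean(.data$value - .data$obs),
      mare = mean(abs(.data$value - .data$obs) / .data$obs),
      rmse = sqrt(mean((.data$value - .data$obs)^2)),
      .groups = "drop"
    )
  overall <- cmp |>
    dplyr::summarise(
      n_units = dplyr::n_distinct(.data$unit_id),
      n_cells = dplyr::n(),
      bias = mean(.data$value - .data$obs),
      mare = mean(abs(.data$value - .data$obs) / .data$obs),
      rmse = sqrt(mean((.data$value - .data$obs)^2))
    )
  new_cumulair_tbl(per_unit, "holdout_validation",
                   overall = overall, holdout_years = holdout_years)
}
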