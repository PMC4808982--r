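#' Fit log-linear temporal trends to annual concentration series
#'
#' Fits, per series, an ordinary least-squares regression of log annual
#' concentration on calendar year — the trend model used both to describe
#' the modelled period and to extrapolate station levels into the
#' pre-period. Years are centred at the first fitted year (`year0`), so
#' `intercept` is the log level at `year0` and `slope` the log of the
#' annual multiplicative factor. An optional quadratic term accommodates
#' series whose decline is visibly non-linear.
#'
#' @param series Tibble with columns `year`, `value`, and one identifier
#'   column among `series_id`, `station_id`, `unit_id` or `entity_id`.
#'   `NA` values are ignored.
#' @param trend `"linear"` (default) or `"quadratic"` (adds a squared-year
#'   term).
#' @param min_years Minimum usable years per series (default 3); series
#'   with fewer are excluded with a warning.
#' @return A tibble of class `"trend_fit"`: `series_id`, `n_years`,
#'   `year0`, `intercept`, `slope`, `quad` (`NA` for linear fits), `sigma`
#'   (residual sd, log scale) and `r_squared`. Supports [tidy()],
#'   [glance()] and [predict_trend()].
#' @examples
#' s <- tibble::tibble(series_id = "a", year = 2002:2012,
#'                     value = 50 * 0.97^(0:10))
#' fit_trends(s)$slope  # log(0.97)
#' @export
fit_trends <- function(series, trend = c("linear", "quadratic"),
                       min_years = 3L) {
  trend <- match.arg(trend)
  id_col <- intersect(c("series_id", "station_id", "unit_id", "entity_id"),
                      names(series))[1]
  if (is.na(id_col)) {
    stop_cumulair("series needs an identifier column (series_id, station_id, unit_id or entity_id)",
                  "cumulair_parse_error")
  }
  check_columns(series, c(id_col, "year", "value"), "series")
  dat <- series |>
    dplyr::rename(series_id = dplyr::all_of(id_col)) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$series_id, .data$year)

  counts <- dplyr::count(dat, .data$series_id)
  short <- counts$series_id[counts$n < min_years]
  if (length(short) > 0L) {
    warn(sprintf("series excluded from trend fitting (<%d usable years): %s",
                 min_years, paste(short, collapse = ", ")))
    dat <- dplyr::filter(dat, !.data$series_id %in% short)
  }

  if (nrow(dat) == 0L) {
    return(new_cumulair_tbl(
      tibble::tibble(series_id = character(), n_years = integer(),
                     year0 = integer(), intercept = numeric(),
                     slope = numeric(), quad = numeric(), sigma = numeric(),
                     r_squared = numeric()),
      "trend_fit", trend = trend))
  }
  fits <- dat |>
    dplyr::group_by(.data$series_id) |>
    dplyr::group_modify(function(g, key) {
      y0 <- min(g$year)
      t <- g$year - y0
      fit <- if (trend == "quadratic") {
        lm(log(value) ~ t + I(t^2), data = cbind(g, t = t))
      } else {
        lm(log(value) ~ t, data = cbind(g, t = t))
      }
      cf <- coef(fit)
      sm <- suppressWarnings(summary(fit))  # perfect fits are expected on noiseless input
      tibble::tibble(
        n_years = nrow(g), year0 = y0,
        intercept = unname(cf[1]), slope = unname(cf[2]),
        quad = if (trend == "quadratic") unname(cf[3]) else NA_real_,
        sigma = sm$sigma, r_squared = sm$r.squared
      )
    }) |>
    dplyr::ungroup()
  new_cumulair_tbl(fits, "trend_fit", trend = trend)
}

#' Predict annual levels from fitted trends
#'
#' Evaluates each series' log-linear (or log-quadratic) trend at the
#' requested years, back-transformed to the concentration scale.
#'
#' @param trends A `"trend_fit"` tibble from [fit_trends()].
#' @param years Integer years at which to predict.
#' @return A tibble `series_id`, `year`, `value`.
#' @export
predict_trend <- function(trends, years) {
  tidyr::expand_grid(series_id = trends$series_id, year = as.integer(years)) |>
    dplyr::left_join(trends, by = "series_id") |>
    dplyr::mutate(
      t = .data$year - .data$year0,
      value = exp(.data$intercept + .data$slope * .data$t +
                    dplyr::coalesce(.data$quad, 0) * .data$t^2)
    ) |>
    dplyr::select("series_id", "year", "value")
}

#' Calibrate each unit on its index monitor
#'
#' Formalises the weighting of unit annual averages by their index
#' monitor's temporal coefficient as a per-unit log-log regression:
#' `log E_N(y) = a_N + b_N log S_m(y)` over the years where both the unit's
#' annual mean and its index station's annualized mean are observed. When
#' `b = 1` this reduces to a constant-ratio scaling of the monitor; the
#' fitted slope additionally absorbs differences in temporal amplitude.
#' If the station shows zero variance over the overlap, the slope is not
#' identifiable and the fit falls back to the ratio model (`b = 1`,
#' `a` = mean log ratio), flagged in the `method` column.
#'
#' @param unit_annual Annual field tibble (`unit_id`, `year`, `value`).
#' @param station_annual Annualized station means (`station_id`, `year`,
#'   `value`), e.g. from [annualize()].
#' @param index_map Tibble (`unit_id`, `station_id`) from [assign_index()].
#' @param min_years Minimum overlap years (default 3); units with fewer
#'   are excluded with a warning.
#' @return A tibble of class `"calibration_fit"`: `unit_id`, `station_id`,
#'   `n_years`, `a`, `b`, `sigma` (residual sd, log scale), `r_squared`,
#'   `method` (`"ols"` or `"ratio"`).
#' @export
calibrate_units <- function(unit_annual, station_annual, index_map,
                            min_years = 3L) {
  check_columns(index_map, c("unit_id", "station_id"), "index_map")
  dat <- unit_annual |>
    dplyr::inner_join(index_map[c("unit_id", "station_id")], by = "unit_id") |>
    dplyr::inner_join(station_annual |>
                        dplyr::select("station_id", "year", s_value = "value"),
                      by = c("station_id", "year")) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$s_value)) |>
    dplyr::arrange(.data$unit_id, .data$year)

  counts <- dplyr::count(dat, .data$unit_id)
  short <- c(counts$unit_id[counts$n < min_years],
             setdiff(index_map$unit_id, counts$unit_id))
  if (length(short) > 0L) {
    warn(sprintf("unit(s) excluded from calibration (<%d overlap years): %s",
                 min_years, paste(short, collapse = ", ")))
    dat <- dplyr::filter(dat, !.data$unit_id %in% short)
  }

  if (nrow(dat) == 0L) {
    return(new_cumulair_tbl(
      tibble::tibble(unit_id = character(), station_id = character(),
                     n_years = integer(), a = numeric(), b = numeric(),
                     sigma = numeric(), r_squared = numeric(),
                     method = character()),
      "calibration_fit"))
  }
  fits <- dat |>
    dplyr::group_by(.data$unit_id, .data$station_id) |>
    dplyr::group_modify(function(g, key) {
      ls <- log(g$s_value)
      lu <- log(g$value)
      if (sd(ls) == 0) {
        rlang::inform(sprintf(
          "station %s constant over overlap; ratio calibration for unit %s",
          key$station_id, key$unit_id))
        a <- mean(lu - ls)
        resid <- lu - (a + ls)
        n <- length(lu)
        tibble::tibble(n_years = n, a = a, b = 1,
                       sigma = if (n > 1) sqrt(sum(resid^2) / (n - 1)) else 0,
                       r_squared = NA_real_, method = "ratio")
      } else {
        fit <- lm(lu ~ ls)
        sm <- suppressWarnings(summary(fit))
        tibble::tibble(n_years = length(lu),
                       a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                       sigma = sm$sigma, r_squared = sm$r.squared,
                       method = "ols")
      }
    }) |>
    dplyr::ungroup()
  new_cumulair_tbl(fits, "calibration_fit")
}
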