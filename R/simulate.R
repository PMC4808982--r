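#' Specify a synthetic study area
#'
#' Describes the generative model behind [simulate_area()]: a study area
#' whose annual concentration field follows cluster-specific log-linear
#' temporal trends with multiplicative unit-level offsets, monitored by
#' stations whose daily series share their cluster's annual level times a
#' seasonal cycle and lognormal daily noise, plus a row-stochastic
#' residence-transition matrix with an outside-area category.
#'
#' The defaults emulate an NO2 regime typical of a dense European city:
#' a mean annual level near 55 ug/m3 slowly declining over 2002-2012, high
#' between-unit spread relative to within-unit temporal range, about 15% of
#' residents changing unit per 5-year census period, and a small fraction of
#' moves originating outside the study area.
#'
#' @param n_units,n_stations Number of spatial units and monitor stations.
#' @param years_modeled Integer years with observed annual field and daily
#'   monitor data.
#' @param years_hidden Integer years before the modelled period whose annual
#'   field is generated but withheld as ground truth (reconstruction target).
#' @param n_clusters_true Number of temporal-trend clusters.
#' @param trend_slopes Per-cluster annual multiplicative factor (length
#'   `n_clusters_true`); e.g. `0.97` means a 3% decline per year.
#' @param base_level Area-wide annual mean level in the first modelled year,
#'   ug/m3.
#' @param unit_level_spread Standard deviation of unit log-offsets
#'   (between-unit spatial heterogeneity).
#' @param seasonal_amplitude Relative amplitude of the annual sinusoid in
#'   the daily series (0 disables seasonality).
#' @param daily_noise_sd Standard deviation of lognormal daily noise
#'   (log scale; 0 disables noise).
#' @param mobility_intensity Mean per-period probability of changing unit,
#'   i.e. mean `1 - P_NN`; in `[0, 1)`. 0 yields the identity matrix.
#' @param outside_fraction Fraction of the moving mass originating outside
#'   the study area.
#' @param period_years Census inter-period length of the mobility matrix,
#'   years.
#' @param rng_seed Integer seed; identical seeds give identical bundles.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_units = 40L, n_stations = 9L,
                            years_modeled = 2002:2012,
                            years_hidden = 1997:2001,
                            n_clusters_true = 3L,
                            trend_slopes = c(0.96, 0.99, 1.03),
                            base_level = 55,
                            unit_level_spread = 0.15,
                            seasonal_amplitude = 0.25,
                            daily_noise_sd = 0.10,
                            mobility_intensity = 0.15,
                            outside_fraction = 0.05,
                            period_years = 5L,
                            rng_seed = 1L) {
  spec <- list(
    n_units = as.integer(n_units), n_stations = as.integer(n_stations),
    years_modeled = as.integer(years_modeled),
    years_hidden = as.integer(years_hidden),
    n_clusters_true = as.integer(n_clusters_true),
    trend_slopes = as.numeric(trend_slopes), base_level = base_level,
    unit_level_spread = unit_level_spread,
    seasonal_amplitude = seasonal_amplitude,
    daily_noise_sd = daily_noise_sd,
    mobility_intensity = mobility_intensity,
    outside_fraction = outside_fraction,
    period_years = as.integer(period_years),
    rng_seed = as.integer(rng_seed)
  )
  if (spec$n_units < 1L || spec$n_stations < 1L || spec$n_clusters_true < 1L) {
    stop_cumulair("counts must be positive", "cumulair_config_error")
  }
  if (spec$n_stations < spec$n_clusters_true) {
    stop_cumulair("n_stations must be at least n_clusters_true (every cluster needs a monitor)",
                  "cumulair_config_error")
  }
  if (length(spec$trend_slopes) != spec$n_clusters_true) {
    stop_cumulair("trend_slopes must supply one factor per cluster",
                  "cumulair_config_error")
  }
  if (!all(is.finite(spec$trend_slopes)) || any(spec$trend_slopes <= 0)) {
    stop_cumulair("trend_slopes must be finite and positive",
                  "cumulair_config_error")
  }
  if (spec$mobility_intensity < 0 || spec$mobility_intensity >= 1) {
    stop_cumulair("mobility_intensity must lie in [0, 1)", "cumulair_config_error")
  }
  if (spec$outside_fraction < 0 || spec$outside_fraction > 1) {
    stop_cumulair("outside_fraction must lie in [0, 1]", "cumulair_config_error")
  }
  check_years_contiguous(spec$years_modeled, "years_modeled")
  if (length(spec$years_hidden) > 0 &&
      max(spec$years_hidden) >= min(spec$years_modeled)) {
    stop_cumulair("years_hidden must precede years_modeled",
                  "cumulair_config_error")
  }
  structure(spec, class = "simulation_spec")
}

# cluster annual level: exact log-linear trend anchored at the first
# modelled year, so a log-level OLS on year recovers it exactly
cluster_levels <- function(spec, cluster_mult, years) {
  y0 <- min(spec$years_modeled)
  vapply(seq_len(spec$n_clusters_true), function(c) {
    spec$base_level * cluster_mult[c] * spec$trend_slopes[c]^(years - y0)
  }, numeric(length(years)))
}

#' Generate a residence-transition table for a set of units
#'
#' Off-diagonal (moving) mass is split between an outside-area share and
#' interior destinations weighted by inverse distance between unit
#' centroids, giving spatially plausible short-range moves. Rows (indexed
#' by current residence) always sum to exactly 1. Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param units Unit registry tibble (`unit_id`, `x`, `y`, ...).
#' @inheritParams simulation_spec
#' @return A mobility tibble (`dest_id`, `origin_id`, `probability`,
#'   `period_years`) suitable for [exposure_bundle()].
#' @export
simulate_mobility <- function(units, mobility_intensity = 0.15,
                              outside_fraction = 0.05, period_years = 5L) {
  n <- nrow(units)
  ids <- units$unit_id
  if (mobility_intensity == 0) {
    return(tibble::tibble(dest_id = ids, origin_id = ids, probability = 1,
                          period_years = as.integer(period_years)))
  }
  move <- pmin(pmax(mobility_intensity * stats::runif(n, 0.6, 1.4), 0), 0.95)
  d <- as.matrix(stats::dist(units[, c("x", "y")]))
  rows <- purrr::map(seq_len(n), function(i) {
    p_out <- move[i] * outside_fraction
    p_int <- move[i] - p_out
    if (n == 1L) {
      p_out <- move[i]
      p_int <- 0
    }
    orig <- ids[i]
    prob <- 1 - move[i]
    if (p_int > 0) {
      w <- 1 / (d[i, -i] + 1)          # +1 m regularises coincident centroids
      w <- w / sum(w)
      orig <- c(orig, ids[-i])
      prob <- c(prob, p_int * w)
    }
    if (p_out > 0) {
      orig <- c(orig, OUTSIDE_LABEL)
      prob <- c(prob, p_out)
    }
    tibble::tibble(dest_id = ids[i], origin_id = orig,
                   probability = prob / sum(prob))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(period_years = as.integer(period_years))
}

#' Simulate a complete study-input bundle with hidden ground truth
#'
#' Draws a study area from a [simulation_spec()]: unit registry, annual
#' concentration field over the modelled years, station registry, daily
#' monitor series, mobility table and outside-area series — plus a `truth`
#' component holding the withheld pre-period annual field and the true
#' cluster labels, for recovery tests. The same seed always reproduces the
#' same bundle.
#'
#' @param spec A [simulation_spec()].
#' @return A validated [exposure_bundle()] whose `truth` element has tables
#'   `annual` (hidden years) and `labels` (`entity_id`, `kind`, `cluster`).
#' @examples
#' b <- simulate_area(simulation_spec(n_units = 6, n_stations = 3,
#'                                    rng_seed = 42))
#' b
#' @export
simulate_area <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$rng_seed, simulate_area_impl(spec))
}

simulate_area_impl <- function(spec) {
  n <- spec$n_units
  k <- spec$n_clusters_true
  unit_ids <- sprintf("U%03d", seq_len(n))
  station_ids <- sprintf("S%02d", seq_len(spec$n_stations))

  units <- tibble::tibble(
    unit_id = unit_ids,
    x = stats::runif(n, 0, 10000),
    y = stats::runif(n, 0, 10000),
    population = round(stats::rlnorm(n, log(2000), 0.3))
  )

  unit_cluster <- sample(rep_len(seq_len(k), n))
  # every cluster keeps at least one station
  station_cluster <- c(seq_len(k),
                       sample(seq_len(k), spec$n_stations - k, replace = TRUE))
  station_type <- sample(c("urban", "traffic"), spec$n_stations,
                         replace = TRUE, prob = c(0.6, 0.4))
  stations <- tibble::tibble(
    station_id = station_ids,
    type = station_type,
    x = stats::runif(spec$n_stations, 0, 10000),
    y = stats::runif(spec$n_stations, 0, 10000)
  )

  cluster_mult <- exp(stats::rnorm(k, 0, 0.15))
  all_years <- c(spec$years_hidden, spec$years_modeled)
  lev <- cluster_levels(spec, cluster_mult, all_years)  # years x clusters
  rownames(lev) <- all_years

  unit_offset <- exp(stats::rnorm(n, 0, spec$unit_level_spread))
  field_all <- tidyr::expand_grid(unit_id = unit_ids, year = all_years) |>
    dplyr::mutate(
      cl = unit_cluster[match(.data$unit_id, unit_ids)],
      value = lev[cbind(match(.data$year, all_years), .data$cl)] *
        unit_offset[match(.data$unit_id, unit_ids)]
    ) |>
    dplyr::select("unit_id", "year", "value")
  annual <- dplyr::filter(field_all, .data$year %in% spec$years_modeled)
  truth_annual <- dplyr::filter(field_all, .data$year %in% spec$years_hidden)

  # traffic monitors sit higher than background ones at the same dynamics
  station_offset <- exp(stats::rnorm(spec$n_stations, 0, 0.10)) *
    ifelse(station_type == "traffic", 1.7, 1.0)

  dates <- seq(as.Date(sprintf("%d-01-01", min(spec$years_modeled))),
               as.Date(sprintf("%d-12-31", max(spec$years_modeled))),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  season <- 1 + spec$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  yr_idx <- match(as.integer(format(dates, "%Y")), all_years)
  daily <- purrr::map(seq_len(spec$n_stations), function(s) {
    base <- lev[yr_idx, station_cluster[s]] * station_offset[s] * season
    noise <- if (spec$daily_noise_sd > 0) {
      exp(stats::rnorm(length(dates), 0, spec$daily_noise_sd) -
            spec$daily_noise_sd^2 / 2)
    } else 1
    tibble::tibble(station_id = station_ids[s], date = dates,
                   value = unname(base * noise))
  }) |>
    dplyr::bind_rows()

  mobility <- simulate_mobility(units, spec$mobility_intensity,
                                spec$outside_fraction, spec$period_years)

  y0 <- min(spec$years_modeled)
  outside <- tibble::tibble(
    year = all_years,
    value = 0.45 * spec$base_level * 0.99^(all_years - y0)
  )

  labels <- dplyr::bind_rows(
    tibble::tibble(entity_id = unit_ids, kind = "unit",
                   cluster = unit_cluster),
    tibble::tibble(entity_id = station_ids, kind = "station",
                   cluster = station_cluster)
  )

  exposure_bundle(units, annual, stations, daily, mobility, outside,
                  truth = list(annual = truth_annual, labels = labels))
}
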