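# broom-style accessors for the fitted objects.

#' @exportS3Method generics::tidy
tidy.trend_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    n_series = nrow(x),
    trend = attr(x, "trend"),
    median_slope = stats::median(x$slope),
    median_annual_factor = exp(stats::median(x$slope)),
    median_sigma = stats::median(x$sigma)
  )
}

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    n_ratio_fallback = sum(x$method == "ratio"),
    median_b = stats::median(x$b),
    median_r_squared = stats::median(x$r_squared, na.rm = TRUE),
    median_sigma = stats::median(x$sigma)
  )
}

#' @exportS3Method generics::tidy
tidy.station_clustering <- function(x, ...) {
  x$labels
}

#' @exportS3Method generics::glance
glance.station_clustering <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_entities = nrow(x$labels),
    n_units = sum(x$labels$kind == "unit"),
    n_stations = sum(x$labels$kind == "station"),
    mean_silhouette = x$silhouette
  )
}

#' @exportS3Method generics::tidy
tidy.holdout_validation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.holdout_validation <- function(x, ...) {
  attr(x, "overall")
}

#' @exportS3Method generics::glance
glance.cumulative_exposure <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    ref_year = attr(x, "ref_year"),
    lmax = attr(x, "lmax"),
    denominator = attr(x, "denominator"),
    policy = attr(x, "policy"),
    mean_degree = mean(x$degree_of_mobility),
    mean_relative_difference = mean(x$relative_difference)
  )
}
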