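#' Build standardized annual profiles for units and stations
#'
#' Puts spatial units and monitoring stations on a common temporal support:
#' units contribute their annual-field series directly, stations are
#' annualized from their daily series via [annualize()]. Each entity's
#' series over the shared year range is then standardized to zero mean and
#' unit variance, so that the clustering stage compares temporal shape, not
#' level — a traffic monitor can track a unit's dynamics at a much higher
#' concentration.
#'
#' Entities with a constant profile (zero variance) cannot be standardized;
#' they are dropped with a warning and recorded in the `dropped` attribute.
#'
#' @param annual Annual field tibble (`unit_id`, `year`, `value`).
#' @param daily Optional daily monitor tibble (`station_id`, `date`,
#'   `value`); omit to cluster units only.
#' @param min_completeness Completeness threshold passed to [annualize()].
#' @return A tibble of class `"series_features"` with columns `entity_id`,
#'   `kind` (`"unit"`/`"station"`), `year`, `value` (annual mean) and `z`
#'   (standardized profile). Attributes: `years` (shared year range),
#'   `dropped` (constant entities excluded).
#' @export
build_features <- function(annual, daily = NULL, min_completeness = 0.75) {
  check_columns(annual, c("unit_id", "year", "value"), "annual")
  long <- annual |>
    dplyr::transmute(entity_id = .data$unit_id, kind = "unit",
                     year = .data$year, value = .data$value)
  if (!is.null(daily)) {
    st <- annualize(daily, min_completeness) |>
      dplyr::transmute(entity_id = .data$station_id, kind = "station",
                       year = .data$year, value = .data$value)
    long <- dplyr::bind_rows(long, st)
  }
  long <- dplyr::filter(long, !is.na(.data$value))

  # years observed by every entity
  n_entities <- dplyr::n_distinct(long$entity_id)
  shared <- long |>
    dplyr::count(.data$year) |>
    dplyr::filter(.data$n == n_entities) |>
    dplyr::pull(.data$year)
  if (length(shared) < 2L) {
    stop_cumulair("at least 2 modelled years must be shared by all entities",
                  "cumulair_validation_error")
  }
  long <- dplyr::filter(long, .data$year %in% shared)

  long <- long |>
    dplyr::group_by(.data$entity_id, .data$kind) |>
    dplyr::mutate(.sd = sd(.data$value),
                  z = dplyr::if_else(.data$.sd > 0,
                                     (.data$value - mean(.data$value)) / .data$.sd,
                                     NA_real_)) |>
    dplyr::ungroup()
  dropped <- long |>
    dplyr::filter(.data$.sd == 0) |>
    dplyr::distinct(.data$entity_id, .data$kind)
  if (nrow(dropped) > 0L) {
    warn(sprintf("constant profile(s) excluded from clustering: %s",
                 paste(dropped$entity_id, collapse = ", ")))
    long <- dplyr::filter(long, .data$.sd > 0)
  }
  new_cumulair_tbl(dplyr::select(long, -".sd"), "series_features",
                   years = sort(shared), dropped = dropped)
}

# entities x years matrix of standardized profiles, rows sorted by id
feature_matrix <- function(features) {
  wide <- features |>
    dplyr::select("entity_id", "year", "z") |>
    tidyr::pivot_wider(names_from = "year", values_from = "z") |>
    dplyr::arrange(.data$entity_id)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$entity_id
  m
}
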