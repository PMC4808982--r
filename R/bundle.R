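#' Assemble a validated study-input bundle
#'
#' An exposure bundle collects the tabular inputs of a cumulative-exposure
#' study: the spatial-unit registry, the unit-by-year annual concentration
#' field, the monitoring-station registry and their daily series, the
#' residence-transition (mobility) table, and the outside-area annual
#' exposure series. All cross-references between tables are checked on
#' construction.
#'
#' @param units Tibble with columns `unit_id`, `x`, `y` (planar metres) and
#'   `population` (non-negative count).
#' @param annual Tibble with columns `unit_id`, `year`, `value` (annual mean,
#'   ug/m3). Missing cells are carried as `NA`, never as zero.
#' @param stations Optional tibble with columns `station_id`, `type`
#'   (one of `"urban"`, `"peri-urban"`, `"traffic"`), `x`, `y`.
#' @param daily Optional tibble with columns `station_id`, `date` (`Date`),
#'   `value` (daily mean, ug/m3).
#' @param mobility Optional tibble with columns `dest_id`, `origin_id`,
#'   `probability`, `period_years`. Rows are indexed by destination (current
#'   residence): the probabilities in the rows of one `dest_id` give the
#'   distribution of residence one census period earlier, and must sum to 1.
#'   `origin_id` may be the reserved label [OUTSIDE_LABEL].
#' @param outside Optional tibble with columns `year`, `value`: annual mean
#'   exposure assigned to residence outside the study area.
#' @param truth Optional list of ground-truth tables (used by the synthetic
#'   generator): `annual` (hidden pre-period field) and `labels`
#'   (entity-level cluster labels).
#' @param validate If `TRUE` (default), run all invariant checks.
#'
#' @return A list of class `"exposure_bundle"`.
#' @seealso [read_study_inputs()], [write_bundle()], [simulate_area()]
#' @export
exposure_bundle <- function(units, annual, stations = NULL, daily = NULL,
                            mobility = NULL, outside = NULL, truth = NULL,
                            validate = TRUE) {
  bundle <- structure(
    list(
      units = tibble::as_tibble(units),
      annual = tibble::as_tibble(annual),
      stations = if (!is.null(stations)) tibble::as_tibble(stations),
      daily = if (!is.null(daily)) tibble::as_tibble(daily),
      mobility = if (!is.null(mobility)) tibble::as_tibble(mobility),
      outside = if (!is.null(outside)) tibble::as_tibble(outside),
      truth = truth
    ),
    class = "exposure_bundle"
  )
  if (validate) validate_bundle(bundle)
  bundle
}

#' Validate an exposure bundle against its invariants
#'
#' Checks every table-level invariant (positive finite concentrations,
#' unique identifiers, finite coordinates, strictly increasing dates,
#' row-stochastic mobility rows) and every cross-reference (mobility
#' destinations and origins among the registered units, daily series
#' stations among the registered stations).
#'
#' @param bundle An [exposure_bundle()].
#' @param mobility_tol Tolerance on mobility row sums (default `1e-6`).
#' @return The bundle, invisibly. Errors are classed
#'   `cumulair_validation_error` (invariant broken) or
#'   `cumulair_reference_error` (dangling identifier / missing table).
#' @export
validate_bundle <- function(bundle, mobility_tol = 1e-6) {
  stopifnot(inherits(bundle, "exposure_bundle"))
  validate_units(bundle$units)
  validate_annual(bundle$annual, bundle$units)
  if (!is.null(bundle$stations)) validate_stations(bundle$stations)
  if (!is.null(bundle$daily)) validate_daily(bundle$daily, bundle$stations)
  if (!is.null(bundle$mobility)) {
    validate_mobility(bundle$mobility, bundle$units, tol = mobility_tol)
  }
  if (!is.null(bundle$outside)) validate_outside(bundle$outside)
  invisible(bundle)
}

check_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    stop_cumulair(
      sprintf("%s: missing column(s) %s", what, paste(missing, collapse = ", ")),
      "cumulair_parse_error"
    )
  }
  invisible(tbl)
}

validate_units <- function(units) {
  check_columns(units, c("unit_id", "x", "y", "population"), "units")
  if (nrow(units) < 1L) {
    stop_cumulair("units: a study area needs at least one spatial unit",
                  "cumulair_validation_error")
  }
  if (anyDuplicated(units$unit_id)) {
    stop_cumulair(
      sprintf("units: duplicated unit_id(s): %s",
              paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", ")),
      "cumulair_validation_error")
  }
  if (OUTSIDE_LABEL %in% units$unit_id) {
    stop_cumulair(
      sprintf("units: reserved outside label %s used as a unit_id", OUTSIDE_LABEL),
      "cumulair_validation_error")
  }
  if (!all(is.finite(units$x)) || !all(is.finite(units$y))) {
    stop_cumulair("units: coordinates must be finite", "cumulair_validation_error")
  }
  if (any(!is.finite(units$population) | units$population < 0)) {
    stop_cumulair("units: population must be a non-negative count",
                  "cumulair_validation_error")
  }
  invisible(units)
}

validate_annual <- function(annual, units = NULL) {
  check_columns(annual, c("unit_id", "year", "value"), "annual")
  bad <- !is.na(annual$value) & (!is.finite(annual$value) | annual$value <= 0)
  if (any(bad)) {
    stop_cumulair(
      sprintf("annual: non-positive or non-finite value(s), e.g. unit %s year %d",
              annual$unit_id[bad][1L], annual$year[bad][1L]),
      "cumulair_validation_error")
  }
  if (anyDuplicated(annual[c("unit_id", "year")])) {
    stop_cumulair("annual: duplicated (unit_id, year) cell(s)",
                  "cumulair_validation_error")
  }
  check_years_contiguous(annual$year, "annual: years")
  if (!is.null(units)) {
    unknown <- setdiff(annual$unit_id, units$unit_id)
    if (length(unknown) > 0L) {
      stop_cumulair(
        sprintf("annual: unknown unit_id(s): %s", paste(unknown, collapse = ", ")),
        "cumulair_reference_error")
    }
  }
  invisible(annual)
}

validate_stations <- function(stations) {
  check_columns(stations, c("station_id", "type", "x", "y"), "stations")
  if (anyDuplicated(stations$station_id)) {
    stop_cumulair("stations: duplicated station_id(s)", "cumulair_validation_error")
  }
  ok_types <- c("urban", "peri-urban", "traffic")
  if (!all(stations$type %in% ok_types)) {
    stop_cumulair(
      sprintf("stations: type must be one of %s", paste(ok_types, collapse = ", ")),
      "cumulair_validation_error")
  }
  if (!all(is.finite(stations$x)) || !all(is.finite(stations$y))) {
    stop_cumulair("stations: coordinates must be finite", "cumulair_validation_error")
  }
  invisible(stations)
}

validate_daily <- function(daily, stations = NULL) {
  check_columns(daily, c("station_id", "date", "value"), "daily")
  if (!inherits(daily$date, "Date")) {
    stop_cumulair("daily: date column must be of class Date (ISO-8601 in files)",
                  "cumulair_parse_error")
  }
  bad <- !is.na(daily$value) & (!is.finite(daily$value) | daily$value <= 0)
  if (any(bad)) {
    stop_cumulair(
      sprintf("daily: non-positive value(s), e.g. station %s on %s",
              daily$station_id[bad][1L], format(daily$date[bad][1L])),
      "cumulair_validation_error")
  }
  not_incr <- daily |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$date, strictly = TRUE),
                     .groups = "drop")
  if (any(!not_incr$ok)) {
    stop_cumulair(
      sprintf("daily: dates not strictly increasing for station %s",
              not_incr$station_id[!not_incr$ok][1L]),
      "cumulair_validation_error")
  }
  if (!is.null(stations)) {
    unknown <- setdiff(daily$station_id, stations$station_id)
    if (length(unknown) > 0L) {
      stop_cumulair(
        sprintf("daily: unknown station_id(s): %s", paste(unknown, collapse = ", ")),
        "cumulair_reference_error")
    }
  }
  invisible(daily)
}

validate_mobility <- function(mobility, units = NULL, tol = 1e-6) {
  check_columns(mobility, c("dest_id", "origin_id", "probability", "period_years"),
                "mobility")
  if (nrow(mobility) == 0L) {
    stop_cumulair("mobility: table is empty", "cumulair_reference_error")
  }
  if (any(mobility$probability < 0 | mobility$probability > 1)) {
    stop_cumulair("mobility: probabilities must lie in [0, 1]",
                  "cumulair_validation_error")
  }
  pv <- unique(mobility$period_years)
  if (length(pv) != 1L || !is_count(pv) || pv < 1) {
    stop_cumulair("mobility: period_years must be a single positive integer",
                  "cumulair_validation_error")
  }
  sums <- mobility |>
    dplyr::group_by(.data$dest_id) |>
    dplyr::summarise(s = sum(.data$probability), .groups = "drop")
  off <- abs(sums$s - 1) > tol
  if (any(off)) {
    stop_cumulair(
      sprintf("mobility: row for destination %s sums to %.6f, not 1",
              sums$dest_id[off][1L], sums$s[off][1L]),
      "cumulair_validation_error")
  }
  if (!is.null(units)) {
    unknown_dest <- setdiff(mobility$dest_id, units$unit_id)
    unknown_orig <- setdiff(mobility$origin_id, c(units$unit_id, OUTSIDE_LABEL))
    if (length(unknown_dest) > 0L || length(unknown_orig) > 0L) {
      stop_cumulair(
        sprintf("mobility: unknown id(s): %s",
                paste(c(unknown_dest, unknown_orig), collapse = ", ")),
        "cumulair_reference_error")
    }
    missing_rows <- setdiff(units$unit_id, mobility$dest_id)
    if (length(missing_rows) > 0L) {
      stop_cumulair(
        sprintf("mobility: no row for destination unit(s): %s",
                paste(missing_rows, collapse = ", ")),
        "cumulair_reference_error")
    }
  }
  invisible(mobility)
}

validate_outside <- function(outside) {
  check_columns(outside, c("year", "value"), "outside")
  bad <- !is.na(outside$value) & (!is.finite(outside$value) | outside$value <= 0)
  if (any(bad)) {
    stop_cumulair("outside: values must be positive where present",
                  "cumulair_validation_error")
  }
  invisible(outside)
}

#' @export
print.exposure_bundle <- function(x, ...) {
  cat("<exposure_bundle>\n")
  cat(sprintf("  units:    %d spatial units\n", nrow(x$units)))
  yr <- range(x$annual$year)
  cat(sprintf("  annual:   %d cells over %d-%d\n", nrow(x$annual), yr[1], yr[2]))
  if (!is.null(x$stations)) {
    cat(sprintf("  stations: %d (%s)\n", nrow(x$stations),
                paste(sprintf("%d %s", table(x$stations$type),
                              names(table(x$stations$type))), collapse = ", ")))
  }
  if (!is.null(x$daily)) cat(sprintf("  daily:    %d observations\n", nrow(x$daily)))
  if (!is.null(x$mobility)) {
    cat(sprintf("  mobility: %d-year period matrix, %d entries\n",
                x$mobility$period_years[1], nrow(x$mobility)))
  }
  if (!is.null(x$outside)) cat(sprintf("  outside:  %d years\n", nrow(x$outside)))
  if (!is.null(x$truth)) cat("  truth:    hidden field + labels attached\n")
  invisible(x)
}

bundle_files <- c(units = "units.csv", annual = "annual.csv",
                  stations = "stations.csv", daily = "daily.csv",
                  mobility = "mobility.csv", outside = "outside.csv")

# Columns are read as character and converted through base R parsers:
# base as.numeric is correctly rounded, which keeps the write-then-read
# round-trip lossless to the last bit of a double.
read_table_checked <- function(path, schema) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(tbl, names(schema), basename(path))
  for (col in names(schema)) {
    raw <- tbl[[col]]
    parsed <- switch(schema[[col]],
                     c = raw,
                     i = suppressWarnings(as.integer(raw)),
                     d = suppressWarnings(as.numeric(raw)),
                     D = as.Date(raw, format = "%Y-%m-%d"))
    bad <- which(is.na(parsed) & !is.na(raw) & raw != "NA")
    if (length(bad) > 0L) {
      stop_cumulair(
        sprintf("%s: parse failure at line %d, column %s (value \"%s\")",
                basename(path), bad[1L] + 1L, col, raw[bad[1L]]),
        "cumulair_parse_error")
    }
    tbl[[col]] <- parsed
  }
  tbl[names(schema)]
}

#' Read a study-input directory into a validated bundle
#'
#' Reads the delimited study inputs (`units.csv`, `annual.csv`,
#' `stations.csv`, `daily.csv`, `mobility.csv`, `outside.csv`, and an
#' optional `truth/` sub-directory written by the synthetic generator) and
#' returns a validated [exposure_bundle()].
#'
#' @param dir Directory holding the input files.
#' @param config Optional run configuration (see [read_run_config()]); its
#'   `thresholds$mobility_row_tol` entry sets the mobility row-sum tolerance.
#' @param strict If `TRUE` (default) all six tables must be present and
#'   non-empty; if `FALSE` the optional tables (stations, daily, mobility,
#'   outside) may be absent.
#' @return An [exposure_bundle()].
#' @export
read_study_inputs <- function(dir, config = NULL, strict = TRUE) {
  specs <- list(
    units = c(unit_id = "c", x = "d", y = "d", population = "d"),
    annual = c(unit_id = "c", year = "i", value = "d"),
    stations = c(station_id = "c", type = "c", x = "d", y = "d"),
    daily = c(station_id = "c", date = "D", value = "d"),
    mobility = c(dest_id = "c", origin_id = "c", probability = "d",
                 period_years = "i"),
    outside = c(year = "i", value = "d")
  )
  tables <- purrr::imap(bundle_files, function(file, name) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      if (strict || name %in% c("units", "annual")) {
        stop_cumulair(sprintf("required input %s not found in %s", file, dir),
                      "cumulair_reference_error")
      }
      return(NULL)
    }
    tbl <- read_table_checked(path, specs[[name]])
    if (strict && nrow(tbl) == 0L) {
      stop_cumulair(sprintf("%s: required input is empty", file),
                    "cumulair_reference_error")
    }
    tbl
  })
  truth <- NULL
  truth_dir <- file.path(dir, "truth")
  if (dir.exists(truth_dir)) {
    truth <- list(
      annual = read_table_checked(file.path(truth_dir, "annual.csv"),
                                  specs$annual),
      labels = read_table_checked(file.path(truth_dir, "labels.csv"),
                                  c(entity_id = "c", kind = "c",
                                    cluster = "i"))
    )
  }
  tol <- config$thresholds$mobility_row_tol %||% 1e-6
  bundle <- exposure_bundle(
    units = tables$units, annual = tables$annual, stations = tables$stations,
    daily = tables$daily, mobility = tables$mobility, outside = tables$outside,
    truth = truth, validate = FALSE
  )
  validate_bundle(bundle, mobility_tol = tol)
  bundle
}

#' Write an exposure bundle to a directory of delimited files
#'
#' Inverse of [read_study_inputs()]: values survive a write-then-read
#' round-trip at full double precision.
#'
#' @param bundle An [exposure_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "exposure_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(bundle_files)) {
    tbl <- bundle[[name]]
    if (!is.null(tbl)) {
      readr::write_csv(tbl, file.path(dir, bundle_files[[name]]), progress = FALSE)
    }
  }
  if (!is.null(bundle$truth)) {
    truth_dir <- file.path(dir, "truth")
    dir.create(truth_dir, showWarnings = FALSE)
    readr::write_csv(bundle$truth$annual, file.path(truth_dir, "annual.csv"),
                     progress = FALSE)
    readr::write_csv(bundle$truth$labels, file.path(truth_dir, "labels.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Default run configuration
#'
#' Nested list of the tunable thresholds and switches used across the
#' pipeline, serialisable to YAML via [write_run_config()].
#'
#' @return A named list of class `"cumulair_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    thresholds = list(min_completeness = 0.75, mobility_row_tol = 1e-6),
    clustering = list(k = "auto"),
    reconstruction = list(trend = "linear", max_horizon = 10L),
    latency = list(lmax = 5L, denominator = "n_terms"),
    outside = list(policy = "require_series"),
    weighting = "unweighted",
    seed = 1L
  ), class = "cumulair_config")
}

#' Read / write a run configuration file
#'
#' @param path Path of a YAML configuration file.
#' @return For `read_run_config()`, the configuration list (defaults filled
#'   in for absent keys); for `write_run_config()`, `path` invisibly.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  structure(cfg, class = "cumulair_config")
}

#' @rdname read_run_config
#' @param config A configuration list, as from [default_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
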