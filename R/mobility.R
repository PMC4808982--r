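# Mobility-weighted exposure: residence back-propagation, single-year
# weighted exposure, and cumulation over a latency window.

outside_policies <- c("require_series", "renormalize_interior",
                      "impute_area_mean")

# long mobility table -> destination x origin matrix over (units, outside).
# Row i gives the distribution of residence one period earlier for current
# residents of unit i; absent pairs carry probability 0.
mobility_matrix_wide <- function(mobility, unit_ids) {
  cols <- c(unit_ids, OUTSIDE_LABEL)
  M <- matrix(0, nrow = length(unit_ids), ncol = length(cols),
              dimnames = list(unit_ids, cols))
  M[cbind(match(mobility$dest_id, unit_ids),
          match(mobility$origin_id, cols))] <- mobility$probability
  M
}

# apply the outside policy to the destination x origin matrix
apply_outside_policy <- function(M, policy) {
  if (policy == "renormalize_interior") {
    # interior moves only: discard the outside column and rescale rows
    out_col <- ncol(M)
    interior <- M[, -out_col, drop = FALSE]
    rs <- rowSums(interior)
    if (any(rs == 0)) {
      stop_cumulair(
        sprintf("renormalize_interior: unit(s) with all mobility mass outside: %s",
                paste(rownames(M)[rs == 0], collapse = ", ")),
        "cumulair_validation_error")
    }
    M[, -out_col] <- interior / rs
    M[, out_col] <- 0
  }
  M
}

# one back-propagation step over the augmented state (units, outside);
# outside is absorbing: mass that has left the study area stays out
propagate_back <- function(dist_mat, M) {
  n_units <- nrow(M)
  interior <- dist_mat[, seq_len(n_units), drop = FALSE] %*% M
  interior[, ncol(M)] <- interior[, ncol(M)] + dist_mat[, ncol(M)]
  interior
}

# distribution matrix (focal units x state) after `steps` transitions
residence_matrix <- function(M, focal_ids, steps) {
  states <- colnames(M)
  D <- matrix(0, nrow = length(focal_ids), ncol = length(states),
              dimnames = list(focal_ids, states))
  D[cbind(seq_along(focal_ids), match(focal_ids, states))] <- 1
  if (steps > 0) for (s in seq_len(steps)) D <- propagate_back(D, M)
  D
}

mobility_steps <- function(lag, period_years) {
  # residence is held fixed within a census period; a transition is applied
  # once per completed period
  as.integer(lag %/% period_years)
}

#' Where did a unit's residents live L years ago?
#'
#' Back-propagates the residence of the current population of a focal unit
#' through the residence-transition matrix: with a census-period matrix
#' (e.g. 5-year), one transition is applied per completed period within the
#' lag, and residence is held fixed between transitions. Probability mass
#' that reaches the outside-area category stays there (no return
#' migration).
#'
#' @param mobility Mobility tibble (`dest_id`, `origin_id`, `probability`,
#'   `period_years`).
#' @param unit Focal unit id (current residence).
#' @param lag Non-negative lag in years; `lag = 0` is a point mass on
#'   `unit`.
#' @param policy Outside-area handling: `"require_series"` (keep outside
#'   mass; an outside exposure series must be supplied downstream),
#'   `"renormalize_interior"` (consider interior moves only, rescaling each
#'   row), or `"impute_area_mean"` (keep outside mass; expose it at the
#'   area mean downstream).
#' @return A tibble `location`, `probability` over the units (and
#'   [OUTSIDE_LABEL] unless renormalized) carrying positive mass; sums
#'   to 1.
#' @export
residence_distribution <- function(mobility, unit, lag,
                                   policy = outside_policies) {
  policy <- match.arg(policy)
  if (!is_count(lag)) {
    stop_cumulair("lag must be a non-negative integer", "cumulair_config_error")
  }
  unit_ids <- sort(unique(mobility$dest_id))
  if (!unit %in% unit_ids) {
    stop_cumulair(sprintf("unknown focal unit %s", unit),
                  "cumulair_reference_error")
  }
  M <- apply_outside_policy(mobility_matrix_wide(mobility, unit_ids), policy)
  steps <- mobility_steps(lag, mobility$period_years[1])
  D <- residence_matrix(M, unit, steps)
  tibble::tibble(location = colnames(D), probability = unname(D[1, ])) |>
    dplyr::filter(.data$probability > 0)
}

# exposure vector over (units, outside) states for one calendar year
state_exposures <- function(states, year, field, outside, policy,
                            need_outside) {
  vals <- field$value[match(paste(states, year),
                            paste(field$unit_id, field$year))]
  out_idx <- length(states)
  if (need_outside) {
    if (policy == "impute_area_mean") {
      vals[out_idx] <- mean(vals[-out_idx], na.rm = TRUE)
    } else {
      ov <- outside$value[match(year, outside$year)]
      if (is.null(outside) || length(ov) == 0 || is.na(ov)) {
        stop_cumulair(
          sprintf("positive outside-area probability but no outside exposure value for year %d",
                  year),
          "cumulair_reference_error")
      }
      vals[out_idx] <- ov
    }
  } else {
    vals[out_idx] <- 0    # zero mass; never contributes
  }
  vals
}

check_exposure_cells <- function(D, vals, year) {
  bad <- colSums(D > 0) > 0 & is.na(vals)
  if (any(bad)) {
    stop_cumulair(
      sprintf("missing exposure value for %s in year %d with positive residence probability",
              paste(colnames(D)[bad], collapse = ", "), year),
      "cumulair_reference_error")
  }
}

#' Mobility-weighted exposure for a single lagged year
#'
#' Computes, for each focal unit, the expectation of the annual exposure
#' field at year `year - lag` over the distribution of where the unit's
#' current residents lived `lag` years earlier: the sedentary share
#' contributes the unit's own level, intra-area movers contribute the
#' levels of their previous units, and the outside-area share contributes
#' the outside series value (per the chosen policy). The result is a convex
#' combination, so it always lies within the range of the contributing
#' exposures.
#'
#' @inheritParams residence_distribution
#' @param field Annual concentration field (`unit_id`, `year`, `value`),
#'   possibly extended with [backcast()] output; must cover `year - lag`.
#' @param year Reference calendar year.
#' @param outside Optional outside-area series (`year`, `value`); required
#'   by `policy = "require_series"` whenever outside mass is positive.
#' @param units Focal unit ids (default: all destinations in `mobility`).
#' @return A tibble `unit_id`, `year` (the lagged year `year - lag`),
#'   `lag`, `value` (ug/m3).
#' @export
weighted_exposure <- function(field, mobility, year, lag, outside = NULL,
                              policy = outside_policies, units = NULL) {
  policy <- match.arg(policy)
  unit_ids <- sort(unique(mobility$dest_id))
  focal <- units %||% unit_ids
  M <- apply_outside_policy(mobility_matrix_wide(mobility, unit_ids), policy)
  steps <- mobility_steps(lag, mobility$period_years[1])
  D <- residence_matrix(M, focal, steps)
  target_year <- as.integer(year - lag)
  need_outside <- any(D[, ncol(D)] > 0)
  vals <- state_exposures(colnames(D), target_year, field, outside, policy,
                          need_outside)
  check_exposure_cells(D, vals, target_year)
  vals[is.na(vals)] <- 0
  tibble::tibble(unit_id = focal, year = target_year, lag = as.integer(lag),
                 value = as.numeric(D %*% vals))
}

#' Cumulative exposure over a latency window, with and without mobility
#'
#' For each focal unit, averages the mobility-weighted exposures of the
#' `lmax + 1` years `ref_year - lmax, ..., ref_year` (the latency window),
#' and contrasts the result with the sedentary estimate — the plain mean of
#' the unit's own annual levels over the same window. The reported degree
#' of mobility is the percentage of current residents who lived elsewhere
#' one census period earlier, `100 * (1 - P_NN)`.
#'
#' @inheritParams weighted_exposure
#' @param ref_year Reference year `j` (the most recent year of the window).
#' @param lmax Latency `Lmax` in years; the window covers `lmax + 1` years.
#' @param denominator `"n_terms"` (default) divides the summed weighted
#'   exposures by the number of terms (`lmax + 1`), which preserves a
#'   constant field exactly; `"paper_literal"` divides by `lmax`, following
#'   the published formula verbatim (refused for `lmax = 0`).
#' @return A tibble of class `"cumulative_exposure"` with one row per
#'   focal unit: `unit_id`, `degree_of_mobility` (%),
#'   `without_mobility`, `with_mobility` (ug/m3) and
#'   `relative_difference = without_mobility - with_mobility`. Attributes
#'   record `ref_year`, `lmax`, `denominator` and `policy`.
#' @examples
#' units <- tibble::tibble(unit_id = c("A", "B"), x = c(0, 1000),
#'                         y = 0, population = c(100, 100))
#' field <- tidyr::expand_grid(unit_id = c("A", "B"), year = 2008:2012) |>
#'   dplyr::mutate(value = ifelse(unit_id == "A", 50, 30))
#' mob <- tibble::tibble(
#'   dest_id = c("A", "A", "B"), origin_id = c("A", "B", "B"),
#'   probability = c(0.8, 0.2, 1), period_years = 1L)
#' cumulative_exposure(field, mob, ref_year = 2012, lmax = 4)
#' @export
cumulative_exposure <- function(field, mobility, ref_year, lmax,
                                outside = NULL, policy = outside_policies,
                                denominator = c("n_terms", "paper_literal"),
                                units = NULL) {
  policy <- match.arg(policy)
  denominator <- match.arg(denominator)
  if (!is_count(lmax)) {
    stop_cumulair("lmax must be a non-negative integer", "cumulair_config_error")
  }
  if (denominator == "paper_literal" && lmax == 0) {
    stop_cumulair("denominator \"paper_literal\" divides by lmax and cannot be used with lmax = 0",
                  "cumulair_config_error")
  }
  unit_ids <- sort(unique(mobility$dest_id))
  focal <- units %||% unit_ids
  M <- apply_outside_policy(mobility_matrix_wide(mobility, unit_ids), policy)
  period <- mobility$period_years[1]

  # accumulate weighted terms lag by lag, advancing the residence matrix
  # only at period boundaries
  D <- residence_matrix(M, focal, 0L)
  steps_done <- 0L
  acc <- numeric(length(focal))
  for (lag in 0:lmax) {
    steps <- mobility_steps(lag, period)
    while (steps_done < steps) {
      D <- propagate_back(D, M)
      steps_done <- steps_done + 1L
    }
    target_year <- as.integer(ref_year - lag)
    need_outside <- any(D[, ncol(D)] > 0)
    vals <- state_exposures(colnames(D), target_year, field, outside, policy,
                            need_outside)
    check_exposure_cells(D, vals, target_year)
    vals[is.na(vals)] <- 0
    acc <- acc + as.numeric(D %*% vals)
  }
  denom <- if (denominator == "n_terms") lmax + 1 else lmax
  with_mob <- acc / denom

  window_years <- (ref_year - lmax):ref_year
  own <- field |>
    dplyr::filter(.data$unit_id %in% focal, .data$year %in% window_years)
  miss <- tidyr::expand_grid(unit_id = focal, year = window_years) |>
    dplyr::anti_join(dplyr::filter(own, !is.na(.data$value)),
                     by = c("unit_id", "year"))
  if (nrow(miss) > 0L) {
    stop_cumulair(
      sprintf("annual field does not cover the latency window for %s (year %d)",
              miss$unit_id[1], miss$year[1]),
      "cumulair_reference_error")
  }
  without <- own |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(without_mobility = sum(.data$value) / denom,
                     .groups = "drop")

  p_nn <- mobility$probability[match(paste(focal, focal),
                                     paste(mobility$dest_id,
                                           mobility$origin_id))]
  p_nn[is.na(p_nn)] <- 0

  out <- tibble::tibble(unit_id = focal,
                        degree_of_mobility = 100 * (1 - p_nn),
                        with_mobility = with_mob) |>
    dplyr::left_join(without, by = "unit_id") |>
    dplyr::mutate(relative_difference =
                    .data$without_mobility - .data$with_mobility) |>
    dplyr::select("unit_id", "degree_of_mobility", "without_mobility",
                  "with_mobility", "relative_difference")
  new_cumulair_tbl(out, "cumulative_exposure",
                   ref_year = as.integer(ref_year), lmax = as.integer(lmax),
                   denominator = denominator, policy = policy)
}

#' Area-level exposure report, ranked by mobility intensity
#'
#' Arranges per-unit cumulative-exposure results into the standard
#' reporting shape: one row per unit (or per area, when the unit registry
#' carries an `area` column), sorted by descending degree of mobility.
#' Area aggregates average the unit values either unweighted or weighted
#' by unit population.
#'
#' @param results A `"cumulative_exposure"` tibble from
#'   [cumulative_exposure()] (or any tibble with the same columns).
#' @param units Optional unit registry; needed for `weighting =
#'   "population"` and for area aggregation (via an `area` column).
#' @param weighting `"unweighted"` (default) or `"population"`.
#' @return A tibble with columns `unit_id` (or `area`),
#'   `degree_of_mobility`, `without_mobility`, `with_mobility`,
#'   `relative_difference`, sorted by descending degree of mobility.
#' @export
area_report <- function(results, units = NULL,
                        weighting = c("unweighted", "population")) {
  weighting <- match.arg(weighting)
  cols <- c("degree_of_mobility", "without_mobility", "with_mobility",
            "relative_difference")
  check_columns(results, c("unit_id", cols), "results")
  if (weighting == "population" || (!is.null(units) && "area" %in% names(units))) {
    if (is.null(units)) {
      stop_cumulair("population weighting needs the unit registry",
                    "cumulair_config_error")
    }
    results <- dplyr::inner_join(
      results, dplyr::select(units, "unit_id",
                             dplyr::any_of(c("population", "area"))),
      by = "unit_id")
  }
  if ("area" %in% names(results)) {
    w <- if (weighting == "population") rlang::sym("population") else NULL
    results <- results |>
      dplyr::group_by(.data$area) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(cols),
        ~ if (weighting == "population") {
          stats::weighted.mean(.x, w = population)
        } else mean(.x)), .groups = "drop")
  }
  dplyr::arrange(results, dplyr::desc(.data$degree_of_mobility)) |>
    dplyr::select(dplyr::any_of(c("unit_id", "area")), dplyr::all_of(cols))
}
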