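# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's internal computation paths:
# the clustering oracle recomputes average linkage from the original
# distance matrix at every step, and the exposure oracle enumerates
# residence histories exhaustively.

# ---- fixture builders -------------------------------------------------------

# daily series of one station with a constant or per-day value vector
make_daily <- function(station_id, year, values) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  tibble::tibble(station_id = station_id, date = dates,
                 value = rep_len(values, length(dates)))
}

toy_units <- function(ids, x = seq_along(ids), y = 0, population = 100) {
  tibble::tibble(unit_id = ids, x = x, y = y, population = population)
}

# long annual field from a units x years value matrix
field_from_matrix <- function(values, unit_ids, years) {
  tidyr::expand_grid(unit_id = unit_ids, year = years) |>
    dplyr::mutate(value = as.vector(t(values)))
}

# long mobility table from a dest x origin matrix (cols may include outside)
mobility_from_matrix <- function(M, period_years = 1L) {
  tibble::as_tibble(M, rownames = "dest_id") |>
    tidyr::pivot_longer(-"dest_id", names_to = "origin_id",
                        values_to = "probability") |>
    dplyr::filter(.data$probability > 0 | .data$dest_id == .data$origin_id) |>
    dplyr::mutate(period_years = as.integer(period_years))
}

# random row-stochastic dest x origin matrix over n units (+ outside share)
random_mobility_matrix <- function(n, outside_share = 0, concentration = 1) {
  ids <- sprintf("U%02d", seq_len(n))
  M <- matrix(stats::rgamma(n * n, concentration), n, n)
  M <- M / rowSums(M) * (1 - outside_share)
  M <- cbind(M, rep(outside_share, n))
  dimnames(M) <- list(ids, c(ids, cumulair::OUTSIDE_LABEL))
  M
}

well_separated_spec <- function(seed, n_units = 12, n_stations = 6,
                                daily_noise_sd = 0.05) {
  simulation_spec(n_units = n_units, n_stations = n_stations,
                  n_clusters_true = 3,
                  trend_slopes = c(0.85, 0.97, 1.10),
                  daily_noise_sd = daily_noise_sd, rng_seed = seed)
}

noiseless_spec <- function(seed, ...) {
  simulation_spec(daily_noise_sd = 0, seasonal_amplitude = 0,
                  rng_seed = seed, ...)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# ARI between recovered and true labels for a clustered bundle
cluster_recovery_ari <- function(bundle, k = 3) {
  cl <- cluster_profiles(build_features(bundle$annual, bundle$daily), k = k)
  lab <- tidy(cl)
  tr <- bundle$truth$labels
  ari(lab$cluster, tr$cluster[match(lab$entity_id, tr$entity_id)])
}

# ---- brute-force average-linkage oracle -------------------------------------

# At every step, the distance between two clusters is recomputed from the
# original distance matrix as the mean over all cross pairs (no
# Lance-Williams update). Ties break on the lexicographically smallest
# (sorted) pair of smallest member labels. Returns per-step member sets
# (sorted label vectors) and heights.
brute_average_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(seq_len(nrow(D)))
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(D[clusters[[a]], clusters[[b]]])
        ra <- min(labels[clusters[[a]]]); rb <- min(labels[clusters[[b]]])
        key <- c(min(ra, rb), max(ra, rb))
        if (is.null(best) || h < best$h - 1e-15 ||
            (abs(h - best$h) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(a = a, b = b, h = h, key = key)
        }
      }
    }
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    merges[[length(merges) + 1L]] <- sort(labels[merged])
    heights <- c(heights, best$h)
    clusters <- c(clusters[-c(best$a, best$b)], list(merged))
  }
  list(members = merges, heights = heights)
}

# member sets per merge step of an hclust-style tree
tree_member_sets <- function(tree) {
  out <- vector("list", nrow(tree$merge))
  get <- function(id) if (id < 0) tree$labels[-id] else out[[id]]
  for (s in seq_len(nrow(tree$merge))) {
    out[[s]] <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
  }
  out
}

# ---- residence-path enumeration oracle --------------------------------------

# Exhaustively enumerates residence histories over the augmented state
# space (units + outside, with outside absorbing) and averages exposures
# over paths weighted by their probabilities. M is the dest x origin
# matrix including the outside column.
enumerate_weighted_exposure <- function(M, focal, lag, year, field,
                                        outside_values = NULL,
                                        period_years = 1) {
  states <- colnames(M)
  Tm <- rbind(M, 0)
  rownames(Tm) <- states
  Tm[length(states), length(states)] <- 1   # outside absorbs
  steps <- lag %/% period_years
  exposure_at <- function(state, yr) {
    if (state == cumulair::OUTSIDE_LABEL) {
      outside_values[[as.character(yr)]]
    } else {
      field$value[field$unit_id == state & field$year == yr]
    }
  }
  target_year <- year - lag
  if (steps == 0) return(exposure_at(focal, target_year))
  paths <- expand.grid(rep(list(states), steps), stringsAsFactors = FALSE)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    seqn <- c(focal, unlist(paths[r, ], use.names = FALSE))
    p <- 1
    for (s in seq_len(steps)) p <- p * Tm[seqn[s], seqn[s + 1]]
    if (p > 0) total <- total + p * exposure_at(seqn[steps + 1], target_year)
  }
  total
}

enumerate_cumulative <- function(M, focal, ref_year, lmax, field,
                                 outside_values = NULL, period_years = 1,
                                 denom = lmax + 1) {
  terms <- vapply(0:lmax, function(l) {
    enumerate_weighted_exposure(M, focal, l, ref_year, field,
                                outside_values, period_years)
  }, numeric(1))
  sum(terms) / denom
}
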