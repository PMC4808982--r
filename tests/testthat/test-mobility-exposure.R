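# Residence back-propagation, weighted and cumulative exposure, reporting.

test_that("residence distribution base cases: L = 0 and identity matrix", {
  M <- random_mobility_matrix(3)
  mob <- mobility_from_matrix(M)
  d0 <- residence_distribution(mob, "U01", 0)
  expect_equal(d0$location, "U01")
  expect_equal(d0$probability, 1)

  ident <- tibble::tibble(dest_id = c("A", "B"), origin_id = c("A", "B"),
                          probability = 1, period_years = 1L)
  for (L in c(0, 1, 3, 7)) {
    d <- residence_distribution(ident, "A", L)
    expect_equal(d$location, "A")
    expect_equal(d$probability, 1)
  }
})

test_that("two-step back-propagation matches the hand-worked two-unit chain", {
  # N keeps 0.8 and draws 0.2 from U; U keeps 0.5 and draws 0.5 from N
  mob <- tibble::tibble(
    dest_id = c("N", "N", "U", "U"),
    origin_id = c("N", "U", "U", "N"),
    probability = c(0.8, 0.2, 0.5, 0.5),
    period_years = 1L)
  d <- residence_distribution(mob, "N", 2)
  expect_equal(d$probability[d$location == "N"], 0.74, tolerance = 1e-12)
  expect_equal(d$probability[d$location == "U"], 0.26, tolerance = 1e-12)
})

test_that("distributions stay stochastic and outside mass is absorbing", {
  withr::with_seed(5, {
    for (trial in 1:20) {
      n <- sample(2:5, 1)
      M <- random_mobility_matrix(n, outside_share = runif(1, 0.05, 0.4))
      mob <- mobility_from_matrix(M)
      masses <- vapply(0:5, function(L) {
        d <- residence_distribution(mob, rownames(M)[1], L)
        expect_equal(sum(d$probability), 1, tolerance = 1e-12)
        sum(d$probability[d$location == OUTSIDE_LABEL])
      }, numeric(1))
      expect_true(all(diff(masses) >= -1e-12))  # never returns from outside
    }
  })
})

test_that("weighted exposure is the stated convex combination", {
  # E = (10, 20), distribution (0.8, 0.2) -> 12
  field <- field_from_matrix(rbind(c(10), c(20)), c("A", "B"), 2010L)
  mob <- tibble::tibble(
    dest_id = c("A", "A", "B"), origin_id = c("A", "B", "B"),
    probability = c(0.8, 0.2, 1), period_years = 1L)
  w <- weighted_exposure(field, mob, year = 2011, lag = 1, units = "A")
  expect_equal(w$value, 12, tolerance = 1e-12)
  expect_equal(w$year, 2010L)

  # identity mobility passes the unit's own lagged value through
  ident <- tibble::tibble(dest_id = c("A", "B"), origin_id = c("A", "B"),
                          probability = 1, period_years = 1L)
  f2 <- field_from_matrix(cbind(c(10, 20), c(30, 40)), c("A", "B"),
                          2009:2010)
  w2 <- weighted_exposure(f2, ident, year = 2010, lag = 1)
  expect_equal(w2$value, c(10, 20))
})

test_that("a constant field is conserved and results stay within convex bounds", {
  withr::with_seed(11, {
    years <- 2000:2012
    for (trial in 1:20) {
      n <- sample(2:5, 1)
      M <- random_mobility_matrix(n)
      mob <- mobility_from_matrix(M)
      ids <- rownames(M)
      cfield <- tidyr::expand_grid(unit_id = ids, year = years) |>
        dplyr::mutate(value = 42.5)
      ce <- cumulative_exposure(cfield, mob, ref_year = 2012,
                                lmax = sample(0:6, 1))
      expect_equal(ce$with_mobility, rep(42.5, n), tolerance = 1e-12)
      expect_equal(ce$relative_difference, rep(0, n), tolerance = 1e-12)

      # convexity on a heterogeneous field
      vfield <- tidyr::expand_grid(unit_id = ids, year = years) |>
        dplyr::mutate(value = runif(dplyr::n(), 10, 90))
      lag <- sample(0:4, 1)
      w <- weighted_exposure(vfield, mob, year = 2012, lag = lag)
      rng <- range(vfield$value[vfield$year == 2012 - lag])
      expect_true(all(w$value >= rng[1] - 1e-12 & w$value <= rng[2] + 1e-12))
    }
  })
})

test_that("identity mobility makes the with/without contrast vanish", {
  withr::with_seed(3, {
    for (trial in 1:10) {
      n <- sample(1:5, 1)
      ids <- sprintf("U%02d", seq_len(n))
      ident <- tibble::tibble(dest_id = ids, origin_id = ids,
                              probability = 1, period_years = 1L)
      field <- tidyr::expand_grid(unit_id = ids, year = 2005:2012) |>
        dplyr::mutate(value = runif(dplyr::n(), 20, 80))
      ce <- cumulative_exposure(field, ident, ref_year = 2012,
                                lmax = sample(0:7, 1))
      expect_equal(ce$with_mobility, ce$without_mobility, tolerance = 1e-12)
      expect_equal(ce$degree_of_mobility, rep(0, n))
    }
  })
})

test_that("recursive computation equals exhaustive path enumeration", {
  withr::with_seed(2024, {
    for (trial in 1:50) {
      n <- sample(2:4, 1)
      out_share <- sample(c(0, runif(1, 0, 0.3)), 1)
      M <- random_mobility_matrix(n, outside_share = out_share)
      mob <- mobility_from_matrix(M)
      ids <- rownames(M)
      years <- 2006:2012
      field <- tidyr::expand_grid(unit_id = ids, year = years) |>
        dplyr::mutate(value = runif(dplyr::n(), 15, 85))
      outside <- tibble::tibble(year = years,
                                value = runif(length(years), 10, 30))
      out_vals <- setNames(as.list(outside$value), outside$year)
      lmax <- sample(0:4, 1)
      ce <- cumulative_exposure(field, mob, ref_year = 2012, lmax = lmax,
                                outside = outside)
      for (focal in ids) {
        oracle <- enumerate_cumulative(M, focal, 2012, lmax, field, out_vals)
        expect_equal(ce$with_mobility[ce$unit_id == focal], oracle,
                     tolerance = 1e-12)
      }
      # single lag as well
      lag <- sample(0:4, 1)
      w <- weighted_exposure(field, mob, year = 2012, lag = lag,
                             outside = outside)
      for (focal in ids) {
        oracle <- enumerate_weighted_exposure(M, focal, lag, 2012, field,
                                              out_vals)
        expect_equal(w$value[w$unit_id == focal], oracle, tolerance = 1e-12)
      }
    }
  })
})

test_that("census-period matrices transition once per completed period", {
  mob <- tibble::tibble(
    dest_id = c("A", "A", "B", "B"), origin_id = c("A", "B", "B", "A"),
    probability = c(0.7, 0.3, 0.9, 0.1), period_years = 5L)
  # lags within the first period keep residence fixed
  for (L in 0:4) {
    d <- residence_distribution(mob, "A", L)
    expect_equal(d$probability[d$location == "A"], 1)
  }
  d5 <- residence_distribution(mob, "A", 5)
  expect_equal(d5$probability[d5$location == "A"], 0.7)
  expect_equal(d5$probability[d5$location == "B"], 0.3)
  # after two periods, mass at B propagates through B's row (P(A|B) = 0.1)
  d10 <- residence_distribution(mob, "A", 10)
  expect_equal(d10$probability[d10$location == "A"],
               0.7 * 0.7 + 0.3 * 0.1, tolerance = 1e-12)
})

test_that("outside-area policies behave as documented", {
  M <- rbind(c(0.6, 0.2, 0.2), c(0.1, 0.8, 0.1))
  dimnames(M) <- list(c("A", "B"), c("A", "B", OUTSIDE_LABEL))
  mob <- mobility_from_matrix(M)
  field <- tidyr::expand_grid(unit_id = c("A", "B"), year = 2010:2012) |>
    dplyr::mutate(value = ifelse(unit_id == "A", 60, 30))

  # require_series with no outside table -> error naming the year
  expect_error(
    weighted_exposure(field, mob, year = 2012, lag = 1, units = "A"),
    class = "cumulair_reference_error")

  # with the series, outside mass contributes its value
  outside <- tibble::tibble(year = 2010:2012, value = 20)
  w <- weighted_exposure(field, mob, year = 2012, lag = 1, outside = outside,
                         units = "A")
  expect_equal(w$value, 0.6 * 60 + 0.2 * 30 + 0.2 * 20, tolerance = 1e-12)

  # renormalize_interior reproduces the interior-only illustration
  w_ren <- weighted_exposure(field, mob, year = 2012, lag = 1,
                             policy = "renormalize_interior", units = "A")
  expect_equal(w_ren$value, (0.6 * 60 + 0.2 * 30) / 0.8, tolerance = 1e-12)

  # impute_area_mean exposes outside mass at the area mean
  w_imp <- weighted_exposure(field, mob, year = 2012, lag = 1,
                             policy = "impute_area_mean", units = "A")
  expect_equal(w_imp$value, 0.6 * 60 + 0.2 * 30 + 0.2 * 45, tolerance = 1e-12)
})

test_that("latency-window edge cases behave per contract", {
  ids <- c("A", "B")
  mob <- tibble::tibble(dest_id = c("A", "A", "B"),
                        origin_id = c("A", "B", "B"),
                        probability = c(0.9, 0.1, 1), period_years = 1L)
  field <- tidyr::expand_grid(unit_id = ids, year = 2010:2012) |>
    dplyr::mutate(value = ifelse(unit_id == "A", 50, 30))

  # Lmax = 0: with = without = the unit's own value in the reference year
  ce0 <- cumulative_exposure(field, mob, ref_year = 2012, lmax = 0)
  expect_equal(ce0$with_mobility, c(50, 30))
  expect_equal(ce0$without_mobility, c(50, 30))

  # literal published denominator divides by Lmax and refuses Lmax = 0
  ce_lit <- cumulative_exposure(field, mob, ref_year = 2012, lmax = 2,
                                denominator = "paper_literal")
  ce_def <- cumulative_exposure(field, mob, ref_year = 2012, lmax = 2)
  expect_equal(ce_lit$with_mobility, ce_def$with_mobility * 3 / 2,
               tolerance = 1e-12)
  expect_error(cumulative_exposure(field, mob, ref_year = 2012, lmax = 0,
                                   denominator = "paper_literal"),
               class = "cumulair_config_error")

  # window not covered by the field -> reference error naming the gap
  expect_error(cumulative_exposure(field, mob, ref_year = 2012, lmax = 5),
               class = "cumulair_reference_error")
})

test_that("area report ranks by mobility and handles the degenerate single unit", {
  mob1 <- tibble::tibble(dest_id = "A", origin_id = c("A", OUTSIDE_LABEL),
                         probability = c(0.85, 0.15), period_years = 5L)
  field1 <- tibble::tibble(unit_id = "A", year = 2008:2012, value = 50)
  outside <- tibble::tibble(year = 2008:2012, value = 20)
  ce1 <- cumulative_exposure(field1, mob1, ref_year = 2012, lmax = 4,
                             outside = outside)
  rep1 <- area_report(ce1)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$degree_of_mobility, 100 * (1 - 0.85), tolerance = 1e-12)

  # ranking: descending degree of mobility
  res <- tibble::tibble(
    unit_id = c("A", "B", "C"), degree_of_mobility = c(5, 25, 15),
    without_mobility = c(50, 40, 45), with_mobility = c(49, 35, 43),
    relative_difference = c(1, 5, 2))
  rep3 <- area_report(res)
  expect_equal(rep3$unit_id, c("B", "C", "A"))

  # population weighting aggregates areas by population
  units <- toy_units(c("A", "B", "C")) |>
    dplyr::mutate(population = c(100, 300, 100), area = c("a1", "a1", "a2"))
  repw <- area_report(res, units, weighting = "population")
  expect_equal(repw$relative_difference[repw$area == "a1"],
               (1 * 100 + 5 * 300) / 400, tolerance = 1e-12)
})

test_that("movers from lower-exposure origins always depress the estimate", {
  # exposure decreases with unit index; every unit's movers come from
  # strictly lower-exposure units (higher index)
  withr::with_seed(6, {
    n <- 5
    ids <- sprintf("U%02d", 1:n)
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in 1:n) {
      stay <- runif(1, 0.6, 0.9)
      M[i, i] <- stay
      lower <- if (i < n) (i + 1):n else i  # last unit: sedentary
      if (i < n) M[i, lower] <- (1 - stay) / length(lower) else M[i, i] <- 1
    }
    M <- cbind(M, 0); colnames(M)[n + 1] <- OUTSIDE_LABEL
    mob <- mobility_from_matrix(M)
    field <- tidyr::expand_grid(unit_id = ids, year = 2006:2012) |>
      dplyr::mutate(value = 80 - 10 * as.integer(substr(unit_id, 2, 3)))
    ce <- cumulative_exposure(field, mob, ref_year = 2012, lmax = 4)
    movers <- ce$degree_of_mobility > 0
    expect_true(all(ce$with_mobility[movers] < ce$without_mobility[movers]))
    expect_true(all(ce$relative_difference[movers] > 0))
  })
})

test_that("published arrondissement rows satisfy the arithmetic contract", {
  tab <- paris_arrondissement_exposure()
  recomputed <- tab$without_mobility - tab$with_mobility
  expect_true(all(abs(recomputed - tab$relative_difference) <= 0.01 + 1e-12))
  for (arr in c(15, 17, 14)) {
    row <- tab[tab$arrondissement == arr, ]
    expect_lt(abs(row$without_mobility - row$with_mobility -
                    row$relative_difference), 1e-3)
  }
  # ranked by descending mobility, 19.0 down to 8.8
  expect_equal(tab$degree_of_mobility,
               sort(tab$degree_of_mobility, decreasing = TRUE))
  expect_equal(area_report(dplyr::rename(tab, unit_id = "arrondissement")),
               dplyr::rename(tab, unit_id = "arrondissement") |>
                 dplyr::mutate(unit_id = unit_id))
  # the mobility-aware estimate is lower everywhere, increasingly so with
  # the degree of mobility
  expect_true(all(tab$with_mobility < tab$without_mobility))
  expect_gt(cor(tab$degree_of_mobility, tab$relative_difference,
                method = "spearman"), 0)
})
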