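# cumulair

Cumulative air-pollution exposure assessment at a fine spatial scale, with
residential mobility.

## The problem

Epidemiological studies of long-term pollutant effects (cancer,
cardiovascular disease) need each subject's *cumulative* exposure over a
latency window of 5–20 years. Two things make that hard at a fine spatial
scale such as the French census block (IRIS):

1. **Retrospective reconstruction.** Modelled unit-level annual
   concentrations typically exist only for a recent period; earlier years
   must be reconstructed from the long series of fixed monitoring stations.
2. **Residential mobility.** People move. Assigning a unit's current
   concentration history to its current residents misclassifies the
   exposure of everyone who lived elsewhere during the window.

`cumulair` implements a complete workflow for both, plus a synthetic-data
generator that emulates the assumed data regime so every stage can be
validated without proprietary monitoring or census data.

## The model

**Index monitors.** Spatial units and monitoring stations are clustered by
hierarchical agglomerative clustering (correlation distance `1 − r` on
standardized annual profiles, average linkage, deterministic tie-breaks).
Within its cluster, each unit is assigned the spatially nearest station —
its *index monitor*.

**Backcasting.** Per series, a log-linear trend
`log C(y) = α + β y` is fitted by OLS. Each unit is calibrated on its
index monitor, `log E_N(y) = a_N + b_N log S_m(y)`, over the overlapping
years, and pre-period unit levels are reconstructed as
`Ê_N(y) = exp(a_N + b_N log S_m(y))`, with `S_m(y)` observed or
trend-extrapolated. A hold-out scheme (`holdout_validate()`) refits with a
block of observed years withheld and reports bias, MARE and RMSE against
the withheld values.

**Mobility weighting.** A census mobility matrix gives
`P(origin i | current residence N)` per inter-census period, including an
absorbing outside-area category `C`. The single-year weighted exposure is

    W[E(j−L)] = Σ_i P_iN(L) · E_i(j−L),

where `P_·N(L)` back-propagates residence one matrix application per
completed period, and the cumulative exposure over latency `Lmax` is

    Cumul[E_N] = Σ_{L=0..Lmax} W[E(j−L)] / (Lmax + 1),

contrasted with the sedentary estimate (the unit's own mean over the same
window). The *degree of mobility* is `100·(1 − P_NN)` %.

## Worked example

```r
library(cumulair)

b      <- simulate_area(simulation_spec(rng_seed = 42))  # 40 units, 9 monitors
feats  <- build_features(b$annual, b$daily)
cl     <- cluster_profiles(feats, k = 3)
glance(cl)
#>       k n_entities n_units n_stations mean_silhouette
#> 1     3         49      40          9           0.906

imap   <- assign_index(cl, b$units, b$stations)
sa     <- annualize(b$daily)
trends <- fit_trends(dplyr::rename(sa, series_id = station_id))
calib  <- calibrate_units(b$annual, sa, imap)
glance(calib)
#>   n_units n_ratio_fallback median_b median_r_squared median_sigma
#> 1      40                0    0.998            0.979      0.00510

rec    <- backcast(calib, sa, 1997:2001, trends = trends)
field  <- dplyr::bind_rows(b$annual, rec[, c("unit_id", "year", "value")])
ce     <- cumulative_exposure(field, b$mobility, ref_year = 2002, lmax = 5,
                              outside = b$outside)
head(area_report(ce), 3)
#>   unit_id degree_of_mobility without_mobility with_mobility relative_difference
#> 1 U009                  20.5             60.5          60.5              0.0646
#> 2 U024                  20.2             50.9          51.2             -0.237
#> 3 U007                  20.1             58.0          57.9              0.152
```

The clustering recovers the three planted trend groups (silhouette 0.91);
the calibrations sit near `b = 1` with high R², as expected when a unit
shares its monitor's dynamics up to a multiplicative offset; and the
report ranks units by their degree of mobility, contrasting the cumulative
1997–2002 exposure with and without residence changes. In this randomly
mixed area the differences are small and of both signs — directional bias
appears only when movers systematically originate from cleaner (or
dirtier) units, which is the situation the method exists to correct.

Reconstruction error can be quantified on observed years:

```r
glance(holdout_validate(b, 2002:2004, index_map = imap))
#>   n_units n_cells   bias    mare  rmse
#> 1      40     120 -0.206 0.00383 0.346
```

A reference table of published arrondissement-level cumulative NO₂
estimates for Paris (5-year window, interior moves only) ships with the
package: `paris_arrondissement_exposure()`.

A command-line front end wrapping these functions is installed at
`system.file("exec", "cumulair", package = "cumulair")` with verbs
`simulate`, `cluster`, `reconstruct`, `cumexp` and `report`.

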