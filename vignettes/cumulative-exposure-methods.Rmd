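---
title: "Methods: retrospective reconstruction and mobility-weighted cumulative exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective reconstruction and mobility-weighted cumulative exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumulair)
```

`cumulair` assesses cumulative long-term exposure to an air pollutant
(NO~2~ is the motivating case) at a fine spatial scale, for semi-ecological
epidemiological designs in which health outcomes are individual but
exposure is assigned at the level of a small spatial unit such as a census
block. This vignette is the package's own account of the statistical
choices made, their assumptions, and what the validation suite does and
does not demonstrate.

## 1. The estimation problem

For a unit *N*, a reference year *j*, and a disease latency *L*~max~, the
target is the average exposure its current residents actually accumulated
over years *j − L*~max~ … *j*. Two gaps separate this target from the data
typically available:

* modelled unit-level annual means exist only for a recent window (the
  *modelled period*, e.g. 2002–2012), while the latency window may reach
  earlier years; and
* residents of *N* in year *j* may have lived elsewhere during the window.

The pipeline therefore has three stages: (i) group units with the
monitoring stations whose long daily series best track them ("index"
monitors); (ii) backcast unit-level annual means through those monitors;
(iii) weight each lagged year's exposure field by the distribution of
prior residence implied by census mobility matrices.

## 2. Station assignment

**Feature space.** Stations and units live on different temporal supports
(daily vs annual), so both are expressed as annual series: units directly
from the annual field, stations via `annualize()`, which requires at least
`min_completeness` (default 0.75, a common monitoring-network data-capture
convention) of calendar days before an annual mean is accepted. Each
entity's series over the years shared by all entities is standardized to
zero mean and unit variance. Standardization makes the comparison about
temporal *shape*: a traffic station measuring at twice a unit's level but
moving in lockstep with it is a perfect index monitor, and observed
station means in dense networks do span ranges as wide as roughly
40–100 µg/m³.

**Distance and linkage.** Profiles are compared by correlation distance
(1 − Pearson *r*) under average-linkage agglomeration. The agglomeration
is implemented directly (not via `stats::hclust`) because the assignment
contract demands determinism under input permutation: entities are sorted
canonically before any distance is computed, and merge ties are broken by
the lexicographically smallest entity id in the candidate clusters. A test
verifies exact agreement with `stats::hclust` on tie-free data and with a
brute-force all-pairs scan on small problems. A caveat inherent to this
geometry: two clusters whose trends decline at different rates are still
strongly correlated (both are near-monotone), so correlation distance
resolves opposite-trend groups much more sharply than same-direction
groups. Consequences: recovery of same-direction clusters relies on their
within-cluster dispersion being very small, and the automatic choice of
*k* (maximum mean silhouette over *k* ∈ 2…min(10, *n* − 1), smallest *k*
on ties) tends to undercount same-direction subgroups. `k` is therefore
user-settable and the silhouette default is a convenience, not an
inference.

**Index monitor.** Within each cluster, every unit takes the spatially
nearest station (planar Euclidean distance; coordinates are assumed to be
in metres in a common projection — no CRS handling is attempted, since
distance comparison is the only spatial operation). Exact ties resolve to
the lexicographically smallest station id and are reported. A cluster
containing units but no station is an error rather than a silent fallback:
such units have no defensible index monitor and the user must either
lower *k* or supply an assignment.

**Constant profiles** cannot be standardized; they are excluded with a
warning and recorded on the feature object rather than silently dropped.

## 3. Retrospective reconstruction

**Trend family.** Per-series OLS of log concentration on calendar year.
The log scale keeps every back-transformed concentration positive and
turns the smooth multi-year decline seen in dense urban NO~2~ records into
an approximately linear signal. Years are centred at the first fitted year
so the intercept is interpretable as the log level there. An optional
quadratic term (`trend = "quadratic"`, default off) accommodates units
whose trajectories visibly bend; such non-linear unit behaviour within a
cluster is exactly why the calibration below is per-unit rather than
per-cluster.

**Calibration.** The reconstruction couples a unit-level component to a
monitor-level component: per unit, OLS of log unit annual mean on log
index-monitor annual mean over the overlap years,
`log E_N(y) = a_N + b_N log S_m(y)`. This formalises "weight the unit's
annual average by the monitor's temporal coefficient" in a way that (a)
reduces to constant-ratio scaling when `b = 1`, (b) is multiplicative, so
no negative concentrations can be produced, and (c) is exactly invertible,
which makes the noiseless-recovery test sharp. The alternative pure
slope-ratio reading is recovered as the degenerate case: if the monitor is
constant over the overlap, `b` is not identifiable and the fit falls back
to the ratio model (`b = 1`, `a` = mean log ratio), flagged in the output.

**Backcasting.** `Ê_N(y) = exp(a_N + b_N log S_m(y))` for target years,
with `S_m(y)` taken from observed annualized values where available and
otherwise extrapolated from the station's fitted trend. Extrapolation is
refused beyond `max_horizon` years (default 10) before the first observed
station year: a decade is the farthest the log-linear assumption is worth
carrying, even though latency ambitions may reach twenty years. The
per-cell uncertainty column carries the calibration residual SD on the log
scale (a multiplicative one-sigma band); trend-extrapolation uncertainty
in `S_m(y)` is *not* propagated and the band should be read as a lower
bound on reconstruction uncertainty.

**Hold-out validation.** `holdout_validate()` rehearses the pre-period
case on observed years: it truncates all inputs to the non-withheld years,
refits everything (including, by default, the clustering), backcasts the
withheld years through trend extrapolation alone, and reports per-unit and
pooled bias, mean absolute relative error (MARE) and RMSE. At least three
fit years must remain. This is the package's honest error meter: on
noiseless synthetic data it returns zeros to numerical precision, and its
error grows monotonically with injected daily noise.

## 4. Mobility-weighted cumulation

**Matrix semantics.** Mobility tables are destination-indexed: the row of
unit *N* is the probability distribution of residence one census period
earlier for current residents of *N*, including a reserved outside-area
origin. Rows must sum to 1 (file tolerance 10^−6^; generated matrices are
exact to 10^−12^).

**Back-propagation.** Residence *L* years before *j* is obtained by
applying the matrix once per *completed* census period
(`floor(L / period_years)` applications), holding residence fixed within a
period. With an annual matrix this is one application per year. Computing
an annual root of a 5-year matrix was deliberately rejected: matrix roots
of stochastic matrices need not be stochastic, and inventing sub-period
moves adds no information the census does not contain. The outside state
is absorbing — census tables describe inflows to the study area, not
return migration; this is a documented limitation, not a modelling claim.

**Outside-area policies.** `require_series` (default) demands an annual
outside exposure series whenever outside mass is positive — refusing to
guess. `renormalize_interior` reproduces the interior-moves-only
illustration by rescaling each row over interior origins.
`impute_area_mean` prices outside residence at the study-area mean of that
year. The choice is exposed rather than fixed because the right answer
depends on what the outside area actually is (rural hinterland vs another
conurbation).

**Cumulation and the denominator.** The cumulative estimate averages the
`L`~max~ + 1 weighted terms. The source formulation divides the sum of
`L`~max~ + 1 terms by `L`~max~; taken literally this fails the most basic
sanity check — a field constant at *c* would not cumulate to *c*. The
default therefore divides by the number of terms, and
`denominator = "paper_literal"` retains the literal reading for
comparability (refused at `L`~max~ = 0). The same denominator is applied
to the without-mobility mean so that the with/without contrast is never an
artefact of the normalisation.

**Reporting.** `area_report()` emits the standard four-column contrast
(degree of mobility `100·(1 − P_NN)` %, cumulative exposure without and
with mobility, and their difference), ranked by descending mobility.
Whether multi-unit area aggregates should be population-weighted is not
settled by the source material; it is a `weighting` switch (default
unweighted) rather than a hidden assumption. The bundled
`paris_arrondissement_exposure()` table carries the published 20-row
example as printed; its text summary elsewhere states a maximum difference
of 5.6 µg/m³ while the printed rows reach 5.91 — the package carries the
table and leaves the discrepancy to the reader.

## 5. The synthetic-data generator

`simulate_area()` draws bundles from the generative model the pipeline
assumes, so that recovery tests have known ground truth:

* cluster annual levels follow exact log-linear trends
  (`base_level` × `trend_slopes[c]`^(y − y₀)^), with multiplicative
  unit offsets (log-SD `unit_level_spread`) — by construction the
  between-unit spread can dominate the within-unit temporal range, which
  is the regime in which fine-scale assignment matters at all;
* station daily series are their cluster's annual level × an annual
  sinusoid (relative amplitude `seasonal_amplitude`) × mean-one lognormal
  daily noise (log-SD `daily_noise_sd`); traffic stations sit ~70% above
  background at identical dynamics;
* mobility rows keep `1 − mobility_intensity` (jittered per unit) on the
  diagonal, send `outside_fraction` of the moving mass outside, and spread
  the rest over interior units by inverse centroid distance — spatially
  plausible short-range moves without gravity-model machinery.

Defaults describe a Paris-like NO~2~ regime: 40 units and 9 monitors over
2002–2012 with five hidden years (1997–2001), base level 55 µg/m³, slopes
{0.96, 0.99, 1.03}, unit spread 0.15, seasonal amplitude 0.25, daily noise
0.10, 15% per-5-year mobility with 5% of moves from outside. These sizes
(and the test-suite settings built on them: 8–12 units for repeated-seed
studies, 50 seeds for recovery rates, 20 seeds per noise level for the
hold-out curve) are the package's chosen study conditions.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: spatially correlated concentration fields
(unit offsets are independent), non-log-linear trends (real urban series
bend), monitor relocation and missingness patterns, measurement error in
the annual field itself (the generator's unit field is noiseless by
construction; only stations carry noise), age- or cohort-structured
mobility, and return migration. The noiseless-recovery results say the
implementation is faithful to its model class, not that the model class is
faithful to any particular city.

## 6. Numerical contracts

* All concentrations are µg/m³ throughout; no unit conversion layer.
* Concentrations must be strictly positive; missing cells are explicit
  `NA`s, never zeros, and any cell with positive residence probability
  that is missing raises an error naming unit and year.
* Weighted exposures are convex combinations and are tested to stay within
  the range of contributing exposures to 10^−12^.
* The recursion/enumeration agreement, constant-field conservation and
  identity-mobility equivalence are all asserted at 10^−12^; noiseless
  reconstruction recovery at 10^−9^ MARE.
* File round-trips are lossless: doubles are written at shortest
  round-trippable precision and re-parsed through base R's correctly
  rounded reader.
* Determinism: a fixed generator seed reproduces byte-identical files;
  clustering and assignment are invariant to input row order; all ties
  (merge heights, station distances, silhouette over *k*) break by
  documented deterministic rules.

## 7. Known limitations

Beyond the generator gaps above: the calibration transfers a monitor's
*temporal* pattern and cannot recover unit-specific shocks (a new road,
construction) absent from its monitor; uncertainty from trend
extrapolation of the monitor itself is unquantified; the mobility
correction operates at whatever spatial scale the census matrix offers,
which may be coarser than the exposure field; and the degree-of-mobility
summary collapses a full origin distribution to its diagonal, which can
understate heterogeneous mobility structures.
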