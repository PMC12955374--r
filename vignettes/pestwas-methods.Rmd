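---
title: "Duration-based pesticide-wide association scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duration-based pesticide-wide association scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pestwas implements a record-based ambient-exposure pipeline for case-control
studies of Parkinson's disease (PD) in agricultural regions: buffer-based
annual exposure construction from pesticide application records,
proportion-of-years duration metrics with a prodromal lag, an agnostic
per-pesticide logistic scan with fixed-effect meta-analysis and false
discovery rate (FDR) control, constrained distributed-lag models (DLMs) over
decade-long pre-diagnostic windows, and agreement analyses between
duration-based and intensity-based effect estimates. Because use-reporting
linkage studies of this kind rest on confidential participant addresses, the
package ships a synthetic-data generator with known ground truth, so every
stage is testable end to end.

## Exposure model

Applications and addresses live on a common projected plane in meters. For a
participant-year with an address of a given type (residential `R` or
occupational `O`), a pesticide counts as applied nearby when any recorded
application of that pesticide in that year lies within a fixed-radius buffer
(default 500 m, membership inclusive at exactly the radius — the boundary is
measure zero and fixing it keeps tests exact). Annual intensity is the sum of
in-buffer pounds divided by the buffer area in acres, with 1 acre =
4046.856 m^2; the denominator convention matters only as a fixed scale since
all analyses are per standard deviation (SD).

An *index year* anchors each participant: diagnosis year for cases,
enrollment year for controls. With *lag* = index year minus exposure year,
the cumulative exposure period runs from the start of mandatory use
reporting (1974) to lags of at least `min_lag = 11` years. The 1--10-year
window before diagnosis is excluded as prodromal: exposures that recent are
unlikely to have initiated disease. The phrase "up to 10 years prior" is
ambiguous at lag exactly 10; we resolve it by excluding lag 10 (eligible
lags are >= 11), which keeps the cumulative period disjoint from the first
DLM window, and expose `min_lag` as a parameter.

Cumulative metrics per participant, pesticide and location type:

* duration = N / T, where N is the number of eligible years with any
  in-buffer application and T the number of eligible address-years;
* weighted duration = (N/T) * log(N + 1) (natural log; the reference scale
  is "log-transformed years exposed, offset by one"), which damps the
  degenerate case where a single observable year yields duration 1;
* intensity = mean annual pounds per acre over eligible years, zero years
  included in the denominator (so duration = 0 iff intensity = 0).

Window metrics repeat the same constructions inside four 10-year lag windows
(1--10, 11--20, 21--30, 31--40), residential addresses only: patients often
stop working before diagnosis, so occupational windows are differentially
truncated for cases and would distort lag patterns. A year in which a
participant holds two same-type addresses (a move year) counts once in T and
is exposed if any of that year's addresses is exposed; a field inside both
buffers is counted once. Years with an address but no usable location are
simply absent from T.

Pesticides enter the scan when at least 25 participants have any exposure at
either location type. Sensitivity exclusions drop participants with fewer
than 5 or 10 observable exposure years ("fewer than" is strict: exactly 5
is retained under the 5-year rule).

## The scan

For each eligible pesticide, the exposure metric is z-scaled separately per
location type over that location's analytic sample (n-1 SD), so estimates
are per 1 SD of the metric. The per-location model is unconditional logistic
regression adjusted for age, sex, ethnicity (reference non-Hispanic White),
education years, smoking status (reference non-smoker), study wave and index
year, fitted by binomial IRLS with Wald inference. Location strata are
combined by inverse-variance fixed-effect meta-analysis; a single valid
stratum passes through tagged. Benjamini-Hochberg FDR correction is applied
across the scan's meta-analytic p-values (one family per scan — the
reference presentation reports one FDR per pesticide). Zero-variance
exposure strata, rank-deficient designs and non-converged fits are flagged
and dropped from the meta stage; a scan never aborts on one pesticide.

## Constrained distributed-lag models

The lag-response over windows 1--4 is a natural cubic spline with internal
knots at windows 2 and 3, boundary knots at 1 and 4, no intercept (basis
dimension 3), and the exposure-response is linear. We implement the "null
first lag period" by centering the basis at window 1, `b_k(t) - b_k(1)`, so
every fitted lag curve is exactly zero at the first window. The reference
software's `intercept = FALSE` option does not literally pin the first lag
to zero; the stated intent — a null effect in the prodromal decade — is
taken as normative, and centering makes it exact.

Each participant contributes cross-basis regressors `CB_k = sum_w x_w
b_k(w)`. Window exposures share one scale: the pooled SD over all
window-exposure values of the pesticide (per-window SDs would make the lag
curve scale-incoherent). Windows without address coverage are imputed as
zero exposure with a flag (a complete-window switch exists). Because the
centered basis is saturated on windows 2--4, the DLM equals a free logistic
model with unconstrained coefficients for windows 2--4 and window 1 omitted;
this equivalence is verified to 1e-6 in the tests and anchors the delta-method
window standard errors.

Sensitivity models: per-window logistic fits with and without mutual
adjustment (collinear windows are dropped with a flag and the design's
condition number reported), and an L2-penalized fit shrinking only the four
window coefficients, with the penalty chosen by 20-fold stratified
cross-validated binomial deviance. The ridge fit is a penalized IRLS written
here so that the penalty convention is explicit: at lambda = 0 it equals the
unpenalized joint MLE to numerical precision, and as lambda grows the window
coefficients vanish while the unpenalized covariates converge to the
covariate-only fit. Lag-window units (not yearly lags collapsed by the
spline) are the analysis units, matching the knot placement "at 2 and 3".
The reported per-window ORs are window-specific contrasts.

## Agreement between duration and intensity

Paired per-pesticide estimates from two scans are compared on the log scale:
the ratio of odds ratios (ROR), a Bland-Altman analysis of log RORs against
the geometric mean of the paired ORs (the log-scale convention), a paired
t-test of log RORs against zero, and a Pearson correlation. The published
correlation between the metrics is ambiguous between exposure values and
effect estimates; we correlate per-pesticide log-OR estimates and note the
alternative. Limits of agreement use the classical approximations
(`se_bias = sd/sqrt(n)`, `se_loa = sd*sqrt(3/n)`, t quantiles); several
refinements exist, and the classical forms are documented as the choice.

## The synthetic world

The generator emulates the *structure* of a multi-decade use-reporting
system and a two-wave case-control study, not any real landscape:

* fields scattered around cluster centers on a planar region (out-of-extent
  draws are resampled, not clamped, so field density has no boundary
  artifacts), with log-normal acreage and poundage;
* co-application groups: pesticides in a group share fields, which induces
  strongly correlated exposure metrics (empirically ~0.9 within groups);
  pesticides on disjoint fields have correlations centered at zero, though
  any single world retains weak positive correlation through shared
  geography and differential mobility — a feature real data share;
* address histories from 1974 to the index year with geometric move times;
  occupational histories end early for cases (default 3 years before index),
  reproducing the healthy-worker-style truncation that motivates
  residential-only lag analyses;
* covariates drawn to match the direction of the published demographic
  table (cases slightly older, configurable shift), with index years split
  by wave over 1998--2016;
* outcomes drawn from a linear-logistic model on true (pre-outcome)
  z-scaled exposures, with the intercept calibrated by bisection so the
  expected case fraction matches the design (829 cases / 824 controls).

The defaults are the emulated study's conditions: 287 active ingredients,
1974--2016 records, 1653 participants. Landscape density (5 fields per
pesticide on an 18 x 18 km region, annual application probability 0.25) was
chosen so that essentially all 287 pesticides clear the 25-exposed filter
with exposed counts in the tens, the regime the scan is meant for. Design
labels drive structural features that precede outcome ascertainment
(occupational cessation, the case age shift), while the analyzed case status
is redrawn from exposure; effect-recovery presets therefore use a
residential-only cohort so the two labelings cannot diverge in a way that
matters.

What the generator does *not* emulate: real co-exposure networks beyond the
group structure (the joint distribution of exposures across hundreds of
agents is a modeling choice, not an inferred quantity), crop phenology and
seasonality, geocoding error, land-use polygons (applications are located
events at field centroids), and drift physics. Passing tests demonstrate
that the statistical machinery is correct and calibrated under a known
data-generating process — not that any particular real-world association is
reproduced.

## Numerical choices and test sizing

* IRLS convergence: deviance tolerance 1e-12, 100 iterations; agreement
  with an independent Newton optimizer to 1e-6 is part of the test suite.
* Wald 95% intervals on the log-OR scale; two-sided normal p-values.
* Separation or non-convergence is flagged (`converged = FALSE`, SE cap 50)
  rather than raised.
* Seed cascade: every generator and stage derives its own substream from
  the master seed and a stage label, so adding a stage never perturbs
  another's stream, and identical configuration plus seed reproduces
  byte-identical output files.
* Calibration and recovery properties are exercised at the emulated study's
  own sizes: 300 outcome replicates for cumulative-effect recovery
  (planted OR 1.25 per SD at n = 1653), 200 replicate 287-pesticide null
  scans for family-wise calibration, 200 replicates for window-3 recovery.
  Under the null the pooled Wald z-statistics are slightly conservative
  (SD ~ 0.92) because many pesticides have a few dozen exposed
  participants and heavily skewed z-scored exposure; the
  Kolmogorov-Smirnov distance to the standard normal stays below 0.05 and
  the family-wise discovery rate stays at or below its nominal level, which
  is the operationally relevant direction.

## Known limitations

Geocoding, land-use integration and treed distributed-lag models are out of
scope; the package consumes coordinates and located application events. The
fixed-effect meta-analysis of residential and occupational strata ignores
that both strata share participants; under the null this proved benign in
calibration runs, and effect-recovery presets avoid the issue by design.
Real-data adapters would additionally need an equal-area projection for
address coordinates.
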