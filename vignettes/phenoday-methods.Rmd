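---
title: "phenoday: models and methods for daily passive-sensing features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoday: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoday)
```

## The problem

Smartphone passive sensing (digital phenotyping) turns a participant's own
phone into a behavioral sensor: the accelerometer, GPS, call registry,
screen on/off events and per-app traffic are logged continuously in the
background and condensed into one behavioral feature vector per calendar
day. Two practical obstacles dominate this kind of study:

1. **Data integrity.** Android manufacturers ship power-saving policies
   that kill background acquisition when the phone is idle (screen off for
   a while, GPS unchanging), so raw streams arrive with large structured
   holes. Any analysis has to quantify how much of the intended
   acquisition actually happened, and for which devices the holes are
   policy-driven.
2. **Interpretation at the day level.** With a single free-living subject
   there is no case/control contrast; the natural question is *which days
   differ from this person's own routine* — weekends versus workdays, and
   public holidays as the strongest outliers.

phenoday implements the full server-side path: raw per-sensor logs in,
integrity report and per-day anomaly ranking out, plus a seeded simulator
so every stage is testable with no participant data.

## Data model and integrity

Each sensor is one CSV stream of epoch-millisecond records (one file per
sensor). A **segment** is a maximal run of samples whose consecutive
spacings never exceed 1 s (the tolerance matching the 5 Hz nominal rate of
the embedded sensors; for the 1-per-minute GPS cadence the default
tolerance is 120 s). Gaps are the complement of segments within the
observed span, and an isolated sample forms a zero-length segment, which
makes the conservation identity exact:

$$\sum \text{segment durations} + \sum \text{gap durations} = t_{last} - t_{first}.$$

The **data-integrity percentage** is
$100 \cdot \text{acquired hours} / \text{running hours}$, where running
hours are supplied explicitly as the spans during which acquisition was
supposed to be active. The package does not guess the denominator: with
real uploads the app-alive spans should be passed in; for synthetic data
the full generated span is used. Multi-sensor summaries aggregate by
duration weighting.

Devices are classified into power-saving **subgroup A/B** by a declared
rule rather than a brand table: a device is *B* when gaps exceed a floor
(default 5% of running time) and at least 80% of total gap time lies
inside screen-off spans; *A* when gaps are at or below the floor;
*indeterminate* otherwise (substantial gaps uncorrelated with screen
state). Both thresholds are configurable; the floor separates boundary
truncation losses from genuine policy kills.

## Daily features

Hour-slot convention: slot $n \in 1..24$ covers local time $[n-1, n)$.
Calendar days are cut at local midnight in a configured IANA timezone
(default UTC) — upload formats rarely state one, so it must be explicit.

* **Calls** — mean incoming and outgoing durations, total call time,
  outgoing count. Missed calls are carried in the data model but excluded
  from every feature (they have no duration and the feature definitions
  only involve placed/received calls).
* **Screen** — on/off events are normalized (repeated states collapse to
  the first occurrence, as happens after reboots), paired into sessions,
  and split at midnight so per-day time conservation is exact:
  $\sum_n b_n$ equals the day's total session time. A session open at the
  day boundary is truncated and its remainder credited to the next day.
* **Apps** — kilobytes summed per category (social / communication /
  navigation, with the conventional app lists) plus an uncategorized-
  inclusive daily total; matching is case-insensitive on app id.
* **Activity** — the signal amplitude of a sample is the 3-axis Euclidean
  norm (orientation-invariant); the *dynamic* amplitude subtracts standing
  gravity, $|\,\lVert a \rVert - 9.81\,|$. Every wall-clock second with
  samples is classified *high* when its mean dynamic amplitude exceeds
  0.5 m/s² (configurable; roughly the boundary between hand gestures and
  gait), giving hourly high/low second counts $s_{a,n}$, $s_{r,n}$, hourly
  mean amplitude $m_{amp,n}$, and
  $\text{percentage\_activity} = \sum s_a / (\sum s_a + \sum s_r)$.

Empty-denominator means (a day with no incoming calls, an hour with no
samples) are reported as `NA` with a missing mask, never as 0: "no
observation" and "zero duration" are behaviorally different, and the
anomaly stage owns the imputation decision.

## GPS mobility features

Fixes implying over 1.5 m/s relative to the previous fix are transit and
are excluded from clustering while keeping their dwell. Stationary fixes
are clustered once over the whole observation window (so cluster
identities — and hence *home* — are stable across days) by density
joining on great-circle distance with a 100 m radius; the implementation
bins fixes into radius/2 grid cells and single-links occupied cells, a
standard accelerated equivalent. Clusters with under 300 s of total dwell
dissolve into noise. Dwell per fix is the time since the previous fix
capped at twice the fix cadence, so tracking holes do not inflate
residence time.

*Home* is the cluster with the greatest local 00:00–06:00 dwell (ties to
total dwell; with no night fixes at all the top-dwell cluster is used and
flagged low-confidence). Per day:

* `location_variance` $= \sigma^2_{lon} + \sigma^2_{lat}$, population
  variance of the day's raw coordinates in degrees² (coordinates are
  deliberately not projected; the quantity is a variability index, not an
  area).
* `entropy` $= -\sum_i p_i \log p_i$ in nats over the day's dwell
  proportions across clusters; `normalized_entropy` divides by $\log k$
  over the day's visited clusters, removing the base dependence (0 when
  fewer than two clusters are visited). Per-day rather than whole-study
  proportions are used because the downstream unit of analysis is the day.
* `time_outside` — percent of the day's attributed dwell (transit
  included) spent away from the home cluster.
* `visited_clusters` — the day's places ordered by haversine distance
  from home (6371 km sphere).

## Anomaly screening

The day × feature matrix is z-standardized per feature over non-missing
entries; zero-variance columns are dropped; missing entries are imputed
with the per-feature median of the standardized observed values
(configurable). Standardization before distance computation is essential:
the pool mixes seconds, kilobytes and degrees².

**PCA screen.** The leading principal components explaining ≥ 90% of
variance are retained and each feature is scored by its strongest
contribution to them. The score is the maximum over kept components of
|loading| × component standard deviation. The scaling matters and is a
deliberate design choice: with ~90 features and only tens of days, each
near-noise feature ends up owning some low-variance minor component with
a raw loading near 1, so an unweighted max-|loading| rule systematically
selects noise (we observed exactly this — hourly mean-amplitude slots,
which carry almost no day-to-day signal, crowded out everything else).
Weighting by the component scale ranks features by the variance they
actually carry. Features at or above the 0.75 quantile of scores are kept,
with a never-empty fallback (top 5). On simulated data the surviving set
concentrates, as expected, on daytime activity and screen slots and the
traffic/usage totals — an emergent property, not a hard-coded band.

**k-NN global anomaly score.** Each day's score is the mean Euclidean
distance to its $k = 5$ nearest other days in the screened, standardized
space; ties in neighbor distance break by day order so results are
deterministic. Days are ranked by descending score and the top
$\lceil 5\% \rceil$ flagged. Mean aggregation (rather than max or sum) is
the common definition of the global anomaly score and keeps the score in
distance units.

## The synthetic world

The simulator emulates one office worker's phone over `n_days`:

* **Regimes.** Mon–Fri workdays, Sat/Sun weekends, plus explicit holiday
  day indices. Workdays: home until 08:45, 15 min transit, work 9:00–17:30
  (2 km from home), home for the evening. Weekends and holidays are spent
  at home — holidays differ through *usage*, not location: heavier and
  longer screen sessions, several-fold app traffic, many long calls, and
  sustained daytime activity, each holiday with its own lognormal
  amplitude so holidays do not form a tight cluster of their own.
* **Sensors.** Accelerometer at 5 Hz: magnitude $9.81$ m/s² plus
  sd-0.05 noise at rest, realized on a fixed vertical axis; high-activity
  seconds add a walking-like 2 Hz oscillation of amplitude 1.5 m/s²
  (per-second mean dynamic amplitude ≈ 0.95 m/s², so the 0.5 m/s²
  classifier threshold separates the classes nearly deterministically — a
  Gaussian dynamic component of the same scale would misclassify ~4% of
  high seconds, contradicting exact-recovery expectations). GPS: one fix
  per 60 s with 10 m Gaussian jitter, linear interpolation during transit.
  Screen sessions: inhomogeneous Poisson per hour with per-regime
  intensity profiles and exponential lengths. Calls and app traffic:
  Poisson counts / gamma totals with per-regime means, app records hourly
  in proportion to screen-on time. A lognormal day-level rate multiplier
  (sd 0.2) adds natural day-to-day variability.
* **Power-saving policy.** Subgroup A never interrupts. Subgroup B kills
  the embedded sensors (accelerometer, GPS) 300 s into any screen-off
  span while the user is stationary, rewaking at the next screen-on;
  transit windows keep the sensors up when GPS-change suspension is
  enabled. Gap intervals are recorded in the ground truth per sensor.
* **Determinism.** One seed; each sensor block draws from its own derived
  substream, so restricting generation to a sensor subset does not change
  the draws of the sensors kept.

What a green test does *not* establish: the simulator has no multi-user
structure, no battery or connectivity model, no irregular sampling jitter,
no seasonal drift, and its holidays are behaviorally loud by
construction. Recovery results on it validate the pipeline's mechanics
(formulas, conservation, ranking), not field sensitivity on quiet
real-world anomalies. The simulated subgroup-B integrity (~15–20%) is
lower than the ~60% reported for real subgroup-B cohorts, whose registry
streams keep running during sensor kills; only the direction of the A/B
contrast is asserted, not its size.

## Numerical choices and degenerate inputs

* Conservation identities (segments + gaps; $b_n$ totals;
  $s_a + s_r$ = sampled seconds) are exact by construction and tested to
  1 ms / 1 s.
* `integrity_percentage` refuses a zero running denominator; acquired
  time is clipped to running time only after interval intersection.
* Fewer than 2 GPS fixes yield an empty cluster set; a day without fixes
  yields all-`NA` GPS features; a slot without accel samples yields
  `NA` mean amplitude and zero activity seconds.
* `knn_gas` requires $k \le$ days − 1 and rejects anything else
  up front; PCA proceeds with min(days − 1, features) components and a
  warning when the matrix is wider than it is tall.
* All thresholds live in one defaults block (`default_config()`) so every
  value the underlying study never specified is declared and inspectable.

## Known limitations

* Entropy uses per-day dwell proportions; whole-study proportions would
  give smoother but less day-sensitive values.
* The "movement index" occasionally named alongside these GPS features
  has no published definition and is deliberately not implemented.
* Brand lookup of power-saving behavior is out of scope; subgroup
  classification is purely signal-driven.
* Location variance in degrees² is latitude-dependent if compared across
  study sites; within-subject day ranking is unaffected.
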