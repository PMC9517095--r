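---
title: "Methods: forecasting, grading and early warning in wqwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting, grading and early warning in wqwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wqwatch` is a desk-scale re-creation of an operational water-quality
surveillance pipeline: four-hourly multi-indicator monitoring feeds are
ingested into a keyed store, input variables are screened by lagged
dependence metrics, one small LSTM per (watershed, sub-watershed,
indicator) key forecasts the next day, and predicted concentrations are
graded into surface-water classes to drive pollution warnings. This
vignette records the models, the tunable parameters, and the design
choices that were genuinely open.

## The synthetic monitoring feed

Real national feeds cannot be redistributed, so every stage is
exercised against a generator whose structure mirrors what operational
series look like. A series specification (`series_spec()`) draws

$$ y_t = \mu + A \sin\!\left(\tfrac{2\pi t}{P}\right) + d_t,
   \qquad d_t = \phi\, d_{t-1} + \varepsilon_t,\quad
   \varepsilon_t \sim \mathcal N(0, \sigma^2), $$

on a regular grid (default 4 h for water quality, 12 h for hydrology),
with timestamps at whole hours, timezone-naive. The deviation process
starts in its stationary distribution, so the lag-1 autocorrelation of
a de-seasoned series equals $\phi$ — a property the tests check
directly. Parameters and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `baseline` $\mu$ | long-run level, indicator units | — (required) | indicator-specific |
| `seasonal_amplitude` $A$ | sinusoid amplitude | 0 | annual cycles of WT/DO/COD are the visible structure of monitoring series |
| `seasonal_period` $P$ | hours | 8760 | one year |
| `ar_coefficient` $\phi$ | AR(1) coefficient | 0 | short-term persistence |
| `noise_sd` $\sigma$ | innovation sd | 0 | the single noise source; it drives the AR(1) deviation |
| `missing_rate`, `duplicate_rate` | injection probabilities | 0 | feed defects: dropped values, re-published records |

Duplicates are *exact copies* of an existing record, because that is
what a re-published feed page produces and what the ingestion
deduplication keys on. Pollution events (`spike_event()`) add a
constant offset over a time window; the default direction is "worse
water quality", which means *negative* for dissolved oxygen (spills
deplete DO) and positive for everything else.

What the generator does **not** emulate: regime changes, heavy-tailed
sensor glitches, diurnal cycles coupled to weather, cross-indicator
correlation (each indicator is drawn independently), or geographic
realism of coordinates. Green tests therefore certify the machinery —
contracts, chronology, determinism, skill relative to baselines on
*this* family of series — not performance on any particular real river.

## Ingestion rules

Cleaning applies, in order: negative concentrations (for indicators
measured in mg/L, NTU or cells/L) become missing values rather than
deleting the co-measured record; exact duplicates collapse; records
whose indicator values are all missing are dropped; and when two
records share a (station, time) key but disagree in values, the
later-parsed one wins and the conflict is logged — the feed keys
records on measurement time only, so there is no principled way to
prefer either value, and "newest parse wins" matches how a re-crawl
would overwrite a page. Cleaning is idempotent. The store enforces
(station, time) uniqueness per data table; `upsert_records()` never
updates in place, so re-polling an unchanged feed is a no-op.

## Lagged input screening

For a candidate series $x$ and target $y$, each metric is evaluated on
the truncated overlap $(x_{1..n-k},\, y_{k+1..n})$ for lags
$k = 1,\dots,12$ (truncation, never padding). Four metrics are
available: Pearson $r$, cosine similarity, distance correlation, and
MIC. Pearson delegates to `stats::cor` behind domain checks; dCor and
MIC are implemented in the package:

* **dCor** uses the double-centered pairwise-distance matrices
  $A, B$ and returns
  $\sqrt{\widehat{dCov}^2(x,y) / \sqrt{\widehat{dVar}^2(x)\,
  \widehat{dVar}^2(y)}}$, defined as 0 when the denominator vanishes
  (constant input). The implementation is vectorized $O(n^2)$; the test
  suite checks it against an independent loop-written oracle to 1e-10.
* **MIC** maximizes normalized mutual information
  $I(x,y)/\log_2\min(n_x,n_y)$ over *equal-frequency* grid partitions
  with $n_x n_y < B(n) = n^{0.6}$, entropies in bits. Restricting the
  search to equipartitions (rather than the full MINE dynamic program)
  keeps the estimator simple and exactly enumerable — the tests compare
  it against exhaustive grid enumeration — at the cost of slightly
  lower sensitivity to some non-functional association shapes.

`select_inputs()` keeps candidates whose best absolute score reaches a
threshold (default 0.3 — a deliberately permissive screen; there is no
canonical cut-off for "related" indicators), ordered by score, with the
target's own history always first. No significance testing is done:
screening feeds a forecaster, it does not make inferential claims.

## The LSTM forecaster

`wq_lstm()` fits a single-layer LSTM (gates $i_t, f_t, o_t$, candidate
state $\tilde c_t$, cell state $c_t$, output $h_t$) on sliding windows
of $L$ standardized steps predicting one step ahead, with mean-squared
error loss and mini-batch Adam. Design choices that matter:

* **Increment read-out.** The network output is the *change*
  $\hat z_{t+1} - z_t$; the forecast adds it to the last window value.
  An untrained network therefore starts at the persistence forecast,
  and training only models the correction. For strongly autocorrelated
  series this removes most of the estimation burden: the alternative
  level read-out must first re-learn the identity map from a few
  thousand windows before it can improve on it.
* **Validation checkpointing.** Every second epoch the validation MSE
  is evaluated and the best weights are kept. Window sets from a single
  sub-watershed are small (order 10³), and un-checkpointed training
  visibly overfits past its optimum.
* **Chronological 70/15/15 split**, scaler fitted on the training
  segment only, windows never straddling split boundaries (validation
  and test targets lie strictly after all training targets) and windows
  containing a missing value dropped rather than imputed — after
  cleaning, gaps are real and imputation would leak smoothness.
* **Hyperparameter grid** (defaults: units ∈ {16, 32} ×
  lookback ∈ {8, 16}, 50 epochs, batch 32, learning rate 0.01, Glorot
  initialization, forget-gate bias 1): each combination is fitted and
  the best validation CC is kept. The grid is small by design; these
  nets saturate quickly on series of this length.
* **Pooling.** All stations sharing a (watershed, position, indicator)
  key pool their *windows* (not averaged series) for one model; each
  pooled series is split chronologically on its own.

Training rejects constant series (no scaler exists), and `predict`
refuses histories shorter than the lookback.

### Hourly output from four-hourly data

The feed is four-hourly but the daily product is hourly. The model
recurses at its native 4-h step (each prediction fed back as input;
exogenous inputs, when present, held at their last observed value) and
the hourly values are linear interpolations anchored at the last
observation. Interpolation adds no information — it is a resampling
convention for the reporting grid, and the honest statement of what a
4-h model can say about 13:00.

### Skill measurement and the persistence baseline

Forecasts are scored by cross-correlation (CC, lag-0 Pearson by
default) and Nash–Sutcliffe efficiency (NSE), with verdicts
*acceptable* at CC ≥ 0.65 and *very good* at CC ≥ 0.75 (both
inclusive). The reference forecaster is persistence,
$\hat y_t = y_{t-1}$.

One property of this benchmark is worth recording: for an AR(1)
deviation process the optimal one-step predictor is proportional to the
last value, hence *perfectly correlated* with the persistence forecast.
A slowly varying seasonal term breaks the tie only marginally at a 4-h
step. CC therefore barely separates a near-optimal forecaster from
persistence on such series, while NSE separates them cleanly (the
optimal predictor shrinks the deviation, persistence does not). The
test suite accordingly treats NSE as the discriminating skill margin on
the annual-cycle series, and demonstrates a decisive CC margin on a
series with a resolvable (diel) cycle, where persistence lags the cycle
systematically.

## Grading, assessment, warnings

Class labels are I–V plus inferior-V ("worse than class V"). Grading
conventions: boundary values grade into the *better* class (a
concentration exactly at a class limit attains that class); indicators
with tied limits for two classes make the better class absorb the
boundary; range-type indicators (pH, acceptable 6–9 at every class)
grade I in range and inferior-V outside; indicators without class
limits in the shipped standard (water temperature, turbidity) are
marked `none` and skipped. A record's overall class is the worst
single-indicator class — the single-factor method standard in Chinese
surface-water assessment; it is conservative by construction. The
shipped boundaries (GB 3838-2002, river limits for total phosphorus)
live in a plain-text config (`inst/extdata/gb3838_scheme.cfg`) and are
treated as opaque, so deployments under other standards only edit that
file.

Assessment reports bundle attainment (fraction of records at or better
than the target class), category proportions over the six classes, and
the link relative ratio — the percent change of a period's mean over
the preceding period's mean, undefined (flagged) when the previous mean
is zero. Periods default to calendar months, matching the monthly
reporting mode.

Warnings compare *predicted* classes against a target class (default
III, the common attainment benchmark; configurable per deployment
because the regulatory target is site-specific). One event is raised
per (station, hour, indicator) whose predicted class is strictly worse
than the target, and a Markdown report is written to an outbox
directory — the stand-in for the administrator's mailbox. The automatic
daily run (`run_auto()`, designed to be invoked by the host scheduler
at 00:00) predicts every station-indicator pair with a trained model,
grades, warns, and aggregates worst classes to sub-watershed and
watershed level; `run_manual()` is the user-scoped restriction of the
same computation, so both modes agree on identical inputs by
construction.

## Problem sizes and determinism

The test suite runs the full machinery at deliberately small sizes:
unit fits use 60–120 days of four-hourly data with 4–8 units, and the
one full-scale check trains the default grid on a 2000-record series
(about 11 months), which completes in well under a minute on one CPU
core. All stochastic stages (network layout, series draws, injection,
weight initialization, batch shuffling) derive child seeds from a
single root seed by string hashing, so identical calls are bit
reproducible and independent stages do not share streams.

## Known limitations

* The LSTM engine is deliberately minimal: one layer, no dropout or
  weight decay (checkpointing is the only regularizer), full BPTT over
  short windows, CPU only.
* Multi-step recursion holds exogenous inputs constant; models with
  selected exogenous inputs degrade over long horizons.
* The generator's independence across indicators means cross-indicator
  input selection is only exercised on constructed couplings.
* Grading treats each record in isolation; no duration or frequency
  criteria (e.g. "IV for six consecutive hours") are applied before
  warning.
* The store is an in-memory/CSV contract, adequate for desk scale; a
  production deployment would put a database behind the same five-table
  interface.
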