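---
title: "Spatio-temporal multilayer connectivity networks and dynamic rich-club metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal multilayer connectivity networks and dynamic rich-club metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mlfcn)
library(dplyr)
```

## The model

Functional connectivity analysis usually represents the brain as a single
graph: nodes are atlas regions (ROIs), edges reflect correlated BOLD
signals.  That representation misses two things at once — the *high-order*
coordination of whole resting-state networks (several networks co-activating
as a group, which no pairwise edge captures), and the *temporal* drift of
network organisation over a scanning session.  This package implements a
multilayer construction that addresses both, together with four node-level
metrics describing how the network's rich-club core changes over time.

### Node sets

A multi-scale parcellation (`parcellation()`, bundled default:
`default_parcellation()`) defines three node sets:

* 90 gray-matter ROIs grouped into 14 macroscale resting-state networks
  (MRSNs) — salience, default-mode, visual, executive-control systems and so
  on;
* the 14 MRSNs themselves, each represented by one signal;
* 48 white-matter tracts, treated as a single additional WM group,
  so 15 networks and 138 ROIs in total.

The bundled table reproduces the published per-network member counts (the
auditory network has 3 members; counts sum to 90) with generic member
labels; users with a concrete atlas supply their own four-column TSV.

### Three spatial layers per time window

For each sliding window (length `W`, stride `S`, giving
`T = floor((L - W)/S) + 1` temporal layers):

1. **Hypergraph layer `H` (14 x 14).**  Each MRSN representative signal is
   taken in turn as the central response and regressed on the other 13 under
   an L1 penalty (lasso).  Nodes with strictly positive coefficients form
   that centre's hyperedge.  Positive-only membership means a hyperedge
   collects networks that *co-activate* with the centre; anti-correlated
   networks are excluded.  A node is never a member of its own central
   hyperedge, so the theoretical maximum hypergraph degree is 13.
2. **Within-network GM adjacency `A1` (90 x 90, block diagonal).**  Pearson
   correlations are computed inside each MRSN block and binarised at an
   adaptive threshold — the mean plus one standard deviation of that block's
   off-diagonal correlations.  Between-network GM pairs are structurally
   zero: between-network structure lives in the hypergraph layer only.
3. **WM-GM adjacency `A2` (48 x 90).**  The full WM-by-GM correlation
   matrix, binarised at its own mean-plus-SD threshold.

### Rich-club core and the four metrics

Per window, every ROI gets a normalised multilayer degree: the sum of its
three layer degrees (GM ROIs inherit their MRSN's hyperedge count as the
layer-1 degree) divided by the sum of the per-layer theoretical maxima —
for an auditory-network GM node, (13, 2, 48); for a WM tract, 90 in total.
The top 15 ROIs (one per network in spirit: 14 GM MRSNs + 1 WM group) form
that window's rich-club core; all 138 ROIs, WM included, compete.  Ties at
the cutoff are broken by ascending ROI index so selection is deterministic.

From the binary core-assignment matrix `R` (ROI x window):

* **Temporal centrality** `TC_i = mean_t R_i(t)` — the fraction of windows
  in which a node is core.  Node TCs always sum to the core size.
* **Temporal stability** — the persistence of a node's core/peripheral
  identity between consecutive windows.  The defining formula, read
  literally, counts *consistent* transitions and subtracts, so a node that
  never changes identity scores 0 while the surrounding prose describes a
  stability score that such a node should maximise.  Both readings are
  computed (`ts_literal`, `ts_prose = 1 - ts_literal`); the prose reading is
  the default `ts` column because it matches the metric's stated intent.
* **Local / joint functionality** — from the shared-core matrix `P`, whose
  entry (i, j) counts, summed over windows and scaled by `T * n_core`, the
  core nodes to which both *peripheral* nodes i and j are simultaneously
  connected.  `LF_i` averages `P_ij` over same-network partners (divided by
  the network size `n_S`, the literal normaliser; `n_S - 1` is available as
  an option), `JF_i` over out-of-network partners (divided by `N - n_S`).
  The summation for the joint metric runs over *other* networks: the
  definition's summation index as printed duplicates the local one, but the
  accompanying description makes the complementary index set the only
  coherent reading.

Two further conventions deserve a note because the definitions leave them
open.  First, the layer sum in `P` runs over all `T` windows with the
`T * n_core` normaliser (a per-window quantity summed over every window);
an option reproduces the `T - 1` upper limit that appears in print.
Second, "connected to" across layers is resolved by a connectivity policy:
the default union graph joins the within-network adjacency, the WM-GM
adjacency, and a hypergraph clique expansion at MRSN level (two GM ROIs are
connected when their MRSNs share at least one hyperedge).  This is the
largest interpretive decision in the package and is isolated behind the
`connectivity` argument (`"adjacency_only"` drops the hypergraph term), so
its effect can be measured rather than assumed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window`, `stride` | data-dependent | window length and step, in time points (TRs); 200/100 for 1200-point runs, 20/10 for 150-point runs are the standard configurations |
| `lambda` | 0.1 | lasso penalty on the mean-squared-error scale, applied to column-standardized series |
| `n_core` | 15 | rich-club core size per window (matches the 15 networks of the default parcellation; scaled to the network count + 1 for smaller parcellations) |
| `ts_mode` | `"prose"` | which stability reading fills the `ts` column |
| `connectivity` | `"union_clique"` | cross-layer connectivity policy for `P` |
| `abs_corr` | `FALSE` | threshold signed correlations (default) or magnitudes |

The penalty is defined on the `(1/2n)`-scaled squared loss so that one
value of `lambda` means the same thing at any window length; series are
standardized per window, making the penalty scale-free in the data units
as well.  With standardized columns, a predictor enters a regression
roughly when its (partial) correlation with the response exceeds `lambda`,
which makes 0.1 a mild default that suppresses sample noise at
`W = 200` (noise correlations ~ `1/sqrt(W)` ≈ 0.07) without erasing real
structure.  `lambda` is deliberately exposed everywhere; hyperedge sizes as
a function of `lambda` are worth inspecting on any new dataset.

The MRSN representative signal is the unweighted mean of member ROI series
(`mrsn_series()`, with a first-principal-component option).  The mean is
the simplest convention consistent with treating each network as a single
node; nothing downstream depends on the choice beyond the hypergraph layer.

## The synthetic generator

`sim_config()` / `simulate_cohort()` generate seeded cohorts with the
statistical structure the pipeline assumes, so every stage is testable
without imaging data:

* one latent factor per MRSN; ROI series are `sqrt(w)` times their factor
  plus idiosyncratic noise, so any two same-network ROIs correlate at
  `w = within_block_corr` (default 0.8, a strong but realistic
  within-network coherence);
* a global factor on which every network loads — non-hub networks at
  `baseline_cross = 0.35`, the planted hub network at
  `cross_block_corr = 0.95`.  This makes the hub the dominant shared
  signal: in each lasso regression the hub is the best single predictor of
  any other network (marginal correlation ≈ 0.33), while after the hub
  enters the model the remaining networks' partial correlations collapse
  (≈ 0.02, well under the penalty), so hub hyperedge membership is
  recovered cleanly and non-hub membership stays at noise level;
* designated hub WM ROIs couple to the hub network's factor at 0.95,
  remaining WM ROIs to cyclically assigned factors at 0.15;
* optional regime switches rotate the hub role to the next network at
  stated window starts;
* group B reduces the hub loading by `group_effect_size` (default 0.4);
* session 2 equals `r` times session 1's underlying standard-normal draws
  plus `sqrt(1 - r^2)` fresh ones (`r = retest_reliability`), so `r = 1`
  reproduces session 1 bit-for-bit and every metric's ICC is exactly 1.

Defaults use the small test parcellation (5 networks x 4 GM ROIs + 6 WM
ROIs, core size 5) and the long-run window configuration
`L = 1200, W = 200, S = 100`.  The factor construction guarantees a valid
(positive semidefinite) covariance for any admissible loadings, and a
config's seed fully determines every output (R's default Mersenne-Twister
generator; one derived seed per subject, a fixed offset stream for
session-2 innovations).

What the generator does *not* emulate: hemodynamic autocorrelation,
scanner drift and motion artefacts, heavy-tailed noise, spatially smooth
signal leakage between neighbouring ROIs, and site effects.  Passing
recovery tests on this generator therefore demonstrates that the
estimator chain — windowing, lasso incidence estimation, adaptive
thresholding, degree normalisation, core selection, metric computation,
group statistics — is correct and well-calibrated under its own model
assumptions; it does not certify performance on real fMRI, where window
length and the penalty interact with autocorrelation.

## Numerical and degenerate-input choices

* **Thresholding.**  Strict inequality against mean + SD; a block whose
  correlations have zero spread produces no edges (with a warning in the
  all-identical case).  Single-pair blocks can never self-exceed, so
  two-member networks get empty within-network blocks — their structure
  still enters through the other layers.  NA correlations (zero-variance
  series) are treated as zero strength.
* **Zero-variance series** are flagged on load, excluded from hyperedge
  regressions (their hyperedges are empty), and never crash a correlation.
* **Lasso.**  glmnet solves each regression along a short decreasing path
  ending at the target penalty (convergence threshold 1e-12); the
  two-network case falls back to the exact closed-form soft-threshold
  solution since a one-column design is below glmnet's minimum.
  Determinism: identical input and penalty give identical `H`.
* **Ragged windows.**  When `(L - W)` is not divisible by `S` the trailing
  remainder is dropped with a warning; the standard parameter sets divide
  evenly.
* **ICC** is the one-way random-effects ICC(1,1), computed from the
  between/within mean squares; it is negative when subjects agree less
  with themselves than with each other (lower bound -1 at two sessions)
  and undefined (NA, with a warning) when every value is identical.
  Classification thresholds are strict: > 0.6 (GM) or > 0.5 (WM) indicates
  individual differences, > 0.8 significant individual differences for
  either tissue — the WM bar is lower because WM BOLD signals are weaker.
* **Group contrasts** use the pooled-variance Student t-test — the stated
  degrees of freedom `n1 + n2 - 2` (158 for 80 vs 80, 171 for 87 vs 86)
  identify it over the Welch variant — with Benjamini-Hochberg FDR applied
  within each metric family across units; the family scope is an argument
  of record, not hard-coded.
* **Whole-brain temporal centrality** is reported by `aggregate_metrics()`
  but is constant by construction (node TCs sum to the core size), so it
  carries no between-subject information and is excluded from analysis by
  default in examples.

## Problem sizes used in the test-suite experiments

Oracle-equivalence checks run the full metric chain against independent
brute-force implementations on 500 random instances of at most 8 ROIs, 3
networks and 4 temporal layers.  Hub-recovery checks average 12
single-subject cohorts at the default generator settings.  Type-I
calibration runs 200 null cohorts (no group effect) of 6 + 6 subjects at
`L = 240, W = S = 80` — three non-overlapping windows — and requires the
q < 0.05 discovery fraction across all unit x metric tests to stay at the
nominal level.  These sizes were chosen as the smallest at which each
property is statistically meaningful.

## A worked run

```{r example}
parc <- toy_parcellation()
cfg <- sim_config(parcellation = parc, seed = 1)
ts1 <- simulate_subject(cfg, "demo-subject")
net <- build_temporal_fcn(ts1, parc, window = cfg$W, stride = cfg$S)
net

metrics <- richclub_metrics(net, n_core = 5)
metrics |> arrange(desc(tc)) |> head(7)
glance(metrics)
```

The planted hub network's four ROIs (1-4) and the hub WM tract (21) take
the top temporal-centrality ranks.  `autoplot(metrics)` and
`plot_core_assignment(metrics)` visualise the metric distributions and the
core raster; `run_pipeline()` chains construction, metrics, and the ICC or
group-difference analyses over a whole cohort.

## Known limitations

* Layers are binary; no weighted variant is provided.
* No inter-layer coupling terms enter the degree — each layer contributes
  additively.
* The hypergraph layer is estimated per window independently; no temporal
  smoothing or penalty coupling across windows.
* The package performs no fMRI preprocessing and no atlas registration;
  inputs are assumed detrended, nuisance-regressed ROI series on a common
  grid.
* FDR family scope, the cross-layer connectivity policy, and the local
  functionality normaliser are documented interpretive choices; all three
  are exposed as arguments so sensitivity to them can be checked.
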