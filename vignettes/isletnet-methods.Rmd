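---
title: "Methods: models, parameters and design choices in isletnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in isletnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement model

The pipeline's input is a time × cell matrix of Ca²⁺-indicator
fluorescence, per-cell 2-D positions in µm, and a stimulation onset. Two
acquisition regimes are supported, differing in what can be resolved:

* **mouse-like**: single-cell traces at 10 Hz. Fast oscillations
  (seconds) are resolvable; the conditioning filter is a band-pass.
* **human-like**: traces of 15 µm square islet subregions (ISRs) at
  0.33 Hz, used when single cells cannot be segmented. Only slow
  dynamics are resolvable; the conditioning filter is a high-pass, and
  all spatial defaults switch to the grid geometry (fixed 22 µm local
  neighbourhood).

## 2. Trace conditioning and binarization

**Zero-phase filtering.** The filters apply, in the frequency domain, the
*squared magnitude* response of a 4th-order Butterworth design — exactly
the magnitude a forward–backward (filtfilt) time-domain Butterworth would
apply — to the even-reflected signal. A purely real transfer function
gives strictly zero phase shift, so pulse edges and threshold crossings
are not displaced; even reflection removes the wrap-around discontinuity
that would otherwise leak edge artefacts into the interior. Defaults are
the midpoints of the conventional ranges: band-pass 0.035–1.5 Hz (mouse),
high-pass 0.0075 Hz (human).

**Binarization.** A cell is active where its filtered, smoothed signal
exceeds `median + θ_amp × (95th percentile − median)`, i.e. a fraction
(default θ_amp = 0.3) of the robust oscillation amplitude above the
baseline. Active runs shorter than `min_dur_s` are removed first, then
silent gaps shorter than `min_dur_s/2` are bridged. The generic default
`min_dur_s` is 3 frames, but the pipeline uses 1 s (mouse) / 9 s (human):
in validation against generator ground truth, the 3-frame rule let
threshold chatter through (roughly twice as many detected onsets as true
ones at default noise), which polluted the wave catalog with spurious
small space–time clusters. Oscillations at these dynamics last seconds,
so a 1 s minimum discards only noise.

**Why the robust amplitude.** `q95 − median` estimates the plateau height
of a duty-cycle-limited pulse train while ignoring both baseline noise and
occasional overshoots; it degrades only when a cell is active more than
half the time, which at these stimulation levels is rare. Flat cells
(zero robust amplitude) are marked inactive with a warning rather than
erroring.

**Response times.** The experimental workflow picks response onsets
manually; the package automates it as the first post-stimulus time at
which the smoothed trace exceeds the pre-stimulus median by 3 baseline
SDs continuously for a hold time (2 s mouse / 15 s human — at 0.33 Hz a
2 s hold would be less than one frame). A manually curated CSV can
override the detector. First responders are the earliest
⌈N/6⌉ responders; all top-1/6 selections in the package break ties by
ascending cell index, making every subpopulation deterministic.

## 3. Waves and initiator scoring

Onset events `(cell, t)` are linked when both within `R_s` µm and `R_t` s;
waves are connected components with at least `min_wave_size = 5` events.
The construction is order-independent and, by a union–find over a
time-sorted sliding window, near-linear in events. Within a wave each
cell keeps its earliest event, and ranks follow activation times.

The "first" set of a wave is its earliest `max(1, ⌈0.1 × size⌉)`
activations; a cell's initiator score is the share of its waves in which
it was in the first set, and initiators are the top 1/6 by score. Both
the leading-set fraction and the single-earliest-cell reading are
supported (`first_fraction` ≤ 1/size gives the latter); neither is
asserted to be the historically used variant.

Defaults: `R_t` = 0.5 s (10 Hz) / 6 s (0.33 Hz); `R_s` = 1.5× the median
nearest-neighbour distance (scatter) or 22 µm (grid). The pipeline
passes a slightly different radius: the islet-wide local-neighbourhood
radius (1.5× the mean 6-neighbour mean distance), because the median-NN
default can be *shorter than the longest coupling edges* of the
6-nearest-neighbour graph waves actually travel on, which fragments
genuine waves into pieces. Using one neighbourhood definition across the
wave and community-contrast analyses is also conceptually cleaner.

## 4. Functional networks, communities, hubs

Edges connect cell pairs whose filtered sustained-phase traces exceed a
Pearson correlation threshold. The threshold is *variable*: the N(N−1)/2
pair correlations are sorted and cut at rank `round(N × k_target / 2)`,
so the mean degree equals the target (default `k_avg = 8`) exactly, up to
ties at the cut (reported with a warning; tolerance 0.2 binds only
there). Correlations are computed on filtered continuous traces by
default — "temporal similarity of activity" is read as trace similarity —
with binarized-input correlation available as an option
(`correlate_on = "binary"`).

Communities come from Louvain modularity maximization (resolution 1,
fixed seed); the reported Q is recomputed from the adjacency with the
package's own Newman–Girvan implementation, so the optimizer and the
quality function cross-check each other, and tests compare both against
exhaustive search on small graphs. Louvain visits vertices in order, so
exact invariance under node permutation is not guaranteed; the test suite
asserts near-invariance (ARI ≥ 0.85) plus exact reproducibility at fixed
seed. Isolated nodes become singleton communities and are ineligible as
hubs. Hubs are the top 1/6 by degree.

## 5. Spatial statistics

`ΔP̄(d)` accumulates `|P_i − P_j|` over unordered pairs into distance
bins of width Δd (default 10 µm scatter / 15 µm grid, up to the 90th
percentile of pairwise distances; neither width is prescribed by the
source analyses). Empty bins carry `NA`, never 0. The bracket in the
defining equation is read as absolute value, as the surrounding
description of "absolute differences" dictates.

The same/different-community contrast computes, per cell, the mean
absolute parameter difference to same- and to different-community
neighbours within the local radius, and compares the two per-cell
distributions with a two-sided Mann–Whitney U test. The U statistic uses
midranks; p comes from exact enumeration when both groups have ≤ 8
untied observations, otherwise the tie-corrected normal approximation
with continuity correction.

Hierarchical clustering uses average linkage (no linkage is prescribed;
average is the least shape-biased of the common choices) on one of three
pairwise metrics — Euclidean distance, |Δ active time|, |Δ response
time| — cut to the number of detected communities. Cluster–community
overlap aligns labels by maximum-agreement one-to-one matching
(enumeration for ≤ 7 labels, Hungarian-style weighted bipartite matching
via igraph above), and the baseline shuffles cluster labels (preserving
group sizes) rather than drawing uniform labels.

Concentric regions: the convex hull of the positions is scaled about its
centroid by `s_i = √(i/8)`, making all eight annuli equal in area
*exactly* (areas scale with s²); cells are assigned by their minimal
enclosing scale factor, hull-boundary cells to region 8. The
nested-cumulative alternative can be recovered by accumulating the
annuli. Subpopulation distributions report both the share of flagged
cells per region and the enrichment relative to the region's share of
all cells.

## 6. The synthetic islet generator

The generator is a *stated world*, not a biophysical model. It emulates
exactly the statistical structure the analysis assumes, with ground-truth
labels for every quantity the pipeline estimates:

* **Geometry** — Poisson-disk (dart-throwing) positions with ≥ 10 µm
  spacing inside an ellipse (defaults 110 × 85 µm semi-axes for 150
  cells), or the 15 µm ISR mesh in grid mode.
* **Modules** — Voronoi regions of randomly chosen seed cells: spatially
  contiguous by construction. Default 12 modules for 150 cells. This
  value is deliberate: with the k_avg = 8 rank-cut construction, the
  modularity-optimal community scale is roughly 10–15 cells, and planted
  modules much larger than that are *provably* split by any modularity
  maximizer (a refinement of a 30-cell module scored higher Q than the
  true partition in validation). Twelve contiguous modules match both
  that natural scale and the community counts visible in representative
  islet networks.
* **Intrinsic parameters** — module mean active time ~ U(0.12, 0.35)
  plus i.i.d. per-cell jitter (SD 0.03); module mean response delay
  ~ U(4, 24) s plus jitter (SD 2 s mouse / 10 s human), giving the
  clustered activation the analysis expects.
* **Initiators** — ⌈N/6⌉ cells, allocated to modules proportionally
  (≥ 1 each) as a contiguous rim patch grown from each module's most
  peripheral cell; their intrinsic active time is raised to at least the
  raw 60th percentile, which provably keeps them at or above the
  post-boost population median (at most N/6 values are raised, so the
  median cannot pass the raw 0.583 quantile). This encodes two facts the
  world must express: waves start repeatedly from elevated-excitability
  peripheral regions, and initiator cells are themselves more active.
* **Waves** — a Poisson process (default 0.3 Hz islet-wide) during the
  sustained phase; each wave is global with probability 0.1, else
  confined to a uniformly chosen module; it seeds at an initiator of
  that module and propagates at 90 µm/s (20 µm/s human) along shortest
  paths of the symmetrized 6-nearest-neighbour coupling graph (the
  electrophysiologically motivated 5–6 connections per cell). The
  default rate gives per-cell event rates near 0.1 Hz and pulse
  durations of 1–5 s — realistic fast oscillations, and short enough to
  pass the band-pass plateau sag.
* **Active-time realization** — each cell's per-wave pulse duration is
  solved from `Σ min(d, gap_j) = target × window` so the *union* of its
  pulses occupies exactly its intrinsic active-time fraction of the
  sustained window; recovery tests can therefore use tight tolerances
  honestly.
* **Fluorescence** — binary activity through an indicator-like kernel
  (exponential rise τ = 0.2 s, decay τ = 0.08 s at 10 Hz; single-frame
  boxcar at 0.33 Hz), plus a sinusoid-plus-linear drift and i.i.d.
  Gaussian noise (default SD 0.15 of the unit pulse amplitude — noise at
  ~15 % of signal, drift amplitude 0.3). The decay constant is
  deliberately fast: with a slow (~1 s) decay and a 0.3 amplitude
  threshold, binarized offsets trail the true state change by ~12
  frames, which is inconsistent with frame-accurate edge recovery and
  with active-time recovery at the 0.02 level. With τ_rise = 0.2 s,
  τ_decay = 0.08 s and θ_amp = 0.3, both threshold crossings fall within
  one 10 Hz frame of the true edges (crossing time = τ·ln(1/θ)); this
  was derived analytically, not tuned against test outcomes.
* **Reproducibility** — one RNG stream per `generate_islet()` call,
  seeded from `config$seed`, consumed in the documented order; the
  caller's RNG state is restored afterwards.

**What the generator does not emulate** — and hence what a green test
does *not* establish: ionic/metabolic β-cell biophysics, 3-D geometry,
non-β cell types and heterotypic contacts, motion artefacts,
photobleaching beyond linear drift, glucose-dependent recruitment, or
the empirical effect sizes of real islets (e.g. the measured same- vs
different-community percentage differences). Tests against this world
verify that the *pipeline recovers what was planted*, not that real
islets behave this way.

## 7. The sustained-phase window

All network and parameter analyses run on the sustained phase. Its bounds
are not prescribed numerically anywhere, so the pipeline defaults to
`[stimulus + first-quartile response time + 60 s, end of recording]` —
late enough that the activation transients of three quarters of cells are
over well before the window starts, early enough to keep several minutes
of oscillations. It is overridable (`sustained_window`), and the value
used is always echoed in the manifest.

## 8. Numerical and degenerate-input conventions

* Flat cells: inactive (binarization), zero correlation row (networks),
  excluded from hub eligibility.
* Zero oscillations in the window: frequency 0 but duration `NA` — an
  undefined flag, never silently 0. Empty distance bins likewise `NA`.
* Ties: all top-1/6 selections and the rank cut break ties by ascending
  index; tied correlations at the threshold trigger a warning.
* Exact Mann–Whitney p values fold U to `min(U_a, U_b)` and take the
  plain tail probability of the folded statistic (the fold already pools
  both tails).
* Wave-count monotonicity in `R_t` holds for the unfiltered
  decomposition; with a minimum wave size, merging two sub-threshold
  fragments can legitimately create a wave.
* `generate_islet()` validates its configuration strictly (minimum 12
  cells so top-1/6 sets are non-empty, grid factorization no more
  elongated than 4:1, probability bounds), and the pipeline names the
  failing stage in every error.

## 9. Known limitations

* Louvain community detection is order-dependent; results are exactly
  reproducible at a fixed seed but only near-invariant under node
  relabelling.
* The wave detector merges waves that overlap in space and time (it
  reports fewer, larger waves at high wave rates) and cannot split a
  wave that re-enters the same territory within `R_t`.
* Human-mode (0.33 Hz) response times are quantized to 3 s frames, which
  bounds the achievable rank correlation with continuous ground truth.
* `ΔP̄(d)` bins at large distances can be thin; the default `d_max` (90th
  percentile of pair distances) trims the noisiest tail but profiles
  should be read together with their `n_pairs`.
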