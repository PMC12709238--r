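# isletnet

Functional-network and spatial analysis of collective β-cell Ca²⁺ dynamics
in pancreatic islets.

β-cells respond to glucose with Ca²⁺ oscillations that are coordinated
across the islet through gap-junctional coupling. Recordings of this
activity — per-cell fluorescence traces from mouse tissue slices sampled at
10 Hz, or per-15 µm-subregion (ISR) traces from isolated human islets
sampled at 0.33 Hz — carry a rich multicellular structure: intercellular
waves, functional subpopulations (hub cells, wave initiators, first
responders), and a modular network organization that mirrors the spatial
clustering of signalling phenotypes. `isletnet` implements that analysis
chain as a tested, reusable R pipeline, together with a synthetic-islet
generator with ground-truth labels so that every stage can be verified
without experimental data.

## The analysis

Given a trace matrix **F** (time × cells), positions, and a stimulation
onset:

1. **Conditioning** — zero-phase band-pass filtering (mouse mode,
   0.035–1.5 Hz) or high-pass filtering (human mode, 0.0075 Hz), then
   adjacent averaging. Zero phase shift means threshold crossings are not
   displaced in time.
2. **Binarization** — a cell is active where its filtered signal exceeds
   `median + θ·(q95 − median)`; brief runs are removed and brief gaps
   bridged. Per-cell parameters over the sustained phase: relative active
   time, oscillation frequency *f*, mean oscillation duration *Dur*, and
   the response time after the glucose step. The earliest-responding 1/6 of
   cells are *first responders*.
3. **Waves** — onset events `(cell, t)` are linked when within `R_s` µm and
   `R_t` s of each other; connected components of this space–time graph are
   intercellular waves, with activation ranks inside each. Cells most often
   among the earliest activators (top 1/6 by score) are *wave initiators*.
4. **Networks** — the Pearson correlation matrix of the filtered traces
   over the sustained phase is thresholded by rank so the mean node degree
   is exactly the target `k_avg = 8`; *hub cells* are the top 1/6 by
   degree. Communities are found by Louvain modularity maximization, with
   Newman–Girvan `Q = Σ_c [e_c/m − (d_c/2m)²]` computed independently.
5. **Spatial statistics** — the distance-binned mean absolute parameter
   difference `ΔP̄(d) = (1/N(d)) Σ |P_i − P_j|` for pairs with
   `d ≤ d_ij < d + Δd`; same- vs different-community neighbourhood
   contrasts within the local radius (1.5× the mean 6-neighbour distance,
   or 22 µm on the ISR grid) tested by Mann–Whitney U; overlap between
   network communities and hierarchical clusters (Euclidean / active-time /
   response-time metrics) via maximum-agreement label matching against a
   shuffle baseline; and eight equal-area concentric regions of the islet
   hull to localize each subpopulation.

## Worked example

```r
library(isletnet)

cfg <- run_config("mouse", seed = 1)   # synthetic 150-cell mouse-like islet
res <- run_islet_pipeline(cfg)
res
#> <islet_result> 150 cells (mouse mode)
#>   k_avg = 8.00 (target 8), 21 communities, Q = 0.756
#>   50 waves, sustained window [127, 360] s

head(res$params, 3)
#>              cell active_time    freq_hz    dur_s response_time_s first_responder
#> cell_000 cell_000   0.2823378 0.05586592 5.053846             6.9           FALSE
#> cell_001 cell_001   0.2922217 0.06016330 4.857143            20.1           FALSE
#> cell_002 cell_002   0.2870649 0.06016330 4.771429            10.8           FALSE

ct <- res$contrasts$active_time
c(same = ct$median_same, diff = ct$median_diff, p = ct$test$p)
#>        same        diff           p
#> 1.89e-02    4.90e-02    6.99e-26
```

The network achieved a mean degree of 8.00 by placing the correlation
threshold at r = 0.826. Exactly ⌈150/6⌉ = 25 cells are flagged as hubs,
first responders and wave initiators. Active-time differences between
nearby same-community cells (median 0.019) are well below those between
nearby different-community cells (median 0.049) — the spatial signature of
modular organization the pipeline is built to quantify. Against the
generator's ground truth, the detected communities recover the planted
modules (adjusted Rand index ≈ 0.93 on this seed), and true wave-initiator
cells score ≈ 3.6× higher than other cells on the initiator index (mean
over seeds 1–10).

A full run writes plain-text results (`params.csv`, `waves.json`,
`net.graphml`, `manifest.json`, …) via
`run_islet_pipeline(cfg, out_dir = "out")`, and `make_report(res, "out")`
renders the summary figures. A minimal command-line interface is installed
at `inst/cli/islet.R` (`simulate`, `run`, `report` subcommands).

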