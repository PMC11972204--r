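# layerquartet

Simulation and analysis of mesoscopic, depth-resolved (laminar) fMRI
responses to the bistable **motion quartet** — a four-dot apparent-motion
display that is alternately perceived as horizontal or vertical motion.
Contrasting an unambiguous ("physical") version of the quartet with the
ambiguous one turns the paradigm into a feedforward-vs-feedback probe: during
physical motion V1 receives stimulus-driven feedforward input, while during
ambiguity the retinotopic V1 territory between the inducers is driven mostly
by feedback (putatively from hMT+). The package is for methodologists and
layer-fMRI practitioners who want a fully ground-truthed, scanner-free
implementation of that analysis chain.

## What it implements

* **Design** — frame-accurate quartet timing (9 frames on / 4 frames gap at
  60 Hz → 2.3-Hz apparent-motion cycle), block schedules (10-s motion
  blocks, 80-s super-blocks, 16-s flicker, 20-s fixation bookends, TR 2 s),
  truncated-gamma percept-switch streams (dwells in 3–20 s) and the 5-s
  switch-rate screening rule.
* **Generator** — cortical patches with columnar H/V preference, exact
  equivolume depth from an annulus area-fraction rule, and laminar BOLD with
  a linear draining-vein model:

  `PSC_c(d) = mu_c * p(d) + g * d * mean_column(mu_c * p)`

  (microvascular amplitude `mu_c`, unit-mean depth profile `p`
  — middle-layer-weighted for feedforward, uniform for feedback — and a
  macrovascular term rising linearly with equivolume depth `d`). Feedback
  scenarios: `hypothesis1` (cluster-matched feedback), `hypothesis2` (both
  V1 clusters equally active), `null`, `matched`.
* **GLM** — percent-signal-change normalization (`y / mean(y) * 100`),
  HRF-convolved designs (three predictors: horizontal, vertical, flicker;
  percept-locked in ambiguous runs), DCT high-pass (5 cycles/run), AR(2)
  prewhitening (two Cochrane–Orcutt iterations, Yule–Walker), balanced
  H>V contrast t-maps.
* **Clusters & specificity** — 95th-percentile winner-take-all cluster
  definition per hemisphere, cluster PSC summaries, and a rescaled-cosine
  selectivity score in [0, 1] (equal response → 0, pure preference → 1).
* **Laminar analysis** — column-wise cluster extension (tangential radius
  0.39), three equivolume layers, differential (physical − ambiguous)
  profiles, and per-subject slope tests against zero.
* **Event-related averages** — onset-locked PSC trials (`(t − t0)/t0·100`),
  ≥ 10-s trial selection, 5-TR balanced window, preferred/not-preferred role
  pooling, Spearman similarity with exact Wilcoxon group tests.
* **Statistics** — an exact two-sided Wilcoxon signed-rank test (shift
  convolution over tie-averaged ranks, exact for N ≤ 25 even with ties).

## Worked example

```r
library(layerquartet)

cfg <- pipeline_config(seed = 7, runs_per_condition = 2, n_columns = 12,
                       voxels_per_column = 6, repetitions = 3)
res <- run_pipeline(cfg)      # simulate -> GLM -> clusters -> laminar -> ERA
g   <- res$group
```

On this hypothesis-2 cohort (8 subjects × 2 hemispheres) the run prints:

```
recovery: 1.00
V1 H cluster PSC: physical 4.58 vs ambiguous 2.03, exact p = 3.05e-05 (N = 16)
hMT H cluster PSC: physical 4.37 vs ambiguous 4.05, exact p = 0.175
V1 specificity: 0.958 vs 0.276, p = 0.0078
V1 differential slope: 0.71 PSC/unit depth, p = 0.0391
hMT differential slope: 0.38 PSC/unit depth, p = 0.15
```

Reading: every ground-truth cluster voxel was recovered by the
winner-take-all mapping; V1 responses drop by half during ambiguity
(smallest attainable exact p at N = 16 is 2/2^16 ≈ 3.05e-05) while hMT+ is
condition-invariant; V1 selectivity collapses during ambiguity because both
retinotopic clusters respond (the hypothesis-2 signature); and the
differential laminar profile keeps a positive slope in V1 (draining-vein
increase present only at full feedforward drive) but not in hMT+.

The numbered scripts under `analysis/` run the same workflow at the default
study scale and write stage tables and figures under `results/`:

```sh
Rscript analysis/01_design.R          # schedules, events TSVs, arithmetic
Rscript analysis/02_simulate_and_fit.R
Rscript analysis/03_cluster_psc.R
Rscript analysis/04_specificity.R
Rscript analysis/05_laminar.R
Rscript analysis/06_era.R
```

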