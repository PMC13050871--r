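# ribbonquant

Quantification pipeline for activity-dependent structural plasticity at
cochlear inner-hair-cell (IHC) ribbon synapses. Early postnatal IHCs fire
spontaneous calcium action potentials, and the structure of their afferent
synapses — the presynaptic ribbon (marker: RibeyeA/CtBP2), its Ca_v1.3
calcium-channel cluster, and the postsynaptic density (marker: PSD95) —
remodels with that activity. `ribbonquant` implements the full measurement
chain used to study this in organotypic cochlear cultures:

- **2D-STED cluster areas** — Gaussian blur (σ = 1 px), Kapur
  maximum-entropy dark thresholding, watershed separation of touching
  clusters, a strict > 50 px size filter, moment-matched ellipse fits, and
  Spearman/OLS correlation of paired CtBP2 vs Ca_v1.3 areas (15 nm pixels).
- **3D puncta reconstruction** — an open, parameterized surface pipeline
  (local background subtraction, smoothing at a surface-detail grain,
  entropy auto-threshold, 26-connected components, distance-transform-
  seeded watershed with seed suppression at a split distance, quality
  filter), with the four published parameter profiles preloaded
  (`ribbon-wt`, `psd-wt`, `ribbon-ko`, `psd-ko`) and per-object volume /
  integrated intensity measured on the raw stack (80 × 80 × 200 nm voxels).
- **Synaptic engagement** — each ribbon is assigned its nearest PSD by
  minimum surface-to-surface distance; ribbons with distance < 0.5 μm are
  synaptically engaged, the rest cytoplasmically floating; counts are
  normalized per IHC.
- **Activity traces** — GCaMP time-lapse ROI masking (maximum projection →
  entropy threshold → size filter), ΔF − F₀ baseline correction, and peak
  frequency in min⁻¹; current-clamp supra-threshold event detection at
  V_m = −35 mV with trapezoidal spike-integral (AUC, mV·s).
- **Optogenetic schedules** — the evenly spaced `oSparse` protocol (5 ms
  pulses at 5 Hz, one every 200 ms) and the `oBurst` protocol (five 5 ms
  pulses at 50 Hz once per second), dose-matched at 18,000 pulses per
  one-hour session, with exact integer-microsecond bookkeeping.
- **Statistics** — Mann–Whitney U (exact for small samples), Welch and
  paired t, Shapiro–Wilk, one/two-way ANOVA (type-II SS) with Šídák /
  Holm-Šídák / Dunn post-hoc corrections, reported with medians + IQR and
  means ± SEM.

A synthetic-data generator (`synth_config()`, `make_confocal_stack()`,
`make_sted_pair_frames()`, `make_gcamp_trace()`, `make_voltage_trace()`)
produces every input with a ground-truth manifest, so the entire pipeline
is testable without any raw microscopy or electrophysiology data.

## Worked example

```r
library(ribbonquant)

sim <- make_confocal_stack(synth_config(seed = 7))
ribbons <- reconstruct(sim$stacks$ribbon, recon_profile("ribbon-wt"))
psds    <- reconstruct(sim$stacks$psd,    recon_profile("psd-wt"))
asg <- classify_ribbons(attr(ribbons, "labels"), attr(psds, "labels"),
                        sim$stacks$ribbon$voxel_size_um)
summarize_engagement(asg, sim$manifest$n_ihc)
```

On this stack the pipeline reconstructs 15 of the 16 generated ribbons and
all 16 PSDs, and classifies 13 ribbons as synaptic and 2 as cytoplasmic
(4.33 and 0.67 per IHC with 3 IHCs in the ROI) — matching the generator's
ground truth, which placed 13 of 16 partner PSDs within the 0.5 μm rule.

The numbered scripts under `analysis/` run the whole workflow and write
tables under `results/`:

```
Rscript analysis/01_simulate_inputs.R       # synthetic stacks, frames, traces
Rscript analysis/02_sted_area_correlation.R # n = 99: r_s = 0.369, p = 1.7e-4
Rscript analysis/03_reconstruct_and_engage.R
Rscript analysis/04_activity_traces.R       # 12 peaks -> 1.20 min^-1; 10 events
Rscript analysis/05_protocols.R             # 18,000 pulses, 90 s on-time each
Rscript analysis/06_statistics.R
```

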