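---
title: "Quantifying ribbon-synapse structure and activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribbon-synapse structure and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonquant)
```

`ribbonquant` measures structural and functional properties of cochlear
inner-hair-cell (IHC) ribbon synapses: cluster areas in 2D-STED frames,
puncta volumes and intensities in confocal z-stacks, synaptic-engagement
classification, calcium- and voltage-trace event statistics, and the
patterned optogenetic stimulation schedules used to drive activity. This
vignette explains the models behind each stage, the parameters that
matter, and the choices made where the underlying methods (notably the
commercial surface-reconstruction tool the field uses) leave the
algorithm under-specified.

## 1. The 2D-STED cluster-area routine

Single synapses are imaged as 1 × 1 μm two-colour STED crops at 15 nm
pixels, one ribbon (CtBP2) and one calcium-channel (Ca_v1.3) cluster per
crop. The routine is deliberately simple and fully specified:

1. Gaussian blur, σ = 1 px, symmetric (reflective) boundaries.
2. Kapur–Sahoo–Wong maximum-entropy threshold over a 256-bin equal-width
   histogram; candidate thresholds are interior bin edges; foreground is
   strictly above the threshold (dark-background convention); ties go to
   the lowest edge. The implementation is verified in the test suite
   against exhaustive enumeration of the Kapur objective.
3. Watershed separation of touching clusters (section 3 describes the
   shared watershed core).
4. Size filter: objects *larger than* 50 px survive — a strict
   inequality, so a 50-px object is discarded and a 51-px object kept.
5. Moment-matched ellipse per survivor: orientation and aspect from the
   second-order central moments of the binary region (with the 1/12 px²
   per-pixel term of a uniform square pixel), rescaled so the ellipse
   area equals the region's pixel area. The reported `area_um2` is the
   calibrated mask area (pixel count × pixel area); the ellipse is a
   shape descriptor only, since mask area is the unambiguous quantity.
6. One pair per crop. If several objects survive in one channel the
   largest is used and the crop is flagged (`multi`), because the crop
   geometry is designed around a single synapse.

Paired areas are summarized by a two-sided Spearman rank correlation and
an OLS fit with 95% confidence intervals.

## 2. Synthetic data: what it emulates and what it does not

All inputs are generated with ground-truth manifests.

**Confocal stacks** (`make_confocal_stack`): a 72 × 72 × 36-voxel volume
at 80 × 80 × 200 nm (≈ 5.8 × 5.8 × 7.2 μm, the scale of a few IHC
basolateral poles), 16 ribbons with log-normal radii (median 0.18 μm,
σ_log 0.2), one partner PSD per ribbon (median radius 0.22 μm), log-normal
peak intensities (median 150 a.u., σ_log 0.25) on a 20 a.u. background
with Poisson shot noise and Gaussian read noise (SD 3). Spots are rendered
as Gaussians whose per-axis σ combines the object's own extent (radius/2)
with a confocal-like PSF (σ 0.09 μm laterally, 0.3 μm axially) in
quadrature — analytically identical to rendering then convolving.
Placement is by rejection sampling with a 0.6 μm minimum centre
separation per channel; an impossible request fails explicitly rather
than degrading.

Engagement ground truth: a chosen fraction of ribbons (default 0.8, as
most ribbons in control cultures are synaptic) receive their PSD at a
surface gap drawn from (0.05, 0.25) μm, the rest from (0.7, 1.5) μm.
These ranges clear the 0.5 μm classification rule by more than the
voxelization error: discretizing a sphere can *increase* the apparent
surface gap by up to about one voxel diagonal (0.23 μm) but never
decrease it, so 0.25 + 0.23 < 0.5 < 0.7. The manifest's engaged flags are
nonetheless computed from the rendered label volumes with the same exact
voxel-surface distance the classifier uses, and the test suite re-derives
them with an independent O(n²) brute-force check. Non-partner
ribbon–PSD gaps are constrained to ≥ 0.7 μm during placement so the
nearest-neighbour assignment is unambiguous.

The number of IHCs in the field is carried in the manifest (default 3)
rather than inferred from the rendered context channel, mirroring the
manual cell counting used in practice.

**STED pairs** (`make_sted_pair_frames`): true areas for the two channels
are drawn from a Gaussian copula with latent Pearson correlation
r = 2·sin(πρ_s/6), which yields the target Spearman ρ_s exactly for the
continuous margins used (log-normal areas, median 0.04 μm², σ_log 0.35 —
comfortably above the 51-px ≈ 0.011 μm² size filter). Blobs are rendered
as flat-top (super-Gaussian) ellipses with area-preserving ellipticity.
Over 200 replicates at n = 99 the mean sample Spearman recovers any
target in {−0.8, 0, 0.35, 0.8} within ±0.05.

**Traces**: GCaMP traces are sampled at the 0.78 s time-lapse interval:
baseline + linear drift + a fast-rise/exponential-decay transient at each
true peak time + Gaussian noise. Transient kinetics default to
τ_rise = 0.5 s, τ_decay = 3 s — the slow GCaMP6s regime appropriate for
the seconds-long spontaneous activity waves of the immature cochlea.
Voltage traces place Gaussian-shaped spikes (σ = 10 ms) on a resting
potential (default −58 mV), and record the analytic per-spike integral
A·σ·√(2π) as ground truth.

What the generator does **not** emulate: STED depletion physics, spectral
bleed-through, anatomically realistic cell shapes, ribbon/PSD morphology
beyond spheres, photobleaching, or correlated (structured) noise. Passing
tests therefore demonstrate that the algorithms recover a *known* truth
under controlled optics-like degradation — not performance on real
tissue, where segmentation parameters must still be validated per
dataset.

## 3. The 3D surface pipeline and its parameter mapping

The commercial tool's surface semantics are proprietary, so each named
parameter is mapped to a documented, overridable convention:

| parameter | mapping |
|---|---|
| surface detail (μm) | σ of the pre-threshold Gaussian smoothing |
| max sphere diameter (μm) | background Gaussian σ = diameter/2 per axis |
| split distance (μm) | minimum physical separation of watershed seeds, and 2h of the basin-merging dynamic |
| quality | maximum background-subtracted intensity within the object |

The pipeline is: local background subtraction (raw − blurred, clipped at
0) → smoothing at the surface-detail grain → threshold → 26-connected
components → seeded watershed → quality filter → measurement on the raw
stack. All σ conversions go through the physical voxel size, so the
2.5-fold z-anisotropy of confocal stacks is handled explicitly; a
spherical test object comes back with isotropic physical extent to within
one z-step.

The four published parameter profiles are preloaded: ribbons at
0.048/0.280 μm (split 0.150 μm) and PSDs at 0.150/0.520 μm for the main
datasets; 0.140/0.250 μm (split 0.350 μm) and 0.163/0.611 μm for the
knockout-analysis sets. Where no split distance is published (PSDs) it
defaults to the surface detail.

**Thresholding.** The auto-threshold applies the same Kapur
maximum-entropy criterion as the 2D routine, for internal consistency,
to the smoothed background-subtracted stack (the same array the mask is
taken from). A numeric override is supported because no threshold values
are published. Entropy thresholds assume a signal/background mixture; on
a stack containing *only* noise the criterion lands mid-noise and would
segment a large fraction of the volume. Puncta occupy well under 1% of a
real stack, so a mask exceeding 3% of the volume under the auto-threshold
is treated as signal-free. One further guard: detections smaller than
`min_voxels` (default 4, ≈ 0.005 μm³ — far below any ribbon) are
discarded as isolated shot-noise voxels, the 3D analogue of the 2D
routine's own 50-px filter.

**Watershed.** One seeded-watershed core serves both 2D and 3D paths:
exact anisotropic Euclidean distance transform (Felzenszwalb–Huttenlocher
separable algorithm), seeds at EDT local maxima, priority-flood label
growth with deterministic tie-breaking. Two refinements proved necessary
beyond the naive "maxima + minimum separation" recipe. First, seed
candidates must lie more than one voxel diagonal inside the surface —
boundary-roughness maxima (one noisy voxel protruding from a blob)
otherwise nucleate spurious fragments. Second, after flooding, basins are
merged by *dynamics*: a basin whose EDT peak rises less than h = split
distance/2 above its highest saddle to a neighbour is merged into that
neighbour, weakest first. This is the standard morphological h-maxima
criterion; it removes roughness-driven splits while preserving genuine
waists between touching puncta (a waist whose depth exceeds half the
split distance still separates). On the default noisy stacks these two
rules take recovery from heavy over-segmentation (38 objects for 16 true
puncta) to 159/160 detected with zero false positives. Every connected
component is guaranteed at least one seed, so the labels always
partition the mask.

**Quality.** Quality is the object's peak background-subtracted
intensity; the "auto" cutoff reuses the surface threshold (a real object's
peak must clear the level its own mask was cut at). No quality values are
published, so this too is an explicit convention, and raising the cutoff
can only shrink the object list.

## 4. Engagement classification

The surface-to-surface distance between two voxelized objects is the
minimum Euclidean distance between voxel centres, 0 when the sets overlap
or touch (26-adjacency). This is well-defined and oracle-checkable; it
differs from a sub-voxel mesh distance by at most one voxel diagonal,
which is why the generator keeps its gap ranges clear of the cutoff by
more than that. The accelerated implementation (hashed adjacency test
plus axis-sorted pruned search) is tested against an O(n²) scan over all
voxel pairs. Classification is nearest-PSD with a strict `< 0.5 μm` rule
— a ribbon at exactly 0.5 μm is cytoplasmic — and counts are divided by
the explicit IHC count. Classification is invariant under label
permutation and rigid translation, and lowering the cutoff can only
reduce the synaptic count.

## 5. Trace analysis

**Calcium.** ROI masks come from the temporal maximum-intensity
projection (entropy threshold, then removal of components < 20 px); the
trace is the per-frame masked mean. Baseline correction subtracts F₀ —
by default the 10th percentile of the trace, a definition that equals
the true baseline exactly whenever transients occupy less than 90% of
samples; a mean-of-initial-samples mode is provided, and the mode and
value used are always recorded, since ΔF − F₀ is otherwise ambiguous.

Peak counting applies a 5-sample moving average (noise reduction matched
to the slow indicator kinetics) and keeps local maxima whose topographic
prominence exceeds 6× a robust noise estimate — the MAD of the first
differences of the smoothed trace, rescaled by √(k/2) for the k-sample
smoothing autocorrelation, which is independent of the signal itself. The
floor is set at 6σ because band-limited noise extrema reach ~5–6σ
prominence over typical inter-event intervals; a lower multiple (e.g. 4×)
admits false peaks at *any* noise level, since both the floor and the
noise prominence scale with σ. At signal-to-noise 5 the transients retain
~8σ prominence after smoothing and recovery of a 12-peak, 10-minute trace
is exact in 48 of 50 seeds (the remainder being the resolution limit at
that boundary); recovery is exact at SNR ≥ 10 and for noise-free traces.
Two transients closer than one 0.78 s sample merge into one peak — a
sampling limit, not a detector choice. Frequency is peaks per minute of
the nominal recording duration.

**Voltage.** Supra-threshold events are maximal runs above −35 mV (the
action-potential threshold used for these cells), merged when their
extensions meet without an intervening return to baseline, then extended
outward to the surrounding baseline crossings. The baseline is the median
of sub-threshold samples ("rmp" mode) or a user value. AUC is the
trapezoidal integral of (V − baseline) over the extended event, reported
in mV·s. Published spike-integral values for this preparation carry no
units, so they are not reproduction targets; the package's AUC is
dimensionally explicit instead. The event count is monotone
non-increasing in the threshold for noise-free (unimodal-spike) traces;
with noise, a run can split at the threshold crossing — the merging rule
above absorbs exactly the splits that never return to baseline.

## 6. Stimulation schedules

Both protocols deliver 5 ms pulses and are dose-matched: `oSparse` fires
at 5 Hz (every 200 ms, from t = 0); `oBurst` fires five pulses at 50 Hz
(every 20 ms) at the start of each 1 s epoch, then rests ≈ 915 ms. Over a
3600 s session each delivers exactly 18,000 pulses and 90 s of light
(duty cycle 0.025). Epochs are phase-locked to the session start, with
the first pulse at t = 0; both choices are configurable. Times are exact
integer microseconds internally, so an hour-long schedule accumulates no
floating-point drift, and the audit (counts, on-time, duty, onset
intervals) is computed from the pulse list itself and validates the
non-overlap invariant.

## 7. Statistics

Two-group comparisons use the Mann–Whitney U test (exact enumeration when
the smaller group has ≤ 8 observations and no ties — verified against
full permutation enumeration in the tests — otherwise midranks with
normal approximation and continuity correction), Welch's t, or the paired
t-test (a zero-variance paired difference is reported as t = 0, p = 1).
Factorial designs use one-way ANOVA or, for two factors, type-II sums of
squares with an interaction term (the conventional default for unbalanced
layouts). Post-hoc pairwise comparisons between design cells are Welch
t-tests corrected by Šídák (1 − (1 − p)^m) or step-down Holm–Šídák; a
rank-based Dunn variant and a Dunnett-T3-style option (Welch pairwise
with a Šídák bound standing in for the studentized-maximum-modulus
critical value — a conservative, documented approximation) complete the
menu. Shapiro–Wilk covers 3 ≤ n ≤ 5000. The omnibus type-I error is
calibrated by simulation: over 1000 null datasets (3 groups × 10), the
rejection rate at α = 0.05 falls within [3.5%, 6.5%].

## 8. Problem sizes and determinism

Everything is seeded and bit-reproducible: identical configuration and
seed give identical stacks, frames, traces and schedules. The shipped
tests and the acceptance script use 72³-scale stacks with 16–50 puncta
(single stacks reconstruct in well under a minute), 200-replicate
correlation calibrations at n = 99, 10-minute traces, hour-long pulse
schedules, and 1000-replicate null calibrations — sizes chosen so the
statistical claims are sharp at a few percent while a full run stays
interactive on a single core.

## 9. Known limitations

- Sphere-based morphology: real ribbons are ellipsoidal-to-droplet
  shaped and PSDs are plaque-like; volume and engagement biases under
  non-spherical geometry are untested.
- The voxel-centre surface distance deviates from mesh-based distances
  by up to one voxel diagonal near the cutoff; borderline synapses
  (0.4–0.6 μm) can classify differently than a mesh-based tool.
- The entropy auto-threshold assumes sparse, bright objects; dense or
  dim stacks need a manual threshold.
- No bleed-through or colocalization-by-chance correction: channels are
  assumed spectrally clean.
- Peak counting at SNR ≈ 5 is at its resolution limit; below that,
  counts are not reliable and no attempt is made to extrapolate.
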