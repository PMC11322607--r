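---
title: "Quantifying T-cell attack on ECM-embedded tumoroids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T-cell attack on ECM-embedded tumoroids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The assay and its readouts

The package analyses co-cultures in which a multicellular tumor spheroid
("tumoroid", initial diameter around 150 µm) is embedded in a collagen gel,
T-cells and a bispecific antibody (bsAb) are added on top of the gel, and the
well is imaged as a three-channel confocal z-stack over several days: a
nuclear stain labels all tumor nuclei, propidium iodide (PI) labels dead
cells, and a cytoplasmic tracker labels T-cells. Stacks use a 10 µm z-step
and an hourly frame interval by default.

Two scalar readouts summarise each timepoint:

* **killing fraction** — the fraction of PI-positive tumor nuclei pooled over
  every z-plane of the tumoroid;
* **T-cell recruitment count** — the sum over z-sections of T-cell objects
  whose centroid lies inside the tumoroid boundary.

An effective bsAb produces a characteristic sequence: an initial phase of
random T-cell migration through the gel, a contact-triggered wave of T-cell
recruitment into the tumoroid, and finally large-scale killing during which
T-cell localisation declines again. The package reproduces this sequence on
synthetic data and measures it with the same operations that would be applied
to real stacks.

## Segmentation and masking

Each z-plane of each channel is segmented independently: Gaussian smoothing
(default σ = 2 µm), a global threshold (per-plane Otsu, or a fixed value for
reproducibility across planes — the pipeline default is a fixed 0.1 on the
16-bit-normalised intensity scale, which is robust on planes that contain no
objects, where Otsu would split background noise), an optional
distance-transform watershed that splits touching objects, and an area filter
(default 20–2000 µm²). Labels are assigned deterministically in raster order,
so reruns are bit-identical.

The tumoroid boundary is built per plane from the nuclei channel: the union
of nucleus footprints is morphologically closed with a disc (default radius
15 µm, about twice the nucleus spacing, enough to bridge gaps between
neighbouring nuclei without inflating the outline) and hole-filled. A T-cell
belongs to the tumoroid iff its centroid falls on a mask-true pixel; a
centroid exactly on a boundary pixel counts as inside. This centroid rule
(rather than any-pixel overlap) is unambiguous and conserves counts:
inside plus outside detections always equal the input.

PI objects are related to nuclei the same way: a PI object is assigned to
the nucleus whose footprint contains the PI centroid, PI signal over
background is discarded, and a nucleus is dead iff at least one PI object is
assigned to it (so several PI fragments in one nucleus count once). The
centroid semantics were chosen over pixel-overlap because they are exact,
order-independent and idempotent; on blob-rendered data the two rules agree.

Counting note: the per-plane z-sum counts a T-cell once per plane it appears
in. With a 10 µm z-step and cell-sized objects a cell can span up to two
planes, a known small inflation that is kept because it is exactly how the
readout is defined.

## 3D tracking

T-cell volumes are thresholded per timepoint and 26-connected components are
labelled in 3D (compiled union-find). Components are retained iff their
physical volume lies **strictly** between 280 and 10,000 µm³ — the expected
volume range of a single cell; merged clumps and debris fall outside the
gate. Positions are intensity-weighted centres of mass in µm (anisotropic
voxels are handled through the lateral and axial calibrations).

Frame-to-frame linking solves, for each consecutive frame pair, the global
minimum-cost one-to-one assignment over detection pairs within a
displacement gate (default 30 µm per frame, which comfortably exceeds the
diffusive-plus-directed step of the default motility). The assignment is
computed with the Hungarian algorithm (Jonker–Volgenant shortest augmenting
path, compiled); among all maximum-cardinality gated matchings the cheapest
one is selected, and the result is verified in the test-suite against
exhaustive enumeration for small frames. Unmatched detections end or begin
tracks. There is **no gap closing**: a detection missing for one frame
splits its track. This is deliberate — it keeps the linker deterministic and
simple, and the subsequent duration filter (default 10 h, matching the data
requirement of the diffusive-fraction statistic at its 10 h lag) removes the
fragments.

## Motility model

For a track sampled at uniform intervals the time-averaged mean squared
displacement at lag τ averages the squared 3D displacement over **all**
ordered position pairs separated by τ (overlapping windows — the standard
estimator; the test-suite checks it against a brute-force double loop to
1e-10 relative error). Per-cell curves use lags 1–25 h, capped at half the
track length to avoid the noisy high-lag tail; the population curve uses
lags 1–30 h and reports mean, SD and the number of contributing tracks per
lag.

The two-component motility model is

    msd(τ) = 4 D τ + v² τ²

with a diffusion coefficient D (µm²/h) and a directed speed v (µm/h). The
fit is unweighted least squares in the parameters (a, b) = (4D, v²), both
constrained non-negative: the unconstrained two-term solution is used when
admissible, otherwise the best of the clipped one-term solutions. Pair-count
weighting is available as an option but is off by default since the
reference procedure states none.

A convention worth being explicit about: the diffusive term uses the
two-dimensional prefactor 4D, but it is applied verbatim to 3D
displacements. The package keeps this exactly as printed. The consequence
is a fixed mapping to the generator's per-axis diffusion coefficient
`d_axis`: a pure random walk has 3D MSD `6 · d_axis · τ`, so the fitted D
equals `1.5 · d_axis`. All parameter-recovery tests assert against this
mapping rather than against `d_axis` itself.

The **diffusive fraction** compresses a fit into one number: the share of
the MSD at a fixed lag t_D explained by the diffusive term,

    f_D = 1 / (1 + v² t_D / (4 D)),

evaluated at t_D = 10 h by default. It is 1 for purely diffusive motion, 0
for purely directed motion, strictly increasing in D and strictly decreasing
in v and t_D, and undefined (flagged `NA`) for a degenerate fit with
D = v = 0. Populations are summarised by median and SD per parameter, and
compared with a Kruskal–Wallis test followed by Dunn's pairwise post-hoc
z-statistics with tie correction (Bonferroni-adjusted by default, matching
the adjustment used elsewhere in the package; the Dunn statistic is
implemented in-package and cross-checked in the tests against an independent
computation from the rank machinery).

Killing between conditions is compared with a two-way ANOVA (condition ×
concentration) followed by Bonferroni-adjusted contrasts of each condition
against a designated reference, computed through estimated marginal means
(`emmeans`). Killing can be normalised to a positive control (percentage of
the mean control killing fraction; values above 100 are allowed).

## The synthetic generator

No raw imaging accompanies the assay, so the package ships a ground-truthed
generator used by every test. It has three layers:

1. **Geometry** — `make_tumoroid()` packs nuclei uniformly into the tumoroid
   sphere by dart throwing with a hard minimum spacing (default 7 µm);
   packing failure raises an error naming the density.
2. **Dynamics** — `simulate_tcells()` is an agent-based simulation with 0.1 h
   sub-steps sampled at the frame interval. Every T-cell performs a per-axis
   Gaussian random walk (variance `2 d_axis dt` per axis). With
   `switch_mode = "on_first_contact"`, the first T-cell to come within the
   contact radius of the tumoroid surface triggers the recruitment phase,
   standing in for the paracrine signal of the real assay: from then on,
   cells within the sensing radius drift at constant speed toward the
   tumoroid, and cells that have arrived steer toward their nearest
   surviving nucleus, so the attack sweeps the sphere from the outside in.
   Nuclei simultaneously contacted by the required number of T-cells die
   with a fixed hazard; PI appears after an onset delay. Once the surviving
   fraction drops below `disengage_alive_frac` the recruitment signal
   ceases and intratumoral cells drift back out — this disengagement rule is
   what produces the peak-then-decline recruitment curve of the effective
   condition. Volume faces reflect, which preserves cell counts.
   `switch_mode = "never"` gives the ineffective condition (pure random walk,
   no killing); the two presets differ **only** in switch mode and killing
   parameters, never in geometry. `switch_mode = "always"` forces the drift
   from t = 0 and exists for ballistic benchmarks.
3. **Rendering** — `render_frames()` draws one isotropic Gaussian blob per
   object per channel (default σ = 4 µm, peak 0.6) at its calibrated voxel
   position, adds a constant background (0.02) and Poisson shot noise (200
   photons at full scale), and quantises to a 16-bit grid so that the TIFF
   round trip is bit-exact. Sigmas below one pixel are clamped with a
   warning.

`simulate_trajectories()` is the trajectory-level counterpart for motility
benchmarks: free-space cells with per-axis diffusion plus an optional
constant drift along a random per-cell direction. It exists because the
scene-level simulation deliberately includes walls, phase switches and
target seeking, which are exactly the things one must *exclude* when
checking the estimator against closed forms.

### Study conditions and desk-scale defaults

The default scenario is a desk-scale version of the assay: a 75 µm-radius
tumoroid (the assay's ~150 µm initial diameter) at the centre of a
400 × 400 × 200 µm volume, 300 nuclei (scaled down from the thousands of
cells of a real tumoroid), 100 T-cells entering at the top face, 2 µm/px
lateral calibration, 10 µm z-step, and 72 hourly frames. Scene motility
defaults (`d_axis` = 6 µm²/h, `speed` = 8 µm/h, sensing radius 150 µm,
contact radius 15 µm, kill hazard 0.5/h, PI delay 2 h) were chosen once so
that a collagen-embedded T-cell population covers the scaled geometry on the
72 h clock — contact at hour ~10–20, recruitment peak near hour 35–40,
killing above 0.9 by the final frame — the same phase sequence the real
assay shows over ~6 days at its larger scale. Motility benchmarks use their
own printed conditions (200 cells, 72 frames, `d_axis` = 2 pure diffusion,
`d_axis` = 1 with `speed` = 3 directed) independent of the scene defaults.

### What the generator does and does not emulate

Emulated: two-phase motility, the contact-triggered recruitment wave,
contact killing with delayed PI onset, densely packed nuclei, channel
cross-structure (PI blobs only on dead nuclei), background and shot noise,
anisotropic voxels. Not emulated: optical PSF realism, photobleaching,
stage drift, collagen fibre texture, a mechanistic chemokine
diffusion–decay field (the recruitment signal is a binary switch plus
drift), cell shape, and nucleus movement or division. Passing tests on this
generator therefore validate the *computational* pipeline — its counting
rules, estimators and statistics — not the segmentation's robustness to the
full optical complexity of real microscopy. Noise levels are free
parameters chosen so that default segmentation succeeds, since no raw image
statistics are available to match.

## Numerical and degenerate-input conventions

* Pixel indices are 0-based internally; physical coordinates are
  pixel-centre µm ((i + 0.5) · step); all outputs are in µm.
* A blank plane yields zero objects, not an error; planes with no nuclei
  contribute nothing to either pooled sum and are flagged
  (`zero_denominator`) rather than propagating NaN.
* The volume gate is strict on both sides: a component of exactly 280 µm³
  is rejected.
* Identical groups in the killing comparison give adjusted p = 1 even when
  the residual variance is exactly zero (the NaN from a 0/0 t-statistic is
  resolved to "no evidence of difference").
* All-identical values across Kruskal–Wallis groups give H = 0, p = 1.
* Determinism: every stochastic step takes a seed; identical seeds give
  identical ground truth, stacks, CSV outputs and label grids. Seeds used
  inside multi-stage runs are derived from the configured seed by fixed
  offsets.

## Problem sizes

Test-suite and acceptance runs use the desk-scale defaults above: full
72-frame scenarios for the end-to-end contrasts (a few minutes each on one
CPU), 200-cell populations for parameter recovery, 100-cell scenes for
linking fidelity, and small constructed fixtures everywhere else.

## Known limitations

* The tumoroid boundary procedure is a standard smoothed-threshold +
  watershed + closing pipeline, not a reimplementation of the original
  interactive workflow whose parameters are not recoverable; equivalence is
  asserted at the level of counts and mask geometry on synthetic data.
* No gap closing and no motion-model prediction in the linker; fragmented
  tracks are dropped by the duration filter rather than repaired.
* The constrained MSD fit is slightly biased low in D for purely diffusive
  tracks (the v² term absorbs upward noise curvature); the bias is well
  inside the recovery tolerances and affects all conditions equally.
* The killing ANOVA assumes a complete condition × concentration design;
  heavily unbalanced designs should be compared non-parametrically instead.
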