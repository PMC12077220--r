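---
title: "Methods: thermal motility analysis of microswimmers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal motility analysis of microswimmers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowmotility)
```

# Scope

`snowmotility` implements the analysis chain for temperature-dependent
swimming of ciliated microalgae (snow algae and relatives): simulation of
microswimmer recordings, spot detection and track linking, per-track
motility metrics with motile/non-motile classification, thermal
performance curve (TPC) fitting with bootstrap confidence intervals,
Petri-dish phototaxis scoring, and trait-level cross-species statistics.
Every stage is driven by synthetic data generated inside the package, so
the full chain is testable without any external download. The numbered
scripts under `analysis/` run the chain end to end and write their tables
under `results/`.

# The synthetic recording

Recordings emulate 10 s videos at 30 frames/s of cells in a 20 µm-deep
counting chamber. Because the chamber depth is only a couple of cell
diameters, motion is effectively confined to the focal plane and the
simulation is strictly 2D; the z axis is not modelled. Positions are
emitted at frames $0, \dots, fps \cdot T$ inclusive, so a straight
swimmer covers exactly $speed \times T$ of path — a convenient anchor for
metric tests.

Three behavioural categories cover what the tracker meets in practice:

* **Motile** cells move at a constant per-cell speed drawn from
  $N(\mu_v, \sigma_v)$ (clamped at 0) with a heading that undergoes
  rotational diffusion (`turn_rate_sd_rad_s`, rad/√s) plus a constant
  angular drift (`loop_bias_rad_s`, rad/s). Two parameters suffice to
  reproduce the characteristic alternation of loops and straight runs of
  biciliate swimmers; an Ornstein–Uhlenbeck heading model would add a
  relaxation timescale the downstream metrics never see.
* **Drifting** cells are advected at a fixed velocity plus per-frame
  Gaussian jitter — cells carried by residual flow in the chamber.
* **Stationary** cells show jitter only.

The per-frame jitter stands in for localisation noise of the detector,
not for thermal diffusion (negligible for 5–10 µm cells at these frame
rates). Its default in the analysis scripts is 0.1 µm/frame: apparent
path length of a stationary cell then accumulates to roughly 40 µm over a
10 s track, comfortably below the 100 µm motility threshold — which is
also why the threshold works in practice. Values much above 0.3 µm/frame
would push passive cells over the threshold; a tracker producing such
localisation noise would need the threshold recalibrated from controls.

Walls are reflective (position folded back, heading mirrored). This keeps
tracks in frame without biasing speed; the alternative — discarding
wall-touching tracks — is what the real pipeline's artifact filters do,
and is not needed for synthetic data. Reflection folds the stored
positions, so chord lengths across a reflection are slightly shorter than
the path; tests that assert exact speed recovery therefore use large
arenas.

Detection dropout is i.i.d. per spot; repairing it is the gap-closing
stage's job, mirroring real detection misses. Fixed seeds give
bit-identical spot tables and images.

# Detection and linking

`detect_spots_dog()` band-passes each frame with a difference of
Gaussians at scales $d/(2\sqrt2)$ and $d/2$ for object diameter $d$,
takes strict 8-neighbour local maxima above a quality threshold, and
refines each maximum by a per-axis parabolic fit (±0.5 px clamp).
Quality is the raw DoG response; it is *not* normalised, so thresholds
published for other detectors (for example a "0.67 quality" for a given
plugin version) do not transfer and must be chosen per dataset — blank
synthetic frames show a clean two-decade separation between blob
responses and noise maxima, which makes the choice easy in practice.

`link_tracks()` is a two-stage linear-assignment (LAP) tracker in the
Jaqaman style. Stage 1 solves, per consecutive frame pair, a one-to-one
assignment minimising summed squared distances subject to a maximum link
radius (default 30 px); stage 2 links track-segment ends to later
segment starts within 50 px and 30 frames, again by minimum-cost
assignment. Both stages use a padded square cost matrix whose non-linking
alternative cost is the squared radius, so any feasible link is cheaper
than leaving both parties unlinked. The assignment problem is solved
exactly by a shortest-augmenting-path solver (C++, tested against
brute-force permutation enumeration). Because the alternative cost is
per-node, the objective separates over connected components of the
feasibility graph; the tracker exploits this to solve many small LAPs
instead of one large one, which makes linking near-linear when cells are
well separated. Ties are impossible in generic data and resolved
deterministically by the solver's fixed scan order; linking is
deterministic for a fixed input ordering. No splitting or merging is
attempted.

`filter_tracks()` removes tracks whose frame span (first to last,
inclusive) is under 75 frames (2.5 s at 30 fps), the conventional cutoff
for reliable per-track statistics at these settings.

Coordinates are pixel-based, origin top-left, x right / y down, frames
0-based; conversion to µm happens only via `pixel_size_um` (exposed as a
free parameter: the camera-and-objective combination fixes it per
dataset, and no single value is assumed).

# Motility metrics and classification

For each track: total distance is the sum of consecutive-spot distances
(a closed gap contributes its straight chord); maximum distance is the
largest displacement **from the first spot** — the track-feature
convention of the common tracking software this pipeline mirrors; the
any-pair maximum is available behind a flag for sensitivity analysis.
Mean speed is path speed (total distance over elapsed time), consistent
with the threshold equivalence below; confinement ratio is maximum over
total distance (1 = straight, → 0 = confined; defined as 0 for a track
that never moves), and dispersal is mean speed × confinement ratio, an
effective net-displacement rate convertible to m/day (86,400 × 10⁻⁶;
reported values are conventionally *truncated* to two decimals, so
15 µm/s prints as 1.29 m/day).

A cell is **motile** when total distance ≥ 100 µm per 10 s of recording —
equivalently an average path speed of 10 µm/s; the boundary is inclusive
(a measure-zero choice, but documented) and the threshold rescales
proportionally for other durations. `calibrate_threshold()` reproduces
the threshold from deciliated-control data: `fixed` (100 µm), `quantile`
(99th percentile of control distances), or `valley` (KDE minimum between
the two largest modes of log distance; requires ≥ 30 mixed-control tracks
and errors toward `quantile` otherwise). Replicate summaries report the
motile fraction and motile-only means (each track weighted once; pooling
all displacements instead would overweight long tracks).

# Thermal performance curves

Two model families are the workhorses, a third is kept for comparison:

* **Pawar / modified Sharpe–Schoolfield**, parameterised by the optimum:
  $$r(T) = \frac{r_{tref}\, e^{-\frac{e}{k}(\frac{1}{T+273.15} -
  \frac{1}{t_{ref}+273.15})}}{1 + \frac{e}{e_h - e}\, e^{\frac{e_h}{k}
  (\frac{1}{T_{opt}+273.15} - \frac{1}{T+273.15})}},$$
  with activation energy $e$ (eV), inactivation energy $e_h > e$,
  $k = 8.62\times10^{-5}$ eV/K and $t_{ref} = 1$ °C (a temperature at
  which rates are not yet inactivated; kelvin conversion is +273.15
  exactly).
* **Thomas2**: $r(T) = a e^{bT} - (c + d e^{eT})$. The printed source
  equation's typography is ambiguous; this difference-of-exponentials
  form is the one matching the verbal parameter descriptions ($a$ = rate
  at 0 °C, $b$ = exponential rise, $c$ = temperature-independent
  inactivation, $d, e$ = scale and sensitivity of exponential
  inactivation) and the established model family of that name. The raw
  value is negative beyond the thermal limits; reporting floors it at 0,
  fitting uses the raw value.
* **Weibull** (4-parameter unimodal form) participates only in AIC
  comparison.

**Fitting.** Weighted least squares on the rate table with weights 1/sd
as stated procedures in this field use (1/sd² available as an option; the
two differ only in how strongly precise points dominate). Optimisation is
Levenberg–Marquardt from a deterministic multi-start grid — Pawar starts
over observed temperatures × $e \in \{0.3, 0.6, 1\}$ × $e_h \in \{2, 4,
8\}$; Thomas2 starts are data-driven (log-linear fit of the rising limb
gives $a, b$; $d$ is pinned so the curve crosses zero where the data do,
over a grid of $e$) — with the best few starts refined and the lowest
weighted SSE kept. Positivity and $e_h > e$ are enforced by
log/`exp`-shift reparameterisation rather than box constraints.
$T_{opt}$/$R_{max}$ come from a 0.01 °C grid argmax over the observed
range ±2 °C; for Pawar the $T_{opt}$ parameter is reported directly and
cross-checked against the argmax (warning beyond 0.5 °C).

**Bootstrap.** Confidence intervals use residual resampling: weighted
residuals are resampled with replacement, added back to the fitted
values, and the model is refit `n_boot` times (default 1000; scaled-down
studies use 200); $T_{opt}$ and $R_{max}$ are recomputed per replicate
and 95% percentile intervals reported. Two numerical choices matter:

1. Residuals are leverage-corrected ($r_i / \sqrt{1 - h_{ii}}$ with
   $h_{ii}$ from the weighted linearised hat matrix). A 4–5 parameter
   nonlinear curve fit on few points absorbs a large share of the noise;
   uncorrected residuals understate it and give badly anticonservative
   intervals.
2. **Fit replicate rows, not means.** With only one row per temperature
   (8 points, 4–5 parameters) these models can almost interpolate, the
   residual pool collapses, and no resampling scheme can recover the
   sampling variance. When per-replicate measurements exist, the fit
   should see them directly; simulation checks in the test suite run the
   full design (8 temperatures × 3 replicates) this way.

Resampling is global across the residual pool by default (fewest
assumptions); within-temperature resampling is available for designs
with strong variance structure. `converged = FALSE` (not an error) marks
fits where under half the bootstrap refits converged. AIC is computed
from the weighted RSS with $k$ = parameters + 1; lowest wins, ties to
fewer parameters.

The recovery simulations freeze one "cryophilic-like" truth per family
(Pawar: $r_{tref}=30$, $e=0.6$, $e_h=4$, $T_{opt}=8$; Thomas2: $a=40$,
$b=0.08$, $c=5$, $d=1$, $e=0.3$; Weibull: $a=50$, $T_{opt}=12$, $b=15$,
$c=3$) on the incubation design {0, 2.5, 5, 10, 15, 20, 25, 30} °C with
3 replicates and 10% CV noise plus a 0.5 µm/s absolute floor — the floor
reflects that speed measurement error does not vanish when speeds are
small, and keeps near-zero high-temperature rates from acquiring
unboundedly large weights.

# Phototaxis

The dish index is the fraction of background-subtracted cell signal in
the light-facing half of the dish:
$$\mathrm{index} = \frac{\sum_{front}(assay - background)^+}
{\sum_{dish}(assay - background)^+}.$$
The printed mean-intensity × area product form of the index is
algebraically the same ratio (the area factors cancel against the means)
and is kept behind a flag as a cross-check. Intensity arithmetic replaces
any black-and-white binarisation; a threshold option reinstates it for
parity checks. The front half is the side of the dish centroid with
non-negative projection on the light axis (the dividing line itself
counts as front — measure zero for generic masks). A dish with zero
difference signal yields a flagged `NA`, never a silent 0.5. Replicates
are tested two-sided against the 0.5 null with a one-sample t-test, and
p-values are Holm-adjusted across the species battery (the adjustment
method is a parameter; Holm is the default because it is conservative
and assumption-free).

The dish simulator shares one background realisation between the pair,
so subtraction is exact and index error is purely binomial placement
noise; real assays add registration error, meniscus vignetting and
settling cells, which the simulator deliberately does not model — passing
simulator tests validates the arithmetic, not image registration.

# Trait-level statistics

Cross-species checks use ordinary least squares with exact small-sample
slope inference (`linear_fit`), the slope-vs-unity criterion (a
relationship is "consistent with slope 1" when the 95% CI for the slope
contains 1), Welch two-sample comparisons of fitted parameters between
conditions, and a per-replicate OLS slope check for constant-temperature
stability (pooled mean slope with t-based CI; "stable" when the CI
includes 0). The stability check deliberately replaces a random-slope
mixed model: with three replicates the pooled per-replicate OLS summary
answers the same question without REML machinery, and the full
mixed-model fit is a one-liner in `lme4` for anyone who wants it.
Thermal classes follow the convention: cryophilic below a 10 °C swimming
optimum, mesophilic above 20 °C, intermediate between.

# Problem sizes and determinism

The shipped simulations use populations of 20–150 cells over 301 frames,
TPC designs of 8 temperatures × 3 replicates, bootstrap sizes of 200,
and 50–100 seeded repeats for recovery and selection checks — sizes at
which every stage's behaviour is already asymptotic enough to test the
claims while keeping the whole chain quick on a single CPU. All
randomness flows through explicit integer seeds; every stochastic entry
point restores the caller's RNG state.

# Known limitations

* 2D only; no hydrodynamic interactions, chemotaxis/gravitaxis fields, or
  cell–cell collision handling.
* The tracker does not split or merge tracks; crossing cells within a
  link radius can swap identities, as with any pure-LAP tracker.
* Thomas2's raw form cannot flatten at zero: fitted to speed data whose
  high-temperature tail is exactly 0 (motility inactivated), it must
  compromise between plunging below zero and missing the peak. Recovery
  is tested against data generated from the raw curve; end-to-end speed
  pipelines preferring a strictly positive model should fit Pawar.
* Bootstrap intervals are percentile intervals; BCa would need jackknife
  machinery that the small designs here do not support well.
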