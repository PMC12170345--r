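---
title: "Quantifying microtubule plus-end dynamics, molecule counts and end geometry with mtdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule plus-end dynamics, molecule counts and end geometry with mtdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdyn)
```

## Scope and model

`mtdyn` quantifies the dynamic behaviour of microtubule (MT) plus ends in
in vitro reconstitution assays of the ciliary tip module (CTM: CEP104,
CSPP1, TOGARAM1, ARMC9, CCDC66) together with the end-binding protein EB3,
and provides a synthetic-data generator that emulates every input the
analysis consumes. Nothing in the analysis depends on the generator: the
same functions accept tip-position CSV files, TIFF kymographs, FRAP trace
CSVs and plain-text 3D protofilament contours from real experiments.

### Tip trajectories as a continuous-time Markov chain

A plus end switches among at most four dynamic states — fast growth, slow
growth, pause and shrinkage — modelled as a continuous-time Markov chain
with per-minute transition hazards. Dwell times in each state are
exponential; within a state the tip advances at a mean velocity
(µm min⁻¹) with Gaussian per-sampling-step noise. The chain is sampled at
3-s intervals for 10 min by default, matching the TIRF acquisition the
package emulates (0.045 µm px⁻¹ camera resolution, 3-s frame interval,
10-min videos).

Two boundary mechanics reflect the assay:

* **Seed floor.** The GMPCPP-stabilized seed is stable, so position is
  floored at 0. A shrinkage excursion reaching the seed either regrows or
  enters a terminal pause (a *block*) with probability
  `block_at_seed_prob`.
* **Terminal blocks.** With `terminal_block = TRUE`, a pause, once
  entered, never ends — the CEP104-style arrest in which no regrowth is
  seen for the remainder of the experiment. Block durations are therefore
  censored by the 600-s recording, which is the maximum reportable
  pause/block duration.

### Condition presets

`builtin_presets()` encodes one generative parameter set per experimental
condition. The **mean velocities are the published rates** for each
condition (e.g. full CTM slow growth 0.19 µm min⁻¹, TOGARAM1 alone
2.27 µm min⁻¹, CEP104+TOGARAM1 0.12 µm min⁻¹, the reduced trio
0.022 µm min⁻¹, control depolymerization 36.91 µm min⁻¹, CEP104+CCDC66
depolymerization 0.12 µm min⁻¹); each preset carries its source rate, its
printed standard error and a citation string.

The **transition hazards are package defaults**, not published values: the
source experiments report dynamic-state time percentages and rate
means, never hazards, so exact hazards are unrecoverable from the text.
Hazards were chosen once so that the simulated composition matches each
condition qualitatively — the full CTM spends almost all time in slow
growth with occasional transient pausing and no catastrophes;
CEP104-containing blocking conditions arrest permanently; controls grow
several micrometres between catastrophes and depolymerize all the way back
to the seed, as in the source kymographs. For the two control presets the
catastrophe hazard is 0.15 min⁻¹, within the band commonly measured for
EB-containing in vitro assays and giving µm-scale excursions whose
depolymerization spans several sampling intervals. Note that the preset
`togaram1` stores its 2.27 µm min⁻¹ velocity under the generative state
label `slow_growth`; generative labels are occupancy labels, while the
analysis-side class of a phase always derives from its measured rate (for
2.27 µm min⁻¹, `fast_growth`).

The generative state labels are recorded per sample as ground truth, and
the exact event path of the chain is kept alongside, so occupancy and
dwell-time statistics can be checked against the analytic stationary
distribution (`stationary_distribution()` solves pi Q = 0 directly).

### Kymograph rendering and tip tracing

`render_kymograph()` rasterizes a trajectory the way a kymograph reslice
of a TIRF movie would: one row per frame (time downward), a lattice signal
from the seed to the tip plus a brighter diffraction-limited tip spot,
Gaussian PSF blur (default sigma 0.1 µm) and Gaussian noise scaled as
`tip_amplitude / snr`.

`trace_kymograph()` inverts this: per row, columns above a robust
background threshold define the signal support; isolated single-pixel
excursions are ignored (a valid distal run needs at least two consecutive
above-threshold columns); the local maximum nearest the distal edge is
refined to sub-pixel precision with a three-point parabola on log
intensity, which is exact for a Gaussian line profile. Signal-free rows
are linearly interpolated and flagged, and a running-median despike
removes isolated outliers. At an SNR of 10 the tracer recovers positions
with roughly half-pixel RMS error; noise-free round trips are within one
pixel everywhere.

### Phase segmentation and classification

`segment_phases()` fits a piecewise-linear model by exact penalized
least-squares changepoint minimization (dynamic programming over all
partitions with at least three samples per segment; per-segment cost is
the residual sum of squares of a line fit, computed in O(1) from
cumulative sums). The default penalty is `6 * sigma^2 * log(n)` with sigma
estimated robustly from second differences, floored at a tiny positive
value so that noise-free polylines are reproduced exactly; an exhaustive
enumeration oracle over all placements of up to two changepoints verifies
the optimum in the test suite. The penalty multiplier was fixed by
simulation so that phase rates, the quantities the analysis reports, are
recovered accurately across the preset battery; on re-traced kymographs at
SNR 10 most residual state-assignment error sits at phase boundaries and
in short pauses of the slow-growth conditions.

Phase rates are classified with the published thresholds: faster than
0.02 and at most 0.5 µm min⁻¹ is slow growth, faster than 0.5 fast
growth, below −0.02 shrinkage, everything else pause. Boundary semantics
follow the wording "faster than": a rate of exactly 0.5 is slow growth
and exactly ±0.02 is a pause.

Two discretization artifacts are handled explicitly:

* A sample interval containing a state switch mixes the two velocities,
  so segments of five or more points exclude the boundary sample on each
  interior side when their slope is fitted.
* A minimal-length phase (three points) has no interior interval at all;
  its slope is structurally biased toward the neighbouring states. Such
  phases count toward state time and transition events but are excluded
  from the per-class rate pools (`min_rate_duration`, default 10 s). This
  matters most for the 36.91 µm min⁻¹ control depolymerization, which
  crosses the field of view in a handful of frames.

`summarize_dynamics()` pools phases across trajectories: per-class rate
pools (plain and duration-weighted means with s.e.m.), percent time per
state, and transition frequencies defined as events per minute of the time
in which the event could have occurred (catastrophes over growth time,
rescues over shrinkage time, pause entries over non-pause time). A
frequency with a zero-time denominator is reported absent (`NA`), never 0.
Both pooled and per-experiment (mean-of-means) summaries are available,
since the source figures mix the two conventions. MTs without growth
events contribute to percent time but not to rate pools.
`weighted_rate_histogram()` weights each growth phase by its duration over
total growth time, so weights sum to 1.

### Group comparisons

`compare_groups()` uses the tests named in the source figure legends: a
two-sided Mann-Whitney U for two groups and Kruskal-Wallis followed by
Dunn's pairwise z-tests (joint ranks, tie-corrected) for more, optionally
against a stated control. Dunn's test is computed from the standard rank
formula because no implementation ships with the environment's R
packages; the k = 2 identity H = z² and `kruskal.test` serve as
cross-checks. The source does not name a multiplicity adjustment for
Dunn's test; Holm is the default and is exposed as an argument.

### Single-molecule photometry

`simulate_spot_field()` draws n-mer spots whose integrated intensity is
the sum of n monomer draws, places them with a 4-sigma minimum spacing and
renders them as symmetric 2D Gaussians. `detect_spots()` finds local
maxima above a robust threshold with non-maximum suppression;
`fit_spot()` performs nonlinear least squares of a symmetric Gaussian plus
offset over a 3-sigma window — wide enough to constrain the offset,
narrow enough that a neighbour at the minimum spacing stays outside; wider
windows systematically squeeze the fitted sigma at high spot density.
Fits whose sigma departs from the PSF by more than a factor of two are
discarded as noise-driven false detections. Integrated intensity is
`2 pi A sigma^2`.

Oligomer stoichiometry is the ratio of kernel-density modes
(Silverman-bandwidth) of target versus monomer-reference intensities —
the mode, not the mean, because overlapping spots skew the right tail —
rounded to the nearest integer with a bootstrap CI; an interval spanning
two integers is flagged ambiguous. The estimate is scale-invariant, which
substitutes for absolute calibration under the same-coverslip assumption.
`count_molecules_at_end()` divides a blocked-end intensity by the monomer
mode; dividing further by the inferred stoichiometry converts molecules to
oligomers (≈6 molecules = 2–3 dimers for a CEP104-style block).

### FRAP

`normalize_frap()` anchors the trace at 1 for the frame immediately before
the bleach and 0 for the frame immediately after, i.e.
`(I_t − I_post) / (I_pre − I_post)`. The source prints the two
parenthesized factors without an operator between them; division is the
only reading consistent with the stated 0/1 anchoring and is adopted
explicitly. `I_pre` is the single last pre-bleach frame per the wording
"immediately before"; averaging several pre-frames is exposed as an
option. `fit_recovery()` fits `plateau * (1 − exp(−k t'))` to the
post-bleach samples; the half-life is `ln 2 / k`. A fitted plateau below
0.05 is classified "no exchange" with `k` reported absent rather than as
an arbitrary number, since the rate of a flat curve is unidentifiable.
The source reports no numeric half-lives, so only qualitative recovery
contrasts (dynamic versus blocked ends) are testable.

### Protofilament flare geometry

`simulate_protofilament_end()` builds traced plus ends: protofilaments run
straight along the axis on a cylinder of 11 nm radius at azimuths
360°/n ± ≤4° (the ±4° margin mirrors the tolerance used when assigning
neighbouring protofilaments in tomograms), leave the wall at axial
positions drawn with the raggedness s.d., and curl outward as planar
circular arcs (the ram's-horn geometry of the tracing literature) of drawn
length and curvature. Flared (control) defaults: length 25 ± 10 nm,
curvature 2.86 deg nm⁻¹ (a 20-nm arc radius), raggedness 8 nm. Corked
(CTM-like) defaults: 8 ± 3 nm, 1.8 deg nm⁻¹ (≈30 nm radius), 4 nm —
chosen once so the control-versus-corked contrasts run in the directions
reported for free versus corked plus ends (shorter flares, smaller
per-MT length s.d., milder curvature, less ragged wall edge). Blunt
protofilaments keep a third point one sampling step upstream of the wall
point, mirroring the three-point requirement of the tracing toolchain.

The analysis side measures, per protofilament: the wall exit (first point
whose outgoing segment deviates from the MT axis by more than the
straightness tolerance, default 10°), the flared length (summed segment
lengths from the last in-wall segment through the tip), and local
curvature (turning angle at each interior flare vertex divided by the mean
adjacent segment length, deg nm⁻¹ — the curvature unit is an assumption,
consistent with an arc-radius reading of the published values, as the
figure axis unit is not stated in the available text). Per MT it reports
the flared-length s.d., the raggedness (sample s.d., n−1, of the axial
wall-exit coordinates) and the unweighted mean of per-protofilament mean
curvatures (weighting by flare length is unstated in the source;
unweighted is used). The MT axis is supplied or estimated as the mean
root-segment direction, since in-wall protofilament segments are parallel
to the axis; all metrics are invariant under rigid motion of the end.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
exponential dwell mixtures, velocity noise, pixelated PSF-blurred
kymographs at realistic SNR, intensity sums for oligomers, exponential
FRAP recovery, and arc-shaped flares with controlled raggedness. It does
not emulate photobleaching, EB comet shape, uneven illumination, stage
drift, tomographic missing-wedge distortion or tracing subjectivity, so
passing recovery tests demonstrates correctness of the estimators under
the stated noise model, not robustness to every real-data artifact.

## Numerical choices and problem sizes

Rate-recovery checks simulate 100 trajectories of 600 s at 3-s sampling
per condition (about 200 phases per class), enough to pin pooled rates to
a few percent; the stationary-distribution check runs a single 10⁴-minute
chain; photometry checks use 10³ spots per field; flare contrasts use 25
ends × 13 protofilaments per condition (≈325 per group). Bootstrap CIs
use 200 resamples. All randomness flows from a single master seed fanned
out deterministically per stage (`derive_seed`), so identical seeds give
byte-identical artifacts.

## Known limitations

* Hazard defaults are qualitative calibrations, not published constants;
  simulated transition frequencies should not be read as predictions.
* Depolymerization at 36.91 µm min⁻¹ crosses a 3-s sampling grid in very
  few frames; catastrophes at low microtubule height are unresolvable and
  their phases are excluded from rate pools by the minimal-duration rule.
* The tip tracer assumes a single microtubule per kymograph with the seed
  at column 1 and growth to the right.
* Stoichiometry inference assumes matched imaging conditions between
  target and reference sets; no absolute intensity calibration is
  attempted.
* Polarity of traced ends is an input label; the package does not call
  polarity from densities.

## A worked example

```{r example, eval = FALSE}
library(mtdyn)

cfg <- run_config(preset = "full_ctm", n_trajectories = 100, seed = 1,
                  rasterize = TRUE)
run <- run_dynamics_pipeline(cfg)
run$summary

tab <- run_recovery_suite(n_trajectories = 100, seed = 1)
tab
```
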