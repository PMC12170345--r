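# mtdyn

Quantification of microtubule (MT) plus-end dynamics for in vitro
reconstitution experiments with ciliary-tip-module (CTM) proteins
(CEP104, CSPP1, TOGARAM1, ARMC9, CCDC66) and EB3 — and a synthetic-data
generator that emulates every input the analysis consumes, so that all of
the package's quantitative claims are checkable without any microscopy
data.

## Who this is for

Groups analysing TIRF kymographs of dynamic microtubules, single-molecule
intensity data, FRAP traces, or cryo-ET protofilament traces, who want a
scripted, testable version of the usual manual workflow: trace the tip,
split the trace into constant-velocity phases, classify, pool statistics,
count molecules, fit recovery curves, and measure end geometry.

## The models at the core

**Tip dynamics.** A plus end switches among fast growth, slow growth,
pause and shrinkage as a continuous-time Markov chain with per-minute
hazards Q; within a state the tip moves at velocity v ± sigma (µm/min),
sampled every 3 s for 10 min. Position is floored at the stabilized seed;
shrinkage reaching the seed either regrows or blocks terminally.
Condition presets carry published rates — full CTM slow growth
0.19 µm/min, TOGARAM1 alone 2.27 µm/min, CEP104+TOGARAM1 0.12 µm/min,
control depolymerization 36.91 µm/min, and more (`builtin_presets()`).

**Phase segmentation.** A trajectory y(t) is split by exact penalized
least-squares changepoint minimization:

    minimize  sum_segments RSS(linear fit) + beta * (#changepoints)

solved by dynamic programming, with rates classified by the published
thresholds (>0.02 to ≤0.5 µm/min slow growth, >0.5 fast growth,
<−0.02 shrinkage, else pause). Transition frequencies are events per
minute of the time in which they could occur (catastrophes / growth time,
rescues / shrinkage time); weighted growth-rate histograms weight each
phase by duration / total growth time.

**Photometry.** Spots are fit with symmetric 2D Gaussians
(I = 2·pi·A·sigma²); oligomer number is the ratio of intensity-histogram
modes against a monomer reference with a bootstrap CI. FRAP traces are
normalized to (I_t − I_post)/(I_pre − I_post) and fit with
plateau·(1 − e^(−kt)), half-life ln2/k.

**Flare geometry.** From 3D protofilament traces: wall exit (first point
deviating from the axis beyond a straightness tolerance), flared length
(last in-wall segment through the tip), local curvature (turning angle /
mean segment length, deg/nm), and per-MT raggedness (s.d. of axial
wall-exit positions). Group contrasts use two-sided Mann-Whitney or
Kruskal-Wallis + Dunn tests.

## Worked example

Simulate 100 full-CTM recordings, rasterize each to a kymograph, re-trace
and summarize:

```r
library(mtdyn)
cfg <- run_config(preset = "full_ctm", n_trajectories = 100, seed = 1,
                  rasterize = TRUE)
run <- run_dynamics_pipeline(cfg)
run$summary
#> <dynamics_summary> 100 trajectories, 1000 min observed
#>   percent time: fast_growth 4.0%, slow_growth 83.8%, pause 5.7%, shrinkage 6.5%
#>   slow_growth: n = 523, rate = 0.180 +/- 0.003 um/min (weighted 0.178)
#>   ...
```

The pooled slow-growth rate (0.180, duration-weighted 0.178 µm/min)
recovers the preset's generative 0.19 µm/min to within a few percent
after passing through pixelation, photon noise, re-tracing and
segmentation; the small fast-growth/shrinkage fractions are
tracing-noise excursions at phase boundaries. Recovery across every
built-in condition:

```r
run_recovery_suite(n_trajectories = 100, seed = 1)
#>                 preset state_class generative_rate recovered_rate relative_error
#> control_shrink           shrinkage         -36.910        -34.35          0.069
#> togaram1               fast_growth           2.270          2.27          0.001
#> cep104_togaram1        slow_growth           0.120          0.116         0.031
#> full_ctm               slow_growth           0.190          0.189         0.004
#> minimal_trio           slow_growth           0.022          0.0236        0.074
#> ...
```

Photometry and geometry follow the same pattern:

```r
mono  <- simulate_spot_field(1000, c("1" = 1), image_size = 900, seed = 1)
dimer <- simulate_spot_field(1000, c("2" = 1), image_size = 900, seed = 2)
infer_stoichiometry(fit_spots(dimer$image), fit_spots(mono$image), seed = 3)
#> <stoichiometry> n = 2 (ratio 2.094, CI [1.910, 2.252])

summarize_end(simulate_protofilament_end(corked = TRUE, seed = 1))
#> <mt_end_geometry> 13 protofilaments
#>   median flared length: 3.9 nm, length sd: 2.95 nm
#>   mean local curvature: 2.026 deg/nm, raggedness: 3.56 nm
```

## File formats

Trajectories: CSV (`time_s`, `position_um`, `true_state`). Kymographs and
spot fields: 16-bit TIFF. FRAP: CSV with a `# bleach_index:` header.
Protofilament contours: plain text (`MT <id> <n_pf> <polarity>` /
`PF <id>` / `x y z` per line, root to tip). Pipeline output: phases CSV,
summary JSON, manifest JSON.
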