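---
title: "Segmented IVIM fitting: models, methods, and design choices"
author: "ivimfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented IVIM fitting: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimfit)
```

## The signal model

Intravoxel incoherent motion (IVIM) imaging models the diffusion-weighted
MRI signal of a voxel as a two-compartment bi-exponential decay,

$$S(b) = S(0)\left[f\,e^{-b(D + D^*)} + (1 - f)\,e^{-bD}\right],$$

where $b$ (s/mm^2) is the diffusion weighting, $D$ (mm^2/s) the
molecular-diffusion coefficient, $D^*$ (mm^2/s) the pseudo-diffusion
coefficient attributed to capillary microcirculation, and $f$ the
pseudo-diffusion (perfusion) fraction. Note the convention used throughout
this package: the perfusion compartment decays with $D + D^*$, so the
apparent diffusion coefficient of the curve at the origin is exactly

$$\mathrm{ADC} = D + f D^*,$$

which `adcAtOrigin()` computes and on which the opAS method rests. The
derived product $fD^*$ (the pseudo-diffusion flux, `perfFlux()`) is always
recomputed from the two stored parameters, never fitted independently.

Because $D^* \gg D$, the perfusion term is negligible above some threshold
$b_t$, which motivates *segmented* fitting: estimate $D$ from the high-$b$
tail first, then recover the perfusion parameters with $D$ fixed. The
package implements four such methods behind one dispatcher, `fitCurve()`:

* **S (segmented)** — `fitS()`. Stage 1: ordinary least squares of
  $\log S$ on $b \ge b_t$ gives $\tilde D$ and the intercept $S_{int}$.
  Stage 2: bounded nonlinear least squares of the full bi-exponential over
  all $b$, with $D$ and the measured $S(0)$ fixed, free $(f, D^*)$.
* **OS (oversegmented)** — `fitOS()`. As S, but $f = 1 - S_{int}/S(0)$ is
  computed in closed form (clipped into $[0,1]$) and only $D^*$ is fitted.
* **AS (analytical segmented)** — `fitAS()`. The signal is transformed to
  $\tilde f(b) = 1 - \frac{S(b)}{S(0)}e^{bD}$, which with an exact $D$
  equals $f(1 - e^{-bD^*})$ identically; the model
  $\tilde f(b) = f_0(1 - e^{-bD^*}) + \varepsilon$ is then fitted over all
  acquired $b$. The $\varepsilon$ offset absorbs error in the measured
  $S(0)$; $f_0$, the asymptotic pseudo-diffusion fraction, is reported as
  $f$.
* **opAS (optimized analytical segmented)** — `fitOpAS()`. Threshold-free:
  the tail fit is repeated for a whole series of thresholds and the series
  $\tilde D(b_t)$ is fitted with
  $\tilde D(b_t) = \mathrm{ADC} - P(1 - e^{-b_t D^*_{tmp}})$,
  $P$ standing for the product $f_0 D^*$. Since contamination dies away as
  $b_t \to \infty$, the limit $D = \mathrm{ADC} - P$ is a
  threshold-independent diffusion estimate; stages 2–3 then proceed as in
  AS with that $D$. The $D^*_{tmp}$ shape parameter of the extrapolation is
  internal and discarded; the reported $D^*$ comes from the
  $\tilde f$ stage.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bt` | 100 s/mm^2 | threshold for S/OS/AS; the in-vivo convention |
| b-values | 18 values, 0–500 s/mm^2 | `defaultBValues()`; `invivoBValues()` gives the sparser 13-value clinical subset |
| bounds | $f, f_0 \in [0,1]$; $D^* \in [10^{-5}, 0.5]$; $\varepsilon \in [-0.5, 0.5]$; ADC $\in [10^{-6}, 0.1]$ mm^2/s | box constraints of every nonlinear stage |
| starts | $f_0 = \max(1 - S_{int}/S(0), 0.01)$, $D^* = 10D$, $\varepsilon = 0$ | all stages start from data-driven values |
| opAS $b_t$ series | every acquired $b$ leaving $\ge 4$ tail points | 0–350 s/mm^2 for the default scheme |

The nonlinear stages use bounded Levenberg–Marquardt least squares
(minpack). Stopping uses the library's standard tolerances deliberately:
the opAS extrapolation objective has, under noise, a statistically
meaningless flat valley toward a degenerate corner ($D^*_{tmp}$ at its
floor, $P$ large, extrapolated $D \to 0$), and ultra-tight tolerances walk
all the way into it.

Three further guards keep the extrapolation stage honest, all inactive on
noiseless data:

1. $P$ is capped at twice the observed span of the $\tilde D(b_t)$ series —
   an extrapolation may not claim more decay than the scanned thresholds
   evidence;
2. $D^*_{tmp} \ge 10^{-3}$ mm^2/s, encoding the IVIM premise that
   pseudo-diffusion is not slower than tissue diffusion;
3. a solution pinned at the $P$ cap, or extrapolating $D < 0$, is treated
   as unsupported: the method degrades gracefully to
   $D = \tilde D(b_{t,\max})$ and the result is flagged
   `converged = FALSE`.

Other numerical conventions: the stage-1 fit is closed-form OLS on
log-signal (deterministic, fast enough for the opAS inner loop);
non-positive signals are excluded from the log fit and fewer than 3 usable
points is an error; duplicate $b$-values are averaged at curve
construction; negative $\tilde f(b)$ values under noise are retained
(clipping would bias $f_0$; the $\varepsilon$ term exists to absorb offset
error); $S(0)$ is always the measured $b = 0$ signal, not a fitted
parameter; clips of $f$ into $[0,1]$ and $D$ to $\ge 0$ are recorded in the
result message; when OS clips $f$ to 0, $D^*$ is unidentifiable and is
parked at its lower bound rather than pseudo-optimized. Optimizer failures
never raise: the starting values are returned flagged, so voxelwise map
fitting cannot abort.

## The simulation benchmark

`SimulationSpec()` carries the benchmark conditions: fixed
$D = 1.0\times10^{-3}$ mm^2/s, $f$ from 0.02 to 0.50 in steps of 0.02,
$D^*$ from 2 to 60 $\times 10^{-3}$ mm^2/s in steps of 2, eighteen
b-values (0, 20, 30, ..., 100, 150, 200, ..., 500 s/mm^2), SNR levels 10,
20 and 40, and 1000 replicates per cell. Rician noise is realized as the
magnitude of a complex Gaussian perturbation with
$\sigma = S(0)/\mathrm{SNR}$ per channel — the standard magnitude-MRI
construction — drawn independently per replicate and per b-value. $S(0)$
is normalized to 1; the model is scale-free, so nothing is lost.
`runSimulationStudy()` seeds every grid cell from the base seed and the
cell's *parameter values*, so thinning a grid never changes a surviving
cell's noise stream and reruns are byte-identical.

`nme()`, `coefVar()` and `nrmse()` score replicate estimates: signed
normalized mean error, population-SD coefficient of variation (the $1/N$
normalization is part of the metric's definition), and normalized RMSE,
with the exact decomposition
$\mathrm{NRMSE}^2 = \mathrm{NME}^2 + \sigma^2_{pop}/\theta_T^2$.
Replicates with `converged = FALSE` are included by default (no published
exclusion rule exists); `summarizeGrid(excludeNonConverged = TRUE)`
recomputes without them for sensitivity analysis.

The test suite exercises a reduced grid ($f \in \{0.02, 0.1, 0.26, 0.5\}$,
$D^* \in \{2, 10, 30, 60\}\times10^{-3}$, SNR $\in \{10, 40\}$, 200
replicates) so the whole suite runs in a few minutes; the problem sizes are
the package's own choice of a scale at which the stochastic assertions are
stable.

## The synthetic phantom and cohort

`generatePhantom()` builds a 4D volume holding two disjoint ellipsoidal
regions — a perfused "control" and a low-perfusion "ischemic" region — in
a signal-free background, plus Rician noise everywhere. It emulates a
paired femoral-head acquisition geometrically; it does **not** model
partial volume, motion, eddy currents, susceptibility distortion, spatial
noise correlation or non-Gaussian diffusion, so passing phantom tests
demonstrates pipeline correctness, not clinical performance.
`runPhantomStudy()` assembles a paired cohort, fits every method voxelwise
(`fitImage()`), extracts ROI medians (`roiMedian()`) and runs two-sided
paired t-tests (`pairedCompare()`, sample-SD convention, with an explicit
zero-variance branch). Between-subject biological variability is emulated
by lognormal jitter of each region's true parameters (CV 0.15 by default,
a deliberately conservative physiological scale); without it a synthetic
paired test has no realistic error term.

## Design choices where the design was genuinely open

* **$b_t$ series for opAS.** All acquired b-values leaving at least 4 tail
  points. Truncating the series' upper end, or dropping $b_t = 0$, was
  evaluated on noiseless grids during development and was uniformly worse:
  the extrapolation needs to see the beginning of the plateau.
* **18 vs 13 b-values.** With the 13-value clinical scheme the series only
  reaches $b_t = 100$, and at low $D^*$ the noiseless extrapolation
  problem is *degenerate* — a near-linear corner fits better than the
  physical optimum. The phantom therefore defaults to the 18-value scheme;
  the cohort study can (and in the acceptance analysis does) use the
  13-value scheme to mirror the acquisition it stands in for, relying on
  ROI medians to tame the per-voxel instability.
* **Eq. ADC parameterization.** The extrapolation is parameterized as
  $(\mathrm{ADC}, P, D^*_{tmp})$ with $P = f_0D^*$ a single free
  parameter; only ADC and $P$ are consumed.
* **Thresholds for S/OS/AS.** Both 100 and 200 s/mm^2 are first-class
  (`defaultMethodGrid()`), matching the benchmark's two operating points.

## Known limitations

* Noiseless opAS recovery of $D$ carries an intrinsic model-approximation
  bias above 5% (up to ~8%) in a small documented region — $f \ge 0.46$
  combined with $D^* \in [8, 16]\times10^{-3}$ mm^2/s — where the tangent
  approximation behind the extrapolation model misfits the actual
  log-linear tail series. A brute-force grid search over the same
  objective lands on the same (or slightly worse) optimum, i.e. the bias
  belongs to the method, not the optimizer. $f$ and $D^*$ recover within
  5% for every grid cell with $D^* \ge 10\times10^{-3}$, and $D$ within 5%
  for $D^* \ge 6\times10^{-3}$ outside that region.
* Under noise, the high-threshold tail fits that opAS consumes are the
  sparsest and noisiest part of the data; at very low $f$ the normalized
  error of $f$ punishes the resulting two-sided $D$ scatter severely. The
  guards above remove the degenerate mass but cannot manufacture
  information the tail does not carry.
* Mean-|NME| summaries over grid cells where estimates saturate their
  fitting bounds (very low $f$ and $D^*$ at low SNR) measure the bound
  conventions more than the estimators; compare methods cell-wise in that
  regime instead.
* The paired-cohort generator draws identically-distributed subjects; real
  cohorts add physiological heterogeneity and acquisition confounds that
  can dominate the between-subject variance of biased estimators.

## File formats

Curves batch-fit from tidy CSV (`id, b, signal`; `fitCurveTable()`).
Volumes are 4D NIfTI with an FSL-style whitespace-separated `.bval`
sidecar; b-value order is taken from the sidecar and re-indexed to
ascending internally (`readDiffusionVolume()`, `writeParameterMaps()`,
`writePhantomNIfTI()`). Simulation and experiment configuration comes from
JSON or YAML (`readSimulationConfig()`, `readExperimentConfig()`), and the
`exec/ivimfit` script exposes the same functionality as shell verbs
(`simulate`, `fit-csv`, `fit-image`, `phantom`, `study`, `metrics`).
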