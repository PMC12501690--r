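# ivimfit

Segmented fitting of the intravoxel incoherent motion (IVIM) model for
diffusion-weighted MRI, aimed at **low-perfused tissues** (bone marrow and
similar), where the perfusion signal is weak and conventional
threshold-based fitting becomes unreliable. The package is for researchers
who need per-curve or voxelwise IVIM parameter estimates, and for
methodologists benchmarking IVIM estimators under controlled noise.

## The model and the four methods

Each voxel's decay is the two-compartment bi-exponential

S(b) = S(0) [ f·e^(−b(D + D\*)) + (1 − f)·e^(−bD) ],

with molecular-diffusion coefficient D (mm²/s), pseudo-diffusion
coefficient D\* (mm²/s), perfusion fraction f, and derived flux f·D\*.
Because D\* ≫ D, the perfusion term vanishes above a threshold b_t, which
segmented methods exploit:

| method | D from | perfusion parameters from |
|---|---|---|
| `fitS()`   | log-linear tail fit above b_t | bi-exponential refit, free (f, D\*) |
| `fitOS()`  | as S | f = 1 − S_int/S(0) closed form; D\* refit |
| `fitAS()`  | as S | f̃(b) = 1 − (S(b)/S(0))e^(bD) fitted as f₀(1 − e^(−bD\*)) + ε |
| `fitOpAS()`| threshold-free: D̃(b_t) scanned over all thresholds and extrapolated to b_t → ∞ via D̃(b_t) = ADC − f₀D\*(1 − e^(−b_t·D\*)) | as AS, with the extrapolated D |

opAS removes the b_t choice entirely: errors in D propagate into every
perfusion estimate, and the threshold that makes D accurate at low D\*
does not exist among practical b-values.

Beyond the fitters, the package ships a Rician-noise simulation benchmark
(`SimulationSpec()`, `runSimulationStudy()`, metrics `nme()`/`coefVar()`/
`nrmse()`), a synthetic two-region phantom and paired cohort
(`generatePhantom()`, `runPhantomStudy()`), a voxelwise NIfTI pipeline
(`readDiffusionVolume()`, `fitImage()`, `roiMedian()`, `pairedCompare()`),
and a command-line front end (`exec/ivimfit`).

## Worked example

The regime the package targets: slow pseudo-diffusion (D\* = 4×10⁻³ mm²/s,
only 4× D) with f = 0.10, where a b_t = 100 s/mm² tail fit is still
contaminated. On the noiseless curve:

```r
library(ivimfit)
b     <- defaultBValues()                      # 0, 20, ..., 500 s/mm^2
truth <- IVIMParams(D = 1.0e-3, Dstar = 4e-3, f = 0.10)
curve <- SignalCurve(b, ivimSignal(truth, b))

fitCurve(curve, "S", bt = 100)
#> FitResult [S]
#> IVIMParams: D = 0.001139 mm^2/s, D* = 0.01099 mm^2/s, f = 0.02877 (f*D* = 0.0003161)
fitCurve(curve, "AS", bt = 100)
#> FitResult [AS]
#> IVIMParams: D = 0.001139 mm^2/s, D* = 0.01291 mm^2/s, f = 0.02939 (f*D* = 0.0003795)
fitCurve(curve, "opAS")
#> FitResult [opAS]
#> IVIMParams: D = 0.001027 mm^2/s, D* = 0.004633 mm^2/s, f = 0.08314 (f*D* = 0.0003852)
```

The threshold methods inherit a 14%-high D from the contaminated tail and
collapse f to ~0.03 (−71%) while inflating D\* to ~0.011 (+175%). opAS's
extrapolated D (+2.7%) keeps f within 17% and D\* within 16% — with no
noise at all, this is pure threshold bias. The flux f·D\* is similar
across methods, illustrating why it is robust even when f and D\*
individually are not.

Voxelwise use follows the same surface:

```r
ph   <- generatePhantom(PhantomSpec(snr = 40, seed = 1))
maps <- fitImage(ph$volume, "opAS", mask = ph$controlMask | ph$ischemicMask)
roiMedian(maps, ph$controlMask)     # named medians of D, Dstar, f, flux
```

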