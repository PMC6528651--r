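# MRguidedPET

MR-guided MAP-EM PET reconstruction at MRI voxel sizes, with a phantom
simulator and evaluation metrics for partial-volume-correction (PVC)
studies.

PET's ~4 mm resolution biases uptake measurements in small structures
(cortical gray matter, the striatum): the partial volume effect. Two
in-reconstruction corrections are implemented and can be combined — PSF
(resolution) modelling, which recovers contrast at the price of Gibbs
edge overshoot, and anatomically guided penalized likelihood, which uses
a simultaneously acquired MR image to smooth within but not across
anatomical boundaries. The package's focus is performing the guided
reconstruction on the MR image's native (finer) voxel grid — "MRvox" —
rather than down-sampling the MR image to the PET grid.

The core pieces:

* **High-resolution system matrix.** A Siddon ray-tracing projector
  `X_lr` with an exactly matched adjoint, composed as `P_hr = X_lr D`
  with `D` a trilinear down-sampling from the fine grid whose transpose
  is used verbatim in the backprojection (`P_hr' = D' X_lr'`). This lets
  reconstruction run on a grid finer than the 2.045 mm line-of-response
  sampling without the gap artifacts a thin-ray projector otherwise
  produces there. Optional image-space Gaussian PSF modelling is part of
  the operator.
* **Smoothed Lange prior with Bowsher guidance.** The edge-preserving
  Lange (Fair) potential `psi(t) = delta [ |t|/delta - log(1+|t|/delta) ]`
  evaluated at each voxel's weighted RMS neighbour difference, with
  normalized inverse-distance proximity weights and binary modified
  (asymmetric) Bowsher similarity weights (the B anatomically most
  similar neighbours per voxel). Optimized by Green's one-step-late
  MAP-EM; `beta` is scaled across `delta` settings by
  `k(delta) = (Dtheta + delta0)/(Dtheta + delta)` and selected from
  sensitivity-scaled candidates by a stability-aware sweep.
* **Phantom simulator.** A procedural brain-like phantom (1 mm grid,
  gray:white uptake exactly 4:1, two-tissue attenuation, pseudo-T1
  guidance image), 4.3 mm system blurring, attenuation and synthetic
  normalization factors, 25% randoms, 28% scatter fraction, seeded
  Poisson realizations.
* **Metrics and study driver.** Contrast, regional COV, ensemble NRMSE
  and ensemble COV on the high-resolution grid; `runStudy()` runs the
  {MLEM, MAP, MR-guided MAP} x {standard, MRvox} x {PSF on/off} matrix
  over seeds and tabulates everything.

## Worked example

One noise realization of the simulated brain study, reconstructed with
standard-grid MLEM-PSF and with MR-guided MAP-PSF on the 1 mm MRvox grid:

```r
library(MRguidedPET)

phantom <- makePhantom(phantomSpec())
geom <- defaultGeometry(phantom$uptake@grid, nAngles = 96)
noiseFree <- simulateNoiseFree(phantom, geom, systemFwhmMm = 4.3)
background <- addBackgroundComponents(noiseFree$truesMean, noiseFree$normalization)
study <- realizeStudy(phantom, noiseFree, background, totalPrompts = 1e6, seed = 1)
study
#> PhantomStudy (seed 1): 1.001e+06 prompts (25.0% randoms, 28.0% scatter fraction)

roiContrast(phantom$uptake, phantom$roiMasks$grayAll, phantom$roiMasks$whiteMatter)
#> [1] 4        # ground-truth gray/white contrast

std <- imageGrid(c(88, 88), 2)
modelStd <- buildSystemModel(std, geom, psfFwhmMm = 4.5)
recMlem <- mlem(study@prompts, modelStd, study@corrections, nIter = 100)

mrvox <- phantom$uptake@grid
modelHr <- buildSystemModel(std, geom, psfFwhmMm = 4.5, reconGrid = mrvox)
sens <- sensitivityImage(modelHr, study@corrections)
pilot <- mlem(study@prompts, modelHr, study@corrections, nIter = 20)
rule <- deltaRule(pilot@final)
beta <- scaleBeta(rule$delta0, rule$delta0, 0.1 * centralSensitivity(sens),
                  rule$dynamicRange)
prior <- priorModel(mrvox, anatomical = phantom$pseudoT1,
                    delta = rule$delta0, beta = beta)
recMr <- oslMapem(study@prompts, modelHr, study@corrections, prior, nIter = 100)

roiMetricTable(recMlem@final, mrvox, phantom$roiMasks)
roiMetricTable(recMr@final, mrvox, phantom$roiMasks)
```

Selected rows of the two metric tables (contrast against white matter,
regional COV, evaluated on the 1 mm grid):

```
method                          roi         contrast   cov
MLEM-PSF (2 mm)                 corticalGM  3.25       0.269
MLEM-PSF (2 mm)                 caudate     3.00       0.248
MLEM-PSF (2 mm)                 grayAll     3.21       0.271
MR-guided MAP-PSF (MRvox 1 mm)  corticalGM  3.99       0.037
MR-guided MAP-PSF (MRvox 1 mm)  caudate     3.94       0.102
MR-guided MAP-PSF (MRvox 1 mm)  grayAll     3.98       0.044
```

The true contrast is 4: MLEM-PSF recovers 3.2 at 27% regional noise,
while the MR-guided MRvox reconstruction reaches 3.98 at 4% — partial
volume correction with simultaneous noise suppression. The full
multi-seed matrix, the `beta` sweep and the Gibbs-overshoot comparison
are one call each: `runStudy(studyManifest())`, `selectBeta()`,
`compareGibbs()`; a thin CLI over the same functions is in
`inst/cli/mrguidedpet.R`.

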