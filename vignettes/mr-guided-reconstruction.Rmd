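---
title: "MR-guided MAP-EM reconstruction at MRI voxel sizes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-guided MAP-EM reconstruction at MRI voxel sizes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

PET images are resolution-limited (about 4 mm in clinical brain scanners),
so small structures — the cortical gray-matter ribbon, the striatum —
exchange counts with their surroundings and their measured uptake is
biased: the partial volume effect. Two in-reconstruction corrections are
studied here: resolution (PSF) modelling, which recovers contrast but
rings at sharp edges (Gibbs overshoot), and anatomically guided penalized
likelihood, which uses a simultaneously acquired MR image to smooth within
— but not across — anatomical boundaries. The package's central question
is the voxel size at which the guided reconstruction is performed: using
the MR image at its native (finer) grid preserves the high-frequency
anatomical detail that is otherwise lost when the MR image is down-sampled
to the PET grid.

# The high-resolution system matrix

The forward model for the expected data is

    q = n .* a .* X theta + r + s

with `X` the geometric projector, `n` and `a` normalization and attenuation
factors, and `r`, `s` expected randoms and scatter. The package uses an
idealized 2-D parallel-beam geometry: `nAngles` views uniformly spaced on
[0, pi) and radial bins of 2.045 mm (the clinical PET-MR sinogram
sampling). `siddonForward()` implements the Siddon ray tracer — each bin is
the intersection-length-weighted sum of voxel values along its line of
response — and `siddonBackward()` is built from the identical traversal, so
the pair is adjoint to machine precision rather than approximately.

A thin-ray projector undersamples any lattice finer than the ray pitch:
reconstructing 1 mm voxels from 2.045 mm bins leaves voxels that no ray
(or almost no ray) intersects, and MLEM pins them near zero — gap
artifacts. Instead of switching to a thicker-ray projector, the system
matrix is modified to

    P_hr = X_lr D,        P_hr' = D' X_lr'

where `D` (`downsampleMatrix()`) is a bilinear/trilinear interpolation from
the fine (MRvox) grid to the standard grid whose weights are computed from
the *fine-grid* voxel coordinates, so each fine voxel is coupled to the
same 4 (8 in 3-D) coarse neighbours in both directions, and the transpose
is the exact matrix transpose — the projector/backprojector pair stays
matched. Rows of `D` are normalized so constants are preserved; `D'` is
used without renormalization (the adjoint requirement wins and is put on
the transpose, constant preservation on `D`). PSF resolution modelling is a
separable image-space Gaussian (`psfBlur()`), kernel truncated at four
sigma and normalized to unit sum, applied before `D`; zero-padded
boundaries keep the operator exactly self-adjoint, which the matched-model
invariant needs (tests keep support away from boundaries, where the unit
gain statement holds).

`patchSingularValues()` assembles the dense system matrix restricted to a
small central patch and returns its spectrum; comparing the standard and
composed matrices over the *same physical patch* shows the composed matrix
retaining more above-threshold singular values — more recoverable spatial
frequencies — especially with PSF modelling. Because the composed matrix
has more columns but its rank is bounded by the coarse-grid support, the
comparison is made at matched absolute index (same patch, hence comparable
frequency content per index), not at index normalized per matrix.

# The smoothed Lange prior with Bowsher guidance

Reconstruction maximizes `L(m|theta) - beta U(theta)`. The penalty is the
smoothed Lange energy

    U(theta) = sum_j psi( sqrt( sum_k xi_jk w_jk (theta_j - theta_k)^2 ) )
    psi(t)   = delta * ( |t|/delta - log(1 + |t|/delta) )

the Lange (Fair) potential of each voxel's weighted root-mean-square
neighbour difference — quadratic for small `|t|`, TV-like for large `|t|`,
with `delta` (image-intensity units) setting the crossover. Evaluating the
potential on the local RMS rather than on each difference separately makes
the penalty more robust to noise-versus-edge discrimination and less
sensitive to `delta`.

* Proximity weights `xi` are inverse physical distances, normalized to sum
  to one per voxel; at image boundaries the normalization runs over the
  in-bounds (truncated) neighbourhood, so the sum stays exactly one.
  Normalization is over the full neighbourhood, with the Bowsher mask
  applied separately (the alternative — normalizing after masking — is a
  documented design fork; this one keeps `beta` comparable across masks).
* Similarity weights `w` follow the modified (asymmetric) Bowsher rule:
  per voxel, the `B` neighbours most similar in the anatomical image get
  weight one, the rest zero. Ties (plateaus, quantized images) are broken
  by smaller physical distance, then lexicographic offset order, making
  the selection deterministic. Boundary voxels select all available
  neighbours when fewer than `B` are in bounds.
* The neighbourhood is a box of fixed *physical* extent (default 5 mm —
  the 5x5(x5) box at 1 mm spacing); on a coarser grid the box edge is the
  odd voxel count nearest to extent/voxel-size, so the same `beta` can be
  used across voxel sizes. The default `B` keeps the 40-of-124 proportion
  of the 3-D reference setting (about a third of the neighbourhood).

The one-step-late (OSL) MAP-EM update divides the EM numerator by
`s + beta * dU/dtheta` evaluated at the previous iterate. The printed
derivative

    dU/dtheta_j = sum_k xi w (theta_j - theta_k) / (delta + t_j)

drops the dependence of the neighbour terms on `theta_j`; it is what the
OSL update uses (`smoothedLangeGradient()`, default), while the full
symmetrized derivative is available (`symmetrized = TRUE`) and is the form
verified against numeric differentiation of the energy in the tests. The
one-sided gradient is bounded by one for normalized weights (a
Cauchy–Schwarz consequence), which is what makes the potential
OSL-compatible at all.

# Hyperparameters

`delta` scales the potential, so `beta` must move with it to keep the
regularization strength comparable:

    beta = k(delta) * beta0,   k(delta) = (Dtheta + delta0) / (Dtheta + delta)

with `Dtheta` 25% of the image dynamic range, `delta0 = 0.1 * Dtheta`
(TV-like reference), and `beta0` a multiple of the mean sensitivity-image
value in the central quarter of the FOV — which makes `beta0` independent
of the system matrix used, since the penalty is additive to the
sensitivity in the OSL denominator. The dynamic range is taken from a
20-iteration MLEM pilot: reproducible, and the counts-preserving uniform
initialization has no usable range of its own.

OSL converges only while the denominator stays positive; the penalty
strength must respect that. `selectBeta()` implements the selection sweep:
the candidates {0.1, 0.2, 0.5, 1, 2} x central sensitivity are each run on
one realization of the reference configuration (MR-guided, PSF, standard
grid), a run is flagged stable when its penalized objective is
non-decreasing and the positivity guard never fires, and the stable
candidate of maximum contrast is selected. At this package's desk scale
(1e6 counts, 2-D) the stable range sits at the low end of the candidate
grid — with two orders of magnitude more counts the likelihood term is
stiffer and larger multipliers become usable, which is why the candidate
grid spans them. Individual runs that still violate positivity abort with
a diagnostic once more than 1% of supported voxels need flooring
(denominators are floored at 1e-3 x median sensitivity and every
activation is logged in the trace flags).

# The phantom simulator

`makePhantom()` draws a 2-D brain-like slice with parametric shapes on a
1 mm grid (176 mm FOV): soft-tissue and skull shells, a CSF layer and
ventricles, a cortical gray-matter ribbon, white matter, and three pairs
of small striatum-like hot structures (caudate, putamen, accumbens).
Uptake is FDG-like with gray matter exactly 4x white matter; attenuation
uses exactly two tissue values (soft tissue 0.0096/mm, bone 0.0151/mm);
the pseudo-T1 image assigns distinct per-tissue intensities (WM bright,
GM intermediate, CSF dark) with 1 mm smoothing and 1% noise — it stands in
for an MR simulation and is labelled synthetic: Bowsher selection only
needs rank-order similarity aligned with the anatomy. Overlapping shapes
resolve by paint order (later shapes overwrite).

`simulateNoiseFree()` blurs the uptake with the 4.3 mm FWHM system
resolution, projects it, and applies attenuation factors (exponentiated
line integrals of the attenuation map) and a synthetic smooth radial
normalization profile (default +/-10%; the scanner's real normalization
structure is not reproducible and is replaced by this declared profile).
`addBackgroundComponents()` models randoms as a uniform sinogram times the
normalization factors and scatter as a radially smoothed (40 mm FWHM
Gaussian; "smoothed" is otherwise unquantified) copy of the trues, with
scales solved so the means hit the configured fractions exactly under the
standard definitions: randoms fraction = randoms/prompts = 25%, scatter
fraction = scatter/(trues+scatter) = 28%. `realizeStudy()` rescales the
means to the target prompts (default 1e6) and draws independent Poisson
counts per bin per component, seeded and bit-reproducible.

What the generator does *not* emulate: 3-D (span-11) axial sampling,
detector-ring geometry and gaps, arc effects, scatter physics, dead time,
PET–MR misregistration, and anatomical mismatch between tracer and
structure. Passing tests therefore demonstrate the mechanics and the
relative orderings of the methods on ideally matched anatomy, not
clinical-data performance — with mismatched boundaries the Bowsher prior
is known to be vulnerable, and that failure mode is outside this
simulator.

# Evaluation

Metrics follow the standard regional definitions: contrast = ROI mean /
white-matter mean; COV = ROI sample standard deviation / mean (N-1
denominator); ensemble NRMSE of the ROI mean over M realizations, with the
squared deviation divided by the first power of the truth mean exactly as
printed in the reference definition (a `normalization = "mean2"` switch
provides the conventional dimensionless variant, since the printed form is
dimensionful and plausibly a typo — both are reported forms, the printed
one is the default); and ensemble COV, the per-voxel across-realization
COV averaged over the ROI, excluding (with a warning) voxels of zero
ensemble mean rather than propagating infinities. All metrics are computed
on the high-resolution grid; standard-grid reconstructions are first
interpolated up with the package's own bilinear interpolation. ROI masks
come from the true tissue labels (gray-matter-restricted), avoiding
segmentation error.

# The desk-scale study

`runStudy()` drives the whole loop: phantom, seeded realizations, the
{MLEM, MAP, MR-guided MAP} x {standard 2 mm, MRvox 1 mm} x {PSF on 4.5 mm /
off 2.5 mm} matrix, per-iteration metrics, and ensemble tables, all
determined by a manifest (and refusing to merge outputs produced under a
different manifest, via a content hash). Problem sizes were chosen so the
full default study — 176x176 at 1 mm, 88x88 at 2 mm, 96 angles, 1e6
prompts, 10 seeds, 100 iterations, 6 configurations — completes in a few
minutes on one CPU; 400-iteration runs remain available through the
manifest. The "no-PSF" mode still uses a narrow 2.5 mm kernel and PSF mode
4.5 mm, mirroring how clinical reconstructions are configured; the
simulated resolution is 4.3 mm.

```{r, eval = FALSE}
library(MRguidedPET)
man <- studyManifest(seeds = 1:10, nIter = 100)
res <- runStudy(man, outDir = "study-out")
plotContrastCov(res$metrics, roi = "corticalGM")
g <- compareGibbs(man)
```

`compareGibbs()` reports rim overshoot and COV of the striatal structures
for MLEM-PSF versus MR-guided MAP-PSF on one realization, plus the
activity mass outside the true tissue support (spill-out) — PSF modelling
reduces spill-out, MR guidance removes the overshoot.

# Numerical choices and degenerate inputs

* Rays missing the FOV contribute exactly zero and are handled through the
  sensitivity image; voxels with zero sensitivity are frozen at zero.
* All-zero prompts return the zero image (the ML solution).
* MLEM initialization: uniform positive image scaled to the measured
  counts net of the additive estimate.
* `q <= 0` bins with zero measured counts contribute zero to the EM ratio.
* Bowsher tie-breaks and ordering are fully deterministic (distance, then
  lexicographic offset), so reconstructions are reproducible bit-for-bit
  given a seed.
* 3-D volumes are handled as independent axial planes sharing the in-plane
  geometry (slice-stacked); nothing in the model equations is
  dimension-specific, but oblique-ray 3-D sampling is out of scope.

# Known limitations

* The idealized 2-D parallel-beam geometry under-expresses the fine-grid
  gap artifact of real scanners: angular rotation largely fills the radial
  sampling gaps, so the plain fine-grid penalty at moderate angular
  density is localized near-zero-sensitivity voxels rather than the
  widespread striping seen with 3-D axial (span-11) undersampling, which
  is out of scope here. `fineGridArtifactDemo()` exposes the honest 2-D
  form of the effect: fine-lattice voxels pinned near zero that the
  composed model repairs.
* OSL is not a convergent MAP algorithm; the convergent alternative
  (De Pierro-style surrogates) is deliberately out of scope, and penalty
  strengths are restricted to the OSL-stable range by the selection sweep.
* The clinical-style comparator (early-stopped MLEM plus a 4 mm
  post-filter) mimics routine practice but claims no vendor-exact match.
* Sinogram I/O uses a documented plain-text JSON container rather than a
  binary scientific container, keeping fixtures and outputs inspectable.
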