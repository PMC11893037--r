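---
title: "Free-breathing lung ventilation mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-breathing lung ventilation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prefulr)
```

# Overview

`prefulr` implements an end-to-end free-breathing proton lung MRI
ventilation pipeline at desk scale: simulation of a FLORET-style 3D
ultrashort-echo-time acquisition of a breathing digital thorax,
respiratory binning of the continuously acquired excitations from a
bellows trace, motion-compensated low-rank (MoCoLoR) reconstruction of a
respiratory-resolved image series, and phase-resolved functional lung
(PREFUL) analysis producing static and dynamic ventilation maps. This
vignette explains the models behind each stage, the parameters that
matter, and the design choices made where the design was genuinely open.

# The sampling model

Each excitation acquires one center-out readout along a Fermat spiral,
$r(\theta) = k_{max}\sqrt{\theta/\theta_{max}}$, traced on a cone and
grouped into up to three mutually orthogonal "hubs". Two constructive
choices matter:

* **Radial sample spacing.** Samples are spaced uniformly in *radius*
  along the spiral path rather than uniformly in spiral angle. With a
  modest number of samples per readout (desk scale uses 48-64 rather
  than the several hundred of a real ADC), equiangular sampling of the
  square-root law leaves the first radial step at
  $k_{max}/\sqrt{J}$ - a hole covering the first few k-space cells that
  corrupts every low-frequency estimate downstream. Uniform-in-radius
  sampling removes the hole while preserving the Fermat-spiral geometry.
* **Interleave ordering.** Azimuths advance by the golden angle and cone
  angles by an independent irrational stratifier
  ($\sqrt 2 - 1$), so that any contiguous acquisition window covers the
  sphere quasi-uniformly. Using the *same* irrational for both (a
  tempting simplification) collapses the trajectory onto a 2D surface of
  the ball.

Gradient waveforms, slew limits and relaxation are not modeled; the
trajectory is geometry only.

# The breathing phantom

The phantom is a soft-tissue ellipsoid body with two lung ellipsoids, an
optional trachea and optional bright vessel cylinders. Breathing is a 1D
cranio-caudal stretch: at inflation state $a \in [0,1]$ the diaphragm
descends by $a \cdot \mathrm{tidal\_amplitude} \cdot$ (lung height),
linearly tapering to zero at the apex, while parenchymal density follows

$$\rho(a) = \frac{\rho_{EE}}{1 + a_{\mathrm{eff}} \cdot FV},$$

where $FV$ is the voxel's fractional-ventilation amplitude. Because the
uniform stretch changes lung volume by exactly $1 + a\,FV$ when
$FV$ equals the tidal amplitude, lung-compartment mass is conserved
(verified to < 1% in the tests). Defects reduce $FV$ inside spheres
(amplitude defects) or delay the filling by a cycle fraction
(phase-lag defects, $a_{\mathrm{eff}} = a(c - \mathrm{lag})$), driving
VTTP and FVL-CM abnormality with normal amplitude.

The bellows trace is a quasi-sinusoid with cycle-to-cycle amplitude
(8%) and period (4%) jitter, optional drift, additive noise and sparse
high-amplitude outliers; the generator logs the true cycle fraction and
outlier positions. The binding bellows-to-state convention is a sliding
3-cycle min-max normalization of the *smoothed* trace (robust to drift
and, through smoothing plus a 2%/98% quantile envelope, to
single-sample outliers); the simulator renders the phantom at exactly
this mapped state, so every ~3-cycle window's deepest breath reaches
full inflation. Coil sensitivities are smooth complex Gaussian lobes
around the body.

For tractability the simulator quantizes the respiratory cycle into 16
rendered states per acquisition and synthesizes k-space per state with a
Kaiser-Bessel gridding NUFFT (oversampling 1.5, width-5 kernel, exact
transpose adjoint). The forward model is validated against a direct DFT
oracle at small grid sizes.

What the phantom does *not* emulate: cardiac motion, T2*/off-resonance
decay, anatomically realistic airway trees, perfusion. Passing tests
demonstrate correct *mechanics* of the pipeline on idealized breathing
anatomy, not clinical performance.

# Respiratory binning

The bellows trace is moving-average smoothed (default window: a quarter
of a breathing period), excitations beyond +-2 SD of the mean reading
are excluded, instantaneous phase is computed by Hilbert transformation,
and excitations are sorted into B equal-count bins centered on
equispaced phase targets. Equal counts are realized by nearest-phase
selection: every usable excitation belongs primarily to its nearest
target, a bin keeps its nearest primaries as unique members and fills
the remainder by borrowing the nearest neighbors' members, never
borrowing more than 50% of its size. The total budget defaults to the
published 240000 excitations (giving per-bin counts 30000...6000 for
8...40 bins) and is scaled to about twice the usable count for
desk-scale runs, capped so the smallest primary pool can still supply
each bin's unique quota.

# Reconstruction

The series of B bin images $x$ solves

$$\hat x = \arg\min_x \tfrac 12 \lVert P(FSx - y)\rVert_2^2
  + \lambda_L \lVert Mx \rVert_*,$$

with $F$ the per-bin NUFFT, $S$ coil maps, $P$ diagonal single-channel
preconditioning weights (kernel-autocorrelation density compensation),
$M$ interpolation-based warping of each phase onto the end-expiration
reference, and the nuclear norm coupling the phases. The solver is
proximal gradient on the weighted normal equations: CG-SENSE
initialization, Lipschitz-normalized gradient steps (inner), singular
value soft-thresholding of the motion-registered stack (outer), and
motion re-estimation (superior), defaulting to the published counts
5/3/3 with step size 1 and $\lambda_L = 0.01$.

Numerical choices worth knowing:

* $\lambda_L$ is dimensionless; its absolute nuclear-norm weight is
  anchored to the intensity scale of the initialized images
  ($\lambda_L \cdot \max|x| \cdot \sqrt{N^3}$), fixed after
  initialization so the composite objective is well defined. With the
  default $\lambda_L$ the threshold sits near the noise singular values
  and well below the respiratory-dynamics singular value.
* The prox is applied as a *warped-domain increment*:
  $x \leftarrow x + M^{-1}(\mathrm{SVT}(Mx) - Mx)$. A full
  warp-threshold-unwarp round trip would blur every bin by two
  interpolations even when the threshold does nothing, which measurably
  inverts the small (10-20%) parenchymal density contrast between
  respiratory extremes.
* $M^{-1}$ uses fixed-point inversion of the displacement field, not
  sign negation.
* Coil maps are estimated JSENSE/NLINV-style: joint per-coil CG
  least-squares images on a half-resolution calibration grid (where the
  central k-space ball is strongly oversampled), smoothed and
  normalized to unit root-sum-of-squares. Full-grid or gridding-based
  calibration fails quietly here because the phantom's coil spectra
  occupy only the first couple of k-space cells.
* Sample processing is ordered by oversampled-grid cell, which makes the
  scattered gather/spread memory access near-sequential (about 4x
  faster on one core).

# PREFUL analysis

The reconstructed series is resorted so the ventilation cycle runs
EE -> EI -> EE (end-expiration = maximal mask-mean parenchymal signal),
bias-field corrected, stepwise-registered to end-inspiration,
interpolated to 16 equidistant phases with a Gaussian kernel
(sigma = 0.3 input spacings), temporally low-passed at 0.7 Hz (cutoff
harmonic = 0.7 x breathing period) and spatially filtered with an
edge-preserving bilateral filter (range sigma = 2x background noise
SD, spatial sigma 1 voxel). Lungs are segmented by two-class k-means
inside the eroded body support; bright tubular structures are removed
as vessels.

Parameters, per voxel on the parenchyma mask:

* **RVent**: $(S_{EE} - S(t))/S(t)$, fractional density change relative
  to end-expiration (mL/mL); the end-inspiration map is the static
  parameter.
* **FVL-CM**: Pearson correlation between the voxel's concatenated
  standardized (volume, flow) series and a high-ventilation reference
  loop built from voxels whose RVent lies in the 75-95% quantile band.
  The default is the zero-lag correlation so that delayed filling
  lowers CM; a maximize-over-circular-lag variant is available behind
  `cm_lag_search`.
* **VTTP**: cycle fraction of the RVent maximum (ties take the earliest
  phase), 50% for symmetric filling.
* **Defects**: RVent below 40% of the 90th percentile; CM below 0.9.
  VDPs are the defect fractions of the parenchyma mask.

Design choices made here:

* **Bias field once, propagated.** The degree-2 log-polynomial field is
  estimated on the first (end-expiration) phase and divided out of all
  phases. A per-phase fit absorbs about a fifth of the parenchymal
  density change into the "bias" field, because the lungs darken at
  inspiration and drag the fit with them.
* **Registration stiffness trades motion compensation against signal
  fidelity.** Demons-style registration matches intensities; it can
  counterfeit a regional density-change pattern (e.g. the bright
  appearance of a non-filling defect at inspiration) as deformation,
  transferring intensity where none moved. The default parameter set
  (3 levels, fluid sigmas 2/1.5/1, elastic sigma 0.5, local-contrast
  normalized forces) balances the two; `stiffRegistrationParams()`
  suppresses the counterfeiting at the cost of residual fine-scale
  motion. This tension is the main known limitation of the analysis on
  this phantom: amplitude recovery of small defects is partial, and the
  voxelwise regression of recovered RVent on the prescribed amplitude
  falls short of unity slope at the 48-voxel desk scale (the
  attenuation budget is roughly: bin-level state averaging and view
  sharing, then the 0.7 Hz low-pass, then registration leakage).
* **EE/EI identification** is the max/min of the mask-mean lung signal
  across phases (parenchymal density is maximal at end-expiration).

# Problem sizes and determinism

All tests and the acceptance analyses run on one CPU core at desk
scale: 12-32 voxel grids for operator-level checks, a 48-voxel grid
with 8 bins, 4 coils and about 40000 excitations for the end-to-end
recovery study, and a 32-voxel grid for solver-behavior checks. Every
stochastic step is seeded; registration and reconstruction contain no
unseeded randomness, so pipelines rerun bit-identically under a fixed
seed and configuration.

# Known limitations

* The registration layer is a contract implementation (multiresolution
  demons with phase-correlation initialization), not a replica of any
  external toolkit; only its invariants (metric non-worsening,
  determinism, stated recovery accuracies) are guaranteed.
* The density-compensated adjoint is quantitatively reliable only
  because the trajectory has no radial gaps; least-squares (CG)
  reconstruction is the quantitative path.
* Desk-scale lungs are a few hundred voxels across their short axis;
  partial-volume effects are correspondingly larger than at clinical
  resolution, and parameter-recovery tolerances were chosen with the
  mechanics, not clinical accuracy, in mind.
* The raw-data container is an R serialization with a validated schema,
  suitable for the package's own pipelines rather than interchange with
  scanner software.
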