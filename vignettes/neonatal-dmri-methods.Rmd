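---
title: "Models and methods behind neodwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neodwi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neodwi)
```

`neodwi` is a desk-scale implementation of an artefact-aware neonatal
diffusion-MRI pipeline: preprocessing, microstructure fitting, fibre
orientation estimation, protocol-driven tractography and quality
control, validated end to end on a bundled synthetic phantom. This
vignette explains the models, the parameters that matter, the
numerical choices, and what the phantom-based validation does and does
not demonstrate.

## The synthetic phantom

Every quantitative claim in the package's tests is made against
`build_phantom()`, which generates multi-shell data with recorded
ground truth. The default layout is a crude but deliberately
neonatal-looking head: a CSF rim over a cortical grey-matter ribbon,
a deep white-matter interior, a laterally offset ventricle (offset so
the head is not rotationally symmetric — a symmetric phantom makes
rigid rotations unidentifiable), an elevated free-water region around
the ventricle, and one or two constant-cross-section fibre bundles
running below the ventricle.

Signals follow a multi-compartment forward model per voxel: an
isotropic ball (free water, d = 3.0e-3 mm²/s), axially symmetric
tensors per bundle with axial diffusivity 1.5e-3 mm²/s and a
radial/axial ratio of 0.3 — the low-anisotropy regime of neonatal
white matter — plus a per-tissue mean-kurtosis term, and Rician noise
(default sigma 35 against a white-matter S0 of 700, i.e. SNR 20).
Grey matter uses d = 1.1e-3 mm²/s with kurtosis 0.4 and 10% free
water; white matter carries 20% free water (45% periventricularly).
These defaults are fixed: they are the study conditions under which
all recovery tests run.

The sampling scheme mirrors the service-scale protocol: 300 volumes
(20 b0s; 64, 88 and 128 directions at b = 400, 1000 and
2600 s/mm²) across 4 phase-encode directions, 1.5 mm voxels, 3 mm
slices at 1.5 mm spacing. Model-recovery tests use this full scheme on
simulated voxel sets (`simulate_voxels()`, which generates from
exactly the model each fitter estimates). Artefact-recovery tests use
a 60-volume desk split (8 b0 + 26 + 26 directions at b = 1000/2600) on
a 32×32×20 grid: with only ~16 directions per shell a three-shell
60-volume split leaves the spherical-harmonic reference signals too
poorly determined, and their deterministic model mismatch — not noise —
produces collateral outlier flags. Two denser shells keep the desk
phantom representative of the estimators' service-scale behaviour.

What the phantom does *not* emulate: within-volume (slice-to-volume)
motion during a single excitation, eddy-current fields, gyrification
and tissue-boundary geometry, field changes over time, and spatially
varying coil sensitivity. Passing recovery tests on the phantom shows
the estimators are correctly implemented and statistically calibrated
under the stated forward models; it does not certify performance on
real scanner data.

`inject_artifacts()` applies motion before distortion (the scanner
order approximation), then multiplicative slice dropout (< 1) and
spin-history gain (> 1); every injected artefact is recorded in the
truth object. The spin-history default gain of 1.2 is a configured
convention, not a measured value.

## Preprocessing

**b0 selection.** Within each phase-encode direction, b0 volumes are
rigidly aligned and scored by mean Pearson correlation to the other
same-PE b0s; the top two per PE are kept and the globally
best-correlating volume becomes the reference. Ties break to the
lowest volume index. The correlation mask defaults to the brain mask.

**Susceptibility field.** A reversed-PE b0 pair carries equal and
opposite distortion along the PE axis. The displacement field (mm) is
parameterised on a coarse trilinear control grid (spacing 4 voxels)
and estimated by Gauss–Newton with backtracking over a ladder of image
smoothing levels (sigmas 2, 1, 0.5 voxels), minimising the masked
squared difference between the two unwarped images — both warps
include Jacobian intensity modulation, since the distortion compresses
and stretches signal as well as displacing it — plus a curvature
penalty (weight `lambda_reg`, default 0.03) with a small
first-difference term so that the infinite-regularisation limit is a
constant field. The control-grid parameterisation was chosen over
independent per-line profiles because per-voxel updates are
ill-determined wherever the image is flat along the PE axis; the
low-dimensional basis couples those voxels to informative ones. On the
desk phantom the estimator recovers a ±2-voxel sinusoidal field with
correlation above 0.9 against truth at SNR 20 (asserted in the tests
and recomputed by the acceptance script).

**Unwarping.** The 1-D distortion maps true coordinate xi to observed
x with xi = x − d(x). `apply_pe_unwarp()` inverts this monotone map
exactly per line (interpolating the inverse and dividing out the
Jacobian) rather than resampling by −d, which is only a first-order
inverse and breaks down at field gradients above ~0.2 voxel/voxel.

**Realignment.** Each volume gets a 6-parameter rigid content-motion
estimate by Nelder–Mead over a normalised-correlation cost evaluated
at ~4000 mask voxels. Two design points matter:

* The cost interpolates the *target* at inversely transformed
  positions and never resamples the moving volume. Resampling the
  moving volume makes whole-voxel shifts artificially sharp (one
  interpolation instead of two) and creates local minima that bias
  translations by up to a third of a voxel.
* Pass 1 uses crude contrast-matched targets (reference b0 / shell
  means); pass 2 re-registers every volume to its own leave-one-out
  spherical-harmonic prediction. The leave-one-out form is essential:
  a plain least-squares prediction contains a substantial fraction of
  the volume's own (possibly misaligned) signal and anchors it in
  place.

The estimated rotation is applied to the volume's b-vector; rotation
preserves norms and b-values exactly. A soft penalty discourages
rotations beyond ~30°, which removes a 180° alias that near-symmetric
heads admit. Interpolation is trilinear throughout.

**Signal prediction.** Per shell, a real even-order spherical-harmonic
series (default order 4) is fitted by least squares and evaluated at
the acquired directions; b0 predictions are the mean of the other b0s.
The order is lowered per shell until the direction count is at least
twice the coefficient count — an exactly determined fit would
reproduce noise rather than average it — and the pseudoinverse uses a
relative singular-value cutoff for clustered direction sets.

**Outlier slices.** For every slice of every weighted volume the
in-mask mean residual against the prediction is scaled by the square
root of the slice's voxel count (slice means over few voxels are
noisier) and standardised per shell with median/MAD. Slices below
−4 SD are flagged (dropout; `two_sided = TRUE` also catches
spin-history hyperintensity). Because a strong outlier contaminates
the predictions of *other* volumes at the same slice through the
signed hat-matrix weights, flags are re-scored against
exclusion-refitted leave-one-out predictions until stable (at most 3
passes). Flagged in-mask voxels are replaced by the refitted
prediction; volumes with more than half their slices flagged are
marked unusable and left untouched. On the desk phantom this flags
every injected 0.2× dropout with zero false positives across seeds.

**Super-resolution.** Thick-slice acquisition is modelled as a known
slice-profile matrix A (default: boxcar of width equal to the slice
thickness; Gaussian optional) applied along the through-plane axis.
Per through-plane column the Tikhonov problem
(AᵀA + λ L ᵀL) x = Aᵀy with a second-difference regulariser
(λ default 0.05) is solved. Since every column shares the same small
SPD matrix, one Cholesky factorisation is applied to all columns of
all volumes — exact and deterministic, so an iterative conjugate
gradient scheme would add convergence bookkeeping for no benefit.
Rows of A are normalised, and L annihilates constants, so constant
volumes are reproduced exactly.

## Microstructure

**Kurtosis tensor.** The model is a second-order expansion of the
log-attenuation in b: ln S = ln S0 − b gᵀDg + (b²/6)(gᵀDg)²·K̄, with a
single mean-kurtosis parameter. The quadratic term uses the
directional diffusivity squared, keeping the model a per-direction
Taylor series; `kurtosis_scale = "md2"` switches to an MD²-scaled
variant. Estimation: a plain tensor fit initialises the directional
diffusivities; one signal-weighted log-domain pass adds the kurtosis
column; then a Levenberg-damped Gauss–Newton refinement fits the
*Rician mean* of the model signal to the raw magnitudes, with sigma
estimated per voxel from the b0 repeats. The last step matters: at
b = 2600 the noise floor otherwise masquerades as substantial positive
kurtosis; with it, the median spurious MK on kurtosis-free data stays
below 0.05 at SNR 30 (asserted in the tests).
Negative tensor eigenvalues are clamped at 1e-6 (flagged); K̄ is
clamped to [−1, 5].

**NODDI-Bingham.** Three water pools: restricted intra-neurite sticks
dispersed by a Bingham distribution (two orthogonal dispersion axes,
concentrations κ1 ≥ κ2, ODI_i = (2/π)·atan(1/κ_i)), a hindered
extra-neurite axially symmetric tensor with tortuosity coupling
d⊥ = d∥(1 − f_in), and free water (d fixed at 3.0e-3 mm²/s). The
parallel diffusivity is fixed (default 1.7e-3 mm²/s; lower values are
appropriate for neonates and configurable). The Bingham convolution is
evaluated by quadrature on a 300-point Fibonacci sphere grid — the
normalising constant has no closed form, and quadrature-normalised
weights make it implicit. Fitting is grid-search initialisation over
orientation, dispersion and fractions, then Nelder–Mead refinement on
logit/log-transformed parameters. Magnitudes are Rician
moment-corrected before fitting so the noise floor is not absorbed
into the restricted fraction.

## Fibre orientations

The deconvolution model treats the FOD as a sum of up to three delta
functions convolved with an axially symmetric tensor kernel:
S/S0 = f_iso·e^(−b·d_iso) + Σ f_i·e^(−b λ∥ (λ_R + (1 − λ_R)(g·v_i)²)),
with the remaining fraction hindered-isotropic at the kernel's mean
diffusivity. The kernel width λ_R is voxel-specific under a Gaussian
prior truncated to (0, 1); `estimate_kernel_prior()` builds that prior
from coherent single-fibre voxels (top-50% FA within a supplied mask,
λ_R = ((λ2 + λ3)/2)/λ1 per voxel, mean/sd across subjects or across
voxels for one subject), and defaults to mean 0.3, sd 0.08 when no
data are supplied. λ∥ is also voxel-wise, under a weakly informative
log-normal prior centred at 1.5e-3 mm²/s.

Posteriors are sampled by per-parameter Metropolis–Hastings under a
Rician likelihood (sigma from b0 repeats), 1000 burn-in and 1250 kept
iterations thinned by 25 by default (reduced schedules are used in the
tests), with proposal scales adapted during burn-in and orientations
proposed as renormalised Gaussian perturbations with antipodal
identification. Automatic relevance determination is a log shrinkage
prior, −2·log(f + 1e-3), applied to *every* fibre fraction: applying
it only to the non-primary fractions leaves a lone spurious fibre
alive in pure free water, where nothing else constrains f1.
Near-parallel compartments (within 20°) are merged in the posterior
summary — the sampler occasionally splits one population over two
deltas. A fibre is reported when its posterior mean fraction reaches
0.05; the 0.05 threshold is applied per voxel, post hoc. Chains with
post-burn-in acceptance under 1% are flagged as unmixed.

## Tractography

Protocols are JSON descriptors naming seed, waypoint, stop and
exclusion masks; bilateral protocols carry mirrored left/right sets.
The default library (16 tracts, 13 bilateral, the standard neonatal
virtual-dissection inventory) is generated programmatically on a
template grid with synthetic box ROIs — stand-ins that exercise the
machinery, not anatomical references. Exclusion masks contain the
mid-sagittal plane except for commissural/brainstem-crossing tracts.
Masks move between template and subject space through dense
displacement fields (`warp_mask()`, nearest neighbour;
`warp_invert()` inverts a field by fixed-point iteration under the
same backward-sampling convention).

Streamlines launch bidirectionally from uniform positions inside each
seed voxel (default 1000 per voxel; the tests use fewer), draw a
surviving fibre compartment proportionally to its posterior fraction,
draw an orientation sample of that fibre, and step 0.75 mm, stopping
on mask exit, curvature (cosine below 0.2), stop-mask entry, fibre-free
voxels, or 2000 steps. A streamline is successful iff it visits every
waypoint and never touches an exclusion mask; visitation counts
accumulate over successful streamlines only, and the probability map
divides by their number. Display thresholds default to (0.005, 0.05);
metric extraction binarises at 0.01. Tract-wise metrics are regressed
on de-meaned age with de-meaned total brain volume as covariate; the
age slope is normalised by the tract's mean metric and p-values are
Bonferroni-corrected across tracts at 0.05.

## Quality control

The report gathers: acquired-volume percentage and the import gate
(34/300 minimum — below that a reversed-PE b0 pair cannot be
guaranteed); average absolute and relative motion, defined as the RMS
displacement of in-mask voxel centres under each volume's rigid
transform relative to the reference and to the previous volume (the
reference's zero row is included in the averages); outlier percentages
in total and per shell, PE direction and volume, plus a per-slice
position flag count; prediction-based CNR per shell
(sd(predicted)/sd(residual)) and SNR from b0s
(mean(predicted)/sd(residual)) averaged within WM/GM masks; and the
masked b0-to-T2 correlation. Degenerate denominators become explicit
nulls with a reason string, never infinities, so reports remain
machine-comparable. The JSON report embeds seeds and provenance.

## Problem sizes and determinism

The shipped tests run the artefact pipeline on a 32×32×20, 60-volume
phantom; microstructure recovery on 50–300 simulated voxels at the
300-volume scheme; the MCMC deconvolution on ~30 voxels with a
400/400/10 schedule; and tractography with 60–200 streamlines per seed
voxel. These sizes were chosen so the whole suite exercises every
claim in a few minutes on one core while keeping each statistical
tolerance attainable with margin. All stochastic components (phantom
noise, MCMC, tracking) are seeded and reproduce bit-identically under
a fixed seed.

## Known limitations

* Volume-level rigid realignment only: within-volume (slice-to-volume)
  motion is generated by the phantom machinery but not corrected, and
  inflates motion/outlier QC metrics when present.
* No eddy-current field model; the field estimator is a simplified
  reversed-PE scheme, not a full spline-field implementation.
* Registration to anatomy is warp *application* only; estimating
  nonlinear warps or boundary-based rigid registration is out of
  scope.
* At desk-scale direction counts (tens per shell) the realignment
  precision for weighted volumes is ~0.1–0.5 mm, limited by the
  spherical-harmonic reference's representational error rather than
  noise; at service-scale counts (64–128) the references are much
  stronger.
* The Watson special case of the dispersion model (κ1 = κ2) is reached
  by the Bingham fit but not offered as a constrained faster path.
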