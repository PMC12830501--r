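---
title: "Tissue-dependent positron range correction for Ga-68 PET: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-dependent positron range correction for Ga-68 PET: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

⁶⁸Ga emits energetic positrons (endpoint kinetic energy 1.899 MeV) that
travel several millimetres before annihilating. PET localizes the
annihilation, not the decay, so every ⁶⁸Ga image is blurred by the positron
range. The blur is tissue dependent: in lung (density ≈ 0.26 g/cm³) the
range is nearly four times that in soft tissue, while in bone it is roughly
half. A single stationary deconvolution kernel therefore undercorrects in
lung and overcorrects in bone.

`gaprc` implements a tissue-dependent, spatially-variant correction (TDSV
PRC): one positron-range kernel per tissue class, applied through binary
CT-derived tissue masks inside the forward and backward projection steps of
OSEM, together with everything needed to study it end to end without
patient data — a Monte Carlo kernel generator, a synthetic torso, an
acquisition simulator with sinogram-domain lesion insertion, lesion metrics
and paired nonparametric statistics.

## The correction operator

For tissue classes $i = 1 \dots n$ with kernels $K_i$ and binary masks
$M_i$ (mutually exclusive, collectively exhaustive on the PET grid), the
corrected image estimate is

$$ \mathrm{img}_{\mathrm{PRC}} \;=\; \sum_{i=1}^{n} \bigl(\mathrm{img}
\otimes K_i\bigr) \odot M_i , $$

i.e. convolve-then-mask. This ordering is what makes the operator
spatially variant: at a tissue boundary each output voxel takes the
convolution of the *whole* neighbourhood with its own tissue's kernel.
Counts are conserved in homogeneous regions (kernels sum to 1) but not
exactly at boundaries — an inherent property of the operator, since the
model does not follow positrons across tissue interfaces with energy-loss
bookkeeping.

The tissue-independent comparison operator is the $n = 1$ special case: the
water kernel convolved over the entire image.

OSEM needs the adjoint as well: the backprojection step uses the exact
transpose $\sum_i K_i^{\mathrm{flip}} \otimes (\mathrm{img} \odot M_i)$,
so the forward/backward pair is matched. Whether a matched adjoint or a
re-applied forward operator is used in the reference implementations is not
observable from outside; we chose the true adjoint because it preserves the
fixed-point properties of EM updates, and tests verify the pair passes an
inner-product adjointness check to 1e−10 relative. Convolutions are
FFT-based with zero padding at the volume border (activity outside the
field of view is zero, matching the physics of a finite sinogram); a direct
convolution path exists as an independent reference and the two agree to
1e−8.

## Positron-range kernels

Kernels are generated by condensed-history Monte Carlo transport in
homogeneous media:

* Initial kinetic energies are drawn from the allowed-shape Fermi β⁺
  spectrum with the nonrelativistic Coulomb factor for positrons
  (daughter Z = 30 for ⁶⁸Ga). The sampler is rejection-based; its mean is
  tested against numerical quadrature of the same density.
* Each positron advances along its residual CSDA range (tabulated electron
  stopping power in water, integrated numerically) in 40 equal mass-length
  substeps, with a Gaussian multiple-scattering deflection (Highland form)
  per substep, until its energy falls below 10 keV, where it annihilates.
* Materials are density-scaled water: transport is computed in unit-density
  water and displacements scaled by $1/\rho$ (lung 0.26, bone 1.90 g/cm³).
  This reproduces the expected range ordering and magnitudes — the mean
  3-D displacement in water comes out at ≈ 3.6 mm and the 99.9th
  percentile at ≈ 8.6 mm — at desk scale, while deliberately ignoring
  composition-specific cross sections, positronium chemistry and magnetic
  fields.

Displacements are binned onto the PET voxel grid (2.73 × 2.73 × 2.80 mm by
default). The kernel half-width is the nearest integer of
maximum-range / voxel-pitch, which reproduces 7³ (water, 8.8 mm), 25³
(lung, 32.3 mm) and 5³ (bone, 4.5 mm) elements; the maximum-range preset
carries those three sizing values, and for user-defined materials the
99.99th percentile of simulated displacements is used instead. Weights are
divided by the number of simulated decays and then renormalized to sum
exactly to 1; the pre-renormalization truncated-tail mass is recorded in
the kernel metadata (`truncated_fraction`). Renormalization is a deliberate
choice: it makes the correction operator count-conserving in homogeneous
regions, at the cost of slightly re-weighting the in-kernel distribution.

Default kernel generation uses 10⁶ decays and seed 20220901; all transport
is bitwise reproducible under a fixed seed.

## Tissue segmentation

CT volumes are resampled to the PET grid (volume-weighted block averaging
when the CT is an integer factor finer — averaging limits aliasing before a
nearest-neighbour decision — and trilinear interpolation otherwise), then
every voxel is assigned to the material with the nearest reference
Hounsfield unit: water 3, lung −695, bone 1226. Exact midpoints go to the
lower-HU material; the mask order (lung, water, bone) is fixed for
reproducible serialization. The three HU references are constants with a
config override, since the procedure that produced them is not part of this
package.

## Acquisition model and OSEM

The scanner model is a 2-D parallel-beam, multi-slice geometry: stacked
independent axial planes, a voxel-driven projector with linear radial
interpolation precomputed as a sparse matrix, attenuation from a
piecewise-linear HU→μ conversion (air −1000 → 0, water 0 → 0.0096 mm⁻¹,
flatter slope above HU 0), and an isotropic image-space Gaussian detector
PSF (default FWHM 4.5 mm). Time-of-flight and oblique 3-D geometries are
out of scope; scatter, randoms, dead time and decay are neither simulated
nor corrected.

OSEM uses multiplicative updates with balanced round-robin angle subsets
(default 4 iterations, 10 subsets for the 120-angle desk geometry), ratio
and sensitivity floors of 1e−12, zero-sensitivity voxels frozen at zero,
and an initial estimate of 1 inside the attenuating body. With the range
correction enabled, the forward model applies PRC then PSF before
projection and the backprojection applies their adjoints — matching how
the correction enters the system matrix of the reference method.

Simulated data always contain positron range: the acquisition simulator
forward-projects under a ground-truth TDSV operator built from the
(lesion-updated) CT masks, scales to the counts budget and Poisson-samples.
Artificial lesions are inserted in the sinogram domain — the lesion-only
activity is range-blurred with the same ground-truth operator,
forward-projected, Poisson-sampled and added bin-wise — and the tissue
masks used by the reconstruction-side TDSV operator are updated with the
lesion HU. Using the same grid and operator for ground truth and matched
reconstruction isolates the algorithmic question (what does the correction
recover?) from model mismatch; a study of mismatch robustness would need a
finer ground-truth grid, which the containers support but the default
experiment does not exercise.

## The synthetic torso and the seven-lesion design

The phantom is a deliberately simple torso analog: an elliptical body
(HU ≈ 30), two ellipsoidal lung fields (HU ≈ −700), a posterior spine
cylinder (HU ≈ 1200) and an ellipsoidal liver. Background activity is
1.0 in soft tissue, 3.0 in liver, 0.2 in lung and 0.5 in bone (arbitrary
concentration units — the study endpoints are percentage changes, which
are scale invariant), modulated by a smoothed ±10% field so that
half-split subtraction has realistic inhomogeneity to cancel.

Seven spherical lesions of radius 5.0 mm reproduce the study design: soft
tissue in high-uptake liver (3:1) and in low-uptake soft tissue (16:1), a
bone lesion and a soft-tissue lesion inside bone (both 16:1), and three
lung-associated lesions (16:1 in lung, 10:1 at the lung–liver boundary,
3:1 in lung). Lesion voxels are set by binary centre inclusion (homogeneous
lesions, no partial-volume weighting; a supersampling oracle in the tests
quantifies the discretization), lesion activity is ratio × local background
mean, and lesion HU replaces the CT inside the sphere so the masks follow.
Centres are placed deterministically in the host compartments with a 30 mm
minimum spacing check. What the phantom does **not** emulate: realistic
anatomy, tracer biodistribution, respiratory motion, scatter/randoms — so
passing the directional study shows the *operator* behaves as reported
under matched conditions, not that patient-cohort effect sizes transfer.

## Quantification and statistics

Lesion metrics follow the standard definitions: SUVmax is the maximum VOI
value (concentration units unless a dose/weight scale is given — the
endpoints are percentage changes either way), CNR is
(lesion mean − background mean) / background SD, and activity recovery is
lesion mean / true inserted activity × 100%. Artificial lesions use 5.0 mm
spherical VOIs at the known centres; patient-style lesions use 50%-of-max
isocontour VOIs (26-connected component around the peak, no background
correction), with lesions above 10 cm³ dropped and at most the five
largest per tissue class per patient retained. Background VOIs are
same-tissue shells at > 5.0 mm from the lesion VOI, collected
nearest-first; the literal 10 mm³ minimum is honoured (and configurable)
even though it is smaller than a single PET voxel (~20.9 mm³) — we did not
second-guess the stated value, and the implementation simply takes at
least a 32-voxel shell so the background SD is stable.

Noise is compared via half-split subtraction: two independent
half-count acquisitions are reconstructed separately, subtracted, and the
SD measured in a 20 mm spherical VOI restricted to the liver or lung
region, with no √2 correction (only cross-reconstruction comparisons are
made). In the packaged experiment the halves are simulated without
lesions, so the noise VOIs need no lesion-avoidance bookkeeping.

Statistics mirror the reference analysis: per-lesion percentage changes,
D'Agostino–Pearson omnibus normality screening (implemented from the
published skewness/kurtosis transforms, validated against an independent
implementation and by type-I-error simulation), two-sided Wilcoxon
signed-rank (zeros dropped, average ranks; exact p by dynamic programming
over all sign assignments for n ≤ 25 — valid under ties — and a
tie-corrected normal approximation above), and Bonferroni adjustment with
an explicitly declared family size at α = 0.05.

## Desk-scale study sizes

The default `experiment_config()` runs the full directional study on a
96 × 96 × 32 grid at the native voxel size, 120 angles in 10 subsets,
5 × 10⁶ counts and 2 × 10⁵ decays per kernel — sizes chosen so the whole
pipeline (three full reconstructions, four half reconstructions, metrics
and statistics) completes in well under an hour on a single core while
leaving all qualitative behaviour intact. Kernel generation for production
use defaults to 10⁶ decays.

One parameter deliberately departs from the reference operating point: the
experiment reconstructs with 24 iterations × 10 subsets (240 multiplicative
updates) rather than 4 × 34. The reference reconstructions include
time-of-flight localization, which accelerates OSEM convergence
substantially; without it, a noiseless convergence sweep shows that
resolution recovery through the wide lung kernel is still far from its
asymptote at ~136 updates — the tissue-dependent estimate of a lung lesion
is then *below* its uncorrected counterpart simply because the
deconvolution has not converged, not because the operator is wrong.
240 updates put all three reconstruction variants in the converged regime
where their orderings are interpretable. `recon_config()` itself defaults
to the reference 4 iterations for users who model faster-converging
systems.

```{r example}
library(gaprc)
res <- run_experiment(experiment_config(master_seed = 1))
res$measurements     # 7 lesions x 4 reconstruction variants
res$noise            # half-split SD per region and variant
res$stats$suv_max    # paired percentage-change tests
```

## Known limitations

* Density-scaled-water transport ignores composition effects; kernels in
  cortical-bone-like media are slightly too wide relative to full-physics
  simulation.
* The convolve-then-mask operator does not conserve counts across tissue
  boundaries and cannot model energy loss across interfaces.
* The parallel-beam stacked-slice geometry has no oblique lines of
  response, so axial resolution effects of a real cylindrical scanner are
  not represented.
* Percentages measured on the synthetic torso are not expected to equal
  patient-cohort values; only their directions and orderings are
  meaningful, and those are what the acceptance checks assert.
* Two lesion configurations expose desk-scale limits of those directional
  checks. A lesion straddling the lung–liver interface sits exactly where
  the convolve-then-mask operator is non-conservative, and its
  tissue-dependent SUVmax converges so slowly without time-of-flight that
  it has not overtaken the uncorrected reading at the default update
  depth (its CNR has). And the borderline-detectability lung lesion (3:1
  over the low lung background) has a VOI maximum that is noise-dominated
  at the default counts budget — deconvolution improves its CNR but
  cannot reliably raise a maximum that noise owns. Both behaviours are
  asserted as-is by the test suite and discussed there.
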