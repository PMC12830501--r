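# gaprc — tissue-dependent positron range correction for ⁶⁸Ga PET

⁶⁸Ga emits positrons energetic enough (endpoint 1.899 MeV) to travel
millimetres before annihilating, and the distance depends strongly on
tissue density: roughly four times farther in lung than in soft tissue,
half as far in bone. The resulting blur depresses SUVmax and
contrast-to-noise of small lesions, most severely in lung. `gaprc`
implements a tissue-dependent, spatially-variant positron range correction
(TDSV PRC) inside iterative PET reconstruction, plus everything needed to
study it end to end on synthetic data: Monte Carlo kernel generation,
CT-driven tissue segmentation, a torso phantom with artificial lesions, a
Poisson acquisition simulator, OSEM with the correction in both projection
directions, lesion quantification and paired nonparametric statistics.

The core operator: per tissue class $i$ with positron-range kernel $K_i$
and binary CT mask $M_i$,

$$ \mathrm{img}_{\mathrm{PRC}} = \sum_{i=1}^{n}\bigl(\mathrm{img} \otimes K_i\bigr)\odot M_i, $$

applied (with its exact adjoint) in the forward and backward projection
steps of OSEM. Kernels are built by condensed-history positron transport in
density-scaled water, voxelized at the PET voxel size
(2.73 × 2.73 × 2.80 mm) and sized by the per-tissue maximum range:
7×7×7 voxels for water (8.8 mm), 25×25×25 for lung (32.3 mm), 5×5×5 for
bone (4.5 mm). Tissue masks come from nearest-neighbour Hounsfield-unit
classification (water 3, lung −695, bone 1226).

Audience: image-reconstruction researchers and physicists who want a
compact, fully inspectable reference implementation of tissue-dependent
range correction and its evaluation workflow — not a clinical tool.

## Worked example

Generate the kernels and inspect their widths:

```r
library(gaprc)
kernels <- make_kernel_set(n_decays = 2e5, seed = 11)
sapply(kernels, function(k) dim(k$weights)[1])
#> lung water  bone
#>   25     7     5
round(sapply(kernels, kernel_fwhm), 2)
#> lung water  bone
#> 3.51  3.41  3.14
```

(The central-profile FWHM differences are modest because the annihilation
density is sharply peaked at the origin; the tails differ enormously —
see `radial_profile()`.)

Run the full artificial-lesion study — seven 5 mm spherical lesions
(soft tissue, bone and lung hosts, activity ratios 3:1 to 16:1) inserted
into the sinogram of a synthetic torso, reconstructed without PRC, with a
stationary water-kernel PRC, and with the TDSV PRC:

```r
res <- run_experiment(experiment_config(master_seed = 1))
subset(as.data.frame(res$measurements), lesion_id == "lung_1",
       c(recon_id, suv_max, cnr, activity_recovery))
#>    recon_id suv_max    cnr activity_recovery
#>  nonprc_6mm   1.728 10.851              33.8
#>      ti_6mm   1.978 18.804              40.1
#>    tdsv_6mm   2.406 35.963              50.8
#>    tdsv_4mm   3.485 45.903              64.7
```

For this 16:1 lesion deep in lung, both corrections raise SUVmax, CNR and
activity recovery relative to the uncorrected reconstruction, the
tissue-dependent correction clearly beats the stationary water kernel
(which undercorrects lung), and the 4.0 mm post-filter variant recovers
the most signal. Contrast-to-noise improves under the tissue-dependent
correction for every one of the seven lesions. `res$noise` holds the
half-split noise SDs — at a matched 6.0 mm filter the tissue-dependent
correction lowers lung noise (0.185 vs 0.286 here) and the 4.0 mm filter
brings it back toward the uncorrected level (0.227) — and `res$stats` the
Wilcoxon/Bonferroni percentage-change tables.

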