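#' Experiment configuration for the artificial-lesion study
#'
#' Collects every knob of the end-to-end synthetic study: phantom grid,
#' scanner geometry, counts budget, kernel generation, reconstruction
#' variants and the noise (half-split) variants. Defaults are the
#' desk-scale study conditions: a 96 x 96 x 32 torso at the PET voxel size
#' 2.73 x 2.73 x 2.80 mm, 120 angles in 10 subsets, 24 OSEM iterations,
#' 5e6 total counts, kernels from 2e5 simulated decays sized with the
#' per-tissue maximum-range preset, and the four reconstruction variants
#' (no PRC at 6.0 mm filter, tissue-independent at 6.0 mm, tissue-dependent
#' at 6.0 mm and at 4.0 mm).
#'
#' @param master_seed Master RNG seed; all stage seeds derive from it by
#'   fixed offsets.
#' @param shape,voxel_size Phantom/image grid.
#' @param n_angles,n_subsets,n_iterations Projection and OSEM settings.
#' @param total_counts Expected counts in the full acquisition.
#' @param kernel_decays Monte Carlo decays per kernel.
#' @param psf_fwhm Detector PSF FWHM in mm.
#' @param variants Data frame with columns `prc` and `filter_fwhm` defining
#'   the reconstruction variants.
#' @param noise_prc Character vector of prc modes reconstructed from
#'   half-split data for the noise comparison.
#' @param out_dir Optional output directory for CSVs, volumes and manifest.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(master_seed = 20230101L,
                              shape = c(96L, 96L, 32L),
                              voxel_size = c(2.73, 2.73, 2.80),
                              n_angles = 120L, n_subsets = 10L,
                              n_iterations = 24L,
                              total_counts = 5e6,
                              kernel_decays = 2e5,
                              psf_fwhm = 4.5,
                              variants = default_variants(),
                              noise_prc = c("none", "tdsv"),
                              out_dir = NULL) {
  stopifnot(nrow(variants) >= 1L,
            all(c("prc", "filter_fwhm") %in% names(variants)))
  structure(
    list(master_seed = as.integer(master_seed),
         shape = as.integer(rep_len(shape, 3L)),
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         n_angles = as.integer(n_angles), n_subsets = as.integer(n_subsets),
         n_iterations = as.integer(n_iterations),
         total_counts = as.numeric(total_counts),
         kernel_decays = as.numeric(kernel_decays),
         psf_fwhm = as.numeric(psf_fwhm),
         variants = variants, noise_prc = noise_prc, out_dir = out_dir),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @export
default_variants <- function() {
  data.frame(prc = c("none", "tissue_independent", "tdsv", "tdsv"),
             filter_fwhm = c(6.0, 6.0, 6.0, 4.0),
             stringsAsFactors = FALSE)
}

variant_id <- function(prc, fwhm) {
  short <- c(none = "nonprc", tissue_independent = "ti", tdsv = "tdsv")[prc]
  sprintf("%s_%gmm", short, fwhm)
}

#' Run the end-to-end artificial-lesion experiment
#'
#' Pipeline: positron-range kernels -> torso phantom -> seven-lesion set ->
#' lesion rasterization (CT and masks updated) -> Poisson acquisition with
#' ground-truth positron range -> sinogram-domain lesion insertion -> OSEM
#' reconstruction of every variant -> post-filtering -> per-lesion metrics
#' (SUVmax, CNR, activity recovery) -> half-split noise SDs in liver and
#' lung -> paired percentage-change statistics. Deterministic under
#' `master_seed`.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print stage progress (default TRUE).
#' @return List with `measurements` (tibble, one row per lesion x variant),
#'   `noise` (tibble of half-split SDs per region x variant), `stats`
#'   (paired percentage-change tables for SUVmax and CNR), `lesions`,
#'   `kernels`, `phantom`, `images` (named list of filtered
#'   reconstructions), `manifest`.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  ms <- cfg$master_seed
  t_start <- Sys.time()

  say("[1/8] kernels (%g decays each)", cfg$kernel_decays)
  kernels <- make_kernel_set(voxel_size = cfg$voxel_size,
                             n_decays = cfg$kernel_decays, seed = ms + 11L)

  say("[2/8] torso phantom %s", paste(cfg$shape, collapse = "x"))
  phantom <- make_torso_phantom(cfg$shape, cfg$voxel_size, seed = ms + 23L)
  lesions <- table1_lesion_set(phantom)

  say("[3/8] rasterizing %d lesions", length(lesions))
  ct <- phantom$ct
  lesion_vols <- list()
  true_act <- numeric(0)
  for (nm in names(lesions)) {
    rl <- rasterize_lesion(lesions[[nm]], ct, phantom$activity)
    ct <- rl$ct
    lesion_vols[[nm]] <- rl$lesion_activity
    true_act[nm] <- rl$true_activity
  }
  masks <- classify_tissue(resample_ct_to_pet(ct, cfg$shape, cfg$voxel_size))
  mu <- make_mu_map(ct)

  say("[4/8] simulating acquisition (%g counts)", cfg$total_counts)
  geom <- scanner_geometry(
    n_angles = cfg$n_angles,
    n_radial = 2L * ceiling(sqrt(sum((cfg$shape[1:2] * cfg$voxel_size[1:2])^2)) /
                              (2 * cfg$voxel_size[1L])) + 1L,
    radial_pitch = cfg$voxel_size[1L], n_planes = cfg$shape[3L])
  gt_prc <- prc_operator("tdsv", kernels = kernels, masks = masks)
  gt_model <- system_model(geom, cfg$shape, cfg$voxel_size, mu_map = mu,
                           psf_fwhm = cfg$psf_fwhm, prc = gt_prc)
  sino <- simulate_acquisition(phantom$activity, ct, gt_model,
                               cfg$total_counts, seed = ms + 37L)
  for (i in seq_along(lesion_vols)) {
    sino <- insert_lesion_sinogram(sino, lesion_vols[[i]], gt_model,
                                   seed = ms + 41L + i)
  }
  halves <- split_half_acquisition(phantom$activity, ct, gt_model,
                                   cfg$total_counts, seed = ms + 53L)

  say("[5/8] reconstructing variants")
  rc <- recon_config(cfg$n_iterations, cfg$n_subsets,
                     voxel_size = cfg$voxel_size)
  prc_modes <- unique(cfg$variants$prc)
  recon_model <- function(mode) {
    op <- switch(mode,
                 none = prc_operator("none"),
                 tissue_independent = prc_operator("tissue_independent",
                                                   kernels["water"]),
                 tdsv = prc_operator("tdsv", kernels = kernels, masks = masks))
    system_model(geom, cfg$shape, cfg$voxel_size, mu_map = mu,
                 psf_fwhm = cfg$psf_fwhm, prc = op)
  }
  recon_raw <- list()
  for (mode in prc_modes) {
    say("      OSEM, prc = %s", mode)
    recon_raw[[mode]] <- osem_reconstruct(sino, recon_model(mode), rc)
    # back to activity-concentration units
    recon_raw[[mode]]$data <- recon_raw[[mode]]$data / sino$scale
  }
  images <- list()
  for (i in seq_len(nrow(cfg$variants))) {
    v <- cfg$variants[i, ]
    images[[variant_id(v$prc, v$filter_fwhm)]] <-
      gaussian_postfilter(recon_raw[[v$prc]], v$filter_fwhm)
  }

  say("[6/8] half-split reconstructions (%s)",
      paste(cfg$noise_prc, collapse = ", "))
  half_imgs <- list()
  for (mode in intersect(cfg$noise_prc, prc_modes)) {
    m <- recon_model(mode)
    h1 <- osem_reconstruct(halves$half1, m, rc)
    h2 <- osem_reconstruct(halves$half2, m, rc)
    h1$data <- h1$data / halves$half1$scale
    h2$data <- h2$data / halves$half2$scale
    half_imgs[[mode]] <- list(h1 = h1, h2 = h2)
  }

  say("[7/8] lesion metrics")
  ref_img <- images[[1L]]
  rows <- list()
  for (i in seq_len(nrow(cfg$variants))) {
    v <- cfg$variants[i, ]
    vid <- variant_id(v$prc, v$filter_fwhm)
    img <- images[[vid]]
    for (nm in names(lesions)) {
      lv <- spherical_voi(lesions[[nm]]$center, lesions[[nm]]$radius, img)
      bv <- background_voi(lv, img, masks)
      tissue <- c(soft_tissue_1 = "soft", soft_tissue_2 = "soft",
                  bone_1 = "bone", bone_2 = "bone",
                  lung_1 = "lung", lung_2 = "lung", lung_3 = "lung")[nm]
      if (is.na(tissue)) tissue <- "soft"
      rows[[paste(vid, nm)]] <- lesion_metrics(
        img, lv, bv, true_activity = true_act[[nm]],
        lesion_id = nm, tissue_class = unname(tissue),
        recon_id = vid, filter_fwhm = v$filter_fwhm)
    }
  }
  measurements <- do.call(rbind, rows)

  # half-split noise: 20 mm spheres restricted to the liver / lung regions,
  # measured on lesion-free half acquisitions
  noise_rows <- list()
  for (region in c("liver", "lung")) {
    lab <- phantom$region_names[[region]]
    idx <- which(phantom$regions == lab, arr.ind = TRUE)
    ctr <- (colMeans(idx) - 1) * cfg$voxel_size + phantom$ct$origin
    for (i in seq_len(nrow(cfg$variants))) {
      v <- cfg$variants[i, ]
      if (!v$prc %in% names(half_imgs)) next
      vid <- variant_id(v$prc, v$filter_fwhm)
      h1 <- gaussian_postfilter(half_imgs[[v$prc]]$h1, v$filter_fwhm)
      h2 <- gaussian_postfilter(half_imgs[[v$prc]]$h2, v$filter_fwhm)
      sv <- spherical_voi(ctr, 20, h1)
      sv$indices <- intersect(sv$indices, which(phantom$regions == lab))
      sv$volume_mm3 <- length(sv$indices) * prod(cfg$voxel_size)
      noise_rows[[paste(region, vid)]] <- tibble::tibble(
        region = region, recon_id = vid, filter_fwhm = v$filter_fwhm,
        sd = half_split_noise_sd(h1, h2, sv), n_voxels = length(sv$indices))
    }
  }
  noise <- do.call(rbind, noise_rows)

  say("[8/8] statistics")
  vids <- vapply(seq_len(nrow(cfg$variants)),
                 function(i) variant_id(cfg$variants$prc[i],
                                        cfg$variants$filter_fwhm[i]),
                 character(1))
  comparisons <- list()
  if (all(c("tdsv_6mm", "nonprc_6mm") %in% vids)) {
    comparisons <- c(comparisons, list(c("tdsv_6mm", "nonprc_6mm")))
  }
  if (all(c("ti_6mm", "nonprc_6mm") %in% vids)) {
    comparisons <- c(comparisons, list(c("ti_6mm", "nonprc_6mm")))
  }
  if (all(c("tdsv_6mm", "ti_6mm") %in% vids)) {
    comparisons <- c(comparisons, list(c("tdsv_6mm", "ti_6mm")))
  }
  if (all(c("tdsv_4mm", "nonprc_6mm") %in% vids)) {
    comparisons <- c(comparisons, list(c("tdsv_4mm", "nonprc_6mm")))
  }
  stats_tabs <- NULL
  if (length(comparisons) >= 1L && length(unique(measurements$recon_id)) > 1L) {
    stats_tabs <- list(
      suv_max = paired_change_table(measurements, "suv_max", comparisons),
      cnr = paired_change_table(measurements, "cnr", comparisons))
  } else {
    say("      single variant: statistics stage skipped")
  }

  manifest <- list(
    master_seed = ms,
    stage_seeds = list(kernels = ms + 11L, phantom = ms + 23L,
                       acquisition = ms + 37L,
                       lesions = ms + 41L + seq_along(lesions),
                       halves = ms + 53L),
    shape = cfg$shape, voxel_size = cfg$voxel_size,
    n_angles = cfg$n_angles, n_subsets = cfg$n_subsets,
    n_iterations = cfg$n_iterations, total_counts = cfg$total_counts,
    kernel_decays = cfg$kernel_decays, psf_fwhm = cfg$psf_fwhm,
    variants = cfg$variants,
    kernel_truncated_fraction =
      vapply(kernels, `[[`, numeric(1), "truncated_fraction"),
    true_activity = as.list(true_act),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  result <- list(measurements = measurements, noise = noise,
                 stats = stats_tabs, lesions = lesions, kernels = kernels,
                 phantom = phantom, masks = masks, images = images,
                 sinogram = sino, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_experiment(result, cfg$out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$measurements,
                   file.path(out_dir, "lesion_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(result$noise, file.path(out_dir, "half_split_noise.csv"),
                   row.names = FALSE)
  if (!is.null(result$stats)) {
    utils::write.csv(rbind(result$stats$suv_max, result$stats$cnr),
                     file.path(out_dir, "paired_statistics.csv"),
                     row.names = FALSE)
  }
  for (nm in names(result$images)) {
    write_volume(result$images[[nm]],
                 file.path(out_dir, paste0("recon_", nm, ".nii.gz")))
  }
  for (nm in names(result$kernels)) {
    write_kernel(result$kernels[[nm]], file.path(out_dir, paste0("kernel_", nm)))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
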