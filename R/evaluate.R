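#' Post-reconstruction Gaussian filter
#'
#' Isotropic 3D Gaussian smoothing with the stated FWHM:
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in mm, converted to voxels per
#' axis. `fwhm = 0` is the identity.
#'
#' @param img An `activity_volume` (or 3D array with `voxel_size` given).
#' @param fwhm Filter FWHM in mm (>= 0).
#' @param voxel_size Required when `img` is a bare array.
#' @return Same type as `img`.
#' @export
gaussian_postfilter <- function(img, fwhm, voxel_size = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (inherits(img, "gaprc_volume")) {
    vx <- img$voxel_size
    arr <- img$data
  } else {
    if (is.null(voxel_size)) stop("voxel_size needed for a bare array")
    vx <- rep_len(voxel_size, 3L)
    arr <- img
  }
  if (fwhm > 0) {
    arr <- separable_gaussian_blur(arr, fwhm_to_sigma(fwhm) / vx)
  }
  if (inherits(img, "gaprc_volume")) {
    out <- img
    out$data <- pmax(arr, 0)
    out
  } else arr
}

#' Spherical volume of interest
#'
#' All voxels whose centres lie within `radius` of `center` (world mm).
#'
#' @param center Length-3 world coordinate in mm.
#' @param radius Radius in mm.
#' @param vol A `gaprc_volume` defining the grid.
#' @return A `voi` object: list with `indices` (linear voxel indices),
#'   `kind`, `volume_mm3` (voxel-count volume) and provenance fields.
#' @export
spherical_voi <- function(center, radius, vol) {
  stopifnot(inherits(vol, "gaprc_volume"))
  ax <- grid_axes(vol)
  rng <- vapply(ax, range, numeric(2))
  if (any(center < rng[1, ] - vol$voxel_size) ||
      any(center > rng[2, ] + vol$voxel_size)) {
    stop("VOI centre lies outside the grid")
  }
  d2 <- outer((ax[[1L]] - center[1L])^2, (ax[[2L]] - center[2L])^2, "+")
  inside <- outer(d2, (ax[[3L]] - center[3L])^2, "+") <= radius^2
  idx <- which(inside)
  if (length(idx) == 0L) stop("VOI is empty (radius below half a voxel off-centre)")
  new_voi(idx, "sphere", vol,
          params = list(center = center, radius = radius))
}

new_voi <- function(idx, kind, vol, params = list()) {
  structure(
    list(indices = idx, kind = kind,
         volume_mm3 = length(idx) * prod(vol$voxel_size),
         grid_dim = dim(vol$data), voxel_size = vol$voxel_size,
         origin = vol$origin, params = params),
    class = "voi"
  )
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<%s VOI: %d voxels, %.1f mm^3>\n", x$kind,
              length(x$indices), x$volume_mm3))
  invisible(x)
}

#' 50% isocontour volume of interest
#'
#' Starting from a seed point, climbs to the local maximum, thresholds the
#' image at `threshold_fraction` of that maximum, and keeps the
#' 26-connected component containing the maximum. No background correction
#' is applied.
#'
#' @param img An `activity_volume`.
#' @param seed_point Length-3 world coordinate (mm) inside the lesion.
#' @param threshold_fraction Fraction of the maximum (default 0.5).
#' @return A `voi`.
#' @export
isocontour_voi <- function(img, seed_point, threshold_fraction = 0.5) {
  stopifnot(inherits(img, "gaprc_volume"))
  d <- dim(img$data)
  vox <- pmin(pmax(round((seed_point - img$origin) / img$voxel_size) + 1, 1), d)
  if (img$data[vox[1L], vox[2L], vox[3L]] <= 0) {
    stop("seed point is not inside a positive region")
  }
  # hill-climb to the local maximum
  cur <- vox
  repeat {
    nb <- neighborhood26(cur, d)
    vals <- img$data[nb]
    best <- nb[which.max(vals), , drop = FALSE]
    if (img$data[best] <= img$data[cur[1L], cur[2L], cur[3L]]) break
    cur <- as.integer(best)
  }
  peak <- img$data[cur[1L], cur[2L], cur[3L]]
  thr <- threshold_fraction * peak
  above <- img$data >= thr
  comp <- flood_fill26(above, cur)
  new_voi(which(comp), "isocontour", img,
          params = list(seed_point = seed_point, peak = peak,
                        threshold_fraction = threshold_fraction))
}

neighborhood26 <- function(v, d) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- sweep(off, 2L, v, "+")
  ok <- nb[, 1L] >= 1 & nb[, 1L] <= d[1L] &
    nb[, 2L] >= 1 & nb[, 2L] <= d[2L] &
    nb[, 3L] >= 1 & nb[, 3L] <= d[3L]
  nb[ok, , drop = FALSE]
}

flood_fill26 <- function(mask, start) {
  d <- dim(mask)
  comp <- array(FALSE, d)
  lin <- function(v) v[, 1L] + (v[, 2L] - 1L) * d[1L] + (v[, 3L] - 1L) * d[1L] * d[2L]
  frontier <- matrix(start, 1L)
  comp[lin(frontier)] <- TRUE
  while (nrow(frontier) > 0L) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(frontier)), function(i) {
      neighborhood26(frontier[i, ], d)
    }))
    nxt <- unique(nxt)
    li <- lin(nxt)
    keep <- mask[li] & !comp[li]
    frontier <- nxt[keep, , drop = FALSE]
    if (nrow(frontier) > 0L) comp[lin(frontier)] <- TRUE
  }
  comp
}

#' Background volume of interest near a lesion
#'
#' A shell of host-tissue voxels around the lesion VOI: voxels farther than
#' `min_distance` from every lesion-VOI voxel centre, collected
#' nearest-first until at least `min_volume` is reached.
#'
#' @param lesion_voi The lesion `voi`.
#' @param img An `activity_volume` on the same grid.
#' @param masks Optional `tissue_masks`; when given, background voxels are
#'   restricted to the host tissue class: the majority class of the voxels
#'   immediately surrounding the lesion VOI (the lesion's own class can
#'   differ from its surroundings, e.g. a soft-tissue nodule in lung).
#' @param min_volume Minimum background volume in mm^3 (default 10).
#' @param min_distance Minimum distance from the lesion VOI in mm
#'   (default 5.0).
#' @return A `voi`.
#' @export
background_voi <- function(lesion_voi, img, masks = NULL,
                           min_volume = 10, min_distance = 5.0) {
  stopifnot(inherits(lesion_voi, "voi"), inherits(img, "gaprc_volume"))
  d <- dim(img$data)
  vx <- img$voxel_size
  les <- arrayInd(lesion_voi$indices, d)
  les_mm <- sweep(sweep(les - 1, 2L, vx, "*"), 2L, img$origin, "+")
  ctr <- colMeans(les_mm)
  # candidates: voxels within a generous search radius of the lesion centre
  les_r <- sqrt(max(rowSums(sweep(les_mm, 2L, ctr)^2)))
  search_r <- max(les_r, 1) + min_distance + 6 * max(vx)
  ax <- grid_axes(img)
  d2 <- outer((ax[[1L]] - ctr[1L])^2, (ax[[2L]] - ctr[2L])^2, "+")
  near <- which(outer(d2, (ax[[3L]] - ctr[3L])^2, "+") <= search_r^2)
  near <- setdiff(near, lesion_voi$indices)
  if (!is.null(masks)) {
    # host class: majority over the ring just outside the lesion VOI
    ring_mm <- sweep(sweep(arrayInd(near, d) - 1, 2L, vx, "*"), 2L,
                     img$origin, "+")
    ring_d <- apply(ring_mm, 1L, function(p) {
      sqrt(min(rowSums(sweep(les_mm, 2L, p)^2)))
    })
    ring <- near[ring_d <= 2 * max(vx)]
    if (length(ring) == 0L) ring <- near
    tissue <- as.integer(names(which.max(table(masks$labels[ring]))))
    near <- near[masks$labels[near] == tissue]
  }
  cand <- arrayInd(near, d)
  cand_mm <- sweep(sweep(cand - 1, 2L, vx, "*"), 2L, img$origin, "+")
  # distance to the nearest lesion voxel centre
  mind <- apply(cand_mm, 1L, function(p) {
    sqrt(min(rowSums(sweep(les_mm, 2L, p)^2)))
  })
  ok <- mind > min_distance
  near <- near[ok]; mind <- mind[ok]
  if (length(near) == 0L) stop("no background voxels available")
  o <- order(mind)
  vox_vol <- prod(vx)
  n_needed <- max(ceiling(min_volume / vox_vol), 2L)
  n_take <- min(max(n_needed, 32L), length(near))  # a stable-SD shell
  new_voi(near[o[seq_len(n_take)]], "background-shell", img,
          params = list(min_volume = min_volume, min_distance = min_distance))
}

#' Lesion quantification
#'
#' Computes the maximum VOI value (SUVmax in activity-concentration units
#' unless a SUV scale factor is supplied), the lesion and background means,
#' the background SD, the contrast-to-noise ratio
#' `CNR = (mean_lesion - mean_background) / sd_background`, and — when the
#' true inserted activity is known — the activity recovery
#' `100 * mean_lesion / true_activity` (%).
#'
#' @param img An `activity_volume`.
#' @param lesion_voi Lesion `voi`.
#' @param bg_voi Background `voi`.
#' @param true_activity Optional true inserted activity concentration.
#' @param suv_scale Optional factor converting concentration to SUV
#'   (body weight / injected dose); default 1 (concentration units).
#' @param lesion_id,tissue_class,recon_id,filter_fwhm Provenance fields.
#' @return A one-row tibble (`lesion_measurement`).
#' @export
lesion_metrics <- function(img, lesion_voi, bg_voi, true_activity = NULL,
                           suv_scale = 1, lesion_id = NA_character_,
                           tissue_class = NA_character_,
                           recon_id = NA_character_, filter_fwhm = NA_real_) {
  stopifnot(inherits(img, "gaprc_volume"),
            inherits(lesion_voi, "voi"), inherits(bg_voi, "voi"))
  lv <- img$data[lesion_voi$indices]
  bv <- img$data[bg_voi$indices]
  if (length(bv) < 2L) stop("background VOI must contain at least 2 voxels")
  mean_l <- mean(lv); mean_b <- mean(bv); sd_b <- stats::sd(bv)
  cnr <- (mean_l - mean_b) / sd_b
  rec <- if (!is.null(true_activity)) 100 * mean_l / true_activity else NA_real_
  tibble::tibble(
    lesion_id = lesion_id, tissue_class = tissue_class, recon_id = recon_id,
    filter_fwhm = filter_fwhm,
    suv_max = max(lv) * suv_scale,
    mean_lesion = mean_l, mean_background = mean_b, sd_background = sd_b,
    cnr = cnr, activity_recovery = rec,
    volume_cm3 = lesion_voi$volume_mm3 / 1000,
    n_voxels = length(lesion_voi$indices)
  )
}

#' Half-split noise standard deviation
#'
#' SD of the voxel-wise difference of two half-duration reconstructions
#' within a VOI; subtracting the halves removes spatial uptake
#' inhomogeneity so the SD reflects noise alone. No sqrt(2) correction is
#' applied (values are only compared across reconstructions).
#'
#' @param recon_half1,recon_half2 `activity_volume`s on the same grid.
#' @param voi A `voi` with at least 2 voxels.
#' @return The SD of the difference image over the VOI.
#' @export
half_split_noise_sd <- function(recon_half1, recon_half2, voi) {
  stopifnot(inherits(voi, "voi"))
  if (!same_grid(recon_half1, recon_half2)) stop("half reconstructions differ in grid")
  if (length(voi$indices) < 2L) stop("VOI must contain at least 2 voxels")
  diff <- recon_half1$data[voi$indices] - recon_half2$data[voi$indices]
  stats::sd(diff)
}

#' Apply the lesion inclusion rules
#'
#' Drops lesions with volume above `max_volume_cm3` (default 10 cm^3) and
#' keeps at most the `max_per_tissue` largest remaining lesions per
#' (patient, tissue class).
#'
#' @param measurements Tibble of lesion measurements (needs columns
#'   `volume_cm3`, `tissue_class`, and optionally `patient_id`).
#' @param max_volume_cm3 Volume cutoff in cm^3 (default 10).
#' @param max_per_tissue Maximum lesions kept per tissue class per patient
#'   (default 5).
#' @return Filtered tibble.
#' @export
filter_lesions <- function(measurements, max_volume_cm3 = 10,
                           max_per_tissue = 5L) {
  if (nrow(measurements) == 0L) return(measurements)
  m <- measurements[measurements$volume_cm3 <= max_volume_cm3, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  pid <- if ("patient_id" %in% names(m)) m$patient_id else rep("p1", nrow(m))
  keep <- unlist(lapply(split(seq_len(nrow(m)),
                              interaction(pid, m$tissue_class, drop = TRUE)),
                        function(ix) {
    o <- ix[order(m$volume_cm3[ix], decreasing = TRUE)]
    o[seq_len(min(max_per_tissue, length(o)))]
  }))
  m[sort(keep), , drop = FALSE]
}
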