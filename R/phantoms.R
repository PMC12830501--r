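#' Synthetic torso phantom
#'
#' Builds co-registered CT (HU) and activity volumes for a simplified torso:
#' an elliptical soft-tissue body, two lung fields, a spine analog
#' (posterior bone cylinder), and a liver sub-region in the lower right
#' body. Background activity is soft tissue 1.0 (arbitrary concentration
#' units), liver 3.0 (high uptake), lung 0.2 (low uptake), bone 0.5, with a
#' mild (+/-10%) smooth multiplicative inhomogeneity field so that
#' half-split noise measurements have realistic structure to cancel.
#'
#' Region labels: 0 air, 1 soft tissue, 2 lung, 3 bone, 4 liver (liver is
#' soft tissue for segmentation purposes; its HU is in the soft-tissue
#' band).
#'
#' @param shape Integer length-3 grid dimensions
#'   (default `c(128, 128, 96)`).
#' @param voxel_size Length-3 voxel size in mm
#'   (default `c(2.73, 2.73, 2.80)`).
#' @param seed RNG seed for the HU texture and activity inhomogeneity.
#' @return List with `ct` (ct_volume), `activity` (activity_volume),
#'   `regions` (3D integer array of labels), `region_names`, and
#'   `activity_levels` (named vector of the mean activity per region).
#' @export
make_torso_phantom <- function(shape = c(128L, 128L, 96L),
                               voxel_size = c(2.73, 2.73, 2.80),
                               seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(shape[1:2] < 16L) || shape[3L] < 1L) {
    stop("grid too small to contain the torso compartments")
  }
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  # voxel-centre coordinates normalized to [-1, 1] per axis
  xs <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  ys <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  zs <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  X <- array(rep(xs, times = ny * nz), dim = shape)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = shape)
  Z <- array(rep(zs, each = nx * ny), dim = shape)

  regions <- array(0L, dim = shape)
  body <- (X / 0.86)^2 + (Y / 0.72)^2 <= 1
  regions[body] <- 1L

  # two large lung fields, upper two thirds of the z-extent, anterior of
  # the spine; sized so a 5 mm lesion at the centroid is surrounded by
  # several centimetres of lung in every direction
  lung_l <- ((X + 0.40) / 0.30)^2 + ((Y + 0.08) / 0.40)^2 +
    ((Z - 0.30) / 0.80)^2 <= 1
  lung_r <- ((X - 0.40) / 0.30)^2 + ((Y + 0.08) / 0.40)^2 +
    ((Z - 0.30) / 0.80)^2 <= 1
  regions[(lung_l | lung_r) & body] <- 2L

  # liver: ellipsoid, right side, below the right lung
  liver <- ((X - 0.30) / 0.36)^2 + ((Y + 0.05) / 0.38)^2 +
    ((Z + 0.35) / 0.48)^2 <= 1
  regions[liver & body & regions != 2L] <- 4L

  # spine: posterior cylinder through all planes (overrides liver overlap)
  spine <- (X / 0.10)^2 + ((Y - 0.52) / 0.10)^2 <= 1
  regions[spine & body] <- 3L

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  hu_mean <- c(`0` = -1000, `1` = 30, `2` = -700, `3` = 1200, `4` = 45)
  hu_sd   <- c(`0` = 0,     `1` = 15, `2` = 30,   `3` = 60,   `4` = 10)
  lab <- as.character(regions)
  hu <- hu_mean[lab] + stats::rnorm(length(regions)) * hu_sd[lab]
  hu <- array(hu, dim = shape)

  act_level <- c(`0` = 0, `1` = 1.0, `2` = 0.2, `3` = 0.5, `4` = 3.0)
  act <- array(act_level[lab], dim = shape)
  # smooth +/-10% multiplicative inhomogeneity
  field <- array(stats::rnorm(length(regions)), dim = shape)
  field <- separable_gaussian_blur(field, sigma_vox = rep(4, 3))
  field <- field / max(stats::sd(field), 1e-12)
  act <- act * (1 + 0.1 * pmax(pmin(field, 2), -2) / 2)
  act[regions == 0L] <- 0

  origin <- -(shape - 1) / 2 * voxel_size  # centred world coordinates
  list(
    ct = ct_volume(hu, voxel_size, origin),
    activity = activity_volume(act, voxel_size, origin),
    regions = regions,
    region_names = c(air = 0L, soft = 1L, lung = 2L, bone = 3L, liver = 4L),
    activity_levels = c(air = 0, soft = 1.0, lung = 0.2, bone = 0.5, liver = 3.0)
  )
}

#' Lesion specification
#'
#' A spherical lesion: its own tissue type (controls the HU written into the
#' CT, hence the tissue masks), the host region it sits in, centre (mm,
#' world coordinates), radius (mm; default 5.0) and lesion-to-background
#' activity ratio.
#'
#' @param name Lesion label.
#' @param lesion_tissue `"water"`, `"bone"` or `"lung"` — the lesion's own
#'   material.
#' @param host_region Host compartment label (informational).
#' @param center Length-3 world coordinate in mm.
#' @param radius Radius in mm (> 0), default 5.0.
#' @param activity_ratio Lesion-to-background activity ratio (> 0).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(name, lesion_tissue, host_region, center,
                        radius = 5.0, activity_ratio) {
  if (radius <= 0) stop("radius must be > 0")
  if (activity_ratio <= 0) stop("activity_ratio must be > 0")
  structure(
    list(name = name, lesion_tissue = lesion_tissue,
         host_region = host_region, center = rep_len(as.numeric(center), 3L),
         radius = as.numeric(radius),
         activity_ratio = as.numeric(activity_ratio)),
    class = "lesion_spec"
  )
}

#' The seven-lesion study set
#'
#' Places the seven spherical lesions of the artificial-lesion study design
#' in a torso phantom: two soft-tissue lesions (in high-uptake liver at 3:1
#' and in low-uptake soft tissue at 16:1), a bone lesion and a soft-tissue
#' lesion inside bone (both 16:1), and three lung-associated lesions (soft
#' tissue inside lung at 16:1, at the lung–liver boundary at 10:1, and
#' inside lung at 3:1). All radii are 5.0 mm. Centres are chosen
#' deterministically inside the requested host compartments, at least 30 mm
#' apart.
#'
#' @param phantom Output of [make_torso_phantom()].
#' @return List of 7 [lesion_spec()] objects, named
#'   `soft_tissue_1, soft_tissue_2, bone_1, bone_2, lung_1, lung_2, lung_3`.
#' @export
table1_lesion_set <- function(phantom) {
  reg <- phantom$regions
  vx <- phantom$ct$voxel_size
  org <- phantom$ct$origin

  centroid <- function(label, zshift = 0, xshift = 0, yshift = 0) {
    idx <- which(reg == label, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("phantom lacks required host region ", label)
    ctr <- colMeans(idx)
    ((ctr - 1) + c(xshift, yshift, zshift)) * vx + org
  }
  d <- dim(reg)

  # right-lung centroid (x above mid-plane)
  lung_idx <- which(reg == 2L, arr.ind = TRUE)
  right <- lung_idx[lung_idx[, 1L] > d[1L] / 2, , drop = FALSE]
  left  <- lung_idx[lung_idx[, 1L] <= d[1L] / 2, , drop = FALSE]
  rl <- (colMeans(right) - 1) * vx + org
  ll <- (colMeans(left) - 1) * vx + org
  liver_c <- centroid(4L)
  bone_idx <- which(reg == 3L, arr.ind = TRUE)
  bone_top <- bone_idx[bone_idx[, 3L] > 0.65 * d[3L], , drop = FALSE]
  bone_bot <- bone_idx[bone_idx[, 3L] < 0.35 * d[3L], , drop = FALSE]
  bone_c1 <- (colMeans(bone_top) - 1) * vx + org
  bone_c2 <- (colMeans(bone_bot) - 1) * vx + org

  # soft-tissue (non-liver) location: anterior midline, lower half
  soft_idx <- which(reg == 1L, arr.ind = TRUE)
  sl <- soft_idx[soft_idx[, 2L] < 0.35 * d[2L] & soft_idx[, 3L] < 0.4 * d[3L], ,
                 drop = FALSE]
  soft_c <- (colMeans(sl) - 1) * vx + org

  # lung-liver boundary: between right lung and liver along z
  boundary_c <- (rl + liver_c) / 2
  boundary_c[1:2] <- liver_c[1:2]

  lesions <- list(
    soft_tissue_1 = lesion_spec("soft_tissue_1", "water", "liver",
                                liver_c + c(-18, -12, -12), 5.0, 3),
    soft_tissue_2 = lesion_spec("soft_tissue_2", "water", "soft tissue",
                                soft_c, 5.0, 16),
    bone_1 = lesion_spec("bone_1", "bone", "bone", bone_c1, 5.0, 16),
    bone_2 = lesion_spec("bone_2", "water", "bone", bone_c2, 5.0, 16),
    lung_1 = lesion_spec("lung_1", "water", "lung", rl + c(0, 0, 16), 5.0, 16),
    lung_2 = lesion_spec("lung_2", "water", "lung-liver boundary",
                         boundary_c, 5.0, 10),
    lung_3 = lesion_spec("lung_3", "water", "lung", ll, 5.0, 3)
  )
  check_lesion_spacing(lesions, min_distance = 30)
  lesions
}

check_lesion_spacing <- function(lesions, min_distance = 30) {
  ctrs <- do.call(rbind, lapply(lesions, `[[`, "center"))
  n <- nrow(ctrs)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dd <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
      if (dd < min_distance) {
        warning(sprintf("lesions %s and %s are %.1f mm apart (< %.0f mm)",
                        names(lesions)[i], names(lesions)[j], dd, min_distance))
      }
    }
  }
  invisible(lesions)
}

#' Rasterize a lesion into CT and activity volumes
#'
#' Voxels whose centres fall inside the lesion sphere receive the lesion
#' activity (`activity_ratio` times the mean pre-insertion activity of those
#' voxels) in a lesion-only activity volume, and the CT HU there is replaced
#' by the lesion tissue's reference HU, so that tissue masks segmented from
#' the updated CT reflect the lesion. Edge voxels are handled by binary
#' centre-inclusion (homogeneous lesion, no partial-volume weighting).
#'
#' @param lesion A [lesion_spec()].
#' @param ct The phantom `ct_volume`.
#' @param act The phantom background `activity_volume`.
#' @param materials Named list of materials providing reference HUs.
#' @return List with `lesion_activity` (lesion-only `activity_volume`),
#'   `ct` (updated `ct_volume`), `true_activity` (inserted concentration),
#'   `voxels` (linear indices inside the sphere).
#' @export
rasterize_lesion <- function(lesion, ct, act,
                             materials = default_materials()) {
  stopifnot(inherits(lesion, "lesion_spec"), inherits(ct, "ct_volume"),
            inherits(act, "activity_volume"))
  if (!same_grid(ct, act)) stop("CT and activity grids differ")
  ax <- grid_axes(ct)
  dx2 <- outer((ax[[1L]] - lesion$center[1L])^2,
               (ax[[2L]] - lesion$center[2L])^2, "+")
  inside <- outer(dx2, (ax[[3L]] - lesion$center[3L])^2, "+") <=
    lesion$radius^2
  idx <- which(inside)
  if (length(idx) == 0L) stop("lesion contains no voxel centres")
  bg <- act$data[idx]
  if (all(bg <= 0)) stop("lesion lies fully outside the body (zero background)")
  true_activity <- lesion$activity_ratio * mean(bg)
  les <- array(0, dim = dim(act$data))
  les[idx] <- true_activity
  hu_ref <- materials[[lesion$lesion_tissue]]$hu_ref
  if (is.null(hu_ref)) stop("unknown lesion tissue ", lesion$lesion_tissue)
  ct2 <- ct
  ct2$data[idx] <- hu_ref
  list(lesion_activity = activity_volume(les, act$voxel_size, act$origin),
       ct = ct2, true_activity = true_activity, voxels = idx)
}
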