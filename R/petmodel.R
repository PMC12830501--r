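#' Scanner geometry for the parallel-beam multi-slice model
#'
#' Projection angles are spread uniformly over 180 degrees; radial bins are
#' centred on the image. Axial planes are treated as independent
#' (stacked-2D acquisition).
#'
#' @param n_angles Number of projection angles over 180 degrees.
#' @param n_radial Number of radial bins.
#' @param radial_pitch Radial bin width in mm.
#' @param n_planes Number of axial planes.
#' @return A `scanner_geometry` object.
#' @export
scanner_geometry <- function(n_angles = 180L, n_radial = 129L,
                             radial_pitch = 2.73, n_planes = 1L) {
  stopifnot(n_angles >= 1, n_radial >= 1, radial_pitch > 0, n_planes >= 1)
  structure(
    list(n_angles = as.integer(n_angles), n_radial = as.integer(n_radial),
         radial_pitch = as.numeric(radial_pitch),
         n_planes = as.integer(n_planes)),
    class = "scanner_geometry"
  )
}

#' Sinogram container
#'
#' @param counts 3D array `[angle, radial, plane]` of expected or observed
#'   counts (non-negative; observed counts are integers).
#' @param geometry A [scanner_geometry()].
#' @param is_noisy Logical; `TRUE` for Poisson-sampled data.
#' @param duration_s Nominal acquisition duration (bookkeeping only).
#' @param scale Counts per unit of (activity concentration x voxel volume);
#'   set by [simulate_acquisition()] and reused by lesion insertion.
#' @return A `sinogram` object.
#' @export
sinogram <- function(counts, geometry, is_noisy = FALSE, duration_s = NA_real_,
                     scale = 1) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  d <- dim(counts)
  if (length(d) != 3L ||
      !identical(as.integer(d),
                 c(geometry$n_angles, geometry$n_radial, geometry$n_planes))) {
    stop("counts must be [n_angles, n_radial, n_planes]")
  }
  # observed data must be non-negative; noiseless expectations may carry
  # signed values when the linear projector is applied to signed test images
  if (isTRUE(is_noisy) && any(counts < 0)) {
    stop("observed sinogram counts must be >= 0")
  }
  structure(
    list(counts = counts, geometry = geometry, is_noisy = isTRUE(is_noisy),
         duration_s = duration_s, scale = scale),
    class = "sinogram"
  )
}

#' @export
print.sinogram <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<sinogram %d angles x %d radial x %d planes, %s, total %.4g counts>\n",
              g$n_angles, g$n_radial, g$n_planes,
              if (x$is_noisy) "noisy" else "noiseless", sum(x$counts)))
  invisible(x)
}

#' Convert a CT volume to a 511 keV attenuation map
#'
#' Piecewise-linear HU-to-mu conversion anchored at air (HU -1000, mu 0) and
#' water (HU 0, mu 0.0096 per mm), with a flatter slope above HU 0
#' (`mu = mu_w * (1 + HU / 2000)`) reflecting the higher Z of bone mineral at
#' 511 keV; clipped at 0.
#'
#' @param ct A `ct_volume` on the image grid.
#' @param mu_water Water attenuation at 511 keV in mm^-1 (default 0.0096).
#' @return 3D array of mu values (mm^-1) with the same dimensions as the CT.
#' @export
make_mu_map <- function(ct, mu_water = 0.0096) {
  stopifnot(inherits(ct, "ct_volume"))
  hu <- ct$data
  mu <- ifelse(hu <= 0,
               mu_water * (hu + 1000) / 1000,
               mu_water * (1 + hu / 2000))
  pmax(mu, 0)
}

#' PET system model
#'
#' Combines the geometry, the image grid, an optional attenuation map, an
#' isotropic Gaussian detector PSF and an optional positron-range-correction
#' operator into a matched forward/backward projector pair. The geometric
#' projector is a voxel-driven parallel-beam operator with linear radial
#' interpolation, precomputed as a sparse matrix shared by all planes.
#'
#' @param geometry A [scanner_geometry()]; `n_planes` must equal the image
#'   z-dimension.
#' @param shape Integer length-3 image dimensions.
#' @param voxel_size Length-3 voxel size in mm.
#' @param mu_map Optional 3D array of attenuation (mm^-1) on the image grid.
#' @param psf_fwhm Detector PSF FWHM in mm (0 disables; default 4.5).
#' @param prc A `prc_operator` (default: none).
#' @param origin Image origin (mm); default centred grid.
#' @return A `system_model` object.
#' @export
system_model <- function(geometry, shape, voxel_size, mu_map = NULL,
                         psf_fwhm = 4.5, prc = prc_operator("none"),
                         origin = NULL) {
  stopifnot(inherits(geometry, "scanner_geometry"),
            inherits(prc, "prc_operator"), psf_fwhm >= 0)
  shape <- as.integer(rep_len(shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (geometry$n_planes != shape[3L]) {
    stop("geometry n_planes must match the image z-dimension")
  }
  if (!is.null(mu_map) && !identical(as.integer(dim(mu_map)), shape)) {
    stop("mu_map grid does not match the image grid")
  }
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size

  A <- build_projection_matrix(geometry, shape, voxel_size)
  af <- attenuation_factors(A, geometry, shape, voxel_size, mu_map)
  structure(
    list(geometry = geometry, shape = shape, voxel_size = voxel_size,
         origin = origin, mu_map = mu_map, psf_fwhm = as.numeric(psf_fwhm),
         prc = prc, A = A, atten = af, cache = new.env(parent = emptyenv())),
    class = "system_model"
  )
}

# sparse [n_angles*n_radial x nx*ny] voxel-driven projector; row index
# (j_angle - 1) * n_radial + i_radial; includes the voxel-volume factor so
# that a voxel of activity a contributes a * voxel_volume_mL per angle.
build_projection_matrix <- function(geom, shape, voxel_size) {
  nx <- shape[1L]; ny <- shape[2L]
  dx <- voxel_size[1L]; dy <- voxel_size[2L]
  vol_ml <- prod(voxel_size) / 1000
  x <- (seq_len(nx) - (nx + 1) / 2) * dx
  y <- (seq_len(ny) - (ny + 1) / 2) * dy
  X <- rep(x, times = ny)
  Y <- rep(y, each = nx)
  nv <- nx * ny
  th <- (seq_len(geom$n_angles) - 1L) * pi / geom$n_angles
  ii <- jj <- xx <- vector("list", geom$n_angles)
  ctr <- (geom$n_radial + 1) / 2
  for (j in seq_len(geom$n_angles)) {
    s <- X * cos(th[j]) + Y * sin(th[j])
    u <- s / geom$radial_pitch + ctr
    i0 <- floor(u)
    fr <- u - i0
    v <- seq_len(nv)
    keep0 <- i0 >= 1 & i0 <= geom$n_radial
    keep1 <- (i0 + 1) >= 1 & (i0 + 1) <= geom$n_radial
    ii[[j]] <- c((j - 1L) * geom$n_radial + i0[keep0],
                 (j - 1L) * geom$n_radial + i0[keep1] + 1L)
    jj[[j]] <- c(v[keep0], v[keep1])
    xx[[j]] <- c((1 - fr[keep0]) * vol_ml, fr[keep1] * vol_ml)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(geom$n_angles * geom$n_radial, nv))
}

# attenuation factor exp(-line integral of mu) per sinogram bin and plane
attenuation_factors <- function(A, geom, shape, voxel_size, mu_map) {
  nb <- geom$n_angles * geom$n_radial
  if (is.null(mu_map)) {
    return(matrix(1, nb, shape[3L]))
  }
  # the projector carries a voxel-volume (mL) factor; a ray's line integral
  # (mm) of mu is (A mu) * dx*dy / (pitch * vol_mL)
  geom_fac <- voxel_size[1L] * voxel_size[2L] /
    (geom$radial_pitch * prod(voxel_size) / 1000)
  af <- matrix(0, nb, shape[3L])
  for (p in seq_len(shape[3L])) {
    li <- as.numeric(A %*% as.vector(mu_map[, , p])) * geom_fac
    af[, p] <- exp(-li)
  }
  af
}

# image-space model blur: PRC then detector PSF (forward order)
model_blur_forward <- function(arr, model) {
  arr <- apply_prc_arr(arr, model$prc, adjoint = FALSE)
  if (model$psf_fwhm > 0) {
    sig <- fwhm_to_sigma(model$psf_fwhm) / model$voxel_size
    if (dim(arr)[3L] == 1L) sig[3L] <- 0
    arr <- separable_gaussian_blur(arr, sig)
  }
  arr
}

# adjoint: PSF (self-adjoint) then PRC adjoint
model_blur_adjoint <- function(arr, model) {
  if (model$psf_fwhm > 0) {
    sig <- fwhm_to_sigma(model$psf_fwhm) / model$voxel_size
    if (dim(arr)[3L] == 1L) sig[3L] <- 0
    arr <- separable_gaussian_blur(arr, sig)
  }
  apply_prc_arr(arr, model$prc, adjoint = TRUE)
}

apply_prc_arr <- function(arr, op, adjoint = FALSE) {
  if (op$mode == "none") return(arr)
  if (adjoint) apply_adjoint(arr, op) else apply_prc(arr, op)
}

#' Forward projection
#'
#' Applies the configured range correction and detector PSF in image space,
#' then computes attenuated parallel-beam line integrals plane by plane.
#' Linear in the image.
#'
#' @param img An `activity_volume` or 3D array on the model grid.
#' @param model A [system_model()].
#' @param subset_rows Optional integer vector of sinogram row indices
#'   (angle-subset support for OSEM); default all rows.
#' @return A `sinogram` of expected counts (a bare matrix when
#'   `subset_rows` is given).
#' @export
forward_project <- function(img, model, subset_rows = NULL) {
  arr <- if (inherits(img, "gaprc_volume")) img$data else img
  if (!identical(as.integer(dim(arr)), model$shape)) {
    stop("image grid does not match the system model")
  }
  arr <- model_blur_forward(arr, model)
  g <- model$geometry
  A <- if (is.null(subset_rows)) model$A else model$A[subset_rows, , drop = FALSE]
  af <- if (is.null(subset_rows)) model$atten else
    model$atten[subset_rows, , drop = FALSE]
  nb <- nrow(A)
  y <- matrix(0, nb, g$n_planes)
  for (p in seq_len(g$n_planes)) {
    y[, p] <- as.numeric(A %*% as.vector(arr[, , p])) * af[, p]
  }
  if (!is.null(subset_rows)) return(y)
  counts <- array(0, c(g$n_angles, g$n_radial, g$n_planes))
  for (p in seq_len(g$n_planes)) {
    counts[, , p] <- t(matrix(y[, p], g$n_radial, g$n_angles))
  }
  sinogram(counts, g, is_noisy = FALSE)
}

#' Backprojection (adjoint of the forward projector)
#'
#' Exact transpose of [forward_project()], including the attenuation
#' weights, the detector PSF and the range-correction adjoint.
#'
#' @param sino A `sinogram` (or bare `[rows x planes]` matrix with
#'   `subset_rows`).
#' @param model A [system_model()].
#' @param subset_rows Optional sinogram row indices matching a bare matrix.
#' @return 3D array on the image grid.
#' @export
back_project <- function(sino, model, subset_rows = NULL) {
  g <- model$geometry
  if (inherits(sino, "sinogram")) {
    y <- matrix(0, g$n_angles * g$n_radial, g$n_planes)
    for (p in seq_len(g$n_planes)) {
      y[, p] <- as.vector(t(sino$counts[, , p]))
    }
  } else y <- sino
  A <- if (is.null(subset_rows)) model$A else model$A[subset_rows, , drop = FALSE]
  af <- if (is.null(subset_rows)) model$atten else
    model$atten[subset_rows, , drop = FALSE]
  arr <- array(0, model$shape)
  for (p in seq_len(g$n_planes)) {
    arr[, , p] <- matrix(as.numeric(Matrix::crossprod(A, af[, p] * y[, p])),
                         model$shape[1L], model$shape[2L])
  }
  model_blur_adjoint(arr, model)
}

#' Simulate a Poisson PET acquisition
#'
#' The expected sinogram is the forward projection of the activity under a
#' ground-truth model that always contains positron range: if `model$prc` is
#' not already a tissue-dependent operator, one is built from the CT via
#' [classify_tissue()] using `kernels`. The expectation is scaled to
#' `total_counts` and Poisson-sampled.
#'
#' @param act An `activity_volume`.
#' @param ct The co-registered `ct_volume` (used to build the ground-truth
#'   tissue masks when needed).
#' @param model A [system_model()]; its `prc` should be the ground-truth
#'   tissue-dependent operator (otherwise one is built from `ct`).
#' @param total_counts Expected total counts over the whole sinogram (>= 1).
#' @param seed RNG seed.
#' @param kernels Kernel set for building a ground-truth operator when
#'   `model$prc$mode != "tdsv"`.
#' @return A noisy `sinogram` with its `scale` field set.
#' @export
simulate_acquisition <- function(act, ct, model, total_counts, seed = 1L,
                                 kernels = NULL) {
  if (total_counts < 1) stop("total_counts must be >= 1")
  model <- ensure_ground_truth_prc(model, ct, kernels)
  expected <- forward_project(act, model)
  tot <- sum(expected$counts)
  if (tot <= 0) {
    return(sinogram(expected$counts, model$geometry, is_noisy = TRUE,
                    scale = 1))
  }
  s <- total_counts / tot
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  counts <- array(stats::rpois(length(expected$counts),
                               pmax(expected$counts * s, 0)),
                  dim = dim(expected$counts))
  sinogram(counts, model$geometry, is_noisy = TRUE, scale = s)
}

ensure_ground_truth_prc <- function(model, ct, kernels) {
  if (model$prc$mode == "tdsv") return(model)
  if (is.null(kernels)) {
    stop("ground-truth simulation requires a tdsv prc in the model or a kernel set")
  }
  masks <- classify_tissue(ct)
  model$prc <- prc_operator("tdsv", kernels = kernels, masks = masks)
  model
}

#' Insert an artificial lesion into an observed sinogram
#'
#' The lesion-only expected sinogram is computed under the ground-truth
#' model (positron range applied to the lesion activity), scaled by the host
#' sinogram's counts scale, Poisson-sampled and added bin-wise. No scatter
#' or randoms are simulated.
#'
#' @param sino An observed (noisy) `sinogram` from [simulate_acquisition()].
#' @param lesion_img Lesion-only `activity_volume`.
#' @param model The ground-truth [system_model()] (tdsv prc built from the
#'   lesion-updated CT).
#' @param seed RNG seed.
#' @return The `sinogram` with lesion counts added.
#' @export
insert_lesion_sinogram <- function(sino, lesion_img, model, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"))
  if (!sino$is_noisy) stop("lesion insertion expects an observed (noisy) sinogram")
  expected <- forward_project(lesion_img, model)
  lam <- pmax(expected$counts * sino$scale, 0)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  add <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  out <- sino
  out$counts <- sino$counts + add
  out
}

#' Split an acquisition into two independent halves
#'
#' Equivalent to dividing a Poisson acquisition into two equal time
#' segments: two independent Poisson realizations, each with half the
#' expected counts.
#'
#' @inheritParams simulate_acquisition
#' @return List of two noisy `sinogram`s (`half1`, `half2`).
#' @export
split_half_acquisition <- function(act, ct, model, total_counts, seed = 1L,
                                   kernels = NULL) {
  model <- ensure_ground_truth_prc(model, ct, kernels)
  expected <- forward_project(act, model)
  tot <- sum(expected$counts)
  s <- total_counts / tot
  lam <- pmax(expected$counts * s / 2, 0)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  h1 <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  h2 <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  list(half1 = sinogram(h1, model$geometry, TRUE, scale = s / 2),
       half2 = sinogram(h2, model$geometry, TRUE, scale = s / 2))
}

#' OSEM reconstruction settings
#'
#' @param n_iterations Full passes over all subsets (default 4).
#' @param n_subsets Number of angle subsets (default 10); angles are
#'   assigned round-robin so subsets are balanced.
#' @param post_filter_fwhm Post-reconstruction Gaussian filter FWHM in mm
#'   (applied by [gaussian_postfilter()], not inside the iterations).
#' @param voxel_size Image voxel size in mm.
#' @return A `recon_config` object.
#' @export
recon_config <- function(n_iterations = 4L, n_subsets = 10L,
                         post_filter_fwhm = 6.0,
                         voxel_size = c(2.73, 2.73, 2.80)) {
  stopifnot(n_iterations >= 1, n_subsets >= 1)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_subsets = as.integer(n_subsets),
         post_filter_fwhm = as.numeric(post_filter_fwhm),
         voxel_size = rep_len(as.numeric(voxel_size), 3L)),
    class = "recon_config"
  )
}

subset_row_indices <- function(geom, n_subsets) {
  lapply(seq_len(n_subsets), function(s) {
    ang <- seq(s, geom$n_angles, by = n_subsets)
    as.vector(outer(seq_len(geom$n_radial), (ang - 1L) * geom$n_radial, "+"))
  })
}

#' OSEM reconstruction
#'
#' Ordered-subset expectation maximization with the model's PSF and
#' optional range correction inside both projection directions:
#' `x <- x * backproject_s(y_s / forward_s(x)) / sens_s` with subset
#' sensitivities `sens_s = backproject_s(1)`. Ratio denominators and
#' sensitivities are floored at 1e-12; voxels with zero sensitivity (or a
#' zero initial estimate) stay at 0. The initial estimate is 1 inside the
#' attenuating body (mu > 0.001 per mm) and 0 outside when the model has an
#' attenuation map, else 1 everywhere.
#'
#' @param sino A `sinogram` of observed counts.
#' @param model A [system_model()] whose `prc` is the reconstruction-side
#'   correction operator.
#' @param cfg A [recon_config()].
#' @param x0 Optional initial `activity_volume`/array.
#' @param track_rmse Optional reference array; when given, the attribute
#'   `"rmse"` of the result holds the voxel RMSE against it after every full
#'   iteration.
#' @return An `activity_volume` (unfiltered).
#' @export
osem_reconstruct <- function(sino, model, cfg = recon_config(), x0 = NULL,
                             track_rmse = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  g <- model$geometry
  if (g$n_angles %% cfg$n_subsets != 0L) {
    # balanced round-robin still works; warn only on gross imbalance
    if (g$n_angles < cfg$n_subsets) stop("more subsets than angles")
  }
  rows <- subset_row_indices(g, cfg$n_subsets)
  y <- matrix(0, g$n_angles * g$n_radial, g$n_planes)
  for (p in seq_len(g$n_planes)) y[, p] <- as.vector(t(sino$counts[, , p]))

  floor_eps <- 1e-12
  x <- if (!is.null(x0)) {
    if (inherits(x0, "gaprc_volume")) x0$data else x0
  } else if (!is.null(model$mu_map)) {
    (model$mu_map > 0.001) * 1
  } else array(1, model$shape)

  # cache per-subset projector slices and attenuation columns
  As <- lapply(rows, function(r) model$A[r, , drop = FALSE])
  afs <- lapply(rows, function(r) model$atten[r, , drop = FALSE])
  sub_forward <- function(arr, s) {
    arr <- model_blur_forward(arr, model)
    y <- matrix(0, nrow(As[[s]]), g$n_planes)
    for (p in seq_len(g$n_planes)) {
      y[, p] <- as.numeric(As[[s]] %*% as.vector(arr[, , p])) * afs[[s]][, p]
    }
    y
  }
  sub_back <- function(y, s) {
    arr <- array(0, model$shape)
    for (p in seq_len(g$n_planes)) {
      arr[, , p] <- matrix(as.numeric(Matrix::crossprod(As[[s]],
                                                        afs[[s]][, p] * y[, p])),
                           model$shape[1L], model$shape[2L])
    }
    model_blur_adjoint(arr, model)
  }
  sens <- lapply(seq_along(rows), function(s) {
    ones <- matrix(1, length(rows[[s]]), g$n_planes)
    pmax(sub_back(ones, s), 0)
  })

  rmse <- numeric(0)
  for (it in seq_len(cfg$n_iterations)) {
    for (s in seq_len(cfg$n_subsets)) {
      r <- rows[[s]]
      fp <- sub_forward(x, s)
      ratio <- y[r, , drop = FALSE] / pmax(fp, floor_eps)
      bp <- sub_back(ratio, s)
      upd <- bp / pmax(sens[[s]], floor_eps)
      upd[sens[[s]] <= floor_eps] <- 0
      x <- pmax(x * upd, 0)
    }
    if (!is.null(track_rmse)) {
      rmse <- c(rmse, sqrt(mean((x - track_rmse)^2)))
    }
  }
  out <- activity_volume(x, model$voxel_size, model$origin)
  if (!is.null(track_rmse)) attr(out, "rmse") <- rmse
  out
}
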