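#' Resample a CT volume onto the PET grid
#'
#' When the CT grid is finer than the PET grid by integer factors, HU values
#' are volume-weighted block averages (limits aliasing at tissue boundaries
#' before the nearest-neighbour HU decision); otherwise trilinear
#' interpolation at the PET voxel centres is used. A CT already on the PET
#' grid is returned unchanged.
#'
#' @param ct A `ct_volume`.
#' @param shape Integer length-3 PET grid dimensions.
#' @param voxel_size Length-3 PET voxel size in mm.
#' @param origin Length-3 PET origin (mm, first voxel centre); default
#'   the CT origin adjusted so both grids cover the same extent when block
#'   averaging, else the CT origin.
#' @return A `ct_volume` on the PET grid.
#' @export
resample_ct_to_pet <- function(ct, shape, voxel_size, origin = NULL) {
  stopifnot(inherits(ct, "ct_volume"))
  shape <- as.integer(rep_len(shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  d <- dim(ct$data)
  if (identical(d, shape) && all(abs(ct$voxel_size - voxel_size) < 1e-9) &&
      (is.null(origin) || all(abs(ct$origin - origin) < 1e-9))) {
    return(ct)
  }
  fac <- voxel_size / ct$voxel_size
  int_fac <- all(abs(fac - round(fac)) < 1e-9) && all(round(fac) >= 1)
  if (int_fac && identical(as.integer(d / round(fac)), shape)) {
    f <- as.integer(round(fac))
    blk <- block_average(ct$data, f)
    new_origin <- ct$origin + (f - 1) / 2 * ct$voxel_size
    return(ct_volume(blk, voxel_size, new_origin))
  }
  if (is.null(origin)) origin <- ct$origin
  out <- trilinear_sample(ct$data, ct$voxel_size, ct$origin,
                          shape, voxel_size, origin)
  ct_volume(out, voxel_size, origin)
}

block_average <- function(a, f) {
  d <- dim(a)
  nd <- d %/% f
  a <- a[seq_len(nd[1L] * f[1L]), seq_len(nd[2L] * f[2L]),
         seq_len(nd[3L] * f[3L]), drop = FALSE]
  dim(a) <- c(f[1L], nd[1L], f[2L], nd[2L], f[3L], nd[3L])
  out <- apply(a, c(2L, 4L, 6L), mean)
  array(out, dim = nd)
}

trilinear_sample <- function(a, vx_in, org_in, shape, vx_out, org_out) {
  d <- dim(a)
  ax_out <- lapply(1:3, function(k) org_out[k] + (seq_len(shape[k]) - 1) * vx_out[k])
  # continuous voxel index in the input grid
  ci <- lapply(1:3, function(k) (ax_out[[k]] - org_in[k]) / vx_in[k] + 1)
  ci <- lapply(1:3, function(k) pmin(pmax(ci[[k]], 1), d[k]))
  i0 <- lapply(ci, function(v) pmin(floor(v), rep(Inf, length(v))))
  i0 <- lapply(seq_along(i0), function(k) pmin(as.integer(i0[[k]]), d[k] - 1L))
  i0 <- lapply(seq_along(i0), function(k) pmax(i0[[k]], 1L))
  fr <- lapply(1:3, function(k) ci[[k]] - i0[[k]])
  out <- array(0, dim = shape)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1L]] else fr[[1L]]
    wy <- if (cy == 0) 1 - fr[[2L]] else fr[[2L]]
    wz <- if (cz == 0) 1 - fr[[3L]] else fr[[3L]]
    ix <- pmin(i0[[1L]] + cx, d[1L]); iy <- pmin(i0[[2L]] + cy, d[2L])
    iz <- pmin(i0[[3L]] + cz, d[3L])
    w <- outer(outer(wx, wy), wz)
    out <- out + w * a[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Classify CT voxels into tissue masks
#'
#' Assigns every voxel to the material whose reference HU is nearest
#' (`|HU - hu_ref|` minimal), producing mutually exclusive, collectively
#' exhaustive binary masks — the mask set used by the tissue-dependent
#' correction operator. Exact midpoints are assigned to the lower-HU
#' material.
#'
#' @param ct_on_pet A `ct_volume` on the PET grid.
#' @param materials List of [material_spec()] with distinct `hu_ref` values;
#'   default [default_materials()] (order lung, water, bone).
#' @return A `tissue_masks` object: list with `masks` (named list of 3D 0/1
#'   arrays), `materials`, `labels` (integer array, 1-based index into
#'   `materials`), `voxel_size`, `origin`.
#' @export
classify_tissue <- function(ct_on_pet, materials = default_materials()) {
  stopifnot(inherits(ct_on_pet, "ct_volume"))
  if (length(materials) < 1L) stop("need at least one material")
  hu_refs <- vapply(materials, `[[`, numeric(1), "hu_ref")
  if (anyDuplicated(hu_refs)) stop("duplicate hu_ref values in materials")
  hu <- ct_on_pet$data
  n <- length(materials)
  best <- array(1L, dim = dim(hu))
  bestd <- abs(hu - hu_refs[1L])
  if (n > 1L) {
    for (i in 2:n) {
      di <- abs(hu - hu_refs[i])
      # strict improvement, or exact tie resolved toward the lower hu_ref
      take <- di < bestd | (di == bestd & hu_refs[i] < hu_refs[best])
      best[take] <- i
      bestd[take] <- di[take]
    }
  }
  masks <- lapply(seq_len(n), function(i) (best == i) * 1)
  names(masks) <- vapply(materials, `[[`, character(1), "name")
  structure(
    list(masks = masks, materials = materials, labels = best,
         voxel_size = ct_on_pet$voxel_size, origin = ct_on_pet$origin),
    class = "tissue_masks"
  )
}

#' @export
print.tissue_masks <- function(x, ...) {
  counts <- vapply(x$masks, sum, numeric(1))
  cat("<tissue masks: ",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Write tissue masks as a label volume plus JSON metadata
#'
#' @param masks A `tissue_masks` object.
#' @param stem Path stem; writes `<stem>.nii.gz` (integer labels, 1-based in
#'   material order) and `<stem>.json` (material names, densities, hu_refs).
#' @return `stem`, invisibly.
#' @export
write_tissue_masks <- function(masks, stem) {
  stopifnot(inherits(masks, "tissue_masks"))
  vol <- ct_volume(array(as.numeric(masks$labels), dim = dim(masks$labels)),
                   masks$voxel_size, masks$origin)
  write_volume(vol, paste0(stem, ".nii.gz"))
  meta <- lapply(masks$materials, function(m)
    list(name = m$name, density = m$density, hu_ref = m$hu_ref))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}
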