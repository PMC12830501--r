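#' Voxel volume containers
#'
#' `ct_volume()` wraps a 3D array of Hounsfield units, `activity_volume()` a
#' 3D array of activity concentration (Bq/mL or any fixed concentration
#' unit). Both carry the voxel size (mm) and the world coordinate of the
#' centre of voxel `[1, 1, 1]` (`origin`, mm). World coordinates are
#' voxel-centre based.
#'
#' @param data 3D numeric array.
#' @param voxel_size Length-3 voxel size in mm.
#' @param origin Length-3 world coordinate (mm) of the first voxel centre.
#' @return A `ct_volume` / `activity_volume` object (also class `gaprc_volume`).
#' @export
ct_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  new_volume(data, voxel_size, origin, "ct_volume")
}

#' @rdname ct_volume
#' @export
activity_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (any(data < 0)) stop("activity must be >= 0")
  new_volume(data, voxel_size, origin, "activity_volume")
}

new_volume <- function(data, voxel_size, origin, class) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!all(is.finite(data))) stop("volume values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  structure(
    list(data = data, voxel_size = voxel_size,
         origin = rep_len(as.numeric(origin), 3L)),
    class = c(class, "gaprc_volume")
  )
}

#' @export
print.gaprc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s %d x %d x %d, voxel %.2f x %.2f x %.2f mm, range [%.3g, %.3g]>\n",
              class(x)[1L], d[1L], d[2L], d[3L],
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L],
              min(x$data), max(x$data)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# world coordinates (mm) of voxel centres along each axis
grid_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1L) * vol$voxel_size[a])
}

#' Write / read volumes in NIfTI format
#'
#' Volumes are written as NIfTI-1 (`.nii.gz`) with the voxel size in the
#' pixdim and the origin encoded in the sform translation. Round-trips
#' preserve the array, voxel size and origin.
#'
#' @param vol A `ct_volume` or `activity_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param kind For `read_volume`: `"ct"` or `"activity"`.
#' @return `write_volume` returns `path` invisibly; `read_volume` the volume.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gaprc_volume"))
  img <- RNifti::asNifti(vol$data)
  aff <- diag(c(vol$voxel_size, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = c("activity", "ct")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vx <- abs(diag(aff)[1:3])
  org <- aff[1:3, 4]
  data <- array(as.numeric(img), dim = dim(img))
  if (kind == "ct") ct_volume(data, vx, org) else activity_volume(data, vx, org)
}
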