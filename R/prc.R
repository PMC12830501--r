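#' Positron range correction operator
#'
#' Bundles a correction mode with its kernels and (for the
#' tissue-dependent, spatially-variant mode) the binary tissue masks:
#' \describe{
#'   \item{`none`}{no correction; the operator is the identity.}
#'   \item{`tissue_independent`}{one stationary water kernel convolved over
#'     the whole image.}
#'   \item{`tdsv`}{per-tissue kernels: the image is convolved with each
#'     tissue's kernel, masked by that tissue's binary mask, and the masked
#'     results are summed (convolve-then-mask, which is what makes the
#'     operator spatially variant at tissue boundaries).}
#' }
#'
#' @param mode `"none"`, `"tissue_independent"` or `"tdsv"`.
#' @param kernels For `tdsv`: named list of `positron_kernel`, one per mask;
#'   for `tissue_independent`: a single water `positron_kernel` (or a list
#'   containing `water`).
#' @param masks A `tissue_masks` object (`tdsv` only); mask names must match
#'   kernel names one-to-one.
#' @return A `prc_operator` object.
#' @export
prc_operator <- function(mode = c("none", "tissue_independent", "tdsv"),
                         kernels = NULL, masks = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(structure(list(mode = mode, kernels = NULL, masks = NULL),
                     class = "prc_operator"))
  }
  if (mode == "tissue_independent") {
    if (inherits(kernels, "positron_kernel")) kernels <- list(water = kernels)
    if (is.null(kernels$water)) {
      stop("tissue_independent mode requires the water kernel")
    }
    return(structure(list(mode = mode, kernels = kernels["water"],
                          masks = NULL,
                          cache = new.env(parent = emptyenv())),
                     class = "prc_operator"))
  }
  stopifnot(inherits(masks, "tissue_masks"))
  if (is.null(kernels) || !setequal(names(kernels), names(masks$masks))) {
    stop("tdsv mode requires one kernel per tissue mask (matching names)")
  }
  kernels <- kernels[names(masks$masks)]
  structure(list(mode = mode, kernels = kernels, masks = masks,
                 cache = new.env(parent = emptyenv())),
            class = "prc_operator")
}

#' @export
print.prc_operator <- function(x, ...) {
  cat(sprintf("<prc operator: mode %s%s>\n", x$mode,
              if (!is.null(x$kernels))
                paste0(", kernels ", paste(names(x$kernels), collapse = "/"))
              else ""))
  invisible(x)
}

#' Apply the tissue-dependent spatially-variant correction
#'
#' For each tissue i the image is convolved with that tissue's
#' positron-range kernel and multiplied element-wise by its binary mask; the
#' masked per-tissue images are summed. Zero padding at the volume border.
#'
#' @param img An `activity_volume` (or bare 3D array on the mask grid).
#' @param op A `prc_operator` with `mode = "tdsv"`.
#' @return Same type as `img`.
#' @export
apply_tdsv <- function(img, op) {
  stopifnot(inherits(op, "prc_operator"), op$mode == "tdsv")
  arr <- volume_array(img, op$masks)
  convs <- multi_convolve(arr, op, flip = FALSE)
  out <- array(0, dim(arr))
  for (nm in names(op$kernels)) {
    out <- out + op$masks$masks[[nm]] * convs[[nm]]
  }
  volume_like(out, img)
}

# convolve one image with every kernel of the operator, sharing the image
# FFT and caching kernel FFTs (keyed by padded size) in the operator
multi_convolve <- function(arr, op, flip = FALSE) {
  d <- dim(arr)
  kd_max <- max(vapply(op$kernels, function(k) dim(k$weights)[1L], integer(1)))
  pd <- vapply(d + kd_max - 1L, stats::nextn, integer(1),
               factors = c(2L, 3L, 5L))
  ip <- array(0, pd)
  ip[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] <- arr
  fi <- stats::fft(ip)
  out <- vector("list", length(op$kernels))
  names(out) <- names(op$kernels)
  for (nm in names(op$kernels)) {
    kw <- op$kernels[[nm]]$weights
    if (flip) kw <- flip3(kw)
    kd <- dim(kw)
    key <- paste(nm, flip, paste(pd, collapse = "x"), sep = "|")
    fk <- op$cache[[key]]
    if (is.null(fk)) {
      kp <- array(0, pd)
      kp[seq_len(kd[1L]), seq_len(kd[2L]), seq_len(kd[3L])] <- kw
      fk <- stats::fft(kp)
      op$cache[[key]] <- fk
    }
    hw <- (kd - 1L) %/% 2L
    full <- Re(stats::fft(fi * fk, inverse = TRUE)) / prod(pd)
    out[[nm]] <- full[hw[1L] + seq_len(d[1L]), hw[2L] + seq_len(d[2L]),
                      hw[3L] + seq_len(d[3L])]
  }
  out
}

#' Adjoint of the range-correction operator
#'
#' The exact transpose of [apply_tdsv()]: each tissue's mask is applied
#' first, the masked image is convolved with the flipped kernel, and the
#' results are summed. Needed for the backprojection step of a matched
#' forward/backward OSEM pair. For `tissue_independent`, the adjoint is the
#' convolution with the flipped water kernel; for `none`, the identity.
#'
#' @param img An `activity_volume` or 3D array.
#' @param op A `prc_operator`.
#' @return Same type as `img`.
#' @export
apply_adjoint <- function(img, op) {
  stopifnot(inherits(op, "prc_operator"))
  if (op$mode == "none") return(img)
  if (op$mode == "tissue_independent") {
    arr <- volume_array(img, NULL)
    return(volume_like(multi_convolve(arr, op, flip = TRUE)$water, img))
  }
  arr <- volume_array(img, op$masks)
  out <- array(0, dim(arr))
  for (nm in names(op$kernels)) {
    op1 <- op; op1$kernels <- op$kernels[nm]
    out <- out + multi_convolve(arr * op$masks$masks[[nm]], op1,
                                flip = TRUE)[[nm]]
  }
  volume_like(out, img)
}

#' Apply the tissue-independent correction
#'
#' A single stationary convolution of the whole image with the water
#' positron-range kernel.
#'
#' @param img An `activity_volume` or 3D array.
#' @param op A `prc_operator` with `mode = "tissue_independent"`.
#' @return Same type as `img`.
#' @export
apply_tissue_independent <- function(img, op) {
  stopifnot(inherits(op, "prc_operator"), op$mode == "tissue_independent")
  arr <- volume_array(img, NULL)
  volume_like(multi_convolve(arr, op, flip = FALSE)$water, img)
}

#' Apply a range-correction operator in its own mode
#'
#' Dispatches to [apply_tdsv()], [apply_tissue_independent()] or the
#' identity according to `op$mode`.
#'
#' @inheritParams apply_adjoint
#' @return Same type as `img`.
#' @export
apply_prc <- function(img, op) {
  switch(op$mode,
         none = img,
         tissue_independent = apply_tissue_independent(img, op),
         tdsv = apply_tdsv(img, op))
}

flip3 <- function(a) {
  d <- dim(a)
  a[d[1L]:1L, d[2L]:1L, d[3L]:1L, drop = FALSE]
}

volume_array <- function(img, masks) {
  arr <- if (inherits(img, "gaprc_volume")) img$data else img
  if (!is.null(masks) && !identical(dim(arr), dim(masks$labels))) {
    stop("image grid does not match the tissue-mask grid")
  }
  arr
}

volume_like <- function(arr, template) {
  if (inherits(template, "gaprc_volume")) {
    out <- template
    # FFT round-off can leave activity values at tiny negatives; clamp
    out$data <- if (inherits(template, "activity_volume")) pmax(arr, 0) else arr
    out
  } else arr
}
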