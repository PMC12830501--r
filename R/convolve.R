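# 3D convolution and Gaussian blurring primitives shared by the range
# correction operator, the detector PSF and the post-reconstruction filter.
# All convolutions use zero padding at the volume border (activity outside
# the field of view is taken to be zero).

#' Convolve a 3D array with a 3D kernel
#'
#' Zero-padded ("full" support, cropped back to the input extent)
#' convolution. The FFT path and the direct path are mathematically
#' identical; the direct path exists as an independent reference for tests
#' and small kernels.
#'
#' @param img 3D numeric array.
#' @param kern 3D kernel array with odd dimensions.
#' @param method `"fft"` (default) or `"direct"`.
#' @return Array of the same dimensions as `img`.
#' @export
convolve3d <- function(img, kern, method = c("fft", "direct")) {
  method <- match.arg(method)
  kd <- dim(kern)
  if (any(kd %% 2L == 0L)) stop("kernel dimensions must be odd")
  if (identical(method, "direct")) return(convolve3d_direct(img, kern))
  d <- dim(img)
  hw <- (kd - 1L) %/% 2L
  pd <- vapply(d + kd - 1L, stats::nextn, integer(1), factors = c(2L, 3L, 5L))
  ip <- array(0, pd); ip[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] <- img
  kp <- array(0, pd); kp[seq_len(kd[1L]), seq_len(kd[2L]), seq_len(kd[3L])] <- kern
  out <- Re(stats::fft(stats::fft(ip) * stats::fft(kp), inverse = TRUE)) /
    prod(pd)
  out[hw[1L] + seq_len(d[1L]), hw[2L] + seq_len(d[2L]), hw[3L] + seq_len(d[3L])]
}

convolve3d_direct <- function(img, kern) {
  d <- dim(img); kd <- dim(kern); hw <- (kd - 1L) %/% 2L
  out <- array(0, d)
  for (oz in -hw[3L]:hw[3L]) for (oy in -hw[2L]:hw[2L]) for (ox in -hw[1L]:hw[1L]) {
    w <- kern[hw[1L] + 1L + ox, hw[2L] + 1L + oy, hw[3L] + 1L + oz]
    if (w == 0) next
    out <- out + w * shift_zero(img, c(ox, oy, oz))
  }
  out
}

# shift an array by integer offsets, zero-filling: out[i] = a[i - off]
shift_zero <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- (1L + o):d[k]; src[[k]] <- 1L:(d[k] - o) }
    else { dst[[k]] <- 1L:(d[k] + o); src[[k]] <- (1L - o):d[k] }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# 1D normalized Gaussian taps for a sigma given in voxels
gaussian_taps <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  hw <- max(1L, ceiling(4 * sigma_vox))
  x <- (-hw):hw
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# separable zero-padded Gaussian blur, sigma per axis in voxels
separable_gaussian_blur <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    w <- gaussian_taps(sigma_vox[ax])
    if (length(w) == 1L) next
    hw <- (length(w) - 1L) %/% 2L
    acc <- array(0, dim(a))
    for (t in seq_along(w)) {
      off <- c(0L, 0L, 0L); off[ax] <- t - hw - 1L
      acc <- acc + w[t] * shift_zero(a, off)
    }
    a <- acc
  }
  a
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
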