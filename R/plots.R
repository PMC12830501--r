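#' Plot kernel radial profiles
#'
#' Cumulative annihilation fraction against radius for a set of
#' positron-range kernels (requires ggplot2).
#'
#' @param kernels Named list of `positron_kernel` objects.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(kernels) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  if (inherits(kernels, "positron_kernel")) kernels <- list(kernel = kernels)
  df <- do.call(rbind, lapply(names(kernels), function(nm) {
    p <- radial_profile(kernels[[nm]])
    p$tissue <- nm
    p
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$cdf,
                                   colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = "cumulative annihilation fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-lesion percentage changes between reconstructions
#'
#' @param measurements Lesion measurement tibble from [run_experiment()].
#' @param metric Metric column (default `"suv_max"`).
#' @param ref Reference recon id (default `"nonprc_6mm"`).
#' @return A ggplot object.
#' @export
plot_percent_change <- function(measurements, metric = "suv_max",
                                ref = "nonprc_6mm") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  refs <- measurements[measurements$recon_id == ref, ]
  oth <- measurements[measurements$recon_id != ref, ]
  oth$change <- percent_change(
    oth[[metric]],
    refs[[metric]][match(oth$lesion_id, refs$lesion_id)])
  ggplot2::ggplot(oth, ggplot2::aes(x = .data$lesion_id, y = .data$change,
                                    fill = .data$recon_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("%% change in %s vs %s", metric, ref),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Display an axial slice of a volume
#'
#' @param vol A `gaprc_volume`.
#' @param slice Axial slice index (default middle).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  stopifnot(inherits(vol, "gaprc_volume"))
  d <- dim(vol$data)
  if (is.null(slice)) slice <- ceiling(d[3L] / 2)
  df <- expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]))
  df$value <- as.vector(vol$data[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (inherits(vol, "ct_volume")) "HU" else "activity") +
    ggplot2::theme_minimal()
}
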