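# Electron/positron stopping power in liquid water, MeV cm^2/g (total),
# log-log interpolated. Standard tabulated values; positron values differ from
# electron values by less than the fidelity of the transport model.
WATER_STOPPING_E_MEV <- c(0.010, 0.015, 0.020, 0.030, 0.040, 0.050, 0.070,
                          0.100, 0.150, 0.200, 0.300, 0.400, 0.500, 0.700,
                          1.000, 1.500, 2.000, 3.000)
WATER_STOPPING_MEVCM2G <- c(22.56, 16.47, 13.17, 9.653, 7.777, 6.603, 5.212,
                            4.115, 3.238, 2.793, 2.355, 2.148, 2.034, 1.931,
                            1.862, 1.841, 1.850, 1.880)
RADIATION_LENGTH_WATER <- 36.08  # g/cm^2

water_stopping_power <- function(e_mev) {
  lg <- stats::approx(log(WATER_STOPPING_E_MEV), log(WATER_STOPPING_MEVCM2G),
                      xout = log(pmax(e_mev, 1e-4)), rule = 2)$y
  exp(lg)
}

# CSDA range in water (g/cm^2 == cm at unit density) by integrating 1/S(E)
# from 1 keV up; cached fine grid for both directions of the lookup.
csda_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      e <- exp(seq(log(1e-3), log(3.0), length.out = 600L))
      inv_s <- 1 / water_stopping_power(e)
      r <- c(0, cumsum(diff(e) * (inv_s[-1] + inv_s[-length(e)]) / 2))
      tab <<- list(e = e, r = r)
    }
    tab
  }
})

#' CSDA range of a positron in water
#'
#' Continuous-slowing-down-approximation range in water, by numerical
#' integration of the reciprocal stopping power.
#'
#' @param e_mev Kinetic energy in MeV.
#' @return Range in g/cm^2 (equals cm in unit-density water).
#' @export
csda_range_water <- function(e_mev) {
  tab <- csda_table()
  stats::approx(tab$e, tab$r, xout = pmax(e_mev, 1e-3), rule = 2)$y
}

energy_from_residual_range <- function(r) {
  tab <- csda_table()
  stats::approx(tab$r, tab$e, xout = pmax(r, 0), rule = 2)$y
}

#' Monte Carlo positron transport in a homogeneous material
#'
#' Condensed-history transport of positrons from a point source in an
#' unbounded homogeneous medium. Initial kinetic energies are drawn from the
#' allowed beta-plus spectrum; each particle then advances along its residual
#' CSDA range in equal mass-length substeps, with a Gaussian multiple-
#' scattering deflection (Highland form) applied per substep, until its
#' energy falls below `cutoff_kev`, where it is taken to annihilate.
#' Materials are density-scaled water: transport is computed in unit-density
#' water and displacements scaled by `1 / density`.
#'
#' @param spectrum A [beta_spectrum()]; default ⁶⁸Ga.
#' @param material A [material_spec()]; its density scales the displacement.
#' @param n Number of decays to simulate (>= 1).
#' @param seed Integer RNG seed; identical inputs give identical endpoints.
#' @param cutoff_kev Kinetic-energy cutoff in keV below which the positron is
#'   considered annihilated (default 10).
#' @param n_steps Number of condensed-history substeps per particle
#'   (default 40).
#' @return An object of class `annihilation_endpoints`: list with
#'   `displacements` (n x 3 matrix, mm), `n_events`, `seed`, `material`,
#'   `spectrum`.
#' @export
transport_positrons <- function(spectrum = beta_spectrum(),
                                material = default_materials()$water,
                                n, seed = 1L,
                                cutoff_kev = 10, n_steps = 40L) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  if (!inherits(material, "material_spec") || !is.finite(material$density) ||
      material$density <= 0) {
    stop("unknown or invalid material density")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)

  e0 <- sample_beta_energy(spectrum, n, seed = seed)
  rng <- local_rng(seed + 1L)
  on.exit(rng(), add = TRUE)

  r_cut <- csda_range_water(cutoff_kev / 1000)
  r_res <- csda_range_water(e0)              # residual range, g/cm^2
  ds <- pmax(r_res - r_cut, 0) / n_steps     # per-particle substep

  pos <- matrix(0, n, 3L)
  # isotropic initial directions
  u <- matrix(stats::rnorm(3L * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))

  alive <- ds > 0
  for (k in seq_len(n_steps)) {
    if (!any(alive)) break
    i <- which(alive)
    e_mid <- energy_from_residual_range(r_res[i] - ds[i] / 2)
    etot <- e_mid + ELECTRON_MASS_MEV
    p <- sqrt(etot^2 - ELECTRON_MASS_MEV^2)
    beta <- p / etot
    theta0 <- 0.0136 / (beta * p) * sqrt(ds[i] / RADIATION_LENGTH_WATER)
    # advance (cm in unit-density water), then deflect
    pos[i, ] <- pos[i, ] + u[i, , drop = FALSE] * ds[i]
    e1 <- orthonormal_to(u[i, , drop = FALSE])
    e2 <- cross3(u[i, , drop = FALSE], e1)
    tx <- stats::rnorm(length(i), 0, theta0)
    ty <- stats::rnorm(length(i), 0, theta0)
    nu <- u[i, , drop = FALSE] + e1 * tx + e2 * ty
    u[i, ] <- nu / sqrt(rowSums(nu^2))
    r_res[i] <- r_res[i] - ds[i]
    alive[i] <- k < n_steps
  }

  disp_mm <- pos * 10 / material$density
  structure(
    list(displacements = disp_mm, n_events = n, seed = as.integer(seed),
         material = material, spectrum = spectrum),
    class = "annihilation_endpoints"
  )
}

# a unit vector orthogonal to each row of u
orthonormal_to <- function(u) {
  # pick the axis least aligned with u to avoid degeneracy
  a <- matrix(0, nrow(u), 3L)
  amin <- max.col(-abs(u), ties.method = "first")
  a[cbind(seq_len(nrow(u)), amin)] <- 1
  v <- cross3(u, a)
  v / sqrt(rowSums(v^2))
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' @export
print.annihilation_endpoints <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("<annihilation endpoints: %d decays in %s, mean range %.2f mm, max %.2f mm>\n",
              x$n_events, x$material$name, mean(mag), max(mag)))
  invisible(x)
}

#' Kernel half-width from maximum positron range
#'
#' Number of voxels on each side of the centre voxel needed to cover the
#' maximum positron range: the nearest integer (half away from zero) of
#' `max_range / voxel_size`. The kernel side length is `2 * half_width + 1`,
#' reproducing 7/25/5 elements per axis for the water/lung/bone sizing
#' ranges (8.8/32.3/4.5 mm) at 2.73 mm pitch.
#'
#' @param max_range Maximum positron range in mm (>= 0).
#' @param voxel_size Voxel pitch in mm (> 0).
#' @return Integer half-width in voxels.
#' @examples
#' kernel_half_width(8.8, 2.73)   # 3 -> 7 elements per axis
#' kernel_half_width(32.3, 2.73)  # 12 -> 25
#' kernel_half_width(4.5, 2.73)   # 2 -> 5
#' @export
kernel_half_width <- function(max_range, voxel_size) {
  if (any(max_range < 0)) stop("max_range must be >= 0")
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  as.integer(floor(max_range / voxel_size + 0.5))
}

#' Build a positron-range kernel from annihilation endpoints
#'
#' Bins annihilation displacements into a cubic voxel grid centred on the
#' emission voxel. Weights are first divided by the total number of simulated
#' decays (events outside the kernel extent are truncated), then renormalized
#' to sum exactly to 1 so that the range-correction operator conserves counts
#' in homogeneous regions. The truncated-tail mass is recorded in
#' `truncated_fraction`.
#'
#' @param endpoints An `annihilation_endpoints` object.
#' @param voxel_size Numeric length-3 voxel size (dx, dy, dz) in mm.
#' @param max_range Maximum positron range in mm used for sizing.
#' @param material Optional [material_spec()]; defaults to the endpoints'.
#' @return An object of class `positron_kernel`: `weights` (cubic 3D array),
#'   `half_width`, `voxel_size`, `material`, `max_range`, `n_events`, `seed`,
#'   `truncated_fraction`.
#' @export
build_kernel <- function(endpoints, voxel_size, max_range, material = NULL) {
  stopifnot(inherits(endpoints, "annihilation_endpoints"))
  if (!is.numeric(max_range) || max_range <= 0) stop("max_range must be > 0")
  d <- endpoints$displacements
  if (is.null(d) || nrow(d) == 0L) stop("empty endpoints")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(material)) material <- endpoints$material

  hw <- kernel_half_width(max_range, voxel_size[1L])
  side <- 2L * hw + 1L
  # voxel index offset per axis, nearest-voxel binning
  idx <- sweep(d, 2L, voxel_size, "/")
  idx <- floor(idx + 0.5)
  inside <- abs(idx[, 1L]) <= hw & abs(idx[, 2L]) <= hw & abs(idx[, 3L]) <= hw
  w <- array(0, dim = c(side, side, side))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE] + hw + 1L
    lin <- ii[, 1L] + (ii[, 2L] - 1L) * side + (ii[, 3L] - 1L) * side^2
    tb <- tabulate(lin, nbins = side^3)
    w[] <- tb
  }
  w <- w / endpoints$n_events
  truncated <- 1 - sum(w)
  if (sum(w) <= 0) stop("no annihilation events fall inside the kernel extent")
  w <- w / sum(w)
  structure(
    list(weights = w, half_width = hw, voxel_size = voxel_size,
         material = material, max_range = as.numeric(max_range),
         n_events = endpoints$n_events, seed = endpoints$seed,
         truncated_fraction = truncated),
    class = "positron_kernel"
  )
}

#' Generate a positron-range kernel for one material
#'
#' Convenience wrapper: Monte Carlo transport with [transport_positrons()]
#' followed by [build_kernel()]. By default `max_range` comes from the
#' per-tissue sizing preset ([max_range_preset()]) when the material is one
#' of lung/water/bone; otherwise the 99.99th percentile of the simulated
#' displacement magnitudes is used.
#'
#' @param material A [material_spec()].
#' @param voxel_size Length-3 voxel size in mm
#'   (default `c(2.73, 2.73, 2.80)`).
#' @param n_decays Number of simulated decays (default 1e6).
#' @param seed RNG seed (default 20220901).
#' @param max_range Maximum range in mm for sizing, or `NULL` for the
#'   preset/percentile rule above.
#' @param spectrum A [beta_spectrum()]; default ⁶⁸Ga.
#' @return A `positron_kernel`.
#' @export
make_positron_kernel <- function(material,
                                 voxel_size = c(2.73, 2.73, 2.80),
                                 n_decays = 1e6, seed = 20220901,
                                 max_range = NULL,
                                 spectrum = beta_spectrum()) {
  ep <- transport_positrons(spectrum, material, n = n_decays, seed = seed)
  if (is.null(max_range)) {
    preset <- max_range_preset()
    if (material$name %in% names(preset)) {
      max_range <- unname(preset[material$name])
    } else {
      mag <- sqrt(rowSums(ep$displacements^2))
      max_range <- unname(stats::quantile(mag, 0.9999))
    }
  }
  build_kernel(ep, voxel_size, max_range, material)
}

#' Generate the default kernel set
#'
#' One kernel per default material (lung, water, bone), sized with the
#' per-tissue maximum-range preset.
#'
#' @inheritParams make_positron_kernel
#' @param materials Named list of [material_spec()] (default
#'   [default_materials()]).
#' @return Named list of `positron_kernel` objects in mask-set order
#'   (lung, water, bone).
#' @export
make_kernel_set <- function(materials = default_materials(),
                            voxel_size = c(2.73, 2.73, 2.80),
                            n_decays = 1e6, seed = 20220901,
                            spectrum = beta_spectrum()) {
  out <- lapply(seq_along(materials), function(i) {
    make_positron_kernel(materials[[i]], voxel_size = voxel_size,
                         n_decays = n_decays, seed = seed + i - 1L,
                         spectrum = spectrum)
  })
  names(out) <- names(materials)
  out
}

#' A discrete delta kernel
#'
#' Single-voxel kernel (identity under convolution); used for non-PRC
#' comparisons and tests.
#'
#' @param voxel_size Length-3 voxel size in mm.
#' @param material Optional material tag.
#' @return A `positron_kernel` with `half_width = 0` and centre weight 1.
#' @export
delta_kernel <- function(voxel_size = c(2.73, 2.73, 2.80), material = NULL) {
  if (is.null(material)) material <- material_spec("delta", 1, 0)
  structure(
    list(weights = array(1, c(1L, 1L, 1L)), half_width = 0L,
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         material = material, max_range = 0, n_events = NA_integer_,
         seed = NA_integer_, truncated_fraction = 0),
    class = "positron_kernel"
  )
}

#' @export
print.positron_kernel <- function(x, ...) {
  s <- dim(x$weights)[1L]
  cat(sprintf("<positron kernel '%s': %d x %d x %d, max range %.1f mm, FWHM %.2f mm>\n",
              x$material$name, s, s, s, x$max_range, kernel_fwhm(x)))
  invisible(x)
}

#' Radial cumulative annihilation profile of a kernel
#'
#' Distance of every kernel voxel centre from the kernel centre together
#' with the annihilation probability there, accumulated into a cumulative
#' distribution over radius.
#'
#' @param kernel A `positron_kernel`.
#' @return A tibble with columns `radius_mm`, `pdf` (probability mass at that
#'   radius) and `cdf` (cumulative fraction, ending at 1).
#' @export
radial_profile <- function(kernel) {
  stopifnot(inherits(kernel, "positron_kernel"))
  hw <- kernel$half_width
  ax <- (-hw):hw
  g <- expand.grid(x = ax * kernel$voxel_size[1L],
                   y = ax * kernel$voxel_size[2L],
                   z = ax * kernel$voxel_size[3L])
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  w <- as.vector(kernel$weights)
  agg <- rowsum(w, group = round(r, 6))
  radius <- as.numeric(rownames(agg))
  o <- order(radius)
  tibble::tibble(radius_mm = radius[o], pdf = as.vector(agg)[o],
                 cdf = cumsum(as.vector(agg)[o]))
}

#' Effective FWHM of a kernel
#'
#' Full width at half maximum of the kernel's central x-axis profile,
#' estimated by linear interpolation between voxel centres. A delta kernel
#' reports 0.
#'
#' @param kernel A `positron_kernel`.
#' @return FWHM in mm.
#' @export
kernel_fwhm <- function(kernel) {
  hw <- kernel$half_width
  if (hw == 0L) return(0)
  c0 <- hw + 1L
  prof <- kernel$weights[, c0, c0]
  half <- max(prof) / 2
  x <- ((-hw):hw) * kernel$voxel_size[1L]
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  left <- if (lo > 1L) {
    x[lo - 1L] + (half - prof[lo - 1L]) / (prof[lo] - prof[lo - 1L]) *
      (x[lo] - x[lo - 1L])
  } else x[1L]
  right <- if (hi < length(prof)) {
    x[hi] + (prof[hi] - half) / (prof[hi] - prof[hi + 1L]) *
      (x[hi + 1L] - x[hi])
  } else x[length(prof)]
  right - left
}

#' Write / read a positron kernel as plain text
#'
#' The kernel is stored as a JSON header (`<stem>.json`: material, voxel
#' size, sizing range, event count, seed, truncated fraction) plus a CSV of
#' voxel weights (`<stem>.csv`: columns `i, j, k, weight`, zero-based offsets
#' from the kernel centre) and the radial-profile CSV (`<stem>_profile.csv`).
#'
#' @param kernel A `positron_kernel`.
#' @param stem Path stem (no extension).
#' @return `write_kernel` returns `stem` invisibly; `read_kernel` returns the
#'   `positron_kernel`.
#' @export
write_kernel <- function(kernel, stem) {
  stopifnot(inherits(kernel, "positron_kernel"))
  meta <- list(material = kernel$material$name,
               density = kernel$material$density,
               hu_ref = kernel$material$hu_ref,
               voxel_size = kernel$voxel_size,
               half_width = kernel$half_width,
               max_range = kernel$max_range,
               n_events = kernel$n_events,
               seed = kernel$seed,
               truncated_fraction = kernel$truncated_fraction)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  hw <- kernel$half_width
  ax <- (-hw):hw
  g <- expand.grid(i = ax, j = ax, k = ax)
  df <- data.frame(g, weight = as.vector(kernel$weights))
  df <- df[df$weight > 0, , drop = FALSE]
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  utils::write.csv(radial_profile(kernel), paste0(stem, "_profile.csv"),
                   row.names = FALSE)
  invisible(stem)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(stem, ".csv"))
  hw <- as.integer(meta$half_width)
  side <- 2L * hw + 1L
  w <- array(0, c(side, side, side))
  w[cbind(df$i + hw + 1L, df$j + hw + 1L, df$k + hw + 1L)] <- df$weight
  structure(
    list(weights = w, half_width = hw, voxel_size = as.numeric(meta$voxel_size),
         material = material_spec(meta$material, meta$density, meta$hu_ref),
         max_range = meta$max_range, n_events = meta$n_events,
         seed = meta$seed, truncated_fraction = meta$truncated_fraction),
    class = "positron_kernel"
  )
}
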