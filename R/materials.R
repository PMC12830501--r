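#' Material specification
#'
#' A tissue material used for positron transport and CT segmentation. The
#' transport model treats every material as density-scaled water (same
#' effective composition), so a material is fully described by its mass
#' density plus the reference Hounsfield unit used by the nearest-neighbour
#' tissue classifier.
#'
#' @param name Material label, e.g. `"water"`, `"lung"`, `"bone"`.
#' @param density Mass density in g/cm^3; must be positive.
#' @param hu_ref Reference Hounsfield unit (integer-valued) for segmentation.
#' @return An object of class `material_spec`.
#' @examples
#' material_spec("water", 1.0, 3)
#' @export
material_spec <- function(name, density, hu_ref) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("material density must be a positive finite number (g/cm^3)")
  }
  stopifnot(is.numeric(hu_ref), length(hu_ref) == 1L, is.finite(hu_ref))
  structure(
    list(name = name, density = as.numeric(density), hu_ref = as.numeric(hu_ref)),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material '%s': density %.3g g/cm^3, HU ref %g>\n",
              x$name, x$density, x$hu_ref))
  invisible(x)
}

#' Default tissue materials
#'
#' The three tissue classes used throughout: lung, water (soft-tissue
#' surrogate) and bone. Reference Hounsfield units are the segmentation
#' constants (water 3, lung -695, bone 1226). Densities are those of the
#' density-scaled-water transport model: water 1.00, lung 0.26 and bone
#' 1.90 g/cm^3, chosen so that the density-scaled maximum positron ranges
#' track the per-tissue kernel sizing ranges (8.8 mm water, 32.3 mm lung,
#' 4.5 mm bone).
#'
#' The list is ordered (lung, water, bone) and this order is preserved in
#' mask sets and serialized output.
#'
#' @return Named list of [material_spec()] objects, in order lung, water, bone.
#' @export
default_materials <- function() {
  list(
    lung  = material_spec("lung",  0.26, -695),
    water = material_spec("water", 1.00,    3),
    bone  = material_spec("bone",  1.90, 1226)
  )
}

#' Maximum positron range presets for kernel sizing
#'
#' Maximum ⁶⁸Ga positron ranges (mm) per tissue used to size the
#' positron-range kernels: 8.8 mm in water, 32.3 mm in lung, 4.5 mm in bone.
#'
#' @return Named numeric vector of ranges in mm.
#' @export
max_range_preset <- function() {
  c(lung = 32.3, water = 8.8, bone = 4.5)
}

#' Beta-plus decay spectrum
#'
#' Describes an allowed beta-plus emitter by its endpoint kinetic energy and
#' the proton number of the daughter nuclide (which sets the Coulomb
#' correction). The default is ⁶⁸Ga: endpoint 1.899 MeV, daughter ⁶⁸Zn
#' (Z = 30).
#'
#' @param isotope Isotope label.
#' @param e_max Endpoint kinetic energy in MeV; must be positive.
#' @param z_daughter Proton number of the daughter nuclide.
#' @return An object of class `beta_spectrum`.
#' @examples
#' beta_spectrum()            # Ga-68
#' beta_spectrum("F-18", 0.634, 8)
#' @export
beta_spectrum <- function(isotope = "Ga-68", e_max = 1.899, z_daughter = 30) {
  if (!is.numeric(e_max) || length(e_max) != 1L || !is.finite(e_max) ||
      e_max <= 0) {
    stop("invalid spectrum: endpoint energy e_max must be positive (MeV)")
  }
  stopifnot(is.numeric(z_daughter), z_daughter >= 1)
  structure(
    list(isotope = isotope, e_max = as.numeric(e_max),
         z_daughter = as.numeric(z_daughter)),
    class = "beta_spectrum"
  )
}

ELECTRON_MASS_MEV <- 0.51099895
FINE_STRUCTURE <- 1 / 137.035999

#' Allowed beta-plus spectrum density
#'
#' Unnormalized allowed-shape Fermi spectrum density for positron kinetic
#' energy `e` (MeV): `p * E_tot * (e_max - e)^2 * F(Z, e)` with the
#' nonrelativistic Coulomb factor for positrons,
#' `F = 2 pi eta / (1 - exp(-2 pi eta))`, `eta = -Z alpha / beta` (repulsive).
#'
#' @param e Kinetic energies in MeV.
#' @param spectrum A [beta_spectrum()].
#' @return Unnormalized density values (0 outside `(0, e_max)`).
#' @export
beta_spectrum_density <- function(e, spectrum = beta_spectrum()) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  dens <- numeric(length(e))
  ok <- e > 0 & e < spectrum$e_max
  if (!any(ok)) return(dens)
  ek <- e[ok]
  etot <- ek + ELECTRON_MASS_MEV
  p <- sqrt(etot^2 - ELECTRON_MASS_MEV^2)      # momentum in MeV/c
  beta <- p / etot
  eta <- -spectrum$z_daughter * FINE_STRUCTURE / beta
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  dens[ok] <- p * etot * (spectrum$e_max - ek)^2 * fermi
  dens
}

#' Sample positron emission energies
#'
#' Draws kinetic energies from the allowed beta-plus spectrum by rejection
#' sampling against a uniform envelope over `(0, e_max)`. Reproducible under
#' a fixed seed.
#'
#' @param spectrum A [beta_spectrum()].
#' @param n Number of energies to draw (>= 1).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `n` kinetic energies in MeV, all in `(0, e_max]`.
#' @export
sample_beta_energy <- function(spectrum = beta_spectrum(), n, seed = 1L) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  e_grid <- seq(1e-4, spectrum$e_max, length.out = 2048L)
  d_max <- max(beta_spectrum_density(e_grid, spectrum)) * 1.02
  out <- numeric(0)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1024L)
    e_try <- stats::runif(m, 0, spectrum$e_max)
    u <- stats::runif(m, 0, d_max)
    out <- c(out, e_try[u < beta_spectrum_density(e_try, spectrum)])
  }
  out[seq_len(n)]
}

# Set the RNG to a fixed state and return a restorer, so that package
# functions are seed-reproducible without clobbering the caller's stream.
local_rng <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
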