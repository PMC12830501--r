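test_that("beta spectrum sampling stays in support, is seed-deterministic, and matches the quadrature mean", {
  sp <- beta_spectrum()
  e <- sample_beta_energy(sp, 1e5, seed = 10)
  expect_true(all(e > 0 & e <= sp$e_max))

  e2a <- sample_beta_energy(sp, 2, seed = 77)
  e2b <- sample_beta_energy(sp, 2, seed = 77)
  expect_identical(e2a, e2b)

  # quadrature oracle for the mean of the same spectrum density
  eg <- seq(1e-6, sp$e_max, length.out = 4e4)
  d <- beta_spectrum_density(eg, sp)
  mu_quad <- sum(eg * d) / sum(d)
  sem <- stats::sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - mu_quad), 3 * sem)

  expect_error(beta_spectrum(e_max = -1), "invalid spectrum")
})

test_that("transport displacement scales inversely with density", {
  sp <- beta_spectrum()
  m1 <- material_spec("unit", 1.0, 0)
  m2 <- material_spec("double", 2.0, 0)
  a <- transport_positrons(sp, m1, n = 2e4, seed = 3)
  b <- transport_positrons(sp, m2, n = 2e4, seed = 3)
  ra <- mean(sqrt(rowSums(a$displacements^2)))
  rb <- mean(sqrt(rowSums(b$displacements^2)))
  expect_lt(abs(rb / ra - 0.5), 0.02 * 0.5)
  # density-scaled water model: same seed means exact rescaling
  expect_equal(b$displacements, a$displacements / 2, tolerance = 1e-12)
})

test_that("transport is seed-deterministic and bounded by the CSDA endpoint range", {
  sp <- beta_spectrum()
  w <- default_materials()$water
  a <- transport_positrons(sp, w, n = 500, seed = 9)
  b <- transport_positrons(sp, w, n = 500, seed = 9)
  expect_identical(a$displacements, b$displacements)
  mag <- sqrt(rowSums(a$displacements^2))
  expect_true(all(mag <= csda_range_water(sp$e_max) * 10 + 1e-9))
  expect_error(transport_positrons(sp, list(density = -1), n = 10),
               "material")
})

test_that("water 99.9th-percentile displacement is near the water kernel sizing range", {
  ep <- transport_positrons(beta_spectrum(), default_materials()$water,
                            n = 1e5, seed = 2024)
  p999 <- unname(stats::quantile(sqrt(rowSums(ep$displacements^2)), 0.999))
  expect_lt(abs(p999 - 8.8), 0.20 * 8.8)
})

test_that("kernel half-width rule reproduces the per-tissue kernel sizes", {
  expect_identical(kernel_half_width(8.8, 2.73), 3L)   # 7 per axis
  expect_identical(kernel_half_width(32.3, 2.73), 12L) # 25 per axis
  expect_identical(kernel_half_width(4.5, 2.73), 2L)   # 5 per axis
  expect_identical(kernel_half_width(0, 2.73), 0L)
  # consistent with the axial pitch too
  expect_identical(kernel_half_width(8.8, 2.80), 3L)
  expect_error(kernel_half_width(-1, 2.73), "max_range")
  expect_error(kernel_half_width(1, 0), "voxel_size")
})

test_that("build_kernel bins, normalizes to exactly 1 and reports truncation", {
  # all displacements zero -> discrete delta
  ep0 <- structure(list(displacements = matrix(0, 100, 3), n_events = 100L,
                        seed = 1L, material = default_materials()$water,
                        spectrum = beta_spectrum()),
                   class = "annihilation_endpoints")
  k0 <- build_kernel(ep0, c(2.73, 2.73, 2.80), max_range = 8.8)
  expect_equal(dim(k0$weights), c(7, 7, 7))
  expect_equal(k0$weights[4, 4, 4], 1)
  expect_equal(sum(k0$weights), 1, tolerance = 1e-12)

  k <- cached_water_kernel()
  expect_equal(dim(k$weights), c(7, 7, 7))
  expect_equal(sum(k$weights), 1, tolerance = 1e-12)
  expect_gte(k$truncated_fraction, 0)
  expect_lt(k$truncated_fraction, 0.05)

  ep_empty <- ep0; ep_empty$displacements <- matrix(0, 0, 3)
  expect_error(build_kernel(ep_empty, c(2.73, 2.73, 2.80), 8.8), "empty")
})

test_that("kernels are point-symmetric within Monte Carlo error", {
  k <- cached_water_kernel()
  w <- k$weights
  d <- dim(w)
  wf <- w[d[1]:1, d[2]:1, d[3]:1]
  # pooled MC standard error of the mirrored-pair difference, with a
  # small-count floor (corner voxels hold only a handful of events)
  se_diff <- sqrt((w + wf) / k$n_events)
  expect_true(all(abs(w - wf) <= 4 * se_diff + 4 / k$n_events))
})

test_that("kernel FWHM ordering follows tissue density: lung > water > bone", {
  ks <- make_kernel_set(n_decays = 3e4, seed = 55L)
  f <- vapply(ks, kernel_fwhm, numeric(1))
  expect_gt(f[["lung"]], f[["water"]])
  expect_gt(f[["water"]], f[["bone"]])
  expect_equal(dim(ks$lung$weights)[1], 25L)
  expect_equal(dim(ks$water$weights)[1], 7L)
  expect_equal(dim(ks$bone$weights)[1], 5L)
})

test_that("radial profile is a proper CDF and matches the endpoint-magnitude CDF", {
  k0 <- delta_kernel()
  p0 <- radial_profile(k0)
  expect_equal(p0$radius_mm, 0)
  expect_equal(p0$cdf, 1)

  ep <- transport_positrons(beta_spectrum(), default_materials()$water,
                            n = 2e4, seed = 321L + 0L)
  k <- cached_water_kernel()
  p <- radial_profile(k)
  expect_true(all(diff(p$cdf) >= -1e-12))
  expect_equal(p$cdf[nrow(p)], 1, tolerance = 1e-12)

  # endpoint-CDF oracle: empirical CDF of raw magnitudes at mid radii agrees
  # within binning error (half a voxel diagonal) and truncation
  ep <- transport_positrons(beta_spectrum(), default_materials()$water,
                            n = 2e4, seed = 321L)
  mag <- sqrt(rowSums(ep$displacements^2))
  half_diag <- sqrt(sum(k$voxel_size^2)) / 2
  for (r in c(3, 5, 7)) {
    kcdf <- max(p$cdf[p$radius_mm <= r])
    lo <- mean(mag <= r - half_diag) - 0.02
    hi <- mean(mag <= r + half_diag) + 0.02
    expect_gte(kcdf, lo)
    expect_lte(kcdf, hi)
  }
})

test_that("kernel text round-trip preserves weights and metadata", {
  k <- cached_water_kernel()
  stem <- file.path(withr::local_tempdir(), "water")
  write_kernel(k, stem)
  k2 <- read_kernel(stem)
  expect_equal(k2$weights, k$weights, tolerance = 1e-12)
  expect_equal(k2$voxel_size, k$voxel_size)
  expect_equal(k2$material$name, "water")
  expect_equal(k2$max_range, k$max_range)
})
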