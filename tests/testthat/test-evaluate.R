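grid_vol <- function(shape = c(24L, 24L, 12L), vx = c(2.73, 2.73, 2.80),
                     value = 0) {
  activity_volume(array(value, shape), vx, -(shape - 1) / 2 * vx)
}

test_that("Gaussian post-filter preserves counts, is the identity at fwhm 0, and has the stated FWHM", {
  set.seed(30)
  # interior support: the 6 mm blur spans ~9 voxels, so keep that margin
  vol <- grid_vol(c(40L, 40L, 30L), value = 0)
  vol$data[16:24, 16:24, 12:18] <- stats::runif(9 * 9 * 7) + 1
  expect_identical(gaussian_postfilter(vol, 0)$data, vol$data)
  sm <- gaussian_postfilter(vol, 6.0)
  expect_lt(abs(sum(sm$data) - sum(vol$data)) / sum(vol$data), 1e-8)

  # point source profile FWHM ~ 6.0 mm +/- half a voxel
  ps <- grid_vol(c(33L, 33L, 17L), c(2, 2, 2))
  ps$data[17, 17, 9] <- 1
  f <- gaussian_postfilter(ps, 6.0)
  prof <- f$data[, 17, 9]
  half <- max(prof) / 2
  x <- (seq_len(33) - 17) * 2
  above <- range(which(prof >= half))
  interp <- function(i, j) {
    x[i] + (prof[i] - half) / (prof[i] - prof[j]) * (x[j] - x[i])
  }
  measured <- interp(above[2], above[2] + 1) - interp(above[1], above[1] - 1)
  expect_lt(abs(measured - 6.0), 1.0)
})

test_that("spherical VOI matches the supersampling count and rejects bad centres", {
  vol <- grid_vol()
  v <- spherical_voi(c(1.1, -0.7, 0.9), 5.0, vol)
  f <- 10L
  sub <- expand.grid(x = seq(-6, 6, by = 2.73 / f),
                     y = seq(-6, 6, by = 2.73 / f),
                     z = seq(-6, 6, by = 2.80 / f))
  frac <- mean(sub$x^2 + sub$y^2 + sub$z^2 <= 25)
  vol_ss <- frac * 12 * 12 * 12
  expect_lt(abs(v$volume_mm3 - vol_ss), 2 * prod(vol$voxel_size))
  # radius below half a voxel at a voxel centre -> single voxel
  vol <- grid_vol()
  at_voxel <- vol$origin + (c(12, 12, 6) - 1) * vol$voxel_size
  v1 <- spherical_voi(at_voxel, 1.0, vol)
  expect_length(v1$indices, 1L)
  expect_error(spherical_voi(c(1e3, 0, 0), 5, vol), "outside")
})

test_that("isocontour VOI selects the seeded 50% component only", {
  vol <- grid_vol(c(40L, 20L, 1L), c(2, 2, 2))
  xs <- (seq_len(40) - 10) * 2
  ys <- (seq_len(20) - 10) * 2
  # two Gaussian blobs, one seeded
  for (i in 1:40) for (j in 1:20) {
    vol$data[i, j, 1] <- exp(-((xs[i])^2 + ys[j]^2) / (2 * 9)) +
      0.8 * exp(-((xs[i] - 40)^2 + ys[j]^2) / (2 * 9))
  }
  seed_world <- c(0, 0, 0) + vol$origin + c(9, 9, 0) * vol$voxel_size
  v <- isocontour_voi(vol, seed_world, 0.5)
  pts <- arrayInd(v$indices, dim(vol$data))
  # only the first blob: all member x-indices well left of the second peak
  expect_true(all(pts[, 1] < 25))
  expect_gt(length(v$indices), 3)
  # symmetric blob gives a VOI symmetric about the peak in y
  expect_equal(sort(unique(pts[, 2] - 10)), sort(unique(10 - pts[, 2])))

  # single hot voxel -> that voxel only
  hot <- grid_vol(c(9L, 9L, 3L), c(2, 2, 2))
  hot$data[5, 5, 2] <- 1
  vh <- isocontour_voi(hot, c(0, 0, 0), 0.5)
  expect_length(vh$indices, 1L)
})

test_that("background VOI respects the distance and volume rules", {
  vol <- grid_vol(c(32L, 32L, 16L), value = 1)
  set.seed(41)
  vol$data <- vol$data + 0.05 * array(stats::rnorm(length(vol$data)),
                                      dim(vol$data))
  vol$data <- pmax(vol$data, 0)
  lv <- spherical_voi(c(0, 0, 0), 5.0, vol)
  bv <- background_voi(lv, vol, min_volume = 10, min_distance = 5)
  expect_gte(bv$volume_mm3, 10)
  expect_length(intersect(bv$indices, lv$indices), 0L)
  # every background voxel is > 5 mm from every lesion voxel
  d <- dim(vol$data)
  les <- arrayInd(lv$indices, d)
  bg <- arrayInd(bv$indices, d)
  to_mm <- function(m) sweep(sweep(m - 1, 2, vol$voxel_size, "*"), 2,
                             vol$origin, "+")
  les_mm <- to_mm(les); bg_mm <- to_mm(bg)
  mind <- apply(bg_mm, 1, function(p) sqrt(min(rowSums(sweep(les_mm, 2, p)^2))))
  expect_true(all(mind > 5))
  # homogeneous background recovered within noise
  expect_lt(abs(mean(vol$data[bv$indices]) - 1), 0.05)
})

test_that("lesion metrics implement the CNR and recovery formulas exactly", {
  vol <- grid_vol(c(16L, 16L, 8L), value = 1)
  lv <- spherical_voi(c(0, 0, 0), 5, vol)
  bv <- background_voi(lv, vol, min_distance = 5)
  vol$data[lv$indices] <- 3
  # force a known background sd
  set.seed(7)
  vol$data[bv$indices] <- 1 + c(-0.5, 0.5, rep(0, length(bv$indices) - 2))
  mb <- mean(vol$data[bv$indices]); sb <- stats::sd(vol$data[bv$indices])
  m <- lesion_metrics(vol, lv, bv, true_activity = 3)
  expect_equal(m$cnr, (3 - mb) / sb)
  expect_equal(m$activity_recovery, 100)
  expect_equal(m$suv_max, 3)
  # mean lesion == mean background -> CNR 0
  vol2 <- grid_vol(c(16L, 16L, 8L), value = 1)
  set.seed(8)
  vol2$data[bv$indices] <- 1 + 0.1 * stats::rnorm(length(bv$indices))
  vol2$data[lv$indices] <- mean(vol2$data[bv$indices])
  expect_equal(lesion_metrics(vol2, lv, bv)$cnr, 0, tolerance = 1e-12)
})

test_that("CNR is invariant under affine intensity maps with positive scale", {
  vol <- grid_vol(c(16L, 16L, 8L), value = 1)
  set.seed(9)
  vol$data <- vol$data + 0.1 * array(stats::rnorm(length(vol$data)),
                                     dim(vol$data))
  lv <- spherical_voi(c(0, 0, 0), 5, vol)
  bv <- background_voi(lv, vol)
  vol$data[lv$indices] <- vol$data[lv$indices] + 2
  c1 <- lesion_metrics(vol, lv, bv)$cnr
  vol2 <- vol; vol2$data <- 3.7 * vol$data + 0.9
  c2 <- lesion_metrics(vol2, lv, bv)$cnr
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("half-split noise SD matches the Gaussian oracle and guards its inputs", {
  vol1 <- grid_vol(c(24L, 24L, 12L))
  vol2 <- grid_vol(c(24L, 24L, 12L))
  set.seed(10)
  sigma <- 0.4
  vol1$data[] <- 5 + sigma * stats::rnorm(length(vol1$data))
  vol2$data[] <- 5 + sigma * stats::rnorm(length(vol2$data))
  v <- spherical_voi(c(0, 0, 0), 14, vol1)
  s <- half_split_noise_sd(vol1, vol2, v)
  n <- length(v$indices)
  expect_lt(abs(s - sigma * sqrt(2)), 4 * sigma * sqrt(2) / sqrt(2 * (n - 1)))
  expect_equal(half_split_noise_sd(vol1, vol1, v), 0)
  v1 <- v; v1$indices <- v$indices[1]
  expect_error(half_split_noise_sd(vol1, vol2, v1), "at least 2")
})

test_that("lesion inclusion rules drop large lesions and cap five per tissue", {
  m <- tibble::tibble(
    lesion_id = sprintf("l%02d", 1:10),
    patient_id = "p1",
    tissue_class = c(rep("bone", 7), rep("lung", 3)),
    volume_cm3 = c(12, 6, 5, 4, 3, 2, 1, 0.5, 11, 2))
  out <- filter_lesions(m)
  expect_false(any(out$volume_cm3 > 10))
  expect_equal(sum(out$tissue_class == "bone"), 5L)  # 6 small bone, keep largest 5
  expect_equal(sum(out$tissue_class == "lung"), 2L)
  # kept bone lesions are the largest remaining ones
  expect_setequal(out$volume_cm3[out$tissue_class == "bone"], c(6, 5, 4, 3, 2))
  expect_identical(nrow(filter_lesions(m[0, ])), 0L)
})
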