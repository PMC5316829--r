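test_that("constant volumes segment to zero vacuoles (strict inequality)", {
  v <- voxel_volume(array(7, c(16, 16, 8)), c(90, 90, 150))
  lab <- segment_vacuoles(v, percentile = 55)
  expect_identical(attr(lab, "n_components"), 0L)
  expect_error(segment_vacuoles(v, percentile = 0), "\\(0, 100\\)")
})

test_that("bright vacuoles on a dim-tubule background segment exactly", {
  # vacuolated-state acquisition: the trapped dye is drawn into the
  # vacuoles and the tubule signal sits at the background level
  spec <- vacuolated_spec(3L)
  g <- generate_tsys_volume(spec, seed = 31)
  lab <- segment_vacuoles(g$volume, percentile = 55)
  expect_identical(attr(lab, "n_components"), 3L)
  vol_meas <- sum(lab > 0)
  vol_truth <- sum(g$truth$vacuole_mask)
  expect_lt(abs(vol_meas - vol_truth) / vol_truth, 0.1)

  # raising the percentile never increases the segmented volume
  vols <- vapply(c(40, 55, 70, 90, 99.9), function(p)
    sum(segment_vacuoles(g$volume, percentile = p) > 0), 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("speckle noise is removed by the minimum-size filter", {
  spec <- vacuolated_spec(2L)
  g <- generate_tsys_volume(spec, seed = 33)
  arr <- g$volume$data
  # sparse single-voxel dark counts above threshold
  set.seed(33)
  idx <- which(g$volume$fibre_mask & arr <= 0.1)
  arr[sample(idx, 200)] <- 0.9
  noisy <- voxel_volume(arr, spec$voxel_size,
                        fibre_mask = g$volume$fibre_mask)
  lab <- segment_vacuoles(noisy, percentile = 55)
  expect_identical(attr(lab, "n_components"), 2L)
})

test_that("roundness follows the per-plane inverse aspect ratio", {
  vs <- c(90, 90, 90)
  d <- c(48L, 48L, 48L)
  mk <- function(semi) {
    idx <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
    ell <- ((idx$x - 24) / semi[1])^2 + ((idx$y - 24) / semi[2])^2 +
      ((idx$z - 24) / semi[3])^2 <= 1
    array(as.integer(ell), d)
  }
  # digital sphere
  r_sph <- vacuole_roundness(mk(c(10, 10, 10)), vs)
  expect_equal(r_sph$roundness, 1, tolerance = 0.05)
  # 2:1 in-plane ellipsoid
  r_ell <- vacuole_roundness(mk(c(20, 10, 8)), vs)
  expect_equal(r_ell$roundness, 0.5, tolerance = 0.05)
  # needle along z: circular cross-sections, roundness ~1 despite
  # elongation (documents the strictly 2D convention)
  needle <- array(0L, d)
  needle[22:26, 22:26, 4:44] <- 0L
  idx <- expand.grid(x = 1:d[1], y = 1:d[2])
  disc <- matrix(((idx$x - 24)^2 + (idx$y - 24)^2) <= 16, d[1], d[2])
  for (z in 4:44) needle[, , z] <- as.integer(disc)
  r_needle <- vacuole_roundness(needle, vs)
  expect_equal(r_needle$roundness, 1, tolerance = 0.05)
})

test_that("vacuole summary reports fraction, count and density", {
  spec <- tiny_spec(vacuole_count = 7L, vacuole_series_length = 2L,
                    tubule_intensity = 0, background = 0.1)
  g <- generate_tsys_volume(spec, seed = 41)
  lab <- segment_vacuoles(g$volume, percentile = 55)
  tab <- vacuole_summary(lab, g$volume$fibre_mask, spec$voxel_size)
  s <- attr(tab, "summary")
  expect_identical(s$vacuole_count, nrow(tab))
  # measured fraction within 0.5 percentage points of phantom truth
  expect_lt(abs(s$volume_fraction - g$truth$vacuole_volume_fraction), 0.5)
  expect_true(all(tab$roundness > 0 & tab$roundness <= 1))
  # summary is recomputable from the rows
  expect_equal(s$volume_fraction,
               100 * sum(tab$voxel_count) / sum(g$volume$fibre_mask))
  expect_error(vacuole_summary(lab, array(FALSE, dim(lab)),
                               spec$voxel_size), "empty")
})

test_that("count density scales linearly with vacuole count", {
  mk <- function(n, seed) {
    spec <- tiny_spec(vacuole_count = n, vacuole_series_length = 2L,
                      tubule_intensity = 0, background = 0.1)
    g <- generate_tsys_volume(spec, seed = seed)
    lab <- segment_vacuoles(g$volume, percentile = 55)
    attr(vacuole_summary(lab, g$volume$fibre_mask, spec$voxel_size),
         "summary")
  }
  s3 <- mk(3L, 51)
  s6 <- mk(6L, 52)
  ratio <- s6$count_density_per_1000um3 / s3$count_density_per_1000um3
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("volume fractions 0.5-5% are recovered within 15%", {
  for (i in 1:10) {
    n <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 2L, 4L, 6L)[i]  # ~0.7-5% of volume
    spec <- tiny_spec(vacuole_count = n, vacuole_series_length = 2L,
                      tubule_intensity = 0, background = 0.1)
    g <- generate_tsys_volume(spec, seed = 60 + i)
    truth_frac <- g$truth$vacuole_volume_fraction
    lab <- segment_vacuoles(g$volume, percentile = 55)
    s <- attr(vacuole_summary(lab, g$volume$fibre_mask, spec$voxel_size),
              "summary")
    expect_lt(abs(s$volume_fraction - truth_frac) / truth_frac, 0.15)
    expect_identical(s$vacuole_count, g$truth$vacuole_count)
  }
})

test_that("physical metrics are invariant to isotropic voxel relabelling", {
  spec <- vacuolated_spec(2L)
  g <- generate_tsys_volume(spec, seed = 71)
  lab <- segment_vacuoles(g$volume, percentile = 55)
  t1 <- vacuole_summary(lab, g$volume$fibre_mask, spec$voxel_size)
  t2 <- vacuole_summary(lab, g$volume$fibre_mask, spec$voxel_size * 2)
  s1 <- attr(t1, "summary"); s2 <- attr(t2, "summary")
  expect_equal(s1$volume_fraction, s2$volume_fraction)
  expect_equal(t1$roundness, t2$roundness, tolerance = 1e-12)
  expect_equal(t2$volume_um3, t1$volume_um3 * 8, tolerance = 1e-12)
})

test_that("cylinder geometry: tenfold diameter means hundredfold volume", {
  v1 <- tubule_cylinder_volume(0.1, 2)
  v10 <- tubule_cylinder_volume(1.0, 2)
  expect_equal(v10 / v1, 100, tolerance = 1e-12)
  expect_error(tubule_cylinder_volume(-1, 1), ">= 0")
})
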