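test_that("binarization contracts hold", {
  expect_error(binarize_tubules(array(5, c(8, 8, 8))), "constant")
  # binary input passes through unchanged
  b <- array(0, c(8, 8, 8)); b[3:5, 3:5, 3:5] <- 1
  out <- binarize_tubules(b)
  expect_identical(out & TRUE, b > 0)
  expect_identical(attr(out, "method"), "binary-passthrough")
  expect_error(binarize_tubules(array(c(NA, 1:7), c(2, 2, 2))), "finite")
})

test_that("Otsu binarization recovers the phantom tubule fraction within 30%", {
  spec <- small_spec()
  g <- generate_tsys_volume(spec, seed = 4)
  p <- gaussian_psf(voxel_size = spec$voxel_size)
  img <- simulate_imaging(g$volume, p, noise_model = spec$noise_model,
                          seed = 5)
  dec <- richardson_lucy(img, p, iterations = 25)
  mask <- binarize_tubules(dec, "otsu")
  truth_frac <- mean(g$truth$tsys_mask)
  expect_lt(abs(mean(mask) - truth_frac) / truth_frac, 0.3)
})

test_that("a straight cylinder skeletonizes to its analytic centreline", {
  vs <- c(90, 90, 150)
  m <- cylinder_mask(c(24L, 40L, 24L), radius = 2.5)
  sk <- skeletonize(m, vs, prune_spurs = 0L)
  expect_true(sk$border_touching)
  # all skeleton voxels lie inside the mask
  expect_true(all(m[sk$skeleton_mask]))
  # one dominant segment whose polyline hugs the central axis
  lens <- vapply(sk$segments, function(s) s$n, 0L)
  main <- sk$segments[[which.max(lens)]]
  expect_gt(main$n, 30)
  ctr_x <- (12 - 0.5) * vs[1]
  ctr_z <- (12 - 0.5) * vs[3]
  dev_x <- max(abs(main$points[, 1] - ctr_x)) / vs[1]
  dev_z <- max(abs(main$points[, 3] - ctr_z)) / vs[3]
  expect_lt(dev_x, 1)
  expect_lt(dev_z, 1)
})

test_that("crossing cylinders produce a branch node near the intersection", {
  vs <- c(90, 90, 90)
  d <- c(40L, 40L, 9L)
  m <- array(FALSE, d)
  m[, 19:21, 4:6] <- TRUE   # bar along x
  m[19:21, , 4:6] <- TRUE   # bar along y
  sk <- skeletonize(m, vs, prune_spurs = 0L)
  expect_gte(length(sk$segments), 3L)
  ctr <- c(20, 20, 5) * vs
  ends <- do.call(rbind, lapply(sk$segments, function(s)
    rbind(s$points[1, ], s$points[nrow(s$points), ])))
  d_end <- sqrt(rowSums(sweep(ends, 2, ctr)^2))
  # at least three segment endpoints meet near the crossing
  expect_gte(sum(d_end < 3 * vs[1]), 3L)
  expect_error(skeletonize(array(FALSE, c(8, 8, 8)), vs), "empty")
})

test_that("segments classify by chord angle with the stated tie break", {
  mk_seg <- function(p0, p1) list(points = rbind(p0, p1), n = 2L)
  skel <- structure(list(segments = list(
    mk_seg(c(0, 0, 0), c(0, 1000, 0)),      # along fibre axis -> 90 deg
    mk_seg(c(0, 0, 0), c(1000, 0, 500)),    # in transverse plane -> 0 deg
    mk_seg(c(0, 0, 0), c(1000, 1000, 0))),  # exactly 45 deg
    voxel_size = c(90, 90, 150), dim = c(32L, 32L, 32L),
    border_touching = FALSE), class = "skeleton")
  out <- classify_segments(skel, angle_threshold = 45)
  th <- vapply(out$segments, function(s) s$theta, 0)
  lab <- vapply(out$segments, function(s) s$label, "")
  expect_equal(th, c(90, 0, 45), tolerance = 1e-10)
  expect_identical(lab, c("longitudinal", "transverse", "longitudinal"))
})

test_that("thinning preserves connected-component count on phantom masks", {
  g <- generate_tsys_volume(tiny_spec(), seed = 9)
  m <- g$truth$tsys_mask
  d <- dim(m)
  before <- max(tsysquant:::label3d_cpp(as.logical(m), as.integer(d)))
  sk <- skeletonize(m, tiny_spec()$voxel_size, prune_spurs = 0L,
                    min_component_voxels = 1L)
  after <- max(tsysquant:::label3d_cpp(as.logical(sk$skeleton_mask),
                                       as.integer(d)))
  expect_identical(before, after)
  expect_true(all(m[sk$skeleton_mask]))
})

test_that("directionality histogram concentrates stripes at 0 degrees", {
  m <- stripe_image()
  h <- directionality_histogram(m, n_bins = 18L)
  expect_equal(sum(h$percent), 100, tolerance = 1e-6)
  near0 <- h$percent[h$bin_start_deg < 10]
  expect_gte(sum(near0), 80)
  # rotating the image by 90 degrees moves the mass to 90 degrees
  h90 <- directionality_histogram(rotate90(m), n_bins = 18L)
  near90 <- h90$percent[h90$bin_end_deg > 80]
  expect_gte(sum(near90), 80)
  expect_equal(sum(h90$percent), 100, tolerance = 1e-6)
  expect_equal(h$percent, rev(h90$percent), tolerance = 1e-9)
  expect_error(directionality_histogram(matrix(1, 32, 32)), "constant")
  expect_error(directionality_histogram(m, n_bins = 3L), ">= 4")
})

test_that("isotropic noise gives a near-uniform directionality histogram", {
  n_bins <- 12L
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(runif(128 * 128), 128, 128)
    h <- directionality_histogram(m, n_bins = n_bins)
    expect_lt(max(h$percent), 3 * 100 / n_bins)
  }
})

test_that("radial profile recovers the peripheral bias of longitudinal tubules", {
  # tiny fibres hit the lattice floor (the central cross) before the
  # budget, so give the phantom enough tubular volume for longitudinal
  # tubules to be allocated
  spec <- tiny_spec(target_tsys_volume_fraction = 2.5,
                    longitudinal_fraction = 0.4)
  outer_minus_inner <- 0
  for (s in 1:5) {
    g <- generate_tsys_volume(spec, seed = 100 + s)
    sk <- classify_segments(skeletonize(g$truth$tsys_mask, spec$voxel_size,
                                        prune_spurs = 0L))
    pr <- longitudinal_radial_profile(sk, g$truth$fibre_centre_nm,
                                      g$truth$fibre_radius_nm, n_shells = 4L)
    outer_minus_inner <- outer_minus_inner +
      (pr$density[4] - pr$density[1])
  }
  expect_gt(outer_minus_inner, 0)
})

test_that("uniform longitudinal placement gives a flat radial profile", {
  # null simulation: exponent 0 places tubules uniformly per unit area,
  # so shell densities agree up to Monte-Carlo error (pooled, 10 seeds)
  spec <- tiny_spec(target_tsys_volume_fraction = 2.5,
                    longitudinal_exponent = 0, longitudinal_fraction = 0.5)
  len <- rep(0, 4)
  for (s in 1:10) {
    g <- generate_tsys_volume(spec, seed = 200 + s)
    sk <- classify_segments(skeletonize(g$truth$tsys_mask, spec$voxel_size,
                                        prune_spurs = 0L))
    pr <- longitudinal_radial_profile(sk, g$truth$fibre_centre_nm,
                                      g$truth$fibre_radius_nm, n_shells = 4L)
    len <- len + pr$length_nm
  }
  dens <- len / diff(seq(0, 1, length.out = 5)^2)
  expect_lt(max(dens) / min(dens), 2.5)
})

test_that("zero longitudinal tubules give an all-zero radial profile", {
  spec <- tiny_spec(longitudinal_fraction = 0)
  g <- generate_tsys_volume(spec, seed = 5)
  sk <- classify_segments(skeletonize(g$truth$tsys_mask, spec$voxel_size,
                                      prune_spurs = 0L))
  pr <- longitudinal_radial_profile(sk, g$truth$fibre_centre_nm,
                                    g$truth$fibre_radius_nm)
  expect_true(all(pr$density == 0))
})

test_that("fibre axis estimation finds the y axis of a phantom", {
  g <- generate_tsys_volume(tiny_spec(longitudinal_fraction = 0), seed = 3)
  ax <- estimate_fibre_axis(g$volume)
  expect_gt(abs(ax[2]), 0.99)
})
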