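test_that("transverse lattice places two planes per sarcomere at A-I offsets", {
  spec <- phantom_spec(fibre_radius = 1.2, fibre_length = 20,
                       sarcomere_length = 2, vacuole_count = 0,
                       dim = c(40L, 224L, 24L))
  g <- generate_tsys_volume(spec, seed = 3)
  expect_identical(g$truth$n_transverse_planes, 20L)
  expect_equal(g$truth$vacuole_volume_fraction, 0)
  expect_identical(g$truth$vacuole_count, 0L)
})

test_that("tubular volume fraction matches the target by voxel counting", {
  spec <- phantom_spec()  # target 1.0% of fibre volume
  g <- generate_tsys_volume(spec, seed = 1)
  # independent brute-force voxel count against the rendered masks
  n_fibre <- sum(g$volume$fibre_mask)
  frac <- 100 * sum(g$truth$tubule_mask & g$volume$fibre_mask) / n_fibre
  expect_equal(frac, g$truth$tubule_volume_fraction, tolerance = 1e-12)
  expect_lt(abs(frac - 1.0), 0.1)
})

test_that("phantom truth masks are consistent label sets", {
  g <- generate_tsys_volume(tiny_spec(vacuole_count = 4L), seed = 7)
  tr <- g$truth
  expect_false(any(tr$tubule_mask & tr$vacuole_mask))
  expect_identical(tr$tsys_mask, tr$tubule_mask | tr$vacuole_mask)
  n_fibre <- sum(g$volume$fibre_mask)
  expect_equal(tr$vacuole_volume_fraction,
               100 * sum(tr$vacuole_mask) / n_fibre)
  expect_gt(tr$vacuole_count, 0L)
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_tsys_volume(tiny_spec(vacuole_count = 2L), seed = 11)
  b <- generate_tsys_volume(tiny_spec(vacuole_count = 2L), seed = 11)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$segments, b$truth$segments)
  c <- generate_tsys_volume(tiny_spec(vacuole_count = 2L), seed = 12)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(fibre_radius = -1), "positive")
  expect_error(phantom_spec(target_tsys_volume_fraction = 0), "\\(0, 100\\)")
  expect_error(phantom_spec(vacuole_count = 1, vacuole_axes = c(5, 5, 5)),
               "fibre radius")
  expect_error(phantom_spec(vacuole_count = 1,
                            vacuole_axes = c(0.05, 0.9, 0.9)),
               "tubule_width")
  expect_warning(generate_tsys_volume(tiny_spec(tubule_width = 50), seed = 1),
                 "1 voxel wide")
})

test_that("bead stacks render detectable point sources", {
  spec <- tiny_spec()
  p <- gaussian_psf(voxel_size = spec$voxel_size)
  st <- generate_bead_stack(15, 100, p, spec = spec, amplitude = 10,
                            noise = FALSE, seed = 5)
  # 15 well-separated local maxima above half the global peak
  lab <- tsysquant:::label3d_cpp(as.logical(st$data > 0.3 * max(st$data)),
                                 dim(st$data))
  expect_identical(max(lab), 15L)
  expect_identical(nrow(attr(st, "bead_centres_vox")), 15L)

  # a single bead through an identity kernel is a single bright voxel
  st1 <- generate_bead_stack(1, 100, identity_psf(spec$voxel_size),
                             spec = spec, amplitude = 7, noise = FALSE,
                             subvoxel = FALSE, seed = 5)
  expect_identical(sum(st1$data > 0), 1L)
  expect_equal(max(st1$data), 7)

  # bead FWHM matches the Gaussian closed form 2.355 sigma
  sig <- c(120, 120, 240)
  pg <- gaussian_psf(sig, spec$voxel_size)
  stg <- generate_bead_stack(5, 100, pg, spec = spec, amplitude = 10,
                             noise = FALSE, subvoxel = FALSE, seed = 9)
  ctr <- attr(stg, "bead_centres_vox")[1, ]
  prof <- stg$data[, ctr[2], ctr[3]]
  fw <- tsysquant:::profile_fwhm(prof, spacing = spec$voxel_size[1])
  expect_lt(abs(fw - 2.3548 * sig[1]) / (2.3548 * sig[1]), 0.1)

  expect_error(generate_bead_stack(500, 100, p, spec = spec),
               "separation|too small")
})

test_that("simulate_imaging follows the forward model contracts", {
  spec <- tiny_spec()
  g <- generate_tsys_volume(spec, seed = 2)
  idp <- identity_psf(spec$voxel_size)
  out <- simulate_imaging(g$volume, idp)
  expect_identical(out$data, g$volume$data)

  p <- gaussian_psf(voxel_size = spec$voxel_size)
  # structures near the volume border gain/lose a little mass under the
  # reflective boundary; conservation holds to well under 0.5%
  blurred <- simulate_imaging(g$volume, p)
  expect_equal(sum(blurred$data), sum(g$volume$data), tolerance = 5e-3)

  # away from the border, conservation is exact to float tolerance
  dv <- delta_volume()
  bl <- apply_psf(dv, p)
  expect_equal(sum(bl), sum(dv), tolerance = 1e-9)
  expect_lt(max(bl), max(dv))

  big <- psf(array(1 / 27, c(3, 3, 3)), spec$voxel_size)
  expect_error(apply_psf(array(1, c(2, 2, 2)), big), "larger")
})

test_that("noise draws are reproducible under a fixed seed", {
  spec <- tiny_spec()
  g <- generate_tsys_volume(spec, seed = 2)
  p <- gaussian_psf(voxel_size = spec$voxel_size)
  a <- simulate_imaging(g$volume, p, noise_model = spec$noise_model, seed = 4)
  b <- simulate_imaging(g$volume, p, noise_model = spec$noise_model, seed = 4)
  expect_identical(a$data, b$data)
  c <- simulate_imaging(g$volume, p, noise_model = spec$noise_model, seed = 5)
  expect_false(identical(a$data, c$data))
})
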