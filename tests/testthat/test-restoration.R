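test_that("PSF estimation recovers the blurring kernel from bead stacks", {
  spec <- tiny_spec()
  sig <- c(150, 150, 250)
  p_true <- gaussian_psf(sig, spec$voxel_size)
  st <- generate_bead_stack(15, 100, p_true, spec = spec, amplitude = 50,
                            noise = FALSE, subvoxel = FALSE, seed = 21)
  est <- estimate_psf(st, half_size = c(4L, 4L, 5L))
  expect_s3_class(est, "psf")
  expect_identical(est$provenance, "estimated")
  expect_equal(sum(est$kernel), 1, tolerance = 1e-12)
  expect_true(all(est$kernel >= 0))
  # noise-free identical beads: the average equals one bead normalized,
  # i.e. the true kernel restricted to the window
  fw_x <- psf_fwhm(est, 1)
  fw_z <- psf_fwhm(est, 3)
  expect_lt(abs(fw_x - 2.3548 * sig[1]) / (2.3548 * sig[1]), 0.1)
  expect_lt(abs(fw_z - 2.3548 * sig[3]) / (2.3548 * sig[3]), 0.1)

  # with noise on, the estimate is still close in width
  stn <- generate_bead_stack(15, 100, p_true, spec = spec, amplitude = 50,
                             noise = TRUE, seed = 22)
  estn <- estimate_psf(stn)
  expect_lt(abs(psf_fwhm(estn, 1) - 2.3548 * sig[1]) / (2.3548 * sig[1]), 0.1)
})

test_that("PSF estimation errors and exclusions", {
  spec <- tiny_spec()
  empty <- voxel_volume(array(0, c(32, 32, 16)), spec$voxel_size)
  expect_error(estimate_psf(empty), "no beads")
  expect_error(estimate_psf(list()), "no bead stacks")

  # two overlapping beads plus one isolated: overlappers are excluded
  p_true <- gaussian_psf(voxel_size = spec$voxel_size)
  a <- array(0, c(48, 48, 24))
  # two beads far enough apart to detect separately but with
  # overlapping extraction windows, plus one isolated bead
  a[10, 10, 12] <- 50; a[18, 10, 12] <- 50; a[36, 36, 12] <- 50
  st <- voxel_volume(apply_psf(a, p_true), spec$voxel_size)
  expect_warning(est <- estimate_psf(st), "excluded")
  expect_identical(attr(est, "n_beads"), 1L)
})

test_that("Richardson-Lucy honours its fixed points", {
  spec <- tiny_spec()
  g <- generate_tsys_volume(spec, seed = 2)
  # identity PSF: exact fixed point for any iteration count
  out <- richardson_lucy(g$volume, identity_psf(spec$voxel_size),
                         iterations = 10)
  expect_identical(out$data, g$volume$data)
  # constant volume: fixed point of any unit-sum kernel (float path)
  const <- array(3.7, c(24, 24, 16))
  p <- gaussian_psf(voxel_size = spec$voxel_size)
  outc <- richardson_lucy(const, p, iterations = 5)
  expect_equal(as.numeric(outc), rep(3.7, length(const)), tolerance = 1e-5)
})

test_that("Richardson-Lucy input validation", {
  p <- gaussian_psf(voxel_size = c(90, 90, 150))
  bad <- array(1, c(16, 16, 16)); bad[1] <- NaN
  expect_error(richardson_lucy(bad, p), "NaN")
  expect_error(richardson_lucy(array(1, c(16, 16, 16)), p, iterations = 0),
               ">= 1")
  k <- p$kernel * 2
  attr_psf <- p; attr_psf$kernel <- k
  expect_warning(richardson_lucy(array(1, c(16, 16, 16)), attr_psf,
                                 iterations = 1),
                 "normaliz")
})

test_that("deconvolving a blurred delta sharpens monotonically in place", {
  vs <- c(90, 90, 150)
  p <- gaussian_psf(c(150, 150, 250), vs)
  dv <- delta_volume(c(32L, 32L, 32L), value = 1000)
  blurred <- apply_psf(dv, p)
  peaks <- numeric(0)
  logliks <- numeric(0)
  pos <- NULL
  for (it in c(1, 5, 10, 25)) {
    est <- richardson_lucy(blurred, p, iterations = it)
    peaks <- c(peaks, max(est))
    logliks <- c(logliks, tsysquant:::rl_loglik(blurred, est, p))
    pos <- rbind(pos, which(est == max(est), arr.ind = TRUE)[1, ])
    expect_true(all(est >= 0))
  }
  expect_true(all(diff(peaks) > 0))
  expect_lt(max(peaks), 1001)
  # Poisson log-likelihood of the re-blurred estimate is non-decreasing
  # (tolerance for the single-precision convolution path)
  expect_true(all(diff(logliks) > -1e-6 * abs(logliks[-length(logliks)])))
  # peak stays put
  expect_true(all(pos[, 1] == 16 & pos[, 2] == 16 & pos[, 3] == 16))
  # total intensity conserved within 0.5%
  est25 <- richardson_lucy(blurred, p, iterations = 25)
  expect_lt(abs(sum(est25) - sum(blurred)) / sum(blurred), 0.005)
})

test_that("restoration improves tubule contrast on the phantom", {
  spec <- tiny_spec()
  g <- generate_tsys_volume(spec, seed = 6)
  p <- gaussian_psf(voxel_size = spec$voxel_size)
  img <- simulate_imaging(g$volume, p, noise_model = spec$noise_model,
                          seed = 7)
  dec <- richardson_lucy(img, p, iterations = 10)
  tub <- g$truth$tubule_mask
  bg <- g$volume$fibre_mask & !g$truth$tsys_mask
  contrast <- function(v) mean(v$data[tub]) / max(mean(v$data[bg]), 1e-9)
  expect_gt(contrast(dec), contrast(img))
})

test_that("early stopping halts when the iterate stabilizes", {
  vs <- c(90, 90, 150)
  p <- gaussian_psf(c(150, 150, 250), vs)
  blurred <- apply_psf(delta_volume(c(24L, 24L, 24L)), p)
  out <- richardson_lucy(blurred, p, iterations = 200, stop_tol = 1e-2)
  expect_lt(attr(out, "rl_iterations"), 200)
})
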