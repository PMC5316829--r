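cal <- calibration_params(K_D = 0.8, F_min = 100, F_max = 1100)

test_that("the calibration relationship hits its analytic anchors", {
  expect_equal(calibrate(100, cal), 0)
  # half-saturation returns the dissociation constant (0.8 mM)
  expect_equal(calibrate(600, cal), 0.8, tolerance = 1e-12)
  # hand evaluation: Fmin 0, Fmax 1000, F 800, K_D 0.8 -> 3.2 mM
  c2 <- calibration_params(0.8, 0, 1000)
  expect_equal(calibrate(800, c2), 3.2, tolerance = 1e-12)
})

test_that("calibration guards against saturation and bad ranges", {
  expect_error(calibrate(1100, cal), "F_max")
  expect_error(calibrate(2000, cal), "F_max")
  expect_error(calibrate(70, cal), "below F_min")
  expect_equal(calibrate(85, cal), 0)  # small undershoot clamps to zero
  expect_error(calibration_params(F_min = 10, F_max = 10), "exceed")
  expect_error(calibration_params(K_D = 0), "positive")
})

test_that("calcium-to-fluorescence round trips are analytic", {
  ca <- seq(0, 8, by = 0.05)   # up to 10 K_D
  back <- calibrate(ca_to_fluorescence(ca, cal), cal)
  expect_equal(back, ca, tolerance = 1e-9)
  f <- seq(100, 1050, by = 1)
  expect_true(all(diff(calibrate(f, cal)) > 0))  # strictly increasing
})

test_that("flux derivation is exact on constants and linear ramps", {
  tt <- seq(0, 80, by = 0.8)
  trc <- structure(data.frame(time_s = tt, ca_mM = rep(1.2, length(tt))),
                   class = c("calcium_trace", "data.frame"))
  fx <- derive_flux(trc)
  expect_true(all(abs(fx$flux$flux_mM_per_s) < 1e-12))
  ramp <- structure(data.frame(time_s = tt, ca_mM = 0.5 + 0.013 * tt),
                    class = c("calcium_trace", "data.frame"))
  fr <- derive_flux(ramp, B = 1)
  expect_equal(fr$flux$flux_mM_per_s, rep(0.013, length(tt)),
               tolerance = 1e-10)
  fr2 <- derive_flux(ramp, B = 2.5)
  expect_equal(fr2$flux$flux_mM_per_s, rep(2.5 * 0.013, length(tt)),
               tolerance = 1e-10)
  expect_error(derive_flux(ramp[1:3, ]), "5 samples")
})

test_that("peak fluxes are recovered from a simulated protocol", {
  sp <- sample_protocol(7)
  sim <- simulate_ca_protocol(sp$protocol, sp$params, noise_sd = 2,
                              seed = 7)
  ca <- calibrate(sim$trace)
  fx <- derive_flux(ca, B = sp$params$buffering_B)
  eps <- sim$truth$epochs
  true_peak <- eps[[3]]$peak_flux_tt
  expect_rel_error(fx$peak_uptake, true_peak, 0.1)
  expect_lte(fx$peak_soce, 0)
  expect_identical(fx$peak_uptake_epoch, "uptake")
  expect_identical(fx$peak_soce_epoch, "caffeine")
  # per-fibre-volume rescaling is a pure unit change
  fx2 <- derive_flux(ca, per_fibre_volume = 1.4)
  expect_equal(fx2$peak_uptake_per_fibre_uM_s,
               fx2$peak_uptake * 14, tolerance = 1e-12)
})

test_that("steady_state averages the epoch tail and flags drifts", {
  tt <- seq(0.8, 160, by = 0.8)
  lab <- rep(c("a", "b"), each = length(tt) / 2)
  trc <- structure(data.frame(time_s = tt, ca_mM = c(
    rep(1.4, length(tt) / 2),
    1.0 - exp(-seq_len(length(tt) / 2) * 0.8 / 10))),
    class = c("calcium_trace", "data.frame"))
  trc$epoch_label <- lab
  v <- steady_state(trc, "a")
  expect_equal(as.numeric(v), 1.4)
  expect_false(attr(v, "unsteady"))
  # saturating exponential with the tail at plateau: within 2%
  v2 <- steady_state(trc, "b")
  expect_rel_error(as.numeric(v2), 1.0, 0.02)
  # ramp epoch: value returned but flagged unsteady
  trc$ca_mM[lab == "b"] <- seq(0, 2, length.out = sum(lab == "b"))
  v3 <- steady_state(trc, "b")
  expect_true(attr(v3, "unsteady"))
  expect_error(steady_state(trc, "missing"), "not present")
  expect_error(steady_state(trc, "a", tail_fraction = 0), "\\(0, 1\\]")
})

test_that("SOCE regression reproduces exact generating lines", {
  x <- c(0.1, 0.4, 0.8, 1.2, 1.6)
  y <- -0.42 * x + 0.19
  r <- soce_regression(x, y)
  expect_equal(r$slope, -0.42, tolerance = 1e-12)
  expect_equal(r$intercept, 0.19, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  r2 <- soce_regression(c(0.2, 1.0), c(0.3, -0.1))
  expect_equal(r2$slope, -0.5, tolerance = 1e-12)
  expect_equal(r2$r2, 1)
  r3 <- soce_regression(c(0.2, 0.6, 1.0), c(0.4, 0.4, 0.4))
  expect_equal(r3$slope, 0, tolerance = 1e-12)
  expect_error(soce_regression(c(0.5, 0.5), c(1, 2)), "distinct")
})

test_that("the calcium budget is exact and linear", {
  # luminal calcium x volume fraction: 1.4 mM in 1.4% of fibre = 19.6 uM
  expect_equal(calcium_budget(1, 1.4, 1.4)$content, 19.6, tolerance = 1e-12)
  expect_equal(calcium_budget(1, 1.5, 4.8)$content, 72.0, tolerance = 1e-12)
  expect_equal(calcium_budget(1, 1.5, 4.4)$content, 66.0, tolerance = 1e-12)
  expect_equal(calcium_budget(1, 2.0, 0)$content, 0)
  # exact linearity in each argument
  b0 <- calcium_budget(1, 1.4, 1.4)$content
  expect_equal(calcium_budget(3, 1.4, 1.4)$content, 3 * b0)
  expect_equal(calcium_budget(1, 2.8, 1.4)$content, 2 * b0)
  expect_equal(calcium_budget(1, 1.4, 2.8)$content, 2 * b0)
  expect_error(calcium_budget(1, -0.1, 1), "non-negative")
})

test_that("vacuolation raises the t-system calcium content over fivefold", {
  pre <- calcium_budget(1, 1.4, 1.0)    # unvacuolated volume is 1.0%
  post <- calcium_budget(1, 1.5, 4.8)
  fc <- budget_fold_change(pre, post)
  expect_equal(fc, 72 / 14, tolerance = 1e-12)
  expect_gt(fc, 5)
  expect_equal(budget_fold_change(pre, pre), 1)
  expect_equal(budget_fold_change(pre, calcium_budget(1, 0, 4.8)), 0)
  expect_error(budget_fold_change(calcium_budget(1, 0, 1), post),
               "positive")
})
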