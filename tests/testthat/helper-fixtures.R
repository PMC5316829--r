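# Shared fixtures: everything is generated in code at test time.

# small, fast phantom: ~1/4-scale grid, 2 sarcomeres across the fibre
tiny_spec <- function(...) {
  phantom_spec(fibre_radius = 1.8, fibre_length = 5.76,
               dim = c(64L, 64L, 32L), ...)
}

# mid-size phantom for imaging-chain tests
small_spec <- function(...) {
  phantom_spec(fibre_radius = 2.7, fibre_length = 11.52,
               dim = c(96L, 128L, 48L), ...)
}

# vacuolated-state phantom: trapped dye drawn into vacuoles, the tubule
# dye below the detection floor (signal indistinguishable from the
# diffuse background)
vacuolated_spec <- function(vacuole_count, ...) {
  tiny_spec(vacuole_count = vacuole_count, vacuole_series_length = 2L,
            tubule_intensity = 0, background = 0.1,
            vacuole_intensity = 0.9, ...)
}

# solid cylinder mask along the y axis; the default centre is on a voxel
# so the cross-section has odd width and a voxel-aligned medial axis
cylinder_mask <- function(d = c(32L, 32L, 32L), radius = 2,
                          centre = floor(d[c(1, 3)] / 2), axis = "y") {
  a <- array(FALSE, d)
  ix <- seq_len(d[1]); iz <- seq_len(d[3])
  cs <- outer((ix - centre[1])^2, (iz - centre[2])^2, `+`) <= radius^2
  for (j in seq_len(d[2])) a[, j, ] <- cs
  a
}

# delta volume with a centred spike
delta_volume <- function(d = c(32L, 32L, 32L), value = 100) {
  a <- array(0, d)
  a[(d[1] + 1) %/% 2, (d[2] + 1) %/% 2, (d[3] + 1) %/% 2] <- value
  a
}

# horizontal stripe image: lines along dim1 (the transverse direction)
stripe_image <- function(n = 96L, period = 8L, width = 2L) {
  m <- matrix(0, n, n)
  m[, (seq_len(n) %% period) < width] <- 1
  m
}

rotate90 <- function(m) t(m[nrow(m):1, ])

expect_rel_error <- function(x, target, tol) {
  expect_lt(abs(x - target) / abs(target), tol)
}
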