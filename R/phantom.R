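#' Phantom specification
#'
#' Describes a synthetic muscle-fibre t-system phantom: a straight
#' cylindrical fibre aligned with the y (long image) axis carrying two
#' transverse tubule lattices per sarcomere at the A-I junction positions,
#' peripherally biased longitudinal tubules, and optional vacuole series.
#'
#' Lengths are in micrometres except `tubule_width` and `voxel_size`,
#' which are in nm. `vacuole_axes` are full ellipsoid diameters (x, y, z).
#'
#' @param fibre_radius fibre radius, um.
#' @param fibre_length fibre length along y, um.
#' @param sarcomere_length sarcomere length, um (default 2).
#' @param tubule_width rendered tubule diameter, nm. Tubules narrower than
#'   one voxel are rendered one voxel wide (with a warning at generation).
#' @param target_tsys_volume_fraction target tubular (non-vacuole) volume
#'   as % of fibre volume; the transverse lattice pitch is calibrated so
#'   the rendered mask meets this target (default 1.0, the unvacuolated
#'   t-system volume).
#' @param longitudinal_exponent radial placement exponent k; longitudinal
#'   tubule density is proportional to (r/R)^k, concentrating them at the
#'   fibre periphery (default 4).
#' @param longitudinal_fraction fraction of the tubular volume budget
#'   assigned to longitudinal tubules (default 0.15).
#' @param vacuole_count number of vacuoles (default 0, the pre-exercise
#'   state).
#' @param vacuole_axes vacuole diameters (x, y, z) in um; vacuoles are
#'   0.8-1 um across, well above the confocal resolution limit.
#' @param vacuole_series_length number of sarcomeres spanned by one
#'   longitudinal series of vacuoles.
#' @param voxel_size voxel size in nm; structural imaging requires
#'   dx = dy <= 90 and dz <= 150.
#' @param noise_model list with `photon_scale` (Poisson photon count at
#'   unit intensity) and `read_sd` (additive Gaussian read noise, in
#'   normalized intensity units).
#' @param tubule_pitch optional fixed transverse-lattice pitch in um
#'   (~1 um encircles myofibril cross-sections); `NULL` calibrates the
#'   pitch against `target_tsys_volume_fraction`.
#' @param tubule_intensity,vacuole_intensity,background rendered
#'   intensities (arbitrary units in [0, 1]). In heavily vacuolated fibres
#'   the trapped dye is drawn into the vacuoles and the tubule signal
#'   falls to the background level; emulate that state with
#'   `tubule_intensity = background`.
#' @param dim voxel grid dimensions (nx, ny, nz).
#' @param rng_seed integer seed used by [generate_tsys_volume()] when no
#'   explicit seed is given.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(fibre_radius = 4.2,
                         fibre_length = 23.04,
                         sarcomere_length = 2,
                         tubule_width = 100,
                         target_tsys_volume_fraction = 1.0,
                         longitudinal_exponent = 4,
                         longitudinal_fraction = 0.15,
                         vacuole_count = 0L,
                         vacuole_axes = c(0.9, 1.0, 0.9),
                         vacuole_series_length = 5L,
                         voxel_size = c(90, 90, 150),
                         noise_model = list(photon_scale = 500, read_sd = 0),
                         tubule_pitch = NULL,
                         tubule_intensity = 0.5,
                         vacuole_intensity = 1.0,
                         background = 0,
                         dim = c(256L, 256L, 64L),
                         rng_seed = 1L) {
  spec <- list(fibre_radius = fibre_radius, fibre_length = fibre_length,
               sarcomere_length = sarcomere_length, tubule_width = tubule_width,
               target_tsys_volume_fraction = target_tsys_volume_fraction,
               longitudinal_exponent = longitudinal_exponent,
               longitudinal_fraction = longitudinal_fraction,
               vacuole_count = as.integer(vacuole_count),
               vacuole_axes = vacuole_axes,
               vacuole_series_length = as.integer(vacuole_series_length),
               voxel_size = as.numeric(voxel_size),
               noise_model = noise_model, tubule_pitch = tubule_pitch,
               tubule_intensity = tubule_intensity,
               vacuole_intensity = vacuole_intensity,
               background = background,
               dim = as.integer(dim), rng_seed = rng_seed)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  lens <- c(s$fibre_radius, s$fibre_length, s$sarcomere_length,
            s$tubule_width, s$vacuole_axes, s$voxel_size)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive")
  if (s$target_tsys_volume_fraction <= 0 || s$target_tsys_volume_fraction >= 100)
    stop("target_tsys_volume_fraction must be in (0, 100)")
  if (abs(s$voxel_size[1] - s$voxel_size[2]) > 1e-9)
    stop("voxel dx and dy must be equal")
  if (s$vacuole_count > 0) {
    if (any(s$vacuole_axes * 1000 < s$tubule_width))
      stop("vacuole axes must each be >= tubule_width")
    if (any(s$vacuole_axes > s$fibre_radius))
      stop("vacuole axes exceed the fibre radius")
  }
  if (s$longitudinal_fraction < 0 || s$longitudinal_fraction >= 1)
    stop("longitudinal_fraction must be in [0, 1)")
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> fibre R=%g um, L=%g um, SL=%g um, ",
                     "t-sys target %.2f%%, %d vacuole(s), grid %s\n"),
              x$fibre_radius, x$fibre_length, x$sarcomere_length,
              x$target_tsys_volume_fraction, x$vacuole_count,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# Transverse-lattice cross-section (x-z plane) at a given pitch: a grid of
# tubules encircling ~pitch-sized myofibril cross-sections, clipped to the
# fibre circle. Returns a logical nx x nz matrix.
lattice_cross_section <- function(spec, pitch, geom) {
  w_um <- max(spec$tubule_width, spec$voxel_size[1]) / 1000
  # at least half a voxel spacing so every line renders >= 1 voxel wide,
  # including lines falling exactly midway between voxel centres
  half_x <- max(w_um / 2, geom$dxu / 2 + 1e-9)
  half_z <- max(w_um / 2, geom$dzu / 2 + 1e-9)
  xk <- abs(geom$X - geom$cx - pitch * round((geom$X - geom$cx) / pitch))
  zk <- abs(geom$Z - geom$cz - pitch * round((geom$Z - geom$cz) / pitch))
  list(mask = geom$cross & (xk <= half_x | zk <= half_z),
       # lines at constant x extend along z: their voxels each represent
       # dz (not dx) of tubule length, so they carry proportionally more
       # dye to keep the rendered dye mass per unit length uniform
       along_z = geom$cross & (xk <= half_x))
}

phantom_geometry <- function(spec) {
  d <- spec$dim
  dxu <- spec$voxel_size[1] / 1000
  dyu <- spec$voxel_size[2] / 1000
  dzu <- spec$voxel_size[3] / 1000
  xc <- (seq_len(d[1]) - 0.5) * dxu
  yc <- (seq_len(d[2]) - 0.5) * dyu
  zc <- (seq_len(d[3]) - 0.5) * dzu
  cx <- d[1] * dxu / 2
  cz <- d[3] * dzu / 2
  X <- matrix(xc, d[1], d[3])
  Z <- matrix(zc, d[1], d[3], byrow = TRUE)
  cross <- (X - cx)^2 + (Z - cz)^2 <= spec$fibre_radius^2
  list(d = d, dxu = dxu, dyu = dyu, dzu = dzu, xc = xc, yc = yc, zc = zc,
       cx = cx, cz = cz, X = X, Z = Z, cross = cross)
}

#' Generate a synthetic t-system volume with ground truth
#'
#' Renders the fibre described by a [phantom_spec()]: two transverse
#' tubule lattice planes per sarcomere at the A-I junction positions
#' (offsets 0.25 and 0.75 of the sarcomere), longitudinal tubules placed
#' with peripheral radial bias, and vacuole ellipsoids arranged in
#' longitudinal series. The transverse lattice pitch is calibrated by
#' bisection so that the tubular volume fraction (by exact voxel count)
#' matches the spec target.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed (defaults to `spec$rng_seed`). Identical spec
#'   and seed give bit-identical output.
#' @return a list with elements `volume` (a [voxel_volume()] with fibre
#'   mask) and `truth`, the ground truth: `segments` (list of centreline
#'   polylines in nm with transverse/longitudinal labels), `tsys_mask`,
#'   `tubule_mask` and `vacuole_mask` (disjoint label sets whose union is
#'   `tsys_mask`), and the voxel-counted `tubule_volume_fraction`,
#'   `vacuole_volume_fraction` and `vacuole_count`.
#' @export
generate_tsys_volume <- function(spec, seed = spec$rng_seed) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    g <- phantom_geometry(spec)
    d <- g$d
    vs <- spec$voxel_size

    if (spec$tubule_width < vs[1])
      warning("tubule_width is below one voxel; rendering tubules 1 voxel wide")

    nsarc <- floor(spec$fibre_length / spec$sarcomere_length + 1e-9)
    y_planes <- as.vector(outer(c(0.25, 0.75), seq_len(nsarc) - 1, `+`)) *
      spec$sarcomere_length
    y_planes <- sort(y_planes[y_planes < d[2] * g$dyu])
    wy_vox <- max(1L, round(spec$tubule_width / vs[2]))
    plane_iy <- lapply(y_planes, function(yp) {
      i0 <- 1L + floor(yp / g$dyu)
      iy <- i0 + seq_len(wy_vox) - 1L - (wy_vox %/% 2L)
      iy[iy >= 1L & iy <= d[2]]
    })

    fibre_mask <- array(rep(g$cross, d[2]), c(d[1], d[3], d[2]))
    fibre_mask <- aperm(fibre_mask, c(1, 3, 2))
    n_fibre <- sum(g$cross) * d[2]
    target_total <- spec$target_tsys_volume_fraction / 100 * n_fibre
    target_trans <- target_total * (1 - spec$longitudinal_fraction)
    n_plane_vox <- sum(lengths(plane_iy))

    # calibrate the lattice pitch against the transverse voxel budget
    if (is.null(spec$tubule_pitch)) {
      count_at <- function(p)
        sum(lattice_cross_section(spec, p, g)$mask) * n_plane_vox
      lo <- 0.4; hi <- 8
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (count_at(mid) > target_trans) lo <- mid else hi <- mid
      }
      # take the undershooting bound: the voxel-count jumps at pitch
      # changes are coarse, and longitudinal tubules (fine-grained) top
      # the budget up to the target
      pitch <- hi
    } else pitch <- spec$tubule_pitch

    lat_cs <- lattice_cross_section(spec, pitch, g)
    lat <- lat_cs$mask
    tubule_mask <- array(FALSE, d)
    for (iy in plane_iy) for (j in iy)
      tubule_mask[, j, ] <- tubule_mask[, j, ] | lat
    along_z <- array(FALSE, d)
    for (iy in plane_iy) for (j in iy)
      along_z[, j, ] <- along_z[, j, ] | lat_cs$along_z

    # ground-truth transverse segments: full lattice chords across the fibre
    segments <- list()
    R <- spec$fibre_radius
    line_centres <- function(c0, extent)
      c0 + pitch * seq(ceiling((-R) / pitch), floor(R / pitch))
    for (yp in y_planes) {
      y_nm <- yp * 1000
      for (sx in line_centres(0)) {       # lines at constant x, running in z
        if (abs(sx) >= R) next
        dz <- sqrt(R^2 - sx^2)
        segments[[length(segments) + 1L]] <- list(
          points = rbind(c((g$cx + sx) * 1000, y_nm, (g$cz - dz) * 1000),
                         c((g$cx + sx) * 1000, y_nm, (g$cz + dz) * 1000)),
          label = "transverse")
      }
      for (sz in line_centres(0)) {       # lines at constant z, running in x
        if (abs(sz) >= R) next
        dx <- sqrt(R^2 - sz^2)
        segments[[length(segments) + 1L]] <- list(
          points = rbind(c((g$cx - dx) * 1000, y_nm, (g$cz + sz) * 1000),
                         c((g$cx + dx) * 1000, y_nm, (g$cz + sz) * 1000)),
          label = "transverse")
      }
    }

    # longitudinal tubules: radial density ~ (r/R)^k, spanning whole
    # sarcomeres between transverse planes; added until the total tubular
    # budget is met
    wx_vox <- max(1L, round(spec$tubule_width / vs[1]))
    wz_vox <- max(1L, round(spec$tubule_width / vs[3]))
    n_tub <- sum(tubule_mask)
    k <- spec$longitudinal_exponent
    margin <- max(spec$tubule_width / 1000, 2 * g$dxu)
    R_eff <- R - margin
    guard <- 0L
    while (spec$longitudinal_fraction > 0 && n_tub < target_total &&
           guard < 10000L && nsarc >= 1) {
      guard <- guard + 1L
      r <- R_eff * runif(1)^(1 / (k + 2))
      phi <- runif(1, 0, 2 * pi)
      x0 <- g$cx + r * cos(phi)
      z0 <- g$cz + r * sin(phi)
      len_s <- min(1L + stats::rgeom(1, 0.6), nsarc)
      s0 <- sample.int(max(1L, nsarc - len_s + 1L), 1L) - 1L
      ya <- (s0 + 0.25) * spec$sarcomere_length
      yb <- (s0 + len_s + 0.25 - 1) * spec$sarcomere_length +
        0.5 * spec$sarcomere_length
      iy <- which(g$yc >= ya & g$yc <= yb)
      if (length(iy) < 2L) next
      ix0 <- 1L + floor(x0 / g$dxu); iz0 <- 1L + floor(z0 / g$dzu)
      ix <- ix0 + seq_len(wx_vox) - 1L - (wx_vox %/% 2L)
      iz <- iz0 + seq_len(wz_vox) - 1L - (wz_vox %/% 2L)
      ix <- ix[ix >= 1L & ix <= d[1]]; iz <- iz[iz >= 1L & iz <= d[3]]
      before <- sum(tubule_mask[ix, iy, iz])
      tubule_mask[ix, iy, iz] <- TRUE
      n_tub <- n_tub + length(ix) * length(iy) * length(iz) - before
      segments[[length(segments) + 1L]] <- list(
        points = rbind(c(x0 * 1000, ya * 1000, z0 * 1000),
                       c(x0 * 1000, yb * 1000, z0 * 1000)),
        label = "longitudinal")
    }

    # vacuoles: ellipsoids in longitudinal series at peripheral positions
    vac_mask <- array(FALSE, d)
    n_vac_placed <- 0L
    if (spec$vacuole_count > 0) {
      semi <- spec$vacuole_axes / 2
      per_series <- max(1L, spec$vacuole_series_length)
      remaining <- spec$vacuole_count
      max_sarc_start <- max(0L, nsarc - per_series)
      placed_xz <- matrix(numeric(0), 0, 2)
      min_sep <- 2.1 * max(semi[1], semi[3])
      while (remaining > 0L) {
        n_here <- min(per_series, remaining)
        rmax <- R - max(semi[1], semi[3]) - margin
        x0 <- z0 <- NA_real_
        for (try in 1:200) {   # keep series laterally separated
          r <- max(0, rmax) * runif(1)^(1 / (k + 2))
          phi <- runif(1, 0, 2 * pi)
          xc <- g$cx + r * cos(phi)
          zc <- g$cz + r * sin(phi)
          if (!nrow(placed_xz) ||
              all(sqrt((placed_xz[, 1] - xc)^2 +
                         (placed_xz[, 2] - zc)^2) >= min_sep)) {
            x0 <- xc; z0 <- zc
            break
          }
        }
        if (is.na(x0)) { x0 <- xc; z0 <- zc }  # crowded: accept overlap
        placed_xz <- rbind(placed_xz, c(x0, z0))
        s0 <- sample.int(max_sarc_start + 1L, 1L) - 1L
        for (j in seq_len(n_here)) {
          y0 <- (s0 + j - 0.5) * spec$sarcomere_length
          if (y0 + semi[2] > d[2] * g$dyu) next
          ix <- which(abs(g$xc - x0) <= semi[1])
          iy <- which(abs(g$yc - y0) <= semi[2])
          iz <- which(abs(g$zc - z0) <= semi[3])
          if (!length(ix) || !length(iy) || !length(iz)) next
          ell <- outer(outer(((g$xc[ix] - x0) / semi[1])^2,
                             ((g$yc[iy] - y0) / semi[2])^2, `+`),
                       ((g$zc[iz] - z0) / semi[3])^2, `+`) <= 1
          sub <- vac_mask[ix, iy, iz]
          vac_mask[ix, iy, iz] <- sub | ell
          n_vac_placed <- n_vac_placed + 1L
        }
        remaining <- remaining - n_here
      }
    }

    # vacuoles and tubules are disjoint label sets within the t-sys union
    tubule_mask <- tubule_mask & !vac_mask
    tsys_mask <- tubule_mask | vac_mask
    # count by connected components so touching ellipsoids (if placement
    # was crowded) are not over-counted
    if (n_vac_placed > 0L)
      n_vac_placed <- max(label3d_cpp(as.logical(vac_mask), d))

    # intensity = diffuse background + dye contrast; the per-length dye
    # normalization (voxels on z-extended lines represent dz of tubule)
    # scales the dye term only, so zero-dye tubules stay at background
    intensity <- array(0, d)
    intensity[fibre_mask] <- spec$background
    zfac <- vs[3] / vs[1]
    intensity[tubule_mask] <- spec$background + spec$tubule_intensity
    intensity[tubule_mask & along_z] <-
      spec$background + spec$tubule_intensity * zfac
    intensity[vac_mask] <- spec$background + spec$vacuole_intensity

    truth <- list(
      segments = segments,
      tsys_mask = tsys_mask,
      tubule_mask = tubule_mask,
      vacuole_mask = vac_mask,
      tubule_volume_fraction = 100 * sum(tubule_mask) / n_fibre,
      vacuole_volume_fraction = 100 * sum(vac_mask) / n_fibre,
      vacuole_count = n_vac_placed,
      n_transverse_planes = length(y_planes),
      pitch = pitch,
      fibre_centre_nm = c(g$cx, NA, g$cz) * 1000,
      fibre_radius_nm = R * 1000)

    list(volume = voxel_volume(intensity, vs, fibre_mask = fibre_mask),
         truth = truth)
  })
}

#' Simulate confocal imaging of a volume
#'
#' Forward imaging model: convolution with the PSF followed by scaled
#' Poisson photon noise and additive Gaussian read noise. With an identity
#' PSF and no noise the output equals the input. Intensities are clipped
#' to the 16-bit range only on TIFF export, never internally.
#'
#' @param volume a `voxel_volume` or 3D array.
#' @param p a `psf`, normalized to unit sum.
#' @param noise_model `NULL` (noise off) or a list with `photon_scale`
#'   (expected photon count at unit intensity; Poisson) and `read_sd`
#'   (Gaussian read noise sd in intensity units).
#' @param seed optional RNG seed for the noise draw.
#' @return imaged volume, same type as `volume`.
#' @export
simulate_imaging <- function(volume, p, noise_model = NULL, seed = NULL) {
  s <- sum(p$kernel)
  if (abs(s - 1) > 1e-6) stop("PSF must be normalized to unit sum")
  out <- apply_psf(volume, p)
  if (!is.null(noise_model)) {
    arr <- if (inherits(out, "voxel_volume")) out$data else out
    arr <- with_seed(seed, {
      sc <- noise_model$photon_scale
      a <- if (!is.null(sc) && sc > 0)
        array(rpois(length(arr), pmax(arr, 0) * sc) / sc, dim(arr))
      else arr
      rs <- noise_model$read_sd
      if (!is.null(rs) && rs > 0)
        a <- a + array(rnorm(length(a), 0, rs), dim(a))
      a
    })
    if (inherits(out, "voxel_volume")) out$data <- arr else out <- arr
  }
  out
}

#' Generate a synthetic bead stack
#'
#' Places `n_beads` sub-voxel point sources (polystyrene microsphere
#' surrogates) with at least two PSF widths of separation, convolves with
#' the true PSF and optionally adds noise. Used to exercise PSF
#' estimation; the true bead centres are returned for ground truth.
#'
#' @param n_beads number of beads (>= 1).
#' @param bead_diameter bead diameter in nm (100 nm beads are below one
#'   voxel and treated as point sources).
#' @param psf_truth the true `psf` to blur with.
#' @param spec a `phantom_spec` providing voxel size, grid and noise model.
#' @param amplitude peak source intensity per bead.
#' @param noise apply the spec's noise model.
#' @param subvoxel place beads at sub-voxel positions (default); set
#'   FALSE to snap beads to voxel centres (exact delta sources).
#' @param seed RNG seed.
#' @return a `voxel_volume` with attribute `bead_centres_vox` (fractional
#'   voxel coordinates, one row per bead).
#' @export
generate_bead_stack <- function(n_beads, bead_diameter = 100, psf_truth,
                                spec = phantom_spec(), amplitude = 1,
                                noise = TRUE, subvoxel = TRUE,
                                seed = spec$rng_seed) {
  if (n_beads < 1) stop("n_beads must be >= 1")
  d <- spec$dim
  vs <- spec$voxel_size
  with_seed(seed, {
    fw <- sapply(1:3, function(a) psf_fwhm(psf_truth, a))
    fw[!is.finite(fw)] <- vs[!is.finite(fw)]
    min_sep_vox <- 2 * fw / vs      # two PSF widths, per-axis, in voxels
    kh <- (dim(psf_truth$kernel) - 1) / 2
    pad <- kh + 2
    if (any(d - 2 * pad <= 1)) stop("volume too small to place beads")
    centres <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(centres) < n_beads) {
      tries <- tries + 1L
      if (tries > 2000L * n_beads)
        stop("volume too small to place ", n_beads,
             " beads with the required separation")
      cand <- runif(3, pad + 1, d - pad)
      ok <- TRUE
      if (nrow(centres) > 0) {
        rel <- abs(sweep(centres, 2, cand))
        ok <- all(apply(sweep(rel, 2, min_sep_vox, `/`), 1, max) >= 1)
      }
      if (ok) centres <- rbind(centres, cand)
    }
    if (!subvoxel) centres <- round(centres)
    vol <- array(0, d)
    for (i in seq_len(nrow(centres))) {
      c0 <- floor(centres[i, ])
      fr <- centres[i, ] - c0
      for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
        w <- prod(ifelse(c(ox, oy, oz) == 1, fr, 1 - fr))
        vol[c0[1] + ox, c0[2] + oy, c0[3] + oz] <-
          vol[c0[1] + ox, c0[2] + oy, c0[3] + oz] + amplitude * w
      }
    }
    out <- apply_psf(vol, psf_truth)
    if (noise) {
      nm <- spec$noise_model
      out <- simulate_imaging(out, identity_psf(vs), noise_model = nm)
    }
    v <- voxel_volume(out, vs)
    attr(v, "bead_centres_vox") <- centres
    v
  })
}
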