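#' Point spread function
#'
#' Container for a 3D point spread function (PSF): a non-negative kernel
#' with unit sum, centred on its peak voxel, with the voxel spacing it was
#' sampled at and a provenance tag (`"estimated"` from bead stacks or
#' `"synthetic"`).
#'
#' @param kernel numeric 3D array with odd dimensions; negatives are not
#'   allowed and the kernel is normalized to unit sum (with a warning if it
#'   was not already).
#' @param voxel_size voxel size in nm (dx, dy, dz).
#' @param provenance `"estimated"` or `"synthetic"`.
#' @return an object of class `psf`.
#' @export
psf <- function(kernel, voxel_size, provenance = c("synthetic", "estimated")) {
  provenance <- match.arg(provenance)
  if (length(dim(kernel)) != 3L) stop("PSF kernel must be a 3D array")
  if (any(dim(kernel) %% 2L == 0L)) stop("PSF kernel dimensions must be odd")
  if (any(!is.finite(kernel))) stop("PSF kernel contains non-finite values")
  if (any(kernel < 0)) stop("PSF kernel must be non-negative")
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel sums to zero")
  if (abs(s - 1) > 1e-8) {
    warning("PSF kernel not unit-sum; normalizing")
    kernel <- kernel / s
  }
  structure(list(kernel = kernel, voxel_size = as.numeric(voxel_size),
                 provenance = provenance),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<psf> %d x %d x %d (%s), voxel %g x %g x %g nm\n",
              d[1], d[2], d[3], x$provenance,
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Synthetic Gaussian PSF
#'
#' Confocal-like anisotropic Gaussian PSF sampled on the voxel grid.
#'
#' @param sigma_nm Gaussian standard deviation in nm per axis (x, y, z).
#'   The default approximates a high-NA confocal system (~250 nm lateral,
#'   ~600 nm axial FWHM).
#' @param voxel_size voxel size in nm.
#' @param half_size optional integer half-widths of the kernel per axis;
#'   defaults to ~2.5 sigma in voxels.
#' @return a `psf` with provenance `"synthetic"`.
#' @export
gaussian_psf <- function(sigma_nm = c(106, 106, 255), voxel_size = c(90, 90, 150),
                         half_size = NULL) {
  sv <- sigma_nm / voxel_size
  if (is.null(half_size)) half_size <- pmax(1L, ceiling(2.5 * sv))
  ax <- lapply(1:3, function(i) seq(-half_size[i], half_size[i]))
  k <- exp(-outer(outer(ax[[1]]^2 / (2 * sv[1]^2),
                        ax[[2]]^2 / (2 * sv[2]^2), `+`),
                  ax[[3]]^2 / (2 * sv[3]^2), `+`))
  psf(k / sum(k), voxel_size, provenance = "synthetic")
}

#' Identity (delta) PSF
#' @param voxel_size voxel size in nm.
#' @return a 1x1x1 `psf` that leaves volumes unchanged.
#' @export
identity_psf <- function(voxel_size = c(90, 90, 150)) {
  psf(array(1, c(1, 1, 1)), voxel_size, provenance = "synthetic")
}

# Convert a PSF kernel into a pruned tap list for spatial convolution.
# Taps below `prune` * max are dropped and the rest renormalized; this
# bounds the cost of direct convolution with negligible mass loss.
psf_taps <- function(kernel, prune = 1e-4, flip = FALSE) {
  d <- dim(kernel)
  ctr <- (d + 1L) %/% 2L
  keep <- which(kernel > prune * max(kernel), arr.ind = TRUE)
  w <- kernel[keep]
  taps <- sweep(keep, 2L, ctr)
  if (flip) taps <- -taps
  list(taps = matrix(as.integer(taps), ncol = 3L), w = w / sum(w))
}

# Resample a PSF kernel onto a different voxel grid by trilinear
# interpolation (the volume itself is never resampled).
resample_psf <- function(p, voxel_size) {
  if (all(abs(p$voxel_size - voxel_size) < 1e-9)) return(p)
  d <- dim(p$kernel)
  ctr <- (d + 1) / 2
  half_nm <- (d - 1) / 2 * p$voxel_size
  half_new <- pmax(1L, floor(half_nm / voxel_size))
  ax <- lapply(1:3, function(i) seq(-half_new[i], half_new[i]) *
                 voxel_size[i] / p$voxel_size[i] + ctr[i])
  gg <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  k <- array(trilinear_sample(p$kernel, gg$x, gg$y, gg$z), 2L * half_new + 1L)
  k[k < 0] <- 0
  psf(k / sum(k), voxel_size, provenance = p$provenance)
}

#' Convolve a volume with a PSF
#'
#' Direct spatial convolution with reflective boundary padding. This is the
#' forward model used both by the imaging simulator and inside
#' Richardson-Lucy iterations.
#'
#' @param volume a `voxel_volume` or 3D array.
#' @param p a `psf` (resampled to the volume's grid if spacings differ).
#' @param flip convolve with the spatially flipped kernel (the adjoint
#'   operation used in the Richardson-Lucy update).
#' @param prune relative tap pruning threshold.
#' @return object of the same type as `volume`.
#' @export
apply_psf <- function(volume, p, flip = FALSE, prune = 1e-4) {
  arr <- if (inherits(volume, "voxel_volume")) volume$data else volume
  if (inherits(volume, "voxel_volume")) p <- resample_psf(p, volume$voxel_size)
  if (any(dim(p$kernel) > dim(arr)))
    stop("PSF kernel is larger than the volume")
  tp <- psf_taps(p$kernel, prune = prune, flip = flip)
  out <- conv3_taps_cpp(as.numeric(arr), as.integer(dim(arr)), tp$taps, tp$w)
  out <- array(out, dim(arr))
  if (inherits(volume, "voxel_volume")) {
    volume$data <- out
    volume
  } else out
}

#' PSF full width at half maximum
#'
#' FWHM of the PSF along one axis, measured on the 1D profile through the
#' kernel centre with linear interpolation.
#'
#' @param p a `psf`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return FWHM in nm.
#' @export
psf_fwhm <- function(p, axis = 1L) {
  d <- dim(p$kernel)
  ctr <- (d + 1L) %/% 2L
  prof <- switch(axis,
                 p$kernel[, ctr[2], ctr[3]],
                 p$kernel[ctr[1], , ctr[3]],
                 p$kernel[ctr[1], ctr[2], ])
  profile_fwhm(prof, spacing = p$voxel_size[axis])
}
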