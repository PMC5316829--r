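# Internal numerical helpers shared across modules.

# Evaluate expr with the RNG seeded locally, restoring the caller's RNG
# state afterwards so analyses stay reproducible without side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Otsu's threshold on a 256-bin histogram; returns the bin upper edge that
# maximizes between-class variance.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image (no contrast)")
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# Triangle threshold (Zack): distance-maximizing point between the
# histogram peak and its far tail; suited to skewed histograms where a
# small, dim foreground rides on a dominant background mode.
triangle_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image (no contrast)")
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  pk <- which.max(h)
  # tail on the side with more dynamic range
  last <- max(which(h > 0))
  first <- min(which(h > 0))
  if ((last - pk) >= (pk - first)) {
    bins <- pk:last
    d <- abs((h[last] - h[pk]) * bins - (last - pk) * h[bins] +
               last * h[pk] - h[last] * pk) /
      sqrt((h[last] - h[pk])^2 + (last - pk)^2)
  } else {
    bins <- first:pk
    d <- abs((h[pk] - h[first]) * bins - (pk - first) * h[bins] +
               pk * h[first] - h[pk] * first) /
      sqrt((h[pk] - h[first])^2 + (pk - first)^2)
  }
  k <- bins[which.max(d)]
  rng[1] + k / n_bins * diff(rng)
}

# 1D Gaussian kernel (unit sum), half-width ~3 sigma.
gaussian_kernel_1d <- function(sigma, half = max(1L, ceiling(3 * sigma))) {
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D convolution (replicate padding) used by the structure
# tensor; kx acts along rows (dim 1), ky along columns (dim 2).
conv_sep2 <- function(m, kx, ky = kx) {
  conv_dim <- function(m, k, dim) {
    h <- (length(k) - 1L) / 2L
    n <- base::dim(m)[dim]
    idx <- function(i) pmin(pmax(i, 1L), n)
    acc <- array(0, base::dim(m))
    for (j in seq_along(k)) {
      off <- j - h - 1L
      if (dim == 1L) acc <- acc + k[j] * m[idx(seq_len(n) + off), , drop = FALSE]
      else acc <- acc + k[j] * m[, idx(seq_len(n) + off), drop = FALSE]
    }
    acc
  }
  conv_dim(conv_dim(m, kx, 1L), ky, 2L)
}

# Central-difference gradient along a matrix dimension (replicate edges).
grad_dim2 <- function(m, dim) {
  n <- base::dim(m)[dim]
  lo <- pmax(seq_len(n) - 1L, 1L)
  hi <- pmin(seq_len(n) + 1L, n)
  sc <- (hi - lo)
  if (dim == 1L) (m[hi, , drop = FALSE] - m[lo, , drop = FALSE]) / sc
  else t(t(m[, hi, drop = FALSE] - m[, lo, drop = FALSE]) / sc)
}

# Trilinear sampling of a 3D array at fractional voxel coordinates
# (1-based voxel-centre convention); out-of-range samples clamp to edge.
trilinear_sample <- function(a, xi, yi, zi) {
  d <- dim(a)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  xi <- cl(xi, d[1]); yi <- cl(yi, d[2]); zi <- cl(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(yi), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(zi), d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- 1 }
  if (d[2] == 1L) { y0 <- y1 <- 1 }
  if (d[3] == 1L) { z0 <- z1 <- 1 }
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  g <- function(i, j, k) a[cbind(i, j, k)]
  (1 - fx) * (1 - fy) * (1 - fz) * g(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * g(x1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * g(x0, y1, z0) +
    fx * fy * (1 - fz) * g(x1, y1, z0) +
    (1 - fx) * (1 - fy) * fz * g(x0, y0, z1) +
    fx * (1 - fy) * fz * g(x1, y0, z1) +
    (1 - fx) * fy * fz * g(x0, y1, z1) +
    fx * fy * fz * g(x1, y1, z1)
}

# Savitzky-Golay smoothed first derivative. Interior points use a centred
# least-squares polynomial fit of the given order; edges use one-sided
# windows of the same length. Returns dy/dt given sampling interval dt.
sg_derivative <- function(y, dt, window = 5L, order = 2L) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) window <- if (n %% 2L) n else n - 1L
  if (window < 3L) {
    # fall back to plain finite differences
    if (n < 2L) return(rep(0, n))
    return(c(diff(y) / dt, (y[n] - y[n - 1]) / dt)[seq_len(n)])
  }
  order <- min(order, window - 1L)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (hi - lo + 1L < window) {
      lo <- max(1L, min(lo, n - window + 1L))
      hi <- min(n, lo + window - 1L)
    }
    t_loc <- (seq(lo, hi) - i) * dt
    X <- outer(t_loc, 0:order, `^`)
    cf <- qr.coef(qr(X), y[lo:hi])
    out[i] <- cf[2]
  }
  out
}

# Linear-interpolated full width at half maximum of a 1D profile.
profile_fwhm <- function(v, spacing = 1) {
  pk <- which.max(v)
  if (length(v) < 3 || pk == 1L || pk == length(v)) return(NA_real_)
  half <- v[pk] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(pk, 2)) {
    if (v[i - 1] <= half) {
      left <- (i - 1) + (half - v[i - 1]) / (v[i] - v[i - 1])
      break
    }
  }
  for (i in seq(pk, length(v) - 1)) {
    if (v[i + 1] <= half) {
      right <- i + (v[i] - half) / (v[i] - v[i + 1])
      break
    }
  }
  (right - left) * spacing
}
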