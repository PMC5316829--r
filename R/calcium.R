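#' Calibration constants for a trapped low-affinity indicator
#'
#' The t-system-trapped dye (rhod-5N) reports luminal calcium through the
#' saturable binding relationship; `F_min`/`F_max` come from an end-of-
#' experiment ionophore calibration (0 and 5 mM calcium), and `K_D` is
#' the indicator's in-situ dissociation constant (0.8 mM).
#'
#' @param K_D dissociation constant, mM (default 0.8).
#' @param F_min,F_max fluorescence at zero and saturating calcium, a.u.
#' @return object of class `calibration_params`.
#' @export
calibration_params <- function(K_D = 0.8, F_min = 100, F_max = 1100) {
  if (!is.finite(K_D) || K_D <= 0) stop("K_D must be positive")
  if (!(F_max > F_min)) stop("F_max must exceed F_min")
  structure(list(K_D = K_D, F_min = F_min, F_max = F_max),
            class = "calibration_params")
}

#' Convert fluorescence to luminal calcium
#'
#' Applies the calibration relationship
#' \deqn{[Ca](t) = K_D (F(t) - F_{min}) / (F_{max} - F(t))}
#' so that calcium is zero at `F_min`, equals `K_D` at half-saturation,
#' and diverges at `F_max`. Values beyond the calibrated range by more
#' than 2% of the range are an error (saturation); within that tolerance
#' they are clamped, and a guard at 98% of the range prevents the
#' hyperbolic transform from blowing up.
#'
#' @param trace data.frame with columns `time_s`, `F` and optionally
#'   `epoch_label`, or a numeric vector of fluorescence values.
#' @param calib a [calibration_params()]; defaults to the trace's
#'   `calib` attribute.
#' @param compartment `"t_system"` or `"vacuole"`; in heavily vacuolated
#'   fibres the resolved signal is vacuole calcium.
#' @return for a data.frame input, a data.frame with `time_s`, `ca_mM`
#'   (and `epoch_label` if present), classed `calcium_trace` with the
#'   compartment and calibration as attributes; for a vector input, a
#'   numeric vector.
#' @export
calibrate <- function(trace, calib = attr(trace, "calib"),
                      compartment = c("t_system", "vacuole")) {
  compartment <- match.arg(compartment)
  if (is.null(calib)) stop("calibration parameters required")
  f <- if (is.data.frame(trace)) trace$F else as.numeric(trace)
  rng <- calib$F_max - calib$F_min
  if (any(f >= calib$F_max))
    stop("fluorescence at or above F_max (saturated; calcium unbounded)")
  if (any(f < calib$F_min - 0.02 * rng))
    stop("fluorescence below F_min by more than 2% of range")
  f <- pmin(pmax(f, calib$F_min), calib$F_min + 0.98 * rng)
  ca <- calib$K_D * (f - calib$F_min) / (calib$F_max - f)
  if (!is.data.frame(trace)) return(ca)
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("time must be strictly increasing")
  out <- data.frame(time_s = trace$time_s, ca_mM = ca)
  if (!is.null(trace$epoch_label)) out$epoch_label <- trace$epoch_label
  class(out) <- c("calcium_trace", "data.frame")
  attr(out, "compartment") <- compartment
  attr(out, "calib") <- calib
  attr(out, "epochs") <- attr(trace, "epochs")
  out
}

#' Forward saturable dye curve
#'
#' Exact inverse of [calibrate()]: maps calcium to fluorescence via
#' `F = F_min + (F_max - F_min) * ca / (K_D + ca)`, so calibration
#' round-trips are analytic.
#'
#' @param ca calcium concentration(s), mM.
#' @param calib a [calibration_params()].
#' @return fluorescence, a.u.
#' @export
ca_to_fluorescence <- function(ca, calib) {
  calib$F_min + (calib$F_max - calib$F_min) * ca / (calib$K_D + ca)
}

#' Derive the t-system calcium flux from a calibrated trace
#'
#' Flux is `B * d[Ca]/dt` in luminal concentration units, computed by
#' Savitzky-Golay smoothed differentiation. The peak uptake flux is the
#' maximum over uptake epochs (elevated cytoplasmic calcium, no caffeine)
#' and the peak store-operated entry (SOCE) flux is the minimum (signed
#' negative, an efflux from the lumen) over caffeine epochs.
#'
#' @param ca_trace a `calcium_trace` (with `epoch_label` and an `epochs`
#'   attribute naming caffeine epochs), or a plain data.frame.
#' @param B dimensionless luminal buffering power (default 1).
#' @param window smoothing window in samples (default 5, i.e. 4 s at the
#'   0.8 s frame interval).
#' @param uptake_min_cyto mM; uptake epochs are non-caffeine epochs whose
#'   cytoplasmic calcium is at least this (default 200 nM).
#' @param per_fibre_volume optional t-system volume fraction (%); when
#'   given, fluxes are also reported rescaled per fibre volume.
#' @return list with `flux` (data.frame `time_s`, `flux_mM_per_s`),
#'   `peak_uptake`, `peak_soce` (NA when no epoch of that kind exists),
#'   their epochs of occurrence, and the smoothing parameters used.
#' @export
derive_flux <- function(ca_trace, B = 1, window = 5L,
                        uptake_min_cyto = 2e-4, per_fibre_volume = NULL) {
  tt <- ca_trace$time_s
  ca <- ca_trace$ca_mM
  n <- length(ca)
  if (n < 5L) stop("need at least 5 samples to derive a flux")
  dt <- median(diff(tt))
  epochs <- attr(ca_trace, "epochs")
  lab <- ca_trace$epoch_label
  if (!is.null(epochs) && !is.null(lab)) {
    min_ep <- min(table(factor(lab, levels = epochs$label)))
    if (min_ep > 0 && min_ep < window) {
      warning("epoch shorter than the smoothing window; window shrunk to ",
              min_ep)
      window <- max(3L, as.integer(min_ep))
    }
  }
  fl <- B * sg_derivative(ca, dt, window = window)
  out <- list(flux = data.frame(time_s = tt, flux_mM_per_s = fl),
              B = B, window = window,
              peak_uptake = NA_real_, peak_uptake_epoch = NA_character_,
              peak_soce = NA_real_, peak_soce_epoch = NA_character_)
  if (!is.null(epochs) && !is.null(lab)) {
    caffeine <- epochs$label[epochs$caffeine]
    uptake <- epochs$label[!epochs$caffeine & epochs$cyto_ca >= uptake_min_cyto]
    in_up <- lab %in% uptake
    in_caf <- lab %in% caffeine
    if (any(in_up)) {
      i <- which(in_up)[which.max(fl[in_up])]
      out$peak_uptake <- max(0, fl[i])
      out$peak_uptake_epoch <- lab[i]
    }
    if (any(in_caf)) {
      i <- which(in_caf)[which.min(fl[in_caf])]
      out$peak_soce <- min(0, fl[i])
      out$peak_soce_epoch <- lab[i]
    }
  }
  if (!is.null(per_fibre_volume)) {
    sc <- per_fibre_volume / 100 * 1000   # mM (lumen) -> uM per fibre volume
    out$peak_uptake_per_fibre_uM_s <- out$peak_uptake * sc
    out$peak_soce_per_fibre_uM_s <- out$peak_soce * sc
  }
  out
}

#' Steady-state luminal calcium within an epoch
#'
#' Mean of the final `tail_fraction` of the epoch's samples. The result
#' carries an `unsteady` attribute set when the tail slope exceeds 1% of
#' the epoch's range per sample.
#'
#' @param ca_trace a `calcium_trace` with `epoch_label`.
#' @param epoch epoch label to evaluate.
#' @param tail_fraction fraction in (0, 1] of the epoch to average.
#' @return steady-state calcium, mM.
#' @export
steady_state <- function(ca_trace, epoch, tail_fraction = 0.2) {
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]")
  idx <- which(ca_trace$epoch_label == epoch)
  if (!length(idx)) stop("epoch not present in trace: ", epoch)
  ca <- ca_trace$ca_mM[idx]
  n <- length(ca)
  k <- max(2L, ceiling(tail_fraction * n))
  tail_ca <- ca[(n - k + 1L):n]
  val <- mean(tail_ca)
  rng <- diff(range(ca))
  slope <- if (k >= 2) coef(lm(tail_ca ~ seq_len(k)))[2] else 0
  attr(val, "unsteady") <- is.finite(slope) && rng > 0 &&
    abs(slope) > 0.01 * rng
  val
}

#' SOCE flux versus luminal calcium regression
#'
#' Ordinary least squares of peak store-operated entry flux against the
#' luminal calcium at which it was measured.
#'
#' @param ca_t_sys luminal calcium values, mM.
#' @param peak_soce_flux matching peak SOCE fluxes.
#' @return list with `slope`, `intercept` and `r2`.
#' @export
soce_regression <- function(ca_t_sys, peak_soce_flux) {
  if (length(ca_t_sys) < 2 || length(unique(ca_t_sys)) < 2)
    stop("need at least two distinct luminal calcium values")
  fit <- lm(peak_soce_flux ~ ca_t_sys)
  r2 <- if (length(ca_t_sys) == 2) 1 else summary(fit)$r.squared
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}

#' T-system calcium-content budget
#'
#' The calcium held by the t-system per fibre volume is
#' `B x [Ca]_t-sys x t-sysVol`: buffering power times luminal free
#' calcium (mM) times the t-system volume as a fraction of fibre volume,
#' expressed in uM relative to fibre volume.
#'
#' @param B dimensionless buffering power (1 for the t-system).
#' @param ca_t_sys luminal calcium, mM.
#' @param t_sys_vol t-system volume, % of fibre volume.
#' @return a `calcium_budget` with `content` in uM per fibre volume.
#' @export
calcium_budget <- function(B = 1, ca_t_sys, t_sys_vol) {
  vals <- c(B = B, ca_t_sys = ca_t_sys, t_sys_vol = t_sys_vol)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("budget inputs must be non-negative")
  structure(list(B = B, ca_t_sys = ca_t_sys, t_sys_vol = t_sys_vol,
                 content = B * ca_t_sys * (t_sys_vol / 100) * 1000),
            class = "calcium_budget")
}

#' @export
print.calcium_budget <- function(x, ...) {
  cat(sprintf(
    "<calcium_budget> B=%g x %g mM x %g%% fibre volume = %g uM per fibre volume\n",
    x$B, x$ca_t_sys, x$t_sys_vol, x$content))
  invisible(x)
}

#' Fold change between two calcium budgets
#'
#' @param pre,post `calcium_budget` objects (e.g. pre- and post-exercise).
#' @return `post$content / pre$content`.
#' @export
budget_fold_change <- function(pre, post) {
  if (pre$content <= 0) stop("pre-condition budget content must be positive")
  post$content / pre$content
}
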