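#' Solution-exchange protocol
#'
#' Ordered, contiguous epochs of the bathing (cytoplasmic-facing) internal
#' solution applied to a skinned fibre: each epoch has a duration, a free
#' cytoplasmic calcium concentration, and a caffeine flag (caffeine
#' depletes the SR and activates store-operated entry across the
#' transverse tubules).
#'
#' @param duration_s epoch durations, s (all > 0).
#' @param cyto_ca cytoplasmic free calcium per epoch, mM (experimental
#'   range 28 nM to 1.3 uM, i.e. 2.8e-5 to 1.3e-3 mM).
#' @param caffeine logical per epoch.
#' @param label optional epoch labels; defaults to `epoch1`, `epoch2`, ...
#' @return a `solution_protocol` data.frame with `t_start`/`t_end`.
#' @export
solution_protocol <- function(duration_s, cyto_ca, caffeine,
                              label = paste0("epoch", seq_along(duration_s))) {
  n <- length(duration_s)
  if (n == 0) stop("protocol must contain at least one epoch")
  if (length(cyto_ca) != n || length(caffeine) != n || length(label) != n)
    stop("epoch fields must have equal length")
  if (any(duration_s <= 0)) stop("epoch durations must be positive")
  if (any(cyto_ca < 0)) stop("cytoplasmic calcium must be non-negative")
  t_end <- cumsum(duration_s)
  out <- data.frame(label = label, duration_s = duration_s,
                    cyto_ca = cyto_ca, caffeine = as.logical(caffeine),
                    t_start = c(0, utils::head(t_end, -1)), t_end = t_end)
  class(out) <- c("solution_protocol", "data.frame")
  out
}

#' Two-compartment luminal calcium model parameters
#'
#' Rate constants of the t-system calcium model. Both compartments pump
#' calcium in from the cytoplasm with a rate scaled by a saturable
#' activation function of cytoplasmic calcium; only the transverse
#' tubules conduct store-operated entry (an efflux from the lumen during
#' caffeine epochs) and carry a basal leak setting their steady state;
#' vacuoles cannot conduct SOCE and their luminal connection to the
#' transverse tubules is restricted (`junction_permeability`, 0 = fully
#' restricted).
#'
#' @param uptake_rate_tt,uptake_rate_vac maximal uptake rates, mM/s.
#' @param leak_rate_tt,leak_rate_vac basal leak rate constants, 1/s
#'   (default 0 for vacuoles: they retain calcium during store
#'   depletion).
#' @param soce_conductance_tt store-dependent efflux rate constant, 1/s,
#'   active during caffeine epochs; identically zero for vacuoles.
#' @param junction_permeability exchange rate constant between the
#'   transverse-tubule and vacuole lumina, 1/s.
#' @param activation_K cytoplasmic calcium at half-maximal uptake, mM
#'   (Hill coefficient 1).
#' @param initial_ca_tt,initial_ca_vac initial luminal calcium, mM.
#' @param buffering_B dimensionless luminal buffering power.
#' @return object of class `compartment_params`.
#' @export
compartment_params <- function(uptake_rate_tt = 0.035,
                               uptake_rate_vac = 0.035,
                               leak_rate_tt = 0.02,
                               leak_rate_vac = 0,
                               soce_conductance_tt = 0.05,
                               junction_permeability = 0,
                               activation_K = 3e-4,
                               initial_ca_tt = 0.1,
                               initial_ca_vac = 0.1,
                               buffering_B = 1) {
  rates <- c(uptake_rate_tt, uptake_rate_vac, leak_rate_tt, leak_rate_vac,
             soce_conductance_tt, junction_permeability, activation_K)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be non-negative")
  if (initial_ca_tt < 0 || initial_ca_vac < 0)
    stop("initial calcium must be non-negative")
  structure(list(uptake_rate_tt = uptake_rate_tt,
                 uptake_rate_vac = uptake_rate_vac,
                 leak_rate_tt = leak_rate_tt, leak_rate_vac = leak_rate_vac,
                 soce_conductance_tt = soce_conductance_tt,
                 junction_permeability = junction_permeability,
                 activation_K = activation_K,
                 initial_ca_tt = initial_ca_tt,
                 initial_ca_vac = initial_ca_vac,
                 buffering_B = buffering_B),
            class = "compartment_params")
}

#' Simulate a calcium protocol
#'
#' Integrates the two-compartment rate model over a solution protocol
#' with fixed-step RK4 (10 ms internal step), samples at the imaging
#' frame interval, maps the reported compartment's calcium to
#' fluorescence through the saturable dye curve, and adds Gaussian
#' measurement noise. Per-compartment ground truth (fine-grid calcium and
#' true flux) is returned alongside the observable trace.
#'
#' The model is, per epoch (a(c) = c / (c + K_act)):
#' \preformatted{
#'   d[Ca]_tt/dt  = up_tt a(cyto) - leak_tt [Ca]_tt
#'                  - g_soce [Ca]_tt [caffeine] - J ([Ca]_tt - [Ca]_vac)
#'   d[Ca]_vac/dt = up_vac a(cyto) - leak_vac [Ca]_vac
#'                  + J ([Ca]_tt - [Ca]_vac)
#' }
#'
#' @param protocol a [solution_protocol()].
#' @param params a [compartment_params()].
#' @param frame_interval imaging frame interval, s (default 0.8).
#' @param calib a [calibration_params()].
#' @param noise_sd Gaussian fluorescence noise sd, a.u.
#' @param report which compartment the fluorescence reports
#'   (`"t_system"` for regular fibres, `"vacuole"` for heavily
#'   vacuolated ones).
#' @param dt_internal RK4 step, s.
#' @param seed RNG seed for the noise draw.
#' @return list with `trace` (data.frame `time_s`, `F`, `epoch_label`,
#'   with `calib` and `epochs` attributes) and `truth` (fine-grid times,
#'   per-compartment calcium, true flux `B * d[Ca]/dt`, per-epoch
#'   steady-state values and true peak fluxes).
#' @export
simulate_ca_protocol <- function(protocol, params, frame_interval = 0.8,
                                 calib = calibration_params(),
                                 noise_sd = 0,
                                 report = c("t_system", "vacuole"),
                                 dt_internal = 0.01, seed = NULL) {
  report <- match.arg(report)
  if (!inherits(protocol, "solution_protocol")) stop("invalid protocol")
  if (!inherits(params, "compartment_params")) stop("invalid params")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  total <- sum(protocol$duration_s)
  nt <- ceiling(total / dt_internal)
  t_fine <- seq(0, by = dt_internal, length.out = nt + 1L)
  ca_tt <- numeric(nt + 1L)
  ca_vac <- numeric(nt + 1L)
  dtt <- numeric(nt + 1L)
  dvac <- numeric(nt + 1L)
  ca_tt[1] <- params$initial_ca_tt
  ca_vac[1] <- params$initial_ca_vac

  epoch_at <- function(t) {
    i <- findInterval(t, protocol$t_start, rightmost.closed = FALSE)
    pmin(pmax(i, 1L), nrow(protocol))
  }
  # per-epoch constants, precomputed on the fine grid so the RK4 loop is
  # plain scalar arithmetic
  act_ep <- protocol$cyto_ca / (protocol$cyto_ca + params$activation_K)
  act_ep[protocol$cyto_ca == 0] <- 0
  soce_ep <- ifelse(protocol$caffeine, params$soce_conductance_tt, 0)
  i_lo <- epoch_at(t_fine)
  i_mid <- epoch_at(t_fine + dt_internal / 2)
  utt <- params$uptake_rate_tt; uva <- params$uptake_rate_vac
  ltt <- params$leak_rate_tt; lva <- params$leak_rate_vac
  J <- params$junction_permeability
  f_tt <- function(a, so, x, v) utt * a - ltt * x - so * x - J * (x - v)
  f_va <- function(a, x, v) uva * a - lva * v + J * (x - v)
  x <- ca_tt[1]; v <- ca_vac[1]
  dtt[1] <- f_tt(act_ep[i_lo[1]], soce_ep[i_lo[1]], x, v)
  dvac[1] <- f_va(act_ep[i_lo[1]], x, v)
  h <- dt_internal
  for (i in seq_len(nt)) {
    a0 <- act_ep[i_lo[i]]; s0 <- soce_ep[i_lo[i]]
    am <- act_ep[i_mid[i]]; sm <- soce_ep[i_mid[i]]
    a1 <- act_ep[i_lo[i + 1L]]; s1 <- soce_ep[i_lo[i + 1L]]
    k1x <- f_tt(a0, s0, x, v);                 k1v <- f_va(a0, x, v)
    k2x <- f_tt(am, sm, x + h / 2 * k1x, v + h / 2 * k1v)
    k2v <- f_va(am, x + h / 2 * k1x, v + h / 2 * k1v)
    k3x <- f_tt(am, sm, x + h / 2 * k2x, v + h / 2 * k2v)
    k3v <- f_va(am, x + h / 2 * k2x, v + h / 2 * k2v)
    k4x <- f_tt(a1, s1, x + h * k3x, v + h * k3v)
    k4v <- f_va(a1, x + h * k3x, v + h * k3v)
    x <- max(x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x), 0)
    v <- max(v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v), 0)
    ca_tt[i + 1L] <- x
    ca_vac[i + 1L] <- v
    dtt[i + 1L] <- f_tt(a1, s1, x, v)
    dvac[i + 1L] <- f_va(a1, x, v)
  }

  t_frame <- seq(0, total, by = frame_interval)
  interp <- function(v) stats::approx(t_fine, v, xout = t_frame, rule = 2)$y
  ca_tt_f <- interp(ca_tt)
  ca_vac_f <- interp(ca_vac)
  lab <- protocol$label[epoch_at(t_frame)]
  ca_rep <- if (report == "t_system") ca_tt_f else ca_vac_f
  f <- ca_to_fluorescence(ca_rep, calib)
  if (noise_sd > 0)
    f <- with_seed(seed, f + rnorm(length(f), 0, noise_sd))

  B <- params$buffering_B
  # true per-epoch quantities from the fine grid
  ep_idx <- epoch_at(t_fine)
  truth_eps <- lapply(seq_len(nrow(protocol)), function(i) {
    sel <- ep_idx == i
    list(label = protocol$label[i],
         ca_tt_end = ca_tt[max(which(sel))],
         ca_vac_end = ca_vac[max(which(sel))],
         peak_flux_tt = B * max(dtt[sel]),
         min_flux_tt = B * min(dtt[sel]))
  })
  trace <- data.frame(time_s = t_frame, F = f, epoch_label = lab)
  attr(trace, "calib") <- calib
  attr(trace, "epochs") <- protocol
  list(trace = trace,
       truth = list(time_s = t_fine,
                    ca_tt = ca_tt, ca_vac = ca_vac,
                    flux_tt = B * dtt, flux_vac = B * dvac,
                    frame_time_s = t_frame,
                    ca_tt_frames = ca_tt_f, ca_vac_frames = ca_vac_f,
                    epochs = truth_eps,
                    report = report))
}

#' Sample a randomized uptake/SOCE protocol
#'
#' Draws a three-epoch protocol (rest, caffeine store-depletion, calcium
#' uptake at elevated cytoplasmic calcium) and compartment parameters
#' jittered around their defaults; used for parameter-recovery
#' benchmarking of the flux and steady-state estimators.
#'
#' @param seed integer seed.
#' @return list with `protocol`, `params` and the drawn uptake
#'   cytoplasmic calcium (mM).
#' @export
sample_protocol <- function(seed) {
  with_seed(seed, {
    cyto_hi <- runif(1, 2e-4, 1.3e-3)     # 200 nM .. 1.3 uM
    prot <- solution_protocol(
      duration_s = c(40, stats::runif(1, 60, 90), stats::runif(1, 150, 250)),
      cyto_ca = c(6.7e-5, 0, cyto_hi),
      caffeine = c(FALSE, TRUE, FALSE),
      label = c("rest", "caffeine", "uptake"))
    pars <- compartment_params(
      uptake_rate_tt = runif(1, 0.02, 0.05),
      uptake_rate_vac = runif(1, 0.02, 0.05),
      leak_rate_tt = runif(1, 0.012, 0.03),
      soce_conductance_tt = runif(1, 0.03, 0.08),
      initial_ca_tt = runif(1, 0.2, 0.5),
      initial_ca_vac = runif(1, 0.2, 0.5))
    list(protocol = prot, params = pars, cyto_hi = cyto_hi)
  })
}
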