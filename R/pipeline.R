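#' Pipeline run configuration
#'
#' Validated bag of stage parameters for the end-to-end pipelines.
#' Unknown keys are rejected so typos cannot silently change an analysis.
#'
#' @param ... configuration values; see Details.
#' @details Recognized keys (with defaults):
#' \itemize{
#' \item `phantom`: a [phantom_spec()] (or `NULL` when `volume` given)
#' \item `volume`: path to a TIFF volume to analyse instead of a phantom
#' \item `seed`: integer master seed (1)
#' \item `simulate_imaging`: apply PSF + noise to the phantom (TRUE)
#' \item `psf_sigma_nm`: true/assumed PSF sigma (c(106, 106, 255))
#' \item `estimate_psf_from_beads`: estimate the PSF from a simulated
#'   bead stack rather than using the true kernel (TRUE)
#' \item `n_beads`: beads in the simulated stack (15)
#' \item `rl_iterations`: Richardson-Lucy iterations (25)
#' \item `binarize_method`: "triangle" (default), "otsu" or a numeric
#'   threshold
#' \item `angle_threshold`: transverse/longitudinal split, degrees (45)
#' \item `directionality_bins`: histogram bins (18)
#' \item `vacuole_percentile`: vacuole threshold percentile (55)
#' \item `calib`: a [calibration_params()]
#' \item `protocols`: list of lists with `protocol`, `params` and
#'   optionally `report` for the calcium pipeline
#' \item `frame_interval`: s (0.8)
#' \item `noise_sd`: fluorescence noise, a.u. (2)
#' \item `B`: buffering power for budgets (1)
#' \item `t_sys_vol`: t-system volume %, for budgets (NULL = from
#'   structure truth when available)
#' \item `out_dir`: directory for artifacts (NULL = no files written)
#' \item `blinded`: hash condition labels in reports (FALSE)
#' }
#' @return a `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    phantom = NULL, volume = NULL, seed = 1L,
    simulate_imaging = TRUE, psf_sigma_nm = c(106, 106, 255),
    estimate_psf_from_beads = TRUE, n_beads = 15L, rl_iterations = 25L,
    binarize_method = "triangle", angle_threshold = 45,
    directionality_bins = 18L, vacuole_percentile = 55,
    calib = calibration_params(), protocols = NULL,
    frame_interval = 0.8, noise_sd = 2, B = 1, t_sys_vol = NULL,
    out_dir = NULL, blinded = FALSE)
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  class(cfg) <- "run_config"
  cfg
}

config_echo <- function(cfg) {
  ser <- lapply(cfg, function(v) {
    if (inherits(v, "phantom_spec")) unclass(v)
    else if (inherits(v, "calibration_params")) unclass(v)
    else if (is.list(v)) "<list>"
    else v
  })
  ser
}

blind_label <- function(lab) {
  # stable short hash for blinded reports (no condition names leak)
  vapply(lab, function(s) {
    h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)) * 131L) %% 99991L
    sprintf("cond_%05d", h)
  }, "")
}

#' Run the structure pipeline
#'
#' Phantom generation (or TIFF input) -> simulated imaging -> PSF
#' estimation from beads -> Richardson-Lucy restoration -> binarization
#' -> skeletonization -> segment classification -> directionality ->
#' vacuole quantification, with a manifest echoing every parameter.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with per-stage summaries; when the input
#'   was a phantom, also ground truth and segment-recovery scores.
#' @export
run_structure_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stages <- list()
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
    stages[[name]] <<- TRUE
    res
  }

  truth <- NULL
  if (!is.null(config$volume)) {
    vol <- step("load", read_tiff_volume(config$volume))
    raw <- vol
  } else {
    spec <- config$phantom
    if (is.null(spec)) spec <- phantom_spec()
    gen <- step("phantom", generate_tsys_volume(spec, seed = config$seed))
    vol <- gen$volume
    truth <- gen$truth
    raw <- vol
  }

  vs <- vol$voxel_size
  psf_true <- gaussian_psf(config$psf_sigma_nm, vs)
  if (isTRUE(config$simulate_imaging) && is.null(config$volume)) {
    nm <- if (!is.null(config$phantom)) config$phantom$noise_model
    else phantom_spec()$noise_model
    raw <- step("imaging", simulate_imaging(vol, psf_true, noise_model = nm,
                                            seed = config$seed + 1L))
  }

  p <- psf_true
  if (isTRUE(config$estimate_psf_from_beads)) {
    spec_b <- if (!is.null(config$phantom)) config$phantom else phantom_spec()
    beads <- step("beads", generate_bead_stack(
      config$n_beads, 100, psf_true, spec = spec_b, amplitude = 20,
      noise = TRUE, seed = config$seed + 2L))
    p <- step("estimate_psf", estimate_psf(beads))
  }

  dec <- step("restore", richardson_lucy(raw, p,
                                         iterations = config$rl_iterations))
  mask <- step("binarize", binarize_tubules(dec, config$binarize_method))
  skel <- step("skeletonize", skeletonize(mask, vs))
  skel <- step("classify", classify_segments(skel, config$angle_threshold))

  d <- dim(dec)
  plane <- dec$data[, , max(1L, round(d[3] / 2))]
  dirhist <- step("directionality",
                  directionality_histogram(plane, config$directionality_bins))

  vac_labels <- step("vacuoles", segment_vacuoles(
    raw, percentile = config$vacuole_percentile))
  fm <- raw$fibre_mask
  if (is.null(fm)) fm <- array(TRUE, dim(raw$data))
  vac_tab <- step("vacuole_summary", vacuole_summary(vac_labels, fm, vs))

  recovery <- NULL
  radial <- NULL
  if (!is.null(truth)) {
    recovery <- step("recovery",
                     segment_recovery(truth$segments, skel, vs))
    radial <- step("radial_profile", longitudinal_radial_profile(
      skel, truth$fibre_centre_nm, truth$fibre_radius_nm))
  }

  lab <- vapply(skel$segments, function(s) s$label %||% "unlabelled", "")
  report <- list(
    kind = "structure",
    config = config_echo(config),
    seed = config$seed,
    psf = list(provenance = p$provenance,
               fwhm_xy_nm = psf_fwhm(p, 1), fwhm_z_nm = psf_fwhm(p, 3)),
    n_segments = length(skel$segments),
    n_transverse = sum(lab == "transverse"),
    n_longitudinal = sum(lab == "longitudinal"),
    directionality = as.data.frame(dirhist),
    vacuoles = attr(vac_tab, "summary"),
    vacuole_table = as.data.frame(vac_tab),
    radial_profile = radial,
    recovery = if (!is.null(recovery))
      list(recovered_percent = recovery$recovered_percent,
           n_truth_segments = nrow(recovery$detail)),
    truth = if (!is.null(truth)) list(
      tubule_volume_fraction = truth$tubule_volume_fraction,
      vacuole_volume_fraction = truth$vacuole_volume_fraction,
      vacuole_count = truth$vacuole_count),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tiff_volume(dec, file.path(config$out_dir, "restored.tif"),
                      bits = 32L)
    write_tiff_volume(array(as.numeric(vac_labels), dim(vac_labels)),
                      file.path(config$out_dir, "vacuole_labels.tif"),
                      bits = 16L)
    utils::write.csv(report$directionality,
                     file.path(config$out_dir, "directionality.csv"),
                     row.names = FALSE)
    utils::write.csv(report$vacuole_table,
                     file.path(config$out_dir, "vacuole_table.csv"),
                     row.names = FALSE)
    skeleton_to_json(skel, file.path(config$out_dir, "skeleton.json"))
    manifest <- report[setdiff(names(report), c("vacuole_table"))]
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Export a skeleton as a JSON graph
#' @param skel a `skeleton`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
skeleton_to_json <- function(skel, path) {
  segs <- lapply(skel$segments, function(s) list(
    points_nm = unname(apply(s$points, 1, as.numeric, simplify = FALSE)),
    n = s$n, theta_deg = s$theta %||% NA, label = s$label %||% NA))
  jsonlite::write_json(list(voxel_size_nm = skel$voxel_size,
                            border_touching = skel$border_touching,
                            segments = segs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the calcium pipeline
#'
#' For each condition: simulate (or load) a fluorescence trace, calibrate
#' to luminal calcium, derive fluxes and steady states; across
#' conditions, fit the SOCE-versus-luminal-calcium regression when at
#' least two conditions provide SOCE measurements; finally compute
#' calcium-content budgets.
#'
#' @param config a [run_config()] with a `protocols` list.
#' @return a `run_report`.
#' @export
run_calcium_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$protocols) || !length(config$protocols))
    stop("config$protocols must list at least one condition")
  calib <- config$calib
  if (is.null(calib$F_max)) stop("missing calibration epoch value: F_max")
  if (is.null(calib$F_min)) stop("missing calibration epoch value: F_min")
  t0 <- Sys.time()
  conds <- list()
  soce_pts <- data.frame(ca = numeric(0), flux = numeric(0))
  for (i in seq_along(config$protocols)) {
    pc <- config$protocols[[i]]
    sim <- simulate_ca_protocol(pc$protocol, pc$params,
                                frame_interval = config$frame_interval,
                                calib = calib, noise_sd = config$noise_sd,
                                report = pc$report %||% "t_system",
                                seed = config$seed + i)
    ca <- calibrate(sim$trace, calib,
                    compartment = pc$report %||% "t_system")
    fx <- derive_flux(ca, B = config$B)
    prot <- pc$protocol
    ss <- lapply(prot$label, function(l) {
      v <- steady_state(ca, l)
      list(epoch = l, ca_mM = as.numeric(v),
           unsteady = isTRUE(attr(v, "unsteady")))
    })
    caf <- prot$label[prot$caffeine]
    soce_absent <- length(caf) == 0L
    if (!soce_absent && is.finite(fx$peak_soce)) {
      # luminal calcium just before store depletion began
      pre_idx <- which(prot$label == fx$peak_soce_epoch) - 1L
      ca_at <- if (length(pre_idx) && pre_idx >= 1)
        as.numeric(steady_state(ca, prot$label[pre_idx]))
      else ca$ca_mM[1]
      soce_pts <- rbind(soce_pts, data.frame(ca = ca_at, flux = fx$peak_soce))
    }
    lab_i <- pc$label %||% paste0("condition", i)
    if (isTRUE(config$blinded)) lab_i <- blind_label(lab_i)
    conds[[i]] <- list(
      label = lab_i,
      peak_uptake = fx$peak_uptake,
      peak_soce = if (soce_absent) NA_real_ else fx$peak_soce,
      soce_absent = soce_absent,
      steady_states = ss)
  }
  reg <- if (nrow(soce_pts) >= 2 && length(unique(soce_pts$ca)) >= 2)
    soce_regression(soce_pts$ca, soce_pts$flux) else NULL

  budgets <- NULL
  if (!is.null(config$t_sys_vol)) {
    last_ss <- vapply(conds, function(cd)
      cd$steady_states[[length(cd$steady_states)]]$ca_mM, 0)
    budgets <- lapply(seq_along(conds), function(i)
      calcium_budget(config$B, last_ss[i], config$t_sys_vol))
  }

  report <- list(kind = "calcium", config = config_echo(config),
                 seed = config$seed, conditions = conds,
                 soce_points = soce_pts, soce_regression = reg,
                 budgets = budgets,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "config")],
                         file.path(config$out_dir, "calcium_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report:%s> seed %d, %.1f s\n", x$kind, x$seed,
              x$elapsed_s))
  if (x$kind == "structure") {
    cat(sprintf("  segments: %d (%d transverse, %d longitudinal)\n",
                x$n_segments, x$n_transverse, x$n_longitudinal))
    cat(sprintf("  vacuoles: %d, %.3f%% of fibre volume\n",
                x$vacuoles$vacuole_count, x$vacuoles$volume_fraction))
    if (!is.null(x$recovery))
      cat(sprintf("  truth-segment recovery: %.1f%%\n",
                  x$recovery$recovered_percent))
  } else {
    for (cd in x$conditions)
      cat(sprintf("  %s: peak uptake %.4g mM/s, peak SOCE %s\n", cd$label,
                  cd$peak_uptake,
                  if (cd$soce_absent) "absent" else sprintf("%.4g mM/s",
                                                            cd$peak_soce)))
    if (!is.null(x$soce_regression))
      cat(sprintf("  SOCE regression: slope %.3f, intercept %.3f, r2 %.3f\n",
                  x$soce_regression$slope, x$soce_regression$intercept,
                  x$soce_regression$r2))
    if (!is.null(x$budgets))
      for (b in x$budgets) cat(sprintf("  budget: %.4g uM\n", b$content))
  }
  invisible(x)
}
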