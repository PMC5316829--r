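#' Crop a volume to its fibre bounding box
#'
#' Restricts a volume to the bounding box of its fibre mask plus a
#' margin, which speeds up restoration considerably when the fibre
#' occupies a minority of the field of view. The voxel offset of the crop
#' is recorded so physical coordinates can be mapped back.
#'
#' @param volume a `voxel_volume` with a fibre mask.
#' @param margin_vox margin in voxels around the fibre bounding box.
#' @return cropped `voxel_volume` with attribute `offset_vox` (0-based).
#' @export
crop_to_fibre <- function(volume, margin_vox = 8L) {
  if (is.null(volume$fibre_mask)) return(volume)
  d <- dim(volume$data)
  idx <- which(volume$fibre_mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin_vox, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_vox, d)
  out <- voxel_volume(volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                  drop = FALSE],
                      volume$voxel_size,
                      fibre_mask = volume$fibre_mask[lo[1]:hi[1], lo[2]:hi[2],
                                                     lo[3]:hi[3], drop = FALSE])
  attr(out, "offset_vox") <- lo - 1L
  out
}

#' End-to-end structural recovery benchmark
#'
#' Runs the full structural chain for one seed: phantom generation,
#' simulated confocal imaging (PSF + Poisson/Gaussian noise), PSF
#' estimation from a simulated bead stack, Richardson-Lucy restoration,
#' binarization, skeletonization, transverse/longitudinal classification,
#' and scoring of ground-truth segment recovery.
#'
#' @param seed integer seed controlling phantom, beads and noise.
#' @param spec a [phantom_spec()].
#' @param iterations Richardson-Lucy iterations.
#' @param binarize_method passed to [binarize_tubules()]; the pipeline
#'   default is `"triangle"`, which keeps dim sub-resolution tubules.
#' @param n_beads beads in the PSF-estimation stack.
#' @param crop crop to the fibre bounding box before restoration.
#' @return list with `recovered_percent`, `detail`, the labelled
#'   `skeleton`, the phantom `truth` and the estimated `psf`.
#' @export
structure_recovery_benchmark <- function(seed, spec = phantom_spec(),
                                         iterations = 25L,
                                         binarize_method = "triangle",
                                         n_beads = 15L, crop = TRUE) {
  g <- generate_tsys_volume(spec, seed = seed)
  psf_true <- gaussian_psf(voxel_size = spec$voxel_size)
  beads <- generate_bead_stack(n_beads, 100, psf_true, spec = spec,
                               amplitude = 20, noise = TRUE,
                               seed = seed + 500L)
  p_est <- estimate_psf(beads)
  img <- simulate_imaging(g$volume, psf_true,
                          noise_model = spec$noise_model,
                          seed = seed + 1000L)
  off_nm <- c(0, 0, 0)
  if (crop) {
    img <- crop_to_fibre(img)
    off_nm <- attr(img, "offset_vox") * spec$voxel_size
  }
  dec <- richardson_lucy(img, p_est, iterations = iterations)
  mask <- binarize_tubules(dec, binarize_method)
  skel <- skeletonize(mask, spec$voxel_size, prune_spurs = 0L)
  skel <- classify_segments(skel)
  truth_segs <- lapply(g$truth$segments, function(s) {
    s$points <- sweep(s$points, 2L, off_nm)
    s
  })
  rec <- segment_recovery(truth_segs, skel, spec$voxel_size)
  list(recovered_percent = rec$recovered_percent, detail = rec$detail,
       skeleton = skel, truth = g$truth, psf = p_est)
}

#' Flux and steady-state recovery benchmark
#'
#' Simulates `n` randomized solution protocols (see [sample_protocol()]),
#' runs the calibration / flux / steady-state estimators on the noisy
#' fluorescence traces, and compares against the ODE ground truth.
#'
#' @param n number of protocols.
#' @param seed master seed; protocol i uses `seed * 1000 + i`.
#' @param noise_sd fluorescence noise, a.u.
#' @return data.frame with per-protocol true and estimated peak uptake
#'   flux and steady-state luminal calcium, and their relative errors.
#' @export
flux_recovery_benchmark <- function(n = 20L, seed = 1L, noise_sd = 2) {
  out <- lapply(seq_len(n), function(i) {
    sp <- sample_protocol(seed * 1000L + i)
    sim <- simulate_ca_protocol(sp$protocol, sp$params,
                                calib = calibration_params(),
                                noise_sd = noise_sd,
                                seed = seed * 1000L + i + 7L)
    ca <- calibrate(sim$trace)
    fx <- derive_flux(ca, B = sp$params$buffering_B)
    ss_est <- as.numeric(steady_state(ca, "uptake"))
    eps <- sim$truth$epochs
    up_i <- which(vapply(eps, function(e) e$label, "") == "uptake")
    true_peak <- eps[[up_i]]$peak_flux_tt
    true_ss <- eps[[up_i]]$ca_tt_end
    data.frame(protocol = i,
               peak_uptake_true = true_peak, peak_uptake_est = fx$peak_uptake,
               peak_soce_est = fx$peak_soce,
               steady_true = true_ss, steady_est = ss_est,
               rel_err_peak = abs(fx$peak_uptake - true_peak) /
                 abs(true_peak),
               rel_err_steady = abs(ss_est - true_ss) / abs(true_ss))
  })
  do.call(rbind, out)
}
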