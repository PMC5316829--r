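# tsysquant

Quantification of skeletal-muscle **t-system** structure and calcium
handling from 3D confocal volumes, with a fully ground-truthed synthetic
phantom generator for validation.

## The problem

The tubular (t-) system of a skeletal muscle fibre — two transverse
tubules per sarcomere near the A–I band junctions plus peripherally
located longitudinal tubules, together about 1% of fibre volume — can
remodel dramatically: after eccentric exercise or high cytoplasmic
Ca²⁺, the longitudinal elements swell into series of vacuoles
(~0.8–1 µm across). Because a low-affinity Ca²⁺ indicator (rhod-5N,
in-situ K_D = 0.8 mM) can be trapped in the sealed t-system lumen of a
mechanically skinned fibre, both the network geometry and its luminal
Ca²⁺ handling are measurable by confocal microscopy. This package
implements the full analysis chain:

* **Restoration** — PSF estimation from 100 nm bead stacks and
  Richardson–Lucy maximum-likelihood deconvolution.
* **Network** — 3D topology-preserving skeletonization, classification
  of segments as transverse (θ < 45° to the transverse plane) or
  longitudinal, structure-tensor directionality histograms, and radial
  profiles of longitudinal-tubule density.
* **Vacuoles** — percentile-threshold segmentation (50–60th percentile
  of the within-fibre histogram), count, % fibre volume, and per-plane
  inverse-aspect-ratio roundness.
* **Calcium** — calibration
  `[Ca²⁺](t) = K_D · (F(t) − F_min)/(F_max − F(t))`, Savitzky–Golay
  flux extraction (`flux = B · d[Ca²⁺]/dt`), epoch steady states, the
  SOCE-versus-luminal-Ca²⁺ regression, and the calcium-content budget
  `content (µM per fibre volume) = B × [Ca²⁺]_t-sys (mM) × t-sysVol%/100 × 1000`.
* **Phantom** — a seeded generator of fibres with transverse lattices,
  peripheral longitudinal tubules, vacuole series, bead stacks, and a
  two-compartment luminal Ca²⁺ ODE (uptake, SOCE restricted to
  transverse tubules, restricted vacuole–tubule junction), so every
  operation is tested against exact ground truth.

The methods vignette (`vignettes/tsysquant-methods.Rmd`) documents the
models, defaults and numerical choices in detail.

## Worked example

```r
library(tsysquant)

## structure: phantom -> imaging -> restoration -> skeleton -> scoring
spec <- phantom_spec(fibre_radius = 2.7, fibre_length = 11.52,
                     dim = c(96L, 128L, 48L))
g    <- generate_tsys_volume(spec, seed = 1)
p    <- gaussian_psf(voxel_size = spec$voxel_size)
img  <- simulate_imaging(g$volume, p, noise_model = spec$noise_model, seed = 2)
dec  <- richardson_lucy(img, p, iterations = 25)
skel <- classify_segments(skeletonize(binarize_tubules(dec, "triangle"),
                                      spec$voxel_size))
segment_recovery(g$truth$segments, skel, spec$voxel_size)$recovered_percent

## calcium: simulate a protocol, calibrate, extract fluxes and budgets
cal <- calibration_params(K_D = 0.8, F_min = 100, F_max = 1100)
sp  <- sample_protocol(7)
sim <- simulate_ca_protocol(sp$protocol, sp$params, calib = cal,
                            noise_sd = 2, seed = 7)
ca  <- calibrate(sim$trace)
derive_flux(ca)[c("peak_uptake", "peak_soce")]
calcium_budget(B = 1, ca_t_sys = 1.4, t_sys_vol = 1.4)
budget_fold_change(calcium_budget(1, 1.4, 1.0), calcium_budget(1, 1.5, 4.8))
```

Output on this machine:

```
truth: tubules 1.00% of fibre volume, 10 transverse planes
<skeleton> 64 segments (1181 voxels): 50 transverse, 14 longitudinal
ground-truth segment recovery: 97.2%
peak uptake flux: 0.0182 mM/s (epoch uptake)
peak SOCE flux:   -0.0174 mM/s (epoch caffeine)
<calcium_budget> B=1 x 1.4 mM x 1.4% fibre volume = 19.6 uM per fibre volume
fold change on vacuolation: 5.14
```

Reading the numbers: the phantom renders the unvacuolated t-system at
1.0% of fibre volume; after simulated imaging and 25 Richardson–Lucy
iterations, 97% of ground-truth tubule segments are recovered with the
correct transverse/longitudinal label. On the calcium side, raising
cytoplasmic Ca²⁺ drives luminal uptake (positive flux) while caffeine
(store depletion) drives store-operated entry, an efflux from the lumen
(negative flux). A lumen holding 1.4 mM free Ca²⁺ in 1.4% of the fibre
volume amounts to 19.6 µM of calcium per fibre volume; vacuolation to
4.8% at 1.5 mM raises the held calcium just over five-fold.

## Command line

```sh
Rscript inst/cli/tsysquant.R phantom  --seed 1 --out phantom_out/
Rscript inst/cli/tsysquant.R restore  --volume phantom_out/volume.tif --iters 25 --out restored.tif
Rscript inst/cli/tsysquant.R network  --volume restored.tif --out skeleton.json
Rscript inst/cli/tsysquant.R vacuoles --volume raw.tif --percentile 55 --out vacuoles.csv
Rscript inst/cli/tsysquant.R calcium  --trace trace.csv --calib calib.json --out calcium_out/
```

Volumes are multi-page TIFF (16-bit acquisition, 32-bit float
intermediates) with JSON sidecars; traces are CSV
(`time_s, F, epoch_label`); configs are JSON.

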