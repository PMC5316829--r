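---
title: "Quantifying t-system remodelling and calcium handling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying t-system remodelling and calcium handling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsysquant)
```

## Scope

The tubular (t-) system of a skeletal muscle fibre is a network of
plasmalemmal invaginations — predominantly transverse tubules, two per
sarcomere near the A–I band junctions, plus peripherally concentrated
longitudinal tubules — that can seal off with a fluorescent calcium
indicator trapped in its lumen. After eccentric exercise, or under high
cytoplasmic calcium, the longitudinal elements swell into series of
vacuoles roughly 0.8–1 µm across. `tsysquant` quantifies both sides of
this biology:

* **structure** — deconvolution of confocal z-stacks, skeletonization of
  the tubular network, transverse/longitudinal classification,
  directionality histograms, and vacuole morphometrics (count, % fibre
  volume, roundness);
* **calcium handling** — conversion of trapped-dye fluorescence to
  luminal calcium, flux extraction, steady states, the store-operated
  calcium entry (SOCE) regression, and the luminal calcium-content
  budget `B × [Ca²⁺] × vol%`.

No raw imaging data are distributed; every analysis is exercised on a
ground-truthed synthetic phantom generator that emulates the imaging and
physiology, so all tests are self-contained and reproducible.

## The phantom: a stated world

`phantom_spec()` describes a straight cylindrical fibre aligned with the
y (long image) axis on a 256 × 256 × 64 voxel grid at 90 × 90 × 150 nm
voxels (finer than the 90/150 nm sampling limits of the source
acquisitions).

* **Transverse lattice.** Two perforated lattice planes per 2 µm
  sarcomere, at 0.25 and 0.75 of the sarcomere, each a rectangular grid
  of tubules encircling myofibril-sized cells. The lattice pitch is
  *calibrated by bisection* so the tubular mask hits the target volume
  fraction (default 1.0% of fibre volume, the unvacuolated t-system
  value) by exact voxel counting; the rendered pitch lands near ~2 µm
  because sub-voxel tubule widths cannot be rendered thinner than one
  voxel. The pitch can be pinned with `tubule_pitch`.
* **Longitudinal tubules.** Placed with radial probability ∝ (r/R)^k,
  k = 4 by default. The source imagery shows a peripheral bias but no
  functional form; the exponent is a free parameter and the radial
  profile analysis recovers whatever bias was generated.
* **Dye mass normalization.** Voxels on lines extended along z represent
  dz (150 nm) of tubule length rather than dx (90 nm), so they carry
  proportionally more dye. Without this, anisotropic rasterization would
  silently change the physics; with it, z-extended lines genuinely
  restore brighter (their blur spreads over less volume), which is why
  the pipeline's default binarization is the triangle threshold (below).
* **Vacuoles.** Ellipsoids (default 0.9 × 1.0 × 0.9 µm diameters) in
  longitudinal series spanning `vacuole_series_length` sarcomeres, one
  per sarcomere, at laterally separated peripheral positions. Vacuole
  and tubule voxels are disjoint label sets whose union is the t-system
  mask; all truth fractions are recomputable by voxel counting.
* **Noise.** Imaging applies PSF convolution, Poisson photon noise at
  `photon_scale` expected photons per unit intensity, and optional
  Gaussian read noise. The default (`photon_scale = 500`, no read
  noise) puts a blurred sub-voxel tubule at a peak SNR of ≈ 5–7 — a
  conservative setting for averaged structural confocal imaging. An
  earlier draft used a far dimmer setting under which a sub-resolution
  tubule carried ~3 expected photons; that regime is
  information-theoretically undetectable and does not correspond to
  structural acquisitions, so it was revised once and frozen.

What a green test does *not* establish: the phantom has no sarcomere
misalignment, no fibre curvature, no depth-dependent attenuation, no
spectral bleed-through, and its PSF is a separable Gaussian rather than
a measured aberrated kernel. Recovery percentages on this world are an
upper bound on what identical code would achieve on real volumes.

## Restoration

The PSF is estimated by averaging sub-resolution bead images
(`estimate_psf()`): detection at mean + 5 sd, sub-voxel centroid
refinement, trilinear alignment, background subtraction, clipping and
unit-sum normalization; beads with overlapping windows are excluded with
a warning. `richardson_lucy()` is the standard multiplicative update
with three numerical choices worth stating:

* **Boundary handling** is reflective padding by the kernel support,
  which keeps total intensity conserved to well under 0.5% on
  fibre-cropped volumes and avoids edge ringing.
* **Iterations** default to 25; the source methods do not state a count,
  and 25 is where tubule contrast has clearly converged on the phantom.
  Optional early stopping (`stop_tol`) is off by default.
* **Precision and truncation.** Convolutions inside the iteration run in
  single precision, and kernel taps below 1% of the peak are dropped
  and the rest renormalized (keeping > 97% of a confocal Gaussian's
  mass). Both effects are orders of magnitude below the photon noise
  floor; an identity kernel short-circuits so the fixed-point identity
  is exact. Anisotropic voxel mismatches are handled by resampling the
  PSF onto the volume's grid, never the data.

## Network extraction

Binarized volumes are thinned with a 3D topology-preserving algorithm
(simple-point deletion in six directional sub-iterations, endpoint
preservation), giving a one-voxel centreline whose branch points and
endpoints define segment polylines. Two thresholding methods are
offered: Otsu (the `binarize_tubules()` default, adequate when
foreground intensities are homogeneous) and triangle (the pipeline
default, which keeps the dim half of an anisotropically restored
network; see the dye-normalization note above).

Segment orientation θ is the angle between the segment's end-to-end
chord and the transverse plane; `label = transverse` when θ < 45°, else
longitudinal, with 45° itself longitudinal. The chord convention (vs
per-voxel tangents) was chosen for robustness on short noisy segments
and is the documented tie-break for everything downstream. Closed loops
(no endpoints) fall back to the principal axis of their polyline.

Recovery scoring (`segment_recovery()`) walks each ground-truth
centreline and takes, per sample point, the label of the *nearest*
skeleton voxel within a 2-voxel Chebyshev tolerance; a truth segment is
recovered when ≥ 60% of its samples are matched and the matched labels
agree by majority. Nearest-voxel voting matters: pooling all voxels in
the tolerance window lets the dense transverse lattice outvote a thin
longitudinal tubule that passes through it.

The directionality histogram uses the smoothed structure tensor
(gradient σ = 1 px, integration window σ = 2 px — the deterministic
choice; the plugin it emulates does not specify its internals), with
orientations weighted by the tensor anisotropy (λ₁ − λ₂) and expressed
as percentages over [0°, 90°] (signed [−90°, 90°] is available).

## Vacuole morphometrics

`segment_vacuoles()` thresholds at a percentile (default 55, midpoint of
the typical 50–60 range) of the intensity histogram *within the fibre
mask*, keeps voxels strictly greater than the threshold value, labels
26-connected components, and discards components smaller than a 0.4 µm
sphere. A point worth being explicit about: a percentile threshold with
a strict inequality can only isolate bright vacuoles when the
sub-threshold mass is tie-heavy — e.g. a mostly-zero quantized
background — because with a continuous unimodal background the 55th
percentile passes ~45% of voxels, which percolates into one giant
26-connected component. That tie-heavy regime is exactly the
vacuolated-state acquisition this operation is meant for: once dye has
been drawn from the tubules into the vacuoles, the transverse-tubule
signal sits at or below the detection floor. The quantile is computed
with type 1 (an actual data value) so the tie logic is exact, and a
constant volume yields an empty labelling rather than an error.

Roundness is the per-plane inverse aspect ratio from a second-moment
ellipse fit (with the pixel self-variance added so one-pixel-wide slices
stay finite), aggregated per vacuole by area-weighted mean — the
aggregation is not specified in the source description; area weighting
makes large, well-determined slices dominate. The 2D convention is
deliberate: a needle along z still scores ≈ 1. Count density is
reported per 1000 µm³ of fibre volume.

## Calcium model and analysis

Fluorescence calibrates through
`[Ca] = K_D (F − F_min)/(F_max − F)` with the in-situ K_D of 0.8 mM;
the forward map used by the simulator is its exact algebraic inverse, so
round trips are analytic. F ≥ F_max is an error (saturation), small
undershoots below F_min (≤ 2% of range) clamp to zero, and a guard at
98% of the range keeps the hyperbola finite.

The protocol simulator integrates, with fixed-step RK4 at 10 ms
(dynamics here have ≥ 10 s time constants; stiffness is not a concern):

```
d[Ca]_tt/dt  = up_tt a(c) − leak_tt [Ca]_tt − g_soce [Ca]_tt 1[caffeine] − J([Ca]_tt − [Ca]_vac)
d[Ca]_vac/dt = up_vac a(c) − leak_vac [Ca]_vac + J([Ca]_tt − [Ca]_vac)
```

with `a(c) = c/(c + K_act)` (Hill coefficient 1, the simplest monotone
activation consistent with uptake rising over the 28 nM–1.3 µM
cytoplasmic range; `K_act` defaults to 300 nM). Two modelling choices:

* **A basal leak for the transverse tubules** (default 0.02 s⁻¹) is not
  in the minimal uptake − SOCE − exchange formulation, but without it
  the lumen has no steady state under sustained uptake — contradicting
  the observed cytoplasmic-calcium-dependent steady states the
  `steady_state()` operation exists to measure. The vacuole leak
  defaults to 0 so that, with a fully restricted junction (J = 0),
  vacuoles never lose calcium during store depletion — the qualitative
  signature that vacuoles do not conduct SOCE.
* **SOCE as a first-order luminal efflux** gated by the caffeine epoch:
  caffeine is a boolean driving condition, not an SR model (out of
  scope).

Fluxes are `B × d[Ca]/dt` by Savitzky–Golay differentiation (window 5
frames = 4 s at the 0.8 s frame interval, order 2; edges use one-sided
fits, so linear ramps differentiate exactly). Peak uptake is the flux
maximum over non-caffeine epochs with cytoplasmic calcium ≥ 200 nM;
peak SOCE is the minimum over caffeine epochs (signed negative). The
flux units are luminal mM s⁻¹; an optional rescaling by the t-system
volume fraction reports µM s⁻¹ per fibre volume, since the axis units
of the source figures are not restated in its text and the regression
is treated as unit-agnostic.

The calcium budget is exact arithmetic:
`content (µM per fibre volume) = B × [Ca] (mM) × vol%/100 × 1000`, with
B = 1 for the t-system (and, conservatively, for vacuoles; a different
`B` can be passed).

```{r budget}
pre  <- calcium_budget(B = 1, ca_t_sys = 1.4, t_sys_vol = 1.0)
post <- calcium_budget(B = 1, ca_t_sys = 1.5, t_sys_vol = 4.8)
c(pre = pre$content, post = post$content,
  fold = budget_fold_change(pre, post))
```

## Performance choices

The 10-seed structural benchmark at 256 × 256 × 64 voxels runs in about
35 s per seed on one CPU: volumes are cropped to the fibre bounding box
(plus a PSF-support margin) before restoration, and Richardson–Lucy uses
the single-precision, tap-pruned convolution described above. Tests use
quarter-scale phantoms wherever full scale adds nothing.

## Known limitations

* The skeleton graph uses 26-connectivity chords; tubules thinner than a
  voxel are rendered one voxel wide (with a warning), so sub-voxel
  width variation is not modelled.
* Vacuole counting follows connected components; touching vacuoles are
  not separated by watershed, and vacuoles are not tracked over time.
* The SOCE regression is ordinary least squares over whatever flux units
  are supplied; no errors-in-variables treatment.
* Human-subject statistics from the source study (group comparisons,
  incidence counts) are out of scope; the property benchmarks on the
  phantom stand in for them.
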