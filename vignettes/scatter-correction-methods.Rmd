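---
title: "Iterative Monte Carlo scatter correction for cone-beam CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative Monte Carlo scatter correction for cone-beam CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Flat-panel cone-beam CT (CBCT) irradiates a large volume per projection, so
a substantial fraction of the detected signal is scattered radiation. In
the log-normalized projection $r_i = \ln(B_i / R_i)$ — with $B_i$ the blank
(air) scan and $R_i = P_i + S_i$ the total of primary and scatter — the
scatter term biases the line integrals downward, producing cupping,
streaks, reduced contrast-to-noise ratio (CNR), and CT numbers that are
unusable for dose calculation. `cbctscatter` implements a projection-domain
correction in which the scatter entering each projection is *estimated by
Monte Carlo simulation through the patient/phantom estimate itself*, and
the estimate is refined by iterating reconstruction and simulation.

## The correction model

If tilded symbols denote simulated quantities, the corrected log
projection is

$$p_i \;=\; (1+\alpha)\,r_i \;-\; \alpha\,\tilde r_i \;-\;
\ln \frac{\tilde P_i}{\tilde P_i + \beta \tilde S_i},$$

where

* $\alpha$ (dimensionless, default 0) is a relaxation parameter: the term
  $\alpha (r_i - \tilde r_i)$ compensates for systematic differences
  between measured and simulated attenuation. Our experiments reproduce
  the finding that $\alpha > 0$ does not speed convergence and amplifies
  voxel noise (see `test-acceptance.R`, criterion 4: the converged RMSE
  with $\alpha = 0.5$ exceeds that with $\alpha = 0$).
* $\beta \in (0,1]$ models an antiscatter grid as a pure scaling of the
  simulated scatter. It equals the ratio of scatter-to-primary ratios with
  and without the grid, `grid_beta()`; $\beta = 1$ means no grid, and a
  10:1 grid at SAD 100 cm / SDD 150 cm is around $\beta = 0.5$ (the
  clinical default here).
* $\tilde r_i$ is not defined explicitly in the original method description; we
  define it as $\ln(\tilde B_i / (\tilde P_i + \beta\tilde S_i))$, the
  simulated counterpart of the measurement with the grid effect applied,
  so that $r_i - \tilde r_i \to 0$ when simulation matches measurement.

The iteration (the loop of `run_correction()`):

1. Reconstruct the raw data (iteration 0) with FDK.
2. Convert the attenuation volume to a material + density phantom through
   the ramp (`volume_from_mu()`); negative FDK noise is clamped to zero.
3. Simulate primary (deterministic ray tracing) and scatter (Monte Carlo,
   adaptively smoothed, bicubically upsampled) for every projection angle.
4. Apply the correction above and reconstruct; repeat from 2 until the
   inter-iteration volume RMSE changes by less than `conv_tol` (default
   1%) or `max_iter` (default 3) is reached — the convergence criterion is
   not specified in the original method description and is our declared choice.

## Materials, ramp, density conversion

A voxel is assigned the material whose attenuation interval contains its
reconstructed $\mu_i$, and the density
$\rho_i = (\mu_i / \mu_\text{mat})\,\rho_\text{mat}$ — the fractional
method: transport recovers the attenuation *ratio* through the density
ratio. Interval ends are half-open $[\mu_\text{low}, \mu_\text{high})$ so
the ramp is a partition (the published table does not state open/closed
ends; this is our convention, tested at the boundaries).

Two consequences worth noting:

* The ramp's $\mu_\text{mat}$ must refer to the scan's reference spectrum.
  The Catphan ramp shipped in `inst/extdata/ramp_catphan.csv` belongs to a
  100 kVp clinical beam. For the monoenergetic 60 keV water-phantom
  experiment the package builds a spectrum-matched ramp
  (`make_mono_ramp(60)`); using the clinical ramp there biases densities
  by ~15% and stalls the iteration at a residual cupping plateau — this
  was observed directly during development.
* Cross sections are embedded (10–150 keV, 1 keV grid, per material:
  photoelectric, incoherent, coherent mass attenuation), generated once
  from a public XCOM-equivalent tabulation; `material_mu()` interpolates
  log–log. Interpolation error at grid midpoints is below 1% (tested
  against frozen values from a denser tabulation).

## Monte Carlo engine and variance reduction

Photons are transported with:

* **Woodcock (delta) tracking**: free paths are sampled from the volume's
  majorant attenuation $\mu_\max(E)$; interactions are real with
  probability $\mu_\text{local}/\mu_\max$, otherwise fictitious. This
  removes per-voxel ray tracing from transport.
* **Interaction splitting + Russian roulette**: at its first interaction a
  photon splits into $N_p$ daughters of weight $1/N_p$; daughters headed
  for scoring keep that weight, the rest survive roulette with probability
  $1/N_s$ at weight $N_s/N_p$; later interactions split by $N_s$, so every
  scored photon carries exactly $1/N_p$ (asserted at run time).
* **Forced detection**: at every Compton/Rayleigh vertex the analytic,
  attenuated contribution toward sampled detector points is scored
  (angular pdf × solid-angle factor × $e^{-\tau}$ × deposited energy).
  The scatter image is the sum of all scatter orders.
* **Path stretching**: an isotropic exponential transform (sampling rate
  $\mu_\max/(1+\kappa)$ with exact weight compensation), default off
  ($\kappa = 0$); the original direction-independent biasing scheme is not
  publicly specified.

Physics simplifications (documented, deliberate): Compton sampling is
free-electron Klein–Nishina (no binding/Doppler); channel *probabilities*
still come from the embedded bound (XCOM-style) cross sections, so total
attenuation is correct and only the angular/energy sampling is
approximate — a sub-percent effect on water scatter fractions at 60 keV.
Rayleigh uses independent-atom squared form factors per material with
rejection sampling. No electron transport; photons terminate below 10 keV.
The detector is an ideal energy integrator; absolute calibration cancels
in $\ln(B/R)$.

Primary images in the *pipeline* come from the deterministic Siddon ray
tracer (noiseless, exact voxel traversal); the Monte Carlo primary
estimator exists to verify unbiasedness (it agrees with the ray tracer
within 3σ on ≥99% of pixels). The blank scan is analytic.

Uncertainties are per-pixel batch standard errors (20 batches by default);
per-(angle, history) counter-based RNG streams make runs bit-reproducible
at fixed seed regardless of execution order.

### Scatter smoothing

Scatter distributions are low-frequency, so the raw Monte Carlo scatter
image is smoothed by a locally adaptive 2-D quadratic Savitzky–Golay
smoother: per pixel the largest square window is kept whose residuals are
χ²-consistent with the per-pixel uncertainties. The cited smoothing
algorithm's equations are not public; this implementation matches its
*contract* (large noise reduction on smooth fields, no bias at genuine
gradients), not its internals. On a flat field with 5% noise the smoother
reaches below 1% uncertainty; in the pipeline (windows up to 33×33 on the
256×192-style coarse scoring grid) the desk-scale post-smoothing scatter
uncertainty is ≈1%, approaching the published sub-percent regime.
$N_p = 32$, $N_s = 8$ defaults were chosen for the same reason; the original
experiments do not state their splitting parameters.

## Reconstruction

FDK filtered backprojection with cosine weighting, a smooth partial-arc
redundancy window, row-wise convolution with the discrete Shepp–Logan
kernel $h(n) = -2 / (\pi^2 \Delta u^2 (4n^2-1))$ on the virtual
(isocenter-plane) detector, and distance-weighted backprojection. The arc
window assigns each ray $w = s(\lambda) / (s(\lambda) + s(\lambda_c))$
with a raised-cosine taper $s$ and $\lambda_c$ the conjugate source angle;
rays measured once get weight 1, so conjugate weights sum to exactly 1
(tested to 1e-6) and a 360° arc reduces to uniform 1/2. On analytic
projections of a uniform water cylinder the central attenuation is
recovered to 0.3% (the acceptance bound is 2%).

Coordinate conventions (none are standard in the literature, so ours are fixed and documented): right-handed frame,
isocenter at origin, rotation axis z, source on +y at angle 0, detector u
along +x, v along +z, 0-based pixel indices with centers at
(index + 0.5) × pitch, half-open angle schedule. Scatter is scored on a
coarse grid (default half the detector resolution; 256×192 in the clinical
preset) and upsampled bicubically with an area rescaling, exactly because
scatter is smooth.

## The synthetic world and what green tests establish

`generate_fixture()` builds the two reference experiments:

* **water_phantom** — a 20 cm × 20 cm water cylinder with a coaxial
  2 cm × 10 cm air cavity, monoenergetic 60 keV, 360° arc, no grid
  (β = 1). Desk scale: 128³ voxels of 2 mm, 90 projections, 128×96
  detector, 10⁵ histories per simulated angle, and the rotational-symmetry
  shortcut the original experiment used (one projection computed, then
  replicated). The raw "measurement" is itself simulated (ray-traced
  primary + smoothed MC scatter), so the experiment has a noiseless
  scatter-free reference and the RMSE-vs-iteration curve can be measured
  exactly.
* **catphan_like** — a water-equivalent cylinder with the eight
  sensitometry inserts of the ramp table on a 6 cm ring under the clinical
  preset (200° arc, 100 kVp model spectrum, β = 0.5).

What these do **not** emulate: a real polyenergetic vendor spectrum with
bowtie filtration, detector blur/lag/energy response, beam hardening,
mechanical flex, or the vendor's raw projection format. A green
convergence test therefore establishes that the *algorithm* removes the
scatter it models — not that a physical scanner's CT numbers would reach
the same accuracy. The published per-ROI Catphan measurements are
reproduced only as metric arithmetic from the printed table (they require
the physical scanner); the printed, integer-rounded table limits how
exactly the published summary CNR ratio can be recomputed, and the
acceptance suite documents one such clause as unattainable (19.4% vs the
printed 18% ± 1 point).

## Numerical choices and degenerate inputs

* Intensities below $10^{-6} \max(B)$ are floored before logs (Monte Carlo
  zeros must not become infinities); counts are reported.
* Negative reconstructed attenuation is clamped to 0 before material
  assignment (the ramp has no negative bin); counts are reported.
* Vacuum is handled explicitly: density 0, no interactions, zero cross
  sections; `mu_to_density()` maps anything assigned to vacuum to 0.
* Per-iteration Monte Carlo seeds advance deterministically from the base
  seed, so iterations are statistically independent but reruns are
  bit-identical.
* The convergence RMSE is evaluated in HU over a cylindrical mask (default
  radius 11 cm) to exclude the empty corners of the field of view.
* `run_correction()` halts with a warning (partial results returned) if
  the convergence metric increases on two consecutive iterations.

## Known limitations

* Free-electron Compton and approximate Rayleigh angular models; no
  binding effects or Doppler broadening.
* No beam hardening correction: air-cavity CT numbers converge with a
  residual offset, consistent with the published observation that air ROIs
  dominate the corrected RMSE.
* The 100 kVp spectrum model is a filtered Kramers shape, not a measured
  tube spectrum.
* FDK is approximate off the central plane (cone artifacts at large |z|);
  both the corrected volume and the reference share them, so convergence
  metrics are unaffected, but absolute edge-slice accuracy is not claimed.
* The replicate-projection shortcut is valid only for rotationally
  symmetric phantoms and correlates the Monte Carlo noise across angles,
  which sets the plateau level of the RMSE-vs-iteration curve (visible as
  ring-like residuals, as in the original experiment).
* At the desk-scale history budget, `alpha = 0.5` settles onto its
  (noisier) stationary level through a damped oscillation: the relaxation
  term overshoots from the heavily contaminated start, iteration 2 dips
  below the stationary RMSE and iteration 3 returns to it (a 6-iteration
  trace reads 102.8 → 50.8 → 26.9 → 31.7 → 30.6 → 30.3 → 31.5 HU versus
  102.8 → 29.0 → 19.6 → 19.3 → 19.9 → 19.6 → 20.2 for `alpha = 0`). At
  ~100× more histories per projection the transient is invisible; with
  the desk budget the corresponding plateau-flatness acceptance clause
  for `alpha = 0.5` sits at the edge of its band (it passes at the
  suite's default seed, and seed-to-seed variation can push it over; the
  band was not widened to hide this). The practical reading is
  unchanged: use `alpha = 0`.
* A related pitfall, fixed in the spectrum-matched ramp: with the vacuum
  threshold at the air attenuation itself, zero-clamped reconstruction
  noise in empty space adds net scattering mass to the phantom estimate
  and biases the loop toward over-correction; the mono ramp therefore
  assigns vacuum below 0.02 cm⁻¹ (air's density is a negligible
  scatterer, so nothing physical is lost).
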