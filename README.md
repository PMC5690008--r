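# cbctscatter

Iterative Monte Carlo scatter correction for cone-beam CT (CBCT), as an R
package.

Flat-panel CBCT projections are heavily contaminated by scattered X-rays,
which produce cupping artifacts, CT-number errors of hundreds of HU, and
degraded contrast-to-noise ratio (CNR). This package implements, end to
end, a projection-domain correction in which the scatter reaching the
detector is estimated by Monte Carlo photon transport through the
patient/phantom estimate itself, and refined iteratively:

> reconstruct → assign materials/densities → simulate primary + scatter →
> correct projections → reconstruct → …

It is aimed at medical imaging physicists who want a self-contained,
testable implementation: digital voxel phantoms with embedded photon cross
sections, a transport engine with the standard variance-reduction stack,
FDK reconstruction, the correction itself, and Catphan-style image-quality
metrics.

## The model

With `B` the blank scan, `R = P + S` the measured total, and tilded
quantities simulated, the corrected log projection is

    p_i = (1 + alpha) * r_i - alpha * r~_i - ln( P~_i / (P~_i + beta * S~_i) ),
    r_i = ln(B_i / R_i)

`alpha` is a relaxation parameter (default 0); `beta` in (0, 1] models an
antiscatter grid as the ratio of scatter-to-primary ratios with/without
the grid (≈0.5 for a 10:1 grid at SAD 100 / SDD 150 cm). Voxels are
assigned materials by an attenuation ramp and densities by the fractional
rule `rho_i = mu_i / mu_mat * rho_mat`. Image quality is quantified by
`RMSE = sqrt(mean((mu_i - mu_i,ref)^2))` over ROI means and
`CNR = |mu_A - mu_B| / sqrt(sd_A^2 + sd_B^2)`, on a CT-number scale with
water = 1024 HU.

The transport engine uses Woodcock (delta) tracking, interaction splitting
(Np) + Russian roulette (Ns) so that every scored photon carries weight
1/Np, forced detection at every scatter vertex, and a locally adaptive
Savitzky–Golay smoother for the scatter projections. Primary and blank
images come from a deterministic Siddon ray tracer. Reconstruction is FDK
with a Shepp-Logan kernel and a smooth partial-arc redundancy window.

See `vignettes/scatter-correction-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

The bundled water-phantom experiment: a 20 cm water cylinder with a 2 cm
air cavity, monoenergetic 60 keV, 360° arc, no grid (`beta = 1`), with the
raw scan itself simulated (ray-traced primary + Monte Carlo scatter):

```r
library(cbctscatter)

fx  <- generate_fixture("water_phantom", "desk", seed = 1)
raw <- simulate_raw_scan(fx)
cfg <- fx$config
cfg$reference <- fx$reference          # scatter-free reference volume

res <- run_correction(raw, fx$params, cfg)
print(res$trace)
```

Output from this code (seed 1, desk scale: 128³ phantom, 90 projections,
1e5 histories per simulated angle):

```
  iteration rmse_vs_prev rmse_vs_reference
1         0           NA            100.94
2         1       82.695             27.36
3         2       21.096             19.19
4         3        6.747             19.94
```

`rmse_vs_reference` is the HU root-mean-square error of each volume
against the scatter-free reconstruction: the uncorrected scan (iteration
0) is off by ~100 HU from scatter-induced cupping; two iterations remove
most of it and the curve plateaus at the Monte Carlo noise floor — the
signature convergence behavior of the method. The uncorrected volume shows
a center-to-edge attenuation ratio of ≈0.90 (cupping); the corrected one
is flat.

Metric arithmetic on the published Catphan sensitometry table (printed
per-ROI means/SDs/CNRs are shipped as data):

```r
rep <- metrics_report_from_stats(catphan_roi_table(), "pCT",
                                 exclude = c("Air1", "Air2"))
print(rep)
#>  metrics_report (reference: pCT )
#>       recon  rmse rmse_excl mean_sd mean_cnr
#>         pCT    NA        NA     8.9     38.5
#>         raw 175.8     153.5    18.8     12.4
#>   corrected  65.4      34.4    20.0     14.8
#>      varian  47.7      50.4    28.4     13.0
```

The RMSE drops from 175.8 HU (raw CBCT) to 65.4 HU after correction
(34.4 HU when the beam-hardening-dominated air ROIs are excluded), and the
mean CNR rises from 12.4 to 14.8 — the published improvement pattern.

## Command line

```sh
Rscript -e 'cbctscatter::cbct_cli()' phantom  --name water_phantom --scale desk --out ph.egsphant
Rscript -e 'cbctscatter::cbct_cli()' correct  --name water_phantom --scale desk --seed 1 --out vol.mha
Rscript -e 'cbctscatter::cbct_cli()' metrics  --exclude Air1,Air2 --out report.csv
```

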