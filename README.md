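# gpmembrane

Quantitative analysis of environment-sensitive membrane dye readouts in
R: generalized polarization (GP) from spectra and two-channel images,
manually seeded watershed segmentation with per-cell plasma-membrane GP,
cross-dye statistics (Tukey HSD, Deming errors-in-variables regression),
and bilayer-trajectory geometry for probe-localization analysis.

## The scientific problem

Dyes such as di-4-ANEPPDHQ, Laurdan and di-8-ANEPPS shift their
emission with the physical state of the surrounding membrane. The
standard readout is the **generalized polarization**

```
GP = (I_blue − I_red) / (I_blue + I_red),   GP ∈ [−1, 1]
```

computed either from band-integrated emission spectra of cell
suspensions or pixel-by-pixel in two-channel confocal images. Comparing
such readouts across dyes and sterol treatments — and interpreting the
comparison through where each probe's sensing moiety actually sits in
the bilayer — requires a reproducible chain: pixel GP with explicit
validity masking, seeded-watershed identification of cells and of their
plasma-membrane pixels, per-cell median GP, treatment statistics
(one-way ANOVA + Tukey HSD), Deming regression between dye readouts
(both variables carry error, so ordinary least squares is wrong), and
trajectory post-processing that measures P–P bilayer thickness, probe
tilt to the membrane normal, heavy-atom RMSD, and the signed depth of
the chromophore edge atoms (N2, C23) below the phosphate plane, with
trailing-window means and a two-start convergence check.

gpmembrane implements that chain for analysts working with this dye
family, plus a synthetic-data module (`make_cell_image()`,
`make_spectrum()`, `make_trajectory()`) that generates images, spectra
and bilayer-like trajectories with recorded ground truth, so the whole
pipeline is testable end to end without any external download. Packaged
depth presets place the probes at 4.4 Å (di-4-ANEPPDHQ), 3.7 Å
(di-8-ANEPPS) and 10.6 Å (Laurdan) below the membrane–water interface
with a 30° mean tilt.

## Worked example

Segment a synthetic 20-cell field and recover per-cell membrane GP,
then measure a probe's insertion depth on a synthetic trajectory:

```r
library(gpmembrane)

set.seed(7)
spec  <- image_spec(image_shape = c(384L, 384L), n_cells = 20L,
                    per_cell_gp = runif(20, 0.1, 0.6), seed = 7)
field <- make_cell_image(spec)

out <- run_pipeline(list(
  input = list(image = field$image, seeds = truth_seeds(field$truth),
               treatment = "CHOL"),
  seed = 1))
out$report
#> gpmembrane run report (v0.1.0)
#>   pixels valid: 3540 / 147456 (threshold 344.5)
#>   cells: 20 seeded, 20 reported, 0 excluded
head(out$records, 3)
#>   cell_id treatment median_gp n_membrane_pixels
#> 1       1      CHOL 0.5936986               194
#> 2       2      CHOL 0.2979814               131
#> 3       3      CHOL 0.1651609               147

summarize_treatments(out$records$median_gp, out$records$treatment)
#>   treatment  n      mean        sem   median        q1        q3
#> 1      CHOL 20 0.3054554 0.03663542 0.259227 0.1717251 0.4026878
```

Each record is one cell's median GP over its plasma-membrane pixels
(valid pixels only, at least 20 per cell); the Otsu threshold 344.5
masked everything but the bright membrane rings. The recovered medians
track the simulated per-cell truth to a few thousandths of a GP unit.

```r
tj <- make_trajectory(trajectory_spec(dye_depth = "di4-ANEPPDHQ", seed = 42))
window_average(depth_series(tj$trajectory), window_ns = 100)
#> Window 200.0-300.0 ns (1001 frames): midpoint depth 4.46 +/- 1.36 A (SD)
#>   edge atoms: 8.71 / 0.22 A; SEM(midpoint) 0.275 A
```

The chromophore-midpoint depth over the last 100 ns, 4.46 Å, recovers
the di-4-ANEPPDHQ preset (4.4 Å) well within one standard error — the
superficial localization that distinguishes the ANEP-type probes from
deeply buried Laurdan (preset 10.6 Å).

For shell use there is a thin wrapper over the same functions in
`inst/scripts/gp-pipeline.R`
(`--image field.tif --seeds seeds.csv --out dir`).

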