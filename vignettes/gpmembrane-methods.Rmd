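---
title: "Models and methods behind gpmembrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpmembrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmembrane)
```

# Scope

gpmembrane quantifies readouts of environment-sensitive membrane dyes
(di-4-ANEPPDHQ, Laurdan, di-8-ANEPPS) along four connected stages:

1. **Generalized polarization (GP)** from emission spectra and,
   pixel-by-pixel, from two-channel images.
2. **Manually seeded watershed segmentation** with per-cell
   plasma-membrane pixel extraction and per-cell median GP.
3. **Group statistics**: treatment summaries, one-way ANOVA with Tukey
   HSD, and Deming errors-in-variables regression for comparing two dye
   readouts across treatments.
4. **Bilayer-trajectory geometry**: phosphate-plane (P–P) thickness,
   probe tilt to the membrane normal, heavy-atom RMSD, and the signed
   depth of the chromophore edge atoms below the membrane–water
   interface, with trailing-window averages and a two-start convergence
   criterion.

Because no raw experimental data ship with the package, a first-class
synthetic-data module generates images, spectra and bilayer-like
trajectories with recorded ground truth; every downstream stage is
validated against that truth.

# Generalized polarization

For blue- and red-edge emission intensities $I_B$ and $I_R$,

$$\mathrm{GP} = \frac{I_B - I_R}{I_B + I_R} \in [-1, 1],$$

the canonical ratiometric index for this dye family: a blue-shifted
(dehydrated, ordered) environment raises GP. `compute_gp()` implements
exactly this and signals the undefined $I_B = I_R = 0$ case as `NA`,
which `gp_map()` converts into a validity mask.

*Spectral GP.* `spectrum_gp()` integrates a measured emission spectrum
over a blue and a red window by the trapezoid rule with linear
interpolation at the window edges (`integrate_band()`). The default
windows, 500–580 nm and 620–750 nm, follow common di-4-ANEPPDHQ practice
after 488 nm excitation; they are instrument settings, so both are plain
arguments, never hard-coded.

*Pixel GP.* `gp_map()` evaluates GP wherever the summed channel
intensity strictly exceeds a threshold; other pixels are invalid. The
default threshold is Otsu's method on the summed image (parameter-free
and reproducible); any numeric threshold can be supplied instead.
Optional constant background subtraction per channel
(`subtract_background()`) clips negative intensities to zero and records
the constants it applied.

# Synthetic imaging model

`make_cell_image()` renders non-overlapping disc cells with a bright
membrane annulus, a dimmer interior, and a dark background; per-cell GP
values split the total expected intensity into channels by
$I_B = I\,(1+\mathrm{GP})/2$, $I_R = I\,(1-\mathrm{GP})/2$, inverting
the GP definition exactly. Noise is Poisson photon noise plus additive
Gaussian read noise per channel, negatives clipped at zero. Defaults:
600 photons/pixel on the membrane, 120 in the interior, 20 background,
read noise SD 3 — typical confocal orders of magnitude, chosen once as
conventions (the real microscope's noise characteristics are not
published, so these are not calibrations). The membrane annulus is
rendered 2 px wide: at the usual ~0.2 µm sampling a plasma membrane is
diffraction-limited to about that apparent width, and the extraction
band (3 px, below) must be wider than the ring for its intensity
refinement to trim band contamination rather than genuine membrane
pixels. An optional `noise_seed` separates the noise draw from the
placement draw so that noise replicates over a fixed field can be
generated; with the single `seed`, regeneration is bit-identical.

What the generator does *not* emulate: real cell morphology,
intensity inhomogeneity along the membrane, out-of-focus light,
spectral bleed-through, and interior organelles. Passing the recovery
tests therefore demonstrates correctness of the algorithms under the
stated noise model, not robustness to every property of real
micrographs.

# Seeded watershed and membrane extraction

`seeded_watershed()` floods the gradient magnitude of a
Gaussian-smoothed copy of the summed-intensity image from user-supplied
seeds (a CSV of clicked points in the interactive workflow; perfect
seeds from ground truth in the synthetic one). Design points:

* Landscape: gradient magnitude by central differences after Gaussian
  smoothing. The smoothing SD defaults to **1 px**, matched to the
  apparent membrane thickness: for a thin bright ring, the outer
  gradient crest of the blurred profile drifts outward by roughly a
  third of the smoothing SD, so heavier smoothing (e.g. 2 px)
  systematically inflates every label by about a pixel. The SD remains
  configurable.
* Connectivity 8; ties in the flood are broken first-in-queue with a
  fixed seed insertion order (background seeds, then cell seeds in file
  order), making the partition deterministic — including on constant
  images.
* Every pixel receives exactly one label; the region grown from the
  background seeds is label 0 and cell labels are numbered in seed
  order.
* If two cell regions first touch at a flood level no higher than
  either seed's own gradient value, the seeds likely sit in one
  catchment basin; both labels are kept and a warning is raised (no
  silent merge).
* A rank-based landscape option replaces intensities by their ranks
  before smoothing, making the partition invariant under any strictly
  increasing intensity transform.

One known failure mode, visible in the 50-cell stress field: when two
cells approach within ~2 px, the background basin can annex one cell's
bright ring through the low-gradient saddle in the gap. The interior
label, the per-cell GP (synthetic interiors share the cell's GP) and
the field-level pixel accuracy are unaffected, but that cell's membrane
mask is then wrong; field-aggregate membrane overlap remains high.
Wider seeds or per-case smoothing resolve it interactively.

`extract_membrane()` defines each cell's plasma-membrane pixels as the
band within `band_width` (default 3) of the label boundary on the inner
side — the label minus its box erosion, so masks are disjoint across
cells by construction — refined by keeping pixels at or above the
`refinement_quantile` (default 0.5) intensity quantile within the band.
The quantile rule is closed (ties retained), so a uniform band is kept
whole. `per_cell_median_gp()` then takes the median GP over each cell's
membrane pixels intersected with the validity mask, excluding cells
with fewer than `min_pixels` (default 20) valid pixels; exclusions are
counted in the run report. Medians use the standard midpoint convention
for even counts.

# Group statistics

`summarize_treatments()` reports mean, SEM ($s/\sqrt{n}$ with the
$n-1$ sample SD; a single observation yields `NA`, not 0), median and
quartiles per treatment.

`anova_tukey()` fits the one-way ANOVA with `stats::aov()` and derives
all-pairs Tukey HSD comparisons from the pooled MSE: the Tukey–Kramer
standard error $\sqrt{\tfrac{MSE}{2}(n_a^{-1}+n_b^{-1})}$, the
studentized-range statistic $q = |\bar y_b - \bar y_a|/SE$, and
$p = P(Q_{k,\nu} > q)$ via `stats::ptukey()`. With two groups this
reduces exactly to the pooled two-sided t-test ($q = t\sqrt 2$). A
zero pooled variance with unequal means is reported as the $p \to 0$
limit with a warning; identical constants give $F = 0$ and $p = 1$.

`deming_fit()` implements the closed-form Deming estimator for error
variance ratio $\delta = \sigma^2_y/\sigma^2_x$:

$$\hat\beta = \frac{s_{yy} - \delta s_{xx} +
 \sqrt{(s_{yy}-\delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}},
 \qquad \hat\alpha = \bar y - \hat\beta \bar x.$$

$\delta$ defaults to 1 (orthogonal regression), the standard choice
when the error-variance ratio is unknown; it is echoed in every result.
Standard errors come from the leave-one-out jackknife and the slope
p-value from $t = \hat\beta/\widehat{SE}$ with $n-2$ degrees of
freedom — a distribution-free recipe appropriate when both dye readouts
carry error. In-sample $s_{xy}=0$ leaves the slope undefined and is an
error rather than a silent fallback. Two calibration facts, both
measured by this package's own simulations: at $n \ge 8$ the test is
well calibrated (empirical type-I error 0.049 at $n=8$), but at $n = 4$
— the treatment-level design, one point per treatment — it is
conservative (type-I error ≈ 0.034 at nominal 0.05). Users comparing
dye pairs over four treatments should read non-significance
accordingly. `correlate_dyes()` applies the fit per response column
against a common predictor over matched treatment rows and flags
significance at raw (unadjusted) p-values; that no multiple-testing
correction is applied across the (two) dye pairs is recorded in the
output attributes.

# Bilayer-trajectory geometry

Conventions, fixed and recorded: the membrane normal is the laboratory
+z axis (flat synthetic bilayers; no per-frame plane fitting); lengths
in Angstrom, times in ns, angles in degrees.

* `assign_leaflets()` splits phosphate atoms at their median z; an atom
  exactly at the median goes to the bottom leaflet.
* `membrane_thickness()` is the difference of leaflet-mean phosphate z
  (P–P thickness).
* `tilt_angle()` is the angle between a named atom pair (default the
  N2–N3 chromophore pair) and +z, reported in [0°, 180°]; folding to
  [0°, 90°] is an explicit option, never silent.
* `heavy_atom_rmsd()` superposes the dye's heavy atoms onto a
  reference by translation plus the Kabsch rotation (proper rotation
  enforced) and reports the residual RMSD. In `depth_series()` the
  reference is the first analyzed frame and the fitting group is the
  dye's heavy atoms; both choices are stated here because other
  conventions exist.
* `interface_distance()` measures from the mean z of the proximal
  leaflet's phosphates (the membrane–water interface) to a named atom,
  signed positive toward the bilayer centre; the proximal leaflet is
  determined once, from the first frame (the dye is assumed not to
  flip), and recorded.
* `window_average()` averages the trailing window (default 100 ns,
  closed at its left edge) and reports, besides means and SDs, a
  batch-means standard error of the windowed midpoint mean (20
  batches), which absorbs the autocorrelation of the depth process.
* `convergence_time()` compares the running means of two trajectories'
  chromophore-midpoint depths and reports the earliest time from which
  they stay within a tolerance (default 1 Å) for a full hold period
  (default 20 ns); series on different grids are linearly interpolated
  onto their common grid. A pair that never satisfies the criterion
  returns `NA` explicitly.

# Synthetic trajectories

`make_trajectory()` builds a kinematic bilayer: two phosphate grids at
$\pm$ thickness/2 with per-frame Gaussian jitter, and a rigid-rod dye
in the top leaflet whose chromophore-midpoint depth below the proximal
phosphate plane and whose tilt both follow exact-discretization
Ornstein–Uhlenbeck processes. The OU choice is deliberate: its
stationary mean and SD are closed-form, so recovery tests can state
their tolerances from first principles (the effective sample size of a
window of length $T$ is about $T/2\tau$ for relaxation time $\tau$).
`initial_depth_offset` starts the depth away from its mean — 5 Å
emulates a second embedding model placed deeper toward the bilayer
centre — and decays with the relaxation time, which is what the
two-start convergence analysis exercises.

The packaged depth presets place the probes' sensing moieties at
4.4 Å (di-4-ANEPPDHQ), 3.7 Å (di-8-ANEPPS) and 10.6 Å (Laurdan) below
the interface, with a 30° mean tilt: the superficial ANEP-type
localization versus Laurdan's deep one is the geometric contrast the
depth-recovery tests reproduce, including the >5 Å Laurdan-minus-di-4
gap. Edge atoms carry the chromophore-boundary names N2 (deep edge in
this generator) and C23, with N3 adjacent to N2 so the N2→N3 vector
lies along the rod axis; all names are arguments downstream, nothing is
hard-wired. No force field, no interactions, no curvature: these are
coordinates with the right statistics, not physics.

# Problem sizes and numerical choices

Test and acceptance workloads are sized for a laptop-class single core:
300 ns trajectories at 0.1–0.25 ns frames (1 201–3 001 frames,
32 phosphates), 512×512 px fields with 40–50 cells, 200-replicate
ANOVA simulations and $10^4$-replicate Deming null simulations; the
whole suite runs in well under a minute. Tolerances: exact algebraic
identities at 1e-9 or machine precision; the spectral round trip at
1e-6 (the generator solves band amplitudes with the same quadrature the
analysis uses, so the noiseless round trip is exact by construction);
stochastic recoveries at 3 standard errors with SEs stated from OU
theory or batch means. Trapezoid integration is used throughout for
spectra; watershed determinism comes from the fixed tie-break, not from
floating-point luck.

# Known limitations

* The segmentation is 2-D, single-frame, and requires seeds; there is
  no automatic detection or tracking.
* Near-touching ring-stained cells can lose their membrane band to the
  background basin (see above).
* The Deming slope test is conservative at $n = 4$.
* Trajectory analysis assumes a flat bilayer normal to z, a non-flipping
  dye and pre-unwrapped coordinates; sterol-containing bilayers,
  curvature and order parameters are out of scope.
* The synthetic generators trade realism for analytic ground truth;
  conclusions about real micrographs or real simulations require the
  corresponding real inputs, which the readers and writers accept in
  standard formats (TIFF, CSV, PDB, multi-model PDB).
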