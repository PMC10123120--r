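---
title: "Methods: simulating and analysing intracellular locus search dynamics"
author: "locusdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing intracellular locus search dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(locusdyn)
```

## The problem

After conjugative transfer into a recipient cell, an integrative and
conjugative element (ICE) must physically locate its chromosomal attachment
site (*attB*) before it can integrate. Two-colour single-particle tracking
of the element (green channel) and of the labelled *attB* loci (red channel)
in rod-shaped bacteria turns this search into a quantitative trajectory
problem: where do the loci sit along the cell, how do they move, and which
stochastic process class is compatible with that motion?

`locusdyn` implements the full measurement chain — stochastic motion models,
a diffraction-limited microscopy renderer, sub-pixel spot localization in
cell-frame coordinates, trajectory linking, anomalous-diffusion statistics,
and behaviour classification — so that every analysis stage can be validated
against simulations with known ground truth.

## Motion models

### Fractional Brownian motion

The workhorse model is fractional Brownian motion (FBM), parameterised by a
scaling exponent $\alpha \in (0, 1]$ and an apparent diffusion coefficient
$D$ so that the ensemble mean square displacement is exactly

$$\mathrm{MSD}(\tau) = D\,\tau^{\alpha}.$$

Its increments (fractional Gaussian noise) are stationary with
autocovariance

$$\gamma(k) = \frac{D\,\Delta t^{\alpha}}{2}
  \left(|k+1|^{\alpha} - 2|k|^{\alpha} + |k-1|^{\alpha}\right),$$

negative for all $k \ge 1$ when $\alpha < 1$ (antipersistence, the
signature of a viscoelastic medium). `simulate_fgn_axis()` draws these
increments *exactly* by circulant embedding (Davies–Harte): the covariance
is embedded in a circulant matrix whose eigenvalues are obtained by FFT, so
generation is $O(n \log n)$ with no approximation. For $\alpha \le 1$ the
embedding is positive semi-definite in practice; should the eigenvalues come
out materially negative on some parameter combination, the code falls back
to an exact $O(n^2)$ Cholesky factorisation rather than truncating.

```{r fgn}
x <- simulate_fgn_axis(alpha = 0.5, D = 1, dt = 1, n_frames = 5e4, seed = 1)
c(empirical_lag1 = mean(x[-1] * x[-length(x)]),
  theory_lag1 = fgn_autocov(1, alpha = 0.5))
```

Axes are simulated independently with their own $(\alpha, D)$, which is how
the anisotropy between motion along (longitudinal, $y$) and across
(transversal, $x$) the cell is modelled.

### Alternatives: CTRW and obstructed diffusion

Two alternative subdiffusion mechanisms are provided because the analysis
must be able to *exclude* them:

* **Continuous-time random walk** (`model = "ctrw"`): renewal process with
  Pareto waiting times $\psi(w) \sim w^{-1-\beta}$, $\beta \in (0,1)$
  (default $0.5$), and Gaussian jumps, observed on the regular frame grid.
  The waiting-time scale defaults to $\Delta t / 100$ so that the frame lags
  sit deep in the ageing regime, where the ensemble-averaged MSD grows as
  $\tau^{\beta}$ while the time-averaged MSD stays near-linear — the
  ergodicity contrast the analysis looks for.
* **Obstructed diffusion** (`model = "od"`): nearest-neighbour lattice walk
  (lattice constant 20 nm, 10 attempted moves per frame) among quenched
  blocked sites (default density 0.35). Near the site-percolation threshold
  this walk is transiently subdiffusive.

A caveat discovered by simulation and asserted in the test suite: at density
0.35 the obstructed walk is genuinely antipersistent on the observation
scale and its velocity autocorrelation tracks the FBM curve *at its own
mild effective exponent* (about 0.8). What obstructed diffusion cannot do is
reproduce the deep antipersistence dip that FBM shows at a strongly
subdiffusive exponent such as 0.36; that, not a flat VACF, is the
discriminating observable. Similarly, an ageing CTRW observed far above its
waiting-time scale has uncorrelated velocities, so its rescaled VACF
collapses — but onto the *uncorrelated* curve, far from the FBM prediction
at its own (subdiffusive) ensemble exponent.

## Anomalous-diffusion statistics

### MSD, time- and ensemble-averaged

`ta_msd()` computes the time-averaged MSD with overlapping windows (all
valid start times contribute at every lag; frames lost to linking gaps are
excluded pairwise), per axis or in 2D; `ea_msd()` averages the squared
displacement from each trajectory's first frame across the ensemble, with
no time averaging. `fit_power_law()` fits $\log \mathrm{MSD}$ against
$\log \tau$ by ordinary least squares — the simplest defensible reading of
"power-law fit"; a weighted fit is deliberately not the default because the
weights would have to come from a model of the very correlations being
estimated. The default fit range is lags 2–10: on image-derived data the
static localization error adds a floor that inflates lag 1, and no
correction for it is attempted (a stated limitation); on noise-free
simulated input the fitted values are range-invariant, which the tests
assert. The fit returns a classed model object:

```{r fit}
cfg <- sim_config("fbm", alpha_x = 0.36, alpha_y = 0.36, D_x = 2000,
                  D_y = 2000, dt = 4.23, n_frames = 90, n_traj = 59,
                  seed = 2)
fit <- fit_power_law(ta_msd(simulate_trajectories(cfg)), lag_range = 1:10)
summary(fit)
```

### Velocity autocorrelation and the self-similarity collapse

`vacf()` correlates finite-difference velocities
$\bar u(t) = (\bar r(t+\delta) - \bar r(t))/\delta$ at lag $\tau$,
time-averaged within each trajectory and ensemble-averaged with equal
weights (each trajectory counts once regardless of length), then normalized
by the zero-lag value. For FBM the normalized curve depends on $\delta$ and
$\tau$ only through $\xi = \tau/\delta$:

$$C(\xi) = \tfrac12\left\{(\xi+1)^{\alpha} + |\xi-1|^{\alpha}
  - 2\xi^{\alpha}\right\},$$

with its minimum $(2^{\alpha} - 2)/2$ at $\xi = 1$. `rescale_collapse()`
interpolates curves measured at different $\delta$ onto a common $\xi$ grid
(default $0$–$4$ in steps of $0.25$) and reports the RMS spread across
curves plus the RMS deviation from the closed form — both below 0.05 for
well-sampled FBM ensembles.

```{r vacf, fig.alt = "Rescaled velocity autocorrelation curves collapsing onto the FBM master curve"}
trajs <- simulate_trajectories(sim_config("fbm", alpha_x = 0.36,
                                          alpha_y = 0.36, D_x = 2000,
                                          D_y = 2000, dt = 4.23,
                                          n_frames = 200, n_traj = 100,
                                          seed = 3))
col <- rescale_collapse(lapply(c(1, 2, 4, 8), function(m)
  vacf(trajs, delta = m)), alpha = 0.36)
plot(col)
col
```

### Ergodicity verdict

`ergodicity_report()` fits the power law to both the time-averaged and the
ensemble-averaged MSD and compares the exponents. The verdict is
"consistent" when $|\alpha_{TA} - \alpha_{EA}| \le \max(3\,\mathrm{SE},
0.2)$. The 0.2 floor is chosen a priori as the midpoint between the zero gap
expected for an ergodic process and the gap $1 - \beta = 0.5$ expected for
the default CTRW alternative; it also guards against the optimism of OLS
standard errors computed from correlated log-log points. The walk dimension
$d_w = 2/\alpha$ (`walk_fractal_dimension()`) summarises the consequence:
$d_w > 2$ means compact, space-filling exploration — a thorough search.

## The synthetic population generator

`simulate_population()` is the study-conditions generator: each cell is a
stadium-shaped rod carrying two *attB* trajectories and one ICE trajectory
whose behaviour class is drawn from a configured mixture. Defaults, chosen
once as field-realistic values:

| parameter | default | rationale |
|---|---|---|
| cell length | 3000 ± 300 nm | typical exponential-phase rod |
| cell width | 900 nm | typical rod diameter |
| *attB* positions | 0.25, 0.75 of length | replicated-locus home positions |
| *attB* motion | $\alpha_y = 0.426$, $\alpha_x = 0.247$; $D_y = 2500$, $D_x = 1200$ nm²/s^α | the anisotropic operating point under study; $D$ sized to give ~50–70 nm frame-to-frame steps at 4.23 s framing |
| frame interval | 4.23 s | acquisition interval emulated |
| movie length | 90 frames | ~6 min acquisition |
| tether (integrated) | 200 ± 25 nm | label-geometry offset of an integrated pair |
| fast mobile | $\alpha = 0.6$, $D_y = 5 \times 10^4$ | cell-spanning within one movie |
| locally mobile | $\alpha = 0.5$, $D = 1.5 \times 10^4$, confined ±300 nm of mid-cell | visible steps without spanning |
| trapped | $\alpha = 0.4$, $D = 300$ | radius of gyration below 150 nm |
| camera | 109.76 nm/px, PSF σ 130 nm, 2000 photons/spot, background 100, read noise 2 | shot-noise-limited localization at a few nm |
| localization noise (render bypass) | 20 nm/axis | matches the rendered-route precision |

Positions are confined by *reflection* at the cell envelope (minus an 80 nm
margin); trajectories are parameterised to stay far from the boundary, so
no MSD plateau is induced at the fitted lags. Trapped elements are placed
away from the *attB* home positions, since a trapped-but-not-integrated
element sitting exactly on its target would be observationally
indistinguishable from an integrated one. One global seed expands to
per-cell sub-seeds through a splittable counter (`sub_seed()`), so
populations are reproducible independent of evaluation order.

The relative mobilities of the "fast" and "local" classes are assumptions
(the distinction is qualitative in origin); they are stated here and in
`population_config()`'s documentation rather than hidden.

What the generator does **not** emulate: photophysics (blinking,
bleaching), 3D point-spread functions, cell growth and division, lineage
effects, segmentation artefacts of dense or touching colonies, and any
drug mechanism (the condition presets of `run_config()` only re-weight
mixtures and scale $D$). Passing recovery tests therefore demonstrate that
the estimators and the classifier are correct and well-calibrated for data
of this structure — not that real microscopy meets these assumptions.

## Localization chain

* **Pixel convention**: 0-based indices, pixel center at integer
  coordinates; all CSV output is in nm after scaling by the pixel size.
* **Segmentation** (`segment_cells()`): Otsu threshold, morphological
  closing, hole filling, connected-component labelling (border-touching
  components excluded). The centerline is the sequence of transverse
  midpoints binned along the principal axis, median-smoothed — adequate for
  straight-to-gently-curved rods; the coordinate transform itself accepts
  arbitrary polyline centerlines.
* **Spot detection** (`detect_spots()`): per-cell robust threshold, median
  plus $k$ MADs of in-mask intensities ($k = 5$); the MAD degenerates to
  zero on noise-free synthetic images, in which case the SD is used.
  Clusters above a quarter of the cell area are rejected as artifacts. At
  most two spots per channel per cell are accepted; frames violating this
  are dropped and counted.
* **Sub-pixel fit** (`fit_spot_gaussian()`): Gaussian plus constant over a
  7×7 px window by Levenberg–Marquardt least squares, $\sigma$ bounded to
  $[0.5, 5]$ px; non-converged or bound-hitting fits are rejected. Window
  size and bounds are assumptions, documented here.
* **Cell frame** (`to_cell_frame()`): $x$ = signed perpendicular distance
  to the nearest centerline segment, $y$ = arc length from the
  center-of-mass projection; projections beyond the centerline ends are
  clamped and flagged. Pole identity is frozen at the first frame of a
  movie and re-imposed on later frames by aligning the principal-axis
  direction, because geometry is re-fit every frame.

The rendered-image round trip achieves a localization bias below 5 nm
noiseless and a per-axis RMSE below 25 nm at the default camera settings
(asserted in the test suite).

## Linking and classification

Linking (`link_trajectories()`) is greedy nearest-neighbour with a
displacement gate (800 nm at ~4 s framing), gap closing up to 2 frames, and
deterministic tie-breaks; with at most two spots per channel per cell,
greedy assignment is almost always optimal, and an exhaustive optimal
variant is available behind a flag for validation. Frames with rejected
fits are gaps, never zeros. Trajectories shorter than 20 frames are
discarded.

`classify_ice()` applies an explicit threshold cascade: *integrated* if the
median nearest-*attB* distance over the final half of the series is below
300 nm with no distance step above 500 nm there (300 nm gives margin over
the ~200 nm tether plus localization noise); else *fast mobile* if any step
exceeds 200 nm and the longitudinal span exceeds 40 % of the cell length
("a large portion of the cell" is operationalised as 40 %, a stated
stand-in); else *locally mobile* if any step exceeds 200 nm; else
*trapped*. Fractions are reported with binomial standard errors.
`mobility_filter()` (steps > 200 nm) excludes integrated elements before
pooling longitudinal positions, and `position_distribution()` normalises
positions by cell length, with optional pole folding since pole identity is
arbitrary at the population level.

```{r classify}
pop <- simulate_population(population_config(n_cells = 150, seed = 4))
classify_population(pop$tracks, pop$cells)
```

## Validation problem sizes

The test suite validates: the increment autocovariance over $10^5$ steps
(within 3 SE at lags up to 20); ensemble MSD against $D\tau^{\alpha}$
within 5 % (1000 trajectories); exponent recovery sweeps at 100
trajectories × 100 frames for $\alpha \in \{0.25, 0.5, 0.75, 1\}$ and at
the anisotropic operating point (59–60 trajectories × 90 frames, 20 seed
replicates); classifier recovery on populations of 500–1223 cells within
binomial 95 % confidence intervals; the VACF collapse at 200 trajectories ×
200 frames; ergodicity discrimination at 400 trajectories; and the rendered
localization round trip on single-cell stacks. Exact-identity checks
compare `ta_msd()` and `mobility_filter()` against brute-force $O(n^2)$ /
exhaustive reimplementations.

## Known limitations

* No static-localization-error subtraction from the MSD; lag 1 is excluded
  from fits instead.
* The ergodicity verdict is a two-point exponent comparison, not an
  ageing/EB-parameter analysis.
* The centerline estimator assumes near-straight rods; strongly bent cells
  would need a medial-axis method.
* Obstructed diffusion near the percolation threshold mimics FBM over
  finite observation windows (see above); model exclusion rests on the
  *combination* of ergodicity, exponent depth and collapse, as in the
  analysis this package operationalises.
* Pole identity (and hence the sign of $y$) is arbitrary per cell;
  population position histograms should be read pole-folded unless cells
  were oriented by an independent marker.
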