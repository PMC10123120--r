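# locusdyn

Single-particle dynamics of chromosomal loci and integrative conjugative
elements (ICEs) in rod-shaped bacteria.

After conjugative transfer, an ICE must physically find its chromosomal
attachment site (*attB*) inside the recipient cell before it can integrate.
Two-colour time-lapse microscopy of the element and of labelled *attB* loci
turns that search into a trajectory-analysis problem. `locusdyn` is an R
package for scientists doing this kind of single-particle tracking in
bacteria: it implements the complete chain from stochastic motion models
with known ground truth, through microscopy rendering and sub-pixel
localization in cell-frame coordinates, to anomalous-diffusion statistics
and behaviour classification — so every stage of the analysis can be
validated before it touches real data.

## The statistics at the core

Locus motion is summarised by the mean square displacement
MSD(τ) = ⟨(**r**(t+τ) − **r**(t))²⟩, fitted as a power law

    MSD(τ) = D·τ^α

per axis (longitudinal *y*, transversal *x*) and in 2D, with α < 1
indicating subdiffusion and d_w = 2/α > 2 compact, space-filling search.
Mechanism discrimination uses:

* **Ergodicity**: time-averaged vs ensemble-averaged MSD exponents agree
  for fractional Brownian motion (FBM), diverge for an ageing
  continuous-time random walk (CTRW);
* **Velocity autocorrelation**: C_u^δ(τ) = ⟨ū(t+τ)·ū(t)⟩ with
  ū(t) = (r̄(t+δ) − r̄(t))/δ, which for FBM collapses under ξ = τ/δ onto

      C(ξ) = {(ξ+1)^α + |ξ−1|^α − 2ξ^α} / 2,

  a curve with a negative (antipersistent) minimum at ξ = 1.

The FBM simulator draws exact fractional Gaussian noise by circulant
embedding, so recovery tests run against analytically known targets.

## Worked example

Simulate an ensemble at an anisotropic subdiffusive operating point,
recover the exponents, and check the mechanism diagnostics:

```r
library(locusdyn)
cfg <- sim_config("fbm", alpha_x = 0.247, alpha_y = 0.426,
                  D_x = 1200, D_y = 2500, dt = 4.23,
                  n_frames = 90, n_traj = 60, seed = 8)
trajs <- simulate_trajectories(cfg)
fit_power_law(ta_msd(trajs, component = "y"), lag_range = 1:10)
#> Power-law MSD fit: MSD = D * tau^alpha
#>   component: y (time-averaged), lags 1-10
#>   alpha = 0.428 +/- 0.003
#>   D     = 2564 nm^2/s^alpha (log-scale SE 0.010)
fit_power_law(ta_msd(trajs, component = "x"), lag_range = 1:10)
#>   alpha = 0.277 +/- 0.007
#>   D     = 1124 nm^2/s^alpha (log-scale SE 0.023)
```

The generating exponents (0.426, 0.247) are recovered with a clear
longitudinal/transversal asymmetry. The ergodicity diagnostic and the
antipersistence dip confirm FBM-like motion:

```r
ergodicity_report(trajs)
#>   TA fit: alpha = 0.395 +/- 0.005, D = 3630
#>   EA fit: alpha = 0.461 +/- 0.079, D = 3042
#>   delta alpha = -0.066 +/- 0.079 -> consistent with ergodicity
vacf(trajs, delta = 1)
#>   normalized C at tau = delta: -0.341
```

(The FBM closed form predicts (2^0.395 − 2)/2 ≈ −0.343 at ξ = 1.)

Population-level behaviour classification on a synthetic cohort of
transconjugant cells:

```r
pop <- simulate_population(population_config(n_cells = 200, seed = 9))
classify_population(pop$tracks, pop$cells)
#> Behaviour classification of 200 cells
#>   thresholds: integration 300 nm (step <= 500 nm), mobility 200 nm, span > 0.4 L
#>         label   n            pct
#>    integrated 100 50.0 +/- 3.5 %
#>   mobile_fast  28 14.0 +/- 2.5 %
#>  mobile_local  62 31.0 +/- 3.3 %
#>       trapped  10  5.0 +/- 1.5 %
#>    mobile_any  90 45.0 +/- 3.5 %
```

The classifier recovers the generated mixture (50 % integrated, 14 % fast,
31 % local, 5 % trapped) exactly at this cohort size.

`run_pipeline(run_config(...))` orchestrates the whole chain (optionally
through image rendering and localization) into a run directory with CSV
tables, a resolved YAML config, a JSON summary and SVG figures; a thin
command-line wrapper lives in `inst/scripts/locusdyn.R`.

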