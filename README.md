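# canopyflow

Do canopy-forming nursery habitats shelter juvenile fish from tidal flow?
Answering that requires two quantitative chains, and `canopyflow` implements
both as a tested R package:

* **Turbulence arm** — processes acoustic Doppler velocimeter (ADV) burst
  records (three velocity components at 25 Hz, four-minute bursts, several
  elevations above the seabed): phase-space threshold despiking, zero-phase
  low-pass mean/fluctuation decomposition, streamline coordinate rotation
  with profile-level angle averaging, and estimation of the turbulence
  energy dissipation rate ε from the inertial subrange,

  E_u(k) = E_v(k) = (9/55) α₁ ε^{2/3} k^{−5/3},  E_w(k) = (4/3) E_u(k),

  with α₁ = 1.5, converting frequency to wavenumber spectra via Taylor's
  frozen-turbulence hypothesis (k = 2πf/U, E(k) = E(f)·U/2π) and fitting the
  vertical component, which has the lowest ADV noise floor. An optional
  joint fit estimates a white instrument-noise floor alongside ε.

* **Behaviour arm** — analyses per-minute counts of juvenile fish at four
  camera positions around an artificial seagrass unit (ASU):
  autocorrelation-driven record thinning (ACF acceptable at lag 4 → retain
  every fifth record), median polynomial quantile regression against water
  velocity, a quasi-Poisson GLM for abundance and a binomial GLM for the
  water-column proportion (`~ tide * camera_position`), with Tukey HSD
  pairwise contrasts.

A first-class synthetic-data module (`simulate_adv_burst()`,
`simulate_profile()`, `simulate_counts()`) generates both kinds of input
with known ground truth — spectral synthesis with exact band variances,
injected spikes and sensor misalignment; AR(1)-correlated overdispersed
counts with position/tide effects — so every stage has a recovery test.

## Worked example

Simulate one burst at the canopy trailing edge with a known dissipation rate
of 2×10⁻⁵ m² s⁻³, 0.5% spikes and a (3°, 2°, 1°) sensor misalignment, then
run the full processing chain:

```r
library(canopyflow)
p <- turb_sim_params(epsilon = 2e-5, mean_speed = 0.2, spike_rate = 0.005,
                     angles = c(3, 2, 1), seed = 42)
b <- simulate_adv_burst(p, elevation = 15, location = "C")
r <- process_burst(b)
r$angles
#> <rotation_angles> xy 2.9998 deg, xz 2.0056 deg, cross -22.4468 deg (roll)
r$estimate
#> <dissipation_estimate> epsilon = 2.005e-05 m^2 s^-3 (w component)
#>   band 31.4-377 rad m^-1, 451 bins, RMS log10 resid 0.119, slope -1.28
```

The x–y and x–z misalignments are recovered to hundredths of a degree and
ε to within 0.3% of truth. (The roll angle zeroes the *sample* v′w′
covariance; with weak anisotropy it is scatter-dominated, but a roll of
even 22° perturbs the vertical spectrum by under 4%.)

The count arm, end to end on simulated data shaped like the field design
(10 ASUs × 4 positions × 23 observed minutes):

```r
tab <- simulate_counts(count_sim_params(seed = 42))
k <- select_table_thinning(tab)   # pooled ACF analysis per camera position
k
#> [1] 5
g <- tukey_pairwise(fit_abundance_glm(thin_table(tab, k)))
g
#> <glm_report> quasipoisson GLM (sequential tests), dispersion 7.903
#>                   term df statistic statistic_type         p
#> 1                 tide  1   0.05433              F 0.8159470
#> 2      camera_position  3   6.26928              F 0.0004422
#> 3 tide:camera_position  3   2.08396              F 0.1037080
#> Tukey-adjusted pairwise contrasts:
#>                                       pair estimate     se adjusted_p
#> 1 (down-current 1 m) - (down-current edge)  0.49608 0.1718    0.02025
#> 2   (down-current 1 m) - (up-current edge)  0.54095 0.1748    0.01064
#> ...
```

The generator placed the highest abundance down-current of the canopy; the
fitted model detects the position effect (F = 6.27, p < 0.001) and the Tukey
contrasts localise it to the down-current 1 m camera, mirroring the report
structure of the field analysis (two GLM families × three terms × six
contrasts).

`run_pipeline(demo_config(seed = 1))` executes the whole chain — simulate →
despike/decompose/rotate → ε profiles → thin → GLMs — and writes
`burst_summary.csv`, `epsilon.csv`, `counts_thinned.csv`, `glm_report.json`
and a log, all stamped with the configuration hash and seed; identical
configurations give byte-identical reports.

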