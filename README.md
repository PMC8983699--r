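# nanocapture

Quantifying nano- and microplastic capture on nanocellulose films.

`nanocapture` implements the complete quantitative workflow for measuring
how many model plastic nanoparticles a bio-based film captures from a
dispersion, combining three instruments whose raw signals disagree on
purpose:

- **QCM-D** (quartz crystal microbalance with dissipation) senses the
  *hydrated* adsorbed mass — particles plus their acoustically coupled
  water — through the Sauerbrey relation Δm = −(C/n)Δf.
- **SEM-style image analysis** counts the particles themselves after
  drying, giving the *dry* surface mass density through a global histogram
  threshold, connected components and single/cluster decomposition.
- **Fluorescence depletion** measures the captured amount in bulk from the
  concentration drop of the surrounding dispersion.

The kinetic backbone is **random sequential adsorption (RSA)**:
irreversible placement of non-overlapping disks, whose coverage saturates
at the jamming limit θ∞ ≈ 0.547 (far below hexagonal packing, 0.9069).
Adsorption follows

    dΓ/dt = k_a · c · B(Γa/m),

where the blocking function B(θ) is the probability that an arriving
particle finds room: a cubic expansion at low coverage, the asymptotic
K₀(θ∞ − θ)³ law near jamming, and (by default) a blend that switches
between the two where they intersect (θ ≈ 0.289). Fitting the integrated
rate equation to a QCM-D trace rescaled against the image-analysis dry
mass recovers the adsorption rate coefficient `k_a` and the area `a`
occupied per particle — particle plus bound water — and comparing hydrated
to dry mass yields the coupled-water factor (≈ 3.2 for 100 nm polystyrene
on cellulose nanofibrils: about two thirds of the sensed mass is water).

A Monte Carlo hard-disk deposition simulator (C++ kernel, grid-hashed,
driven by R's RNG) verifies the jamming constant, cross-validates the
blocking function, and supplies planted ground truth to a synthetic-data
generator that emulates all three instruments.

The package is tidyverse-native: tabular results are tibbles, models ship
broom-style `tidy()`/`glance()` accessors and ggplot2 `autoplot()`
methods.

## Worked example

Simulate one full experiment with known ground truth (k_a = 1e-5 cm/s,
a = 6e4 nm², coupled-water factor 3.2, 2 % trace noise) and run the
complete analysis chain — image counting, hydration estimate, rescaling
and kinetic fit:

```r
library(nanocapture)

ps <- particle_spec(100, 1.05, label = "PS(100 nm)")
print(ps)
#> <particle_spec> PS(100 nm)
#>   diameter  100 nm (effective 110 nm)
#>   density   1.05 g cm^-3
#>   mass      5.5e-07 ng

scn <- scenario(seed = 1)
q <- generate_qcmd_trace(scn)

# plant the micrograph at the coverage the kinetics actually reached
gamma_end <- tail(q$truth$gamma$gamma, 1)
img <- generate_sem_image(scn, coverage_solid_air(gamma_end, scn$m, ps))

res <- analyze_capture(
  q$trace, list(img$image), ps,
  c = scn$c, m = scn$m,
  substrate = "CNF film", particle_label = "PS(100 nm)",
  fit_until_s = scn$duration_s, mode = "clustered")

print(res$fit)
#> <rsa_fit>
#>   ka_c = 0.9742 ng cm^-2 s^-1, a/m = 0.001174 cm^2 ng^-1
#>   k_a = 9.742e-06 cm s^-1, a = 6.175e+04 nm^2 (c = 1e+05, m = 5.26e-07)
#>   adjusted R^2 = 0.9936, regime = blended, converged = TRUE

print(res$summary)
#> # A tibble: 1 × 12
#>   substrate particle   delta_f5 delta_D5 water_factor gamma_max theta_air
#>   <chr>     <chr>         <dbl>    <dbl>        <dbl>     <dbl>     <dbl>
#> 1 CNF film  PS(100 nm)    -342.       21          3.2      380.     0.069
#> # ℹ 5 more variables: theta_liquid <dbl>, a_nm2 <dbl>, d_rsa <dbl>,
#> #   k_a <dbl>, fractional_coverage <dbl>
```

Both generating parameters come back within a few percent, and the
declared water factor 3.2 is recovered. The jamming constant itself is one
call:

```r
jam <- simulate_jamming(seeds = 1:10)
sprintf("pooled jamming coverage: %.4f +/- %.4f", jam$theta_inf, jam$se)
#> [1] "pooled jamming coverage: 0.5440 +/- 0.0016"
```

## Modules

| Area | Functions |
|---|---|
| RSA model | `rsa_blocking()`, `rsa_blocking_jamming()`, `rsa_kinetics()`, `integrate_rsa()`, `surface_coverage()` |
| MC simulator | `simulate_rsa()`, `estimate_jamming()`, `simulate_jamming()`, `check_hard_core()` |
| QCM-D | `sauerbrey_mass()`, `dissipation_ok()`, `rescale_to_dry_mass()`, `coupled_water_factor()`, `coverage_summary()` |
| Fitting | `fit_rsa()` (+ `tidy()`, `glance()`, `predict()`, `autoplot()`) |
| Image analysis | `histogram_threshold()`, `threshold_mask()`, `detect_particles()`, `particle_density()`, `surface_mass_density()` |
| Fluorescence | `fit_calibration()`, `captured_particles()`, `captured_mass()`, `quantify_fluorescence()` |
| Synthetic data | `scenario()`, `generate_qcmd_trace()`, `generate_sem_image()`, `generate_fluorescence_dataset()`, `synthesize_dataset()` |
| Pipeline / IO | `analyze_images()`, `analyze_capture()`, `read_qcmd()`, `read_sem_image()`, `read_deposition()` + writers |

The methods vignette (`vignettes/quantifying-capture.Rmd`) documents the
model, the numerical choices and the generator's realism limits.

## License

MIT (see `LICENSE`).
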