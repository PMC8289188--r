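# amypom

Quantitative analysis of polyoxometalate (POM) inhibition of S100A9
amyloid formation.

S100A9 is a pro-inflammatory, amyloidogenic calcium-binding protein;
nanosized polyoxyanion clusters such as decaniobate (Nb10) and
monotitanoniobate (TiNb9) suppress its self-assembly into fibrils. The
package is for biophysicists analysing the standard readouts of such
inhibition experiments — plate-reader thioflavin-T (ThT) kinetics,
fluorescence titrations, acrylamide quenching, circular dichroism (CD)
spectra and AFM cross-sections — and for anyone who wants seeded
synthetic versions of those data to validate an analysis end to end.

## What it computes

* **Isodesmic kinetics.** S100A9 aggregates without a lag phase; the
  normalized ThT signal follows the step-growth extent of reaction
  `p(t) = kt/(1 + kt)` (the closed-form solution with a backward rate is
  also provided). `fit_kinetic_trace()` estimates the apparent rate `k`
  per trace; `fit_rate_concentration()` fits the dose response
  `k(c) = α·exp(−βc) + γ`, with `β` the susceptibility of the rate to
  the inhibitor.
* **Binding isotherms.** `fit_titration()` fits the one-site model
  `S(c) = S0 + (S∞ − S0)·c/(Kd + c)` to decreasing (or increasing)
  fluorescence titrations, with an optional exact depletion-corrected
  variant for Kd near the protein concentration.
* **Quenching.** `fit_quenching()` fits the sphere-of-action model
  `F0/F = (1 + Ksv·Q)·exp(V·Q)` and converts the action volume `V` to a
  radius with the litre-based convention `V = N_A·(4/3)πr³`.
* **Spectra.** Weighted spectral difference
  `WSD = sqrt(mean(w·(ref − test)²))` with reference-magnitude weights,
  repeat-based standard deviations, background subtraction and
  first-derivative peak localization.
* **AFM heights.** Median, median deviation and n; a permutation test
  for shifts between height distributions.
* **Synthetic data.** Seeded generators for every input above
  (`gen_kinetic_panel()`, `gen_titration_curve()`,
  `gen_quenching_curve()`, `gen_spectrum()`, `gen_heights()`).

See `vignettes/pom-inhibition-analysis.Rmd` for the models, their
assumptions and the design choices.

## Worked example

Recover a dissociation constant and a quenching radius from synthetic
curves generated at realistic parameters, then run the whole kinetics
pipeline:

```r
library(amypom)

tc <- gen_titration_curve(Kd = 2.48, S0 = 100, Sinf = 40,
                          noise_fraction = 0.02, seed = 42)
fit_titration(tc$conc_uM, tc$signal)
#> <binding_fit> Kd = 2.424 +/- 0.18 uM, S0 = 102, Sinf = 39.97 (rss 41)

qc <- gen_quenching_curve(Ksv = 5.24, r = 7.7, noise_fraction = 0.01,
                          seed = 42)
fit_quenching(qc$Q_M, qc$F)
#> <quench_fit> Ksv = 5.426 +/- 0.14 1/M, V = 1.107 1/M, r = 7.6 A (rss 0.00986)

res <- run_pipeline(list(output_dir = "amypom-output", seed = 7))
res$summary
#>   pom_id pom_conc_uM  k_mean     k_sd n_replicates
#> 1   none         0.0 0.20639 2.26e-03            3
#> 2    POM        37.5 0.14224 9.76e-04            3
#> 3    POM        75.0 0.09966 1.12e-03            3
#> 4    POM       150.0 0.04943 2.65e-04            3
#> 5    POM       300.0 0.01500 4.16e-05            3
#> 6    POM       600.0 0.00549 1.31e-04            3
#> 7    POM       750.0 0.00518 1.44e-04            3
res$rate_model
#> <rate_conc_fit> alpha = 0.201, beta = 0.0101, gamma = 0.005135 (rss 4.66e-07)
```

The fitted `Kd` (2.42 µM) and radius (7.6 Å) sit within one standard
error of the generating values (2.48 µM, 7.7 Å); the pipeline fits all
21 traces of a simulated plate, aggregates triplicate rates per
condition (`k_mean ± k_sd`, strictly decreasing with POM concentration)
and recovers the dose–response parameters that generated the panel
(α = 0.2, β = 0.01 µM⁻¹, γ = 0.005). `run_pipeline()` also writes
`trace_fits.csv`, `condition_summary.csv`, `rate_model.json` and a run
log to the output directory.

A thin command-line wrapper over the same functions is installed at
`inst/cli/amypom.R` (subcommands `simulate`, `fit-kinetics`,
`fit-rates`, `fit-titration`, `fit-quenching`, `wsd`, `afm-stats`).

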