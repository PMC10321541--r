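# tempozoo

Quantitative toolkit for cross-species ("stem cell zoo") studies of the
mammalian **segmentation clock** — the oscillatory HES7 gene-expression
circuit in presomitic mesoderm (PSM) cells that times somite formation and
runs at a species-specific pace (about 2 h per cycle in mouse, over 6 h in
marmoset). The package is aimed at developmental and systems biologists who
record HES7 reporter dynamics in PSM-like cells differentiated from
pluripotent stem cells of several species and want to turn those recordings,
plus bulk RNA-seq, into comparable tempo measurements.

It provides four connected analyses:

1. **Oscillator model** — the two-variable delayed negative-feedback system

   dM/dt = a_m / (1 + (P(t−τ_M)/p_0)^h) − b_m·M,  dP/dt = a_p·M(t−τ_P) − b_p·P,

   integrated by fixed-step RK4 with the method of steps (compiled), with the
   measured human reference kinetics (b_m = 0.044 min⁻¹, b_p = 0.0175 min⁻¹,
   intron delay 36.7 min, transcription/translation delay 29.8 min) as
   defaults, a peak-to-peak period measure, the closed-form approximation
   T ≈ 2(τ_intron + τ_txtl + 1/b_m + 1/b_p), and a linear scaling sweep
   (rates × s, delays / s) testing whether proportional acceleration of the
   feedback-loop biochemistry accounts for cross-species period differences.

2. **Kinetics estimators** for luminescence reporter traces: wavelet period
   (sinc detrending → amplitude normalization → Morlet continuous wavelet
   transform, time-averaged power over a 100–500-min scan), protein
   half-life (RANSAC search for the most linear part of the log2 decay
   curve, excluding the residual-mRNA plateau), and intron delay
   (non-negative-lag cross-correlation of a dual-reporter pair with
   parabolic sub-sample interpolation).

3. **Cross-species scaling** — OLS fits of the clock period against
   organismal traits and against the measured kinetics, in vivo somite
   periods from embryo staging tables, and the fastest-to-slowest period
   ratio.

4. **Expression profiling** — one-to-one ortholog gluing across species,
   GeTMM normalization (gene-length-corrected trimmed mean of M-values),
   an expression floor, per-gene Spearman correlation of species-mean
   expression with the clock period with *exact* permutation p-values
   (720 permutations at n = 6), tempo-gene-set selection (ρ < −0.8) with a
   pre-ranked export for enrichment tools, and a selected-vs-random
   expression-ratio comparison between conditions.

A first-class **synthetic-data module** generates oscillation traces (drift,
damping, noise), biphasic decay traces, phase-shifted dual-reporter pairs and
planted multi-species count matrices, so every estimator is validated
closed-loop: the measured values seed the generators and the estimators must
return them.

## Worked example

Measure the three kinetic parameters from synthetic marmoset-like recordings,
then place them in the cross-species context:

```r
library(tempozoo)

## period from a drifting, noisy oscillation recording
tr <- gen_oscillation_trace(osc_trace_spec(period = 388, duration = 4320, dt = 10,
                                           drift_slope = 2e-4, noise_sd = 0.05, seed = 1))
estimate_period(tr, detrend_config(cutoff_period = 500))
#> <period_estimate> 387.44 min (power 67.74)

## protein half-life from a biphasic decay recording
dec <- gen_decay_trace(decay_trace_spec(halflife = 46, duration = 900, plateau_min = 120,
                                        noise_sd = 0.01, seed = 1))
estimate_halflife(dec, seed = 0)
#> <halflife_estimate> 46.02 min (slope -0.0217 log2/min, 48 inliers, R2 1.000)

## intron delay from a dual-reporter pair
pair <- gen_dual_reporter(dual_reporter_spec(period = 388, duration = 4320, lag = 54,
                                             noise_sd = 0.05, seed = 1))
estimate_delay(pair$without_intron, pair$with_intron, max_lag = 194,
               config = detrend_config(500))
#> <delay_estimate> 53.17 min (peak correlation 0.989)
```

The period estimate sits on the 2-min scan grid next to the generating
388-min period; the half-life and delay come back within a minute of the
values that seeded the generators (the RANSAC window starts at 120 min,
exactly where the plateau ends). In the species context:

```r
period_ratio_extremes(species_zoo_table())
#> [1] 3.2    # fastest (mouse, 122 min) to slowest (marmoset, 388 min)

kinetics_scaling_report(species_zoo_table())$period_vs_halflife
#> <scaling_fit> period ~ identity(hes7_halflife): slope 10.73, intercept -108.5, R2 0.997 (n = 4, 2 dropped)

scaling_sweep(dde_parameters(), c(0.5, 1, 2))
#>     s   period sustained
#> 1 0.5 592.1333      TRUE
#> 2 1.0 293.0333      TRUE
#> 3 2.0 142.8944      TRUE
```

The clock period is tightly linear in the HES7 protein half-life across the
four species with measured kinetics (R² = 0.997; the two species without
measured kinetics are dropped and counted), and the simulated period halves
when all degradation rates are doubled and all delays halved — the linear
scaling law, with the s = 1 period within 0.1% of the 292.74-min closed
form. `run_pipeline(list(seed = 1))` runs all three analyses end to end on a
freshly generated fixture bundle and returns the estimates plus a provenance
block.

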