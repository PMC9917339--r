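# afmrheo

Analysis of AFM force curves and sweep-frequency microrheology on living
cells, written for single-cell biophysics work such as comparing healthy,
scar and Dupuytren palmar fibroblasts and tracking their response to
cytoskeletal inhibitors.

A conventional force curve yields only an *apparent* Young's modulus
`E_app` through the Hertz contact model,

    F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)        (sphere/paraboloid)
    F = (2/pi) tan(theta) (E / (1 - nu^2)) delta^2        (cone)

because elastic and viscous contributions cannot be separated from a
quasi-static ramp. The sweep-frequency experiment holds the tip in contact
and oscillates the z-piezo at stepped frequencies (1 Hz - 1 kHz, analyzed
to 100 Hz); demodulating force and indentation gives the complex modulus
`E*(f) = E'(f) + i E''(f)`, which is fitted with the power-law structural
damping model

    E*(f) = E0 (1 + i eta) (f / f0)^alpha + i 2 pi f mu,
    eta = tan(pi alpha / 2)

after subtracting the cantilever's hydrodynamic drag force
`i 2 pi f b(0) z_hat`. `E0` is the storage modulus at the reference
frequency `f0` (1 Hz), `alpha` the power-law exponent, `mu` a Newtonian
viscosity and `eta` the hysteresivity coupled to `alpha`.

The package implements the whole chain -- a plain-text force-curve
container, segmentation, contact-point detection, Hertz fitting,
demodulation, drag calibration/correction, structural damping fitting,
cohort statistics (exact rank tests, Cohen's d, the `*`/`#`/`##`
annotation convention), inhibitor time-course fate classification -- plus
a synthetic force-curve generator with known ground truth, so every stage
is verifiable by closed-loop round trips without instrument data.

## Worked example

Synthesize a Dupuytren-like cell, calibrate drag out of contact, and run
the full analysis:

```r
library(afmrheo)
ins <- instrument_config(sweep = sweep_schedule(f_max = 100),
                         sample_rate = 1000,
                         noise_sd_force = 5e-12, b0 = 2e-6)
cell <- cohort_preset("dupuytren")   # E_app 5364 Pa, E0 4259 Pa,
                                     # alpha 0.12, mu 13 Pa.s
curve <- generate_force_curve(cell, ins, seed = 1)
cal <- estimate_drag(generate_drag_curves(ins,
                                          heights = c(1e-6, 2e-6, 4e-6),
                                          seed = 2),
                     n_extrapolate = 2)
res <- analyze_sweep_curve(curve, drag = cal)
res
#> <sweep_analysis>
#>   <hertz_fit> E = 5347 Pa over [1.78e-08, 5.28e-07] m (27 pts, rms 4.02e-12 N)
#>   <structural_damping_fit> E0 = 4237 Pa, alpha = 0.1213, eta = 0.1929,
#>     mu = 13.41 Pa.s (f0 = 1 Hz, rms 73.6 Pa, 19 freqs in 1-100 Hz)
#>   operating indentation 5.3e-07 m, contact quality 1.000
evaluate_model(res$fit, c(1, 10, 100))
#>     f E_storage    E_loss loss_tangent
#> 1   1  4236.795  901.5627       0.2128
#> 2  10  5602.099 1923.5281       0.3434
#> 3 100  7407.372 9857.7584       1.3308
```

With 5 pN force noise the pipeline recovers the generating parameters
closely (apparent modulus 5347 vs 5364 Pa; `E0` 4237 vs 4259 Pa; `alpha`
0.121 vs 0.12; `mu` 13.4 vs 13 Pa·s); noiseless round trips are exact to
better than 1e-4 relative. The fitted model shows the expected
viscoelastic signature: a weak power law in the storage modulus and a loss
tangent that crosses from solid-like (0.21 at 1 Hz) toward liquid-like
with frequency.

Cohort-level work uses `draw_cohort()` to sample lognormally dispersed
cells around preset medians, `summarize_cohort()` for median/quartile and
log-histogram summaries, `pairwise_tests()` for rank tests with effect
sizes, and `generate_timecourse()` / `classify_fate()` / `fate_table()`
for drug-response fate analysis.

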