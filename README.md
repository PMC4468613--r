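# nirsfit

Estimation of the cortical hemodynamic response from functional
near-infrared spectroscopy (fNIRS) recordings, for researchers who need
per-channel response *shapes* — not just activation flags — from
block-design experiments.

Continuous-wave fNIRS measures optical-density changes at two wavelengths
per emitter–detector channel. `nirsfit` covers the full path from there to a
channel activation map:

1. **MBLL conversion** (`od_to_hb()`): the modified Beer–Lambert law turns
   dual-wavelength ΔOD series into relative ΔHbO/ΔHbR concentration changes.
2. **Signal model** (`model_signal()`): each ΔHbO channel is modeled as

   ```
   y(k) = a0 + a1·HRF(k) + a_c sin(2π f_c t_k) + a_r sin(2π f_r t_k) + a_m sin(2π f_m t_k) + ε(k)
   HRF  = h ∗ u,   h(t) = t^(α1−1) β1^α1 e^(−β1 t)/Γ(α1) − t^(α2−1) β2^α2 e^(−β2 t)/(6 Γ(α2))
   ```

   a double-gamma canonical HRF convolved with the boxcar paradigm `u`,
   plus baseline and cardiac / respiratory / Mayer-wave sinusoids.
3. **Constrained fitting** (`fit_channel()`, `fit_hrf()`): all 12 parameters
   (α1, α2, β1, β2, a0, a1, amplitudes, frequencies) are estimated per
   channel by minimizing the residual sum of squares under box constraints,
   with a restarted, box-constrained Nelder–Mead simplex search implemented
   in the package (frequency-profiled starts, stratified shape-grid
   restarts, two-phase explore/finish schedule).
4. **Activation statistics** (`activation_map()`): one-sided t test of
   H0: a1 = 0 per channel (SE from the design linearized at the optimum),
   assembled on the 16-channel optode grid with `autoplot()`.
5. **Synthetic validation** (`simulate_channel()`,
   `simulate_reference_suite()`, `recovery_experiment()`): a seeded
   generator for the model, including the fifteen reference parameter sets
   used to validate parameter recovery.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and plots are
`ggplot2::autoplot()` methods. A thin command-line wrapper lives in
`exec/nirsfit` (subcommands `mbll`, `simulate`, `simulate-suite`, `fit`,
`tmap`, `recover`).

## Worked example

Simulate one channel from reference dataset 10 (α1 = 5.5, α2 = 17,
β1 = 0.8, β2 = 1.4, a0 = 11, a1 = 3, plus three sinusoids), fit it, and test
for activation:

```r
library(nirsfit)

p <- paradigm()                      # 10 s rest / 10 s task / 30 s rest at 1.81 Hz
truth <- dplyr::filter(reference_params(), dataset == 10)
sim <- simulate_channel(truth, p, noise_sd = 0.2, seed = 7)

fit <- fit_channel(sim$y, p, bounds = relaxed_bounds(),
                   control = nm_control(seed = 1))
fit
#> <nm_fit> J = 3.07783 after 26567 iterations (restart 4/10, converged)
tidy(fit)
#> # A tibble: 12 × 2
#>    term   estimate
#>  1 alpha1   5.03
#>  2 alpha2  18.9
#>  3 beta1    0.721
#>  4 beta2    1.50
#>  5 a0      11.0
#>  6 a1       2.99
#>  ...

se <- standard_error_a1(sim$y, fit$par, p)
t_test_a1(fit$par[["a1"]], se$se, se$dof)
#> # A tibble: 1 × 4
#>       t        p t_critical significant
#> 1  72.9 8.23e-74       1.66 TRUE
```

The final cost J ≈ 3.08 sits at the noise floor (90 samples × 0.2² ≈ 3.6).
Baseline and activity strength are recovered to within 0.03 of the truth,
the response delay α1 to ~0.5, and all three frequencies to the grid
resolution; the undershoot parameters (α2, β2) are weakly identified at this
noise level — a property of the model, discussed in the vignette
(`vignettes/hemodynamic-model.Rmd`). The t statistic of a1 declares the
channel active.

`relaxed_bounds()` differs from the canonical `default_bounds()` box only by
letting the Mayer-wave frequency go below 0.09 Hz; the reference datasets
deliberately contain slower Mayer waves, and under the strict box such
components bias the HRF shape (see the vignette).

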