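# ikkdelay

Mechanistic ODE modelling of delayed IKKβ phosphorylation at low IL-1
doses, for systems biologists studying NF-κB pathway activation.

Human epithelial cells phosphorylate the kinase IKKβ within minutes of a
saturating IL-1 stimulus (10 ng/ml ≙ 0.588 nM), but show a pronounced
*delay* at a low dose (0.5 ng/ml ≙ 0.029 nM). `ikkdelay` implements a
core receptor-driven model of IKKβ (de)phosphorylation,

    d[ILR]/dt  = −k_a·il(t)·[ILR]
    d[ILRc]/dt =  k_a·il(t)·[ILR] − k_i·[ILRc]
    d[IKKp]/dt =  k_p·[kin]·(1−[IKKp]) − k_dp·[PP2A]·[IKKp]
    d[PP2A]/dt = −k_uv·uv(t)·[PP2A]

and three competing delay mechanisms that replace the kinase activity
[kin]: a TRAF6-like positive feedback ([kin] = [Tu]), sequential double
phosphorylation ([kin] = [Ypp]), and an irreversible inhibitor
([kin] = [Xa]). Around the models it provides

* χ² fitting of western-blot time courses with per-dose observation
  scale factors (`chi_squared()`, `fit_model()`, bounded
  Levenberg–Marquardt in log10 space),
* multi-start identifiability analysis (`multistart()`,
  `identifiability_spread()`),
* AICc model discrimination (`aicc()`, `compare_models()`),
* dose-dependent relative sensitivity analysis
  (`relative_sensitivity()`, `dose_sweep()`),
* a synthetic western-blot data generator standing in for the study's
  unpublished quantifications (`generate_dataset()`, `default_design()`),
* an end-to-end workflow (`run_pipeline()`).

## Worked example

```r
library(ikkdelay)

truth <- synthetic_truth()

# the low-dose delay produced by the positive-feedback variant
for (dose in c(0.588, 0.029)) {
  traj <- simulate_model("traf", truth$parameters, stimulus_protocol(dose, 0))
  cat(sprintf("IL-1 %.3f nM: peak %.2f, half-max at %.1f min\n",
              dose, peak_amplitude(traj), time_to_half_max(traj) / 60))
}
#> IL-1 0.588 nM: peak 0.88, half-max at 6.7 min
#> IL-1 0.029 nM: peak 0.46, half-max at 18.1 min

# fit all four variants to synthetic blot data generated from the
# TRAF variant and rank them by AICc
ds <- generate_dataset(seed = 1)
fits <- list()
for (i in seq_along(model_variants())) {
  v <- model_variants()[i]
  ref <- if (v == truth$variant) truth$parameters else default_parameters(v)
  fits[[v]] <- best_fit(multistart(v, ds, c(ref, scale_low = 2),
                                   n_fits = 25, decades = 2, seed = 30 + i))
}
compare_models(fits, N = n_records(ds))
#> Model comparison (AICc, gaussian form, N = 92):
#>  rank                variant k  chi2     aicc delta_aicc
#>     1                   traf 8 52.64 -33.6280       0.00
#>     2            double_phos 9 52.44 -31.5210       2.11
#>     3               original 6 77.29  -3.0364      30.60
#>     4 irreversible_inhibitor 9 79.28   6.5087      40.10
```

The positive-feedback variant wins: the double-phosphorylation variant
matches its fit quality but pays a parameter penalty, while the core
model cannot reproduce the low-dose delay at all (Δχ² ≈ 25). The
dose-dependence of the system's sensitivity — the hallmark of the
feedback mechanism — is exposed by

```r
dose_sweep("traf", c(truth$parameters, scale_low = 2),
           params = c("k_a", "k_i", "k_aut", "k_du"),
           characteristic = "mean")
```

which shows substantially larger elasticities at 0.029 nM than at
0.588 nM.

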