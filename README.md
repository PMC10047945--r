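# mventropy

Multivariate multi-scale entropy analysis of multichannel time series, for
researchers who quantify the complexity of physiological recordings —
resting-state EEG above all — and need to know not just *a* number but
*which* signal properties their chosen estimator actually responds to.

## What it computes

For a `p x L` channels-by-samples matrix, six estimators of the entropy
rate of the coarse-grained signal at scale factors `s = 1..20`:

| name | estimator | sensitive to |
|---|---|---|
| `mvmse` | multivariate multi-scale sample entropy | irregularity, intra- and inter-channel correlation |
| `mvmfe` | multivariate multi-scale fuzzy entropy | as mvMSE, smoother statistics |
| `rcmvmfe` | refined composite multivariate multi-scale fuzzy entropy | as mvMFE, stable at deep scales and short records |
| `mvmpe` | multivariate multi-scale permutation entropy | ordinal irregularity only |
| `mvmde` | multivariate multi-scale dispersion entropy | amplitude-class irregularity |
| `mvmie` | multivariate multi-scale increment entropy | fluctuation structure of first differences |

The sample/fuzzy family works on composite delay vectors: at scale `s` the
signal is coarse-grained (window means of width `s`; the refined-composite
variant averages the match statistics of all `s` window phases), each
vector stacks `m` delayed samples of every channel, and the entropy is

```
E(s) = -ln( phi_{m+1}(r) / phi_m(r) )
```

with `phi` the mean pairwise similarity of the vectors — a hard Chebyshev
threshold `r` for sample entropy, the fuzzy membership
`exp(-ln2 ((d - lambda*r)/r)^2)` (plateau below `lambda*r`) for the fuzzy
variants; `r = 0.15` in SD units of the once-z-scored signal, `m = 2`,
`d = 1`, `lambda = 0.8` by default. Each of the `p` one-channel extensions
to dimension `m+1` is evaluated within its own vector family and the
per-vector probabilities are averaged; the methods vignette explains why
this formulation — and not an all-pairs pool of the extended vectors — is
the one that behaves correctly.

The package also ships the synthetic signal families used to characterise
the estimators (white/1-over-f noise, correlated pairs, MIX and
coupled-MIX processes, SNR-controlled noise), the five seeded simulation
experiments built on them (complexity, correlation, coupling, noise
resistance, data length), and a region-wise EEG group pipeline (5-s
epochs, robust per-region RCmvMFE, short/long scale-band summaries,
Welch t-tests with Benjamini–Hochberg FDR control, score correlations)
exercised end-to-end on a synthetic two-group cohort generator.

## Worked example

A two-channel coupled-MIX signal — two noisy sinusoids sharing a common
component with coupling weight `C` — analysed with RCmvMFE:

```r
library(mventropy)

x <- gen_coupled_mix(coupled_mix_params(p0 = 0.2, p1 = 0.5, p2 = 0.8,
                                        C = 0.4, N = 2000), seed = 42)
curve <- multiscale_curve(x, "rcmvmfe", entropy_params(max_scale = 10))
round(curve$value, 3)
#>  [1] 1.472 1.219 0.958 0.863 0.887 0.648 0.746 0.640 0.574 0.506
```

The entropy falls with the scale factor: coarse-graining progressively
averages out the Uniform(-3,3) replacement noise and exposes the regular
sinusoid underneath. Sweeping the coupling coefficient shows what makes
this estimator family useful for connected systems — the two-channel
entropy responds to the coupling strength itself, not only to each
channel's own complexity:

```r
spec <- experiment_spec("coupling", reps = 5, length = 2000, seed = 1,
                        algorithms = "rcmvmfe", p_grid = 0.5,
                        C_grid = c(0, 0.5, 1))
tab <- run_joint_coupling_experiment(spec)
aggregate(multi_value ~ C, tab, mean)
#>     C multi_value
#> 1 0.0    1.263413
#> 2 0.5    1.529491
#> 3 1.0    1.468435
```

Uncoupled channels (`C = 0`) give the lowest entropy; by `C = 0.5` the
shared component has raised it by ~0.27. (Permutation and increment
entropy are flat across the same sweep — they cannot see coupling.)

The EEG pipeline runs the same way on real or synthetic recordings:

```r
cohort <- gen_synthetic_cohort(n_mci = 12, n_control = 8, seed = 1)
res <- run_eeg_pipeline(cohort$series, cohort$groups, cohort$scores)
res$group_stats     # per (region, band): means, t, p, BH-adjusted p
res$correlations    # per (region, band, score): Pearson r, adjusted p
```

A thin command-line front end (`inst/cli/mvent.R`) exposes the signal
generators (`simulate-signal`), single-matrix curves (`compute`), the
simulation experiments (`simulate`) and the EEG pipeline (`eeg-run`) for
shell pipelines; matrices travel as labelled delimited text.

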