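---
title: "Multivariate multi-scale entropy: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate multi-scale entropy: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mventropy)
```

## The problem

Resting-state EEG is a multichannel, nonlinear, non-stationary signal, and
"complexity" indices computed from it — entropy rates of coarse-grained
versions of the signal — are candidate biomarkers for early cognitive
decline. A multichannel signal has two distinct sources of structure that a
scalar complexity index can pick up: the temporal irregularity of each
channel, and the coupling between channels. Different multivariate
multi-scale entropy estimators weigh these two sources very differently,
and `mventropy` exists to compute six of them under one set of conventions,
to generate the synthetic signal families on which their behaviour can be
characterised, and to run a region-wise group-analysis pipeline of the kind
used in clinical EEG complexity studies.

## Coarse-graining and embedding

All estimators operate on a `p x L` matrix (channels x samples). The scale
factor `s` replaces each channel by means of non-overlapping windows of
width `s` (`coarse_grain()`); scale 1 is the original series. The
refined-composite variant (`refined_coarse_grain()`) uses all `s` window
phases `t = 1..s` and averages the match statistics across phases before
the logarithm, which reduces the variance of the estimate at deep scales
where the coarse series is short. All offsets are truncated to the common
length `floor((L - s + 1)/s)` so that each contributes equally and no
window reads past the end of the series.

Composite delay vectors concatenate, channel block by channel block, `m`
samples of each channel at stride `d` (`embed_composite()`), giving vectors
of dimension `m*p` compared under the Chebyshev distance. The symbolic
estimators (permutation, dispersion, increment) embed each channel
separately (`embed_per_channel()`) and pool pattern counts across channels.

Channels are z-scored once, on the original series, so the similarity
tolerance `r` is an absolute quantity (0.15 in SD units by default) held
fixed across scales. This is deliberate: the decay of a channel's variance
under coarse-graining is part of what the estimators are supposed to see.
White noise loses variance quickly and its entropy falls with `s`; 1/f
noise retains variance and stays flat. Recomputing `r` per scale would
erase exactly this contrast.

## The sample/fuzzy family and the dimension-(m+1) statistic

`mv_sample_entropy()` is `-ln(phi_{m+1}/phi_m)` where `phi_m` is the mean,
over the `M = N - m*d` composite vectors, of the fraction of other vectors
within Chebyshev distance `r`. `mv_fuzzy_entropy()` replaces the hard
indicator by the membership `1` on `[0, r]` and
`exp(-ln2 ((dist - r)/r)^2)` beyond, so its statistics are always positive
and the estimator never becomes undefined. `mv_rc_fuzzy_entropy()`
(RCmvMFE) additionally averages the phase-shifted coarse-grainings and
moves the membership plateau to `lambda*r` (default `lambda = 0.8`).

There are `p` ways to extend a composite vector from per-channel dimension
`m` to `m+1` — append the next delayed sample of channel `k`. The package
treats each of the `p` extension families as its own vector set, computes
the dimension-`m`-style match statistic *within* each family, and averages
the `p*M` per-vector probabilities. Two alternatives were implemented and
rejected during development, and the choice matters enough to record:

* Pooling all `p*M` extended vectors into one set and counting all pairs
  makes pairs that share the time index — vectors that differ *only* in
  their single extension coordinate, all `m*p` base coordinates being
  identical — dominate the match mass at deep scales (their share is of
  order `1/M` while genuine high-dimensional matches are far rarer). The
  consequences are pathological: trivariate white-noise sample entropy
  turns negative at moderate scales, and the complexity ordering of 1/f
  versus white-noise channel mixtures inverts.
* Pooling while excluding those partial self-matches repairs the
  pathologies but makes the estimators nearly blind to inter-channel
  correlation, which is half of what a multivariate entropy is for.
* The within-family average keeps the self-match exclusion built into the
  per-family statistic and retains correlation sensitivity: the entropy of
  a correlated channel pair exceeds that of an uncorrelated pair of the
  same noise kind, while the complexity ordering over channel compositions
  is preserved. It also has clean limits: at `p = 1`, and for perfectly
  duplicated channels, everything reduces exactly to the univariate
  estimator.

The fuzzy membership is evaluated exactly on its plateau and Gaussian
branches; pairs whose distance exceeds `lambda*r + 8r` contribute less
than `2^-64` and are skipped, which together with an early exit on the
running Chebyshev maximum makes the compiled kernel's typical pair O(1).
The truncation is far below the `1e-10` at which the test suite pins the
estimators to brute-force oracles.

`mv_sample_entropy()` returns `NA` when either match statistic is zero (no
hard matches at all, common for heterogeneous channels at deep scales);
`multiscale_curve()` records such scales as undefined rather than dropping
or raising them.

## The symbolic family

`mv_permutation_entropy()` maps each per-channel window to its ordinal
pattern (stable argsort; earlier index wins ties) and pools counts across
channels; it is bounded by `log(m!)` and blind to amplitude by
construction.

`mv_dispersion_entropy()` maps each channel through the normal CDF and
digitises into `c` classes via `round(c*y + 0.5)` (round half away from
zero, clamped to `[1, c]`). By default the NCDF uses the per-channel mean
and SD of the *original* series at every scale — the dispersion analogue
of holding `r` fixed. The alternative, recomputing the mapping from the
coarse-grained series itself, makes the estimator scale-invariant for
white noise and blind to the variance loss that the other estimators see;
it inverts the estimator's ordering of 1/f versus white-noise channel
mixtures at deep scales, and is therefore only available as the
non-default `mde_frozen_map = FALSE`. Every non-redundant selection of `m`
of the `m*p` composite positions contributes a pattern; the
`choose(m*p, m)` selection count is capped (default 5000) to fail early on
channel counts for which the combinatorics explode.

`mv_increment_entropy()` works on first differences: each window of `m`
increments becomes a word of (sign, magnitude) pairs, the magnitude
quantised as `min(R, floor(|z| * R / sd(window)))` with the window's own
sample SD (zero-SD windows map to magnitude 0). The quantisation uses the
absolute increment with the sign carried separately — the only reading
under which the advertised `(2(R+1)+1)^m` pattern count is attainable —
and `floor` for discretisation.

Natural logarithms are used throughout all six estimators.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `m` | per-channel embedding dimension | 2 (sample/fuzzy), 3 (symbolic) | identical across channels |
| `d` | time delay | 1 | samples |
| `r` | similarity tolerance | 0.15 | in SD units of the z-scored series |
| `lambda` | RCmvMFE plateau adjustment | 0.8 | in `[0.5, 1.5]` |
| `c` | dispersion classes | 3 | `>= 2` |
| `R` | increment quantisation resolution | 4 | `<= 4` typical |
| `max_scale` | largest scale factor | 20 | 10 in the data-length experiment |

`default_entropy_params(algorithm)` encodes the two per-family defaults.

## The synthetic signal families

* `gen_wgn()` — i.i.d. standard-normal channels.
* `gen_pink_noise()` — 1/f noise from the classic third-order pole-zero
  pink filter applied to white noise (2000-sample warm-up, then z-scored).
  Its log-log PSD slope is about -0.98 over the resolvable band, levelling
  off at the very lowest frequencies as physical 1/f sources do. An exact
  spectral-synthesis generator was tried as well; both reproduce the
  qualitative estimator behaviour and the same ordering threshold, but the
  filtered version keeps the correlated/uncorrelated entropy separation at
  deep scales well clear of replicate noise, so it is the one shipped.
* `gen_correlated_pair()` — two channels with population correlation `rho`
  by linear mixing of two independent draws; the mixing preserves the
  marginal spectrum of both white and 1/f noise.
* `gen_mix()` — MIX(p): the sinusoid `2 sin(2*pi*t/fs)` with `round(N*p)`
  positions, drawn uniformly without replacement, replaced by
  Uniform(-3, 3) noise. Complexity rises with `p`.
* `gen_coupled_mix()` — two channels sharing a MIX component:
  `A = C*MIX(p0) + (1-C)*MIX(p1)`, `B = C*MIX(p0) + (1-C)*MIX(p2)` on a
  common time grid; `C` controls inter-channel coupling.
* `add_noise_at_snr()` — per-channel white noise scaled to a target SNR in
  dB, with power taken as mean squared deviation from the channel mean.

Every generator is a pure function of its arguments including the seed.

## The simulation experiments

Five seeded experiments characterise what each estimator measures, each
emitting a tidy long table (`algorithm`, `condition`, `replicate`, `seed`,
`scale`, `value`, `defined`); defaults are 20 replicates of length-6000
signals, scales 1-20:

1. **Complexity** (`run_complexity_experiment()`): three-channel signals
   with 0-3 channels of 1/f noise, remainder white. At scales above 1 the
   sample/fuzzy/dispersion estimators order the conditions by 1/f channel
   count (all-1/f highest); permutation entropy orders them the other way,
   since 1/f noise is more regular sample-by-sample.
2. **Correlation** (`run_correlation_experiment()`): channel pairs, 1/f and
   white, correlated (`rho = 0.95`) versus uncorrelated. The sample/fuzzy
   family places each correlated arm above its uncorrelated counterpart;
   `detect_ordering_threshold()` operationalises "from which scale onwards
   does the full four-way ordering hold".
3. **Coupling** (`run_joint_coupling_experiment()`): coupled-MIX pairs over
   the coupling grid `C = 0, 0.1, ..., 1` with equal probability
   parameters (`p0 = p1 = p2` pins the single-channel complexity, isolating
   the coupling effect; the default grid is 0.1-0.9 in steps of 0.2, with
   arbitrary triples accepted). Reports multi-channel and single-channel
   (channel A) entropy, at scale 1 by default — the single-scale reading of
   a coupling-response surface — or scale-averaged on request.
   `find_peak_coupling()` returns the grid argmax.
4. **Noise** (`run_noise_experiment()`): the coupled-MIX reference model
   (`C = 0.4, p0 = 0.2, p1 = 0.5, p2 = 0.8`) plus white noise at
   20/10/0/-10/-20 dB SNR.
5. **Length** (`run_length_experiment()`): the same model at lengths
   100-2000 in steps of 100. Scales are capped at 10 here so that the
   shortest grid length supports every scale for every estimator;
   `find_stabilization_length()` returns the first grid length from which
   the ensemble mean stays within a tolerance band (5% by default) of the
   value at the largest length.

Replicate `j` of condition `ci` uses seed `base + (ci-1)*10000 + j`, so
conditions are independent and any table cell can be regenerated in
isolation.

Two findings from these experiments are worth stating because they differ
from what one might expect: with the within-family formulation the
scale-averaged RCmvMFE of the coupled-MIX model is essentially flat in the
data length from `N = 100` — fuzzy entropy is genuinely usable for short
records, and apparent strong length-dependence in this setting is a
signature of the pooled-pairs formulation rejected above — and the
two-channel dispersion entropy of the coupled-MIX model peaks at an
interior coupling value (around `C = 0.4` at scale 1 under the defaults)
rather than rising monotonically, so mvMDE should not be used as a
coupling-strength readout.

## The EEG pipeline

`run_eeg_pipeline()` chains the analysis used on a clinical cohort:
non-overlapping epochs (`segment_epochs()`, 5 s at 500 Hz by default), a
robust per-region RCmvMFE curve per subject (`region_entropy()`), band
averages over the short (scales 1-4) and long (scales 10-15) bands
(`band_average()`), a two-sample comparison per (region, band) with
Benjamini-Hochberg control across regions within each band
(`group_compare()`, Welch by default since group variances are not
assumed equal), and Pearson correlations between band entropy and
cognitive scores with BH control across (region x score) within each band
(`correlate_scores()`).

Epoch outliers are removed per scale: an epoch whose value deviates from
the across-epoch median by more than 3 scaled MADs is excluded and the
survivors averaged. This is a deliberately parameter-light robust rule;
the multiplier is exposed (`mad_mult`). A scale at which all epochs are
excluded or undefined propagates as `NA`.

The six canonical regions (F, C, P, O, LT, RT) are supplied as a channel
map; `default_region_map()` ships a 32-channel 10-20-style assignment as a
convenience fixture for synthetic data — it is not any particular study's
montage, and real analyses should provide their own YAML map
(`read_region_map()`).

### The synthetic cohort

Patient EEG of the kind this pipeline targets is not redistributable, so
`gen_synthetic_cohort()` plants a known truth instead: per region, every
channel is a weighted sum of a region-shared component and a private
component, each itself a mixture of 1/f noise and white noise. The
white-noise fraction sets short-scale complexity; the shared weight sets
inter-channel coupling. The clinical group gets both reduced (`effect` and
`coupling_gap`, defaults 0.2 each on fractions of 0.5 and 0.6), planting
lower short-scale region entropy and weaker coupling; scores (`MoCA`,
`AVLT_delayed`) are noisy increasing functions of the subject's frontal
white-noise fraction, so short-scale frontal entropy and scores are
positively related by construction.

What passing tests on this cohort do and do not show: they verify that the
pipeline *recovers a planted effect of known size* — direction in the
band means, significance under FDR at the study's group sizes, calibrated
false-positive rate on null cohorts — not that any particular clinical
effect exists. The surrogate has none of real EEG's nonstationarity,
artifacts, volume conduction, or 1/f-exponent variation across subjects.

## Numerical and degenerate-input conventions

* Sample SD (divisor `n-1`) everywhere an SD is taken.
* Constant channels are rejected by `zscore_channels()` and `ncdf_map()`
  (degenerate input), but constant *increment windows* are well-defined
  (magnitude 0).
* `round(c*y + 0.5)` uses round-half-away-from-zero (R's `round()` rounds
  half to even, which is not what the construction needs), then clamps.
* Ordinal ties break by temporal position (stable sort).
* Estimator-undefined scales are `NA` with `defined = FALSE`, never
  dropped; ensemble summaries average over defined replicates and report
  the count.
* Scale curves are computed on series z-scored once; all estimators are
  invariant to per-channel positive rescaling (verified to `1e-9` in the
  test suite).
* All estimators except `mv_dispersion_entropy()` are exactly invariant
  to channel reordering. Dispersion patterns read their selected elements
  in composite-position order, so permuting channel blocks relabels the
  patterns of cross-channel selections non-uniformly; the entropy is
  invariant only up to that relabelling (observed deviations are of order
  `1e-3`).

## Problem sizes used by the test-suite

The unit tests pin every estimator to brute-force oracles on inputs of
120-500 samples, where exhaustive pairwise computation is exact and fast.
The ensemble-level checks (orderings over channel compositions and
correlation arms, coupling response, planted-effect recovery) run at the
full signal length of 6000 where the claim depends on it, with 20
replicates, and at reduced lengths (400-2000) and small cohorts (4-10
subjects, seconds of data at reduced sampling rates) where only the
direction or calibration of an effect is being verified. These sizes are
the package's choices for tests that a maintainer runs routinely; the
simulation functions themselves default to the full study conditions.

## Known limitations

* Per-channel heterogeneous `m_k`, `d_k` are not supported.
* `mv_dispersion_entropy()` is combinatorial in `choose(m*p, m)`; large
  channel counts require the selection cap to be raised consciously.
* The pipeline consumes already-clean matrices; filtering, artifact
  removal and montage handling are out of scope.
* The coupling-response and length-stabilisation summaries depend visibly
  on formulation details of the dimension-(m+1) statistic (see above);
  comparisons with other software should fix that convention first.
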