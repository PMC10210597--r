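# envsca

Supervised classification of categorical time series from their oscillatory
structure, using the **spectral envelope** and **optimal scalings** as
low-dimensional, interpretable frequency-domain features.

## The problem

Collections of categorical time series — sleep-stage hypnograms annotated
every 30 s, behavioral state sequences, DNA-like symbol series — often come
labeled by group (e.g. patients with nocturnal frontal lobe epilepsy vs.
REM behavior disorder), and the task is to classify new, unlabeled series.
Groups can differ in two distinct ways:

* **how fast** the series cycles through its categories (oscillatory
  pattern), and
* **which categories** the cycles traverse (traversal pattern).

Both are frequency-domain properties, and `envsca` extracts each one as a
dedicated feature.

## The features and the model

A series `X_t` over `m` states is indicator-encoded against a reference
category into a 0/1 vector series `Y_t` of dimension `m − 1`. Its spectral
matrix `f_y(ω)` is estimated by the smoothed periodogram

    f̂_y(ω_s) = Σ_{j=−B}^{B} W_j I(s + j),   I(s) = T⁻¹ d(s) d(s)ᴴ,

on the Fourier frequencies `ω_s = s/T`, `s = 1, …, K = ⌊(T−1)/2⌋`, with
bandwidth `B = ⌊√T⌋` and a modified Daniell kernel by default. At each
frequency,

* the **spectral envelope** `λ̂(ω_s)` is the largest eigenvalue of
  `Re f̂_y(ω_s)` — the largest power any real scaling of the categories can
  achieve at that frequency;
* the **optimal scalings** `γ̂(ω_s)` are the corresponding unit eigenvector —
  the category scores that achieve it.

Group features `Λ̂⁽ʲ⁾, Γ̂⁽ʲ⁾` are per-group averages over training series.
A test series `r` is assigned to the group minimizing one of

    ENV:    ‖λ̂⁽ʳ⁾ − Λ̂⁽ʲ⁾‖₂²
    SCA:    ‖γ̂⁽ʳ⁾ − Γ̂⁽ʲ⁾‖_F²
    EnvSca: κ ‖λ̂⁽ʳ⁾ − Λ̂⁽ʲ⁾‖₂² / ‖λ̂⁽ʳ⁾‖₂²  +  (1 − κ) ‖γ̂⁽ʳ⁾ − Γ̂⁽ʲ⁾‖_F² / ‖γ̂⁽ʳ⁾‖_F²

where the adaptive weight `κ ∈ {0, 0.1, …, 1}` is tuned by leave-one-out
cross-validation on the training set, so the classifier learns whether the
groups differ in oscillation, traversal, or both. Spectral-matrix-based
baselines (total variation, Kullback–Leibler, Chernoff disparities on the
whole smoothed spectral matrix) are included for comparison, as is a lag-1
multinomial-logit simulator whose presets generate the benchmark study
designs, and support for series of unequal length via periodogram
interpolation onto the shortest series' Fourier grid.

## Worked example

```r
library(envsca)

# two groups of synthetic six-state hypnograms, unequal lengths
train <- synth_hypnograms(n_per_group = 8, length_range = c(200, 280), seed = 11)
fit <- envsca_fit(train, state_space = attr(train, "state_space"), ref_state = "W")
glance(fit)
#> # A tibble: 1 x 9
#>   method n_groups n_train     m     k t_ref bandwidth kappa loo_rate
#>   <chr>     <int>   <int> <int> <int> <int>     <dbl> <dbl>    <dbl>
#> 1 envsca        2      16     6   105   211        14     1        1

test <- synth_hypnograms(n_per_group = 3, length_range = c(200, 280), seed = 99)
predict(fit, test)
#> # A tibble: 6 x 4
#>   series_id .pred_group  dist_A  dist_B
#>   <chr>     <chr>         <dbl>   <dbl>
#> 1 h_A_001   A           0.00430 0.0524
#> 2 h_A_002   A           0.0138  0.0191
#> 3 h_A_003   A           0.0139  0.0669
#> 4 h_B_001   B           0.0506  0.00663
#> 5 h_B_002   B           0.0490  0.0133
#> 6 h_B_003   B           0.0525  0.0129
```

`glance()` reports the tuned mixing weight (`kappa = 1`: the groups differ
mainly in cycling speed, and the LOO rate on the training set is 100%).
In `predict()`, `dist_A`/`dist_B` are the adaptive distances to each
group's mean features; every test series is closest to its own group.
`tidy(fit)` returns the group-mean envelope and scalings per frequency,
and `autoplot(fit)` plots them.

A small Monte-Carlo benchmark (two groups that differ in cycling speed,
`m = 4`, printed as percent correctly classified on 50 test series per
group):

```r
run_study(1, n_per_group = 20, t_length = 100, reps = 5, seed = 1)
#> # A tibble: 3 x 9
#>    case     m n_per_group t_length method  mean    sd mean_kappa  reps
#>   <dbl> <int>       <dbl>    <dbl> <chr>  <dbl> <dbl>      <dbl> <dbl>
#> 1     1     4          20      100 envsca  94.6  1.95       0.98     5
#> 2     1     4          20      100 env     94.6  1.95      NA        5
#> 3     1     4          20      100 sca     54    5.79      NA        5
```

The envelope-based classifiers are near 95% while the scalings-only
classifier is at chance — exactly what the design implies, since both
groups traverse categories the same way.

A command-line wrapper with `simulate`, `study`, `fit`, `predict` and
`features` subcommands is installed at `inst/cli/envsca.R`.

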