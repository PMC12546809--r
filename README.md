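# neurotrainr

A fully synthetic, desk-scale simulator of a multimodal neurofeedback
system for the *collaborative* training of executive function and tactical
cognition. It is aimed at computational-neuroscience and sports-science
researchers who want a reproducible, closed-loop testbed — signal
generation → feature extraction → multimodal fusion → cognitive-state
dynamics → adaptive control → cohort evaluation — without any recorded
data: every input is generated in code under explicit seeds.

## What it models

Cognitive scores live on a 0–100 scale. Executive function is the
composite `EF(t) = α₁WM(t) + α₂IC(t) + α₃CF(t) + ε(t)`; tactical cognition
is the lagged composite
`TC(t) = β₁SA(t−δ₁) + β₂PR(t−δ₂) + β₃DM(t−δ₃) + β₄SP(t−δ₄)`; overall
performance is the interaction model
`γ₁·EF·TC + γ₂·EF + γ₃·TC + η`. Sessions update the composites by
`EF(t+1) = EF(t) + Σρᵢ·Δᵢ + λ·FB(t)` and
`TC(t+1) = TC(t) + Σμᵢ·ΔTCᵢ + φ·Context(t) + ψ·Transfer(t)`, clamped to
[0, 100]; the `ψ`-coupling is what separates collaborative from isolated
training. Around this core sit:

- a cohort generator (truncated-normal baselines, 15–25% between-profile
  CV, k-means stratification with a silhouette quality gate),
- a band-structured EEG synthesizer (500 Hz; theta/alpha/beta oscillators
  with drifting instantaneous frequency; 1/f background scaled to an exact
  target SNR) plus GSR/heart-rate/EMG streams,
- spectral features (Welch PSD, band power), phase-locking values, a
  KL-based theta–gamma modulation index, the training-induced plasticity
  index `100·(post − pre)/pre`, and the modified Beer–Lambert ΔHbO₂,
- linear-plus-interaction and scalar-Kalman multimodal fusion,
- BCM plasticity (`Δw = η·y·(y−θ)·x`), an STDP-kernel synaptic
  modification index, a training-adaptation function and a cognitive
  performance index,
- adaptive difficulty control, discounted-reward feedback selection on a
  small discrete model, and a Lyapunov convergence check,
- a 12-week, four-arm protocol (collaborative / isolated-EF / isolated-TC /
  control) whose calibration recovers configured per-domain mean
  improvements, evaluated with repeated-measures ANOVA, Cohen's d (paired
  and pooled) and marker–behaviour correlations.

Everything user-facing takes and returns tibbles and composes with the
pipe; fitted objects have `tidy()`/`glance()` methods and result types have
`autoplot()`.

## Worked example

```r
library(neurotrainr)

cohort <- make_cohort(cohort_spec(n = 12, seed = 7))
res    <- run_protocol(cohort, protocol_config(seed = 42))
res
#> <nt_results> 336 records (12 profiles x 4 condition(s)), seed 42

report <- make_tables(res)
report$table4_summary
#> # A tibble: 3 × 7
#>   domain pre_mean pre_sd post_mean post_sd improvement_sd improvement_pct
#>   <chr>     <dbl>  <dbl>     <dbl>   <dbl>          <dbl>           <dbl>
#> 1 cf         70.8    9.1      91.1     9.6            4.4            28.7
#> 2 ic         71.6   14.3      87.1    12.1            9.3            21.7
#> 3 wm         74.2   18.4      88       16.7          10.6            18.7

tidy(report$anova)
#> # A tibble: 3 × 5
#>   term               df1   df2 statistic  p.value
#>   <chr>            <dbl> <dbl>     <dbl>    <dbl>
#> 1 condition            3    33    471.   3.83e-27
#> 2 domain               6    66      2.81 1.70e- 2
#> 3 condition:domain    18   198     57.0  4.10e-68
```

The summary rows read like the package's bundled benchmark tables: mean
pre/post scores per executive-function domain, the improvement of the
cohort means at one decimal (half-up), and the SD of per-profile
improvements. For this cohort the collaborative arm improves working
memory by 18.7%, inhibitory control by 21.7% and cognitive flexibility by
28.7% — each within sampling noise of its calibration target (20.4 / 23.1 /
29.3) — and the condition × domain ANOVA separates the four arms sharply.
Signals are one call away from the same pipeline:

```r
frame <- synth_eeg(spec = eeg_synth_spec(snr_db = 35, duration_s = 10,
                                         seed = 2))
attr(frame, "realized_snr_db")[1]   # 35 (exact by construction)
band_power(compute_psd(frame), 4, 8)  # ~12.4 uV^2 theta per channel
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/neurotrain.R simulate --config cfg.yaml --seed 1 --out out/
```

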