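---
title: "A closed-loop simulator of multimodal neurofeedback cognitive training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop simulator of multimodal neurofeedback cognitive training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

neurotrainr simulates, end to end and entirely in silico, a multimodal
neurofeedback system for the *collaborative* training of executive function
(EF: working memory, inhibitory control, cognitive flexibility) and tactical
cognition (TC: situational awareness, pattern recognition, decision-making,
strategic planning). The pipeline is: synthetic cohort → synthetic signals →
neural features → multimodal fusion → session-level cognitive dynamics →
adaptive control → cohort evaluation. This vignette explains the models, the
parameters that matter, the numerical choices, and what the simulator does
and does not show about real training data.

## The cognitive-state model

Scores live on a 0–100 scale. The EF composite is a weighted sum
$EF(t) = \alpha_1 WM(t) + \alpha_2 IC(t) + \alpha_3 CF(t) + \varepsilon(t)$
with i.i.d. Gaussian noise; the TC composite is a lagged weighted sum
$TC(t) = \beta_1 SA(t-\delta_1) + \beta_2 PR(t-\delta_2) +
\beta_3 DM(t-\delta_3) + \beta_4 SP(t-\delta_4)$ with integer *session* lags
(time is discrete at session resolution throughout; no millisecond dynamics
are modeled). Overall performance is the interaction model
$\gamma_1\,EF \cdot TC + \gamma_2\,EF + \gamma_3\,TC + \eta$, whose product
term carries the synergy the collaborative protocol is designed to exploit.

Session updates are linear in their increments:
$EF(t{+}1) = EF(t) + \sum_i \rho_i \Delta_i + \lambda\,FB(t)$ and
$TC(t{+}1) = TC(t) + \sum_i \mu_i \Delta TC_i + \phi\,Context(t) +
\psi\,Transfer(t)$, clamped to $[0,100]$ with every clamping event counted
(the scale's bounds are a modelling choice; the clamp count makes ceiling
effects auditable). Greek letters are reused across equations in the
source formulations; the package namespaces every parameter set per equation
(`ef_params()`, `update_params()`, …) so nothing is shared accidentally.
Two readings had to be fixed where the source formulations are garbled: the
training-adaptation function is completed as
$TA(t) = \lambda\,(NF(t)-NF_0)\,e^{-\delta t} + \beta\,Practice(t)$ (a
truncated exponent, read as decay because $\delta$ is described as a decay
constant), and the unnamed TC-update coefficient is named $\phi$ (context).
`Transfer(t)` and `FB(t)` are unitless; in the protocol they carry the other
family's realized relative session gain.

Plasticity is modeled twice, at different grains: the BCM rule
$\Delta w = \eta\,y\,(y-\theta)\,x$ for single-update sign structure
(depression for $0<y<\theta$, potentiation above), and a synaptic
modification index $SMI = \Delta w / w_0$ with
$\Delta w = \eta \int f_{pre}(t)\left[\int g(\tau) f_{post}(t+\tau)\,
d\tau\right] dt$, where $g$ is a two-sided exponential STDP kernel
normalized to unit integral and truncated at eight time constants;
trapezoidal quadrature at $\tau_{STDP}/20$ steps reproduces the
constant-rate closed form $\eta r_1 r_2 T / w_0$ within 1%.

## The synthetic cohort

`make_cohort()` draws `n = 12` profiles by default. Each baseline score is a
truncated normal on $[0,100]$ whose SD is `mean × CV`, with the CV drawn
per profile uniformly from 15–25% — the stated between-profile variability
band of the study conditions the simulator reproduces. Truncation at the
score ceiling would bias the mean downward by more than a point at these
CVs, so the latent location is recentred by root-finding until the
*truncated* mean equals the requested mean. A unit-mean truncated-normal
`responsiveness` multiplier (SD 0.12) carries stable individual differences
in training gain.

One tension is worth stating plainly: the per-profile benchmark table the
package bundles (`ref_ef_assessment()`) implies a baseline CV of only
~3.5% and per-profile improvement SDs of 2.4–3.2 points, which is
incompatible with the stated 15–25% cohort CV. The generator follows the
stated CV band; as a result simulated per-profile improvement SDs are
larger (roughly 5–10 points) even though cohort *means* are calibrated to
the benchmark values. `cluster_profiles()` stratifies cohorts by k-means on
the scaled baselines (ten restarts, best inertia, earliest-restart
tie-break) and reports the mean silhouette width; above 0.6 counts as an
acceptable stratification, a threshold only well-separated cohorts reach —
the default homogeneous cohort does not form meaningful clusters, which is
expected.

## Signals and features

`synth_eeg()` builds each channel as a sum of per-band oscillators plus
$1/f$ background noise, at 500 Hz sampling with theta 4–8, alpha 8–13 and
beta 13–30 Hz bands by default. Each oscillator is an amplitude-modulated
sinusoid (depth 0.3, 0.1–0.3 Hz modulation) whose instantaneous frequency
drifts slowly over the central 40% of its band, giving nontrivial phase
structure for connectivity and coupling measures while keeping spectral
content inside the band; each component is rescaled to its exact target
band power in the time domain. The noise is spectrally shaped white noise
with slope `noise_exponent` (default 1), amplitude-floored below 0.5 Hz,
and scaled so the realized oscillation-to-noise power ratio equals the
target SNR (default 35 dB, the midpoint of the 30–40 dB specification)
*exactly* on the generated samples — the SNR definition (component power
ratio, not in/out-of-band ratio) is recorded in the frame metadata. A
configurable fraction (default 0.2) of each band oscillation is shared
across channels with a 10 ms per-channel lag so cross-channel phase locking
is nontrivial. Auxiliary streams (`synth_physio()`) follow the acquisition
hardware rates: GSR 100 Hz within 0.01–100 µS, heart rate 500 Hz, EMG
2000 Hz. No blink/EMG artifact contamination or volume-conduction head
model is simulated: passing tests show estimator correctness on clean,
band-structured signals, not robustness to real recording artifacts.

Spectra come from averaged modified periodograms (Hann window, 2 s
segments, 50% overlap, per-segment mean removal), scaled so the integrated
density matches the time-domain variance; with a rectangular full-length
window a unit sinusoid integrates to exactly 0.5 µV². Band power is the
trapezoidal integral with edge interpolation, so disjoint adjacent bands
add exactly. Phase-locking uses the trial-averaged unit phasor of the
phase difference, computed per time point when trials exist; with a single
realization it pools across time and flags that deviation. Theta–gamma
coupling uses the Kullback–Leibler modulation index over 18 phase bins of
the analytic phase versus the analytic envelope (zero-phase 4th-order
Butterworth band-passes, 0.5 s transients trimmed); the estimator's
small-sample null bias is reported alongside. The gamma band is taken as
30–50 Hz wherever the neural benchmark table is reproduced (its own
convention), not the wider 30–100 Hz textbook range. The hemodynamic
change uses the modified Beer–Lambert form with the *natural* logarithm;
the wavelength coefficient absorbs any base conversion. The plasticity
index `tipi()` is the percent power change, the same arithmetic as the
behavioural improvement column.

## Fusion

Two fusion rules are implemented. The algebraic rule
$S = \sum_i w_i S_i + \sum_{j<k} w_{jk} S_j S_k$ sums over unordered
modality pairs (the only parseable reading of the pairwise index). The
recursive rule is a scalar random-walk Kalman filter — one filter per fused
feature, since no state dimension is specified anywhere — in which each
modality is assimilated sequentially per step with its own gain
$K_i = P/(P+r_i)$; gains are reported per step and the single-modality
steady state matches the algebraic Riccati solution
$P^- = (q+\sqrt{q^2+4qr})/2$ to $10^{-6}$. Whether the gains should be a
joint vector gain is unknowable from the source description; independent
scalar gains are used and flagged here.

## Closed-loop control

Difficulty follows
$level(t{+}1) = level(t) + \alpha\,(target - performance) + \beta\,load$,
held continuous internally and clamped to each task family's admissible
range (working-memory updating 1–5, inhibitory control 1–4, cognitive
flexibility 1–3, tactical recognition 1–6, strategic planning 1–4,
integrated scenarios 1–5); rounding to integer levels happens only at
presentation time to avoid quantization limit cycles. Feedback selection
maximizes expected discounted return by finite-horizon backward induction
on a small discrete model — coarse cognitive-state bins for states, the
three feedback types (reward tone, visual gauge, difficulty hint) for
actions — because no state space, reward or horizon is specified anywhere;
all three are config-exposed, the default reward being next-step
performance gain. Ties break by action order, and the argmax is invariant
to positive affine reward transforms. Stability is checked by the Lyapunov
criterion: $V(t) = \lVert x(t)-x_{eq}\rVert^2$ must stay under
$V_0 e^{-\delta t}$ with 1% slack, the rate fitted by log-linear
regression when not supplied.

## The protocol and its calibration

`run_protocol()` simulates 12 weeks × 3 sessions per week across four arms:
collaborative (both families trained, transfer couplings active), isolated
EF, isolated TC (own family only, couplings zero) and control (all learning
rates zero — improvements are exactly zero in the noise-free setting). Per
session each active domain receives a direct increment through the
EF/TC update rules, plus — collaborative arm only — a transfer increment
driven by the other family's realized mean relative session gain through
$\lambda$/$\psi$.

The shipped calibration (`calibrate_protocol()`) works on the realized
cohort: for each domain it solves by root-finding for the total relative
gain $g$ such that the cohort mean of the *ceiling-clamped* improvement
equals the configured target (defaults: the benchmark improvement columns,
e.g. +20.4% WM, +23.1% IC, +29.3% CF), then routes `1 − transfer_share` of
$g$ through the direct increments and the rest through the transfer
coupling, scaled per profile by its own baseline. `transfer_share = 0.3`
reflects the benchmark ratio of isolated to collaborative effect sizes
(≈0.67–0.84 vs 0.96–1.24), so isolated arms realize about 70% of the
collaborative gain and the collaborative ≥ isolated ordering holds
per seed. When a small high-baseline cohort cannot reach a target mean
under the score ceiling the calibration warns and saturates rather than
overshooting elsewhere. Session noise is mean-zero with SD
`gain × 5% / √T` per session. At n = 500 the realized mean improvements
recover the configured targets within a tenth of a point; at the default
n = 12 over 20 seeds they land within a point.

Neural markers are produced through the full signal path: for each of the
eight benchmark scalp regions, a pre-training band power is drawn from the
region's benchmark distribution, a post-training power applies the region's
change rate scaled by the profile's realized relative gain in a
generatively linked domain (frontal theta with working memory, parietal
alpha with cognitive flexibility, occipital gamma with pattern recognition,
…), and both are *measured* by synthesizing EEG at those target powers and
integrating the Welch spectrum over the band. Pre and post syntheses share
the profile's waveform seed — individual spectral morphology is stable
across sessions — so the measured change reflects the power contrast, not
waveform resampling. With unit loading and 6% marker noise the linked
marker–behaviour Pearson correlations average ≈0.7 at n = 12, the
benchmark's 0.66–0.74 band, though single-cohort values scatter widely at
that sample size.

## Evaluation

`make_tables()` regenerates the three benchmark-style tables (per-profile
EF rows with the cosmetic fixed-width ±2.6 display interval, TC domain
means, regional band-power means with change rates), Cohen's d in both the
paired and pooled variants — both are reported honestly; no single standard
definition reproduces the printed 0.96–1.24 values from the printed means
and SDs, so none is forced — and a two-factor repeated-measures ANOVA
(`aov` with subject-error strata, Bonferroni post-hoc contrasts). The
widely-quoted F(2,33) degrees of freedom are not consistent with 12
subjects crossed with 3 conditions in a within-subject design; the package
reports the correct df (2, 22) for that design. Percentages are rounded
half-up at one decimal, the rule that reproduces the benchmark cells; the
summary row reports the improvement of the cohort means (not the mean of
row improvements), which is what the benchmark summary line contains. A
handful of printed benchmark cells carry 0.1-point rounding slips
(flagged in `?ref_tables`); recomputation from each row's own pre/post
values is authoritative, and every table the package emits is
self-consistent under that recomputation.

The interaction F test's empirical type-I error under a simulated null
(`rm_anova_type1()`, 200 draws) sits at the nominal 5% level.

## Problem sizes and numerical defaults

Defaults used throughout the test suite and the acceptance script: 10 s of
500 Hz EEG for spectral checks (5 000 samples), 6 s per marker synthesis,
12-profile cohorts over 36 sessions, 20 protocol seeds for stochastic
recovery, 500-profile cohorts for law-of-large-numbers checks, 200
simulations for the type-I error. Root-finding tolerances are $10^{-9}$
(cohort recentring) and $10^{-10}$ (gain calibration); the Kalman
steady-state check runs 300 steps; filter transients of 0.5 s are trimmed
before coupling estimation.

## Known limitations

Everything here is synthetic: the generator encodes the very effects the
evaluation recovers, so passing tests demonstrate internal consistency,
calibration accuracy and estimator correctness — not that collaborative
training works. Real EEG has artifacts, non-stationarities, inter-channel
structure and spectral shapes this generator does not attempt; real
cohorts do not have independent baselines across domains. ERP components
and eye-tracking analyses are out of scope (no defining computation to
implement), as is any claim about real athletes.
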