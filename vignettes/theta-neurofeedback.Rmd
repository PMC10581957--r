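---
title: "Simulating closed-loop intracranial theta neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop intracranial theta neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetanf)
```

## What the package models

`thetanf` simulates an intermittent neurofeedback (NF) loop on
intracranial EEG from a four-contact mesial temporal lobe (MTL) montage
sampled at 512 Hz. The participant encodes five words per trial; the
theta-band (4--8 Hz) power of the encoding period, averaged over
contacts, is shown after each trial as the height of a new bar alongside
all previous bars. Feedback is intermittent -- displayed between task
periods, not during them -- to avoid interference between the memory task
and the regulation process. The toolkit covers four concerns:

1. **Signal synthesis** (`generate_background()`, `add_oscillation()`,
   `inject_spikes()`, `generate_session()`): controllable surrogate iEEG
   with ground truth.
2. **Task paradigm** (`build_lexicon()`, `make_word_sets()`,
   `schedule_session()`, `score_recognition()`): the old/new recognition
   design with familiarity-balanced six-word sets.
3. **Real-time chain** (`preprocess()`, `extract_encoding_epoch()`,
   `welch_psd()`, `band_power()`, `run_closed_loop()`): the feedback
   computation, with optional real-time artifact subspace reconstruction
   (ASR).
4. **Offline battery** (`psd_per_trial()`, `compare_correct_error()`,
   `compare_first_final()`, `session_anova()`,
   `theta_behavior_correlation()`, `holm_bonferroni()`).

## Trial timeline

A published description of this paradigm gives a 2.6 s word cycle and a
13 s encoding extraction window formed as (1.0 + 1.6) s x 5. These are
mutually consistent only if each word cycle is a 1.0 s blank followed by
1.6 s of word presentation; the package adopts exactly that reading. The
"first 1 s" excluded from the 12 s analysis window is then the first
cycle's blank. One trial is 13 + 8 + 8 + 10 = 39 s (encoding, Task 1,
Task 2, feedback) and a session is 20 s rest + 20 trials = 800 s.
Sessions may be truncated after any trial (`truncate_session()`); all
downstream statistics accept unequal trial counts.

```{r timeline}
c(encoding = encoding_duration(), analysis = analysis_duration(),
  trial = trial_duration())
```

## The synthetic signal and its assumptions

Each channel is the sum of three independent parts.

* **Background**: white Gaussian noise spectrally shaped to
  $1/f^\beta$ (FFT-domain gain $f^{-\beta/2}$, flat below 0.5 Hz so the
  variance stays finite), then rescaled to an exact RMS. Shaping in the
  frequency domain rather than by AR filters makes the slope exactly
  controllable and testable by a log--log regression oracle. Defaults:
  $\beta = 1$, RMS 10 µV.
* **Theta oscillation**: either a pure sinusoid or narrowband Gaussian
  noise (Gaussian spectral envelope), calibrated so that peak amplitude
  $A$ always carries band power $A^2/2$. During encoding periods only,
  its amplitude is `osc$amplitude * gain_s * jitter_t`, where `gain_s`
  is the learner's session gain and the per-trial jitter is lognormal
  (sigma 0.1 by default -- positive power with ~10 % trial-to-trial
  variation). Defaults: 6 Hz centre, 1 Hz bandwidth, 5 µV.
* **Spikes**: a homogeneous Poisson process of sharp transients
  (derivative-of-Gaussian by default), synchronous across channels with
  a fixed geometric amplitude profile $0.8^{c-1}$ -- a focal generator
  seen by a short contact strip at increasing distance. Width 50 ms,
  peak 150 µV, 0.2 /s by default.

Recognition behavior is Bernoulli with logit linear in the standardized
log theta factor: $\mathrm{logit}\,p = \mathrm{logit}(p_0) + 2\rho z$,
where $\rho$ is the learner's `behavior_coupling` and $p_0$ its base
success probability (0.9). The slope constant 2 was fixed once so that
$|\rho| = 1$ spans a strong but not deterministic behavioral effect;
coupling 0 makes behavior independent of theta, the null the correlation
battery is calibrated against.

The generator does **not** emulate seizure dynamics, volume conduction,
reference-electrode effects, non-stationary background drift, line-noise
harmonics, or behavioral learning curves unrelated to theta. Passing
tests therefore certify the *pipeline* -- extraction windows, spectral
estimation, artifact handling, statistical calibration -- not the
physiological realism of any conclusion about real patients.

## ASR and the adaptive cutoff

Calibration (`asr_calibrate()`) eigendecomposes the covariance of a
clean reference -- the session's opening 20 s rest, the only segment
guaranteed task-free -- and summarizes each component's sliding-window
RMS by median and scaled MAD. This robust location/scale pair replaces
the mixture fit used by some reference implementations: it is simpler,
exactly testable (doubling the reference doubles the location
parameters), and serves the same contract. Cleaning (`asr_clean()`)
slides 0.5 s windows with 50 % overlap; each window's covariance
eigenbasis is compared against the calibration threshold operator
$V\,\mathrm{diag}(\mu + k\sigma)$, and flagged components are re-imputed
from the retained ones by the conditional expectation under the
reference covariance -- i.e. reconstruction stays inside the calibration
subspace. Windows are re-blended with raised-cosine weights.

The offline cutoff adapts per epoch to the exceedance fraction (share of
samples beyond the 13 s epoch mean ± 3 SD, pooled over channels with
per-channel values reported alongside):
$k = 10$ below 1 %, $k = 6$ in the closed band [1 %, 1.5 %], $k = 4$
above. The band endpoints are taken as closed because the verbal rule
"1--1.5 %" leaves both ambiguous; the choice is stated here once and
frozen in `select_k()`. The real-time path applies either no ASR ("p01"
mode) or a fixed $k = 4$ ("p02" mode); the exceedance rule is an
offline refinement.

Exceedance is measured *after* band-pass/notch filtering and before
cleaning (filter → ASR); the reverse order would let line transients
inflate the artifact estimate the filter is meant to remove.

## Spectral estimation

`welch_psd()` uses 1 s periodic-Hann segments at 50 % overlap (23
segments in the 12 s window), density scaling in µV²/Hz, 1 Hz bins.
`band_power()` integrates by the trapezoid rule from 4 to 8 Hz inclusive
and averages across contacts; `log10` of that mean is the quantity the
session ANOVA runs on. The same spectral engine serves the real-time and
offline paths, which makes the two agree exactly on artifact-free data;
a `use_full_13s` switch reproduces a real-time variant that analyzed the
full encoding window. dB transforms floor the PSD at $10^{-12}$ µV²/Hz
before `10 log10` to avoid $-\infty$ on silent bins.

## The statistics battery and its conventions

* **Correct vs error spectra**: per session, the mean dB spectrum of
  correct and of error trials; sessions lacking either class are
  excluded; each 1 Hz bin from 1--100 Hz is tested with a paired t-test
  whose pairing unit is the *session* -- the only unit for which the
  pairs are well defined. Grouping falls back from Task 1 to Task 2 when
  near-ceiling accuracy leaves fewer than two usable sessions.
* **First vs final session**: per bin, a two-sample Wilcoxon rank-sum
  test between trial-level dB values; the dB scale is used for both
  binwise tests for consistency. Direction is the median difference.
* **Session ANOVA**: classical one-way ANOVA on per-trial log10 theta
  power, $\eta^2 = SS_B/SS_T$, Tukey HSD (Tukey--Kramer under unequal
  counts) on all session pairs. Six 20-trial sessions give the
  design-determined df (5, 114); five sessions of 20/17/20/20/20 give
  (4, 92).
* **Correlations**: three session-level Spearman correlations with
  subset rules (all trials ↔ Task 1 accuracy; old-probe trials ↔
  recall; correctly recognized old probes ↔ Task 2 accuracy). With up
  to 8 sessions the p-value is an exact full-enumeration permutation
  test with average ranks for ties; beyond that a t approximation.
  Zero-variance score series make the correlation undefined: it is
  flagged and removed from the Holm family rather than set to 0.
* **Multiplicity**: Holm--Bonferroni at alpha 0.05, applied over
  frequency bins within each binwise analysis and over the three
  correlation analyses.

Binwise confidence intervals, where displayed, are across-session CIs of
the paired difference -- the across-trial alternative is not computable
once sessions are reduced to paired means.

## Monte-Carlo problem sizes

The calibration and recovery studies shipped in the test suite use
`simulate_session_spectra()`, which synthesizes only the encoding
epochs of a session (no rest or recognition intervals, no spikes, ASR
off). This keeps the statistical questions -- familywise error of the
binwise family under equal gains, and recovery of a [1,1,1,1,1.5,1.5]
gain trajectory -- on the identical spectral/statistical code path while
making 200 null replicates and 50 effect replicates a few minutes'
work; these replicate counts were fixed as the package's study sizes.
Null familywise error is required to stay below alpha plus ~2.6 binomial
standard errors; the gain-recovery checks require at least 90 % of
replicates to flag a positive theta effect both by Tukey (late vs early
sessions) and by the first/final binwise comparison.

## Known limitations

* The ASR variant omits flatline/bad-channel rejection and whole-channel
  interpolation; it assumes all four contacts stay valid.
* EDF export quantizes to 16 bits over a per-channel symmetric range and
  pads recordings to whole one-second records.
* The exact-permutation Spearman test enumerates up to 8! orderings;
  larger session counts silently switch to the t approximation.
* The behavioral model ties Task 1 and Task 2 success to the same
  per-trial theta factor with independent draws; it cannot express
  dissociations between recognition and order memory.
* With six sessions, rank correlations have so little resolution that
  only couplings far beyond the defaults are detectable -- a property the
  null-calibration tests quantify rather than a defect.
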