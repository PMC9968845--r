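---
title: "Simulating and dissecting inter- vs intra-subject variability in motor-imagery BCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting inter- vs intra-subject variability in motor-imagery BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrbci)
```

## The problem

A motor-imagery brain-computer interface (MI-BCI) decodes imagined left-
versus right-hand movement from the sensorimotor rhythms (SMR) of the EEG:
imagery desynchronizes the mu rhythm (8–13 Hz) over the contralateral
motor cortex (event-related desynchronization, ERD) and is typically
followed by a beta (14–30 Hz) rebound (event-related synchronization,
ERS).  A decoder trained on one subject or one day's session rarely works
unchanged on another: the feature distribution shifts (covariate shift)
while the labeling rule stays the same.  This package provides a complete,
testable laboratory for studying that shift at three levels — signal
(time-frequency ERD/ERS), feature (CSP log band-power distributions), and
classifier (training-set selection strategies) — driven by a synthetic SMR
cohort generator, so that every stage can be validated without access to
any particular laboratory's recordings.

## The synthetic cohort generator

### What it emulates

Two study designs are built in as presets: a multi-subject design
(`exp1_config()`: 8 subjects, one session each) and a multi-session design
(`exp2_config()`: 2 subjects, 10 sessions each on different days).  Every
session has 8 runs of 30 trials with balanced classes (15 left + 15 right
per run, 240 trials in total), a 2 s fixation cross, 4 s of imagery and an
inter-trial rest, recorded on a 20-channel grid around C3/Cz/C4 at 250 Hz
(a 5000 Hz mode exists solely to exercise the downsampling stage).

Each simulated subject is a draw from truncated-normal priors
(`param_priors()`): mu and beta peak frequencies, contralateral and
ipsilateral ERD depths, post-imagery beta rebound, signal-to-noise ratio
(log-normal), and the lateral shift/width of two Gaussian scalp
topographies centred on C3 and C4.  Sessions of one subject are
perturbations of the subject's parameters.  The two dispersion multipliers
default to `inter_subject_sd = 1` and `inter_session_sd = 1/3`: day-to-day
drift is three times smaller than subject-to-subject spread, which is the
qualitative contrast the downstream analyses are designed to detect, and
both are configuration-exposed.

### The generative model

A session is the sum of:

* **Spatially correlated 1/f background** — independent pink-noise
  processes per channel (flat below 1 Hz), mixed through a Gaussian
  distance kernel over the electrode grid and scaled to 10 µV RMS per
  channel.  The shared background is what makes CSP non-trivial: a
  spatial filter must suppress it.
* **Four amplitude-modulated narrowband sources** — a mu and a beta
  rhythm under each of the C3- and C4-centred topographies.  Carriers are
  Gaussian narrowband processes (~1 Hz bandwidth) built by spectral
  shaping of white noise; this is the simplest model whose wavelet power
  shows genuine ERD/ERS.  During each imagery interval the source
  contralateral to the imagined hand is scaled in power by
  `1 - erd_depth_contra` and the ipsilateral source by
  `1 - erd_depth_ipsi`; both rhythms desynchronize (beta ERD is
  physiological during imagery), and for 2 s after imagery offset the
  beta source rebounds by `1 + ers_rebound` (contralateral side at full
  strength, ipsilateral at 30%).  Envelope transitions use 250 ms linear
  ramps to avoid edge ringing.
* **Spontaneous waxing and waning** — each source's amplitude is
  additionally multiplied by a slow log-normal process (log-sd 0.25,
  ~0.06 Hz bandwidth, mean-one normalised).  Without this the log
  band-power of a 4 s trial is almost deterministic and the
  feature-distribution statistics below would be measuring nothing but
  estimation error; spontaneous SMR amplitude fluctuation on the scale of
  tens of seconds is a well-established property of real recordings and
  is what gives CSP features their trial-to-trial spread.

The `snr` parameter is the rhythm amplitude at its topography peak
relative to the in-band (8–30 Hz) background RMS; the beta source is half
the mu amplitude.  At high `snr` the wavelet ERD/ERS index of a session
therefore recovers approximately `-100 * erd_depth` percent on the
contralateral channel, which is how the generator is validated end-to-end
against its own ground truth.

### What it does not emulate

No ocular or muscular artifacts, no electrode drift or impedance changes,
no volume-conduction head model, no non-stationary noise floor, no
learning or fatigue trends within a session.  Passing tests on this
generator therefore demonstrate that the analysis chain measures what it
claims to measure under controlled covariate shift — not that any
particular effect size will be observed in a given real cohort.

## The analysis chain

### Preprocessing

`preprocess_session()` applies the offline chain in fixed order:
downsample to 250 Hz (anti-alias low-pass at 80% of the target Nyquist,
then decimation), a 4th-order Butterworth notch at 50 ± 2 Hz (the
stop-band width is our choice; mains interference is not part of the
generator but the stage is always applied for fidelity to the intended
chain), and a 4th-order Butterworth band-pass 8–30 Hz.  All filters are
zero-phase: the designed transfer function is applied forward-backward,
implemented by multiplying the spectrum with the squared magnitude
response in one batched FFT pass (numerically identical to `filtfilt`
away from the recording edges, which the epoch windows never reach; the
test suite verifies the equivalence against `signal::filtfilt`
explicitly).  Zero-phase filtering doubles the effective order and is the
right choice for offline latency-sensitive ERD analysis, even though an
online implementation would have to be causal.

Epochs are cut relative to imagery onset (t = 0): `[0, 4]` s for
classification, `[-2, 8]` s for time-frequency maps.  Because filtering
happens on the whole recording before epoching, no per-epoch padding is
needed.

### Time-frequency analysis

`wavelet_tfr()` uses complex Morlet wavelets with a fixed width of 7
cycles on 8–30 Hz in 1 Hz steps — standard SMR practice, enough to
separate mu from beta.  Power is computed per trial and then averaged
(induced-activity convention), since ERD/ERS is not phase-locked; a test
with antiphase trials guards the order of operations.  Epochs are cut 1 s
wider than the analysis window and trimmed after the transform to keep
wavelet edge contamination out.  The ERD/ERS index is
`(P_post - P_pre)/P_pre * 100` with `P_pre` over −2–0 s, `P_post` over
0–4 s, both averaged over 8–30 Hz — computed from raw (uncorrected)
power.  Baseline-corrected maps (subtraction of the −2–0 s mean per
channel and frequency) are for visualisation.

### CSP and LDA

The normalized spatial covariance of a trial `X` (channels × samples) is
`X Xᵀ / trace(X Xᵀ)`.  Class-mean covariances enter the generalized
eigenvalue problem `Σ_r w = λ Σ_l w`, solved by whitening `Σ_l`
(symmetric inverse square root) followed by a symmetric eigen
decomposition — numerically more stable than forming `Σ_l⁻¹ Σ_r`, which
the test suite keeps as an independent brute-force oracle.  Filters are
unit-norm (any rescaling is absorbed by the affine-invariant classifier),
selected as the `n_pairs` largest plus `n_pairs` smallest eigenvalues,
ties broken by first occurrence; `Σ_l` receives a `1e-10 · trace` ridge
only if its condition number exceeds 1e12.  Features are the log of the
raw projected variance (not the sum-normalised variant, which is provided
as a switch), 6-D with 3 pairs for online-style decoding and 2-D with 1
pair for all distribution analyses, where a low-dimensional feature space
keeps the clouds inspectable.

LDA is the closed-form two-class discriminant: within-class scatter
`S = Σ_k Σ_{x∈D_k} (x−μ_k)(x−μ_k)ᵀ` (unnormalised — any positive scaling
cancels), `w = S⁻¹(μ_1−μ_2)`, `b = −½(μ_1+μ_2)ᵀS⁻¹(μ_1−μ_2)`, so the
discriminant vanishes exactly at the midpoint of the class means.  Exact
ties (`g(x) = 0`) go deterministically to class 1.  `S` receives a ridge
of `1e-8 · trace(S)/d` only when ill-conditioned; coincident class means
raise a warning and fall back to the tie-break.

### Transfer matrices and distribution statistics

`build_cross_matrix()` fits CSP+LDA on every session in turn and scores
every session with every model, giving an m × m accuracy matrix whose
diagonal is the within-session self-test; all trials of a session are
used both for fitting and for the self-test, mirroring the within-session
protocol the matrices are defined by.  Each cell's 2-D feature cloud is
summarised by four statistics: pooled mean and pooled population standard
deviation per dimension (1/(2n) normalisation), the mean Euclidean
distance of trials to their own class centre (`Dist_w`), and the distance
between class centres (`Dist_b`).  Multi-subject and multi-session
experiments are compared per statistic with two-sample t-tests
(equal-variance Student by default, Welch by option) separately for
diagonal and off-diagonal cells, under a Bonferroni family of 12
comparisons (6 statistics × 2 tasks): the adjusted threshold is
0.05/12 ≈ 4.17e-3.  The two multi-session subjects contribute two 10 × 10
matrices whose cells are pooled into one group, matching a single
multi-session column in the comparison.

### Training-set selection strategies

Six rules pick the training data for a target session: **Prev**/**Next**
(adjacent acquisition, cross-session tasks only, unavailable at the
first/last session), **Best**/**Worst** (highest/lowest self-test
accuracy among candidates, the target excluded), **Closest** (smallest
symmetrized Gaussian KL divergence to the target), and **All** (every
candidate concatenated).  The KL divergence is computed in closed form
between single Gaussians fitted to the pooled 2-D feature clouds — with
hundreds of trials per session a 2-D Gaussian fit is stable, and
symmetrization removes the direction ambiguity the bare definition
leaves.  For each candidate, both clouds are extracted with the
*candidate's* CSP filters: the comparison happens in the space in which
that candidate's classifier would actually operate.  Best/Worst use
self-test accuracies computed at the same filter count as the evaluation
(1 pair).  All selections are deterministic; ties break to the lowest
session index.

## Numerical choices and degenerate inputs

* Regularization is always conditional (only on ill-conditioned input)
  and proportional to the trace, so well-posed problems are computed
  exactly.
* A zero trial (`trace = 0`), a zero-variance projection (`log 0`), a
  single-class session, mismatched dimensions, out-of-range epoch
  windows and frequencies above Nyquist all raise immediate errors with
  stage-specific messages rather than propagating NaNs.
* Random number use is isolated: every subject, session and signal has a
  deterministic child seed derived from the cohort seed, so cohorts are
  bit-reproducible and any single session can be regenerated alone;
  `run_study()` outputs are byte-identical across reruns with the same
  seed.

## Problem sizes

The package's own validation runs the full paradigm structure at reduced
trial counts where many replicates are needed: the replicated end-to-end
checks use cohorts with 4 runs × 24 trials per session and a 2 s
inter-trial rest (the presets keep the full 8 × 30 design; the paradigm
leaves the rest duration free).  Sessions much smaller than ~100 trials
were rejected because CSP estimation on 20 channels becomes unstable and
the analyses stop measuring the cohort structure.  Monte-Carlo tolerances in the test suite are
stated per test and derive from the generative ground truth, e.g. a
simulated contralateral ERD depth of 0.3 at high snr must land within
[−40%, −20%] of wavelet index averaged over 20 sessions.

## Known limitations

* The generator's subjects are exchangeable draws from one prior; real
  multi-session studies may enrol subjects whose overall signal quality
  differs systematically from a multi-subject cohort, a component of
  between-experiment contrast the simulation deliberately excludes.  The
  replicated validation reflects this: the compression of the
  between-class distance under transfer (off-diagonal `Dist_b` below the
  self-test diagonal) reproduces on every replicate seed, whereas
  between-design significance of the Std/`Dist_b` statistics and the
  fine ordering of training-set strategies depend on which subjects are
  drawn — with realistic priors a sizeable minority of subjects is
  weakly lateralized (the BCI-inefficiency phenomenon), and their
  near-chance cells make quality rankings unstable across seeds.
* The Gaussian KL divergence ignores the class structure of the feature
  cloud (a bimodal cloud is summarised by one Gaussian); this matches
  the pooled formulation but understates distances between sessions
  whose class geometry differs at equal pooled moments.
* EDF export quantises to 16 bits (~0.003% of full scale per channel);
  the array-bundle format is lossless and carries the generator's ground
  truth with it.
* Accuracy-based strategy rankings on a single scaled cohort are noisy;
  conclusions should always be drawn over replicate seeds, as the test
  suite does.
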