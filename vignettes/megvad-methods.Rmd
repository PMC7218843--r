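---
title: "Detecting voice activity from neuromagnetic signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting voice activity from neuromagnetic signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Speech brain-computer interfaces decode intended speech from neural
recordings, but almost all decoders assume that someone has already marked
*when* the user is speaking. For a conversational BCI that assumption has to
go: the system must detect voice onset and offset directly from the neural
signal, per sample, in real time. `megvad` implements that detection for
multichannel neuromagnetic (MEG) recordings of a time-locked delayed
overt-reading task, together with everything needed to exercise it end to
end on synthetic data with known ground truth.

The working hypothesis is amplitude-based: sensors over speech-related
cortex show selectively elevated signal magnitude while the subject
articulates. Two models operationalize it:

* an **isolated sanity check** — a 2nd-order polynomial-kernel SVM
  classifying whole *Pre-Speech* / *Speech* / *Post-Speech* segments from
  per-sensor RMS features, under stratified 6-fold cross-validation;
* the **continuous detector** — a two-layer LSTM recurrent network that maps
  a small per-sample feature vector to a per-sample Speech / Non-Speech
  probability, trained with backpropagation through time.

## Protocol, labeling convention and the worked example

Each trial is epoched from −0.5 s to 4.5 s around stimulus onset: 0.5 s
baseline, 1 s stimulus display, 1 s preparation, then a 2 s production stage
starting at the articulation cue (at 1 kHz, epoch sample 2501). Only the
production window is analyzed; at the 1 kHz working rate one sample is one
millisecond.

Ground truth comes from the synchronized microphone. The boundary convention
is fixed by a canonical trial in which the subject starts speaking 401 ms
after the cue and stops at 931 ms: milliseconds 1–401 are *Pre-Speech* (the
onset millisecond itself is still Pre), 402–931 are *Speech*, 932–2000 are
*Post-Speech*; the binary collapse maps Pre and Post to *Non-Speech*.
`labelSegments()` implements exactly this partition and
`makeWorkedExample()` reproduces the canonical trial as a test fixture. The
off-by-one is load-bearing — every detector and metric in the package
preserves it.

## The synthetic session generator

No recordings are distributed with the package, so `simulateSession()`
generates sessions with known ground truth. Defaults are the study
conditions: 5 phrase stimuli × 100 trials, 200 sensors, 1 kHz, ~15% of
sensors speech-locked, acoustic onset uniform 300–600 ms after the cue,
speech duration uniform 400–900 ms, neural activity leading the acoustic
onset by 10 ms, and a 25% artifact-trial rate.

Design choices, and what they do and do not emulate:

* **Sensor signals** are 1/f-shaped band-limited Gaussian noise (content
  below ~125 Hz dominant) plus a rank-2 shared background term
  (`sharedBackgroundWeight`, default 0.3). Real inter-sensor covariance of
  MEG is not modeled — the pipeline consumes only amplitude statistics, so
  dipole-level realism would add cost without exercising more code.
* **Speech-locked activity** multiplies the designated sensors by
  `10^(snrDb/20)` between (onset − neural lead) and offset, with 5 ms
  cosine ramps. `snrDb = 0` is the null model: no decodable signal.
* **The acoustic burst** spans *exactly* the speech samples: background
  Gaussian noise everywhere, and inside the span a noise burst
  `audioSnrDb` (default 10 dB) above it, amplitude-modulated at ~6 Hz with
  depth 0.1. The modulator is normalized to unit mean power so the burst
  sits exactly at the configured SNR; a deeper or unnormalized modulation
  would silently lower the boundary-local SNR below the nominal condition.
  Real speech has much deeper envelope structure (syllables, plosives);
  boundary recovery at ±5 ms would not be achievable on real audio with an
  energy detector, which is why the intra-phrase structure is explicitly
  out of scope.
* **Artifact trials** get 50 ms transients at 25× the baseline standard
  deviation on a random ~30% of sensors — large enough that a deterministic
  threshold rule can stand in for visual inspection.

Consequently, passing tests demonstrate correct mechanics and honest
statistical recovery *under this model*; they do not certify performance on
real recordings, where sensor covariance, non-stationary noise and real
speech acoustics all differ.

## Preprocessing

* **Gradiometer selection** keeps only planar-gradiometer rows (they
  suppress distant sources); the microphone channel rides along separately.
* **Bad channels**: variance pooled across trials below `flatThreshold`
  (unresponsive) or above `noiseThreshold` × median (noisy) drops the
  channel everywhere, preserving order.
* **Artifact-trial rejection** replaces visual inspection with a
  reproducible rule: per sensor, the per-trial peak absolute amplitudes form
  a session distribution; a trial is rejected when any sensor's peak sits
  more than 10 robust-z units (median/MAD) above it. The cross-trial form
  matters: during normal speech the expected peak over ~650 speech samples
  at 10 dB elevation is already ~12–14 *baseline-sample* sigmas, so a rule
  z-scored against baseline samples would reject every speaking trial.
  Against the cross-trial peak distribution, speech peaks are typical and
  only genuine transients stand out.
* **Wavelet band restriction**: per channel, a 2-level Daubechies-4
  decomposition; the detail bands are zeroed and the signal reconstructed
  from the approximation, keeping content below ~`sfreq/8` = 125 Hz (the
  high-gamma band) at the 1 kHz working rate. Boundary handling is
  periodized: for even lengths the transform is a square orthonormal
  matrix, so the restriction is an exact orthogonal projection —
  band-restricting twice equals restricting once to machine precision,
  which symmetric extension cannot guarantee. A soft-threshold variant
  (universal threshold on the detail coefficients) sits behind
  `denoiseMode = "threshold"`.
* **Sampling rates**: acquisition may be at 4 kHz, but a 2-level
  approximation reaches "< 125 Hz" only from a 1 kHz base, and labels are
  defined at 1 ms resolution — so everything is resampled to
  `workingSfreq = 1000` first. The resampler is Fourier-domain spectrum
  truncation: exactly zero-phase, so millisecond alignment survives (a
  polyphase FIR resampler was measured to leave a ~1.5-sample group delay,
  enough to corrupt ±5 ms boundary contracts).

## Acoustic labeling

The microphone signal may be Wiener-denoised first: a single-pass
spectral-gain filter whose noise spectrum is estimated from the trial's
initial 200 ms of silence. Two numerical choices matter. The spectral gain
is floored at 0.15 rather than 0, so silence is *attenuated uniformly*
instead of annihilated — a zero floor collapses the noise floor that the
detector's threshold is relative to, and the surviving chi-squared
fluctuations of single periodograms ("musical noise") masquerade as speech
onsets. The optional `smoothing` constant smooths the PSD estimate across
frames (damping that same fluctuation) but blurs sharp energy edges, so it
defaults to off in the detection path.

In the pipeline the detector runs on the *raw* microphone signal by
default (`wienerFirst = FALSE`): on a stationary Gaussian background the
filter removes nothing structured, and its residual alone degrades
boundary recovery within ±5/±10 ms from ~97% of trials to ~53%. Denoising
before detection earns its place when the microphone noise is structured
(hum, interference) — which real MEG-room recordings are, and this
generator's audio deliberately is not.

Voice activity detection is energy-based with a deliberately boring core
and a careful boundary stage:

1. 10 ms frames, 1 ms hop; noise floor = median frame energy over the first
   200 ms; speech frames exceed 3× the floor.
2. Supra-threshold runs shorter than 30 ms are discarded *before* gap
   bridging — one loud noise sample lights up a full frame-length of
   overlapping frames, and bridging would otherwise absorb the glitch into
   the speech span.
3. Gaps shorter than 250 ms are bridged (intra-phrase pauses are not meant
   to be split), runs shorter than 100 ms dropped, and the longest
   surviving run selected. No supra-threshold activity flags the trial as
   "no voice detected", mirroring untimely-articulation rejection.
4. Each coarse boundary is refined to sample resolution by a two-segment
   Gaussian variance-changepoint fit in a ±100 ms window: the quiet-side
   variance is anchored at the (much more precisely estimated) noise floor,
   the loud side at the right-segment empirical level floored at 3× the
   noise floor. Squared samples are pre-smoothed with a 7 ms centered
   moving average *only* when the speech level is below 50× the floor —
   smoothing halves the error variance at 10 dB but would blur an
   essentially clean edge — and an asymmetric penalty of 0.4 nats/sample
   pulls the split toward the quiet side, because misassigning quiet
   samples costs ~0.7 nats each in likelihood while misassigning speech
   samples costs ~3.3, and equalizing the two error tails roughly doubles
   the fraction of trials recovered within ±5 ms.

Detector constants all live in `vadDetectorConfig()`. The ±5 ms (onset) and
±10 ms (offset) recovery tolerances at 10 dB are this package's contract on
its own synthetic audio; the labeling rule they feed is the published
convention.

## Features

Per time point across the `S` retained sensors: `f1` sum of absolute
values, `f2` RMS, `f3` cross-sensor standard deviation, `f4` index of the
maximum-magnitude sensor (ties to the lowest index). The std uses the
population convention (divide by `S`) so `f2² − f3² = mean²` holds exactly
and `f2 ≥ f3` is a testable invariant, not an approximation. `f1` follows
the more specific of the two published descriptions (sum of absolute
values, not mean). For model input, `f1..f3` are z-scored per trial and
`f4` is scaled to (0, 1] by the sensor count — a numerical-conditioning
choice, switchable to raw via `standardize = "none"`, since whether the
original analysis standardized is unstated. Segment-level features are
per-sensor RMS over exactly the samples of one label class, with
*Non-Speech* pooling Pre and Post.

## Models

**SVM.** `e1071::svm` with a 2nd-order polynomial kernel; stratified
6-fold cross-validation with per-fold standardization fit on training folds
only (leakage guard); one-vs-one voting for the 3-class task. On synthetic
sessions Pre and Post segments are statistically identical by construction,
so `PRE-vs-POST` hovers near chance and the 3-class accuracy near 2/3 —
on real recordings both were reported separable, which the generator makes
no attempt to emulate.

**LSTM.** Written from scratch in vectorized R (no deep-learning framework
is assumed): stacked LSTM layers with input/forget/candidate/output gates
vertically concatenated per layer, hard-sigmoid gate activations, tanh cell
and hidden activations, a 2-unit fully connected + softmax head applied at
every time point, per-sample cross-entropy, full BPTT, Adam
(β₁ = 0.9, β₂ = 0.998, ε = 1e−8, learning rate 0.005 — the midpoint of the
0.004–0.006 search range), and per-parameter L2 gradient clipping at 0.1.
Defaults are the published architecture (2 × 256 units, up to 500 epochs).
Training is batched: equal-length sequences are carried as
(units × batch) matrices per step and the input projection for a whole
batch is one matrix product, so the R loop is BLAS-dominated. Analytic
gradients are tested against finite differences.

The published protocol trains on 50 trials per stimulus and tests on the
rest, with the epoch count "decided based on validation performance" but no
explicit validation split stated; this package carves a seeded 20% of the
training trials as validation, keeps the best-validation parameters, and
stops early after `patience` epochs without improvement. Class weighting is
off by default (no reweighting was described); inverse-frequency weighting
sits behind `classWeights = TRUE`. The recurrence is unidirectional —
required for the real-time claim — and inference is deterministic and
bit-identical after save/load.

## Evaluation

Per-sample confusion counts with Speech positive;
`accuracy = (TP + TN) / (TP + TN + FP + FN)`; precision is `NA` (never a
silent 0) when no positive predictions exist. Per-subject summaries use the
population standard deviation; pooled precision/recall micro-average the
summed counts, matching single values reported across subjects. Predicted
onset/offset come from the *longest* predicted Speech run by default
(robust to isolated flipped samples; a first-run rule is available), with
signed errors in ms, negative = early. The sensor-mode analysis counts `f4`
over speech-labeled samples per subject and pooled. One-tailed paired
t-tests wrap `stats::t.test`, with the identical-samples case defined as
t = 0, p = 0.5.

## Scales used in the shipped analyses

The package's own acceptance analyses run at desk scale, chosen so the full
suite completes comfortably on one CPU: detector recovery on 200 trials
(4 sensors — audio statistics do not depend on sensor count); end-to-end
sequence-labeling recovery on 2 subjects × 5 stimuli × 60 trials at 40
sensors with a 16-unit, ≤10-epoch LSTM, trained on 50 trials per stimulus
(the published split) and evaluated on the held-out 10 per stimulus, with
the artifact injector disabled for those runs (60 simulated trials must
survive to honor the 50-train split; rejection is exercised by its own
analysis at the default 25% rate); sensor-mode recovery on 5 seeded runs of
100 trials at 40 sensors (so the designated speech set, 15% of sensors, is
larger than the top-5 report it must contain). The null condition (`snrDb = 0`) reuses one
subject. At these scales held-out per-sample accuracy lands near 99% at
10 dB and exactly at the majority-class rate at 0 dB; with the full
256-unit architecture the same code runs unchanged, only slower.

## Known limitations

* The generator's Pre and Post stages are statistically identical, so
  isolated Pre-vs-Post classification is uninformative on synthetic data.
* Energy-based acoustic labeling presumes quasi-stationary burst-like
  speech; deep envelope modulation or structured microphone noise would
  need a stronger acoustic front end.
* Periodized wavelet boundaries assume the epoch is long relative to the
  filter (8 taps); the exact-projection property needs lengths divisible by
  `2^level`, which all protocol windows satisfy.
* FIF import and head-geometry handling are out of scope; sessions enter
  either through the native container or the generator.
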