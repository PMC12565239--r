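---
title: "Methods: reading EOG from simulation to scalogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reading EOG from simulation to scalogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eogread)
```

## The problem and the signal model

During reading, the horizontal EOG channel traces a staircase: fixations
are plateaus, forward saccades are fast positive steps (the eye approaches
the temporal electrode as gaze moves rightward), regressive saccades are
sudden negative steps, and the end of each text line produces a large
negative sweep back to the line start. The vertical channel is dominated by
blink transients. Readers with dyslexia differ from typically developing
controls (TDC) in four quantities measurable from these channels: reading
time, blink rate, regression rate, and overall signal energy — all higher
in the dyslexia group. `eogread` implements the full chain from raw (or
simulated) two-channel EOG to those features and to a CNN classifier
operating on wavelet scalogram images of the signals.

## The simulator and what it does (and does not) emulate

`simulate_recording()` composes the horizontal channel from per-word
fixation plateaus (Gaussian durations, truncated at 80 ms), 30 ms linear
saccade ramps of one amplitude unit per word, regression events (backward
ramp of 1.5 word-steps, a re-reading fixation, and a compensating forward
ramp), and a 100 ms line-return sweep; the vertical channel carries
biphasic raised-cosine blink pulses (150 ms rise, 20 % undershoot) arriving
as a thinned Poisson process. White Gaussian noise (sd = 5 % of the word
step) and an optional 50 Hz sinusoid are added to both channels. Every
injected event is logged as ground truth, which is what makes the blink and
regression detectors testable: detector scores in this package are measured
against that ground truth, never against human annotation.

The group presets place the two populations where the literature puts their
contrast directions: TDC at 250 ms mean fixations, 0.05 regression
probability per word, 12 blinks/min; dyslexia at 400 ms, 0.20, and
20/min. The magnitudes are chosen for clear separability at desk scale and
are documented as synthetic — they are not a physiological calibration, and
amplitudes are in arbitrary units (no microvolt claim, since acquisition
gain is hardware-dependent). Real recordings additionally contain drift,
electrode artifacts, head-movement crosstalk, amplitude asymmetries between
rightward/leftward saccades, and within-subject fatigue effects that the
simulator does not model. Passing tests therefore demonstrate that the
pipeline recovers what the generative model encodes — correctness of the
algorithms, not clinical performance on patient data.

A consequence worth stating explicitly: on simulated data the two classes
differ strongly in horizontal-channel temporal structure (saccade stepping
rate, regression steps), so the horizontal channel classifies nearly
perfectly while the vertical channel (blink density only) hovers near
chance at small sample sizes. The ordering — horizontal at least as
discriminative as vertical — matches what is reported for real reading
EOG, but the absolute accuracies here say nothing about clinical accuracy.

## Preprocessing choices

* **Band-pass** 0.1–10 Hz, Butterworth order 4, applied with
  `signal::filtfilt` (forward–backward). Zero-phase application is a
  deliberate choice: the blink rule depends on the up-crossing-to-crest
  latency, which a causal filter would shift. The squared magnitude
  response of the double pass gives > 40 dB at 50 Hz for any sampling rate
  where 50 Hz is representable.
* **Notch** at 50 Hz, second-order Butterworth band-stop with Q = 30 (stop
  band ≈ 1.7 Hz wide), which changes in-band amplitudes by well under 2 %.
  At a 100 Hz sampling rate the mains frequency sits exactly at Nyquist;
  `eog_notch()` refuses to design such a filter and
  `preprocess_recording()` skips the stage with a warning — mains energy is
  then handled by the band-pass alone.
* **Baseline correction** subtracts the median, which is robust against the
  blink outliers themselves (a mean would be pulled upward by large
  pulses).
* **Framing** tiles signals into half-open 1000-sample windows, dropping
  the remainder. Padding was rejected because it would fabricate signal
  content that the scalogram stage would faithfully render.

## Event detection

**Blinks.** The per-signal threshold is `median + k·MAD` with `k = 4`; a
fixed absolute threshold cannot work across signals of arbitrary gain, and
the MAD resists exactly the outliers being detected. Contiguous
above-threshold regions become candidate excursions; the crest of a region
is a blink if the latency from the region's first sample (the up-crossing)
to the crest lies in 50–400 ms. The alternative 100–800 ms blink-duration
window quoted in the literature is available via `blink_config()`.

**Regressions.** The detector takes the windowed first difference
`d[i] = x[i+w] − x[i]` with a 50 ms window, and flags drops of at least
`min_drop` (default 0.6 × the median forward word-step, estimated from the
signal's own fast positive excursions, so no oracle knowledge of the
simulator's step size is used). Two guards suppress false positives: the
event's *full* local drop (pre-event maximum minus post-event minimum over
±2–3 windows) must stay below half the signal's 1st–99th percentile range,
which excludes line-return sweeps — the bound is applied to the full drop
rather than the windowed difference because a window sliding across a large
sweep passes transiently through any acceptance band; and events whose
evaluation window is truncated by the signal boundary are discarded, since
they cannot be sized and the boundary carries filter transients. Events
closer than 150 ms are merged (first kept).

## Features and group statistics

`extract_features()` returns one row per recording: reading time
(marker difference over the sampling rate), blink count and blinks per
minute of reading time, regression count and regressions per word, and the
discrete energy `Σ x[n]²` of the horizontal channel (unit sample spacing;
additive over segments, invariant under reversal and sign flip).
`group_report()` computes per-text group means and per-grade two-sample
t-tests (equal variances). Because it is genuinely ambiguous whether the
unit of analysis in such comparisons should be the subject or the
subject-by-text observation, the report computes both and labels them; the
subject level is the conservative choice and is what the printed report
shows. Stars follow the conventional thresholds 0.05 and 1e-4.

## Scalograms

No continuous wavelet transform was available in the installed R stack, so
the package implements the analytic Morlet CWT directly via the FFT method
with Torrence–Compo normalisation (`sqrt(2·pi·a·fs)` per scale). The
wavelet is Morlet with centre frequency 6 — the common default for
time–frequency analysis of physiological signals — with 12 voices per
octave spanning 0.1–10 Hz; all three are configurable via
`wavelet_spec()`. Accuracy is property-tested: the power ridge of a pure
tone between 0.5 and 5 Hz falls within one voice (factor `2^(1/12)`) of the
true frequency.

Images are rendered numerically rather than through a plotting device:
log10 power (offset 1e-12), per-image min–max normalisation, a 256-entry
jet-like lookup table, bilinear resize to the target size (28×28 for the
compact CNN; 227×227 suits AlexNet-shaped models). This path is a pure
function of the scalogram — bit-reproducible, with two useful invariances:
scaling the power by any positive constant leaves the image unchanged, and
a constant scalogram maps to the mid-scale colour instead of erroring.

## The classifier

The architecture is fixed by its layer ledger: four 4×4 convolutions with
16/32/64/64 filters (stride 1, same padding), each followed by batch
normalisation and ReLU; max pooling after blocks one and two; 50 % dropout;
a 2-unit fully connected layer; softmax. The printed activation sizes
(28×28×16 → 7×7×16 → 7×7×32 → 3×3×32 → 3×3×64) force the pooling geometry:
a 2×2/stride-2 pool cannot map 28 to 7, so the first pooling stage uses
pool 4/stride 4 and the second pool 2/stride 2 with floor (7 → 3). This
reproduces every per-layer learnable count (784, 32, 8224, 64, 32832, 128,
65600, 128, 1154; total 108,946) and the fully connected input of
3·3·64 = 576. Where a layer ledger's name strings and learnable columns
disagree (e.g. a batch-normalisation row labelled with half its channels),
the learnable columns win, as they are mutually consistent; a softmax layer
has no learnables by definition.

Forward and backward passes are implemented with im2col patch-gathering and
BLAS matrix products; batch normalisation keeps running moments (momentum
0.1) for evaluation mode, and dropout uses inverted scaling. Training
defaults — Adam, learning rate 1e-3, batch 64, 20 epochs, cross-entropy —
are ordinary choices for a network of this size and are fully configurable
through `cv_config()`; initialisation is He-scaled Gaussian. Every
stochastic component (fold assignment, initialisation, shuffling, dropout)
derives from the configuration seed, so cross-validation runs are exactly
reproducible.

`run_cv()` performs stratified k-fold cross-validation (k = 5 by default).
The split unit defaults to `frame`, mirroring the common frame-level
protocol, but this lets frames of one recording appear in both train and
test folds — an optimistic-leakage risk on real data. Subject-level
splitting (`split_unit = "subject"`) is provided and recommended whenever
subjects contribute multiple frames. Metrics come from the fold confusion
matrices as percentages; a zero-denominator metric is reported as `NaN`
with a flag, never silently zero. Fold summaries are the arithmetic mean
and sample standard deviation, plus the overlapped (element-wise summed)
confusion matrix.

## Problem sizes and numerical choices

The package's own experiments and tests run at desk scale, chosen as the
smallest sizes at which each property is comfortably demonstrated: detector
scores on 20 recordings of a 220-word text (≈ 650 blinks, ≈ 750
regressions); group contrasts at 10 subjects per group over two texts;
learnability on 50 images per class with 5 folds and 6–8 epochs; channel
ordering over 3 seeds with 30 images per class per channel. Type-I error
of the group test is checked over 50 simulated null datasets. Tolerances:
in-band filter gain within 5 %, notch passband within 2 %, CWT ridge within
one voice, blink-latency quantisation one sample at 100 Hz.

## Known limitations

* The simulator omits drift, artifacts and saccade-amplitude asymmetries;
  detector scores on it are upper bounds for real data.
* A 50 Hz notch is unavailable at a 100 Hz sampling rate (Nyquist); the
  band-pass then provides all mains suppression.
* EDF import/export is not implemented; recordings exchange as CSV with a
  JSON sidecar.
* Only the compact CNN is built in; external architectures can be compared
  by training on the exported PNG image datasets, but are out of scope
  here.
* Training is single-threaded CPU code intended for small images and
  datasets; it is not a general-purpose deep-learning engine.
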