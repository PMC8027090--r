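---
title: "Simulating and decoding two-channel motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding two-channel motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micnn)
```

This vignette documents the models, parameter choices and numerical
conventions behind `micnn`'s pipeline: a generative model for two-channel
motor-imagery EEG trials, two time-frequency expansions, band-wise common
spatial pattern (CSP) features, and a small one-dimensional convolutional
network trained by plain gradient descent.

## The signal model behind the simulator

During unilateral hand imagery, the mu rhythm (8–12 Hz) over the
contralateral sensorimotor cortex weakens (event-related
desynchronization, ERD) while the ipsilateral beta rhythm (12–25 Hz)
strengthens (event-related synchronization, ERS). The simulator renders a
cued-trial protocol — 7 s trials at 100 Hz with imagery from 1.5 s to
5.0 s — on the C3/C4 electrode pair, with C3 (left hemisphere)
contralateral to right-hand imagery. The paper-style protocol never states
the montage mapping explicitly; the assignment here is the standard 10–20
physiology and is fixed, not configurable.

Each channel is a sum of three independent processes:

* **Background**: 1/f-shaped Gaussian noise (spectral shaping with a 1 Hz
  floor so near-DC bins do not dominate), parameterized by its RMS
  (`noise_amplitude`, default 1.0 in microvolt-scaled arbitrary units).
* **Mu and beta oscillations**: by default, white noise passed through a
  4th-order Butterworth band-pass (applied forward–backward, so the
  effective attenuation is doubled but the phase is zero) and normalized
  to unit RMS. Band-limited noise rather than a sinusoid gives CSP a
  realistic trial-to-trial variance structure. A `"sinusoid"` mode
  (fixed band-center frequency, random phase) is kept because its band
  power is exactly `A²/2`, which makes the ERD/ERS arithmetic verifiable
  to numerical precision.
* **Lateralized modulation**: inside the imagery window the contralateral
  mu amplitude is multiplied by `1 − erd_depth` and the ipsilateral beta
  amplitude by `1 + ers_gain`. The transition uses a 0.1 s raised-cosine
  ramp at each window edge; an instantaneous amplitude step would inject
  broadband energy exactly at the boundary, which no physiological
  recording shows.

Defaults — mu RMS 1.5, beta RMS 1.0, noise RMS 1.0, `erd_depth = 0.5`,
`ers_gain = 0.5` — describe a clearly expressed, low-artifact motor-imagery
session: the within-band background power (about 9 % of the 1/f total falls
into the mu band) is small against the rhythm power, so halving the mu
amplitude is an unambiguous class signal. Field recordings are harder than
this: the simulator has no eye-blink or EMG artifacts, no inter-subject
variability, no non-stationary baseline drift, and only two channels.
Passing tests on these data therefore demonstrate the *correctness of the
pipeline's computations*, not expected performance on real recordings —
which is why the headline validation accuracies here saturate near 1.0
while comparable real-data systems report around 0.93.

## Time-frequency expansions

**STFT.** The windowed DFT uses a 0.5 s (50-sample) Hamming window. The
canonical 33 × 35 × 2 tensor at 100 Hz over a 3.5 s imagery window pins
down the remaining conventions, which the source protocol leaves open:
frames are *centered* at samples 0, 10, 20, …, 340 (hop 10, zero-padded at
the edges), and each windowed frame is zero-padded to a 64-point transform,
giving 33 one-sided bins. The tensor axes are frequency × time × channel.
Magnitudes (not power, not complex values) are returned.

**CWT.** The mother wavelet is the real Gaussian-enveloped cosine
`ψ(x) = exp(−x²)·cos(π√(2/ln 2)·x)`. Its moments are computed by
trapezoidal quadrature: center time t₀ and RMS time span from `|ψ(t)|²`,
center frequency ω₀ and RMS bandwidth from `|Ψ(ω)|²` with the frequency
integrals restricted to ω ∈ [0, ∞) — over the full line the first moment
of a real wavelet's even power spectrum is identically zero, so the
one-sided domain is the only reading that yields a meaningful center
frequency (ω₀ ≈ 5.34 rad/s, the cosine frequency). The spans are RMS
(square-rooted second central moments); the closed-form check is the pure
Gaussian `e^{−x²}`, whose time span is exactly 1/2.

The transform itself is the plain discrete sum
`W(a,b) = Σ_t x(t)·a^{−1/2}·ψ((t−b)/a)` with one shift per sample. The
default evaluation path computes the same sum by zero-padded FFT
correlation and is required (and tested) to agree with the literal
summation to 10⁻⁸ relative. The 35 scales are log-spaced so that the
pseudo-frequencies ω₀/(2πa) cover 4–40 Hz; the time axis of the scalogram
tensor is simply the full trial (700 samples at the defaults).

## CSP features

Per band (mu, beta), each trial is zero-phase band-pass filtered, its
spatial covariance `XXᵀ` is normalized to unit trace (amplitude-scale
invariance), and the class-averaged covariances C₁ (left) and C₂ (right)
enter the generalized eigenproblem `C₁w = λ(C₁+C₂)w`, solved by whitening
`C₁+C₂` and eigendecomposing the whitened C₁. Filters are scaled so
`W(C₁+C₂)Wᵀ = I`; eigenvalues lie in (0, 1) and are complementary between
classes (λ + λ′ = 1). The m largest- and m smallest-λ filters per band are
kept, and each trial is summarized by the log of each projection's variance
normalized by the within-band total — `N = 4·m` features over the two
bands. With two channels m = 1 is forced (N = 4). A ridge of 10⁻⁸ is added
to a numerically singular composite covariance before whitening; a 10⁻¹²
floor inside the log guards zero-variance projections.

## The network and its training

The architecture is `I1(1×N) − C2(i2×1×n2) − C3(i3×1×n3) − F4 − O5`: two
valid (no-padding) 1-D convolutions with ReLU, a tanh dense layer, and a
two-unit softmax head. Defaults: i2 = 8, i3 = 16, kernel lengths
n2 = n3 = 2, F4 width 32. The kernel counts and dense width follow the
customary doubling pattern for small nets; the kernel length is forced by
the input — with N = 4 two length-2 kernels give the chain 4 → 3 → 2, the
shortest valid two-layer stack (length-3 kernels would collapse the second
feature map to length 0). Pooling layers (max and average, with the usual
delta-routing and delta-splitting backward rules) are implemented and
gradient-checked but disabled by default: on feature maps of length 2–3
they would only discard information. For spectrogram inputs the tensor is
flattened to one row (length 2310) and longer kernels become meaningful —
that is the regime the kernel-length sweep utility explores.

The loss is the squared error `Σ(Yᵢ − Rᵢ)²` applied to the softmax outputs
against one-hot targets. Squared error on probabilities and a softmax head
are an unusual pairing (cross-entropy is the canonical partner and is
available behind `loss = "cross_entropy"`), but the pairing is well-defined:
the output delta is the softmax Jacobian applied to 2(Y − R), and the
finite-difference check covers it like every other path. Initialization:
convolution kernels uniform on [−0.3, 0.3], dense weights normal (sd 0.1)
truncated to the same interval, every bias 0.1 — the two published
initialization statements ("normal random" and "[−0.3, +0.3]") are each
honored in their own layer class. Training: mini-batches of 64, learning
rate η(i) = 0.0002 + 0.0198·e^{−i/1000} (the exponential interpolation
that matches both published endpoints), inverted dropout (rate 0.5) at F4
only, plain SGD, gradients averaged over the batch. Shuffling, dropout and
initialization all derive from one seed, so runs are bit-reproducible.

Numerical conventions worth naming: ReLU′(0) = 0; argmax ties (prediction
and max pooling) resolve to the lowest index; softmax is computed with the
max-subtraction trick; the epoch loop drops a trailing partial batch.

## Experiment drivers

* `split_indices()` performs a stratified shuffled 8:2 split, rounding per
  class so the totals are exact (8,600 → 6,880/1,720).
* `evaluate_model()` reports accuracy, precision (also exposed under the
  field's table heading "discrimination"), sensitivity, specificity and
  the rank-sum (Mann–Whitney) AUC with ties counted one half. The positive
  class is fixed as left-hand imagery.
* `kernel_size_sweep()` retrains per kernel length with a shared seed;
  lengths that collapse the conv chain are skipped with a warning and
  reported as `NA`, and ties for the best length resolve to the smallest.
* `time_segment_analysis()` crops trials to [0, 2), [2, 4), [4, 6) s from
  trial start and runs the full CSP + CNN pipeline per segment, fitting
  CSP on the training split only.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale: 200 trials per class for the training-dynamics and
validation-accuracy checks (8,000 and 2,000 iterations respectively), 100
trials per class for the statistical ERD and symmetry properties, 60 per
class for the segment analysis, and 20 random micro-architectures
(N ≤ 12, ≤ 4-wide kernels, ≤ 3 dense units) for the finite-difference
gradient check. These sizes give the statistical assertions comfortable
margins (3 standard errors) while keeping a full run around a minute.

## Known limitations

Beyond the simulator's idealizations listed above: the CSP path with two
channels cannot use more than one filter pair per band; the CWT uses the
real mother wavelet as defined (no analytic/complex Morlet, so scalogram
coefficients oscillate at the signal frequency rather than tracing a
smooth envelope); and the training loop implements exactly plain SGD — no
momentum, weight decay, or batch normalization — because the method under
study specifies none.
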