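---
title: "Decoding phantom limb movements from intraneural ENG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding phantom limb movements from intraneural ENG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After an above-knee amputation, the efferent motor pathways of the
missing limb survive in the residual nerve. Transversal intrafascicular
multichannel electrodes (TIMEs) implanted in the distal sciatic nerve —
four electrodes of 14 active sites each, 56 recording channels sampled
at 30 kHz — pick up multiunit electroneurographic (ENG) activity while
the user attempts ("phantom") movements of the knee, ankle and toes in
both directions. `engdecode` implements the offline stack that turns
those recordings into movement predictions and physiological maps:
band filtering, multiunit detection, rate-modulation maps, spike-event
encoding, a shallow spiking neural network (SNN) classifier trained by
surrogate gradient, conventional SVM/MLP baselines, and a synthetic
recording generator that emulates the experimental protocol so every
stage can be validated end to end without access to patient data.

The protocol the package assumes (and the generator emulates): six
movement classes (knee/ankle/toes × flexion/extension; for the ankle,
"flexion" denotes plantarflexion and "extension" dorsiflexion, matching
the anatomical flexor/extensor compartments), organized in 3 randomized
blocks × 10 repetitions, each trial 2 s of movement (1 s flexion
immediately followed by 1 s extension) then 2 s of rest. Decoding
samples are 100 ms windows cut from the phase matching each trial's
direction label. Time is handled in seconds with half-open windows
`[start, end)` and sample index `floor(t * fs)`, so contiguous windows
tile a phase exactly once.

# Preprocessing

Four band variants of the signal are used, all 4th-order Butterworth
band-passes applied zero-phase (forward–backward): the ENG band
250–7500 Hz, the inter-muscular EMG (imEMG) band 50–350 Hz, an
ENG-only band 350–7500 Hz, and a hybrid band 50–7500 Hz. Powerline
interference is removed first by a cascade of IIR notch biquads at
every multiple of 50 Hz up to 10 kHz (and below Nyquist), each with
quality factor Q = 100 interpreted as center frequency over bandwidth.
The notch precedes the band-pass in all variants because the imEMG
passband contains powerline harmonics.

Two numerical choices deserve note. First, the band-passes are designed
directly as second-order sections — analog Butterworth prototype poles,
band transformation and bilinear mapping applied pole by pole — because
transfer-function coefficients of an 8-pole band-pass with edges at
0.003–0.023 of the sampling rate are numerically ill-conditioned. The
design is checked in the test suite against an independent
transfer-function design at a benign specification and against the
analytic magnitude response (−3.01 dB at both edges, unit gain at the
warped center). Second, zero-phase application uses odd-reflection
padding of 3× the section count on both ends; this suppresses start-up
transients in short segments and preserves spike timing across bands.

A practical caveat on the notch cascade: with Q = 100 the k-th harmonic
has a bandwidth of `k/2` Hz, so frequencies within a few Hz of a high
harmonic sit on the notch skirt (e.g. the cascade passes 1013 Hz at
about 92% amplitude single-pass, 84% zero-phase). This is a property of
the specified design, not an implementation artifact, and the tests pin
the measured attenuation to the cascade's own frequency response.
Channel quality control is automated: a channel is flagged if more than
1% of its samples are non-finite or its trace is constant.

# Multiunit detection and modulation maps

Spikes are detected per channel where the absolute filtered signal
crosses `k · SD(signal)` from below, with a 1 ms dead time; `k` is a
subject-level constant (3.5 and 4 for the two subjects in the source
protocol). The SD is taken over the full filtered trace of each
channel, and thresholds are fixed once and reused wherever segments of
the same recording are scanned, so the rate information is not absorbed
by per-segment re-thresholding. Firing rates are counts in
non-overlapping 100 ms bins divided by the bin width.

Channel responsiveness to a condition is the z-score

$$z = \frac{\mu_{\text{action}} - \mu_{\text{rest}}}{\sigma_{\text{rest}}}$$

with rates pooled over all repetitions of the condition: action is the
1 s phase matching the class direction, rest the 2 s pause after the
movement. A channel is significant for the condition when `z > 0.5`.
A zero rest-SD makes the score undefined; the package returns a `+Inf`
sentinel (excess action rate) or 0, with a warning. No multiple-testing
correction is applied, matching the source analysis; a Friedman test
on repeated rate measures (channels as subjects) is exposed separately
(`rate_friedman`) as a secondary gate. The Friedman statistic comes
from `stats::friedman.test` (mid-rank ties with tie correction); the
fully tied table, where the corrected statistic degenerates to 0/0, is
mapped to statistic 0 and p = 1 by definition.

Selectivity matrices partition the 56 channels per joint into
flexion-only / extension-only / both / silent (percentages summing to
100), and per channel into silent / single-joint / multi-joint
categories. Motor–sensory overlap tables do the same against a sensory
map (per-channel label of the region where intraneural stimulation
evokes sensation — consumed as a given table, never computed here).

## Herdin distance and muscular involvement

Similarity between two correlation-like matrices uses the Herdin
distance

$$d(R_1, R_2) = 1 - \frac{\operatorname{tr}(R_1 R_2)}
{\|R_1\|_F \, \|R_2\|_F} \in [0, 1],$$

zero for matrices equal up to scale, one for trace-orthogonal pairs.
Neural activation overlap between joints is summarized as a symmetric
Jaccard matrix of the significant-channel sets; muscular involvement
as the analogous Jaccard matrix of the muscles engaged by each joint's
movement. The muscle table shipped with the package
(`inst/extdata/muscle_matrix_synthetic.csv`) is a synthetic
reconstruction from standard lower-leg anatomy restricted to
sciatic-branch innervation below the amputation: 7 flexor-compartment
muscles (gastrocnemius, soleus, plantaris, popliteus, tibialis
posterior, flexor digitorum and hallucis longus) and 4
extensor-compartment muscles (tibialis anterior, extensor digitorum
and hallucis longus, peroneus tertius). Knee extension is driven by
muscles lost above the amputation, so extension-direction comparisons
restrict to ankle/toes via the `joints` argument. The exact
normalization used to turn Venn diagrams into matrices in the source
analysis is not published, so printed distances are not reproduced
here; the package documents its Jaccard choice and exposes the raw
sets for alternatives.

# Event encoding

Three encodings turn a preprocessed 100 ms segment into a spike tensor
of 40 time steps (2.5 ms bins) × channels:

* **Threshold encoding** — multiunit detection as above, counts per
  bin.
* **LIF encoding** — one leaky integrate-and-fire neuron per channel
  integrates the full-wave-rectified, z-scored signal scaled by a
  drive gain: `dU/dt = (drive − U)/τ`, with τ = 10 ms, threshold
  350 mV, reset 0 mV, refractory 1 ms. Integration runs by Euler
  stepping at the signal's own sampling step (1/30000 s); a 1 ms
  refractory period would be meaningless at 2.5 ms steps, so binning to
  2.5 ms happens after integration. Under constant drive `D` above
  threshold the inter-spike interval has the closed form
  `t_refr + τ ln(D/(D − thr))`, which the tests verify to within one
  integration step.
* **Double encoding** — the two tensors concatenated along the channel
  axis (56 → 112 inputs).

Two parameters of the LIF encoder are not published and are fixed here
as package defaults. The drive gain is 400: the mean rectified
z-scored amplitude of a Gaussian channel is ≈ 0.8, so the mean drive
(≈ 320 mV) sits just below the 350 mV threshold and events mark
amplitude excursions — multiunit transients and power rises — rather
than free-running charge/fire cycles. The z-score normalization is
taken per channel over the *whole recording* (the pipeline passes the
same recording-level statistics used for detection thresholds): the
encoder in the source protocol ran over the entire recording, and
normalizing each 100 ms segment separately would cancel exactly the
across-segment power modulation the encoding is meant to extract.
Per-segment statistics remain the fallback when no recording-level
statistics are supplied. Binned values are counts, not binarized; the
refractory period caps them at 3 per 2.5 ms bin.

# The spiking classifier

A single fully connected layer maps input spike tensors to one output
LIF unit per movement class, with synaptic conductance:

$$I_{syn}[t] = \alpha\, I_{syn}[t-1] + W x[t]$$
$$U[t] = \beta\, U[t-1] + I_{syn}[t] - S[t-1]\, U_{thr}$$
$$S[t] = 1 \iff U[t] \ge U_{thr}$$

with α = 0.95 (synaptic current decay), β = 0.98 (membrane decay), and
a soft reset that subtracts exactly `U_thr` after a spike. The
predicted class is the output unit with the highest spike count; ties
break to the lowest class index and are flagged.

Training minimizes the MSE spike-count loss: the firing fraction
(count / 40 steps) of the correct unit is pushed towards 0.8 and all
others towards 0.001, with Adam at learning rate 1e-3, batch size 70,
500 epochs by default. Gradients flow through the spike
non-linearity via a fast-sigmoid surrogate derivative
`1/(1 + 25·|U − U_thr|)²` (slope configurable); thresholds are
co-trained with the weights and clamped positive. Backpropagation
through time is implemented in C++ and is verified in the tests against
an independent R implementation of the same recurrences, and the
forward pass against a scalar step-by-step simulation.

Weights initialize uniformly on `[0, 1]/sqrt(n_inputs)`. The
non-negative range is deliberate: inputs are non-negative event counts,
and a signed initialization leaves some output units net-inhibited from
the start — they never reach threshold, the surrogate gradient vanishes
far below threshold, and the unit stays permanently silent (we observed
exactly one class becoming unlearnable this way). Starting every unit
excitatory guarantees initial firing and gradient flow; the loss then
prunes what should be silent.

Evaluation uses stratified 5-fold cross-validation (per-class
round-robin after a seeded shuffle); the same fold assignment is reused
across the SNN and the baselines so decoders are compared on identical
splits. Accuracy is per 100 ms sample. The electrode-contribution
analysis retrains the classifier on every combination of 1–4
electrodes (channel groups of 14; input widths 14/28/42/56) and reports
per-combination accuracies and the Pearson correlation between
electrode count and accuracy.

# Conventional baselines

The baselines operate on 112-dimensional feature vectors: per channel,
one value per non-overlapping 50 ms sub-window of the 100 ms sample,
concatenated channel-major. Features are RMS, power (= RMS², an
identity the tests assert), and spike rate (detected events / window).
Classifiers are a linear-kernel SVM (`e1071::svm`, C = 1) and an MLP
with one hidden layer of 236 units — 210% of the input width
(`nnet::nnet`). Features are standardized with statistics fitted on
the training fold only; the test fold reuses the training-fold scaler,
so standardization cannot leak fold information. An RBF-kernel SVM is
available behind a flag but excluded from comparisons (it was dominated
by the linear kernel in the source analysis).

# The synthetic generator

`gen_config`/`generate_recording` emulate the study conditions: 56
channels at 30 kHz; per channel, Gaussian broadband noise (SD 1),
powerline sinusoids at 50/100/150 Hz with random phases (amplitudes
0.5/0.25/0.12 noise-SD), and inhomogeneous-Poisson multiunit spikes as
a fixed biphasic 1 ms template (0.3 ms positive lobe at half amplitude,
0.7 ms negative lobe at full amplitude). Baseline rate defaults to
8 Hz and tuned channels rise to `gain × baseline` during the phase
window matching their class — magnitudes chosen to sit in the observed
range of real multiunit rates (medians ≈ 7–25 Hz, with tuned rates up
to tens of Hz). Optional extras: an amplitude-modulated 50–350 Hz
inter-muscular component during tuned movements, and a burst mode that
confines tuned spikes to a fixed-latency window inside each 100 ms
frame. Everything is seed-deterministic: the same configuration
reproduces the recording bit-identically.

Presets freeze the validation conditions: `high-snr-separable`
(round-robin tuning, every electrode carries channels for all six
classes, 5× gain, 8 SD spikes), `low-snr`, `null` (no tuning),
`s2-like` (four classes, flexion-dominant gains), and
`subthreshold-rate` (8× gain but 1 SD spike amplitude — a rate code at
the noise floor, individually invisible to `k·SD` detection but
visible to membrane integration as a power modulation; this is the
regime in which spike-rate features fail and the LIF encoding does
not).

For long protocols the decoding front end streams: each trial's
movement window (±0.25 s margin absorbing filter transients) is
synthesized from a per-trial seed derived from the generator seed,
filtered, and encoded; a first pass accumulates the per-channel moments
that fix detection thresholds and LIF normalization, and a second pass
regenerates identical chunks for encoding. The moments are estimated on
a deterministic, evenly spaced subsample of trials (12 by default,
more than 7×10⁵ filtered samples per channel, pinning the SD to a
fraction of a percent); `stat_max_trials = Inf` reproduces the
full-trace statistic exactly. Peak memory stays near a single 2.5 s chunk
(tens of MB) regardless of protocol length. Because chunks are
independent, nothing is stitched across trial boundaries; rest-period
signal is only materialized by `generate_recording`, which the
modulation-map analyses use at their smaller problem sizes.

What the generator does *not* emulate: electrode impedance and contact
variability, drift and motion artifacts, spike waveform diversity and
unit overlap, co-contraction, and any biophysical volume conduction.
Passing the end-to-end checks therefore demonstrates that the stack
recovers what it is designed to recover under the stated noise model —
not that real intraneural data are this clean. The headline accuracies
of the source study depend on its real recordings and are deliberately
not targets here.

# Validation problem sizes

The end-to-end checks run at reduced, fixed sizes chosen once: the
separable/null pipelines use 6 classes × 1 block × 10 repetitions
(600 samples) at the full 30 kHz and 100 training epochs over five
generator seeds; the encoder-ordering comparison uses 5 repetitions
(300 samples) per seed; the modulation-recovery study uses 50
replicates of 8 channels × 1 class × 5 repetitions; the
electrode-subset analysis reuses the first separable dataset at 60
epochs. `scripts/acceptance.R` recomputes all of these from scratch
with seeds derived from its `--seed` argument.

# Known limitations

* The SNN is single-layer by design; the decoding problems it is
  validated on are approximately linearly separable, as in the source
  setting. No deeper architectures, no online/real-time path, no
  stimulation-artifact handling.
* No spike sorting: detection is multiunit by construction, and the
  same unit recorded on several channels is counted on each.
* `rate_friedman` inherits `stats::friedman.test`'s tie correction;
  exact permutation p-values are not provided.
* The muscle involvement table is an anatomical reconstruction, not
  the study's own supplementary table; Herdin distances against it are
  structurally comparable but not numerically identical to published
  values.
* Accuracy is always per 100 ms sample; per-trial aggregation (e.g.
  majority vote) is easy to add on top of `predict` but is not what
  the reported numbers mean.
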