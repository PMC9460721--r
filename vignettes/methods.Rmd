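---
title: "Synchrosqueezed time-frequency imaging and multi-level CNN features for seizure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrosqueezed time-frequency imaging and multi-level CNN features for seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssqeeg)
```

## The problem

Seizure *prediction* asks whether the minutes leading up to a seizure — the
preictal state — can be distinguished from ordinary baseline brain activity
(interictal) in scalp EEG. `ssqeeg` frames this as patient-specific binary
classification of short fixed-length EEG windows: the positive class is
preictal, and every false positive is a false alarm that would have reached
a patient. The package covers the whole chain — EDF input, period staging,
time-frequency imaging, a convolutional classifier, and segment-based
evaluation — together with a synthetic-EEG generator that makes the chain
testable without clinical recordings.

## Staging the recording

Each record is partitioned with half-open intervals `[start, end)` in
seconds, 0-based sample indexing:

* **preictal** — the `preictal_minutes = 15` minutes ending exactly at
  seizure onset. Fifteen minutes is a deliberate middle ground: long
  horizons (30-60 min) dilute the preictal signature and stress patients
  with early alarms; very short ones leave no time to intervene. The
  window is clipped at the record start and truncated at any earlier
  seizure's offset, so a preictal segment can never overlap ictal data.
* **ictal** — onset to offset, excluded from classification.
* **interictal** — at least `interictal_margin_hours = 4` hours away from
  *every* onset and offset. For patients with several records the margin
  is enforced on a common absolute time axis built from the EDF header
  start times; when no start times are available records are treated
  independently (and this is logged).
* everything else, including the postictal tail, is **excluded**. The
  4-hour rule already removes the postictal period, so it needs no
  separate label.

Windows of 1 s or 3 s tile each usable interval from its start with no
overlap by default (overlap is configurable; nothing in the standard
configuration uses it), and trailing partial windows are dropped, giving
`floor(L / w)` segments per interval. Because interictal data vastly
outnumbers preictal data, the interictal segments are subsampled uniformly
without replacement to a 1:1 ratio (all preictal segments are always
kept). The draw is owned by a seed in the configuration, so a pipeline run
is reproducible end to end.

## The transform

For a signal $x(t)$ and an analytic mother wavelet $\psi$, the continuous
wavelet transform is

$$W_x(a, b) = \int x(t)\, a^{-1/2}\, \overline{\psi\!\left(\tfrac{t - b}{a}\right)} dt,$$

computed in the frequency domain (one FFT of the signal, multiplied per
scale by the conjugate scaled wavelet response). The wavelet is an
analytic Morlet: a Gaussian in frequency centred at $f_c = 1$ cycle with
spread $f_c / 6$ (about six cycles under the envelope), hard-zeroed on
negative frequencies. The scale grid is logarithmic with 8 voices per
octave over 0.5-50 Hz by default; a true 0 Hz is unreachable on a
log-frequency grid, so "0-50 Hz" operationally means "everything the
transform resolves below 50 Hz, down to 0.5 Hz".

The phase transform
$\omega_x(a,b) = \Re[\partial_b W_x / (i 2\pi W_x)]$
estimates the instantaneous frequency carried by each coefficient.
$\partial_b W$ is computed spectrally (a second transform with the
integrand multiplied by $i2\pi\xi$), with a finite-difference evaluation
kept in the test suite as the independent oracle. Where $|W| \le \gamma$
the phase is undefined and masked; $\gamma$ defaults to
$10^{-8}\max|W|$ per map — the theory only requires $W \ne 0$, and this
threshold merely keeps floating-point noise out of the reassignment.

Synchrosqueezing then moves each coefficient to the frequency bin nearest
its $\omega$ estimate:

$$T_x(\xi, b) = \sum_{k:\ \omega(a_k,b) \in \text{bin}(\xi)} W_x(a_k, b)\, \frac{\Delta a_k}{a_k},
\qquad \frac{\Delta a_k}{a_k} = \frac{\ln 2}{v}.$$

The output grid is linear with 128 bins (matching the 128-row classifier
images). Nearest-bin assignment breaks ties toward the lower bin;
estimates outside the grid are discarded. Reassignment moves mass but
never rescales it, so per-column sums of $T$ equal the weighted sums of
the contributing $W$ to machine precision — this conservation identity is
asserted in the tests. Note the measure: the reassignment weight is
$da/a$, as in the formulation this package follows; parts of the
synchrosqueezing literature use $a^{-3/2}da$ instead, which changes only
the fixed per-scale weights, not which bin any coefficient lands in.

Boundary handling: the signal is reflect-padded by five Gaussian standard
deviations of the largest-scale wavelet before the FFT and cropped after,
so edge columns are attenuated rather than wrapped. Coefficients closer
to an edge than the wavelet support at their own scale (the cone of
influence) are *flagged but retained* — `boundary_mask()` exposes the
flags. The flags matter for short windows: on a 3 s segment with the
default 0.5 Hz floor, the bottom octaves' supports exceed the entire
signal, so their coefficients are boundary-contaminated everywhere and
the padding transient deposits a few percent of magnitude mass into the
lowest frequency bins of the squeezed map. Production outputs keep these
coefficients (zeroing them would blank the low-frequency image rows the
classifier feeds on); quantitative localization *measurements* in the
test suite exclude flagged coefficients and evaluate the central 50% of
columns ("interior columns").

Why squeeze at all? For a pure tone the scalogram spreads energy across
neighbouring scales, while the squeezed map concentrates it into one or
two bins; the package quantifies this as a strictly lower entropy of the
frequency marginal, and the test suite asserts it. Sharper ridges are the
entire motivation for feeding the classifier squeezed maps rather than
plain scalograms.

## Images

Per channel of a segment: transform, band-limit to 50 Hz, magnitude
(linear by default; `log1p` is available behind a flag — the reference
work never states which it used), bilinear resize to 128 x 128 under the
half-pixel-center convention (the common image-library default; the
convention matters and is pinned by a closed-form oracle test), then
min-max normalization to [0, 1] per channel. Constant channels map to
zero. Channels stack in montage order, giving 128 x 128 x 18 tensors for
the bundled CHB-MIT bipolar montage and 128 x 128 x 16 for the
referential one. Per-channel (rather than global) normalization was
chosen because channel gains differ and the CNN input must be bounded
either way; a `normalize = "global"` switch exists.

## The classifier

The multi-level-feature CNN is a VGG16-derived graph: five blocks of 3x3
stride-1 ReLU convolutions with 2x2 max-pooling, with the conv counts
reduced to `c(2, 2, 3, 2, 2)` in the standard configuration (the source
architecture "limits" the fourth and fifth blocks without stating exact
counts; the count is configurable). After every block a 1x1 convolution
projects to a common channel width, each projected map is brought to a
common `fusion_size` spatial size — transposed convolution (kernel =
stride = integer factor) for smaller maps, a strided 1x1 for larger ones
— and the five same-size maps are concatenated along channels. A head of
two fully-connected layers with dropout 0.5 each and a softmax over
{interictal, preictal} closes the graph. Probability ties resolve to
interictal, the non-alarm class.

Everything below the R API is compiled code (im2col + GEMM convolutions,
explicit backprop, Adam). Training runs in single precision for memory
bandwidth; gradients are verified against central finite differences in a
double-precision instantiation of the same templated engine. The network
owns a private `mt19937` stream for initialization, shuffling and
dropout, so a seed fully determines a CPU training run — asserted by a
bit-identical-loss test.

Defaults the source work does not state, fixed here once: Adam with
learning rate 1e-4, batch 32, cross-entropy; fusion size 32 (block 2's
resolution — block 1 reaches it by a stride-2 1x1, blocks 3-5 by x2/x4/x8
transposed convolutions); head widths 256/64. Epochs default to 50.

Evaluation is stratified 5-fold cross-validation per patient (one model
per patient — seizure signatures are patient-specific), with accuracy,
sensitivity (recall over preictal), specificity, and false predictions
per interictal hour: raw false-positive segments divided by evaluated
interictal hours, with no alarm clustering or refractory period, because
the reference evaluation describes no post-processing. A refractory
window can be configured but defaults to off. Undefined metrics propagate
as `NaN` and are excluded from averages with a logged count. Summary
"Average" rows are unweighted means over patients.

## The synthetic world

`generate_record()` states a world, not a tunable benchmark: per-channel
$1/f^\beta$ Gaussian background ($\beta = 1$, RMS 30 uV — a realistic
scalp-EEG amplitude scale), plus a 3 Hz sinusoid at `amplitude_ratio`
times the background RMS during the 15 minutes before each onset (random
per-channel phase), plus a high-amplitude 12-to-4 Hz sweep during the
seizure itself. The preictal signature is additive and band-limited below
50 Hz precisely so that the production band-limit retains it: a green
end-to-end test certifies the plumbing from EDF bytes to fold metrics,
*not* that real preictal EEG looks like a 3 Hz tone. Real preictal
signatures are weaker, non-stationary and patient-specific; that gap is
exactly why the published clinical results are not reproduced at desk
scale.

`generate_dataset()` writes, per patient, an interictal-only EDF record
at hour 0 and a second record six hours later holding 300 s of preictal
run-up, a 20 s seizure and a short tail — so the 4-hour margin is
exercised across record boundaries through real EDF headers. Per-patient
seeds derive from the master seed.

The desk-scale evaluation profile (`model_config(profile = "reduced")`)
uses 3 synthetic channels, block widths 4/8/8/8/8, projection 16, fusion
16, head 64/32, 10 epochs, learning rate 1e-3. These were fixed once from
a single-CPU compute budget (the full-width network exists for real
data); on the stated synthetic world this profile separates the classes
essentially perfectly, and a scrambled-label control confirms the
pipeline leaks nothing (held-out accuracy stays at chance).

## Numerical choices and degenerate inputs

* EDF is written with 1 s records, symmetric per-channel physical ranges
  and digital range -32767..32767, so amplitudes round-trip within one
  quantization step; annotation-only channels are dropped on read;
  duplicate labels keep the first occurrence (the CHB-MIT convention for
  its repeated `T8-P8`).
* Channel names canonicalize by uppercasing, whitespace squeezing and
  stripping trailing `-0`/`-REF`, because file labels vary.
* A segment window longer than every usable interval yields an empty list
  with a warning, not an error; a missing class at balancing is an error
  naming the class.
* `fmax` above Nyquist, non-integral sample counts, NaNs in signals, and
  single-class training sets are all hard errors.
* Bilinear resize of a 1-pixel dimension falls back to replication.

## Known limitations

* No artifact rejection, re-referencing, or BIDS support; EDF only.
* No inverse/second-order synchrosqueezing; no STFT-based variants.
* Segment-wise FPR/h (no alarm clustering) is the strictest reading; with
  clustering the reported rates would only drop.
* The published per-patient results on CHB-MIT/ZJU4H require the external
  datasets and GPU-scale training; the package bundles those printed
  per-patient cells (see `reference_results()`) only to validate its
  aggregation arithmetic. Four of the published Average cells differ from
  the mean of their own printed columns by more than print-rounding can
  explain; the aggregation test documents this rather than hiding it.
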