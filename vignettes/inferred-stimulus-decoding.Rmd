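---
title: "Behaviorally informed stimulus reconstruction: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviorally informed stimulus reconstruction: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inferTRF)
```

## The problem

In two-talker ("cocktail party") listening experiments, a participant is
asked to attend one speech stream (the *target*) and ignore a competing
stream (the *masker*) while EEG is recorded. Backward temporal response
functions (TRFs) — linear *decoders* mapping multichannel EEG onto the speech
envelope — quantify how strongly the brain tracks the attended stream: the
Pearson correlation $r$ between the decoded and the true envelope of a
held-out trial is the *reconstruction accuracy*.

Standard analyses train these decoders under the assumption that attention
stayed on the target for the whole trial. That assumption fails exactly when
the task is hard: when the two voices are similar, attention occasionally
slips to the masker, and the decoder is then trained on mislabelled epochs.
This package implements the alternative: use the participant's keyword-recall
responses to build an *inferred* attended stimulus $\hat{x}(t)$ — a
behaviorally informed estimate of what was actually attended — and train on
that instead. Everything needed to exercise the pipeline without recorded
data is generated by the synthetic module.

## The inferred-stimulus model

Each trial provides three *response windows*. Window $i$ spans the union of
the $i$-th target keyword and the $i$-th masker keyword (it starts at the
onset of whichever keyword comes first and ends at the offset of whichever
ends last) and carries a ternary response $R_i$: the participant recalled the
target keyword, the masker keyword, or an extraneous keyword that occurred in
neither stream. The inferred stimulus is piecewise:

$$\hat{x}(t) = \begin{cases}
 f(x_T, x_M, R_i)(t) & t \in \text{window } i\\
 g(x_T, x_M)(t) & \text{otherwise,}
\end{cases}
\qquad
f = \begin{cases}
 x_T & R_i = \text{target}\\
 x_M & R_i = \text{masker}\\
 h(x_T, x_M) & R_i = \text{extraneous.}
\end{cases}$$

Three modelling choices parameterize the construction
(`inference_config()`):

* **Scope** ($g$) — what to assume outside the windows. `"segments"` divides
  the trial into three segments cut halfway between consecutive windows and
  lets each window's source fill its segment; `"target_windows"` confines the
  response's influence to the window itself and assumes the target
  everywhere else.
* **Filler** ($h$) — the attended-signal stand-in for extraneous responses:
  the target+masker `"mixture"` ($h_+ = x_T + x_M$), the `"target"`, the
  `"masker"`, seeded Gaussian `"noise"`, or an unrelated `"other_speech"`
  stream; the last two are scaled to the target's RMS level.
* **Switch duration** — attention does not move instantaneously, so every
  change of source is a complementary raised-cosine crossfade (1, 2, or 3 s
  in the grid) centered on the boundary.

Internally the selection is realized as a partition of unity: per-sample
weights $w_T, w_M, w_F \in [0,1]$ with $w_T + w_M + w_F = 1$ everywhere
(`attention_weights()`), and $\hat{x} = w_T x_T + w_M x_M + w_F h$. This
makes two properties structural rather than incidental: weights always sum
to one (the crossfades are complementary by construction), and when a single
source has unit weight everywhere — in particular when all three responses
are "target" under the target-windows scope — $\hat{x}$ is returned
bit-identical to $x_T$, so the behavioral decoder *exactly* coincides with
the assume-target decoder in the error-free case.

The default configuration (`target_windows`, `mixture`, 2 s) is the one that
reconstructs best; "behavioral decoder" in this package always refers to it.

### Decisions where the construction was genuinely open

* **Crossfade placement.** Ramps are centered on each source-change boundary
  (window edge or segment cut point). Centering is symmetric — the outgoing
  and incoming sources each hold weight exactly 0.5 at the boundary instant.
* **Ramps at segment joins.** Under the segments scope we crossfade at
  segment cut points exactly as at window edges; switching instantaneously
  there would contradict the finite-switch-speed premise.
* **Close boundaries.** If two boundaries are nearer than the switch
  duration, each ramp is compressed to the midpoint of the gap (still a
  raised cosine, so the weights remain complementary) and a warning is
  issued once. Windows shorter than the ramp therefore keep a
  single-instant plateau rather than being skipped.
* **Trial edges.** No ramp at $t = 0$ or trial end; the boundary source
  holds its plateau to the edge.
* **Extraneous granularity.** An extraneous response replaces the whole
  union window with filler; responses are not subdivided within a window.
* **Construction domain.** The reference path builds $\hat{x}$ from
  waveforms and then extracts its envelope. A fast path mixes the two
  stream *envelopes* directly with the same weights; the two agree to
  $r \ge 0.95$ on modulated-noise sources at trial scale (tested), the
  residual coming from the sub-additivity of envelope extraction
  ($|x_T + x_M|^{0.6} \ne |x_T|^{0.6} + |x_M|^{0.6}$) inside mixture-filled
  windows and crossfade regions. Simulation studies use the fast path.

## Envelope extraction and EEG preprocessing

The speech envelope is extracted with a 28-band gammatone filterbank
(4th-order Slaney-style IIR), center frequencies 50–5000 Hz equally spaced
on the ERB$_N$ scale $E(f) = 21.4\,\log_{10}(0.00437 f + 1)$; each band is
full-wave rectified and compressed with exponent 0.6 (Stevens-type loudness
growth), bands are averaged, and the result is brought to the 64 Hz model
rate and low-pass filtered below 8 Hz. EEG is band-pass filtered 2–8 Hz
(zero-phase) and downsampled to 64 Hz. All trial signals share a 64 Hz grid
with sample $k$ covering $[k/64, (k+1)/64)$ s from trial onset.

Numerical choices:

* **Zero-phase (forward–backward) Butterworth filters, order 4 each way.**
  Zero phase matters because any filter-induced lag would bias the TRF lag
  axis.
* **Two-stage anti-aliased downsampling.** A direct low-order IIR at 8 Hz
  cutoff on 44.1 kHz audio has poles too close to the unit circle for double
  precision. Signals are therefore first reduced by *uniform* bin averaging
  (integer decimation factor, so the boxcar is time-invariant; uneven bins
  would modulate out-of-band energy into the passband), filtered at the
  intermediate rate (~256 Hz), and interpolated onto the 64 Hz grid. The
  final sub-8 Hz low-pass runs at the model rate, where the design is
  well-conditioned. Measured passband behavior: 5 Hz gain within 2% of
  unity, 50 Hz attenuated by > 100 dB, DC rejected.
* **No clipping of small negative envelope values** after filtering; Pearson
  correlation is shift- and scale-invariant, so clipping would only
  discard information about filter ringing.

## Backward TRF estimation

The decoder weights solve the regularized normal equations
$d = (R R^\top + \lambda I)^{-1} R S^\top$, where $R$ stacks every channel
at every lag in $-900 \ldots 0$ ms (58 lags in single-sample steps of
15.625 ms at 64 Hz; the envelope precedes the EEG it predicts) and $S$ is
the training envelope zero-padded by 57 samples to match the lagged design.
Choices:

* **Lag rounding.** $-900$ ms at 64 Hz is $-57.6$ samples; the integer grid
  $-57 \ldots 0$ (58 lags) is used.
* **Scaling.** EEG channels are standardized and envelopes mean-centered per
  trial before fitting, so the fixed $\lambda = 10^{1/2}$ is meaningful
  across simulated signal scales. (Standardization is switchable; an
  explicit $\lambda$ can be passed everywhere.)
* **Exactness.** The solver is the direct Cholesky solution of the normal
  equations; when $T < NL$ it uses the algebraically identical dual form
  $R (R^\top R + \lambda I)^{-1} S^\top$. At $\lambda = 0$ with a singular
  Gram matrix it falls back to the SVD pseudo-inverse with a warning.
* **Evaluation.** Each held-out trial is reconstructed with the unweighted
  mean of the other trials' decoders, and $r$ is always computed against the
  trial's *original target* envelope over the full padded support, whichever
  envelope was used for training — this keeps the behavioral and
  assume-target decoders directly comparable, and padding affects both
  identically. Group statistics operate on Fisher-transformed values
  ($z = \operatorname{atanh} r$, variance-stabilizing); mean $z$ is always
  the mean of per-trial $z$, never $\operatorname{atanh}$ of a mean $r$.

## What the synthetic generator emulates

`gen_dataset()` produces subjects x conditions x trials with full seed
provenance (master seed, then per-subject, per-trial, and per-component
seeds, all below $2^{31}$), so any artifact is a pure function of
`(sim_config(), master_seed)`:

* **Streams**: nonnegative envelopes with dominant 2–8 Hz (syllabic-rate)
  modulation — sums of randomized modulation components, rectified; waveform
  mode modulates a noise carrier.
* **Keywords**: one target/masker pair per third of the trial, keyword
  lengths 0.3–0.8 s, paired-onset offsets up to 1 s, windows always ordered
  and disjoint.
* **Latent attention**: starts on the target; switches at Poisson times with
  a per-condition hazard, minimum dwell 1 s. The trial's attended signal is
  the trajectory-weighted mixture of the two envelopes with 250 ms
  raised-cosine transitions.
* **Responses**: the majority-attended source of each window, replaced by an
  extraneous response with a per-condition lapse probability. Lapses are
  response-level, not signal-level: a recall failure need not mean the
  listener heard nothing, and the behavioral data alone cannot distinguish
  divided attention from inattention.
* **EEG**: each channel convolves the attended signal with a forward TRF
  kernel — a gamma-windowed sinusoid peaking near 150 ms with 400 ms
  support — plus white Gaussian noise at a configurable signal-to-noise
  power ratio (default 0.05). Channels vary in gain, peak latency (20%
  jitter) and phase, as scalp TRFs do; without that variation the forward
  model would be rank-1 and the montage would carry no more information
  than a single electrode.

Default conditions (`sim_config()`): switch hazards 0, 0.02, 0.08 per
second with lapse probabilities 0.05, 0.10, 0.15 for the easy /
intermediate / difficult conditions — chosen so the simulated error rates
bracket the two-to-three-fold increase in recall errors that difficult
voice conditions produce, while the easy condition is nearly error-free.
The trial count (48 per condition) and durations (uniform 11–18 s) follow
the study design the simulator stands in for.

What the generator does **not** emulate: linguistic content (keywords are
pure timing), EEG artifacts (blinks, drift, line noise), per-band TRF
structure, voice morphing acoustics, or graded attention levels beyond the
binary trajectory plus response-level lapses. Passing tests on this
generator therefore validate the *pipeline* — estimator correctness,
identity properties, directional behavior — not the physiological effect
sizes of real recordings, whose accuracies are far lower than the clean
simulation's.

## Evaluation structure

`run_grid()` reproduces the strategy comparison — every condition x scope x
filler x switch-duration cell, leave-one-out accuracy trained on that
cell's inferred envelopes — and `contrast_decoders()` the headline
comparison of the behavioral decoder against the assume-target decoder,
as a paired test on per-subject mean $z$ with Benjamini–Hochberg adjustment
across conditions. Mixed-effects modelling of the original analysis is
deliberately out of scope: at simulation scale, paired tests on
subject-level means preserve the comparison structure, and the contribution
under test is the inferred-stimulus model, not the inference machinery
around it. When the two decoders receive bit-identical training envelopes
the paired difference is exactly zero and $p = 1$ by convention.

Typical directional outcomes on synthetic data (computed by the test suite,
not quoted from elsewhere): with no switches and no lapses the contrast is
exactly null; with hazard 0.08 and lapse 0.15 the behavioral decoder's mean
$z$ exceeds the target decoder's with a one-sided paired $p < 0.05$ for 20
subjects; the mixture filler outperforms the unrelated-speech filler under
heavy switching; accuracy decreases with the noise level.

## Problem sizes used in the shipped checks

The test suite runs the full pipeline at reduced scale: most module tests
use 2–8 subjects, 3–8 trials and 2–8 channels; the noiseless
forward-model-recovery check uses the full 31-channel montage with 20
twelve-second trials; the replicated behavioral-contrast check uses 20
subjects x 3 conditions x 16 trials at 8 channels over 10 master seeds.
These sizes were chosen as the smallest at which the corresponding
properties are stable, and are stated here so that readers know what the
shipped checks do and do not exercise.

## Known limitations

* The envelope-domain fast path treats envelope extraction as additive
  across sources; the documented $r \ge 0.95$ agreement bounds, but does not
  eliminate, the approximation.
* The 8 Hz low-pass is applied once during resampling and once at the model
  rate; pipelines that low-pass only after downsampling would see slightly
  more aliasing, so envelope values are not expected to be bit-compatible
  with other implementations (correlations are insensitive to this).
* `lambda` is fixed rather than tuned per subject; an adaptive grid can be
  emulated by calling `loo_reconstruction_accuracy()` over a
  `10^seq(-3, 5)` grid, but no tuning loop ships in the package.
* The minimum-dwell rule slightly thins the nominal Poisson switch rate
  (about 4% of candidate switches are dropped at one switch per second);
  the Monte-Carlo calibration test accounts for this.
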