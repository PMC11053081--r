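---
title: "Decoding pipeline methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pipeline methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecogspeech)
```

## The problem

People who lose the ability to speak intelligibly — for example through
amyotrophic lateral sclerosis — may retain the cortical activity that drives
speech. A speech-synthesis brain-computer interface records
electrocorticographic (ECoG) signals from speech-motor cortex while the user
speaks (or attempts to), detects when speech is being produced, and converts
the neural activity of each utterance back into an acoustic waveform that is
played back as delayed auditory feedback.

`ecogspeech` implements this pipeline end to end as trainable, testable R
code: a synthetic-data generator standing in for patient recordings, causal
broadband high-gamma feature extraction, a recurrent neural voice-activity
detector (nVAD), a bidirectional recurrent decoder into compact acoustic
features, a deterministic vocoder, a packetised streaming replay engine, and
the accompanying analyses (gradient saliency, acoustic-contamination
auditing, evaluation metrics).

## Signal model and feature extraction

Neural input is a 1000 Hz multichannel recording on up to two 8 x 8
electrode grids. Features are broadband high-gamma log powers:

1. **Common-average reference** per 64-contact grid, excluding channels
   flagged as bad (which pass through untouched).
2. **Causal IIR filtering**: an order-8 Butterworth band-pass 70-170 Hz
   followed by an order-8 Butterworth band-stop 118-122 Hz that attenuates
   the first line-noise harmonic. Both filters run forward-only in training
   and replay, because a causal online system cannot use zero-phase
   filtering. The band-stop is realised as a single order-8 band-stop; a
   cascade of narrower notches would also satisfy the published description
   and can be substituted behind `highgamma_filter()`.
3. **Log-power framing** on a 50 ms window advanced by 10 ms: frame *t*
   (0-based) covers samples `[10t, 10t + 50)` ms, left-aligned and
   half-open, giving `floor((n - window)/shift) + 1` frames. The additive
   floor inside the logarithm is `1e-12` (relative to the microvolt scale);
   it only matters for digitally silent channels.
4. **Normalisation** by day-specific per-channel mean and standard
   deviation accumulated over a syllable-repetition baseline task.

The two causal filters delay the neural features slightly; the paired audio
is compensated by a fixed 16 ms lead (`pad_audio()`, configurable).

Because an online system must produce identical features from 40 ms
packets, `highgamma_filter()` carries its taps across calls; packetised
filtering, framing and normalisation reproduce batch processing *bit for
bit*, and the test suite asserts the end-to-end replay difference is below
1e-9.

**Channel selection.** Speech-responsive channels are those whose mean
normalised response at any within-trial time point differs from zero under
a two-sided criterion with Student-t critical values, Bonferroni-corrected
across *time points x channels*. The published description corrects across
time points only; we additionally correct across channels so that the
family-wise probability of admitting any spurious channel is `alpha`
(0.05). With per-channel correction only, roughly `0.05 x n_channels` false
channels would be expected per run, which contradicts the intended
behaviour of selection on a quiet montage. The statistic itself (a
one-sample test of the trial-mean response) is our concrete choice; the
source text names only the confidence criterion.

## The three recurrent networks

All recurrent machinery is implemented in the package itself on BLAS-backed
matrix operations (`rnn_model()`, `rnn_forward()`, `rnn_backward()`), with
gradients verified against central finite differences in the tests. Each
LSTM layer carries two bias vectors (input-hidden and hidden-hidden), so a
layer with input width *i* and *h* units has `4h(i + h) + 8h` parameters.

* **nVAD** (`nvad_model()`): two stacked unidirectional LSTM layers of 150
  units over the 64 selected channels, with a 2-unit linear head (speech /
  non-speech logits). 311,102 trainable weights. Trained with truncated
  backpropagation through time — the unfolding window is `k2 = 100` frames
  (1 s) repeated every `k1 = 50` frames (500 ms), with the recurrent state
  detached between updates — cross-entropy loss, 50% inter-layer dropout,
  RMSprop-adapted SGD at an initial learning rate of 0.001, and early
  stopping that snapshots the weights only when held-out frame-wise
  accuracy strictly improves. Class imbalance is left to the unweighted
  cross-entropy.
* **Decoder** (`decoder_model()`): two stacked bidirectional LSTM layers
  with 100 units per direction and a 20-unit linear regression head;
  378,420 trainable weights. The hidden size is not printed in the source
  description; 100 per direction with depth 2 is the unique round
  configuration that reproduces the printed total with 64 inputs and 20
  outputs under the dual-bias convention
  (`2·[4·100·(64+100)+800] + 2·[4·100·(200+100)+800] + 200·20+20 = 378,420`).
  Training uses standard (full) BPTT per buffered segment, mean squared
  error on per-feature standardised targets (the standardisation is stored
  with the model and inverted at decode time), dropout 0.5, RMSprop, and
  early stopping on validation loss.
* **Vocoder interface**: 18 Bark-scale cepstral coefficients plus pitch
  period and pitch correlation per 10 ms frame (matching the feature
  convention of LPCNet-family neural vocoders).

Streaming prediction (`stream_predict()`) threads the recurrent state frame
by frame and uses arithmetic identical to the batched forward pass, so the
predicted speech onset (PSO) — the first frame with a positive raw
prediction — is strictly causal.

**Temporal-context correction.** The raw frame labels pass through a causal
smoother that the online system needs to avoid fragmented segments. The
published description names the goal but not the mechanism; we use a causal
majority vote over the trailing `W = 7` available frames, a hangover of
`H = 3` consecutive non-speech votes before a speech run may close, and a
refractory hold of `W` frames after every state change. The refractory rule
makes "at most one state change per W-frame window" true by construction,
which the tests verify exhaustively over all 1024 length-10 streams.
Detected runs are buffered with 0.5 s (50 frames) of context on *both*
sides — whether the original system padded both sides or only the onset is
not stated; both-sides is the default and is configurable.

## The codec and vocoder

LPCNet — a *trained* neural vocoder with pretrained weights — is
deliberately replaced by a deterministic classical codec with the identical
18 + 2 per-frame interface, so the whole pipeline is self-contained and
reproducible; a neural vocoder can be swapped in behind
`encode_audio()` / `synthesize_audio()`.

* **Encoder**: 50 ms Hann STFT at 10 ms shift (the same frame grid as the
  neural features, so frame counts match by construction), 18 triangular
  Bark-spaced bands over 0-8 kHz, natural-log energies, orthonormal DCT.
  Pitch is the normalised autocorrelation peak searched over 50-400 Hz;
  frames with pitch correlation above 0.3 are treated as voiced.
* **Synthesiser**: per-frame spectral envelope reconstructed from the
  cepstrum, excited by a pulse train at the (median-smoothed) pitch period
  mixed with seeded Gaussian noise; voiced frames keep only a 15% noise
  floor so sustained vowels synthesise cleanly. Each frame is rescaled so
  its realised Bark-band energy matches the encoded target (the gain track
  is median-smoothed to suppress realisation jitter), then overlap-added.
  Output is deterministic given features and seed, and loudness is
  monotone in cepstral coefficient 0.

## The synthetic-data generator

The generator (`generate_block()`, `generate_baseline_block()`) defines the
study conditions under which everything is trained and tested:

* **Task design**: a closed vocabulary of six command words (*Left, Right,
  Up, Down, Enter, Back*), ten repetitions per block in seeded
  pseudo-random order, 2 s stimulus + 3 s intertrial interval, a silence
  trial every 10th trial (the source text says only "occasionally"; the
  frequency is configurable). The baseline task presents 12
  consonant-vowel syllables five times each, 1 s stimulus, trial durations
  uniform on the 80 ms lattice from 2.5 to 3.5 s.
* **Neural background**: independent 1/f (pink) noise per channel (10 uV)
  plus a shared per-grid common-mode component (50%), so common-average
  referencing is non-trivial. No noise model is published; this is chosen
  for realism.
* **Word responses**: each word bursts on a small set of shared plus
  word-specific channels inside the speech-responsive half of the montage.
  The burst is band-limited 70-170 Hz noise under a raised-cosine envelope,
  with amplitude three baseline in-band standard deviations, beginning
  0.15-0.35 s (word-specific) before voice onset — neural activation
  leading the acoustics as in speech planning.
* **Audio**: additive-harmonic three-formant synthesis with word-specific
  formant trajectories and fundamentals, 50 ms onset/offset ramps, plus 5%
  broadband aspiration so words carry energy across the full 0-8 kHz
  evaluation range; word durations are drawn per trial around nominal
  values of 0.85-1.35 s (slow, effortful speech). A low microphone noise
  floor keeps voice-activity thresholds well defined.
* **Contamination** (`inject_contamination()`): the session's own audio,
  anti-aliased and decimated to 1000 Hz, added to one chosen channel at a
  chosen RMS amplitude — a forward simulation of acoustic leakage used to
  exercise the audit.

What the generator does *not* emulate: realistic cortical topography,
articulatory kinematics, trial-to-trial neural variability beyond amplitude
noise, session-to-session drift, or disease progression. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that it
recovers structure the generator genuinely contains; they do not establish
performance on patient recordings.

## Analyses

* **Saliency** (`relevance_scores()`): at each trial's PSO, gradients of
  the pre-softmax speech-class score (the published description says "class
  scores"; the pre-softmax logit is our choice) with respect to every input
  frame at or before the PSO, computed by BPTT. Relevance is the absolute
  partial derivative; each electrode is summarised by its maximum over time
  and the time of that maximum.
* **Contamination audit** (`contamination_audit()`): neural and audio
  spectrograms on a 200 ms window advanced by 50 ms, restricted to the
  5 Hz-spaced bins inside 70-170 Hz (19 bins; the cited method leaves
  binning open, and the audit needs finer frequency resolution than the
  50 ms feature frames — with only a handful of matching bins the
  permutation null is too coarse to separate frequency-specific leakage
  from broadband speech-locked responses).
  The contamination index is the mean correlation of matching frequencies;
  its null distribution comes from 1000 random row/column permutations of
  the bin-correlation matrix, and the criterion is a t-score against that
  null at the Bonferroni level `0.05 / (n_bins x n_channels)`. Repair
  replaces a flagged channel by the mean of its 8-connected grid
  neighbours, excluding bad channels and off-grid positions.
* **Metrics**: `mel_correlation()` (50 ms/10 ms Hann STFT, 80 triangular
  mel bins, natural-log Gaussianisation, per-bin Pearson correlation
  averaged over bins, zero-variance bins excluded and counted) and
  `vad_levenshtein_ms()` (unit-cost edit distance between binary voice
  labels, times 10 ms).

## Problem sizes, defaults and numerical choices

The package's reference corpus — used by the acceptance checks — is one
baseline block and four word blocks (60 word trials each) on the
128-channel montage, of which 64 channels are selected. The nVAD trains on
two blocks for two epochs (its accuracy saturates within the first epoch at
these noise levels); the decoder trains on three blocks (180 segments) for
twelve epochs; the fourth block is held out for both. These sizes are the
package's chosen desk-scale operating point; all of them are arguments.

Other defaults worth knowing: log-power floor `1e-12`; energy-VAD threshold
12 dB above the 10th-percentile noise floor with a 5-frame hangover;
correction `W = 7`, `H = 3`; context 50 frames; packet size 40 ms; vocoder
voiced threshold 0.3; permutations 1000; selection alpha 0.05. Ties in the
majority vote cannot occur (`W` odd over full windows; partial startup
windows break ties toward non-speech via the strict inequality).

## Known limitations

* Decoded speech is evaluated per word over the voiced span (time-aligned,
  as in the original per-sample comparisons). At these study conditions the
  mel-correlation metric has a *realisation ceiling*: re-synthesising the
  correct word from perfect features scores about 0.87, and two independent
  renditions of the same word about 0.90, while acoustically different
  words still correlate at about 0.43-0.45 because the metric responds
  strongly to shared spectral envelope structure. A label-shuffled control
  decoder therefore sits near 0.43 while the true decoder reaches about
  0.70 — a clear but bounded separation (about 0.28). The per-feature
  decoded tracks correlate with their targets at 0.56-0.99, i.e. the
  decoder is near the information ceiling of the generator; the residual is
  vocoder realisation noise, not decoding error.
* The decoder cannot generalise to unseen words: like the original system,
  it learns whole-word neural-to-acoustic trajectories.
* The bidirectional decoder requires finalized segments, so acoustic
  feedback is inherently delayed until after each utterance — a property
  the replay engine asserts (`emit_frame >= offset_frame`) rather than
  hides.
* The streaming engine preserves the packet/pub-sub/ring-buffer contract
  in-process; it does not model transport latency, multi-process shared
  memory, or audio hardware.
* Segments whose context windows overlap the following trial are emitted
  with overlapping context, without deduplication.
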