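# ecogspeech

Closed-loop synthesis of speech from electrocorticographic (ECoG) signals,
as a self-contained, trainable R package.

Speech-synthesis brain-computer interfaces record neural activity from
speech-motor cortex while a user speaks, detect each utterance, and render
it back into audible speech. This package re-implements such a pipeline end
to end for desk-scale research and teaching: every stage is ordinary R
code, every model is trained from scratch on synthetic paired
neural/audio/trial-log sessions generated by the package itself, and the
online (streaming) and offline (batch) paths are guaranteed to agree.

The pipeline is three recurrent networks around a signal-processing core:

1. **High-gamma features.** 1000 Hz ECoG on two 8 x 8 grids is re-referenced
   per grid (CAR), filtered causally with an order-8 Butterworth band-pass
   (70–170 Hz) plus an order-8 band-stop (118–122 Hz), and reduced to
   log-power frames (50 ms window, 10 ms shift), normalised by
   syllable-repetition baseline statistics; speech-responsive channels are
   selected by a Bonferroni-corrected response criterion.
2. **nVAD.** A unidirectional detector — two LSTM layers of 150 units and a
   2-unit linear head (311,102 weights) — classifies each 10 ms frame as
   speech or non-speech, trained with truncated BPTT (k1 = 50, k2 = 100),
   cross-entropy, dropout 0.5, RMSprop (lr 0.001) and early stopping on
   held-out frame accuracy. A causal majority-vote correction smooths the
   labels and each speech run is buffered with 0.5 s of context.
3. **Decoder + vocoder.** A bidirectional regressor — two BiLSTM layers of
   100 units per direction with a 20-unit linear head (378,420 weights) —
   maps each buffered segment to 18 Bark-scale cepstral coefficients and 2
   pitch parameters per frame; a deterministic vocoder renders the waveform,
   which the replay engine emits as delayed auditory feedback.

Analyses include BPTT gradient saliency at predicted speech onsets,
Roussel-style acoustic-contamination auditing with permutation statistics
and 8-neighbour channel repair, 80-bin mel-spectral correlation, and a
frame-level Levenshtein timing metric.

## Worked example

```r
library(ecogspeech)

# the two networks at their published sizes
nvad_model(input_size = 64)
#> <rnn_model> 2 x LSTM(150) + linear(2) on 64 inputs: 311,102 parameters
decoder_model(input_size = 64)
#> <rnn_model> 2 x BiLSTM(100) + linear(20) on 64 inputs: 378,420 parameters

# a paired synthetic session: 6 words x 2 repetitions on a 16-channel grid
vocab <- lapply(default_vocabulary(), function(t) {
  t$active_channels <- t$active_channels[t$active_channels <= 12]; t
})
session  <- generate_block(vocab, n_reps = 2, seed = 11,
                           noise_params = list(n_channels = 16))
session
#> <synthetic_session> block 'block11': 14 trials (12 words), 71.0 s, seed 11

baseline <- generate_baseline_block(3, 2, seed = 12,
                                    noise_params = list(n_channels = 16),
                                    responsive_channels = 1:16)
stats  <- compute_baseline_stats(extract_highgamma(baseline$ecog))
frames <- extract_highgamma(session$ecog, channels = 1:16, stats = stats)
frames
#> <high_gamma_frames> 7096 frames x 16 channels (normalized)

# train the detector on the session's ground-truth voice labels
labels <- session$ground_truth_vad[seq_len(nrow(frames$values))]
nv <- train_nvad(frames$values, labels, frames$values, labels,
                 nvad_config(epochs = 2, hidden_size = 32), seed = 7)
attr(nv, "val_accuracy")
#> [1] 0.986894

# replay the recording through the 40 ms-packet streaming graph
dec <- decoder_model(16, 12, seed = 6)   # untrained stand-in decoder
attr(dec, "feat_mean") <- c(rep(0, 18), 100, 0.5)
attr(dec, "feat_sd")  <- rep(1, 20)
run_replay(session$ecog, nv, dec, stats, channels = 1:16)
#> <session_result> 1775 packets, 7096 frames, 12 synthesized segments
```

The last line is the closed-loop engine in miniature: 71 s of 16-channel
ECoG chopped into 40 ms packets, filtered and framed with carried state,
classified frame by frame, segmented with 0.5 s context, decoded, vocoded,
and written into a 16 kHz feedback track — one synthesized segment per
spoken word, each emitted only after the word ends. With the trained
decoder of the test corpus the segments become intelligible renditions of
the six command words.

A command-line wrapper over the same functions is installed as
`exec/ecogspeech` (subcommands `simulate`, `extract-features`,
`train-nvad`, `train-decoder`, `replay`).

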