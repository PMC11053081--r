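# Shared fixtures, built once per test run and memoised.
#
# Small sessions use a 16-channel montage with the vocabulary's active
# channels clipped to the montage, which keeps generation and feature
# extraction fast while preserving the full statistical structure.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

small_vocabulary <- function(n_channels = 16, gain = 3.0) {
  lapply(default_vocabulary(gain), function(t) {
    t$active_channels <- t$active_channels[t$active_channels <= n_channels - 4]
    t
  })
}

small_session <- function() {
  memo("small_session", function() {
    generate_block(small_vocabulary(), n_reps = 1, seed = 11,
                   noise_params = list(n_channels = 16))
  })
}

small_stats <- function() {
  memo("small_stats", function() {
    bl <- generate_baseline_block(3, 2, seed = 12,
                                  noise_params = list(n_channels = 16),
                                  responsive_channels = 1:16)
    compute_baseline_stats(extract_highgamma(bl$ecog))
  })
}

small_features <- function() {
  memo("small_features", function() {
    extract_highgamma(small_session()$ecog, channels = 1:16,
                      stats = small_stats())
  })
}

# ground-truth VAD labels truncated to the feature frame count
aligned_labels <- function(session, frames) {
  session$ground_truth_vad[seq_len(nrow(frames$values))]
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}
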