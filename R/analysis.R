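# Interpretation and evaluation analyses.
#
# Saliency: gradients of the speech-class score at the predicted speech
# onset (PSO) with respect to all preceding input frames, via
# backpropagation through time; |R| relevance per channel and time.
# Contamination: Roussel-style audit correlating neural and acoustic
# spectrograms at matching frequencies, with a permutation null and
# Bonferroni criterion, plus 8-neighbour channel repair. Metrics:
# mel-spectral Pearson correlation (80 bins) and the frame-level
# Levenshtein distance between voice-activity sequences.

#' Predicted speech onset
#'
#' The first frame at which the detector makes a positive raw prediction,
#' running frame-by-frame from the supplied state. Causal: frames after the
#' PSO cannot change it.
#'
#' @param model nVAD `rnn_model`
#' @param frames frames-x-channels matrix (e.g. one trial's frames)
#' @param state optional initial recurrent state
#' @return 1-based frame index, or `NA_integer_` if no speech is predicted
#' @export
find_pso <- function(model, frames, state = NULL) {
  for (t in seq_len(nrow(frames))) {
    r <- rnn_step(model, frames[t, ], state)
    state <- r$state
    if (r$logits[2] > r$logits[1]) return(t)
  }
  NA_integer_
}

#' Relevance scores at a predicted speech onset
#'
#' Backpropagation through time of the pre-softmax speech-class score at
#' the PSO with respect to every input frame at or before it. The relevance
#' is `|dscore/dx(channel, t)|`; the per-electrode summary is the maximum
#' over time and the time at which it occurs.
#'
#' @param model nVAD `rnn_model`
#' @param frames frames-x-channels matrix for the trial
#' @param pso PSO frame index (from [find_pso()]); must not be `NA`
#' @return object of class `saliency_map`: `relevance` (pso x channels,
#'   non-negative), `electrode_max`, `electrode_argmax` (frame of the
#'   maximum, <= pso), `pso_frame`
#' @export
relevance_scores <- function(model, frames, pso) {
  if (is.na(pso) || pso < 1) stop("relevance requires a defined PSO")
  X <- frames[seq_len(pso), , drop = FALSE]
  fw <- rnn_forward(model, X, keep_cache = TRUE)
  dY <- lapply(seq_len(pso), function(t) matrix(0, 1, model$output_size))
  dY[[pso]][1, 2] <- 1
  bk <- rnn_backward(model, fw$cache, dY)
  rel <- abs(do.call(rbind, bk$dX))
  structure(list(relevance = rel,
                 electrode_max = apply(rel, 2, max),
                 electrode_argmax = apply(rel, 2, which.max),
                 pso_frame = pso),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> PSO at frame %d; top electrode %d (|R| = %.2e)\n",
              x$pso_frame, which.max(x$electrode_max),
              max(x$electrode_max)))
  invisible(x)
}

# Complex projection spectrogram: log power at the given frequencies.
# Returns frames x freqs.
band_spectrogram <- function(x, fs, freqs_hz, window_ms = 200,
                             shift_ms = 50) {
  idx <- frame_index_matrix(length(x), fs, shift_ms = shift_ms,
                            window_ms = window_ms)
  win <- ncol(idx)
  fm <- matrix(x[t(idx)], nrow = win)
  tt <- (seq_len(win) - 1) / fs
  basis <- exp(-2i * pi * outer(tt, freqs_hz))
  amp <- Mod(t(fm) %*% basis)          # frames x freqs
  log(amp^2 + 1e-12)
}

#' Audit neural channels for acoustic contamination
#'
#' For each channel, the neural spectrogram in the high-gamma range is
#' correlated with the audio spectrogram at matching frequency bins (5 Hz
#' spacing from a 200 ms window advanced by 50 ms; the audit uses its own
#' finer spectral grid than the 50 ms feature frames so that genuine
#' leakage produces frequency-specific matches). The contamination index is
#' the mean correlation of matching frequencies (the diagonal of the
#' channel's bin-correlation matrix); its null distribution is obtained by
#' randomly permuting the rows and columns of that matrix. The statistical
#' criterion is a t-score of the observed index against the permuted
#' indices at a Bonferroni-corrected level `alpha / (n_bins * n_channels)`.
#'
#' @param rec an [ecog_recording]
#' @param audio synchronized audio waveform
#' @param fs_audio audio sampling rate
#' @param n_perm number of row/column permutations (default 1000)
#' @param alpha family-wise significance level before Bonferroni division
#' @param band frequency range audited (default 70-170 Hz)
#' @param seed seed for the permutations
#' @return object of class `contamination_report`: data.frame `table` with
#'   per-channel `index`, `p`, `flagged`, plus `freqs_hz`, `alpha_bonf`
#' @export
contamination_audit <- function(rec, audio, fs_audio = FS_AUDIO,
                                n_perm = 1000, alpha = 0.05,
                                band = c(70, 170), seed = 1) {
  stopifnot(inherits(rec, "ecog_recording"))
  freqs <- seq(0, FS_NEURAL / 2, by = 5)
  freqs <- freqs[freqs > band[1] & freqs < band[2]]
  n_bins <- length(freqs)
  aud_spec <- band_spectrogram(audio, fs_audio, freqs)
  nf <- min(nrow(aud_spec),
            n_frames(nrow(rec$samples), FS_NEURAL, shift_ms = 50,
                     window_ms = 200))
  if (nf < 2) stop("need at least 2 shared frames for the audit")
  aud_spec <- aud_spec[seq_len(nf), , drop = FALSE]
  n_ch <- ncol(rec$samples)
  alpha_bonf <- alpha / (n_bins * n_ch)
  idx_obs <- numeric(n_ch); pvals <- numeric(n_ch)
  with_seed(seed, {
    perms_r <- replicate(n_perm, sample(n_bins))
    perms_c <- replicate(n_perm, sample(n_bins))
    for (ch in seq_len(n_ch)) {
      neu_spec <- band_spectrogram(rec$samples[, ch], FS_NEURAL,
                                   freqs)[seq_len(nf), , drop = FALSE]
      cm <- suppressWarnings(stats::cor(neu_spec, aud_spec))
      cm[!is.finite(cm)] <- 0
      idx_obs[ch] <- mean(diag(cm))
      null <- vapply(seq_len(n_perm), function(k) {
        mean(diag(cm[perms_r[, k], perms_c[, k], drop = FALSE]))
      }, 0)
      tval <- (idx_obs[ch] - mean(null)) / max(stats::sd(null), 1e-12)
      pvals[ch] <- stats::pt(tval, df = n_perm - 1, lower.tail = FALSE)
    }
  })
  structure(list(table = data.frame(channel = seq_len(n_ch),
                                    index = idx_obs, p = pvals,
                                    flagged = pvals <= alpha_bonf),
                 freqs_hz = freqs, alpha_bonf = alpha_bonf,
                 n_perm = n_perm),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  fl <- x$table$channel[x$table$flagged]
  cat(sprintf(
    "<contamination_report> %d channels x %d bins; flagged: %s\n",
    nrow(x$table), length(x$freqs_hz),
    if (length(fl)) paste(fl, collapse = ", ") else "none"))
  invisible(x)
}

#' Repair a contaminated channel from its grid neighbours
#'
#' Replaces the channel's high-gamma features by the per-frame mean of its
#' 8-connected neighbours on the electrode grid, excluding bad channels and
#' off-grid positions.
#'
#' @param frames a `high_gamma_frames` object carrying a grid map
#' @param channel channel id to repair
#' @param bad channel ids excluded from the neighbour average
#' @return frames with the channel's column replaced
#' @export
repair_channel <- function(frames, channel, bad = integer()) {
  stopifnot(inherits(frames, "high_gamma_frames"))
  gm <- frames$grid_map
  me <- gm[gm$channel == channel, ]
  if (nrow(me) != 1) stop("channel ", channel, " not in the grid map")
  nb <- gm$channel[gm$grid == me$grid &
                     abs(gm$row - me$row) <= 1 & abs(gm$col - me$col) <= 1 &
                     gm$channel != channel]
  nb <- setdiff(nb, bad)
  nb <- intersect(nb, frames$channel_ids)
  if (length(nb) == 0) stop("channel ", channel, " has no usable neighbours")
  cols <- match(nb, frames$channel_ids)
  tgt <- match(channel, frames$channel_ids)
  if (is.na(tgt)) stop("channel ", channel, " not among the frames' channels")
  frames$values[, tgt] <- rowMeans(frames$values[, cols, drop = FALSE])
  frames
}

# 80-band triangular mel filterbank over [0, fs/2].
mel_filterbank <- function(freqs, n_bands = 80) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  edges <- seq(0, mel(max(freqs)), length.out = n_bands + 2)
  mq <- mel(freqs)
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    fb[b, ] <- pmax(0, pmin((mq - edges[b]) / (edges[b + 1] - edges[b]),
                            (edges[b + 2] - mq) / (edges[b + 2] -
                                                     edges[b + 1])))
  }
  fb
}

#' Mel-spectral Pearson correlation between two waveforms
#'
#' Both waveforms are trimmed to their common length, transformed with a
#' 50 ms / 10 ms Hann STFT, reduced to 80 triangular mel bins, Gaussianised
#' with the natural logarithm, correlated per bin across time, and averaged
#' over bins. Bins with zero variance in either signal are excluded (the
#' count of used bins is attached as an attribute).
#'
#' @param orig,synth waveforms at the same sampling rate
#' @param fs sampling rate in Hz
#' @return mean Pearson correlation over mel bins, with attribute
#'   `n_bins_used`
#' @export
mel_correlation <- function(orig, synth, fs = FS_AUDIO) {
  n <- min(length(orig), length(synth))
  a <- log(mel_filterbank(attr(stft_mag(orig[seq_len(n)], fs, nfft = 1024),
                               "freqs")) %*%
             stft_mag(orig[seq_len(n)], fs, nfft = 1024)^2 + 1e-10)
  b <- log(mel_filterbank(attr(stft_mag(synth[seq_len(n)], fs, nfft = 1024),
                               "freqs")) %*%
             stft_mag(synth[seq_len(n)], fs, nfft = 1024)^2 + 1e-10)
  rs <- vapply(seq_len(nrow(a)), function(i) {
    if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) return(NA_real_)
    stats::cor(a[i, ], b[i, ])
  }, 0)
  out <- mean(rs, na.rm = TRUE)
  attr(out, "n_bins_used") <- sum(!is.na(rs))
  out
}

#' Frame-level Levenshtein distance between voice-activity sequences
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) between
#' two binary label sequences, expressed in milliseconds at the 10 ms frame
#' rate.
#'
#' @param a,b integer 0/1 vectors
#' @return distance in milliseconds
#' @export
vad_levenshtein_ms <- function(a, b) {
  n <- length(a); m <- length(b)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    ai <- a[i]
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ai != b[j]))
    }
    prev <- cur
  }
  prev[m + 1] * FRAME_SHIFT_MS
}
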