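# Broadband high-gamma feature extraction.
#
# Raw 1000 Hz ECoG is re-referenced per grid (CAR), filtered causally with two
# order-8 IIR Butterworth filters (70-170 Hz band-pass, then a 118-122 Hz
# band-stop attenuating the first line-noise harmonic), and reduced to
# logarithmic power frames on a 50 ms window / 10 ms shift grid. Frames are
# normalised by day-specific statistics from the syllable-repetition baseline
# task. Filtering is identical in batch and streaming modes: packetised
# application with carried filter state reproduces the one-shot result
# exactly.

the_filters <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        bp = signal::butter(4, c(70, 170) / (FS_NEURAL / 2), type = "pass"),
        bs = signal::butter(4, c(118, 122) / (FS_NEURAL / 2), type = "stop"))
    }
    cache
  }
})

#' Causal high-gamma band filter
#'
#' Forward-only application of an order-8 Butterworth band-pass (70-170 Hz)
#' followed by an order-8 Butterworth band-stop (118-122 Hz) at 1000 Hz.
#' Output length equals input length. When `state` is supplied (or
#' `return_state = TRUE`), the filter taps are carried across calls so that
#' packetised streaming application equals one-shot application exactly.
#'
#' @param x single-channel waveform at 1000 Hz (finite values)
#' @param state filter state from a previous call, or `NULL` for rest
#' @param return_state return `list(y, state)` instead of just `y`
#' @return filtered waveform, or `list(y, state)` if state is threaded
#' @export
highgamma_filter <- function(x, state = NULL, return_state = !is.null(state)) {
  if (any(!is.finite(x))) stop("non-finite values in input signal")
  force(return_state)
  flt <- the_filters()
  ord <- length(flt$bp$a) - 1L
  if (is.null(state)) {
    state <- list(x1 = numeric(ord), y1 = numeric(ord),
                  x2 = numeric(ord), y2 = numeric(ord))
  }
  y1 <- as.numeric(signal::filter(flt$bp$b, flt$bp$a, x,
                                  init.x = state$x1, init.y = state$y1))
  y2 <- as.numeric(signal::filter(flt$bs$b, flt$bs$a, y1,
                                  init.x = state$x2, init.y = state$y2))
  if (!return_state) return(y2)
  keep <- function(prev, new) {
    m <- length(new)
    if (m >= ord) utils::tail(new, ord) else c(utils::tail(prev, ord - m), new)
  }
  list(y = y2,
       state = list(x1 = keep(state$x1, x), y1 = keep(state$y1, y1),
                    x2 = keep(state$x2, y1), y2 = keep(state$y2, y2)))
}

#' Per-grid common-average reference
#'
#' Within each electrode grid, subtracts at every sample the mean of that
#' grid's good channels from each good channel. Bad channels are passed
#' through unchanged and excluded from the average.
#'
#' @param rec an [ecog_recording]
#' @return re-referenced [ecog_recording]
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  out <- rec$samples
  for (g in unique(rec$grid_map$grid)) {
    chans <- rec$grid_map$channel[rec$grid_map$grid == g]
    good <- setdiff(chans, rec$bad_channels)
    if (length(good) < 2) {
      stop("grid ", g, " has fewer than 2 good channels; cannot re-reference")
    }
    avg <- rowMeans(rec$samples[, good, drop = FALSE])
    out[, good] <- rec$samples[, good, drop = FALSE] - avg
  }
  rec$samples <- out
  rec
}

#' Log-power frames of a filtered single-channel waveform
#'
#' Frame `t` (0-based) is `log(mean(x[t*shift .. t*shift+window-1]^2) + eps)`
#' over a 50 ms window advanced by 10 ms.
#'
#' @param x filtered waveform at 1000 Hz, at least one window long
#' @param eps additive floor inside the logarithm (default 1e-12, i.e.
#'   1e-12 of a unit-microvolt full scale)
#' @return numeric vector of log-power frames
#' @export
log_power_frames <- function(x, eps = 1e-12) {
  idx <- frame_index_matrix(length(x), FS_NEURAL)
  if (nrow(idx) == 0) stop("input shorter than one 50 ms analysis window")
  fm <- matrix(x[t(idx)]^2, nrow = ncol(idx))
  log(colMeans(fm) + eps)
}

#' High-gamma log-power features of a recording
#'
#' Full batch feature extraction: optional per-grid CAR, causal high-gamma
#' filtering, 50 ms/10 ms log-power framing, and optional normalisation by
#' baseline statistics.
#'
#' @param rec an [ecog_recording]
#' @param channels channels to retain (default: all)
#' @param stats optional [compute_baseline_stats()] result for normalisation
#' @param car apply common-average referencing first (default TRUE)
#' @return an object of class `high_gamma_frames`: `values` (frames x
#'   channels), `channel_ids`, `frame_shift_ms`, `window_ms`, `normalized`,
#'   `grid_map`
#' @export
extract_highgamma <- function(rec, channels = NULL, stats = NULL, car = TRUE) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (car) rec <- common_average_reference(rec)
  if (is.null(channels)) channels <- seq_len(ncol(rec$samples))
  nf <- n_frames(nrow(rec$samples), FS_NEURAL)
  vals <- matrix(0, nf, length(channels))
  for (j in seq_along(channels)) {
    vals[, j] <- log_power_frames(highgamma_filter(rec$samples[, channels[j]]))
  }
  fr <- structure(list(values = vals, channel_ids = as.integer(channels),
                       frame_shift_ms = FRAME_SHIFT_MS,
                       window_ms = FRAME_WINDOW_MS, normalized = FALSE,
                       grid_map = rec$grid_map),
                  class = "high_gamma_frames")
  if (!is.null(stats)) fr <- normalize_frames(fr, stats) else fr
}

#' @export
print.high_gamma_frames <- function(x, ...) {
  cat(sprintf("<high_gamma_frames> %d frames x %d channels (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Channel-wise baseline statistics
#'
#' Mean and standard deviation per channel, accumulated over all frames of
#' the syllable-repetition baseline task, used for day-specific
#' normalisation.
#'
#' @param frames a `high_gamma_frames` object (unnormalised)
#' @param source_day identifier of the recording day
#' @return object of class `baseline_stats` with `mean`, `sd`,
#'   `channel_ids`, `source_day`
#' @export
compute_baseline_stats <- function(frames, source_day = "day1") {
  stopifnot(inherits(frames, "high_gamma_frames"))
  m <- colMeans(frames$values)
  s <- apply(frames$values, 2, stats::sd)
  if (any(s <= 0)) stop("zero standard deviation on a retained channel")
  structure(list(mean = m, sd = s, channel_ids = frames$channel_ids,
                 source_day = source_day),
            class = "baseline_stats")
}

#' Normalise high-gamma frames by baseline statistics
#'
#' @param frames a `high_gamma_frames` object
#' @param stats a `baseline_stats` object over the same channel set
#' @return frames with `(x - mean) / sd` applied per channel and the
#'   `normalized` flag set
#' @export
normalize_frames <- function(frames, stats) {
  stopifnot(inherits(frames, "high_gamma_frames"),
            inherits(stats, "baseline_stats"))
  if (!identical(frames$channel_ids, stats$channel_ids)) {
    stop("baseline statistics are for a different channel set")
  }
  if (any(stats$sd <= 0)) stop("zero standard deviation on a retained channel")
  frames$values <- sweep(sweep(frames$values, 2, stats$mean), 2, stats$sd, "/")
  frames$normalized <- TRUE
  frames
}

#' Select speech-responsive channels
#'
#' For every channel and every within-trial time point, the mean normalised
#' high-gamma response across trials is tested against zero (two-sided
#' one-sample criterion on the standardised mean, with Student-t critical
#' values at `n_trials - 1` degrees of freedom). A channel is selected if
#' any time point is significant at `alpha` after Bonferroni correction
#' across all tested time points and channels, so the family-wise error of
#' selecting any spurious channel is approximately `alpha`.
#'
#' @param task_frames normalised `high_gamma_frames` from the
#'   stimulus-repetition task
#' @param trial_log trial data.frame with a `stimulus_onset_s` column
#' @param alpha two-sided family-wise significance level (default 0.05)
#' @param epoch_s epoch window relative to stimulus onset, in seconds
#' @return sorted integer vector of selected channel ids
#' @export
select_channels <- function(task_frames, trial_log, alpha = 0.05,
                            epoch_s = c(0, 3.5)) {
  stopifnot(inherits(task_frames, "high_gamma_frames"))
  if (!task_frames$normalized) {
    stop("task frames must be normalised before channel selection")
  }
  if (nrow(trial_log) < 2) stop("channel selection requires at least 2 trials")
  tau <- seq(round(epoch_s[1] * 100), round(epoch_s[2] * 100) - 1)
  starts <- floor(trial_log$stimulus_onset_s * 100)
  nf <- nrow(task_frames$values)
  n_ch <- ncol(task_frames$values)
  n_tests <- length(tau) * n_ch
  idx <- outer(starts, tau, `+`) + 1L
  ok <- rowSums(idx > nf | idx < 1) == 0
  if (sum(ok) < 2) stop("channel selection requires at least 2 usable trials")
  crit <- stats::qt(1 - alpha / 2 / n_tests, df = sum(ok) - 1)
  selected <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    # trials x time points response matrix for this channel
    resp <- matrix(task_frames$values[idx[ok, ], ch], nrow = sum(ok))
    m <- colMeans(resp)
    se <- apply(resp, 2, stats::sd) / sqrt(nrow(resp))
    if (any(abs(m) / se > crit)) selected[ch] <- TRUE
  }
  sort(task_frames$channel_ids[selected])
}

#' Pad audio to compensate the neural filter delay
#'
#' The two causal IIR filters delay the neural features; the paired audio is
#' padded at its start by a fixed compensation constant so acoustic and
#' neural frames describe the same instant.
#'
#' @param x audio waveform
#' @param fs audio sampling rate
#' @param pad_ms padding in milliseconds (default 16)
#' @return padded waveform
#' @export
pad_audio <- function(x, fs = FS_AUDIO, pad_ms = 16) {
  c(numeric(round(fs * pad_ms / 1000)), x)
}
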