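# Synthetic paired ECoG + audio sessions.
#
# The generator emulates the statistical structure the decoding pipeline
# assumes: per-channel 1/f ("pink") neural background noise plus a shared
# common-mode component per grid, word-specific broadband high-gamma bursts on
# a subset of channels that lead the acoustic voice onset, formant-synthesised
# word audio at 16 kHz, a syllable-repetition baseline block for
# normalisation statistics, and optional controlled acoustic leakage into
# chosen neural channels.

#' Construct a word template
#'
#' A template describes one vocabulary word: its acoustics (formant
#' trajectories and fundamental frequency) and its neural signature (which
#' channels burst, how strongly, and how far the burst leads voice onset).
#'
#' @param label word label
#' @param duration_s nominal spoken duration in seconds (> 0); per-trial
#'   durations are jittered +/- 10 percent around this value
#' @param formants 2 x 3 matrix: rows are trajectory start/end, columns are
#'   the first three formant frequencies (Hz)
#' @param f0_hz fundamental frequency in Hz
#' @param active_channels integer channel indices carrying the high-gamma
#'   burst
#' @param lead_time_s seconds by which the neural burst precedes voice onset
#'   (in \[0, 0.5\])
#' @param gain burst amplitude as a multiple of the in-band noise standard
#'   deviation (dimensionless)
#' @return an object of class `word_template`
#' @export
word_template <- function(label, duration_s, formants, f0_hz,
                          active_channels, lead_time_s, gain = 3.0) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("invalid template '", label, "': duration_s must be a positive scalar")
  }
  if (lead_time_s < 0 || lead_time_s > 0.5) {
    stop("invalid template '", label, "': lead_time_s must lie in [0, 0.5]")
  }
  formants <- as.matrix(formants)
  if (!all(dim(formants) == c(2, 3))) {
    stop("formants must be a 2 x 3 matrix (start/end x F1..F3)")
  }
  if (gain < 0) stop("gain must be non-negative")
  structure(list(label = label, duration_s = duration_s, formants = formants,
                 f0_hz = f0_hz, active_channels = as.integer(active_channels),
                 lead_time_s = lead_time_s, gain = gain),
            class = "word_template")
}

#' Default six-word vocabulary
#'
#' The command vocabulary used throughout: "Left", "Right", "Up", "Down",
#' "Enter", "Back". Words share a small core of active channels (a common
#' speech-motor population) and additionally recruit word-specific channels,
#' all within the speech-responsive set. Burst lead times are word specific
#' within 0.15-0.35 s, consistent with neural activation preceding acoustic
#' onset during speech planning.
#'
#' @param gain burst amplitude in baseline in-band standard deviations
#' @return list of [word_template] objects
#' @export
default_vocabulary <- function(gain = 3.0) {
  labels <- c("Left", "Right", "Up", "Down", "Enter", "Back")
  durations <- c(0.90, 1.10, 0.85, 1.20, 1.35, 1.00)
  f0 <- c(115, 125, 130, 110, 120, 105)
  leads <- c(0.30, 0.20, 0.25, 0.15, 0.35, 0.22)
  fmts <- list(
    rbind(c(550, 1800, 2500), c(500, 1900, 2500)),
    rbind(c(750, 1150, 2400), c(420, 2000, 2500)),
    rbind(c(640, 1190, 2390), c(640, 1190, 2390)),
    rbind(c(770, 1250, 2450), c(450, 950, 2350)),
    rbind(c(520, 1900, 2550), c(480, 1600, 2500)),
    rbind(c(700, 1650, 2400), c(660, 1700, 2400)))
  lapply(seq_along(labels), function(w) {
    word_template(labels[w], durations[w], fmts[[w]], f0[w],
                  active_channels = c(1:6, 6 + ((w - 1) * 9 + 1:9)),
                  lead_time_s = leads[w], gain = gain)
  })
}

#' Construct an ECoG recording container
#'
#' @param samples numeric matrix, time x channels, in microvolts at 1000 Hz
#' @param grid_map data.frame with columns `channel`, `grid`, `row`, `col`
#'   (defaults to consecutive 8 x 8 grids of up to 64 contacts)
#' @param bad_channels integer indices of channels with poor signal quality
#' @param sr_hz sampling rate; must be 1000
#' @return an object of class `ecog_recording`
#' @export
ecog_recording <- function(samples, grid_map = NULL, bad_channels = integer(),
                           sr_hz = FS_NEURAL) {
  samples <- as.matrix(samples)
  if (sr_hz != FS_NEURAL) stop("ECoG recordings must be sampled at 1000 Hz")
  n_ch <- ncol(samples)
  if (is.null(grid_map)) grid_map <- default_grid_map(n_ch)
  if (nrow(grid_map) != n_ch) stop("grid_map must cover all channels")
  if (length(bad_channels) && any(bad_channels < 1 | bad_channels > n_ch)) {
    stop("bad_channels outside the channel range")
  }
  structure(list(samples = samples, grid_map = grid_map,
                 bad_channels = as.integer(bad_channels), sr_hz = sr_hz),
            class = "ecog_recording")
}

#' Default electrode grid geometry
#'
#' Channels are laid out row-major on consecutive 8 x 8 grids of up to 64
#' contacts each (two grids for the default 128-channel montage).
#'
#' @param n_channels total channel count
#' @return data.frame with columns `channel`, `grid`, `row`, `col`
#' @export
default_grid_map <- function(n_channels) {
  ch <- seq_len(n_channels)
  within <- (ch - 1) %% 64
  data.frame(channel = ch, grid = (ch - 1) %/% 64 + 1L,
             row = within %/% 8 + 1L, col = within %% 8 + 1L)
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %.1f s at %d Hz (%d bad)\n",
              ncol(x$samples), nrow(x$samples) / x$sr_hz, x$sr_hz,
              length(x$bad_channels)))
  invisible(x)
}

#' @export
print.synthetic_session <- function(x, ...) {
  n_words <- sum(x$log$label != "...")
  cat(sprintf(
    "<synthetic_session> block '%s': %d trials (%d words), %.1f s, seed %d\n",
    x$block_id, nrow(x$log), n_words, length(x$audio) / x$fs_audio, x$seed))
  invisible(x)
}

# ---- noise and burst primitives ------------------------------------------

# 1/f amplitude-shaped Gaussian noise via frequency-domain synthesis,
# normalised to unit standard deviation.
pink_noise <- function(n) {
  nfft <- 2^ceiling(log2(max(n, 2)))
  half <- nfft / 2
  f <- seq_len(half - 1)
  amp <- c(0, f^(-0.5), 0)                     # DC and Nyquist zeroed
  re <- stats::rnorm(half + 1) * amp
  im <- stats::rnorm(half + 1) * amp
  im[c(1, half + 1)] <- 0
  spec <- complex(real = re, imaginary = im)
  full <- c(spec, Conj(spec[half:2]))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# White noise band-limited to the high-gamma band, unit standard deviation.
# Used as the carrier of cortical activation bursts.
highgamma_carrier <- function(n) {
  x <- highgamma_filter(stats::rnorm(n + 200))[-seq_len(200)]
  x / stats::sd(x)
}

# Raised-cosine (Hann) burst envelope over `n` samples.
burst_envelope <- function(n) {
  if (n <= 1) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# ---- audio synthesis ------------------------------------------------------

# Lorentzian resonance magnitude of one formant at frequencies f.
formant_gain <- function(f, centre, bw = 90) {
  1 / sqrt(1 + ((f - centre) / (bw / 2))^2)
}

#' Formant-synthesise one word
#'
#' Additive harmonic source-filter synthesis: harmonics of `f0` up to 4 kHz,
#' each weighted by a three-formant Lorentzian spectral envelope evaluated
#' along linear formant trajectories, with 1/k spectral tilt and 50 ms
#' raised-cosine onset/offset ramps. Deterministic given its arguments.
#'
#' @param template a [word_template]
#' @param duration_s realised duration in seconds
#' @param fs audio sampling rate
#' @return numeric waveform with peak amplitude 0.3
#' @export
synth_word_audio <- function(template, duration_s = template$duration_s,
                             fs = FS_AUDIO) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  frac <- t / duration_s
  fm <- template$formants
  x <- numeric(n)
  k_max <- floor(7600 / template$f0_hz)
  for (k in seq_len(k_max)) {
    fk <- k * template$f0_hz
    g <- (formant_gain(fk, fm[1, 1] + frac * (fm[2, 1] - fm[1, 1])) +
          formant_gain(fk, fm[1, 2] + frac * (fm[2, 2] - fm[1, 2])) +
          formant_gain(fk, fm[1, 3] + frac * (fm[2, 3] - fm[1, 3]))) / k
    x <- x + g * sin(2 * pi * fk * t)
  }
  # broadband aspiration so words carry energy across the whole 0-8 kHz
  # evaluation range (deterministic: internally seeded)
  x <- x + 0.05 * max(abs(x)) * with_seed(20201, stats::rnorm(n))
  ramp <- round(0.05 * fs)
  env <- rep(1, n)
  if (n > 2 * ramp) {
    env[seq_len(ramp)] <- 0.5 - 0.5 * cos(pi * (seq_len(ramp) - 1) / ramp)
    env[n - ramp + seq_len(ramp)] <- rev(env[seq_len(ramp)])
  }
  x <- x * env
  0.3 * x / max(abs(x))
}

# ---- session assembly -----------------------------------------------------

default_noise_params <- function() {
  list(n_channels = 128L,      # two 8 x 8 grids
       noise_sd = 10,          # per-channel pink noise, microvolts
       shared_frac = 0.5,      # common-mode pink noise per grid
       silence_every = 10L,    # every k-th trial is a silence trial
       trial_period_s = 5,     # 2 s stimulus + 3 s intertrial interval
       audio_noise = 5e-4)     # microphone noise floor amplitude
}

build_session <- function(trials, vocabulary, seed, block_id, np) {
  n_trials <- nrow(trials)
  total_s <- if (n_trials == 0) 10 else {
    max(trials$stimulus_onset_s) + np$trial_period_s + 1
  }
  n_samp <- round(total_s * FS_NEURAL)
  n_aud <- round(total_s * FS_AUDIO)
  n_ch <- np$n_channels

  # background: independent pink noise per channel + shared grid component
  grid_map <- default_grid_map(n_ch)
  ecog <- matrix(0, n_samp, n_ch)
  for (ch in seq_len(n_ch)) ecog[, ch] <- np$noise_sd * pink_noise(n_samp)
  for (g in unique(grid_map$grid)) {
    shared <- np$noise_sd * np$shared_frac * pink_noise(n_samp)
    ecog[, grid_map$channel[grid_map$grid == g]] <-
      ecog[, grid_map$channel[grid_map$grid == g]] + shared
  }
  # in-band noise level sets the absolute burst amplitude
  inband_sd <- stats::sd(highgamma_filter(ecog[, 1]))

  audio <- np$audio_noise * stats::rnorm(n_aud)
  vad <- integer(floor(total_s * 100))

  by_label <- stats::setNames(vocabulary,
                              vapply(vocabulary, `[[`, "", "label"))
  for (i in seq_len(n_trials)) {
    lab <- trials$label[i]
    if (lab == "...") next
    tpl <- by_label[[lab]]
    onset <- trials$voice_onset_s[i]
    offset <- trials$voice_offset_s[i]
    wav <- synth_word_audio(tpl, offset - onset)
    a0 <- round(onset * FS_AUDIO)
    idx <- a0 + seq_along(wav)
    audio[idx] <- audio[idx] + wav

    burst_start <- round((onset - tpl$lead_time_s) * FS_NEURAL)
    burst_len <- round((offset - onset + tpl$lead_time_s) * FS_NEURAL)
    env <- burst_envelope(burst_len)
    idx <- burst_start + seq_len(burst_len)
    keep <- idx >= 1 & idx <= n_samp          # clip bursts at session edges
    amp <- tpl$gain * inband_sd
    for (ch in tpl$active_channels) {
      if (ch > n_ch) stop("active channel ", ch, " outside the montage")
      carrier <- highgamma_carrier(burst_len)
      ecog[idx[keep], ch] <- ecog[idx[keep], ch] +
        (amp * env * carrier)[keep]
    }
    fr <- which((seq_along(vad) - 1) / 100 + 0.005 >= onset &
                  (seq_along(vad) - 1) / 100 + 0.005 < offset)
    vad[fr] <- 1L
  }

  structure(list(ecog = ecog_recording(ecog, grid_map),
                 audio = audio, fs_audio = FS_AUDIO,
                 log = trials, ground_truth_vad = vad,
                 seed = seed, block_id = block_id),
            class = "synthetic_session")
}

#' Generate one synthetic word-production block
#'
#' Builds a session of `n_reps` repetitions of each vocabulary word in a
#' seeded pseudo-random order, one trial every 5 s (2 s stimulus + 3 s
#' intertrial interval), interrupted by a silence trial every
#' `noise_params$silence_every`-th trial. Each word trial carries a
#' high-gamma burst on its template's active channels beginning
#' `lead_time_s` before voice onset, superimposed on 1/f background noise;
#' the audio track contains the formant-synthesised word in the voice
#' interval and near-silence elsewhere.
#'
#' @param vocabulary list of [word_template]s (labels must be unique)
#' @param n_reps repetitions per word (>= 0; 0 yields a pure-noise session)
#' @param seed integer seed; identical inputs give bit-identical sessions
#' @param noise_params list overriding [default_noise_params()] entries
#' @param block_id block identifier string
#' @return an object of class `synthetic_session` with fields `ecog`,
#'   `audio`, `log` (trial data.frame), `ground_truth_vad` (per-10 ms binary
#'   labels)
#' @export
generate_block <- function(vocabulary = default_vocabulary(), n_reps = 10,
                           seed = 1, noise_params = list(),
                           block_id = paste0("block", seed)) {
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty")
  labels <- vapply(vocabulary, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("vocabulary labels must be unique")
  np <- utils::modifyList(default_noise_params(), noise_params)

  with_seed(seed, {
    word_seq <- if (n_reps >= 1) sample(rep(labels, n_reps)) else character()
    # silence trials interleaved after every (silence_every - 1) words
    seq_all <- character()
    for (i in seq_along(word_seq)) {
      seq_all <- c(seq_all, word_seq[i])
      if (i %% (np$silence_every - 1L) == 0L && i < length(word_seq)) {
        seq_all <- c(seq_all, "...")
      }
    }
    if (length(word_seq)) seq_all <- c(seq_all, "...")
    n_trials <- length(seq_all)
    by_label <- stats::setNames(vocabulary, labels)
    stim <- (seq_len(n_trials) - 1) * np$trial_period_s
    onset <- rep(NA_real_, n_trials)
    offset <- rep(NA_real_, n_trials)
    for (i in seq_len(n_trials)) {
      if (seq_all[i] == "...") next
      tpl <- by_label[[seq_all[i]]]
      onset[i] <- stim[i] + stats::runif(1, 0.3, 0.7)
      offset[i] <- onset[i] + tpl$duration_s * stats::runif(1, 0.9, 1.1)
    }
    trials <- data.frame(trial = seq_len(n_trials),
                         label = seq_all, stimulus_onset_s = stim,
                         voice_onset_s = onset, voice_offset_s = offset)
    build_session(trials, vocabulary, seed, block_id, np)
  })
}

#' Generate a syllable-repetition baseline block
#'
#' The baseline task used for normalisation statistics: `n_syllables`
#' consonant-vowel syllables, each repeated `n_reps` times, with trial
#' durations drawn uniformly from the 80 ms lattice \{2.5, 2.58, ..., 3.5\} s
#' and a 1 s stimulus-presentation period per trial. The repetition response
#' elicits a moderate high-gamma burst on the speech-responsive channels.
#'
#' @param n_syllables number of distinct syllables (>= 1)
#' @param n_reps repetitions per syllable (>= 1)
#' @param seed integer seed
#' @param noise_params list overriding [default_noise_params()] entries
#' @param responsive_channels channels that respond to overt speech
#'   (default: first grid, 1..64, clipped to the montage)
#' @return a `synthetic_session`
#' @export
generate_baseline_block <- function(n_syllables = 12, n_reps = 5, seed = 1,
                                    noise_params = list(),
                                    responsive_channels = NULL) {
  if (n_syllables < 1 || n_reps < 1) stop("counts must be >= 1")
  np <- utils::modifyList(default_noise_params(), noise_params)
  if (is.null(responsive_channels)) {
    responsive_channels <- seq_len(min(64L, np$n_channels))
  }
  with_seed(seed, {
    n_trials <- n_syllables * n_reps
    syl <- sample(rep(seq_len(n_syllables), n_reps))
    lattice <- seq(2.5, 3.5, by = 0.08)
    dur <- sample(lattice, n_trials, replace = TRUE)
    stim <- cumsum(c(0, dur[-n_trials]))
    onset <- stim + 1 + stats::runif(n_trials, 0.2, 0.4)
    offset <- onset + stats::runif(n_trials, 0.35, 0.55)
    # syllable templates: cycle f0 and first two formants
    tpl <- lapply(seq_len(n_syllables), function(s) {
      word_template(paste0("syl", s), 0.45,
                    rbind(c(400 + 30 * (s %% 4), 1000 + 120 * (s %% 6), 2450),
                          c(430 + 30 * (s %% 4), 1050 + 120 * (s %% 6), 2450)),
                    f0_hz = 100 + 4 * s,
                    active_channels = responsive_channels,
                    lead_time_s = 0.2, gain = 2.0)
    })
    trials <- data.frame(trial = seq_len(n_trials),
                         label = paste0("syl", syl),
                         stimulus_onset_s = stim,
                         voice_onset_s = onset, voice_offset_s = offset,
                         trial_duration_s = dur)
    np2 <- np
    np2$trial_period_s <- max(dur)          # only affects the tail padding
    build_session(trials, tpl, seed, paste0("baseline", seed), np2)
  })
}

#' Inject acoustic leakage into a neural channel
#'
#' Adds the session's own audio — anti-alias filtered and decimated to the
#' neural sampling rate — to one named channel, scaled so that `gain` is the
#' added waveform's overall RMS in microvolts. A forward simulation of the
#' acoustic-contamination failure mode, used to exercise the audit.
#'
#' @param session a `synthetic_session`
#' @param channel channel index receiving the leakage
#' @param gain added RMS amplitude in microvolts (>= 0; 0 is a no-op)
#' @return the modified session; all other channels are untouched
#' @export
inject_contamination <- function(session, channel, gain) {
  n_ch <- ncol(session$ecog$samples)
  if (!(channel %in% seq_len(n_ch))) {
    stop("unknown channel: ", channel)
  }
  if (gain < 0) stop("gain must be non-negative")
  if (gain == 0) return(session)
  y <- signal::decimate(signal::decimate(session$audio, 4), 4)
  n <- nrow(session$ecog$samples)
  y <- if (length(y) >= n) y[seq_len(n)] else c(y, numeric(n - length(y)))
  contam <- gain * y / stats::sd(y)
  session$ecog$samples[, channel] <- session$ecog$samples[, channel] + contam
  session
}
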