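# Acoustic front end and codec.
#
# Audio preparation (cross-correlation alignment, 48 -> 16 kHz resampling,
# energy-based voice labelling) and a deterministic codec over the compact
# per-frame feature set consumed by the decoder: 18 Bark-scale cepstral
# coefficients (triangular Bark-band energies -> log -> DCT) plus a pitch
# period and pitch correlation per 10 ms frame. The synthesiser reconstructs
# a spectral envelope from the cepstrum and excites it with a pulse/noise
# mixture governed by the pitch parameters, overlap-added per frame. The
# feature interface (18 + 2 per frame at 100 frames/s) matches what a neural
# vocoder of the LPCNet family consumes, so one can be swapped in behind the
# same module boundary.

N_CEPS <- 18L
PITCH_MIN_HZ <- 50
PITCH_MAX_HZ <- 400
VOICED_THRESHOLD <- 0.3

#' Align two recordings by cross-correlation
#'
#' Returns the lag (in seconds) of `y` relative to `x` that maximises their
#' normalised cross-correlation: if `y` is `x` delayed by `d` seconds, the
#' returned offset is `+d`. Signals sampled at different rates are first
#' brought to the lower of the two rates.
#'
#' @param x,y waveforms with overlapping content
#' @param fs_x,fs_y sampling rates in Hz
#' @return offset in seconds (within one sample at the working rate)
#' @export
align_audio <- function(x, y, fs_x = FS_AUDIO, fs_y = fs_x) {
  if (all(x == 0) || all(y == 0)) stop("all-zero input: alignment undefined")
  fs <- min(fs_x, fs_y)
  resample_q <- function(s, from) {
    if (from == fs) return(s)
    q <- from / fs
    if (q != round(q)) stop("sampling rates must be integer multiples")
    as.numeric(signal::decimate(s, round(q)))
  }
  x <- resample_q(x, fs_x); y <- resample_q(y, fs_y)
  nx <- length(x); ny <- length(y)
  L <- 2^ceiling(log2(nx + ny))
  xp <- c(x, numeric(L - nx)); yp <- c(y, numeric(L - ny))
  # r at index k+1 holds sum_t x[t] y[t + k] (circular, but the zero padding
  # to nx + ny makes positive and negative lags non-overlapping)
  r <- Re(stats::fft(Conj(stats::fft(xp)) * stats::fft(yp), inverse = TRUE)) / L
  lags <- ifelse(0:(L - 1) < L / 2, 0:(L - 1), 0:(L - 1) - L)
  valid <- which(lags > -nx & lags < ny)
  k <- valid[which.max(r[valid])]
  lags[k] / fs
}

#' Resample 48 kHz audio to the 16 kHz working rate
#'
#' Anti-aliased 3:1 decimation; output length is `ceiling(n / 3)`.
#'
#' @param x waveform at 48 kHz
#' @return waveform at 16 kHz
#' @export
resample_to_16k <- function(x) {
  as.numeric(signal::decimate(x, 3))
}

#' Energy-based voice activity detection
#'
#' Smoothed short-time log energy on the 10 ms frame grid, thresholded
#' adaptively at `margin_db` above the 10th-percentile noise floor (with an
#' absolute floor), followed by a hangover that extends and bridges voiced
#' runs.
#'
#' @param audio waveform
#' @param fs sampling rate in Hz
#' @param margin_db threshold margin above the noise floor (dB)
#' @param hangover frames appended after each voiced run (also bridges gaps
#'   of up to this many frames)
#' @param floor_db absolute energy floor in dB full scale
#' @return integer 0/1 labels, one per 10 ms (length `floor(duration/10ms)`)
#' @export
energy_vad <- function(audio, fs = FS_AUDIO, margin_db = 12, hangover = 5,
                       floor_db = -65) {
  hop <- round(fs * 0.01)
  win <- round(fs * 0.025)
  nf <- floor(length(audio) / hop)
  if (nf < 1) stop("audio shorter than one frame")
  pad <- c(audio, numeric(win))
  starts <- (seq_len(nf) - 1) * hop
  e <- vapply(starts, function(s) mean(pad[s + seq_len(win)]^2), 0)
  e_db <- 10 * log10(e + 1e-12)
  e_db <- as.numeric(stats::filter(e_db, rep(1 / 5, 5), sides = 2))
  e_db[is.na(e_db)] <- -120
  thr <- max(stats::quantile(e_db, 0.1) + margin_db, floor_db)
  lab <- as.integer(e_db > thr)
  if (hangover > 0 && any(lab == 1)) {
    ext <- lab
    for (k in seq_len(hangover)) {
      ext <- pmax(ext, c(numeric(k), lab[seq_len(nf - k)]))
    }
    # bridging: a 0-gap shorter than the hangover between two 1-runs closes
    lab <- as.integer(ext)
  }
  lab
}

# ---- Bark filterbank ------------------------------------------------------

hz_to_bark <- function(f) 13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)

# 18 triangular filters with edges equally spaced on the Bark scale over
# [0, fs/2]; rows are bands, columns FFT bins.
bark_filterbank <- function(freqs, n_bands = N_CEPS) {
  edges_bark <- seq(0, hz_to_bark(max(freqs)), length.out = n_bands + 2)
  fb <- matrix(0, n_bands, length(freqs))
  fb_bark <- hz_to_bark(freqs)
  for (b in seq_len(n_bands)) {
    lo <- edges_bark[b]; mid <- edges_bark[b + 1]; hi <- edges_bark[b + 2]
    up <- (fb_bark - lo) / (mid - lo)
    down <- (hi - fb_bark) / (hi - mid)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Encode audio into Bark-cepstral and pitch features
#'
#' Per 10 ms frame (50 ms Hann analysis window): 18 Bark-band log energies
#' compressed by an orthonormal DCT into 18 cepstral coefficients, plus the
#' pitch period (autocorrelation peak searched over 50-400 Hz, in samples)
#' and the pitch correlation (normalised peak height, clipped to \[0, 1\]).
#'
#' @param audio waveform at 16 kHz, at least one 50 ms window long
#' @param fs sampling rate (16 kHz)
#' @return object of class `acoustic_features`: `cepstrum` (frames x 18),
#'   `pitch_period`, `pitch_corr`, `frame_shift_ms`
#' @export
encode_audio <- function(audio, fs = FS_AUDIO) {
  if (n_frames(length(audio), fs) < 1) {
    stop("audio shorter than one analysis window")
  }
  spec <- stft_mag(audio, fs, nfft = 1024)
  freqs <- attr(spec, "freqs")
  fb <- bark_filterbank(freqs)
  band_e <- log(fb %*% (spec^2) + 1e-10)
  ceps <- t(dct_matrix(N_CEPS) %*% band_e)

  # autocorrelation pitch on the same frame grid
  idx <- frame_index_matrix(length(audio), fs)
  win <- ncol(idx)
  nfft <- 2^ceiling(log2(2 * win))
  lag_min <- floor(fs / PITCH_MAX_HZ)
  lag_max <- ceiling(fs / PITCH_MIN_HZ)
  fm <- matrix(audio[t(idx)], nrow = win)
  fm <- sweep(fm, 2, colMeans(fm))
  fz <- rbind(fm, matrix(0, nfft - win, ncol(fm)))
  ac <- Re(stats::mvfft(Mod(stats::mvfft(fz))^2, inverse = TRUE)) / nfft
  r0 <- pmax(ac[1, ], 1e-12)
  lags <- lag_min:lag_max
  rel <- ac[lags + 1, , drop = FALSE] / rep(r0, each = length(lags))
  best <- apply(rel, 2, which.max)
  structure(list(cepstrum = ceps,
                 pitch_period = lags[best],
                 pitch_corr = pmin(1, pmax(0, rel[cbind(best,
                                                        seq_along(best))])),
                 frame_shift_ms = FRAME_SHIFT_MS),
            class = "acoustic_features")
}

#' @export
print.acoustic_features <- function(x, ...) {
  cat(sprintf("<acoustic_features> %d frames x (%d cepstral + 2 pitch)\n",
              nrow(x$cepstrum), ncol(x$cepstrum)))
  invisible(x)
}

#' Synthesise a waveform from codec features
#'
#' Deterministic vocoder: a per-sample excitation (glottal pulse train at
#' the frame's pitch period mixed with Gaussian noise according to the pitch
#' correlation) is shaped frame-by-frame in the frequency domain by the
#' spectral envelope reconstructed from the Bark cepstrum, then
#' overlap-added. Each frame is rescaled so its Bark-band energy matches the
#' encoded target, which makes output loudness monotone in cepstral
#' coefficient 0.
#'
#' @param features an `acoustic_features` object (finite values)
#' @param fs output sampling rate (16 kHz)
#' @param seed seed for the noise excitation; output is deterministic given
#'   `features` and `seed`
#' @return waveform at `fs`
#' @export
synthesize_audio <- function(features, fs = FS_AUDIO, seed = 1) {
  stopifnot(inherits(features, "acoustic_features"))
  ceps <- features$cepstrum
  if (any(!is.finite(ceps)) || any(!is.finite(features$pitch_period)) ||
      any(!is.finite(features$pitch_corr))) {
    stop("non-finite values in acoustic features")
  }
  nf <- nrow(ceps)
  hop <- round(fs * FRAME_SHIFT_MS / 1000)
  win <- round(fs * FRAME_WINDOW_MS / 1000)
  n <- (nf - 1) * hop + win
  nfft <- 1024
  freqs <- (0:(nfft / 2)) * fs / nfft
  fb <- bark_filterbank(freqs)
  centres_hz <- freqs[apply(fb, 1, which.max)]
  band_e <- t(dct_matrix(N_CEPS)) %*% t(ceps)      # bands x frames
  band_e <- band_e - log(pmax(rowSums(fb), 1))     # undo filter bandwidth gain

  with_seed(seed, {
    voiced <- features$pitch_corr > VOICED_THRESHOLD
    w <- ifelse(voiced, pmin(1, features$pitch_corr), 0)
    # median-smoothed pitch track avoids frame-to-frame harmonic jitter
    period <- stats::runmed(features$pitch_period, 5)
    frame_of <- pmin(nf, (seq_len(n) - 1) %/% hop + 1)
    # voiced excitation is dominated by the pulse train; the noise floor in
    # voiced frames is kept low so sustained vowels synthesise cleanly
    noise_amp <- ifelse(voiced, 0.15, 1) * sqrt(pmax(0, 1 - w^2))
    exc <- stats::rnorm(n) * noise_amp[frame_of]
    t_next <- 1
    while (t_next <= n) {
      fr <- frame_of[ceiling(t_next)]
      p <- period[fr]
      if (voiced[fr]) exc[round(t_next)] <- exc[round(t_next)] + w[fr] * sqrt(p)
      t_next <- t_next + p
    }

    hwin <- hann_window(win)
    y <- numeric(n)
    wsum <- numeric(n)
    bark_bins <- hz_to_bark(freqs)
    idct <- t(dct_matrix(N_CEPS))
    gains <- numeric(nf)
    shaped_all <- vector("list", nf)
    for (t in seq_len(nf)) {
      amp <- exp(stats::approx(hz_to_bark(centres_hz), band_e[, t] / 2,
                               xout = bark_bins, rule = 2)$y)
      seg <- exc[(t - 1) * hop + seq_len(win)] * hwin
      spec <- stats::fft(c(seg, numeric(nfft - win)))
      spec[seq_len(nfft / 2 + 1)] <- spec[seq_len(nfft / 2 + 1)] * amp
      spec[(nfft / 2 + 2):nfft] <- Conj(spec[(nfft / 2 + 1):2])[-1]
      shaped_all[[t]] <- Re(stats::fft(spec, inverse = TRUE))[seq_len(win)] /
        nfft
      # match the frame's Bark-band energy to the encoded target
      pow <- Mod(stats::fft(c(shaped_all[[t]] * hwin,
                              numeric(nfft - win))))^2
      target <- sum(exp(as.numeric(idct %*% ceps[t, ])))
      actual <- sum(fb %*% pow[seq_len(nfft / 2 + 1)]) + 1e-10
      gains[t] <- sqrt(target / actual)
    }
    # smoothing the gain track suppresses realisation jitter from pulses
    # falling near window edges
    if (nf >= 5) gains <- stats::runmed(gains, 3)
    for (t in seq_len(nf)) {
      y[(t - 1) * hop + seq_len(win)] <- y[(t - 1) * hop + seq_len(win)] +
        gains[t] * shaped_all[[t]] * hwin
      wsum[(t - 1) * hop + seq_len(win)] <-
        wsum[(t - 1) * hop + seq_len(win)] + hwin^2
    }
    y / pmax(wsum, 0.1)
  })
}
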