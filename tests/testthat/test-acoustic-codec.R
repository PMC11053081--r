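# Audio alignment, resampling, voice labelling, codec round trip.

test_that("cross-correlation alignment recovers constructed shifts", {
  set.seed(7)
  x <- rnorm(16000)
  y <- c(numeric(4000), x)                      # 250 ms delay
  expect_equal(align_audio(x, y), 0.250, tolerance = 1 / 16000)
  expect_equal(align_audio(y, x), -align_audio(x, y),
               tolerance = 1 / 16000)
  # noisy copy at 10 dB SNR: recovered within 2 ms
  yn <- y + rnorm(length(y)) * sd(x) * 10^(-10 / 20)
  expect_lt(abs(align_audio(x, yn) - 0.250), 0.002)
  expect_error(align_audio(numeric(100), x), "all-zero")
})

test_that("48 to 16 kHz resampling is anti-aliased 3:1 decimation", {
  n <- 48000
  t <- (seq_len(n) - 1) / 48000
  tone <- sin(2 * pi * 1000 * t)
  r <- resample_to_16k(tone)
  expect_length(r, ceiling(n / 3))
  expect_equal(resample_to_16k(numeric(300)), numeric(100))
  # amplitude preserved within 1 percent (spectral peak oracle)
  spec <- stft_mag(r, 16000, nfft = 2048)
  pk <- attr(spec, "freqs")[which.max(rowMeans(spec))]
  expect_equal(pk, 1000, tolerance = 16000 / 2048)
  expect_equal(sqrt(2 * mean(r[2000:3000]^2)), 1, tolerance = 0.01)
  # 23 kHz content must not fold into the band
  alias <- resample_to_16k(sin(2 * pi * 23000 * t))
  expect_lt(10 * log10(mean(alias^2) / mean(tone^2)), -40)
})

test_that("energy VAD labels silence and finds word boundaries", {
  expect_true(all(energy_vad(numeric(16000)) == 0))
  expect_length(energy_vad(numeric(16155)), floor(16155 / 160))

  tpl <- default_vocabulary()[[1]]
  wav <- synth_word_audio(tpl, 1.0)
  onset_s <- 0.5
  audio <- c(numeric(onset_s * 16000), wav, numeric(8000))
  audio <- audio + 1e-4 * with_seed_helper(8, rnorm(length(audio)))
  lab <- energy_vad(audio)
  run <- range(which(lab == 1))
  expect_lt(abs((run[1] - 1) * 0.01 - onset_s), 0.03)
  expect_lt(abs(run[2] * 0.01 - (onset_s + 1.0)), 0.08)
})

test_that("encoder measures pitch and codec frame rate matches the contract", {
  tpl <- default_vocabulary()[[3]]
  v <- synth_word_audio(tpl, 1.0)
  f <- encode_audio(v)
  voiced <- f$pitch_corr > 0.5
  expect_gt(mean(voiced), 0.5)
  # independent oracle: true period = fs / f0
  expect_lt(abs(median(f$pitch_period[voiced]) - 16000 / tpl$f0_hz),
            0.1 * 16000 / tpl$f0_hz)
  expect_true(all(f$pitch_period > 0))

  # silence: no periodicity, low energy
  sil <- encode_audio(numeric(8000))
  expect_lt(mean(sil$pitch_corr), 0.05)
  expect_lt(mean(sil$cepstrum[, 1]), -20)

  # frame-rate contract: same duration gives equal frame counts for the
  # audio codec and the neural high-gamma framing
  dur_s <- 1.23
  expect_equal(nrow(encode_audio(numeric(dur_s * 16000))$cepstrum),
               n_frames(dur_s * 1000, 1000))
})

test_that("vocoder is deterministic, energy-monotone, and inverts the encoder", {
  tpl <- default_vocabulary()[[1]]
  v <- c(numeric(4800), synth_word_audio(tpl, 0.9), numeric(4800)) +
    1e-5 * with_seed_helper(9, rnorm(0.9 * 16000 + 9600))
  f <- encode_audio(v)
  y1 <- synthesize_audio(f, seed = 5)
  y2 <- synthesize_audio(f, seed = 5)
  expect_identical(y1, y2)

  # loudness rises monotonically with cepstral coefficient 0
  rms <- vapply(c(-1, 0, 1), function(d) {
    fd <- f; fd$cepstrum[, 1] <- fd$cepstrum[, 1] + d
    sd(synthesize_audio(fd, seed = 5))
  }, 0)
  expect_true(all(diff(rms) > 0))

  # round trip preserves the mel spectrum
  expect_gt(mel_correlation(v, y1), 0.8)

  f_bad <- f; f_bad$cepstrum[1, 1] <- NaN
  expect_error(synthesize_audio(f_bad), "non-finite")
})
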