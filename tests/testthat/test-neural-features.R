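# Feature extraction: CAR, causal filtering, framing, normalisation,
# channel selection.

test_that("common-average reference removes the per-grid mean", {
  rec <- ecog_recording(matrix(c(1, 2, 3), 1, 3),
                        grid_map = data.frame(channel = 1:3, grid = 1,
                                              row = 1, col = 1:3))
  out <- common_average_reference(rec)
  expect_equal(as.numeric(out$samples), c(-1, 0, 1))

  # invariance to a common-mode offset
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  gm <- data.frame(channel = 1:4, grid = 1, row = 1, col = 1:4)
  a <- common_average_reference(ecog_recording(x, gm))
  b <- common_average_reference(ecog_recording(x + 5, gm))
  expect_equal(a$samples, b$samples)
})

test_that("CAR is applied per grid and skips bad channels", {
  # two 2-channel grids; signal only on grid A must not leak into grid B
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4)
  x[, 1] <- x[, 1] + 10
  gm <- data.frame(channel = 1:4, grid = c(1, 1, 2, 2), row = 1,
                   col = c(1, 2, 1, 2))
  out <- common_average_reference(ecog_recording(x, gm))
  # brute-force per-grid means
  expect_equal(out$samples[, 3], x[, 3] - (x[, 3] + x[, 4]) / 2)
  expect_equal(out$samples[, 4], x[, 4] - (x[, 3] + x[, 4]) / 2)
  expect_equal(out$samples[, 1], x[, 1] - (x[, 1] + x[, 2]) / 2)

  # bad channels: passed through untouched, excluded from the average
  rec <- ecog_recording(x, gm, bad_channels = 1L)
  expect_error(common_average_reference(rec), "fewer than 2")
  gm3 <- data.frame(channel = 1:4, grid = 1, row = 1, col = 1:4)
  out3 <- common_average_reference(ecog_recording(x, gm3,
                                                  bad_channels = 2L))
  good_mean <- rowMeans(x[, c(1, 3, 4)])
  expect_equal(out3$samples[, 2], x[, 2])
  expect_equal(out3$samples[, 1], x[, 1] - good_mean)
})

test_that("high-gamma filters match an independent frequency-response oracle", {
  expect_equal(highgamma_filter(numeric(500)), numeric(500))
  expect_error(highgamma_filter(c(1, NA, 2)), "non-finite")

  # steady-state gain measured on long sines
  gain_at <- function(f_hz) {
    t <- (0:4999) / 1000
    y <- highgamma_filter(sin(2 * pi * f_hz * t))
    sqrt(mean(y[3001:5000]^2) / 0.5)
  }
  expect_gt(20 * log10(gain_at(100)), -3)     # pass band within 3 dB
  expect_lt(20 * log10(gain_at(120)), -20)    # notch at first harmonic
  expect_lt(20 * log10(gain_at(30)), -20)     # out of band

  # oracle: the designed transfer functions evaluated via signal::freqz
  flt <- list(bp = signal::butter(4, c(70, 170) / 500, "pass"),
              bs = signal::butter(4, c(118, 122) / 500, "stop"))
  fr <- signal::freqz(flt$bp$b, flt$bp$a, Fs = 1000)
  g100 <- abs(fr$h[which.min(abs(fr$f - 100))])
  expect_equal(gain_at(100), g100, tolerance = 0.01)
})

test_that("packetised filtering with carried state equals one-shot filtering", {
  set.seed(3)
  x <- rnorm(2000)
  full <- highgamma_filter(x)
  st <- NULL
  out <- numeric(0)
  for (p in seq(1, 2000, by = 40)) {          # 40 ms packets
    r <- highgamma_filter(x[p:(p + 39)], state = st, return_state = TRUE)
    st <- r$state
    out <- c(out, r$y)
  }
  expect_lt(max(abs(out - full)), 1e-9)
})

test_that("filtering is causal", {
  set.seed(4)
  x <- rnorm(1000)
  y_full <- highgamma_filter(x)
  x2 <- x; x2[501:1000] <- rnorm(500) * 10    # perturb only the future
  y_trunc <- highgamma_filter(x2)
  expect_equal(y_full[1:500], y_trunc[1:500])
})

test_that("log-power frames follow the closed-form sinusoid power", {
  t <- (0:999) / 1000
  for (A in c(1, 2)) {
    y <- A * sin(2 * pi * 100 * t)
    lp <- log_power_frames(y)
    expect_length(lp, 96)                      # (1000 - 50)/10 + 1
    expect_lt(max(abs(lp[10:80] - log(A^2 / 2))), abs(log(A^2 / 2)) * 0.05 + 0.02)
  }
  # homogeneity: doubling the amplitude raises every frame by log 4
  y1 <- sin(2 * pi * 100 * t)
  expect_equal(log_power_frames(2 * y1) - log_power_frames(y1),
               rep(log(4), 96), tolerance = 1e-6)
  expect_error(log_power_frames(numeric(30)), "short")
})

test_that("baseline statistics match a two-pass oracle and normalise to z-scores", {
  set.seed(5)
  v <- matrix(rnorm(80, mean = 3, sd = 2), 20, 4)
  fr <- structure(list(values = v, channel_ids = 1:4, frame_shift_ms = 10,
                       window_ms = 50, normalized = FALSE,
                       grid_map = default_grid_map(4)),
                  class = "high_gamma_frames")
  st <- compute_baseline_stats(fr)
  # two-pass oracle
  expect_equal(st$mean, colMeans(v))
  expect_equal(st$sd, apply(v, 2, function(col) {
    sqrt(sum((col - mean(col))^2) / (length(col) - 1))
  }))
  z <- normalize_frames(fr, st)
  expect_true(z$normalized)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-9)

  # identity statistics are the identity map
  id <- structure(list(mean = rep(0, 4), sd = rep(1, 4), channel_ids = 1:4,
                       source_day = "d"), class = "baseline_stats")
  expect_equal(normalize_frames(fr, id)$values, v)

  # degenerate: constant channel
  v2 <- v; v2[, 2] <- 1
  fr2 <- fr; fr2$values <- v2
  expect_error(compute_baseline_stats(fr2), "standard deviation")
})

test_that("channel selection recovers exactly the planted channels", {
  vocab <- lapply(small_vocabulary(), function(t) {
    t$active_channels <- c(3L, 7L)
    t
  })
  s <- generate_block(vocab, n_reps = 5, seed = 31,
                      noise_params = list(n_channels = 16))
  fr <- extract_highgamma(s$ecog)
  st <- compute_baseline_stats(fr)
  z <- normalize_frames(fr, st)
  sel <- select_channels(z, s$log[s$log$label != "...", ])
  expect_identical(sel, c(3L, 7L))
})

test_that("selection false positives stay within the alpha expectation", {
  # Monte-Carlo on pure-noise normalised frames: with the family-wise
  # Bonferroni criterion the expected false-positive count over 50 runs is
  # far below one channel per run.
  set.seed(6)
  n_fp <- 0
  trial_log <- data.frame(stimulus_onset_s = seq(0, 45, by = 5))
  for (run in 1:50) {
    v <- matrix(rnorm(1000 * 8), 1000, 8)
    fr <- structure(list(values = v, channel_ids = 1:8, frame_shift_ms = 10,
                         window_ms = 50, normalized = TRUE,
                         grid_map = default_grid_map(8)),
                    class = "high_gamma_frames")
    sel <- select_channels(fr, trial_log, epoch_s = c(0, 0.5))
    n_fp <- n_fp + length(sel)
  }
  expect_lte(n_fp / 50, 0.05 * 8)
  expect_error(select_channels(
    structure(list(values = matrix(0, 5, 2), channel_ids = 1:2,
                   normalized = TRUE, frame_shift_ms = 10, window_ms = 50,
                   grid_map = default_grid_map(2)),
              class = "high_gamma_frames"),
    data.frame(stimulus_onset_s = 0)), "2 trials")
})
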