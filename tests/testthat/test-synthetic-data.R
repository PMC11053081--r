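# Synthetic session generator: task design, determinism, signal structure.

test_that("word blocks follow the task design", {
  s <- small_session()
  words <- s$log[s$log$label != "...", ]
  expect_equal(nrow(words), 6)                 # n_reps * |vocabulary|
  expect_setequal(words$label, c("Left", "Right", "Up", "Down", "Enter",
                                 "Back"))
  # trials time-ordered, non-overlapping, on the 5 s grid
  expect_true(all(diff(s$log$stimulus_onset_s) == 5))
  expect_true(all(words$voice_onset_s >= words$stimulus_onset_s))
  expect_true(all(words$voice_offset_s > words$voice_onset_s))
  # silence trials carry no voice interval
  sil <- s$log[s$log$label == "...", ]
  expect_true(all(is.na(sil$voice_onset_s)))
  # vad length contract
  expect_equal(length(s$ground_truth_vad),
               floor(nrow(s$ecog$samples) / 10))
})

test_that("identical configuration and seed give bit-identical sessions", {
  s1 <- small_session()
  s2 <- generate_block(small_vocabulary(), n_reps = 1, seed = 11,
                       noise_params = list(n_channels = 16))
  expect_identical(s1$ecog$samples, s2$ecog$samples)
  expect_identical(s1$audio, s2$audio)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$ground_truth_vad, s2$ground_truth_vad)
})

test_that("n_reps = 0 yields a pure-noise session", {
  s <- generate_block(small_vocabulary(), n_reps = 0, seed = 4,
                      noise_params = list(n_channels = 4))
  expect_equal(nrow(s$log), 0)
  expect_true(all(s$ground_truth_vad == 0))
  expect_lt(max(abs(s$audio)), 0.01)           # only the mic noise floor
})

test_that("invalid templates are rejected with a message", {
  expect_error(word_template("bad", -1, rbind(c(500, 1500, 2500),
                                              c(500, 1500, 2500)),
                             110, 1:2, 0.2),
               "duration")
  expect_error(word_template("bad", 1, rbind(c(500, 1500, 2500),
                                             c(500, 1500, 2500)),
               110, 1:2, 0.9), "lead_time")
  expect_error(generate_block(list(), n_reps = 1, seed = 1), "non-empty")
})

test_that("ground-truth voice labels agree with audio energy", {
  s <- small_session()
  lab <- energy_vad(s$audio)
  truth <- s$ground_truth_vad[seq_along(lab)]
  # onset/offset agreement within 30 ms (3 frames) per voiced run
  r_t <- rle(truth)
  ends <- cumsum(r_t$lengths); starts <- ends - r_t$lengths + 1
  for (i in which(r_t$values == 1)) {
    win <- max(1, starts[i] - 3):min(length(lab), starts[i] + 3)
    expect_true(any(lab[win] == 1))
    win2 <- max(1, ends[i] - 3):min(length(lab), ends[i] + 3)
    expect_true(any(lab[win2] == 1))
  }
  # frame-level agreement is high overall
  expect_gt(mean(lab == truth), 0.95)
})

test_that("high-gamma bursts exceed baseline by at least 2 SDs", {
  s <- small_session()
  fr <- extract_highgamma(s$ecog)
  # baseline statistics from intertrial (non-speech, non-burst) frames
  lab <- aligned_labels(s, fr)
  base <- fr$values[lab == 0, , drop = FALSE]
  mu <- colMeans(base); sd0 <- apply(base, 2, sd)
  vocab <- small_vocabulary()
  words <- s$log[s$log$label != "...", ]
  by_label <- setNames(vocab, vapply(vocab, `[[`, "", "label"))
  for (i in seq_len(nrow(words))) {
    tpl <- by_label[[words$label[i]]]
    f0 <- floor(words$voice_onset_s[i] * 100)
    f1 <- ceiling(words$voice_offset_s[i] * 100)
    # peak effect on active channels during the word
    peak <- apply(fr$values[f0:f1, tpl$active_channels, drop = FALSE],
                  2, max)
    z <- (peak - mu[tpl$active_channels]) / sd0[tpl$active_channels]
    expect_gt(mean(z), 2)
  }
})

test_that("baseline blocks sample the 80 ms duration lattice", {
  bl <- generate_baseline_block(3, 2, seed = 21,
                                noise_params = list(n_channels = 4),
                                responsive_channels = 1:4)
  expect_equal(nrow(bl$log), 6)                # n_syllables * n_reps
  d_ms <- (bl$log$trial_duration_s - 2.5) * 1000
  expect_true(all(abs(d_ms - 80 * round(d_ms / 80)) < 1e-6))
  expect_true(all(bl$log$trial_duration_s >= 2.5 - 1e-9))
  expect_true(all(bl$log$trial_duration_s <= 3.5 + 1e-9))
  # voice onsets follow the 1 s stimulus period
  expect_true(all(bl$log$voice_onset_s >= bl$log$stimulus_onset_s + 1))
  # different seeds give different duration sequences
  bl2 <- generate_baseline_block(3, 2, seed = 22,
                                 noise_params = list(n_channels = 4),
                                 responsive_channels = 1:4)
  expect_false(identical(bl$log$trial_duration_s,
                         bl2$log$trial_duration_s))
})

test_that("contamination injection is local and zero-gain is a no-op", {
  s <- small_session()
  s0 <- inject_contamination(s, 3, 0)
  expect_identical(s0$ecog$samples, s$ecog$samples)
  s1 <- inject_contamination(s, 3, 20)
  expect_false(identical(s1$ecog$samples[, 3], s$ecog$samples[, 3]))
  other <- setdiff(seq_len(16), 3)
  expect_identical(s1$ecog$samples[, other], s$ecog$samples[, other])
  expect_error(inject_contamination(s, 99, 1), "unknown channel")
})
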