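# Saliency, contamination audit, channel repair, evaluation metrics.

test_that("PSO is the first positive prediction and is causal", {
  m <- nvad_model(4, 8, seed = 21)
  set.seed(17)
  x <- matrix(rnorm(200), 50, 4)
  p <- find_pso(m, x)
  if (!is.na(p)) {
    x2 <- rbind(x, matrix(rnorm(40), 10, 4))   # future frames are irrelevant
    expect_equal(find_pso(m, x2), p)
  }
  # a model biased to non-speech never fires
  m$head$b <- c(10, -10)
  expect_true(is.na(find_pso(m, x)))
})

test_that("relevance vanishes for zeroed input weights and passes a gradient check", {
  m <- nvad_model(4, 6, seed = 22)
  set.seed(18)
  x <- matrix(rnorm(80), 20, 4)
  sal <- relevance_scores(m, x, pso = 15)
  expect_equal(dim(sal$relevance), c(15, 4))
  expect_true(all(sal$relevance >= 0))
  expect_true(all(sal$electrode_argmax <= sal$pso_frame))

  # channel 2's input weights zeroed -> zero relevance on channel 2
  m0 <- m
  m0$layers[[1]]$f$Wx[2, ] <- 0
  sal0 <- relevance_scores(m0, x, pso = 15)
  expect_equal(sal0$electrode_max[2], 0)
  expect_gt(max(sal0$electrode_max[-2]), 0)

  # finite-difference oracle on the speech-class score at the PSO
  eps <- 1e-5
  score <- function(xx) {
    st <- NULL
    for (t in 1:15) {
      r <- ecogspeech:::rnn_step(m, xx[t, ], st)
      st <- r$state
    }
    r$logits[2]
  }
  for (probe in list(c(3, 1), c(15, 4), c(10, 2))) {
    x1 <- x; x1[probe[1], probe[2]] <- x1[probe[1], probe[2]] + eps
    x2 <- x; x2[probe[1], probe[2]] <- x2[probe[1], probe[2]] - eps
    num <- abs((score(x1) - score(x2)) / (2 * eps))
    expect_equal(sal$relevance[probe[1], probe[2]], num,
                 tolerance = 1e-4)
  }
  expect_error(relevance_scores(m, x, NA), "PSO")
})

test_that("channel repair averages 8-connected neighbours", {
  v <- matrix(0, 10, 64)
  gm <- default_grid_map(64)
  fr <- structure(list(values = v, channel_ids = 1:64, frame_shift_ms = 10,
                       window_ms = 50, normalized = TRUE, grid_map = gm),
                  class = "high_gamma_frames")
  # interior channel 19 (row 3, col 3): neighbours all set to 4
  nb_oracle <- function(ch, bad = integer()) {
    me <- gm[gm$channel == ch, ]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      hit <- gm$channel[gm$grid == me$grid & gm$row == me$row + dr &
                          gm$col == me$col + dc]
      nb <- c(nb, hit)
    }
    setdiff(nb, bad)
  }
  fr$values[, nb_oracle(19)] <- 4
  out <- repair_channel(fr, 19)
  expect_equal(out$values[, 19], rep(4, 10))

  # corner channel 1 has exactly 3 on-grid neighbours
  expect_length(nb_oracle(1), 3)
  fr2 <- fr
  fr2$values[, nb_oracle(1)] <- c(3)
  out2 <- repair_channel(fr2, 1)
  expect_equal(out2$values[, 1], rowMeans(fr2$values[, nb_oracle(1)]))

  # excluded bad neighbour matches the brute-force oracle
  set.seed(19)
  fr3 <- fr
  fr3$values <- matrix(rnorm(640), 10, 64)
  bad <- 20L
  out3 <- repair_channel(fr3, 19, bad = bad)
  expect_equal(out3$values[, 19],
               rowMeans(fr3$values[, nb_oracle(19, bad), drop = FALSE]))
  expect_error(repair_channel(fr, 1, bad = nb_oracle(1)), "neighbour")
})

test_that("contamination index is 1 for a perfectly leaked channel", {
  s <- small_session()
  # one channel carrying only the (decimated) audio: diagonal structure
  s2 <- inject_contamination(s, 5, gain = 1)
  pure <- s2$ecog$samples[, 5] - s$ecog$samples[, 5]
  s$ecog$samples[, 5] <- pure * 50
  rep_ <- contamination_audit(s$ecog, s$audio, n_perm = 200, seed = 2)
  expect_gt(rep_$table$index[5], 0.9)
  expect_true(rep_$table$flagged[5])
  expect_true(all(rep_$table$index >= -1 & rep_$table$index <= 1))
  expect_true(all(rep_$table$p > 0 & rep_$table$p <= 1))
})

test_that("permutation null yields approximately uniform p-values on clean data", {
  set.seed(20)
  ps <- numeric(0)
  for (run in 1:12) {
    rec <- ecog_recording(matrix(rnorm(20000 * 3), 20000, 3),
                          grid_map = data.frame(channel = 1:3, grid = 1,
                                                row = 1, col = 1:3))
    audio <- rnorm(20 * 16000) * 1e-3
    rep_ <- contamination_audit(rec, audio, n_perm = 200, seed = run)
    ps <- c(ps, rep_$table$p)
    expect_false(any(rep_$table$flagged))
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mel correlation behaves as a calibrated similarity", {
  set.seed(23)
  x <- rnorm(16000)
  expect_equal(as.numeric(mel_correlation(x, x)), 1.0)
  # independent noises decorrelate
  for (k in 1:10) {
    a <- rnorm(16000); b <- rnorm(16000)
    expect_lt(abs(mel_correlation(a, b)), 0.1)
  }
  # invariance to a global gain on both inputs
  tpl <- default_vocabulary()[[2]]
  v <- synth_word_audio(tpl, 0.8)
  w <- synth_word_audio(default_vocabulary()[[4]], 0.8)
  expect_equal(as.numeric(mel_correlation(3 * v, 3 * w)),
               as.numeric(mel_correlation(v, w)), tolerance = 1e-10)
})

test_that("frame-level Levenshtein distance matches brute-force oracles", {
  expect_equal(vad_levenshtein_ms(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(vad_levenshtein_ms(c(0, 0, 1, 1), c(0, 1, 1, 1)), 10)
  set.seed(24)
  for (k in 1:20) {
    a <- rbinom(sample(5:30, 1), 1, 0.5)
    b <- rbinom(sample(5:30, 1), 1, 0.5)
    expect_equal(vad_levenshtein_ms(a, b), vad_levenshtein_ms(b, a))
    # independent oracle: generalised string edit distance
    oracle <- utils::adist(paste(a, collapse = ""),
                           paste(b, collapse = ""))[1, 1]
    expect_equal(vad_levenshtein_ms(a, b), oracle * 10)
  }
})
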