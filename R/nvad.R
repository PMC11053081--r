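# Neural voice-activity detection (nVAD).
#
# A unidirectional recurrent detector: two stacked LSTM layers of 150 units
# over the selected high-gamma channels, with a two-unit linear head giving
# speech/non-speech logits per 10 ms frame. Trained with truncated
# backpropagation through time (window k2 = 100 frames repeated every
# k1 = 50), cross-entropy loss, 50% dropout, RMSprop-adapted SGD, and early
# stopping on held-out frame-wise accuracy. At run time the raw frame
# labels pass through a causal temporal-context correction, and each
# detected speech run is buffered with 0.5 s of context on both sides.

#' nVAD model
#'
#' @param input_size number of selected channels (default 64)
#' @param hidden_size LSTM units per layer (default 150)
#' @param seed initialisation seed
#' @return an `rnn_model` with a 2-unit linear head (logit order:
#'   non-speech, speech)
#' @export
nvad_model <- function(input_size = 64, hidden_size = 150, seed = 1) {
  rnn_model(input_size, hidden_size, n_layers = 2, output_size = 2,
            bidirectional = FALSE, seed = seed)
}

#' Training configuration for the nVAD detector
#'
#' @param k1 update interval in frames (backpropagation repeats every `k1`)
#' @param k2 unfolding length in frames per update (`k1 <= k2`)
#' @param dropout dropout probability between LSTM layers
#' @param lr initial learning rate of the RMSprop-adapted SGD optimiser
#' @param epochs maximum training epochs
#' @param chunk subsequence length used to batch long recordings
#' @param batch_size subsequences per parameter update
#' @param hidden_size LSTM units per layer
#' @return a list of class `nvad_config`
#' @export
nvad_config <- function(k1 = 50, k2 = 100, dropout = 0.5, lr = 1e-3,
                        epochs = 6, chunk = 2000, batch_size = 8,
                        hidden_size = 150) {
  if (k1 > k2) stop("k1 must not exceed k2")
  structure(list(k1 = k1, k2 = k2, dropout = dropout, lr = lr,
                 epochs = epochs, chunk = chunk, batch_size = batch_size,
                 hidden_size = hidden_size),
            class = "nvad_config")
}

# Chop sequences into fixed-length subsequences for lock-step batching.
chop_sequences <- function(x_list, y_list, chunk) {
  xs <- list(); ys <- list()
  for (i in seq_along(x_list)) {
    x <- x_list[[i]]; y <- y_list[[i]]
    stopifnot(nrow(x) == length(y))
    n_sub <- max(1, floor(nrow(x) / chunk))
    for (s in seq_len(n_sub)) {
      a <- (s - 1) * chunk + 1
      b <- if (s == n_sub) nrow(x) else s * chunk
      xs[[length(xs) + 1]] <- x[a:b, , drop = FALSE]
      ys[[length(ys) + 1]] <- y[a:b]
    }
  }
  list(x = xs, y = ys)
}

#' Train the nVAD detector
#'
#' Truncated BPTT: each subsequence is processed in overlapping windows of
#' `k2` frames advanced by `k1`; every window yields one cross-entropy
#' gradient step, with the recurrent state carried (detached) between
#' windows. After each epoch the frame-wise accuracy on the held-out split
#' is evaluated; the returned model is the weights snapshot with the best
#' validation accuracy (updated only on strict improvement).
#'
#' @param train_x,train_y training sequences: lists of frames-x-channels
#'   matrices and matching integer 0/1 label vectors
#' @param val_x,val_y held-out validation sequences (disjoint from training)
#' @param cfg an [nvad_config()]
#' @param seed seed controlling initialisation, batching and dropout
#' @return the best `rnn_model`, with attributes `history` (per-epoch
#'   data.frame of loss and validation accuracy) and `best_epoch`
#' @export
train_nvad <- function(train_x, train_y, val_x, val_y, cfg = nvad_config(),
                       seed = 7) {
  if (!is.list(train_x)) { train_x <- list(train_x); train_y <- list(train_y) }
  if (!is.list(val_x)) { val_x <- list(val_x); val_y <- list(val_y) }
  for (i in seq_along(train_x)) {
    if (nrow(train_x[[i]]) != length(train_y[[i]])) {
      stop("frame/label length mismatch in training sequence ", i)
    }
  }
  model <- nvad_model(ncol(train_x[[1]]), cfg$hidden_size, seed = seed)
  opt <- list(layers = rmsprop_init(model$layers),
              head = rmsprop_init(model$head))
  ch <- chop_sequences(train_x, train_y, cfg$chunk)
  n_sub <- length(ch$x)
  best <- list(model = model, acc = -Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_acc = numeric())

  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order_sub <- sample(n_sub)
      total_loss <- 0; n_loss <- 0
      for (b0 in seq(1, n_sub, by = cfg$batch_size)) {
        ids <- order_sub[b0:min(b0 + cfg$batch_size - 1, n_sub)]
        len <- min(vapply(ch$x[ids], nrow, 0L))
        B <- length(ids)
        state <- NULL
        for (s in seq(1, max(1, len - cfg$k1 + 1), by = cfg$k1)) {
          e <- min(s + cfg$k2 - 1, len)
          Tw <- e - s + 1
          X <- lapply(s:e, function(t) {
            do.call(rbind, lapply(ch$x[ids], function(m) m[t, ]))
          })
          yw <- vapply(s:e, function(t) {
            vapply(ch$y[ids], function(v) v[t], 0)
          }, numeric(B))
          fw <- rnn_forward(model, X, state = state, dropout = cfg$dropout,
                            keep_cache = TRUE)
          dY <- vector("list", Tw)
          for (t in seq_len(Tw)) {
            z <- fw$Y[[t]]
            z <- z - apply(z, 1, max)
            p <- exp(z) / rowSums(exp(z))
            tgt <- cbind(1 - yw[, t], yw[, t])
            total_loss <- total_loss - sum(log(pmax(p[cbind(seq_len(B),
                                                            yw[, t] + 1)],
                                                    1e-12)))
            n_loss <- n_loss + B
            dY[[t]] <- (p - tgt) / (B * Tw)
          }
          bk <- rnn_backward(model, fw$cache, dY)
          upd <- apply_update(model, bk$grads, opt, cfg$lr)
          model <- upd$model; opt <- upd$opt
          # carry the detached state from k1 frames into the window
          if (Tw > cfg$k1) {
            state <- state_at(fw, cfg$k1)
          } else {
            state <- fw$state
          }
        }
      }
      acc <- nvad_accuracy(model, val_x, val_y)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss = total_loss / max(n_loss, 1),
                                     val_acc = acc))
      if (acc > best$acc) best <- list(model = model, acc = acc,
                                       epoch = epoch)
    }
  })
  out <- best$model
  attr(out, "history") <- hist
  attr(out, "best_epoch") <- best$epoch
  attr(out, "val_accuracy") <- best$acc
  out
}

# Per-layer (h, c) at window-internal time t, read out of the forward cache.
state_at <- function(fw, t) {
  lapply(fw$cache$layer_caches, function(lc) {
    cc <- lc$f
    h <- if (t < cc$T_) cc$hp[[t + 1]] else NULL
    if (is.null(h)) h <- cc$hp[[cc$T_]]
    list(h = h, c = cc$cc[[t]])
  })
}

#' Frame-wise accuracy of an nVAD model
#'
#' @param model an nVAD `rnn_model`
#' @param x_list,y_list sequences and labels as in [train_nvad()]
#' @return fraction of frames whose argmax logit matches the label
#' @export
nvad_accuracy <- function(model, x_list, y_list) {
  if (!is.list(x_list)) { x_list <- list(x_list); y_list <- list(y_list) }
  n_ok <- 0; n <- 0
  for (i in seq_along(x_list)) {
    pred <- nvad_predict(model, x_list[[i]])
    n_ok <- n_ok + sum(pred == y_list[[i]])
    n <- n + length(pred)
  }
  n_ok / n
}

#' Raw frame predictions over a whole sequence
#'
#' Runs the detector frame by frame with threaded state — the same
#' arithmetic as streaming replay, so batch and streaming labels agree
#' exactly.
#'
#' @param model an nVAD `rnn_model`
#' @param frames frames-x-channels matrix
#' @param state optional initial state
#' @return integer vector of raw 0/1 predictions
#' @export
nvad_predict <- function(model, frames, state = NULL) {
  out <- integer(nrow(frames))
  for (t in seq_len(nrow(frames))) {
    r <- rnn_step(model, frames[t, ], state)
    state <- r$state
    out[t] <- as.integer(r$logits[2] > r$logits[1])
  }
  out
}

#' Single-frame streaming prediction
#'
#' @param model an nVAD `rnn_model`
#' @param frame one input frame (numeric vector over selected channels)
#' @param state recurrent state from the previous frame (`NULL` to start)
#' @return list with `label` (raw 0/1), `logits`, and `state` to thread into
#'   the next call
#' @export
stream_predict <- function(model, frame, state = NULL) {
  r <- rnn_step(model, frame, state)
  list(label = as.integer(r$logits[2] > r$logits[1]), logits = r$logits,
       state = r$state)
}

#' Causal temporal-context label correction
#'
#' The raw frame labels are smoothed by a causal majority vote over the
#' trailing `W` available frames, with two stabilisers: a transition from
#' speech to non-speech additionally requires `H` consecutive non-speech
#' votes (hangover), and after any state change the output is held for at
#' least `W` frames. The corrected stream therefore changes state at most
#' once within any `W`-frame window, realising smooth transitions between
#' speech and non-speech.
#'
#' @param raw integer vector of raw 0/1 labels
#' @param W majority-vote window length in frames (default 7)
#' @param H hangover length in frames (default 3)
#' @return corrected integer 0/1 vector of the same length
#' @export
correct_labels <- function(raw, W = 7, H = 3) {
  st <- correction_state(W, H)
  out <- integer(length(raw))
  for (t in seq_along(raw)) {
    r <- correct_step(st, raw[t])
    st <- r$state
    out[t] <- r$label
  }
  out
}

#' @rdname correct_labels
#' @param state a correction state from [correction_state()] / a previous
#'   [correct_step()] call
#' @param raw_t one raw label
#' @return `correct_step`: list with the corrected `label` and new `state`
#' @export
correct_step <- function(state, raw_t) {
  n <- min(state$seen + 1L, state$W)
  buf <- c(state$buf, raw_t)
  if (length(buf) > state$W) buf <- buf[-1]
  vote <- as.integer(2L * sum(buf) > n)
  cur <- state$cur
  since <- state$since + 1L
  zeros <- state$zeros
  if (cur == 0L) {
    if (vote == 1L && since >= state$W) {
      cur <- 1L; since <- 0L; zeros <- 0L
    }
  } else {
    zeros <- if (vote == 0L) zeros + 1L else 0L
    if (zeros >= state$H && since >= state$W) {
      cur <- 0L; since <- 0L; zeros <- 0L
    }
  }
  list(label = cur,
       state = list(W = state$W, H = state$H, buf = buf,
                    seen = state$seen + 1L, cur = cur, since = since,
                    zeros = zeros))
}

#' @rdname correct_labels
#' @export
correction_state <- function(W = 7, H = 3) {
  list(W = as.integer(W), H = as.integer(H), buf = integer(), seen = 0L,
       cur = 0L, since = as.integer(W), zeros = 0L)
}

#' Extract buffered speech segments
#'
#' A segment is emitted for every run of corrected speech frames; its slice
#' spans the run plus `context` frames (0.5 s at default) on each side,
#' clipped at the stream bounds. Adjacent segments may overlap in their
#' context.
#'
#' @param corrected corrected 0/1 label vector
#' @param frames frames-x-channels matrix (or `high_gamma_frames`) aligned
#'   with `corrected`
#' @param context context frames on each side (default 50 = 0.5 s)
#' @return list of `speech_segment` objects with fields `frames` (slice),
#'   `onset_frame`, `offset_frame`, `start_frame`, `end_frame` (all 1-based,
#'   inclusive)
#' @export
extract_segments <- function(corrected, frames, context = 50) {
  if (inherits(frames, "high_gamma_frames")) frames <- frames$values
  nf <- if (is.null(frames)) length(corrected) else nrow(frames)
  r <- rle(corrected)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] != 1) next
    a <- max(1, starts[i] - context)
    b <- min(nf, ends[i] + context)
    segs[[length(segs) + 1]] <- structure(
      list(frames = if (is.null(frames)) NULL else
        frames[a:b, , drop = FALSE],
        onset_frame = as.integer(starts[i]), offset_frame = as.integer(ends[i]),
        start_frame = as.integer(a), end_frame = as.integer(b),
        context = context),
      class = "speech_segment")
  }
  segs
}

#' @export
print.speech_segment <- function(x, ...) {
  cat(sprintf("<speech_segment> speech [%d, %d], slice [%d, %d] (%d frames)\n",
              x$onset_frame, x$offset_frame, x$start_frame, x$end_frame,
              x$end_frame - x$start_frame + 1))
  invisible(x)
}
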