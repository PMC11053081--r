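# Bidirectional decoding model.
#
# Regression from a buffered speech segment of high-gamma frames to the
# per-frame acoustic features (18 Bark cepstral + 2 pitch). Two stacked
# bidirectional LSTM layers with 100 units per direction and a 20-unit
# linear head; with 64 input channels this architecture has exactly 378,420
# trainable weights. Because the model is bidirectional it consumes whole
# finalized segments (standard BPTT over each segment), which is what delays
# the acoustic feedback until after the speaker finishes a word.

N_ACOUSTIC <- 20L

#' Decoder model
#'
#' @param input_size number of selected channels (default 64)
#' @param hidden_size LSTM units per direction per layer (default 100)
#' @param seed initialisation seed
#' @return an `rnn_model` (bidirectional) with a 20-unit linear head
#' @export
decoder_model <- function(input_size = 64, hidden_size = 100, seed = 1) {
  rnn_model(input_size, hidden_size, n_layers = 2,
            output_size = N_ACOUSTIC, bidirectional = TRUE, seed = seed)
}

#' Training configuration for the decoder
#'
#' @param dropout dropout probability between LSTM layers
#' @param lr initial learning rate (RMSprop-adapted SGD)
#' @param epochs maximum training epochs
#' @param batch_size segments per parameter update
#' @param hidden_size LSTM units per direction
#' @return a list of class `decoder_config`
#' @export
decoder_config <- function(dropout = 0.5, lr = 1e-3, epochs = 40,
                           batch_size = 16, hidden_size = 100) {
  structure(list(dropout = dropout, lr = lr, epochs = epochs,
                 batch_size = batch_size, hidden_size = hidden_size),
            class = "decoder_config")
}

# Coerce a speech_segment / high_gamma_frames / matrix to a plain matrix.
seg_matrix <- function(s) {
  if (inherits(s, "speech_segment")) return(s$frames)
  if (inherits(s, "high_gamma_frames")) return(s$values)
  as.matrix(s)
}

# Coerce acoustic_features / matrix to the frames x 20 target matrix.
target_matrix <- function(a) {
  if (inherits(a, "acoustic_features")) {
    return(cbind(a$cepstrum, a$pitch_period, a$pitch_corr))
  }
  as.matrix(a)
}

#' Train the bidirectional decoder
#'
#' Standard (full) BPTT over each buffered segment with a mean-squared-error
#' objective on per-feature standardised targets; 50% dropout; RMSprop-
#' adapted SGD. Weights are kept only when the loss on the held-out
#' validation segments strictly improves.
#'
#' @param train_segments,train_targets lists of segments (frames x channels)
#'   and aligned acoustic targets (frames x 20); frame counts must match per
#'   segment
#' @param val_segments,val_targets held-out validation split
#' @param cfg a [decoder_config()]
#' @param seed seed controlling initialisation, batching and dropout
#' @return the best `rnn_model` with attributes `history`, `best_epoch`,
#'   `feat_mean`, `feat_sd` (the target standardisation, inverted by
#'   [decode_segment()])
#' @export
train_decoder <- function(train_segments, train_targets, val_segments,
                          val_targets, cfg = decoder_config(), seed = 7) {
  xs <- lapply(train_segments, seg_matrix)
  ys <- lapply(train_targets, target_matrix)
  for (i in seq_along(xs)) {
    if (nrow(xs[[i]]) != nrow(ys[[i]])) {
      stop("segment/target frame count mismatch in segment ", i)
    }
  }
  vxs <- lapply(val_segments, seg_matrix)
  vys <- lapply(val_targets, target_matrix)
  all_y <- do.call(rbind, ys)
  feat_mean <- colMeans(all_y)
  feat_sd <- pmax(apply(all_y, 2, stats::sd), 1e-8)
  std <- function(m) sweep(sweep(m, 2, feat_mean), 2, feat_sd, "/")
  ys <- lapply(ys, std)
  vys_s <- lapply(vys, std)

  model <- decoder_model(ncol(xs[[1]]), cfg$hidden_size, seed = seed)
  opt <- list(layers = rmsprop_init(model$layers),
              head = rmsprop_init(model$head))
  n_seg <- length(xs)
  best <- list(model = model, loss = Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_loss = numeric())

  val_loss <- function(m) {
    tot <- 0; n <- 0
    for (i in seq_along(vxs)) {
      pred <- rnn_forward(m, vxs[[i]])$Y
      pm <- do.call(rbind, pred)
      tot <- tot + sum((pm - vys_s[[i]])^2)
      n <- n + length(pm)
    }
    tot / n
  }

  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n_seg)
      tr_loss <- 0; tr_n <- 0
      for (b0 in seq(1, n_seg, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1, n_seg)]
        B <- length(ids)
        lens <- vapply(xs[ids], nrow, 0L)
        Tmax <- max(lens)
        nc <- ncol(xs[[1]])
        X <- lapply(seq_len(Tmax), function(t) {
          m <- matrix(0, B, nc)
          for (j in seq_len(B)) if (t <= lens[j]) m[j, ] <- xs[[ids[j]]][t, ]
          m
        })
        fw <- rnn_forward(model, X, dropout = cfg$dropout, keep_cache = TRUE)
        n_valid <- sum(lens) * N_ACOUSTIC
        dY <- vector("list", Tmax)
        for (t in seq_len(Tmax)) {
          tgt <- matrix(0, B, N_ACOUSTIC)
          mask <- as.numeric(t <= lens)
          for (j in seq_len(B)) if (t <= lens[j]) tgt[j, ] <- ys[[ids[j]]][t, ]
          resid <- (fw$Y[[t]] - tgt) * mask
          tr_loss <- tr_loss + sum(resid^2)
          tr_n <- tr_n + sum(mask) * N_ACOUSTIC
          dY[[t]] <- 2 * resid / n_valid
        }
        bk <- rnn_backward(model, fw$cache, dY)
        upd <- apply_update(model, bk$grads, opt, cfg$lr)
        model <- upd$model; opt <- upd$opt
      }
      vl <- val_loss(model)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = tr_loss / tr_n,
                                     val_loss = vl))
      if (vl < best$loss) best <- list(model = model, loss = vl,
                                       epoch = epoch)
    }
  })
  out <- best$model
  attr(out, "history") <- hist
  attr(out, "best_epoch") <- best$epoch
  attr(out, "feat_mean") <- feat_mean
  attr(out, "feat_sd") <- feat_sd
  out
}

#' Decode one buffered segment into acoustic features
#'
#' Forward pass of the bidirectional decoder over a finalized segment; one
#' 20-vector per input frame, de-standardised into codec units. Pitch
#' period is clipped to the codec's search range and pitch correlation to
#' \[0, 1\].
#'
#' @param model a trained decoder from [train_decoder()]
#' @param segment a `speech_segment` or frames-x-channels matrix (non-empty)
#' @return an `acoustic_features` object with one frame per input frame
#' @export
decode_segment <- function(model, segment) {
  x <- seg_matrix(segment)
  if (is.null(x) || nrow(x) == 0) stop("cannot decode an empty segment")
  pred <- do.call(rbind, rnn_forward(model, x)$Y)
  fm <- attr(model, "feat_mean"); fs <- attr(model, "feat_sd")
  if (!is.null(fm)) pred <- sweep(sweep(pred, 2, fs, "*"), 2, fm, "+")
  structure(list(cepstrum = pred[, seq_len(N_ACOUSTIC - 2), drop = FALSE],
                 pitch_period = pmin(pmax(round(pred[, N_ACOUSTIC - 1]),
                                          floor(FS_AUDIO / PITCH_MAX_HZ)),
                                     ceiling(FS_AUDIO / PITCH_MIN_HZ)),
                 pitch_corr = pmin(1, pmax(0, pred[, N_ACOUSTIC])),
                 frame_shift_ms = FRAME_SHIFT_MS),
            class = "acoustic_features")
}
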