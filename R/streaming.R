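# Streaming replay engine.
#
# The closed-loop system as a directed acyclic graph of processing units
# exchanging 40 ms packets through a publish/subscribe dispatcher: source ->
# features (CAR + causal filtering + framing + normalisation) -> nVAD
# (streaming prediction + temporal correction) -> segment buffer (ring
# buffer with 0.5 s context) -> decoder -> vocoder -> sink, plus logger
# units hanging off the main path. Real-time transport (sockets, shared
# memory, loudspeakers) is replaced by deterministic in-process message
# passing and file sinks; packet size, ordering and fan-out semantics are
# preserved. All timing is accounted in stream time (frame counts), never
# wall clock.

#' Fixed-capacity ring buffer
#'
#' @param capacity maximum number of stored elements (fixed at build time)
#' @return an object with methods `$append(x)` (constant amortised),
#'   `$snapshot(n)` (last `n` elements in arrival order), and `$size()`
#' @export
ring_buffer <- function(capacity) {
  stopifnot(capacity >= 1)
  buf <- vector("list", capacity)
  head <- 0L   # slot written most recently
  n <- 0L
  append <- function(x) {
    head <<- head %% capacity + 1L
    buf[[head]] <<- x
    n <<- min(n + 1L, capacity)
    invisible(NULL)
  }
  snapshot <- function(k) {
    if (k > n) stop("snapshot(", k, ") exceeds the ", n, " stored elements")
    if (k == 0L) return(list())
    idx <- ((head - k + seq_len(k) - 1L) %% capacity) + 1L
    buf[idx]
  }
  structure(list(append = append, snapshot = snapshot, size = function() n,
                 capacity = capacity),
            class = "ring_buffer")
}

#' Define a processing unit
#'
#' A unit is a named node of the streaming graph: it subscribes to the
#' output topics of other units, and its handler is called once per round
#' with the messages published this round on those topics.
#'
#' @param name unique unit name (also its output topic)
#' @param fn handler `function(inputs)` returning the unit's output message
#'   for this round, or `NULL` to publish nothing; state is typically kept
#'   in the handler's closure environment
#' @param subscribes character vector of topic names
#' @param logger logger units are leaves: nothing may subscribe to them,
#'   and disabling them cannot alter the main path
#' @return a `stream_unit`
#' @export
stream_unit <- function(name, fn, subscribes = character(), logger = FALSE) {
  structure(list(name = name, fn = fn, subscribes = subscribes,
                 logger = logger),
            class = "stream_unit")
}

#' Build and validate a unit graph
#'
#' Checks that all subscriptions resolve, that logger units are leaves, and
#' that the publisher/subscriber graph is acyclic; units are stored in a
#' topological order so each round is a single deterministic sweep.
#'
#' @param units list of [stream_unit()]s
#' @return a `unit_graph`
#' @export
build_unit_graph <- function(units) {
  names(units) <- vapply(units, `[[`, "", "name")
  if (anyDuplicated(names(units))) stop("duplicate unit names")
  for (u in units) {
    missing <- setdiff(u$subscribes, c(names(units), "source"))
    if (length(missing)) {
      stop("unit '", u$name, "' subscribes to unknown topic(s): ",
           paste(missing, collapse = ", "))
    }
    bad <- intersect(u$subscribes,
                     names(units)[vapply(units, `[[`, TRUE, "logger")])
    if (length(bad)) {
      stop("unit '", u$name, "' subscribes to logger unit(s): ",
           paste(bad, collapse = ", "))
    }
  }
  # Kahn topological sort over publisher -> subscriber edges
  order <- character()
  placed <- "source"
  remaining <- names(units)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      all(units[[nm]]$subscribes %in% placed)
    }, TRUE)]
    if (!length(ready)) stop("unit graph contains a cycle")
    order <- c(order, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(units = units[order]), class = "unit_graph")
}

# One dispatch round: push a source message through the graph.
graph_round <- function(graph, packet) {
  msgs <- list(source = packet)
  for (u in graph$units) {
    inputs <- msgs[intersect(u$subscribes, names(msgs))]
    if (length(inputs) == 0 && length(u$subscribes) > 0) next
    out <- u$fn(inputs)
    if (!is.null(out) && !u$logger) msgs[[u$name]] <- out
  }
  msgs
}

#' Replay configuration
#'
#' @param packet_ms packet length in milliseconds (default 40)
#' @param context_frames context on each side of a speech run (default 50)
#' @param W,H temporal-correction window and hangover (see
#'   [correct_labels()])
#' @param buffer_capacity frame ring-buffer capacity
#' @param vocoder_seed base seed for the vocoder noise excitation
#' @param loggers enable the logger units
#' @return list of class `replay_config`
#' @export
replay_config <- function(packet_ms = 40, context_frames = 50, W = 7, H = 3,
                          buffer_capacity = 3000, vocoder_seed = 1,
                          loggers = TRUE) {
  structure(list(packet_ms = packet_ms, context_frames = context_frames,
                 W = W, H = H, buffer_capacity = buffer_capacity,
                 vocoder_seed = vocoder_seed, loggers = loggers),
            class = "replay_config")
}

#' Replay a recording through the closed-loop graph
#'
#' The recording is chopped into 40 ms packets and pushed through the unit
#' graph. Every detected speech segment is decoded and vocoded once
#' finalized (its right context complete), and its waveform is appended to
#' the session audio at its emission time — always at or after the
#' segment's offset, i.e. delayed auditory feedback.
#'
#' @param rec an [ecog_recording]
#' @param nvad trained nVAD model
#' @param decoder trained decoder model
#' @param stats baseline statistics for normalisation
#' @param channels selected channel ids (must match both models' input
#'   width)
#' @param cfg a [replay_config()]
#' @return a `session_result`: `segments` (data.frame with onset/offset,
#'   slice bounds, emission frame and decode latency in frames), `audio`
#'   (16 kHz feedback track), `n_packets`, and — when loggers are enabled —
#'   `features`, `raw_labels`, `corrected_labels` as logged on the bus
#' @export
run_replay <- function(rec, nvad, decoder, stats, channels,
                       cfg = replay_config()) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (nvad$input_size != length(channels) ||
      decoder$input_size != length(channels)) {
    stop("model input width does not match the selected channel set")
  }
  if (!identical(as.integer(channels), as.integer(stats$channel_ids))) {
    stop("baseline statistics do not cover the selected channel set")
  }
  packet_len <- round(FS_NEURAL * cfg$packet_ms / 1000)
  win <- round(FS_NEURAL * FRAME_WINDOW_MS / 1000)
  hop <- round(FS_NEURAL * FRAME_SHIFT_MS / 1000)
  grid_map <- rec$grid_map
  good_by_grid <- lapply(split(grid_map$channel, grid_map$grid),
                         setdiff, y = rec$bad_channels)

  # --- feature unit state
  filt_states <- vector("list", length(channels))
  sample_buf <- matrix(0, 0, length(channels))
  next_start <- 1L
  feature_unit <- stream_unit("features", function(inputs) {
    pkt <- inputs$source
    car <- pkt
    for (g in seq_along(good_by_grid)) {
      gc <- good_by_grid[[g]]
      car[, gc] <- pkt[, gc, drop = FALSE] -
        rowMeans(pkt[, gc, drop = FALSE])
    }
    filt <- matrix(0, nrow(pkt), length(channels))
    for (j in seq_along(channels)) {
      r <- highgamma_filter(car[, channels[j]], state = filt_states[[j]],
                            return_state = TRUE)
      filt_states[[j]] <<- r$state
      filt[, j] <- r$y
    }
    sample_buf <<- rbind(sample_buf, filt)
    frames <- list()
    # frame starting at absolute sample next_start needs win samples;
    # sample_buf holds samples from absolute index buf_origin
    repeat {
      avail <- next_start + win - 1L <= buf_offset + nrow(sample_buf)
      if (!avail) break
      rel <- next_start - buf_offset
      w <- sample_buf[rel:(rel + win - 1L), , drop = FALSE]
      lp <- log(colMeans(w^2) + 1e-12)
      frames[[length(frames) + 1]] <- (lp - stats$mean) / stats$sd
      next_start <<- next_start + hop
      # drop samples no longer needed
      drop_n <- next_start - buf_offset - 1L
      if (drop_n > 0) {
        sample_buf <<- sample_buf[-seq_len(drop_n), , drop = FALSE]
        buf_offset <<- buf_offset + drop_n
      }
    }
    if (length(frames)) frames else NULL
  }, subscribes = "source")
  buf_offset <- 0L   # absolute index of the sample before sample_buf[1, ]

  # --- nVAD unit state
  rnn_state <- NULL
  corr_state <- correction_state(cfg$W, cfg$H)
  frame_idx <- 0L
  nvad_unit <- stream_unit("nvad", function(inputs) {
    out <- list()
    for (fr in inputs$features) {
      sp <- stream_predict(nvad, fr, rnn_state)
      rnn_state <<- sp$state
      cs <- correct_step(corr_state, sp$label)
      corr_state <<- cs$state
      frame_idx <<- frame_idx + 1L
      out[[length(out) + 1]] <- list(frame = frame_idx, raw = sp$label,
                                     corrected = cs$label,
                                     features = fr)
    }
    if (length(out)) out else NULL
  }, subscribes = "features")

  # --- segment buffer unit state
  fbuf <- ring_buffer(cfg$buffer_capacity)
  prev_corr <- 0L
  run_onset <- NA_integer_
  pending <- list()
  segment_unit <- stream_unit("segmenter", function(inputs) {
    emitted <- list()
    for (rec_t in inputs$nvad) {
      fbuf$append(rec_t$features)
      t <- rec_t$frame
      if (rec_t$corrected == 1L && prev_corr == 0L) run_onset <<- t
      if (rec_t$corrected == 0L && prev_corr == 1L) {
        pending[[length(pending) + 1]] <<- list(onset = run_onset,
                                                offset = t - 1L)
        run_onset <<- NA_integer_
      }
      prev_corr <<- rec_t$corrected
      # finalize pending segments whose right context is complete
      still <- list()
      for (p in pending) {
        if (t >= p$offset + cfg$context_frames) {
          a <- max(1L, p$onset - cfg$context_frames)
          b <- p$offset + cfg$context_frames
          k <- t - a + 1L
          sl <- fbuf$snapshot(min(k, fbuf$size()))
          sl <- sl[seq_len(b - a + 1L)]
          emitted[[length(emitted) + 1]] <- structure(
            list(frames = do.call(rbind, sl), onset_frame = p$onset,
                 offset_frame = p$offset, start_frame = a, end_frame = b,
                 context = cfg$context_frames, emit_frame = t),
            class = "speech_segment")
        } else {
          still[[length(still) + 1]] <- p
        }
      }
      pending <<- still
    }
    if (length(emitted)) emitted else NULL
  }, subscribes = "nvad")

  # --- decoder + vocoder units
  seg_count <- 0L
  decoder_unit <- stream_unit("decoder", function(inputs) {
    lapply(inputs$segmenter, function(seg) {
      list(segment = seg, features = decode_segment(decoder, seg))
    })
  }, subscribes = "segmenter")
  vocoder_unit <- stream_unit("vocoder", function(inputs) {
    lapply(inputs$decoder, function(d) {
      seg_count <<- seg_count + 1L
      d$wave <- synthesize_audio(d$features,
                                 seed = cfg$vocoder_seed + seg_count)
      d
    })
  }, subscribes = "decoder")

  # --- sink and loggers
  n_samples <- nrow(rec$samples)
  audio_out <- numeric(ceiling(n_samples / FS_NEURAL * FS_AUDIO) +
                         4 * FS_AUDIO)
  seg_log <- list()
  sink_unit <- stream_unit("sink", function(inputs) {
    for (d in inputs$vocoder) {
      seg <- d$segment
      at <- round((seg$emit_frame - 1) * FS_AUDIO * FRAME_SHIFT_MS / 1000)
      idx <- at + seq_along(d$wave)
      idx <- idx[idx <= length(audio_out)]
      audio_out[idx] <<- audio_out[idx] + d$wave[seq_along(idx)]
      seg_log[[length(seg_log) + 1]] <<- data.frame(
        onset_frame = seg$onset_frame, offset_frame = seg$offset_frame,
        start_frame = seg$start_frame, end_frame = seg$end_frame,
        emit_frame = seg$emit_frame,
        latency_frames = seg$emit_frame - seg$offset_frame)
    }
    NULL
  }, subscribes = "vocoder")

  log_features <- list(); log_raw <- integer(); log_corr <- integer()
  units <- list(feature_unit, nvad_unit, segment_unit, decoder_unit,
                vocoder_unit, sink_unit)
  if (cfg$loggers) {
    units <- c(units, list(
      stream_unit("feature_logger", function(inputs) {
        log_features[[length(log_features) + 1]] <<-
          do.call(rbind, inputs$features)
        NULL
      }, subscribes = "features", logger = TRUE),
      stream_unit("label_logger", function(inputs) {
        for (r in inputs$nvad) {
          log_raw[length(log_raw) + 1] <<- r$raw
          log_corr[length(log_corr) + 1] <<- r$corrected
        }
        NULL
      }, subscribes = "nvad", logger = TRUE)))
  }
  graph <- build_unit_graph(units)

  n_packets <- floor(n_samples / packet_len)
  for (p in seq_len(n_packets)) {
    pkt <- rec$samples[(p - 1) * packet_len + seq_len(packet_len), ,
                       drop = FALSE]
    graph_round(graph, pkt)
  }

  segments <- if (length(seg_log)) do.call(rbind, seg_log) else
    data.frame(onset_frame = integer(), offset_frame = integer(),
               start_frame = integer(), end_frame = integer(),
               emit_frame = integer(), latency_frames = integer())
  res <- list(segments = segments, audio = audio_out,
              n_packets = n_packets, n_frames = frame_idx)
  if (cfg$loggers) {
    res$features <- do.call(rbind, log_features)
    res$raw_labels <- log_raw
    res$corrected_labels <- log_corr
  }
  structure(res, class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "<session_result> %d packets, %d frames, %d synthesized segments\n",
    x$n_packets, x$n_frames, nrow(x$segments)))
  invisible(x)
}
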