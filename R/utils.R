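# Shared constants and small numeric helpers.

# Frame grid used throughout the pipeline: 10 ms shift, 50 ms analysis window.
FRAME_SHIFT_MS <- 10
FRAME_WINDOW_MS <- 50
FS_NEURAL <- 1000L
FS_AUDIO <- 16000L

#' Number of analysis frames for a signal
#'
#' Left-aligned, half-open framing: frame `t` (0-based) covers samples
#' `[t * shift, t * shift + window)`. The last frame must fit entirely.
#'
#' @param n_samples signal length in samples
#' @param fs sampling rate in Hz
#' @param shift_ms frame shift in milliseconds
#' @param window_ms window length in milliseconds
#' @return integer frame count, `floor((n - window) / shift) + 1`
#' @export
n_frames <- function(n_samples, fs,
                     shift_ms = FRAME_SHIFT_MS, window_ms = FRAME_WINDOW_MS) {
  shift <- round(fs * shift_ms / 1000)
  window <- round(fs * window_ms / 1000)
  if (n_samples < window) return(0L)
  as.integer(floor((n_samples - window) / shift) + 1L)
}

# Index matrix for framing: rows are frames, columns the window samples.
frame_index_matrix <- function(n_samples, fs, shift_ms = FRAME_SHIFT_MS,
                               window_ms = FRAME_WINDOW_MS) {
  shift <- round(fs * shift_ms / 1000)
  window <- round(fs * window_ms / 1000)
  nf <- n_frames(n_samples, fs, shift_ms, window_ms)
  if (nf == 0L) return(matrix(integer(0), 0, window))
  starts <- (seq_len(nf) - 1L) * shift
  outer(starts, seq_len(window), `+`)
}

#' Short-time Fourier transform magnitude
#'
#' Hann-windowed STFT. Frames follow the shared left-aligned 10 ms grid so
#' that spectral frames line up one-to-one with high-gamma feature frames.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param shift_ms,window_ms frame grid (defaults 10/50 ms)
#' @param nfft FFT length (default: next power of two >= window)
#' @return matrix `nfft/2 + 1` frequency bins x frames of magnitudes, with
#'   attribute `freqs` (bin centre frequencies in Hz)
#' @export
stft_mag <- function(x, fs, shift_ms = FRAME_SHIFT_MS,
                     window_ms = FRAME_WINDOW_MS, nfft = NULL) {
  window <- round(fs * window_ms / 1000)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(window))
  idx <- frame_index_matrix(length(x), fs, shift_ms, window_ms)
  nf <- nrow(idx)
  win <- hann_window(window)
  frames <- matrix(0, nfft, max(nf, 1L))
  if (nf > 0L) {
    fm <- matrix(x[t(idx)], nrow = ncol(idx)) * win
    frames[seq_len(window), seq_len(nf)] <- fm
  } else {
    frames <- matrix(0, nfft, 0)
  }
  spec <- stats::mvfft(frames)
  keep <- seq_len(nfft / 2 + 1)
  out <- Mod(spec[keep, , drop = FALSE])
  attr(out, "freqs") <- (keep - 1) * fs / nfft
  out
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Orthonormal DCT-II and its inverse (DCT-III), applied to columns.
dct_matrix <- function(n) {
  k <- seq_len(n) - 1
  m <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Read a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/WAVE reader for the formats this package writes.
#'
#' @param path file path
#' @return numeric vector in \[-1, 1\] with attribute `fs`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fs <- NULL; bits <- NULL; n_ch <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little",
                     signed = FALSE)
      n_ch <- fmt[2]
      fs <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data)) stop("no data chunk in ", path)
  if (!identical(bits, 16L) && !identical(bits, 16)) {
    stop("only 16-bit PCM supported")
  }
  x <- data / 32768
  if (!is.null(n_ch) && n_ch > 1) x <- x[seq(1, length(x), by = n_ch)]
  attr(x, "fs") <- fs
  x
}

#' Write a 16-bit PCM WAV file
#'
#' @param x numeric vector in \[-1, 1\] (clipped)
#' @param path output file path
#' @param fs sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(x, path, fs = FS_AUDIO) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards so library internals never perturb user-level streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
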