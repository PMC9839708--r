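# Time-frequency preprocessing: short-time Fourier magnitude, per-axis
# z-scoring, and the two-channel (row-normalized / column-normalized)
# spectrogram tensor consumed by the autoencoder.

#' Spectrogram configuration
#'
#' @param window_size STFT window length in samples.
#' @param hop frame advance in samples (window_size - overlap).
#' @param log_transform apply `log(1 + magnitude)` before normalization;
#'   compresses the dynamic range between mains peaks and background.
#' @param amplitude_norm rescale the segment to unit RMS before the STFT.
#'   Removes acquisition-gain differences between channels and makes the
#'   tensor exactly invariant to input rescaling.
#' @param eps zero-variance guard for the z-scoring.
#' @return a `spectro_config` list.
#' @export
spectro_config <- function(window_size = 256L, hop = 128L,
                           log_transform = TRUE, amplitude_norm = TRUE,
                           eps = 1e-8) {
  if (window_size < 2 || hop < 1) {
    ieeg_error("window_size must be >= 2 and hop >= 1", "ieegsift_bad_params")
  }
  structure(list(window_size = as.integer(window_size), hop = as.integer(hop),
                 log_transform = isTRUE(log_transform),
                 amplitude_norm = isTRUE(amplitude_norm), eps = eps),
            class = "spectro_config")
}

#' Short-time Fourier magnitude of a signal
#'
#' Frames start at samples `0, hop, 2*hop, ...`; a trailing partial frame is
#' discarded. Each frame is Hann-windowed and the one-sided DFT magnitude is
#' returned, so the output has `window_size/2 + 1` frequency rows and
#' `floor((L - window_size)/hop) + 1` time columns.
#'
#' @param samples numeric vector of length `L >= window_size`.
#' @param window_size window length in samples.
#' @param hop frame advance in samples.
#' @return numeric matrix `[F, T]` of magnitudes.
#' @export
stft_magnitude <- function(samples, window_size = 256L, hop = 128L) {
  L <- length(samples)
  if (L < window_size) {
    ieeg_error(sprintf("signal length %d is shorter than the %d-sample window",
                       L, window_size), "ieegsift_short_signal")
  }
  assert_finite(samples, "input signal")
  n_frames <- (L - window_size) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) samples[(s + 1L):(s + window_size)],
                   numeric(window_size))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window_size - 1)) / (window_size - 1))
  spec <- stats::mvfft(frames * w)
  Mod(spec[1:(window_size %/% 2L + 1L), , drop = FALSE])
}

#' Z-score a matrix along rows or columns
#'
#' Each slice along the chosen axis is replaced by `(slice - mean)/std` with
#' the population (divide-by-n) standard deviation; slices whose std does not
#' exceed `eps` map to all zeros.
#'
#' @param m numeric matrix.
#' @param axis `"row"` or `"column"`.
#' @param eps zero-variance guard.
#' @return matrix of the same shape.
#' @export
normalize_axis <- function(m, axis = c("row", "column"), eps = 1e-8) {
  axis <- match.arg(axis)
  if (!all(is.finite(m))) {
    ieeg_error("normalize_axis requires finite input", "ieegsift_nonfinite")
  }
  if (axis == "column") return(t(normalize_axis(t(m), "row", eps)))
  n <- ncol(m)
  mu <- rowMeans(m)
  sd_pop <- sqrt(pmax(rowMeans(m * m) - mu * mu, 0))
  live <- sd_pop > eps
  out <- (m - mu) / ifelse(live, sd_pop, 1)
  out[!live, ] <- 0
  out
}

#' Build the two-channel normalized spectrogram tensor of a segment
#'
#' Computes the STFT magnitude, optionally applies `log(1 + m)`, and stacks
#' the row-normalized matrix (channel 1) and the column-normalized matrix
#' (channel 2) into a `[2, F, T]` array.
#'
#' @param segment a `segment_record` (or any list with `samples`,
#'   `sampling_rate_hz` and `segment_id`).
#' @param config a [spectro_config()].
#' @return a `spectrogram_tensor`: list with `values` (`[2, F, T]` array) and
#'   metadata fields `window_size`, `hop`, `sampling_rate_hz`, `segment_id`.
#' @export
build_tensor <- function(segment, config = spectro_config()) {
  samples <- segment$samples
  if (config$amplitude_norm) {
    rms <- sqrt(mean(samples^2))
    if (rms > 0) samples <- samples / rms
  }
  mag <- stft_magnitude(samples, config$window_size, config$hop)
  if (config$log_transform) mag <- log1p(mag)
  ch_row <- normalize_axis(mag, "row", config$eps)
  ch_col <- normalize_axis(mag, "column", config$eps)
  values <- array(0, dim = c(2L, nrow(mag), ncol(mag)))
  values[1L, , ] <- ch_row
  values[2L, , ] <- ch_col
  structure(
    list(values = values, window_size = config$window_size, hop = config$hop,
         sampling_rate_hz = segment$sampling_rate_hz,
         segment_id = segment$segment_id %||% NA_character_),
    class = "spectrogram_tensor"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert segments to a frame-sequence array for the autoencoder
#'
#' Each tensor becomes a sequence of `T` frames; a frame is the 2F-length
#' concatenation of the two channels' frequency columns at one time step.
#'
#' @param segments list of `segment_record`s.
#' @param config a [spectro_config()].
#' @return array `[n, T, 2F]` with `dimnames[[1]]` the segment ids.
#' @export
tensor_stack <- function(segments, config = spectro_config()) {
  tensors <- lapply(segments, build_tensor, config = config)
  frames_of <- function(tn) {
    d <- dim(tn$values)                       # 2 x F x T
    t(rbind(tn$values[1L, , ], tn$values[2L, , ]))   # T x 2F
  }
  mats <- lapply(tensors, frames_of)
  n <- length(mats)
  TT <- nrow(mats[[1]])
  P <- ncol(mats[[1]])
  out <- array(0, dim = c(n, TT, P))
  for (i in seq_len(n)) out[i, , ] <- mats[[i]]
  dimnames(out) <- list(vapply(tensors, function(x) x$segment_id, character(1)),
                        NULL, NULL)
  out
}

# single tensor -> T x 2F frame matrix
tensor_frames <- function(tensor) {
  t(rbind(tensor$values[1L, , ], tensor$values[2L, , ]))
}
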