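# Synthetic iEEG segment generator.
#
# Emulates the four segment classes used for semi-supervised iEEG
# classification: 0 = power-line noise, 1 = muscle artifact, 2 = pathological
# activity (interictal epileptiform discharges, optionally with
# high-frequency-oscillation bursts), 3 = physiological background.

CLASS_CODES <- 0:3
CLASS_NAMES <- c(
  "0" = "power-line noise",
  "1" = "artifact",
  "2" = "pathological",
  "3" = "physiological"
)

#' Parameters of the synthetic iEEG generator
#'
#' Bundles every knob of the four-class segment generator. Defaults describe a
#' desk-scale 512 Hz setting; set `sampling_rate_hz = 5000` for clinical-scale
#' 3-s segments of 15,000 samples.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param segment_seconds segment duration in seconds; `sampling_rate_hz *
#'   segment_seconds` must be a whole number of samples.
#' @param background_exponent exponent alpha of the 1/f^alpha background.
#' @param osc_band_hz `(low, high)` band of the physiological oscillation, Hz.
#' @param ied_width_ms `(min, max)` half-wave width of the epileptiform sharp
#'   wave, milliseconds.
#' @param ied_amp_factor sharp-wave peak amplitude as a multiple of the
#'   background standard deviation.
#' @param hfo_band_hz `(low, high)` band of high-frequency-oscillation bursts;
#'   skipped when the Nyquist frequency is below the upper edge.
#' @param emg_band_low_hz high-pass edge of muscle-artifact bursts, Hz.
#' @param mains_hz power-line frequency, 50 or 60.
#' @param snr_db mains/EMG signal-to-background ratio in dB.
#' @param background_sd_uv standard deviation of the physiological background
#'   in microvolts; fixes the absolute amplitude scale.
#' @return a `generator_params` list, validated.
#' @export
generator_params <- function(sampling_rate_hz = 512,
                             segment_seconds = 3,
                             background_exponent = 1,
                             osc_band_hz = c(8, 12),
                             ied_width_ms = c(30, 70),
                             ied_amp_factor = 6,
                             hfo_band_hz = c(80, 200),
                             emg_band_low_hz = 30,
                             mains_hz = 50,
                             snr_db = 20,
                             background_sd_uv = 10) {
  p <- list(
    sampling_rate_hz = sampling_rate_hz, segment_seconds = segment_seconds,
    background_exponent = background_exponent, osc_band_hz = osc_band_hz,
    ied_width_ms = ied_width_ms, ied_amp_factor = ied_amp_factor,
    hfo_band_hz = hfo_band_hz, emg_band_low_hz = emg_band_low_hz,
    mains_hz = mains_hz, snr_db = snr_db, background_sd_uv = background_sd_uv
  )
  if (sampling_rate_hz <= 0 || segment_seconds <= 0) {
    ieeg_error("sampling_rate_hz and segment_seconds must be positive",
               "ieegsift_bad_params")
  }
  L <- sampling_rate_hz * segment_seconds
  if (abs(L - round(L)) > 1e-9) {
    ieeg_error("sampling_rate_hz * segment_seconds must be a whole number of samples",
               "ieegsift_bad_params")
  }
  nyq <- sampling_rate_hz / 2
  if (osc_band_hz[2] >= nyq) {
    ieeg_error("oscillation band must lie below the Nyquist frequency",
               "ieegsift_bad_params")
  }
  if (!mains_hz %in% c(50, 60)) {
    ieeg_error("mains_hz must be 50 or 60", "ieegsift_bad_params")
  }
  p$n_samples <- as.integer(round(L))
  class(p) <- "generator_params"
  p
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise, unit sd
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)            # symmetric frequency index, DC at 0
  scale <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# raised-cosine (Hann) lobe of `len` samples
hann_lobe <- function(len) {
  if (len < 1) return(numeric(0))
  0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
}

# add `wave` into `x` starting at sample `at` (clipped at the ends)
add_at <- function(x, wave, at) {
  idx <- at + seq_along(wave) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + wave[keep]
  x
}

# shared physiological background: pink noise + band-limited oscillation.
# Classes 2 and 3 draw this identically first, so a pathological segment and
# the physiological segment with the same seed share their background.
draw_background <- function(p) {
  bg <- pink_noise(p$n_samples, p$background_exponent) * p$background_sd_uv
  f_osc <- stats::runif(1, p$osc_band_hz[1], p$osc_band_hz[2])
  phase <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(p$n_samples) - 1) / p$sampling_rate_hz
  bg + p$background_sd_uv * sin(2 * pi * f_osc * t + phase)
}

draw_ieds <- function(x, p, bg_sd) {
  fs <- p$sampling_rate_hz
  n_ied <- sample(1:5, 1)
  amp <- p$ied_amp_factor * bg_sd
  for (i in seq_len(n_ied)) {
    w_ms <- stats::runif(1, p$ied_width_ms[1], p$ied_width_ms[2])
    w <- max(3L, as.integer(round(w_ms / 1000 * fs)))
    sgn <- sample(c(-1, 1), 1)
    onset <- sample.int(max(1L, p$n_samples - 3L * w), 1)
    # biphasic sharp wave: fast lobe followed by a slower opposite lobe
    x <- add_at(x, sgn * amp * hann_lobe(w), onset)
    x <- add_at(x, -sgn * 0.45 * amp * hann_lobe(2L * w), onset + w)
  }
  nyq <- fs / 2
  if (p$hfo_band_hz[2] < nyq) {
    n_hfo <- sample(1:3, 1)
    t_sigma <- 0.02 * fs                       # 20 ms Gabor envelope
    half <- as.integer(round(4 * t_sigma))
    for (i in seq_len(n_hfo)) {
      f0 <- stats::runif(1, p$hfo_band_hz[1], p$hfo_band_hz[2])
      phi <- stats::runif(1, 0, 2 * pi)
      center <- sample.int(p$n_samples, 1)
      tt <- (-half):half
      atom <- 2 * bg_sd * exp(-tt^2 / (2 * t_sigma^2)) *
        cos(2 * pi * f0 * tt / fs + phi)
      x <- add_at(x, atom, center - half)
    }
  }
  x
}

draw_artifact <- function(p) {
  fs <- p$sampling_rate_hz
  bg <- pink_noise(p$n_samples, p$background_exponent) * p$background_sd_uv
  hp <- signal::butter(4, p$emg_band_low_hz / (fs / 2), type = "high")
  n_burst <- sample(2:4, 1)
  target_rms <- p$background_sd_uv * 10^(p$snr_db / 20)
  x <- bg
  for (i in seq_len(n_burst)) {
    dur <- as.integer(round(stats::runif(1, 0.3, 1.0) * fs))
    carrier <- signal::filtfilt(hp, stats::rnorm(dur + 2L * fs %/% 10))
    carrier <- carrier[(fs %/% 10 + 1):(fs %/% 10 + dur)]  # drop filter edges
    burst <- carrier * hann_lobe(dur)
    rms <- sqrt(mean(burst^2))
    if (rms > 0) burst <- burst * target_rms / rms
    onset <- sample.int(max(1L, p$n_samples - dur), 1)
    x <- add_at(x, burst, onset)
  }
  x
}

draw_mains <- function(p) {
  fs <- p$sampling_rate_hz
  t <- (seq_len(p$n_samples) - 1) / fs
  mains_rms <- p$background_sd_uv
  a1 <- mains_rms * sqrt(2)
  x <- a1 * sin(2 * pi * p$mains_hz * t + stats::runif(1, 0, 2 * pi))
  for (h in 2:3) {
    if (h * p$mains_hz < fs / 2) {
      gain <- 10^(-10 * (h - 1) / 20)          # -10 dB per harmonic order
      x <- x + a1 * gain * sin(2 * pi * h * p$mains_hz * t + stats::runif(1, 0, 2 * pi))
    }
  }
  pink_rms <- mains_rms / 10^(p$snr_db / 20)
  x + pink_noise(p$n_samples, p$background_exponent) * pink_rms
}

#' Generate one labeled synthetic iEEG segment
#'
#' Deterministic for a fixed `(label, params, seed)` triple. Class
#' construction: 3 = pink-noise background plus a band-limited oscillation;
#' 2 = the class-3 background plus 1-5 biphasic epileptiform sharp waves and,
#' when the Nyquist frequency permits, 1-3 Gabor-atom HFO bursts; 1 = pink
#' noise plus 2-4 amplitude-modulated bursts of high-passed white noise;
#' 0 = a mains sinusoid with 2nd/3rd harmonics at -10/-20 dB over low-level
#' pink noise.
#'
#' @param label class code in `0:3` (0 power-line noise, 1 artifact,
#'   2 pathological, 3 physiological).
#' @param params a [generator_params()] object.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param segment_id,patient_id,institution provenance strings.
#' @return a `segment_record`: list with `segment_id`, `samples` (microvolts),
#'   `sampling_rate_hz`, `label`, `patient_id`, `institution`.
#' @examples
#' seg <- generate_segment(3, generator_params(), seed = 1)
#' length(seg$samples)  # 1536 samples = 3 s at 512 Hz
#' @export
generate_segment <- function(label, params = generator_params(), seed = 1,
                             segment_id = sprintf("seg_%d_%d", label, seed),
                             patient_id = "P01", institution = "SYNTH-A") {
  if (!inherits(params, "generator_params")) {
    ieeg_error("params must be created by generator_params()", "ieegsift_bad_params")
  }
  if (length(label) != 1 || !label %in% CLASS_CODES) {
    ieeg_error(sprintf("unknown class label code: %s", paste(label, collapse = ",")),
               "ieegsift_bad_label")
  }
  samples <- withr::with_seed(seed, {
    switch(as.character(label),
      "3" = draw_background(params),
      "2" = {
        bg <- draw_background(params)
        draw_ieds(bg, params, stats::sd(bg))
      },
      "1" = draw_artifact(params),
      "0" = draw_mains(params)
    )
  })
  assert_finite(samples, "generated segment")
  structure(
    list(segment_id = segment_id, samples = samples,
         sampling_rate_hz = params$sampling_rate_hz, label = as.integer(label),
         patient_id = patient_id, institution = institution),
    class = "segment_record"
  )
}

#' Generate a labeled synthetic dataset with per-class counts
#'
#' Per-segment seeds are derived from the master seed and the segment index,
#' so the dataset is reproducible. Segments are assigned synthetic patient ids
#' round-robin (8 patients across 2 institutions) so that stratified folds can
#' be exercised.
#'
#' @param counts named vector/list mapping class codes `"0".."3"` to
#'   non-negative counts.
#' @param params a [generator_params()] object.
#' @param seed integer master seed.
#' @return list of `segment_record`s, ordered by class then index.
#' @export
generate_dataset <- function(counts, params = generator_params(), seed = 0) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || !all(names(counts) %in% as.character(CLASS_CODES))) {
    ieeg_error("counts must be named by class codes 0-3", "ieegsift_bad_label")
  }
  if (any(counts < 0)) {
    ieeg_error("per-class counts must be non-negative", "ieegsift_bad_params")
  }
  n_pat <- 8L
  out <- vector("list", sum(counts))
  idx <- 0L
  for (cls in sort(as.integer(names(counts)))) {
    for (j in seq_len(counts[[as.character(cls)]])) {
      idx <- idx + 1L
      pat <- (idx - 1L) %% n_pat + 1L
      out[[idx]] <- generate_segment(
        cls, params, seed = derive_seed(seed, idx),
        segment_id = sprintf("seg%06d", idx),
        patient_id = sprintf("P%02d", pat),
        institution = if (pat <= n_pat / 2) "SYNTH-A" else "SYNTH-B"
      )
    }
  }
  out
}

#' Generate a long pseudo-prospective recording with rare discharges
#'
#' Emits consecutive 3-s segments of a single synthetic channel in which each
#' segment is pathological (contains epileptiform discharges) with probability
#' `ied_prevalence` and physiological otherwise. Labels are re-coded for this
#' mode as binary: 0 = physiological, 1 = interictal epileptiform discharge.
#'
#' @param duration_s total recording duration in seconds.
#' @param ied_prevalence probability in `[0, 1]` that a segment contains
#'   discharges.
#' @param params a [generator_params()] object.
#' @param seed integer master seed.
#' @return list of `segment_record`s with binary labels; the list carries
#'   attribute `label_mode = "binary"`.
#' @export
generate_recording <- function(duration_s, ied_prevalence,
                               params = generator_params(), seed = 0) {
  if (ied_prevalence < 0 || ied_prevalence > 1) {
    ieeg_error("ied_prevalence must lie in [0, 1]", "ieegsift_bad_params")
  }
  if (duration_s < params$segment_seconds) {
    ieeg_error("duration_s must be at least one segment long", "ieegsift_bad_params")
  }
  n <- floor(duration_s / params$segment_seconds)
  is_ied <- withr::with_seed(seed, stats::runif(n) < ied_prevalence)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- generate_segment(
      if (is_ied[i]) 2L else 3L, params, seed = derive_seed(seed, i),
      segment_id = sprintf("rec%06d", i),
      patient_id = "PP01", institution = "SYNTH-REC"
    )
    rec$label <- as.integer(is_ied[i])
    out[[i]] <- rec
  }
  attr(out, "label_mode") <- "binary"
  out
}

#' Fraction of spectral power inside a frequency band
#'
#' Periodogram band power over total power (DC excluded); the spectral
#' fingerprint used to sanity-check class separability of synthetic segments.
#'
#' @param samples numeric signal vector.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param band `(low, high)` band edges in Hz.
#' @return scalar in `[0, 1]`.
#' @export
band_power_ratio <- function(samples, sampling_rate_hz, band) {
  n <- length(samples)
  spec <- Mod(stats::fft(samples))^2
  half <- spec[2:(n %/% 2 + 1)]               # one-sided, DC dropped
  freqs <- (1:(n %/% 2)) * sampling_rate_hz / n
  sum(half[freqs >= band[1] & freqs <= band[2]]) / sum(half)
}

# convenience accessors used across modules
segment_matrix <- function(segments) {
  do.call(rbind, lapply(segments, function(s) s$samples))
}

segment_labels_raw <- function(segments) {
  vapply(segments, function(s) as.integer(s$label), integer(1))
}

segment_ids <- function(segments) {
  vapply(segments, function(s) s$segment_id, character(1))
}
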