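test_that("fixed seed reproduces segments bit-identically", {
  p <- generator_params()
  for (lbl in 0:3) {
    a <- generate_segment(lbl, p, seed = 1)
    b <- generate_segment(lbl, p, seed = 1)
    expect_identical(a$samples, b$samples)
    expect_length(a$samples, p$n_samples)
    expect_true(all(is.finite(a$samples)))
    expect_identical(a$label, lbl)
  }
})

test_that("power-line segments peak at the mains frequency", {
  p <- generator_params(mains_hz = 50)
  seg <- generate_segment(0, p, seed = 7)
  spec <- Mod(fft(seg$samples))
  n <- length(seg$samples)
  freqs <- (1:(n %/% 2)) * p$sampling_rate_hz / n
  peak <- freqs[which.max(spec[2:(n %/% 2 + 1)])]
  expect_equal(peak, 50, tolerance = 1 / 3 + 1e-9)  # nearest bin at 1/3 Hz resolution
})

test_that("pathological segments carry high-amplitude sharp waves over the paired background", {
  p <- generator_params()
  s2 <- generate_segment(2, p, seed = 3)
  s3 <- generate_segment(3, p, seed = 3)   # same background seed
  expect_gte(max(abs(s2$samples)), p$ied_amp_factor / 2 * sd(s3$samples))
})

test_that("HFO components are skipped above Nyquist while sharp waves remain", {
  p <- generator_params(sampling_rate_hz = 256, hfo_band_hz = c(200, 400),
                        osc_band_hz = c(8, 12))
  s2 <- generate_segment(2, p, seed = 4)
  s3 <- generate_segment(3, p, seed = 4)
  expect_length(s2$samples, 768)
  expect_gte(max(abs(s2$samples)), p$ied_amp_factor / 2 * sd(s3$samples))
})

test_that("unknown label codes are rejected", {
  expect_error(generate_segment(7, generator_params(), seed = 1),
               class = "ieegsift_bad_label")
})

test_that("generate_dataset honors counts, determinism and round-robin patients", {
  p <- generator_params()
  ds <- generate_dataset(c("0" = 5, "1" = 5, "2" = 5, "3" = 5), p, seed = 0)
  expect_length(ds, 20)
  labs <- vapply(ds, `[[`, integer(1), "label")
  expect_equal(as.numeric(table(labs)), rep(5, 4))

  ds2 <- generate_dataset(c("0" = 5, "1" = 5, "2" = 5, "3" = 5), p, seed = 0)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))
  expect_identical(vapply(ds, `[[`, character(1), "segment_id"),
                   vapply(ds2, `[[`, character(1), "segment_id"))

  ds3 <- generate_dataset(c("2" = 0, "3" = 10), p, seed = 0)
  expect_length(ds3, 10)
  expect_false(any(vapply(ds3, `[[`, integer(1), "label") == 2L))
  expect_gt(length(unique(vapply(ds3, `[[`, character(1), "patient_id"))), 1)

  expect_error(generate_dataset(c("0" = -1), p, seed = 0),
               class = "ieegsift_bad_params")
})

test_that("recordings have floor(duration/segment) segments and binary labels", {
  p <- generator_params()
  rec0 <- generate_recording(30, 0, p, seed = 1)
  expect_length(rec0, 10)
  expect_true(all(vapply(rec0, `[[`, integer(1), "label") == 0L))

  rec <- generate_recording(1800, 0.1, p, seed = 5)
  expect_length(rec, 600)
  frac <- mean(vapply(rec, `[[`, integer(1), "label"))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 600))

  expect_error(generate_recording(1800, 1.5, p, seed = 1),
               class = "ieegsift_bad_params")
  expect_error(generate_recording(1, 0.1, p, seed = 1),
               class = "ieegsift_bad_params")
})

test_that("band-power fingerprints separate the signature classes", {
  p <- generator_params()
  n_per <- 100
  ds <- make_small_dataset(per_class = n_per, seed = 21)
  labs <- vapply(ds, `[[`, integer(1), "label")
  ratio <- function(seg, band) band_power_ratio(seg$samples, seg$sampling_rate_hz, band)

  mains <- vapply(ds, ratio, numeric(1), band = c(p$mains_hz - 2, p$mains_hz + 2))
  emg <- vapply(ds, ratio, numeric(1), band = c(p$emg_band_low_hz, p$sampling_rate_hz / 2))
  osc <- vapply(ds, ratio, numeric(1), band = p$osc_band_hz)

  auc <- function(scores, pos, neg) {
    keep <- labs %in% c(pos, neg)
    brute_auroc(scores[keep], as.numeric(labs[keep] == pos))
  }
  # each class's signature band against the classes lacking that signature
  for (other in 1:3) expect_gt(auc(mains, 0, other), 0.9)
  for (other in 2:3) expect_gt(auc(emg, 1, other), 0.9)
  for (other in 0:1) expect_gt(auc(osc, 3, other), 0.9)
})
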