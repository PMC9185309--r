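fs <- 360

test_that("Pan-Tompkins recovers clean synthetic R peaks and rejects degenerate input", {
  syn <- quiet_record(seed = 11, duration_s = 30)
  rec <- preprocess_record(syn$record)
  peaks <- detect_r_peaks(rec$samples, fs)
  gt <- syn$ground_truth$r_indices
  expect_gte(length(peaks), 28)
  expect_lte(length(peaks), 31)
  expect_equal(match_rate(gt, peaks, tol = round(0.025 * fs)), 1)
  expect_true(all(diff(peaks) > round(0.2 * fs)))
  # flat signal: nothing to detect
  expect_length(detect_r_peaks(numeric(10 * fs), fs), 0)
  # too short for the initialization window
  expect_error(detect_r_peaks(numeric(fs), fs), "2 s")
})

test_that("R-peak recovery stays above 95% at 20 dB SNR", {
  syn <- quiet_record(seed = 12, duration_s = 60)
  clean <- syn$record$samples
  sigma <- sqrt(mean(clean^2)) / 10^(20 / 20)
  set.seed(99)
  noisy <- clean + rnorm(length(clean), 0, sigma)
  rec <- preprocess_record(ecg_record("noisy", fs, noisy))
  peaks <- detect_r_peaks(rec$samples, fs)
  rate <- match_rate(syn$ground_truth$r_indices, peaks, round(0.050 * fs))
  expect_gte(rate, 0.95)
})

test_that("T points land on the T wave, equivariantly, including inverted T", {
  syn <- quiet_record(seed = 13, duration_s = 30)
  rec <- preprocess_record(syn$record)
  r <- detect_r_peaks(rec$samples, fs)
  tp <- locate_t_points(rec$samples, fs, r)
  off <- (tp - r) / fs
  # generator puts the T wave ~300 ms after R (subject jitter aside)
  expect_lt(max(abs(stats::na.omit(off) - 0.30)), 0.04 + 0.05)
  # translation equivariance: two identical concatenated beats
  beat <- rec$samples[(r[3] - 100):(r[3] + 180)]
  two <- c(beat, beat)
  rr <- c(100, 100 + length(beat))
  tp2 <- locate_t_points(two, fs, rr)
  expect_equal(tp2[2] - rr[2], tp2[1] - rr[1])
  # inverted T (ventricular morphology): still inside the search window
  synv <- quiet_record(seed = 14, duration_s = 30,
                       props = c(N = 0, S = 0, V = 1, F = 0, Q = 0))
  recv <- preprocess_record(synv$record)
  rv <- detect_r_peaks(recv$samples, fs)
  tpv <- locate_t_points(recv$samples, fs, rv)
  offv <- (tpv - rv) / fs
  expect_true(all(stats::na.omit(offv) >= 0.08 & stats::na.omit(offv) <= 0.41))
  expect_error(locate_t_points(rec$samples, fs, r[1]), "2 R peaks")
})

test_that("interval rescaling is linear interpolation with preserved endpoints", {
  v <- sin(seq(0, 3, length.out = 200))
  expect_identical(rescale_interval(v, 200), v)
  ramp <- seq(2, 5, length.out = 73)
  out <- rescale_interval(ramp, 200)
  expect_length(out, 200)
  expect_equal(out, seq(2, 5, length.out = 200), tolerance = 1e-12)
  expect_equal(rescale_interval(rep(1.3, 17), 200), rep(1.3, 200))
  expect_equal(out[c(1, 200)], c(2, 5))
  mono <- rescale_interval(cumsum(runif(50)), 200)
  expect_true(all(diff(mono) >= 0))
  expect_error(rescale_interval(1, 200), "at least 2")
})

test_that("T-to-T segments are 400 samples with labels in beat order", {
  syn <- quiet_record(seed = 15, duration_s = 10,
                      props = c(N = 0.7, S = 0, V = 0.3, F = 0, Q = 0))
  rec <- preprocess_record(syn$record)
  r <- detect_r_peaks(rec$samples, fs)
  tp <- locate_t_points(rec$samples, fs, r)
  ds <- extract_segments(rec, syn$annotations, tp)
  n_beats <- nrow(syn$annotations)
  # the first beats lack a preceding interval: a few drops expected
  expect_gte(nrow(ds$x), n_beats - 4)
  expect_lte(nrow(ds$x), n_beats)
  expect_equal(nrow(ds$x) + ds$dropped, n_beats)
  expect_equal(ncol(ds$x), 400)
  expect_true(all(is.finite(ds$x)))
  # labels preserved in order: the emitted labels are a contiguous
  # subsequence of the annotation classes
  kept <- ds$meta$beat_index
  expect_identical(as.character(ds$labels),
                   syn$annotations$aami_class[kept])
  expect_equal(sum(ds$class_counts), nrow(ds$x))
  # determinism
  ds2 <- extract_segments(rec, syn$annotations, tp)
  expect_identical(ds$x, ds2$x)
})

test_that("segment counts on clean generator output equal beats minus boundary drops", {
  syn <- quiet_record(seed = 16, duration_s = 40,
                      props = c(N = 0.85, S = 0.05, V = 0.1, F = 0, Q = 0))
  ds <- segment_record(syn$record, syn$annotations)
  expect_equal(nrow(ds$x) + ds$dropped, nrow(syn$annotations))
  expect_lte(ds$dropped, 4)
  tab <- table(factor(syn$annotations$aami_class, levels = AAMI_CLASSES))
  # per-class counts match up to the dropped boundary beats
  expect_true(all(abs(as.integer(ds$class_counts) - as.integer(tab)) <=
                    ds$dropped))
})

test_that("segment datasets round-trip through the CSV store", {
  ds <- synthesize_segments(c(8, 3, 3, 2, 2), seed = 17)
  f <- withr::local_tempfile(fileext = ".csv")
  write_segments(ds, f)
  back <- read_segments(f)
  expect_equal(back$x, ds$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$meta$record_id, ds$meta$record_id)
})
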