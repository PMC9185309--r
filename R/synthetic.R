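# Synthetic single-lead ECG with Gaussian P-QRS-T morphology and analytic
# ground-truth fiducials, so detection and classification can be tested
# without any clinical database.

# Canonical wave parameters (amplitude mV, width s, centre offset s from the
# R peak) for a normal beat.
.normal_waves <- function() {
  m <- rbind(
    P = c(0.15, 0.025, -0.200),
    Q = c(-0.10, 0.010, -0.040),
    R = c(1.00, 0.012, 0.000),
    S = c(-0.15, 0.012, 0.035),
    T = c(0.30, 0.060, 0.300)
  )
  colnames(m) <- c("amp", "width", "offset")
  m
}

.ventricular_waves <- function() {
  m <- rbind(
    P = c(0.00, 0.025, -0.200),
    Q = c(-0.05, 0.020, -0.060),
    R = c(1.25, 0.040, 0.000),
    S = c(-0.40, 0.030, 0.060),
    T = c(-0.35, 0.070, 0.320)   # discordant (inverted) T
  )
  colnames(m) <- c("amp", "width", "offset")
  m
}

# Class-conditional morphology. N: canonical; S: premature with reduced P
# (the RR shortening is handled by the rhythm generator); V: wide
# high-amplitude QRS, absent P, inverted T; F: midpoint of N and V;
# Q: broad random morphology (unclassifiable beats have none to model).
.class_waves <- function(class) {
  switch(class,
    N = .normal_waves(),
    S = { m <- .normal_waves(); m["P", "amp"] <- 0.04; m },
    V = .ventricular_waves(),
    F = (.normal_waves() + .ventricular_waves()) / 2,
    Q = {
      m <- .normal_waves()
      m[, "amp"] <- stats::runif(5, -0.6, 1.2)
      m["R", "amp"] <- stats::runif(1, 0.5, 1.4)
      m[, "width"] <- m[, "width"] * stats::runif(5, 0.6, 2.5)
      m
    },
    stop("unknown class: ", class)
  )
}

# Per-subject morphology factors: multiplicative perturbations of wave
# amplitudes and widths, emulating inter-patient variation.
.subject_factors <- function(jitter = 0.15) {
  list(amp = stats::runif(5, 1 - jitter, 1 + jitter),
       width = stats::runif(5, 1 - jitter, 1 + jitter))
}

.apply_factors <- function(waves, fac, within = 0) {
  waves[, "amp"] <- waves[, "amp"] * fac$amp *
    stats::runif(5, 1 - within, 1 + within)
  waves[, "width"] <- waves[, "width"] * fac$width *
    stats::runif(5, 1 - within, 1 + within)
  waves
}

#' Configuration for the synthetic ECG generator
#'
#' @param fs Sampling rate in Hz (default 360, the MIT-BIH rate).
#' @param duration_s Record duration in seconds.
#' @param mean_hr_bpm Mean heart rate (default 60).
#' @param hr_jitter Coefficient of variation of the RR intervals.
#' @param class_proportions Named probabilities over the AAMI classes; must
#'   sum to 1.
#' @param noise List with `baseline_amp` (mV), `baseline_hz`,
#'   `powerline_amp` (mV), `powerline_hz`, `white_sigma` (mV).
#' @param subject_jitter Inter-subject morphology perturbation (fraction).
#' @param within_jitter Beat-to-beat morphology variation (fraction).
#' @param seed Integer seed; fixes all randomness of the generator.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 360, duration_s = 60, mean_hr_bpm = 60,
                             hr_jitter = 0.05,
                             class_proportions = c(N = 0.9, S = 0.025,
                                                   V = 0.06, F = 0.01,
                                                   Q = 0.005),
                             noise = list(baseline_amp = 0.15,
                                          baseline_hz = 0.25,
                                          powerline_amp = 0.02,
                                          powerline_hz = 60,
                                          white_sigma = 0.01),
                             subject_jitter = 0.15, within_jitter = 0.05,
                             seed = 1L) {
  p <- class_proportions
  if (abs(sum(p) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (length(p) != 5L) stop("class proportions must cover the 5 AAMI classes")
  if (fs <= 2 * noise$powerline_hz) {
    stop("fs must exceed twice the powerline frequency")
  }
  structure(list(fs = fs, duration_s = duration_s,
                 mean_hr_bpm = mean_hr_bpm, hr_jitter = hr_jitter,
                 class_proportions = p, noise = noise,
                 subject_jitter = subject_jitter,
                 within_jitter = within_jitter, seed = as.integer(seed)),
            class = "synthetic_config")
}

.render_beats <- function(n_samples, fs, r_times, wave_list) {
  x <- numeric(n_samples)
  t_axis <- (seq_len(n_samples) - 1L) / fs
  for (i in seq_along(r_times)) {
    w <- wave_list[[i]]
    for (j in seq_len(nrow(w))) {
      a <- w[j, "amp"]; s <- w[j, "width"]; c0 <- r_times[i] + w[j, "offset"]
      if (a == 0) next
      lo <- max(1L, floor((c0 - 4 * s) * fs) + 1L)
      hi <- min(n_samples, ceiling((c0 + 4 * s) * fs) + 1L)
      if (lo > hi) next
      tt <- t_axis[lo:hi]
      x[lo:hi] <- x[lo:hi] + a * exp(-(tt - c0)^2 / (2 * s^2))
    }
  }
  x
}

.symbol_for_class <- c(N = "N", S = "A", V = "V", F = "F", Q = "Q")

#' Synthesize an annotated ECG record
#'
#' Generates a beat train with class-conditional Gaussian P-QRS-T morphology
#' (supraventricular ectopic beats are premature: the preceding RR interval
#' is shortened by 30%), plus sinusoidal baseline wander, powerline
#' interference and white noise. Returns the record, MIT-BIH-style beat
#' annotations, and the analytic ground-truth fiducials.
#'
#' @param config A [synthetic_config()].
#' @param record_id Identifier for the emitted record.
#' @return List with `record` (an `ecg_record`), `annotations` (a
#'   [beat_annotations()] frame), and `ground_truth` (list of 0-based
#'   `r_indices`, `t_indices`, and `labels`).
#' @export
synthesize_record <- function(config = synthetic_config(),
                              record_id = "synth01") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  fs <- config$fs
  mean_rr <- 60 / config$mean_hr_bpm
  # rhythm: jittered RR sequence, S beats arrive early
  t <- 0.5; r_times <- numeric(0); labels <- character(0)
  while (TRUE) {
    lab <- sample(AAMI_CLASSES, 1L, prob = config$class_proportions)
    rr <- stats::rnorm(1, mean_rr, config$hr_jitter * mean_rr)
    rr <- min(max(rr, mean_rr * (1 - 2.5 * config$hr_jitter)),
              mean_rr * (1 + 2.5 * config$hr_jitter))
    if (lab == "S") rr <- rr * 0.7
    t_next <- if (length(r_times)) r_times[length(r_times)] + rr else t
    if (t_next > config$duration_s - 0.6) break
    r_times <- c(r_times, t_next)
    labels <- c(labels, lab)
  }
  if (length(r_times) >= 2L && min(diff(r_times)) < 0.33) {
    stop("infeasible config: beats overlap at this heart rate")
  }
  sub <- .subject_factors(config$subject_jitter)
  wave_list <- lapply(labels, function(l) {
    .apply_factors(.class_waves(l), sub, config$within_jitter)
  })
  n_samples <- round(fs * config$duration_s)
  x <- .render_beats(n_samples, fs, r_times, wave_list)
  tt <- (seq_len(n_samples) - 1L) / fs
  nz <- config$noise
  x <- x + nz$baseline_amp * sin(2 * pi * nz$baseline_hz * tt +
                                 stats::runif(1, 0, 2 * pi))
  x <- x + nz$powerline_amp * sin(2 * pi * nz$powerline_hz * tt +
                                  stats::runif(1, 0, 2 * pi))
  x <- x + stats::rnorm(n_samples, 0, nz$white_sigma)
  r_idx <- as.integer(round(r_times * fs))            # 0-based
  t_idx <- as.integer(round((r_times + vapply(wave_list, function(w)
    w["T", "offset"], 0)) * fs))
  rec <- ecg_record(record_id, fs, x)
  ann <- beat_annotations(r_idx, unname(.symbol_for_class[labels]),
                          n_samples = n_samples)
  list(record = rec, annotations = ann,
       ground_truth = list(r_indices = r_idx, t_indices = t_idx,
                           labels = labels))
}

# Render one segment of a given class directly: a 3-beat mini-train
# (N, N, target) sampled at fs, cut at the analytic T points of beats 1..3
# and rescaled to 2 x n_per_interval samples. Bypasses peak detection.
.render_segment <- function(class, fs, sub, within, white_sigma,
                            n_per_interval = 200L) {
  rr <- c(0.8, 0.8)
  if (class == "S") rr[2L] <- rr[2L] * 0.7
  r_times <- c(0.5, 0.5 + rr[1L], 0.5 + sum(rr))
  labs <- c("N", "N", class)
  wave_list <- lapply(labs, function(l) {
    .apply_factors(.class_waves(l), sub, within)
  })
  dur <- r_times[3L] + 0.6
  n <- round(dur * fs)
  x <- .render_beats(n, fs, r_times, wave_list)
  x <- x + stats::rnorm(n, 0, white_sigma)
  t_idx <- round((r_times + vapply(wave_list, function(w)
    w["T", "offset"], 0)) * fs)  # 0-based
  prev <- x[(t_idx[1L] + 1L):(t_idx[2L] + 1L)]
  targ <- x[(t_idx[2L] + 1L):(t_idx[3L] + 1L)]
  c(rescale_interval(prev, n_per_interval),
    rescale_interval(targ, n_per_interval))
}

#' Synthesize labelled 400-sample segments directly
#'
#' Draws segments from the class-conditional beat model with exact per-class
#' counts, bypassing peak detection — the fixture generator for model and
#' loss experiments.
#'
#' @param n_per_class Named (or AAMI-ordered) integer vector of segment
#'   counts per class.
#' @param seed Integer seed.
#' @param fs Sampling rate used for rendering.
#' @param subject Optional subject morphology factors (from an internal
#'   draw); supply the same object to generate same-subject data.
#' @param within_jitter Beat-to-beat morphology variation.
#' @param white_sigma Additive white-noise level (mV).
#' @param record_id Provenance tag stored in the dataset.
#' @return A `segment_dataset` with the requested counts, rows shuffled.
#' @export
synthesize_segments <- function(n_per_class, seed = 1L, fs = 360,
                                subject = NULL, within_jitter = 0.08,
                                white_sigma = 0.05, record_id = "synthseg") {
  if (length(n_per_class) != 5L) stop("need counts for the 5 AAMI classes")
  n_per_class <- stats::setNames(as.integer(n_per_class), AAMI_CLASSES)
  if (any(n_per_class < 0) || sum(n_per_class) == 0) {
    stop("counts must be nonnegative and not all zero")
  }
  set.seed(seed)
  if (is.null(subject)) subject <- .subject_factors(0.15)
  labs <- rep(AAMI_CLASSES, times = n_per_class)
  segs <- lapply(labs, .render_segment, fs = fs, sub = subject,
                 within = within_jitter, white_sigma = white_sigma)
  x <- do.call(rbind, segs)
  ord <- sample.int(nrow(x))
  segment_dataset(x[ord, , drop = FALSE], labs[ord],
                  record_id = rep(record_id, length(labs)))
}

#' Desk-scale imbalanced benchmark
#'
#' A train/test pair of segment datasets whose class proportions match the
#' full-database imbalance (~0.8947 : 0.0276 : 0.0696 : 0.0080 : 0.00015 for
#' N:S:V:F:Q, the Q count floor-clamped to 2 per split), with distinct
#' subject morphology factors for the two splits to mimic the inter-patient
#' distribution shift.
#'
#' @param seed Integer seed.
#' @param n_train,n_test Approximate split sizes.
#' @return List with `train` and `test` `segment_dataset`s.
#' @export
imbalanced_benchmark <- function(seed = 1L, n_train = 5000L,
                                 n_test = 2000L) {
  props <- c(N = 89976, S = 2774, V = 7002, F = 802, Q = 15) / 100569
  counts_for <- function(n) {
    k <- round(n * props)
    k["Q"] <- max(k["Q"], 2L)
    k["N"] <- k["N"] + (n - sum(k))
    as.integer(k)
  }
  set.seed(seed)
  sub_train <- .subject_factors(0.15)
  sub_test <- .subject_factors(0.15)
  train <- synthesize_segments(counts_for(n_train), seed = seed + 1L,
                               subject = sub_train, record_id = "synth_ds1")
  test <- synthesize_segments(counts_for(n_test), seed = seed + 2L,
                              subject = sub_test, record_id = "synth_ds2")
  list(train = train, test = test)
}
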