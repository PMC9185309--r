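# Independent brute-force oracles used across the test files. These are
# written straight from first principles (loops, direct formulas) and share
# no code with the implementation they check.

# sliding median with reflected edges, one explicit window per position
oracle_sliding_median <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[2:(h + 1L)]), x, x[(n - 1L):(n - h)])
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + w - 1L)]), 0)
}

# direct same-padding 1-D convolution, nested loops
oracle_conv_same <- function(x, W, b = 0) {
  # x: (B, L, C) array; W: (k*C) x F, offset-major rows
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  k <- nrow(W) / C
  f <- ncol(W)
  h <- (k - 1) / 2
  out <- array(0, c(B, L, f))
  for (bb in seq_len(B)) for (i in seq_len(L)) for (ff in seq_len(f)) {
    acc <- b[ff]
    for (m in seq_len(k)) for (cc in seq_len(C)) {
      j <- i + m - 1 - h
      if (j >= 1 && j <= L) {
        acc <- acc + W[(m - 1) * C + cc, ff] * x[bb, j, cc]
      }
    }
    out[bb, i, ff] <- acc
  }
  out
}

# brute-force max pooling of a vector
oracle_max_pool <- function(x, R, T) {
  n_out <- floor((length(x) - R) / T) + 1
  vapply(seq_len(n_out), function(i) max(x[(1 + (i - 1) * T):((i - 1) * T + R)]), 0)
}

# per-batch cost state from the defining formulas, all scalar loops
oracle_batch_cost <- function(y, pred, dataset_counts, C) {
  M <- length(y)
  inv_freq <- function(counts, total) {
    w <- numeric(C)
    for (c in seq_len(C)) {
      w[c] <- if (counts[c] > 0) total / (C * counts[c]) else NA
    }
    w
  }
  CW_D <- inv_freq(dataset_counts, sum(dataset_counts))
  CW_D[is.na(CW_D)] <- 0
  bc <- vapply(seq_len(C), function(c) sum(y == c), 0L)
  CW_b <- inv_freq(bc, M)
  CW_b[is.na(CW_b)] <- CW_D[is.na(CW_b)]
  CW <- sqrt((CW_b^2 + CW_D^2) / 2)
  FPR <- FNR <- HM <- numeric(C)
  for (c in seq_len(C)) {
    tp <- sum(y == c & pred == c); fn <- sum(y == c & pred != c)
    fp <- sum(y != c & pred == c); tn <- sum(y != c & pred != c)
    FPR[c] <- if (fp + tn > 0) fp / (fp + tn) else 0
    FNR[c] <- if (fn + tp > 0) fn / (fn + tp) else 0
    # epsilon-smoothed reciprocals, zero-anchored when either rate is zero
    HM[c] <- if (FPR[c] == 0 || FNR[c] == 0) 0 else
      min(1, 1 / ((1 / (FPR[c] + 1e-7) + 1 / (FNR[c] + 1e-7)) / 2))
  }
  list(CW_b = CW_b, CW_D = CW_D, CW = CW, FPR = FPR, FNR = FNR,
       HM_b = HM, phi = CW + HM)
}

# amplitude of a signal at one frequency, by direct discrete Fourier sum
oracle_tone_amplitude <- function(x, fs, freq) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * freq * t))) / n
}

# frequency response magnitude of an FIR filter at one frequency
oracle_fir_gain <- function(taps, fs, freq) {
  k <- seq_along(taps) - 1
  Mod(sum(taps * exp(-2i * pi * freq * k / fs)))
}

# fraction of reference fiducials matched by a detection within tol samples
match_rate <- function(truth, detected, tol) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(g) any(abs(detected - g) <= tol), TRUE))
}

# small synthetic record helper shared by several files
quiet_record <- function(seed = 1, duration_s = 30, hr = 60,
                         props = c(N = 1, S = 0, V = 0, F = 0, Q = 0),
                         white_sigma = 0, baseline_amp = 0,
                         powerline_amp = 0) {
  cfg <- synthetic_config(
    duration_s = duration_s, mean_hr_bpm = hr, class_proportions = props,
    noise = list(baseline_amp = baseline_amp, baseline_hz = 0.25,
                 powerline_amp = powerline_amp, powerline_hz = 60,
                 white_sigma = white_sigma),
    seed = seed)
  synthesize_record(cfg)
}
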