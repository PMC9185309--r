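#' Estimate the baseline-wander component of an ECG signal
#'
#' Cascades two sliding median filters: a 200 ms window first flattens the
#' P wave and QRS complex, then a 600 ms window removes the T wave; what
#' remains is the slowly varying baseline. Window lengths are
#' `round(0.2 * fs)` and `round(0.6 * fs)` samples, forced odd so the median
#' is an exact order statistic (73 and 217 samples at 360 Hz). Edges are
#' handled by reflection padding.
#'
#' @param samples Numeric voltage vector.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the same length: the estimated baseline.
#' @export
estimate_baseline <- function(samples, fs) {
  stopifnot(fs > 0)
  w1 <- .odd_window(round(0.2 * fs))
  w2 <- .odd_window(round(0.6 * fs))
  if (length(samples) < w2) {
    stop("signal shorter than the 600 ms median window (", w2, " samples)")
  }
  .median_reflect(.median_reflect(samples, w1), w2)
}

.odd_window <- function(w) {
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w + 1L else w
}

# Sliding median with reflection padding, exact over the full window at every
# position including edges.
.median_reflect <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  pad_l <- rev(x[seq_len(h) + 1L])      # x[h+1], ..., x[2]
  pad_r <- x[n - seq_len(h)]
  xp <- c(pad_l, x, pad_r)
  y <- stats::runmed(xp, w, endrule = "keep")
  y[(h + 1L):(h + n)]
}

#' Remove baseline wander
#'
#' Subtracts the cascaded 200 ms / 600 ms median-filter baseline estimate
#' from the raw signal, leaving the cardiac waveform centred on zero.
#'
#' @inheritParams estimate_baseline
#' @return Baseline-corrected signal, same length as the input.
#' @export
remove_baseline <- function(samples, fs) {
  samples - estimate_baseline(samples, fs)
}

#' Low-pass FIR filter for powerline and high-frequency noise
#'
#' A linear-phase FIR filter designed by the Hamming-window method with the
#' given order and cutoff (defaults: order 12, 35 Hz), normalised to unity DC
#' gain and applied with group-delay compensation so the output stays aligned
#' with the input. A 12th-order filter at 360 Hz gives gradual roll-off:
#' powerline components at 50/60 Hz are attenuated relative to the passband
#' rather than notched out.
#'
#' @param samples Numeric voltage vector.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (number of taps minus one).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @return Filtered signal, same length as the input.
#' @export
lowpass_fir <- function(samples, fs, order = 12L, cutoff = 35) {
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  taps <- lowpass_fir_taps(fs, order, cutoff)
  delay <- order %/% 2L
  n <- length(samples)
  # reflect-pad so the delay compensation has real data at both ends
  xp <- c(samples, rev(samples[n - seq_len(min(order, n - 1L))]))
  y <- stats::filter(xp, taps, method = "convolution", sides = 1L)
  y <- as.numeric(y)
  out <- y[(delay + 1L):(delay + n)]
  # leading taps have no history; fall back to the input there
  out[seq_len(min(delay, n))] <- samples[seq_len(min(delay, n))]
  out
}

#' FIR tap coefficients used by [lowpass_fir()]
#'
#' @inheritParams lowpass_fir
#' @return Numeric vector of `order + 1` tap weights summing to 1.
#' @export
lowpass_fir_taps <- function(fs, order = 12L, cutoff = 35) {
  taps <- signal::fir1(as.integer(order), cutoff / (fs / 2), type = "low")
  as.numeric(taps) / sum(taps)
}

#' Full denoising chain
#'
#' Baseline removal followed by the low-pass FIR stage; the standard
#' preprocessing applied to every record before peak detection.
#'
#' @param record An `ecg_record`.
#' @param fir_order,fir_cutoff FIR design parameters, see [lowpass_fir()].
#' @return An `ecg_record` with denoised samples.
#' @export
preprocess_record <- function(record, fir_order = 12L, fir_cutoff = 35) {
  stopifnot(inherits(record, "ecg_record"))
  x <- remove_baseline(record$samples, record$fs)
  x <- lowpass_fir(x, record$fs, fir_order, fir_cutoff)
  record$samples <- x
  record
}
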