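#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detection: 5-15 Hz band-pass (zero-phase Butterworth),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' dual adaptive thresholds with a 200 ms refractory period, the 360 ms
#' T-wave discrimination rule (a candidate closer than 360 ms to the previous
#' QRS is rejected when its peak slope is less than half the previous one's),
#' and a search-back pass at half threshold when an expected beat is missed.
#' Each reported index is refined to the largest absolute excursion of the
#' band-passed signal inside the integration window, so peak positions are in
#' input-signal coordinates.
#'
#' @param samples Preprocessed voltage vector.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 0-based R-peak sample indices, strictly
#'   increasing, no two closer than the refractory period.
#' @export
detect_r_peaks <- function(samples, fs) {
  stopifnot(fs > 0)
  n <- length(samples)
  if (n < 2 * fs) stop("record shorter than the 2 s initialization window")

  bp <- .pt_bandpass(samples, fs)
  der <- .pt_derivative(bp, fs)
  sq <- der^2
  w_int <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w_int, w_int), sides = 1L))
  mwi[seq_len(min(w_int - 1L, n))] <- 0
  mwi[!is.finite(mwi)] <- 0
  if (max(mwi) <= 0) return(integer(0))

  refract <- round(0.200 * fs)
  twave_win <- round(0.360 * fs)
  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) return(integer(0))

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(init)           # running signal-peak estimate
  npki <- 0.5 * mean(init)           # running noise-peak estimate
  thr1 <- npki + 0.25 * (spki - npki)

  qrs_mwi <- integer(0)              # accepted peaks, MWI coordinates
  qrs_slope <- numeric(0)            # peak |derivative| near each QRS
  rr_recent <- numeric(0)

  slope_at <- function(i) {
    lo <- max(1L, i - w_int); hi <- min(n, i)
    max(abs(der[lo:hi]))
  }
  accept <- function(i) {
    qrs_mwi <<- c(qrs_mwi, i)
    qrs_slope <<- c(qrs_slope, slope_at(i))
    spki <<- 0.125 * mwi[i] + 0.875 * spki
    if (length(qrs_mwi) >= 2L) {
      rr <- diff(utils::tail(qrs_mwi, 2L))
      rr_recent <<- utils::tail(c(rr_recent, rr), 8L)
    }
    thr1 <<- npki + 0.25 * (spki - npki)
  }

  for (i in cand) {
    since <- if (length(qrs_mwi)) i - qrs_mwi[length(qrs_mwi)] else Inf
    if (since <= refract) next
    if (mwi[i] > thr1) {
      if (since <= twave_win &&
          slope_at(i) < 0.5 * qrs_slope[length(qrs_slope)]) {
        # T wave masquerading as QRS
        npki <- 0.125 * mwi[i] + 0.875 * npki
        thr1 <- npki + 0.25 * (spki - npki)
        next
      }
      accept(i)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      thr1 <- npki + 0.25 * (spki - npki)
      # search-back: a beat is overdue at 1.66x the recent average RR
      if (length(rr_recent) >= 2L && length(qrs_mwi)) {
        if (since > 1.66 * mean(rr_recent)) {
          window <- cand[cand > qrs_mwi[length(qrs_mwi)] + refract & cand < i]
          window <- window[mwi[window] > 0.5 * thr1]
          if (length(window)) accept(window[which.max(mwi[window])])
        }
      }
    }
  }
  if (!length(qrs_mwi)) return(integer(0))

  # refine each detection to the band-passed signal's largest |excursion|
  # inside the integration window that produced it
  refined <- vapply(qrs_mwi, function(i) {
    lo <- max(1L, i - w_int + 1L); hi <- min(n, i)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period post-refinement (keep the larger peak)
  keep <- rep(TRUE, length(refined))
  last <- 1L
  for (j in seq_along(refined)[-1L]) {
    if (refined[j] - refined[last] <= refract) {
      if (abs(bp[refined[j]]) > abs(bp[refined[last]])) {
        keep[last] <- FALSE; last <- j
      } else keep[j] <- FALSE
    } else last <- j
  }
  as.integer(refined[keep] - 1L)  # 0-based
}

.pt_bandpass <- function(x, fs) {
  ny <- fs / 2
  bf <- signal::butter(3, c(5, 15) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

.pt_derivative <- function(x, fs) {
  # (1/8T) * (2x[n] + x[n-1] - x[n-3] - 2x[n-4]), centred
  k <- c(2, 1, 0, -1, -2) * (fs / 8)
  d <- as.numeric(stats::filter(x, k, sides = 2L))
  d[!is.finite(d)] <- 0
  d
}

#' Locate T points following each R peak
#'
#' For each R peak the T point is the sample of maximum absolute amplitude in
#' the window from 80 ms after the R peak to `min(400 ms, 0.7 * RR)` after
#' it, where RR is the interval to the next R peak (the median RR is used for
#' the final peak). Absolute amplitude makes the rule robust to inverted
#' T waves.
#'
#' @param samples Preprocessed voltage vector.
#' @param fs Sampling rate in Hz.
#' @param r_peaks 0-based R-peak indices from [detect_r_peaks()].
#' @return Integer vector of 0-based T-point indices aligned with `r_peaks`;
#'   `NA` where the search window does not fit inside the record.
#' @export
locate_t_points <- function(samples, fs, r_peaks) {
  if (length(r_peaks) < 2L) stop("need at least 2 R peaks to locate T points")
  n <- length(samples)
  rr <- diff(r_peaks)
  rr_last <- stats::median(rr)
  rr_all <- c(rr, rr_last)
  lo <- r_peaks + round(0.080 * fs)
  hi <- r_peaks + pmin(round(0.400 * fs), round(0.7 * rr_all))
  t_idx <- rep(NA_integer_, length(r_peaks))
  for (j in seq_along(r_peaks)) {
    a <- lo[j] + 1L; b <- min(hi[j] + 1L, n)  # to 1-based, clamp to record
    if (a >= b) next
    t_idx[j] <- a + which.max(abs(samples[a:b])) - 1L - 1L  # back to 0-based
  }
  t_idx
}

#' Rescale an interval to a fixed number of samples
#'
#' Linear interpolation over a uniform grid including both endpoints, so
#' endpoints are preserved and monotone inputs stay monotone.
#'
#' @param values Numeric vector, length at least 2.
#' @param n Target length (default 200).
#' @return Numeric vector of length `n`.
#' @export
rescale_interval <- function(values, n = 200L) {
  m <- length(values)
  if (m < 2L) stop("interval must contain at least 2 samples")
  if (m == n) return(as.numeric(values))
  stats::approx(x = seq_len(m), y = values,
                xout = seq(1, m, length.out = n))$y
}

#' Construct a labelled segment dataset
#'
#' @param x Numeric matrix, one 400-sample segment per row.
#' @param labels Character or factor vector of AAMI classes, one per row.
#' @param record_id,beat_index Optional provenance vectors.
#' @param dropped Number of annotated beats that could not be segmented.
#' @return An object of class `segment_dataset` with fields `x`, `labels`,
#'   `meta`, `class_counts`, `dropped`.
#' @export
segment_dataset <- function(x, labels, record_id = NULL, beat_index = NULL,
                            dropped = 0L) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = AAMI_CLASSES)
  stopifnot(nrow(x) == length(labels), !anyNA(labels))
  if (is.null(record_id)) record_id <- rep(NA_character_, nrow(x))
  if (is.null(beat_index)) beat_index <- seq_len(nrow(x))
  structure(
    list(x = x, labels = labels,
         meta = data.frame(record_id = record_id, beat_index = beat_index,
                           stringsAsFactors = FALSE),
         class_counts = table(labels),
         dropped = as.integer(dropped)),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments x %d samples; %d dropped\n",
              nrow(x$x), ncol(x$x), x$dropped))
  print(x$class_counts)
  invisible(x)
}

#' Combine segment datasets
#'
#' @param ... `segment_dataset` objects.
#' @return A single `segment_dataset`.
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "segment_dataset")))
  segment_dataset(
    do.call(rbind, lapply(parts, `[[`, "x")),
    unlist(lapply(parts, function(p) as.character(p$labels))),
    record_id = unlist(lapply(parts, function(p) p$meta$record_id)),
    beat_index = unlist(lapply(parts, function(p) p$meta$beat_index)),
    dropped = sum(vapply(parts, `[[`, 0L, "dropped"))
  )
}

#' Extract two-interval T-to-T beat segments
#'
#' Each annotated beat whose R peak falls in the T-to-T interval
#' `(T[k-1], T[k])` yields the concatenation of the preceding interval
#' `T[k-2] -> T[k-1]` and the target interval `T[k-1] -> T[k]`, each rescaled
#' to `n_per_interval` samples (400 samples total by default). A beat exactly
#' on a T boundary is assigned to the interval starting there. Beats without
#' a full preceding interval (the first beats of a record, or beats beyond
#' the last T point) are dropped and counted. Annotations with class
#' `UNMAPPED` are ignored.
#'
#' @param record A preprocessed `ecg_record`.
#' @param annotations Beat-annotation data frame (0-based `sample_index`).
#' @param t_points 0-based T-point indices from [locate_t_points()] (`NA`s
#'   allowed and skipped).
#' @param n_per_interval Samples per rescaled interval (default 200).
#' @return A `segment_dataset`; `dropped` counts annotated beats not emitted.
#' @export
extract_segments <- function(record, annotations, t_points,
                             n_per_interval = 200L) {
  stopifnot(inherits(record, "ecg_record"))
  tp <- sort(unique(t_points[!is.na(t_points)]))
  ann <- annotations[annotations$aami_class != "UNMAPPED", , drop = FALSE]
  segs <- list(); labs <- character(0); beat_ix <- integer(0)
  dropped <- 0L
  x <- record$samples
  for (i in seq_len(nrow(ann))) {
    r <- ann$sample_index[i]
    k <- findInterval(r, tp)        # tp[k] <= r < tp[k+1]
    if (k < 2L || k >= length(tp)) { dropped <- dropped + 1L; next }
    prev <- x[(tp[k - 1L] + 1L):(tp[k] + 1L)]
    targ <- x[(tp[k] + 1L):(tp[k + 1L] + 1L)]
    segs[[length(segs) + 1L]] <- c(rescale_interval(prev, n_per_interval),
                                   rescale_interval(targ, n_per_interval))
    labs <- c(labs, ann$aami_class[i])
    beat_ix <- c(beat_ix, i)
  }
  xmat <- if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(0), 0L, 2L * n_per_interval)
  segment_dataset(xmat, labs,
                  record_id = rep(record$record_id, length(labs)),
                  beat_index = beat_ix, dropped = dropped)
}

#' Write a segment dataset to a CSV store
#'
#' One row per segment: 400 value columns (`v1..v400`), then `label`,
#' `record_id`, `beat_index`.
#'
#' @param dataset A `segment_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(dataset, path) {
  stopifnot(inherits(dataset, "segment_dataset"))
  df <- as.data.frame(dataset$x)
  names(df) <- paste0("v", seq_len(ncol(df)))
  df$label <- as.character(dataset$labels)
  df$record_id <- dataset$meta$record_id
  df$beat_index <- dataset$meta$beat_index
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a segment dataset from a CSV store
#'
#' @param path CSV written by [write_segments()].
#' @return A `segment_dataset`.
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  segment_dataset(as.matrix(df[, vcols]), df$label,
                  record_id = df$record_id, beat_index = df$beat_index)
}

#' Run preprocessing and segmentation on one record
#'
#' Convenience wrapper: denoise, detect R peaks, locate T points, extract
#' segments labelled from the supplied annotations.
#'
#' @param record An `ecg_record` (raw).
#' @param annotations Beat annotations for the record.
#' @param preprocess Logical; apply [preprocess_record()] first.
#' @return A `segment_dataset`.
#' @export
segment_record <- function(record, annotations, preprocess = TRUE) {
  if (preprocess) record <- preprocess_record(record)
  r <- detect_r_peaks(record$samples, record$fs)
  tp <- locate_t_points(record$samples, record$fs, r)
  extract_segments(record, annotations, tp)
}
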