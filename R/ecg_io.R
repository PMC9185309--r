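#' AAMI beat classes
#'
#' The five heartbeat classes mandated by the Association for the Advancement
#' of Medical Instrumentation (AAMI): N (normal and bundle-branch-block
#' beats), S (supraventricular ectopic), V (ventricular ectopic), F (fusion of
#' ventricular and normal), Q (unclassifiable/paced).
#'
#' @format Character vector of length 5, in canonical reporting order.
#' @export
AAMI_CLASSES <- c("N", "S", "V", "F", "Q")

# MIT-BIH beat symbol -> AAMI class lookup. Non-beat annotation symbols
# (rhythm changes '+', signal quality '~', comments '"', etc.) are absent and
# therefore map to UNMAPPED.
.aami_symbol_map <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' Map an MIT-BIH beat symbol to its AAMI class
#'
#' Beat annotation symbols are grouped into the five AAMI classes:
#' `{N, L, R, e, j} -> N`, `{A, a, J, S} -> S`, `{V, E} -> V`, `{F} -> F`,
#' `{/, f, Q} -> Q`. Any other symbol (rhythm markers such as `"+"`, noise
#' flags, comment annotations) is not a beat and returns `"UNMAPPED"`.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @return Character vector the same length as `symbol` with values in
#'   `c(AAMI_CLASSES, "UNMAPPED")`.
#' @examples
#' map_symbol_to_aami(c("N", "L", "A", "V", "/", "+"))
#' @export
map_symbol_to_aami <- function(symbol) {
  symbol <- as.character(symbol)
  if (any(nchar(symbol) != 1L)) {
    stop("beat symbols must be single characters")
  }
  out <- unname(.aami_symbol_map[symbol])
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Construct an ECG record object
#'
#' @param record_id Record identifier string.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param samples Numeric vector of lead voltages (mV); must be non-empty and
#'   finite.
#' @param lead_name Lead label, e.g. `"MLII"`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, samples, lead_name = "MLII") {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  structure(
    list(record_id = as.character(record_id), fs = fs,
         samples = samples, lead_name = as.character(lead_name)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> lead %s, %d samples at %g Hz (%.1f s)\n",
              x$record_id, x$lead_name, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a beat-annotation table
#'
#' Each row is one annotation: the sample index of its fiducial point (the
#' R peak, by MIT-BIH convention), the single-character symbol, and the AAMI
#' class derived from the symbol. Indices are 0-based to match waveform sample
#' numbering in the WFDB ecosystem.
#'
#' @param sample_index Integer vector of 0-based sample positions.
#' @param symbol Character vector of annotation symbols.
#' @param n_samples Optional record length for bounds checking.
#' @return A `data.frame` with columns `sample_index`, `symbol`, `aami_class`.
#' @export
beat_annotations <- function(sample_index, symbol, n_samples = NULL) {
  sample_index <- as.integer(sample_index)
  symbol <- as.character(symbol)
  stopifnot(length(sample_index) == length(symbol))
  if (length(sample_index) && any(sample_index < 0L)) {
    stop("sample_index must be >= 0")
  }
  if (!is.null(n_samples) && length(sample_index) &&
      any(sample_index >= n_samples)) {
    stop("sample_index must be < record length")
  }
  data.frame(
    sample_index = sample_index,
    symbol = symbol,
    aami_class = map_symbol_to_aami(if (length(symbol)) symbol else character(0)),
    stringsAsFactors = FALSE
  )
}

#' Write a record and its annotations in the package fixture format
#'
#' The fixture layout mirrors a WFDB record in plain text: `<id>.hea.txt`
#' holds `record_id`, `fs` and `lead_name` as `key value` lines,
#' `<id>.sig.txt` holds one sample per line, and `<id>.ann.txt` is a
#' two-column CSV `sample_index,symbol` (0-based indices).
#'
#' @param record An `ecg_record`.
#' @param annotations Annotation data frame from [beat_annotations()] (may
#'   have zero rows).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the record id.
#' @export
write_record_fixture <- function(record, annotations, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  writeLines(c(
    paste("record_id", id),
    paste("fs", format(record$fs, digits = 17)),
    paste("lead_name", record$lead_name)
  ), file.path(dir, paste0(id, ".hea.txt")))
  writeLines(format(record$samples, digits = 17, trim = TRUE, scientific = FALSE),
             file.path(dir, paste0(id, ".sig.txt")))
  ann <- annotations[, c("sample_index", "symbol"), drop = FALSE]
  utils::write.csv(ann, file.path(dir, paste0(id, ".ann.txt")),
                   row.names = FALSE, quote = FALSE)
  invisible(id)
}

#' Load an ECG record with its beat annotations
#'
#' Reads either the package's plain-text fixture layout (see
#' [write_record_fixture()]) or a WFDB header/signal pair (`.hea` +
#' format-212 `.dat`, the MIT-BIH encoding) with a text annotation sidecar.
#' Annotation symbols that are not beat symbols (rhythm or quality codes) are
#' kept in the returned table with class `"UNMAPPED"`; their count is
#' reported via a message so downstream code can drop them knowingly.
#'
#' @param path Path prefix of the record (directory + record id, no
#'   extension).
#' @param lead Lead selector by name (default `"MLII"`). Only consulted for
#'   multi-signal WFDB headers.
#' @return A list with elements `record` (an `ecg_record`) and `annotations`
#'   (a data frame from [beat_annotations()]).
#' @export
load_record <- function(path, lead = "MLII") {
  hea_txt <- paste0(path, ".hea.txt")
  hea_wfdb <- paste0(path, ".hea")
  if (file.exists(hea_txt)) {
    rec <- .load_fixture_record(path)
  } else if (file.exists(hea_wfdb)) {
    rec <- .load_wfdb_record(path, lead)
  } else {
    stop("no record found at ", path, " (tried .hea.txt and .hea)")
  }
  ann_path <- paste0(path, ".ann.txt")
  if (file.exists(ann_path)) {
    ann <- utils::read.csv(ann_path, colClasses = c("integer", "character"))
    if (nrow(ann)) {
      names(ann) <- c("sample_index", "symbol")
    } else {
      ann <- data.frame(sample_index = integer(0), symbol = character(0))
    }
  } else {
    ann <- data.frame(sample_index = integer(0), symbol = character(0))
  }
  annotations <- beat_annotations(ann$sample_index, ann$symbol,
                                  n_samples = length(rec$samples))
  n_unmapped <- sum(annotations$aami_class == "UNMAPPED")
  if (n_unmapped > 0) {
    message(sprintf("record %s: %d non-beat annotation(s) kept as UNMAPPED",
                    rec$record_id, n_unmapped))
  }
  list(record = rec, annotations = annotations)
}

.load_fixture_record <- function(path) {
  hea <- readLines(paste0(path, ".hea.txt"))
  kv <- strsplit(hea, " ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), "")
  samples <- as.numeric(readLines(paste0(path, ".sig.txt")))
  ecg_record(record_id = vals[keys == "record_id"],
             fs = as.numeric(vals[keys == "fs"]),
             samples = samples,
             lead_name = vals[keys == "lead_name"])
}

# Minimal WFDB reader: parses the .hea header and a format-212 .dat file
# (two 12-bit samples packed into 3 bytes -- the MIT-BIH encoding). Values
# are converted to physical units via gain and baseline from the header.
.load_wfdb_record <- function(path, lead) {
  hea <- readLines(paste0(path, ".hea"))
  hea <- hea[!startsWith(trimws(hea), "#")]
  top <- strsplit(trimws(hea[1L]), "\\s+")[[1L]]
  record_id <- sub("/.*$", "", top[1L])
  n_sig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  n_samp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig_lines <- hea[seq_len(n_sig) + 1L]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    # file fmt gain(baseline)/units adcres adczero initval cksum bsize desc
    gain_field <- f[3L]
    gain <- as.numeric(sub("^([-0-9.]+).*$", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^[-0-9.]+\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5L) as.numeric(f[5L]) else 0
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], fmt = f[2L], gain = gain, baseline = baseline,
         desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  descs <- vapply(sigs, `[[`, "", "desc")
  idx <- match(lead, descs)
  if (is.na(idx)) {
    stop("lead '", lead, "' not present; available leads: ",
         paste(descs, collapse = ", "))
  }
  if (any(vapply(sigs, `[[`, "", "fmt") != "212")) {
    stop("only WFDB signal format 212 is supported")
  }
  dat_path <- file.path(dirname(path), sigs[[idx]]$file)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  n_pairs <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n_pairs)]), nrow = 3L)
  s1 <- b[1L, ] + bitwAnd(b[2L, ], 0x0FL) * 256L
  s2 <- b[3L, ] + bitwAnd(bitwShiftR(b[2L, ], 4L), 0x0FL) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  adc <- matrix(rbind(s1, s2), nrow = n_sig)  # interleaved by sample
  x <- adc[idx, ]
  if (!is.na(n_samp)) x <- x[seq_len(min(n_samp, length(x)))]
  phys <- (x - sigs[[idx]]$baseline) / sigs[[idx]]$gain
  ecg_record(record_id, fs, phys, lead_name = lead)
}

# Verbatim DS1/DS2 record lists of the inter-patient protocol; the four
# paced/low-quality recordings 102, 104, 107, 217 are excluded by design.
.ds1_records <- c("101", "106", "108", "109", "112", "114", "115", "116",
                  "118", "119", "122", "124", "201", "203", "205", "207",
                  "208", "209", "215", "220", "223", "230")
.ds2_records <- c("100", "103", "105", "111", "113", "117", "121", "123",
                  "200", "202", "210", "212", "213", "214", "219", "221",
                  "222", "228", "231", "232", "233", "234")

#' Inter-patient dataset splits
#'
#' Returns the standard inter-patient partition of the 44 usable MIT-BIH
#' arrhythmia records into a 22-record training set (DS1) and a 22-record
#' test set (DS2); `"ALL"` is their union. Records 102, 104, 107 and 217 are
#' excluded everywhere (paced or low-quality).
#'
#' @param name One of `"DS1"`, `"DS2"`, `"ALL"`.
#' @return A list with elements `name` and `record_ids`.
#' @export
make_split <- function(name = c("DS1", "DS2", "ALL")) {
  name <- match.arg(name)
  ids <- switch(name,
    DS1 = .ds1_records,
    DS2 = .ds2_records,
    ALL = c(.ds1_records, .ds2_records)
  )
  list(name = name, record_ids = ids)
}
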