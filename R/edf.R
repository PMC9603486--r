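#' Single-channel EEG recording
#'
#' Container for one continuous EEG trace. Polysomnography EEG used for sleep
#' staging is typically recorded at 100 Hz from the Fpz-Cz or Pz-Oz derivation.
#'
#' @param samples numeric vector of samples (microvolts).
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel channel label, e.g. `"Fpz-Cz"`.
#' @return object of class `eeg_recording` with fields `samples`, `fs`,
#'   `channel` and `duration_s` (= `length(samples)/fs`).
#' @export
#' @examples
#' r <- eeg_recording(sin(2 * pi * 2 * (0:999) / 100), fs = 100, channel = "Fpz-Cz")
#' r
eeg_recording <- function(samples, fs, channel = "EEG") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  samples <- as.numeric(samples)
  check_finite(samples, "samples")
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel),
         duration_s = length(samples) / fs),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> channel %s: %d samples at %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, x$duration_s))
  invisible(x)
}

# ---- EDF format internals -------------------------------------------------
# EDF stores a 256-byte ASCII header, then 256 bytes of per-signal header
# fields (field-major), then data records of little-endian int16 samples.
# EDF+ adds an "EDF Annotations" signal carrying time-stamped annotation
# lists (TALs): "+onset[\x15duration]\x14label\x14...\x00".

# numeric rendered to fit an 8-char EDF header field
edf_num8 <- function(v) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  substr(formatC(v, format = "e", digits = 1), 1, 8)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L) stop("corrupt EDF header: file shorter than 256 bytes")
  fld <- function(s, from, len) substr(s, from, from + len - 1L)
  n_records <- suppressWarnings(as.integer(fld(hdr, 237, 8)))
  record_dur <- suppressWarnings(as.numeric(fld(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(hdr, 253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur))
    stop("corrupt EDF header: unparseable record/signal counts")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256L * ns) stop("corrupt EDF header: truncated signal headers")
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset + (i - 1L) * width + 1L, offset + i * width)),
      character(1))
  }
  labels       <- take(16, 0)
  phys_min     <- as.numeric(take(8, ns * (16 + 80 + 8)))
  phys_max     <- as.numeric(take(8, ns * (16 + 80 + 8 + 8)))
  dig_min      <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max      <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  n_samp       <- as.integer(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  if (anyNA(n_samp)) stop("corrupt EDF header: bad samples-per-record field")
  list(version = trimws(fld(hdr, 1, 8)), reserved = trimws(fld(hdr, 193, 44)),
       n_records = n_records, record_dur = record_dur, ns = ns,
       labels = labels, phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samp = n_samp,
       header_bytes = 256L * (ns + 1L))
}

# raw int16 samples of one signal across all records
read_edf_signal_raw <- function(path, h, sig) {
  rec_len <- sum(h$n_samp)                      # int16 per record
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, h$header_bytes)
  dat <- readBin(con, "integer", n = rec_len * h$n_records, size = 2L,
                 signed = TRUE, endian = "little")
  n_rec <- length(dat) %/% rec_len
  offset <- if (sig > 1) sum(h$n_samp[seq_len(sig - 1L)]) else 0L
  idx <- outer(offset + seq_len(h$n_samp[sig]), (seq_len(n_rec) - 1L) * rec_len, "+")
  dat[as.vector(idx)]
}

#' Read one channel of an EDF/EDF+ recording
#'
#' @param path path to an EDF or EDF+ file.
#' @param channel channel label to extract (matched after trimming whitespace).
#' @return [eeg_recording()] with the channel's full trace at its native
#'   sampling rate, in physical units.
#' @export
read_edf_recording <- function(path, channel) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  h <- read_edf_header(path)
  sig <- match(channel, h$labels)
  if (is.na(sig))
    stop("channel '", channel, "' not present; available channels: ",
         paste(setdiff(h$labels, "EDF Annotations"), collapse = ", "))
  dig <- read_edf_signal_raw(path, h, sig)
  scale <- (h$phys_max[sig] - h$phys_min[sig]) / (h$dig_max[sig] - h$dig_min[sig])
  phys <- h$phys_min[sig] + (dig - h$dig_min[sig]) * scale
  fs <- h$n_samp[sig] / h$record_dur
  eeg_recording(phys, fs = fs, channel = channel)
}

#' Write recordings to an EDF/EDF+ file
#'
#' Writes one or more equal-duration recordings as EDF signals (16-bit,
#' 1-second data records). If `annotations` is given the file is written as
#' EDF+C with an `EDF Annotations` signal carrying the intervals as
#' time-stamped annotation lists, so the file doubles as a hypnogram source.
#'
#' Intended for synthetic fixtures and for exporting generated data through
#' the real reader path; amplitude resolution is limited to the 16-bit EDF
#' quantization of the per-signal range.
#'
#' @param recordings an [eeg_recording()] or list of them (equal durations).
#' @param path output path.
#' @param annotations optional `data.frame(onset_s, duration_s, label)`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path, annotations = NULL) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1)
  dur <- vapply(recordings, function(r) r$duration_s, numeric(1))
  if (max(dur) - min(dur) > 1e-9) stop("all recordings must have equal duration")
  n_records <- floor(dur[1])
  if (n_records < 1) stop("recording shorter than one 1-s data record")
  n_samp <- vapply(recordings, function(r) {
    ns <- r$fs           # samples per 1-s record
    if (abs(ns - round(ns)) > 1e-9) stop("fs must be an integer for 1-s EDF records")
    as.integer(round(ns))
  }, integer(1))

  # digital scaling per signal, symmetric range
  dig <- lapply(seq_along(recordings), function(i) {
    x <- recordings[[i]]$samples[seq_len(n_samp[i] * n_records)]
    a <- max(abs(x), 1e-12)
    as.integer(round(x / a * 32767))
  })
  amp <- vapply(seq_along(recordings), function(i) {
    max(abs(recordings[[i]]$samples[seq_len(n_samp[i] * n_records)]), 1e-12)
  }, numeric(1))

  has_ann <- !is.null(annotations)
  tal_recs <- NULL
  if (has_ann) {
    stopifnot(all(c("onset_s", "duration_s", "label") %in% names(annotations)))
    tals <- paste0("+", format(annotations$onset_s, trim = TRUE, scientific = FALSE),
                   "\x15", format(annotations$duration_s, trim = TRUE, scientific = FALSE),
                   "\x14", annotations$label, "\x14")
    # record 0 carries every annotation TAL after its timestamp TAL
    tal_recs <- vapply(seq_len(n_records) - 1L, function(r) {
      ts <- paste0("+", r, "\x14\x14")
      if (r == 0L) paste0(ts, paste(tals, collapse = "")) else ts
    }, character(1))
    ann_bytes <- max(nchar(tal_recs, type = "bytes")) + 2L
    ann_bytes <- ann_bytes + (ann_bytes %% 2L)      # int16 alignment
    ann_nsamp <- ann_bytes %/% 2L
  }

  ns <- length(recordings) + as.integer(has_ann)
  labels <- vapply(recordings, function(r) r$channel, character(1))
  if (has_ann) labels <- c(labels, "EDF Annotations")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr(if (has_ann) "EDF+C" else "", 44)
  wr(n_records, 8); wr(1, 8); wr(ns, 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= length(recordings)) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= length(recordings)) edf_num8(-amp[i]) else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= length(recordings)) edf_num8(amp[i]) else 1, 8)
  for (i in seq_len(ns)) wr(-32767L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  all_nsamp <- c(n_samp, if (has_ann) ann_nsamp)
  for (v in all_nsamp) wr(v, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_records)) {
    for (i in seq_along(recordings)) {
      s <- dig[[i]][((r - 1L) * n_samp[i] + 1L):(r * n_samp[i])]
      writeBin(s, con, size = 2L, endian = "little")
    }
    if (has_ann) {
      b <- charToRaw(tal_recs[r])
      writeBin(c(b, raw(ann_bytes - length(b))), con)
    }
  }
  invisible(path)
}
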