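#' Default raw-label to stage mapping
#'
#' Maps the label dialects found in public sleep-EDF hypnograms onto the
#' canonical six stages. Labels mapped to `NA` (Movement Time, unscored `?`)
#' are representable on input but excluded at segmentation.
#'
#' @return named character vector; names are raw labels, values are canonical
#'   stages or `NA` for excluded labels.
#' @export
default_stage_map <- function() {
  c("Sleep stage W" = "W", "W" = "W", "Awake" = "W",
    "Sleep stage 1" = "S1", "1" = "S1", "S1" = "S1",
    "Sleep stage 2" = "S2", "2" = "S2", "S2" = "S2",
    "Sleep stage 3" = "S3", "3" = "S3", "S3" = "S3",
    "Sleep stage 4" = "S4", "4" = "S4", "S4" = "S4",
    "Sleep stage R" = "REM", "R" = "REM", "REM" = "REM",
    "Movement time" = NA, "Sleep stage ?" = NA, "M" = NA, "?" = NA)
}

#' Read a hypnogram
#'
#' Reads expert sleep-stage annotations either from an EDF+ file with an
#' `EDF Annotations` signal or from a plain 3-column tab-separated table
#' (`onset_s`, `duration_s`, `label`; header optional). Raw labels are kept
#' verbatim -- mapping to canonical stages happens in [segment_epochs()].
#'
#' @param path annotation file.
#' @param format `"auto"` (default; EDF if the file has an EDF header),
#'   `"edf"` or `"tsv"`.
#' @return `data.frame(onset_s, duration_s, label)`, sorted by onset,
#'   non-overlapping.
#' @export
read_hypnogram <- function(path, format = c("auto", "edf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  if (format == "auto") {
    first <- readBin(path, "raw", n = 8L)
    format <- if (identical(trimws(rawToChar(first)), "0")) "edf" else "tsv"
  }
  hyp <- if (format == "edf") read_hypnogram_edf(path) else read_hypnogram_tsv(path)
  hyp <- hyp[order(hyp$onset_s), , drop = FALSE]
  rownames(hyp) <- NULL
  if (nrow(hyp) > 1) {
    ends <- hyp$onset_s + hyp$duration_s
    if (any(hyp$onset_s[-1] < ends[-nrow(hyp)] - 1e-9))
      stop("hypnogram intervals overlap")
  }
  hyp
}

read_hypnogram_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][1])))
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         colClasses = c("numeric", "numeric", "character"),
                         col.names = c("onset_s", "duration_s", "label"),
                         quote = "", comment.char = "")
  d
}

read_hypnogram_edf <- function(path) {
  h <- read_edf_header(path)
  sig <- match("EDF Annotations", h$labels)
  if (is.na(sig)) stop("EDF file has no 'EDF Annotations' signal")
  dig <- read_edf_signal_raw(path, h, sig)
  # int16 stream back to bytes (little-endian)
  b <- writeBin(as.integer(dig), raw(), size = 2L, endian = "little")
  txt <- rawToChar(b[b != as.raw(0)])
  # TALs: [+-]onset[\x15duration]\x14label\x14...; timestamp TALs have no label
  tals <- strsplit(txt, "\x14\\+", perl = TRUE)[[1]]
  out <- list()
  for (t in tals) {
    t <- sub("^\\+", "", t)
    parts <- strsplit(t, "\x14")[[1]]
    head_part <- strsplit(parts[1], "\x15")[[1]]
    labels <- parts[-1]
    labels <- labels[nzchar(labels)]
    if (!length(labels)) next
    onset <- suppressWarnings(as.numeric(head_part[1]))
    durat <- if (length(head_part) > 1) suppressWarnings(as.numeric(head_part[2])) else 0
    if (is.na(onset)) next
    for (lab in labels)
      out[[length(out) + 1L]] <- data.frame(onset_s = onset, duration_s = durat,
                                            label = lab, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
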