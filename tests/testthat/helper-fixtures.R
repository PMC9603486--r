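# Fixture builders shared across test files. Everything is generated in code
# at test time; nothing is read from disk except files these helpers write
# to tempdir().

write_tsv_hypnogram <- function(df, path = tempfile(fileext = ".tsv"),
                                header = FALSE) {
  if (header) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = c("onset_s", "duration_s", "label"),
                       quote = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  path
}

# 60-s two-tone synthetic recording at 100 Hz, amplitude ~50 uV
make_test_recording <- function(seconds = 60, fs = 100, seed = 7) {
  n <- seconds * fs
  t <- (seq_len(n) - 1) / fs
  x <- with_test_seed(seed, 40 * sin(2 * pi * 2 * t) +
                        10 * sin(2 * pi * 11 * t) + rnorm(n, 0, 3))
  eeg_recording(x, fs = fs, channel = "Fpz-Cz")
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# simple two-interval hypnogram covering `seconds` of recording
make_test_hypnogram <- function(seconds = 60) {
  data.frame(onset_s = c(0, seconds / 2),
             duration_s = c(seconds / 2, seconds / 2),
             label = c("Sleep stage W", "Sleep stage 2"),
             stringsAsFactors = FALSE)
}

# Welch-style smoothed periodogram; returns data.frame(freq_hz, power)
psd_estimate <- function(x, fs) {
  p <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(9, 9),
                         taper = 0.1, plot = FALSE, detrend = TRUE)
  data.frame(freq_hz = p$freq, power = p$spec)
}

band_power <- function(psd, lo, hi) {
  sel <- psd$freq_hz >= lo & psd$freq_hz <= hi
  mean(psd$power[sel])
}
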