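#' Labelled epoch set
#'
#' A collection of fixed-length, single-stage EEG epochs. Samples are held as
#' an `n_epochs x n_samples` numeric matrix; per-epoch metadata (stage,
#' source recording, ordinal index) lives in a parallel data frame.
#'
#' @param samples numeric matrix, one epoch per row.
#' @param stage vector coercible by [sleep_stages()]; one label per epoch.
#' @param fs sampling rate (Hz).
#' @param epoch_len_s epoch length in seconds.
#' @param source_id recording identifier(s), recycled.
#' @param index ordinal of each epoch within its recording.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(samples, stage, fs, epoch_len_s,
                      source_id = "synthetic", index = seq_len(nrow(samples))) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(stage) && length(stage) != 0)
    stop("one stage label per epoch required")
  if (nrow(samples) > 0 && ncol(samples) != round(fs * epoch_len_s))
    stop("epoch length ", ncol(samples), " does not match fs * epoch_len_s = ",
         fs * epoch_len_s)
  structure(
    list(samples = samples,
         meta = data.frame(stage = sleep_stages(stage),
                           source_id = rep_len(as.character(source_id), nrow(samples)),
                           index = rep_len(as.integer(index), nrow(samples)),
                           stringsAsFactors = FALSE),
         fs = fs, epoch_len_s = epoch_len_s),
    class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) nrow(x$samples)

#' @export
`[.epoch_set` <- function(x, i, ...) {
  out <- x
  out$samples <- x$samples[i, , drop = FALSE]
  out$meta <- x$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s at %g Hz (%d samples each)\n",
              length(x), x$epoch_len_s, x$fs, ncol(x$samples)))
  if (length(x)) print(table(stage = x$meta$stage))
  invisible(x)
}

#' Combine epoch sets
#' @param ... `epoch_set` objects with identical `fs` and `epoch_len_s`.
#' @return a single `epoch_set`.
#' @export
c.epoch_set <- function(...) {
  sets <- list(...)
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  el <- unique(vapply(sets, function(s) s$epoch_len_s, numeric(1)))
  if (length(fs) != 1 || length(el) != 1) stop("epoch sets differ in fs or epoch length")
  out <- sets[[1]]
  out$samples <- do.call(rbind, lapply(sets, `[[`, "samples"))
  out$meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(out$meta) <- NULL
  out
}

#' Segment a recording into labelled 30-s epochs
#'
#' Cuts the trace into consecutive non-overlapping windows of `epoch_len_s`
#' seconds (a trailing partial window is dropped) and labels each window with
#' the hypnogram stage at the window midpoint. Windows whose raw label maps
#' to Movement Time or an unknown stage, or whose midpoint the hypnogram does
#' not cover, are excluded; exclusion counts are reported via `message()` and
#' attached as the `"exclusions"` attribute.
#'
#' @param rec an [eeg_recording()].
#' @param hyp hypnogram `data.frame(onset_s, duration_s, label)` as returned
#'   by [read_hypnogram()].
#' @param epoch_len_s epoch length in seconds (default 30, the standard
#'   scoring window).
#' @param stage_map named vector mapping raw labels to canonical stages
#'   (`NA` = exclude); see [default_stage_map()].
#' @param source_id identifier stored with each epoch.
#' @return [epoch_set()] of the retained epochs.
#' @export
segment_epochs <- function(rec, hyp, epoch_len_s = 30,
                           stage_map = default_stage_map(),
                           source_id = "recording") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_len_s <= 0) stop("epoch_len_s must be positive")
  spe <- rec$fs * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_len_s = ", spe, " is not an integer number of samples")
  spe <- as.integer(round(spe))
  n_total <- floor(length(rec$samples) / spe)
  if (n_total < 1) {
    warning("recording shorter than one epoch")
    return(epoch_set(matrix(numeric(0), 0, spe), character(0), rec$fs, epoch_len_s))
  }

  onset <- (seq_len(n_total) - 1) * epoch_len_s
  mid <- onset + epoch_len_s / 2
  # hypnogram interval containing each midpoint (hyp sorted by onset)
  iv <- findInterval(mid, hyp$onset_s)
  covered <- iv >= 1 & mid < (hyp$onset_s[pmax(iv, 1)] + hyp$duration_s[pmax(iv, 1)])
  raw_lab <- ifelse(covered, hyp$label[pmax(iv, 1)], NA_character_)
  mapped <- unname(stage_map[raw_lab])
  known_raw <- raw_lab %in% names(stage_map)
  keep <- covered & known_raw & !is.na(mapped)

  n_unc <- sum(!covered)
  n_unk <- sum(covered & !known_raw)
  n_mov <- sum(covered & known_raw & is.na(mapped))
  message(sprintf(
    "segment_epochs: %d epochs (%d retained; excluded: %d movement-time/unscored, %d unknown label, %d uncovered)",
    n_total, sum(keep), n_mov, n_unk, n_unc))
  if (!any(keep)) warning("no epochs retained after exclusions")

  idx <- which(keep)
  samp <- matrix(rec$samples[rep((idx - 1L) * spe, each = spe) + seq_len(spe)],
                 nrow = length(idx), ncol = spe, byrow = TRUE)
  es <- epoch_set(samp, mapped[idx], rec$fs, epoch_len_s,
                  source_id = source_id, index = idx)
  attr(es, "exclusions") <- c(movement_or_unscored = n_mov, unknown = n_unk,
                              uncovered = n_unc, total_before = n_total)
  es
}

#' Split an epoch set into train and test subsets
#'
#' Seed-deterministic random split. By default epochs are pooled and split
#' individually (matching whole-corpus 60/40 segment counts); with
#' `by_recording = TRUE` whole recordings are assigned to one side, the
#' leakage-safe alternative.
#'
#' @param es an [epoch_set()].
#' @param train_frac proportion of epochs for the training set (0 < f < 1).
#' @param seed integer seed; mandatory so splits are reproducible.
#' @param by_recording assign whole recordings rather than epochs.
#' @return `list(train =, test =)` of disjoint, exhaustive `epoch_set`s with
#'   `|train| = round(train_frac * n)` (epoch-wise mode).
#' @export
split_train_test <- function(es, train_frac = 0.6, seed, by_recording = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (missing(seed)) stop("seed is required")
  n <- length(es)
  if (n == 0) stop("cannot split an empty epoch_set")
  if (by_recording) {
    recs <- unique(es$meta$source_id)
    ord <- with_seed(seed, sample(recs))
    counts <- table(es$meta$source_id)[ord]
    n_train_target <- round(train_frac * n)
    take <- which(cumsum(counts) <= n_train_target)
    train_recs <- ord[take]
    tr_idx <- which(es$meta$source_id %in% train_recs)
  } else {
    n_train <- round(train_frac * n)
    perm <- with_seed(seed, sample.int(n))
    tr_idx <- sort(perm[seq_len(n_train)])
  }
  te_idx <- setdiff(seq_len(n), tr_idx)
  out <- list(train = es[tr_idx], test = es[te_idx])
  message(sprintf("split_train_test: %d train / %d test", length(out$train), length(out$test)))
  out
}

#' Write / read an epoch set container
#'
#' The on-disk container is a directory with `meta.csv` (stage, source_id,
#' index), `samples.csv` (one epoch per row) and `info.json` (fs,
#' epoch_len_s). Plain text, byte-stable for a given input.
#'
#' @param es an [epoch_set()].
#' @param dir directory to create/use.
#' @return `dir` (write) or the reconstructed `epoch_set` (read).
#' @export
write_epoch_set <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(es$meta, file.path(dir, "meta.csv"))
  data.table::fwrite(as.data.frame(es$samples), file.path(dir, "samples.csv"),
                     col.names = FALSE)
  jsonlite::write_json(list(fs = es$fs, epoch_len_s = es$epoch_len_s),
                       file.path(dir, "info.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "info.json"), simplifyVector = TRUE)
  meta <- data.table::fread(file.path(dir, "meta.csv"), data.table = FALSE)
  samp <- as.matrix(data.table::fread(file.path(dir, "samples.csv"),
                                      header = FALSE, data.table = FALSE))
  dimnames(samp) <- NULL
  epoch_set(samp, meta$stage, info$fs, info$epoch_len_s,
            source_id = meta$source_id, index = meta$index)
}
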