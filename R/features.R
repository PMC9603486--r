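FEATURE_NAMES <- c("mean", "std", "rms", "ppv", "skewness", "margin_factor",
                   "crest_factor", "impulse_factor", "srm", "kurtosis_value",
                   "kurtosis_factor")

#' Eleven time-domain statistical features
#'
#' Computes, in fixed order: mean; standard deviation (N-1 divisor); RMS;
#' peak-to-peak value; skewness `(1/N) sum(((x - mean)/sd)^3)`; margin factor
#' `max|x| / SRM`; crest factor `max|x| / RMS`; impulse factor
#' `max|x| / mean|x|`; square root of the magnitude
#' `SRM = ((1/N) sum(sqrt(|x|)))^2`; kurtosis value
#' `(1/N) sum(((x - mean)/sd)^4)` (non-excess); kurtosis factor
#' `KV / ((1/N) sum(x^2))^2`.
#'
#' Degenerate inputs never produce NaN/Inf: when `sd == 0` the standardized
#' moments (skewness, kurtosis value, kurtosis factor) are returned as 0;
#' when `x` is all zero the amplitude-ratio features (margin, crest, impulse
#' factor, kurtosis factor) are returned as 0. Affected names are recorded
#' in the `"degenerate"` attribute.
#'
#' @param x finite numeric vector, `length(x) >= 2`.
#' @return named numeric vector of length 11 with attribute `"degenerate"`
#'   (character vector of zero-substituted features, possibly empty).
#' @export
#' @examples
#' statistical_features(sin(2 * pi * (0:299) / 30))
statistical_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  check_finite(x, "x")
  degenerate <- character(0)

  mu <- mean(x)
  sdev <- sqrt(sum((x - mu)^2) / (n - 1))
  rms <- sqrt(mean(x^2))
  ppv <- max(x) - min(x)
  peak <- max(abs(x))
  abs_mean <- mean(abs(x))
  srm <- mean(sqrt(abs(x)))^2
  ms <- mean(x^2)

  if (sdev > 0) {
    z <- (x - mu) / sdev
    sv <- mean(z^3)
    kv <- mean(z^4)
  } else {
    sv <- kv <- 0
    degenerate <- c(degenerate, "skewness", "kurtosis_value", "kurtosis_factor")
  }

  if (peak > 0) {
    mf <- peak / srm
    crest <- peak / rms
    impf <- peak / abs_mean
    kf <- if (sdev > 0) kv / ms^2 else 0
  } else {
    mf <- crest <- impf <- kf <- 0
    degenerate <- unique(c(degenerate, "margin_factor", "crest_factor",
                           "impulse_factor", "kurtosis_factor"))
  }

  out <- c(mu, sdev, rms, ppv, sv, mf, crest, impf, srm, kv, kf)
  names(out) <- FEATURE_NAMES
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-IMF feature vector for one epoch
#'
#' Concatenates [statistical_features()] of IMF1..IMFk into a fixed-length
#' vector of `11 * max_imfs` entries (layout `imf1_mean ... imf1_kurtosis_factor,
#' imf2_mean, ...`). When the decomposition produced fewer than `max_imfs`
#' modes the missing blocks are zero and flagged off in the `"mask"`
#' attribute. The residue is not a mode and is excluded by default.
#'
#' @param d an [emd()] decomposition.
#' @param max_imfs feature-block count (default 10).
#' @param include_residue append an extra 11-feature block for the residue.
#' @return named numeric vector with logical attribute `"mask"` (per-IMF
#'   presence flags).
#' @export
features_from_imfs <- function(d, max_imfs = 10, include_residue = FALSE) {
  stopifnot(inherits(d, "emd"))
  k <- ncol(d$imfs)
  if (k == 0) warning("empty decomposition: all-zero feature vector")
  n_block <- max_imfs + as.integer(include_residue)
  out <- numeric(11L * n_block)
  mask <- logical(n_block)
  for (i in seq_len(min(k, max_imfs))) {
    out[(i - 1L) * 11L + 1:11] <- statistical_features(d$imfs[, i])
    mask[i] <- TRUE
  }
  if (include_residue) {
    out[max_imfs * 11L + 1:11] <- statistical_features(d$residue)
    mask[n_block] <- TRUE
  }
  blocks <- c(paste0("imf", seq_len(max_imfs)), if (include_residue) "residue")
  names(out) <- paste(rep(blocks, each = 11L), FEATURE_NAMES, sep = "_")
  attr(out, "mask") <- mask
  out
}

#' Decompose and featurize every epoch of a set
#'
#' Runs [emd()] on each epoch and assembles the per-epoch feature matrix.
#' With `features_from = "denoised"` the statistics are instead computed on
#' the partial reconstruction after dropping the first `drop_first_k` IMFs
#' (11 features per epoch rather than `11 * max_imfs`).
#'
#' @param es an [epoch_set()].
#' @param max_imfs IMF cap for the decomposition and the feature layout.
#' @param features_from `"imfs"` (default) or `"denoised"`.
#' @param drop_first_k leading IMFs discarded in `"denoised"` mode.
#' @param sd_threshold,max_sift_iters sifting controls, see [sift()].
#' @return list with `X` (feature matrix, one epoch per row, named columns),
#'   `stage` (factor), `mask` (logical matrix of IMF presence) and `meta`.
#' @export
featurize_epochs <- function(es, max_imfs = 10,
                             features_from = c("imfs", "denoised"),
                             drop_first_k = 1,
                             sd_threshold = 0.2, max_sift_iters = 200) {
  stopifnot(inherits(es, "epoch_set"))
  features_from <- match.arg(features_from)
  n <- length(es)
  p <- if (features_from == "imfs") 11L * max_imfs else 11L
  X <- matrix(0, n, p)
  mask <- matrix(FALSE, n, max_imfs)
  for (i in seq_len(n)) {
    d <- emd(es$samples[i, ], max_imfs = max_imfs, sd_threshold = sd_threshold,
             max_sift_iters = max_sift_iters)
    if (features_from == "imfs") {
      fv <- features_from_imfs(d, max_imfs)
      X[i, ] <- fv
      if (i == 1L) colnames(X) <- names(fv)
      mask[i, ] <- attr(fv, "mask")
    } else {
      k <- ncol(d$imfs)
      X[i, ] <- statistical_features(denoise(d, min(drop_first_k, max(k - 1, 0))))
      if (i == 1L) colnames(X) <- FEATURE_NAMES
      mask[i, seq_len(k)] <- TRUE
    }
  }
  list(X = X, stage = es$meta$stage, mask = mask, meta = es$meta)
}

#' Min-max feature scaling fit on the training set
#'
#' Scales every column to `[0, 1]` using the training minima and ranges and
#' applies the same transform to the test matrix (test values outside the
#' training range extrapolate beyond `[0, 1]`; no clipping). Constant
#' training columns map to 0 in both sets.
#'
#' @param train_X,test_X numeric matrices with matching columns
#'   (`test_X` optional).
#' @return `list(train, test, min, range)`.
#' @export
normalize_features <- function(train_X, test_X = NULL) {
  train_X <- as.matrix(train_X)
  if (!nrow(train_X)) stop("empty training matrix")
  mn <- apply(train_X, 2, min)
  rg <- apply(train_X, 2, max) - mn
  scale1 <- function(M) {
    M <- sweep(as.matrix(M), 2, mn, "-")
    M <- sweep(M, 2, ifelse(rg > 0, rg, 1), "/")
    M[, rg == 0] <- 0
    M
  }
  list(train = scale1(train_X),
       test = if (!is.null(test_X)) scale1(test_X),
       min = mn, range = rg)
}

#' Write a feature matrix with labels as CSV
#'
#' @param feats result of [featurize_epochs()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feats, path) {
  d <- data.frame(stage = as.character(feats$stage),
                  source_id = feats$meta$source_id,
                  feats$X, check.names = FALSE)
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  list(X = as.matrix(d[, setdiff(names(d), c("stage", "source_id")), drop = FALSE]),
       stage = sleep_stages(d$stage),
       meta = d[, c("stage", "source_id"), drop = FALSE])
}
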