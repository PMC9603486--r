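#' Locate strict local extrema
#'
#' Finds interior local maxima and minima of a sequence. Flat plateaus
#' contribute a single extremum at the plateau midpoint (the lower of the two
#' middle indices when the plateau has even length); endpoints are never
#' extrema; a constant signal has none.
#'
#' @param x numeric vector, `length(x) >= 3`.
#' @return `list(maxima =, minima =)` of integer index vectors.
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2)
    return(list(maxima = integer(0), minima = integer(0)))
  sv <- s[nz]
  ch <- which(sv[-length(sv)] != sv[-1])
  if (!length(ch))
    return(list(maxima = integer(0), minima = integer(0)))
  i1 <- nz[ch]                 # last nonzero slope before the turn
  i2 <- nz[ch + 1L]            # first nonzero slope after it
  pos <- (i1 + 1L + i2) %/% 2L # plateau midpoint, lower index on ties
  ismax <- sv[ch] > 0
  list(maxima = pos[ismax], minima = pos[!ismax])
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

is_imf <- function(x) {
  e <- find_extrema(x)
  abs(length(e$maxima) + length(e$minima) - count_zero_crossings(x)) <= 1L
}

# mirror-extend k extrema across each end of the signal (about samples 1 and n)
mirror_extend <- function(x, idx, n, k = 2L) {
  k <- min(k, length(idx))
  li <- 2L - idx[seq_len(k)]
  ri <- rev(idx)[seq_len(k)]
  list(i = c(rev(li), idx, 2L * n - ri),
       v = c(rev(x[idx[seq_len(k)]]), x[idx], x[ri]))
}

#' Mean of the upper and lower spline envelopes
#'
#' Interpolates the maxima (upper envelope) and minima (lower envelope) with
#' natural cubic splines through supports mirror-extended by two extrema at
#' each boundary, and returns the pointwise envelope mean -- the quantity
#' subtracted at each sifting step.
#'
#' @param x numeric vector.
#' @param maxima,minima extrema indices, e.g. from [find_extrema()].
#' @param boundary `"mirror"` (default) or `"clamp"` (repeat the outermost
#'   extremum value at the signal ends).
#' @return numeric vector of `length(x)`.
#' @export
mean_envelope <- function(x, maxima, minima, boundary = c("mirror", "clamp")) {
  boundary <- match.arg(boundary)
  n <- length(x)
  if (length(maxima) < 2 || length(minima) < 2)
    stop("need at least 2 maxima and 2 minima to build envelopes")
  sup <- function(idx) {
    if (boundary == "mirror") mirror_extend(x, idx, n)
    else list(i = c(1L, idx, n), v = c(x[idx[1]], x[idx], x[idx[length(idx)]]))
  }
  a <- sup(maxima); b <- sup(minima)
  up <- stats::spline(a$i, a$v, xout = seq_len(n), method = "natural")$y
  lo <- stats::spline(b$i, b$v, xout = seq_len(n), method = "natural")$y
  (up + lo) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h <- h - mean_envelope(h)` until the Cauchy-style criterion
#' `SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold` is met *and* the
#' candidate satisfies the IMF extrema/zero-crossing condition, or the
#' iteration cap is reached (never an error: the partial result is returned
#' with `stop_reason = "max_iters"`).
#'
#' @param x numeric vector with enough extrema to sift.
#' @param sd_threshold Cauchy threshold (default 0.2, the classical value).
#' @param max_sift_iters iteration cap (default 200).
#' @param boundary envelope boundary handling, see [mean_envelope()].
#' @return `list(imf, n_iters, stop_reason)` with `stop_reason` one of
#'   `"sd"`, `"max_iters"`, `"unsiftable"`.
#' @export
sift <- function(x, sd_threshold = 0.2, max_sift_iters = 200,
                 boundary = "mirror") {
  stopifnot(sd_threshold > 0, max_sift_iters >= 1)
  h <- x
  for (it in seq_len(max_sift_iters)) {
    e <- find_extrema(h)
    if (length(e$maxima) < 2 || length(e$minima) < 2)
      return(list(imf = h, n_iters = it - 1L, stop_reason = "unsiftable"))
    m <- mean_envelope(h, e$maxima, e$minima, boundary)
    sd_crit <- sum(m^2) / sum(h^2)
    h <- h - m
    if (sd_crit < sd_threshold && is_imf(h))
      return(list(imf = h, n_iters = it, stop_reason = "sd"))
  }
  list(imf = h, n_iters = max_sift_iters, stop_reason = "max_iters")
}

# residue stopping: unsiftable, or monotone / single hump
# (fewer than 2 maxima or fewer than 2 minima among interior extrema)
residue_done <- function(r) {
  if (length(r) < 3) return(TRUE)
  e <- find_extrema(r)
  length(e$maxima) < 2 || length(e$minima) < 2
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by repeatedly
#' sifting the running residue: IMF1 carries the fastest oscillations, later
#' IMFs successively slower ones, and the residue the remaining trend. The
#' decomposition is complete by construction:
#' `rowSums over IMFs + residue == x` to floating-point accuracy.
#'
#' @param x numeric vector, `length(x) >= 10`, finite.
#' @param max_imfs maximum number of IMFs (default 10).
#' @param sd_threshold,max_sift_iters,boundary passed to [sift()].
#' @return object of class `emd`: `imfs` (`length(x) x k` matrix, one IMF per
#'   column), `residue`, and `meta` (per-IMF sift iteration counts and stop
#'   reasons).
#' @export
#' @examples
#' t <- (0:999) / 100
#' d <- emd(sin(2 * pi * 14 * t) + 4 * sin(2 * pi * 2 * t))
#' d
emd <- function(x, max_imfs = 10, sd_threshold = 0.2, max_sift_iters = 200,
                boundary = "mirror") {
  if (length(x) < 10) stop("signal too short to decompose")
  check_finite(x, "input signal")
  stopifnot(max_imfs >= 1)
  r <- as.numeric(x)
  imfs <- vector("list", 0L)
  n_iters <- integer(0); reasons <- character(0)
  while (length(imfs) < max_imfs && !residue_done(r)) {
    s <- sift(r, sd_threshold, max_sift_iters, boundary)
    if (s$stop_reason == "unsiftable" && s$n_iters == 0L) break
    imfs[[length(imfs) + 1L]] <- s$imf
    n_iters <- c(n_iters, s$n_iters)
    reasons <- c(reasons, s$stop_reason)
    r <- r - s$imf
  }
  k <- length(imfs)
  structure(
    list(imfs = if (k) matrix(unlist(imfs), ncol = k,
                              dimnames = list(NULL, paste0("IMF", seq_len(k))))
                else matrix(numeric(0), length(x), 0),
         residue = r,
         meta = data.frame(imf = seq_len(k), n_sift_iters = n_iters,
                           stop_reason = reasons, stringsAsFactors = FALSE),
         input_length = length(x)),
    class = "emd")
}

#' @export
print.emd <- function(x, ...) {
  cat(sprintf("<emd> %d IMFs + residue (input length %d)\n",
              ncol(x$imfs), x$input_length))
  if (nrow(x$meta)) print(x$meta, row.names = FALSE)
  invisible(x)
}

#' @export
plot.emd <- function(x, fs = NULL, max_panels = ncol(x$imfs) + 2L, ...) {
  k <- ncol(x$imfs)
  n <- x$input_length
  tt <- if (is.null(fs)) seq_len(n) else (seq_len(n) - 1) / fs
  sig <- rowSums(x$imfs) + x$residue
  panels <- min(max_panels, k + 2L)
  old <- par(mfrow = c(panels, 1), mar = c(1.5, 4, 0.5, 1))
  on.exit(par(old))
  plot(tt, sig, type = "l", ylab = "signal", xlab = "")
  for (i in seq_len(min(k, panels - 2L)))
    plot(tt, x$imfs[, i], type = "l", ylab = colnames(x$imfs)[i], xlab = "")
  plot(tt, x$residue, type = "l", ylab = "residue",
       xlab = if (is.null(fs)) "sample" else "time (s)")
  invisible(x)
}

#' Partial reconstruction after discarding leading IMFs
#'
#' EMD-based denoising by IMF selection: the first `drop_first_k` IMFs (the
#' highest-frequency modes, where broadband artifact energy concentrates)
#' are discarded and the remaining modes plus residue are summed. With
#' `drop_first_k = 0` the input is reconstructed exactly.
#'
#' @param d an [emd()] decomposition.
#' @param drop_first_k number of leading IMFs to discard
#'   (`0 <= drop_first_k < ncol(d$imfs)`); default 1.
#' @return numeric vector, the denoised signal.
#' @export
denoise <- function(d, drop_first_k = 1) {
  stopifnot(inherits(d, "emd"))
  k <- ncol(d$imfs)
  if (drop_first_k < 0) stop("drop_first_k must be non-negative")
  if (drop_first_k >= k && !(drop_first_k == 0 && k == 0))
    stop("drop_first_k = ", drop_first_k, " but only ", k, " IMFs present")
  keep <- setdiff(seq_len(k), seq_len(drop_first_k))
  if (length(keep)) rowSums(d$imfs[, keep, drop = FALSE]) + d$residue
  else d$residue
}
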