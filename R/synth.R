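#' Stage-specific synthetic EEG specification
#'
#' Describes the spectral content of one sleep stage as a sum of band-limited
#' random-phase sinusoids, optional burst transients (sleep spindles,
#' sawtooth waves) and additive white baseline noise. Amplitudes are in
#' microvolts; a band's `amplitude` sets the RMS of that band component to
#' `amplitude / sqrt(2)` (the RMS of a single sinusoid at that peak).
#'
#' @param stage canonical stage label.
#' @param bands `data.frame(low, high, amplitude)`, band edges in Hz.
#' @param transient optional
#'   `list(center_hz, duration_s, rate, amplitude, shape)` with `shape`
#'   `"spindle"` (Hann-windowed sinusoid burst) or `"sawtooth"`.
#' @param baseline_noise_sd white-noise standard deviation (microvolts).
#' @return object of class `stage_spec`.
#' @export
stage_spec <- function(stage, bands, transient = NULL, baseline_noise_sd = 4) {
  stage <- as.character(sleep_stages(stage))
  bands <- as.data.frame(bands)
  stopifnot(all(c("low", "high", "amplitude") %in% names(bands)),
            all(bands$amplitude >= 0), all(bands$low < bands$high))
  if (!is.null(transient))
    stopifnot(all(c("center_hz", "duration_s", "rate", "amplitude", "shape")
                  %in% names(transient)))
  structure(list(stage = stage, bands = bands, transient = transient,
                 baseline_noise_sd = baseline_noise_sd),
            class = "stage_spec")
}

#' Default stage specifications
#'
#' The six default generators reflect the textbook wave content of each
#' stage: W desynchronized broadband (4--30 Hz) at low amplitude; S1 slow
#' 2--7 Hz activity at the highest amplitude; S2 a moderate background with
#' 12--14 Hz sleep-spindle bursts; S3 and S4 dominant ~2 Hz slow waves, S4
#' with a larger delta fraction; REM mixed-frequency low-amplitude activity
#' with slow sawtooth bursts.
#'
#' @return named list of [stage_spec()]s in canonical stage order.
#' @export
default_stage_specs <- function() {
  list(
    W  = stage_spec("W",  data.frame(low = 4,  high = 30,  amplitude = 12)),
    S1 = stage_spec("S1", data.frame(low = 2,  high = 7,   amplitude = 60)),
    S2 = stage_spec("S2", data.frame(low = 4,  high = 8,   amplitude = 20),
                    transient = list(center_hz = 13, duration_s = 1, rate = 6,
                                     amplitude = 45, shape = "spindle")),
    S3 = stage_spec("S3", data.frame(low = c(1.5, 4), high = c(2.5, 8),
                                     amplitude = c(60, 20))),
    S4 = stage_spec("S4", data.frame(low = c(1.5, 4), high = c(2.5, 8),
                                     amplitude = c(130, 5))),
    REM = stage_spec("REM", data.frame(low = 2, high = 30, amplitude = 15),
                     transient = list(center_hz = 2.5, duration_s = 1.5, rate = 6,
                                      amplitude = 45, shape = "sawtooth")))
}

# sum of m random-phase sinusoids with frequencies drawn in [low, high];
# per-component amplitude chosen so the band RMS equals amplitude/sqrt(2)
band_component <- function(t, low, high, amplitude, fs) {
  if (amplitude == 0) return(numeric(length(t)))
  if (high >= fs / 2) stop("band upper edge ", high, " Hz at or above Nyquist (fs = ", fs, ")")
  m <- max(5L, ceiling(2 * (high - low)))
  f <- runif(m, low, high)
  ph <- runif(m, 0, 2 * pi)
  a <- amplitude / sqrt(m)
  colSums(a * sin(outer(f, t, function(fr, tt) 2 * pi * fr * tt) + ph))
}

burst_component <- function(t, tr, fs, epoch_len_s) {
  out <- numeric(length(t))
  n_burst <- tr$rate
  if (n_burst < 1) return(out)
  starts <- runif(n_burst, 0, max(epoch_len_s - tr$duration_s, 0))
  nb <- round(tr$duration_s * fs)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))   # Hann
  for (s in starts) {
    i0 <- floor(s * fs) + 1L
    ii <- i0:(i0 + nb - 1L)
    ii <- ii[ii <= length(t)]
    tt <- t[ii]
    w <- win[seq_along(ii)]
    if (tr$shape == "spindle") {
      out[ii] <- out[ii] + tr$amplitude * w * sin(2 * pi * tr$center_hz * tt + runif(1, 0, 2 * pi))
    } else {                                               # sawtooth
      ph <- (tt * tr$center_hz) %% 1
      out[ii] <- out[ii] + tr$amplitude * w * (2 * ph - 1)
    }
  }
  out
}

#' Generate one synthetic EEG epoch
#'
#' @param spec a [stage_spec()].
#' @param fs sampling rate (Hz), default 100.
#' @param epoch_len_s epoch length (s), default 30.
#' @param seed integer seed; the epoch is fully determined by
#'   `(spec, fs, epoch_len_s, seed)`.
#' @return numeric vector of `fs * epoch_len_s` samples (microvolts) with the
#'   stage label attached as attribute `"stage"`.
#' @export
generate_epoch <- function(spec, fs = 100, epoch_len_s = 30, seed) {
  stopifnot(inherits(spec, "stage_spec"))
  if (missing(seed)) stop("seed is required")
  n <- round(fs * epoch_len_s)
  t <- (seq_len(n) - 1) / fs
  x <- with_seed(seed, {
    out <- numeric(n)
    for (b in seq_len(nrow(spec$bands)))
      out <- out + band_component(t, spec$bands$low[b], spec$bands$high[b],
                                  spec$bands$amplitude[b], fs)
    if (!is.null(spec$transient))
      out <- out + burst_component(t, spec$transient, fs, epoch_len_s)
    if (spec$baseline_noise_sd > 0)
      out <- out + rnorm(n, 0, spec$baseline_noise_sd)
    out
  })
  attr(x, "stage") <- spec$stage
  x
}

#' Generate a balanced labelled synthetic dataset
#'
#' Emits `n_per_class` epochs for each of the six stages using the given
#' stage specifications. Per-epoch seeds are derived deterministically from
#' the master seed, so the dataset is reproducible and distinct master seeds
#' give distinct data.
#'
#' @param n_per_class epochs per stage (>= 1).
#' @param fs,epoch_len_s sampling geometry (defaults 100 Hz, 30 s).
#' @param seed master integer seed.
#' @param specs named list of [stage_spec()]s, default [default_stage_specs()].
#' @return [epoch_set()] of `6 * n_per_class` epochs.
#' @export
generate_dataset <- function(n_per_class, fs = 100, epoch_len_s = 30, seed,
                             specs = default_stage_specs()) {
  stopifnot(n_per_class >= 1)
  if (missing(seed)) stop("seed is required")
  n <- round(fs * epoch_len_s)
  stages <- rep(names(specs), each = n_per_class)
  samp <- matrix(0, length(stages), n)
  for (i in seq_along(stages))
    samp[i, ] <- generate_epoch(specs[[stages[i]]], fs, epoch_len_s,
                                seed = derive_seed(seed, i))
  epoch_set(samp, stages, fs, epoch_len_s,
            source_id = "synthetic", index = seq_along(stages))
}

#' Artifact noise specification
#'
#' @param kind one of `"gaussian_broadband"`, `"powerline_50hz"`,
#'   `"baseline_drift"`, `"ocular_blink"`.
#' @param snr_db target signal-to-noise ratio in dB (finite).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian_broadband", "powerline_50hz",
                                "baseline_drift", "ocular_blink"),
                       snr_db) {
  kind <- match.arg(kind)
  stopifnot(is.finite(snr_db))
  structure(list(kind = kind, snr_db = snr_db), class = "noise_spec")
}

#' Contaminate an epoch with artifact noise at a target SNR
#'
#' The noise waveform is generated (seed-deterministic), then scaled so the
#' achieved SNR equals `noise$snr_db` exactly; both the contaminated epoch
#' and the clean reference are returned so denoising can be scored against
#' ground truth.
#'
#' @param x numeric epoch (clean signal).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param fs sampling rate (Hz), default 100.
#' @return `list(noisy =, clean =)` numeric vectors.
#' @export
contaminate <- function(x, noise, seed, fs = 100) {
  stopifnot(inherits(noise, "noise_spec"))
  if (missing(seed)) stop("seed is required")
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  z <- with_seed(seed, switch(noise$kind,
    gaussian_broadband = rnorm(n),
    powerline_50hz = sin(2 * pi * 50 * t + runif(1, 0, 2 * pi)),
    baseline_drift = sin(2 * pi * 0.2 * t + runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * pi * 0.07 * t + runif(1, 0, 2 * pi)),
    ocular_blink = {
      out <- numeric(n)
      centers <- runif(3, 0.05, 0.95) * n / fs
      for (cc in centers) out <- out + exp(-((t - cc) / 0.15)^2 / 2)
      out
    }))
  pz <- mean(z^2)
  ps <- mean(x^2)
  if (pz == 0 || ps == 0) return(list(noisy = x, clean = x))
  target_pn <- ps * 10^(-noise$snr_db / 10)
  list(noisy = x + z * sqrt(target_pn / pz), clean = x)
}

#' Signal-to-noise ratio between a clean and contaminated trace
#'
#' `10 log10( power(clean) / power(noisy - clean) )`. Identical inputs (zero
#' noise power) return `Inf`, the documented sentinel for a noise-free
#' signal.
#'
#' @param clean,noisy equal-length numeric vectors.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(clean, noisy) {
  if (length(clean) != length(noisy)) stop("clean and noisy must have equal length")
  pn <- mean((noisy - clean)^2)
  if (pn == 0) return(Inf)
  10 * log10(mean(clean^2) / pn)
}
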