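# Independent naive-loop oracle for the 11 time-domain statistics.
# Deliberately written with explicit loops and no shared code with the
# package implementation.
oracle_features <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / n

  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  sdev <- sqrt(ss / (n - 1))

  sq <- 0
  for (v in x) sq <- sq + v^2
  rms <- sqrt(sq / n)

  mx <- x[1]; mn <- x[1]; pk <- abs(x[1])
  for (v in x) {
    if (v > mx) mx <- v
    if (v < mn) mn <- v
    if (abs(v) > pk) pk <- abs(v)
  }
  ppv <- mx - mn

  am <- 0
  for (v in x) am <- am + abs(v)
  am <- am / n

  sr <- 0
  for (v in x) sr <- sr + sqrt(abs(v))
  srm <- (sr / n)^2

  if (sdev > 0) {
    s3 <- 0; s4 <- 0
    for (v in x) {
      z <- (v - mu) / sdev
      s3 <- s3 + z^3
      s4 <- s4 + z^4
    }
    sv <- s3 / n
    kv <- s4 / n
  } else {
    sv <- 0; kv <- 0
  }

  if (pk > 0) {
    mf <- pk / srm
    crest <- pk / rms
    impf <- pk / am
    kf <- if (sdev > 0) kv / (sq / n)^2 else 0
  } else {
    mf <- 0; crest <- 0; impf <- 0; kf <- 0
  }

  c(mean = mu, std = sdev, rms = rms, ppv = ppv, skewness = sv,
    margin_factor = mf, crest_factor = crest, impulse_factor = impf,
    srm = srm, kurtosis_value = kv, kurtosis_factor = kf)
}
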