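test_that("all 11 statistics match the naive-loop oracle on random input", {
  set.seed(501)
  for (i in 1:200) {
    n <- sample(5:500, 1)
    x <- switch(1 + i %% 4,
                rnorm(n), rnorm(n, 50, 20), rexp(n) - 0.5, runif(n, -3, 3))
    got <- statistical_features(x)
    want <- oracle_features(x)
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-10)
  }
})

test_that("hand-checked small cases agree with the definitions", {
  # constant vector: degenerate standardized moments
  f <- statistical_features(c(1, 1, 1, 1))
  expect_equal(unname(f["mean"]), 1)
  expect_equal(unname(f["std"]), 0)
  expect_equal(unname(f["rms"]), 1)
  expect_equal(unname(f["ppv"]), 0)
  expect_equal(unname(f["crest_factor"]), 1)
  expect_equal(unname(f["impulse_factor"]), 1)
  expect_equal(unname(f[c("skewness", "kurtosis_value", "kurtosis_factor")]),
               c(0, 0, 0))
  expect_setequal(attr(f, "degenerate"),
                  c("skewness", "kurtosis_value", "kurtosis_factor"))

  # symmetric alternating signal
  a <- 2.5
  g <- statistical_features(rep(c(-a, a), 10))
  expect_equal(unname(g["mean"]), 0)
  expect_equal(unname(g["rms"]), a)
  expect_equal(unname(g["ppv"]), 2 * a)
  expect_equal(unname(g["crest_factor"]), 1)
  expect_equal(unname(g["skewness"]), 0)

  # explicit four-point case against the oracle
  expect_equal(unclass(statistical_features(c(1, 2, 3, 4)))[1:11],
               oracle_features(c(1, 2, 3, 4)), tolerance = 1e-12)
})

test_that("degenerate inputs never produce NaN or Inf", {
  for (x in list(rep(0, 10), rep(7, 10), c(rep(0, 9), 0),
                 rep(c(0, 0), 5))) {
    f <- statistical_features(x)
    expect_true(all(is.finite(f)))
  }
  z <- statistical_features(rep(0, 10))
  expect_true(all(c("margin_factor", "crest_factor", "impulse_factor",
                    "kurtosis_factor") %in% attr(z, "degenerate")))
})

test_that("features transform under amplitude scaling exactly as derived", {
  set.seed(88)
  x <- rnorm(300)
  c0 <- 3.7
  f1 <- statistical_features(x)
  f2 <- statistical_features(c0 * x)
  lin <- c("mean", "std", "rms", "ppv")            # scale by c
  inv <- c("skewness", "kurtosis_value", "crest_factor", "impulse_factor")
  expect_equal(unclass(f2)[lin], c0 * unclass(f1)[lin], tolerance = 1e-10)
  expect_equal(unclass(f2)[inv], unclass(f1)[inv], tolerance = 1e-10)
  expect_equal(unname(f2["srm"]), c0 * unname(f1["srm"]), tolerance = 1e-10)
  # margin factor: peak scales c, SRM scales c -> invariant
  expect_equal(unname(f2["margin_factor"]), unname(f1["margin_factor"]),
               tolerance = 1e-10)
  # kurtosis factor: KV invariant, (mean square)^2 scales c^4
  expect_equal(unname(f2["kurtosis_factor"]),
               unname(f1["kurtosis_factor"]) / c0^4, tolerance = 1e-10)
})

test_that("per-IMF vectors are block-structured, masked and zero-padded", {
  x <- as.numeric(generate_epoch(default_stage_specs()$S2, seed = 31))
  d <- emd(x, max_imfs = 3)
  fv <- features_from_imfs(d, max_imfs = 10)
  expect_length(fv, 110L)
  expect_equal(attr(fv, "mask"), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(unname(fv[34:110]), rep(0, 77))        # absent blocks zero
  expect_equal(unname(fv[1:11]),
               unname(unclass(statistical_features(d$imfs[, 1]))[1:11]))
  expect_match(names(fv)[1], "imf1_mean")
  expect_match(names(fv)[110], "imf10_kurtosis_factor")

  # permutation invariance: every statistic ignores sample order
  d2 <- d
  perm <- with_test_seed(4, sample.int(nrow(d2$imfs)))
  d2$imfs <- d2$imfs[perm, , drop = FALSE]
  expect_equal(unclass(features_from_imfs(d2, 10))[1:110],
               unclass(fv)[1:110], tolerance = 1e-12)

  # residue block appended on request
  fr <- features_from_imfs(d, max_imfs = 3, include_residue = TRUE)
  expect_length(fr, 44L)
  expect_match(names(fr)[44], "residue_kurtosis_factor")
})

test_that("min-max scaling is fit on train only, without clipping", {
  tr <- cbind(a = c(0, 10), b = c(5, 5))
  te <- cbind(a = c(20, -10), b = c(7, 5))
  nf <- normalize_features(tr, te)
  expect_equal(unname(nf$train[, "a"]), c(0, 1))
  expect_equal(unname(nf$test[, "a"]), c(2, -1))     # extrapolates, no clip
  expect_equal(unname(nf$train[, "b"]), c(0, 0))     # constant column -> 0
  expect_equal(unname(nf$test[, "b"]), c(0, 0))
  expect_error(normalize_features(tr[0, , drop = FALSE]), "empty")
})

test_that("feature CSVs round-trip and keep the stage labels aligned", {
  es <- generate_dataset(2, seed = 5)
  fe <- featurize_epochs(es, max_imfs = 5)
  f <- tempfile(fileext = ".csv")
  write_features_csv(fe, f)
  back <- read_features_csv(f)
  expect_equal(back$X, fe$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.character(back$stage), as.character(fe$stage))
})
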