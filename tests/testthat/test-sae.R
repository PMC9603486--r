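ae_reconstruct <- function(layer, X) {
  H <- stats::plogis(X %*% t(layer$W_enc) + rep(layer$b_enc, each = nrow(X)))
  stats::plogis(H %*% t(layer$W_dec) + rep(layer$b_dec, each = nrow(X)))
}

test_that("an autoencoder drives reconstruction error to zero on constant data", {
  X <- matrix(0.63, 50, 8)
  l <- train_autoencoder(X, hidden = 2, seed = 5)
  mse <- mean((ae_reconstruct(l, X) - X)^2)
  expect_lt(mse, 1e-3)
  expect_lt(l$loss_curve[length(l$loss_curve)], l$loss_curve[1])
})

test_that("a 2-unit autoencoder captures rank-2 structure", {
  set.seed(41)
  U <- matrix(rnorm(150 * 2), 150, 2)
  V <- matrix(rnorm(2 * 20), 2, 20)
  X <- U %*% V
  X <- (X - min(X)) / (max(X) - min(X))      # into the sigmoid's range
  # oracle: the best rank-2 linear reconstruction is essentially exact here
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc, nu = 2, nv = 2)
  lin2 <- sv$u %*% diag(sv$d[1:2]) %*% t(sv$v)
  expect_lt(mean((lin2 - Xc)^2), 1e-20)
  l <- train_autoencoder(X, hidden = 2, epochs = 500, learning_rate = 1, seed = 7)
  mse <- mean((ae_reconstruct(l, X) - X)^2)
  expect_lt(mse, 0.1 * mean(Xc^2))           # < 10% of data variance
})

test_that("pretraining loss decreases monotonically over 5-epoch windows", {
  set.seed(12)
  X <- matrix(runif(200 * 10), 200, 10)
  X[, 1:5] <- X[, 1:5] * rep(runif(200), 5)  # correlated structure to learn
  l <- train_autoencoder(X, hidden = 3, epochs = 40, seed = 3)
  w <- stats::filter(l$loss_curve, rep(1 / 5, 5), sides = 1)
  w <- w[!is.na(w)]
  expect_true(all(diff(w) <= 0.01 * w[-length(w)]))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(2)
  X <- matrix(runif(80 * 6), 80, 6)
  l1 <- train_autoencoder(X, hidden = 2, epochs = 10, seed = 9)
  l2 <- train_autoencoder(X, hidden = 2, epochs = 10, seed = 9)
  expect_identical(l1$W_enc, l2$W_enc)
  expect_identical(l1$W_dec, l2$W_dec)
  y <- rep(c("A", "B", "C"), length.out = 80)
  m1 <- sae_fit(X, y, hidden_sizes = c(3, 2), pretrain_epochs = 10,
                head_epochs = 20, finetune_epochs = 20, seed = 4)
  m2 <- sae_fit(X, y, hidden_sizes = c(3, 2), pretrain_epochs = 10,
                head_epochs = 20, finetune_epochs = 20, seed = 4)
  expect_identical(coef(m1), coef(m2))
  expect_identical(predict(m1, X), predict(m2, X))
})

test_that("encoding has closed-form behaviour for degenerate weights", {
  layer <- structure(list(W_enc = matrix(0, 2, 5), b_enc = c(0, 0),
                          activation = "sigmoid"), class = "ae_layer")
  H <- encode(list(layer), matrix(rnorm(30), 6, 5))
  expect_equal(unname(H), matrix(0.5, 6, 2))

  # output width follows the last hidden size; encoding is deterministic
  set.seed(3)
  X <- matrix(runif(40 * 6), 40, 6)
  m <- sae_fit(X, rep(c("A", "B"), 20), hidden_sizes = c(4, 2),
               pretrain_epochs = 5, head_epochs = 10, finetune_epochs = 0,
               seed = 1)
  expect_equal(ncol(encode(m, X)), 2L)
  expect_identical(encode(m, X), encode(m, X))
})

test_that("softmax probabilities are normalized with argmax labels", {
  # hand-built model with zero weights: exactly uniform probabilities
  m <- structure(list(
    layers = list(structure(list(W_enc = matrix(0, 2, 4), b_enc = c(0, 0),
                                 activation = "sigmoid"), class = "ae_layer")),
    softmax_W = matrix(0, 6, 2), softmax_b = numeric(6),
    class_order = c("W", "S1", "S2", "S3", "S4", "REM"),
    head_depth = 1L, scaler = NULL, train_meta = list()), class = "sae")
  P <- predict(m, matrix(rnorm(20), 5, 4), type = "prob")
  expect_equal(unname(P), matrix(1 / 6, 5, 6))
  # uniform probabilities: tie broken toward the lowest class index
  expect_equal(as.character(predict(m, matrix(rnorm(8), 2, 4))), c("W", "W"))

  set.seed(6)
  X <- matrix(runif(60 * 5), 60, 5)
  mf <- sae_fit(X, rep(c("A", "B", "C"), 20), hidden_sizes = c(3),
                pretrain_epochs = 5, head_epochs = 30, finetune_epochs = 10,
                seed = 2)
  P2 <- predict(mf, X, type = "prob")
  expect_equal(rowSums(P2), rep(1, 60), tolerance = 1e-12)
  lab <- predict(mf, X)
  expect_equal(as.integer(lab), apply(P2, 1, which.max))
})

test_that("well-separated Gaussian blobs are classified perfectly", {
  set.seed(10)
  X <- rbind(matrix(rnorm(120, 0, 1), 60, 2),
             matrix(rnorm(120, 10, 1), 60, 2))
  y <- rep(c("A", "B"), each = 60)
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  m <- suppressWarnings(sae_fit(X[tr, ], y[tr], seed = 3))
  expect_equal(mean(predict(m, X[te, ]) == y[te]), 1)
  expect_error(sae_fit(X, rep("A", 120)), "2 classes")
})

test_that("fine-tuning does not degrade the training cross-entropy", {
  set.seed(15)
  X <- matrix(runif(120 * 8), 120, 8)
  y <- rep(c("A", "B", "C"), 40)
  m <- sae_fit(X, y, hidden_sizes = c(4, 2), pretrain_epochs = 20,
               head_epochs = 50, finetune_epochs = 80, seed = 8)
  ft <- m$train_meta$finetune_loss
  expect_lte(ft[length(ft)], 1.01 * ft[1])
})

test_that("models round-trip through the portable serialization exactly", {
  set.seed(20)
  X <- matrix(runif(60 * 6), 60, 6)
  y <- rep(c("A", "B"), 30)
  m <- sae_fit(X, y, hidden_sizes = c(3, 2), pretrain_epochs = 5,
               head_epochs = 10, finetune_epochs = 10, seed = 5)
  f <- tempfile(fileext = ".bin")
  write_sae(m, f)
  m2 <- read_sae(f)
  expect_equal(m2$layers[[1]]$W_enc, m$layers[[1]]$W_enc)
  expect_equal(m2$softmax_W, m$softmax_W)
  expect_equal(m2$class_order, m$class_order)
  expect_identical(predict(m2, X, type = "prob"), predict(m, X, type = "prob"))
  # byte-identical on rewrite
  f2 <- tempfile(fileext = ".bin")
  write_sae(m2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the 2-D abstract pool separates stages better than raw feature pairs", {
  skip_if_not_installed("cluster")
  es <- generate_dataset(25, seed = 42)
  sp <- suppressMessages(split_train_test(es, 0.6, seed = 42))
  fe <- featurize_epochs(sp$train)
  m <- sae_fit(fe$X, fe$stage, seed = 42)
  H <- encode(m, fe$X)
  cls <- as.integer(fe$stage)
  sil <- function(M) {
    if (stats::sd(M[, 1]) + stats::sd(M[, 2]) == 0) return(-1)
    mean(cluster::silhouette(cls, stats::dist(M))[, "sil_width"])
  }
  s_code <- sil(H)
  nf <- normalize_features(fe$X)$train
  keep <- which(apply(nf, 2, stats::sd) > 0)
  pairs <- utils::combn(keep, 2)
  s_raw <- vapply(seq_len(ncol(pairs)), function(j)
    sil(nf[, pairs[, j], drop = FALSE]), numeric(1))
  expect_gt(s_code, max(s_raw))
})
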