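sigmoid <- function(z) 1 / (1 + exp(-z))

ae_init <- function(n_in, n_hidden, seed) {
  # symmetric uniform (Glorot) initialisation
  with_seed(seed, {
    r1 <- sqrt(6 / (n_in + n_hidden))
    W1 <- matrix(runif(n_hidden * n_in, -r1, r1), n_hidden, n_in)
    W2 <- matrix(runif(n_in * n_hidden, -r1, r1), n_in, n_hidden)
    list(W_enc = W1, b_enc = numeric(n_hidden),
         W_dec = W2, b_dec = numeric(n_in), activation = "sigmoid")
  })
}

#' Train a single sigmoid autoencoder layer
#'
#' Minimizes mean squared reconstruction error plus an L2 weight penalty and
#' an optional KL-divergence sparsity penalty on the hidden activations, by
#' seeded mini-batch gradient descent with a fixed learning rate.
#'
#' @param X input matrix (rows = samples), values roughly in `[0, 1]`.
#' @param hidden hidden unit count (must be below `ncol(X)`: compression).
#' @param epochs training epochs.
#' @param learning_rate SGD step size.
#' @param l2_weight L2 penalty coefficient.
#' @param sparsity_target,sparsity_weight KL sparsity penalty (target mean
#'   activation and its weight; weight 0 disables it).
#' @param batch_size mini-batch size.
#' @param seed integer seed (weights and batch order).
#' @return `ae_layer` object: encoder/decoder weights and biases plus the
#'   per-epoch reconstruction `loss_curve`.
#' @export
train_autoencoder <- function(X, hidden, epochs = 60, learning_rate = 0.5,
                              l2_weight = 1e-4, sparsity_target = 0.1,
                              sparsity_weight = 0, batch_size = 32, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (hidden >= d)
    warning("hidden (", hidden, ") not below input dim (", d,
            "): layer is not compressive")
  layer <- ae_init(d, hidden, derive_seed(seed, 1))
  loss_curve <- numeric(epochs)
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- X[idx, , drop = FALSE]
        m <- nrow(B)
        A <- sigmoid(B %*% t(layer$W_enc) + rep(layer$b_enc, each = m))
        R <- sigmoid(A %*% t(layer$W_dec) + rep(layer$b_dec, each = m))
        E <- R - B
        ep_loss <- ep_loss + 0.5 * mean(rowSums(E^2)); nb <- nb + 1
        d2 <- E * R * (1 - R)
        dA <- d2 %*% layer$W_dec
        if (sparsity_weight > 0) {
          rho_hat <- pmin(pmax(colMeans(A), 1e-8), 1 - 1e-8)
          kl_grad <- sparsity_weight *
            (-sparsity_target / rho_hat + (1 - sparsity_target) / (1 - rho_hat))
          dA <- dA + rep(kl_grad, each = m)
        }
        d1 <- dA * A * (1 - A)
        layer$W_dec <- layer$W_dec - learning_rate * (t(d2) %*% A / m + l2_weight * layer$W_dec)
        layer$b_dec <- layer$b_dec - learning_rate * colMeans(d2)
        layer$W_enc <- layer$W_enc - learning_rate * (t(d1) %*% B / m + l2_weight * layer$W_enc)
        layer$b_enc <- layer$b_enc - learning_rate * colMeans(d1)
        if (!all(is.finite(layer$W_enc)))
          stop("non-finite autoencoder weights at epoch ", ep,
               " (loss ", format(ep_loss / nb), "); lower the learning rate")
      }
      loss_curve[ep] <- ep_loss / nb
    }
  })
  structure(c(layer, list(loss_curve = loss_curve, hidden = hidden)),
            class = "ae_layer")
}

encode_layer <- function(layer, X) {
  m <- nrow(X)
  sigmoid(X %*% t(layer$W_enc) + rep(layer$b_enc, each = m))
}

#' Encode data through stacked autoencoder layers
#'
#' Applies each trained encoder in stack order. For a fitted [sae_fit()]
#' model the input is scaled exactly as during training and the result of
#' the full stack (by default the 2-D abstract feature pool) is returned.
#'
#' @param object an `sae` model or list of `ae_layer`s.
#' @param X feature matrix (raw features for an `sae` model; already-encoded
#'   input for a bare layer list).
#' @param depth number of layers to apply (default: all).
#' @return code matrix with `hidden_sizes[depth]` columns.
#' @export
encode <- function(object, X, depth = NULL) {
  if (inherits(object, "sae")) {
    X <- sae_scale(object, X)
    layers <- object$layers
  } else layers <- object
  depth <- depth %||% length(layers)
  H <- as.matrix(X)
  for (i in seq_len(depth)) H <- encode_layer(layers[[i]], H)
  H
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

train_softmax <- function(H, Y, epochs, learning_rate, l2_weight, batch_size,
                          seed, W = NULL, b = NULL) {
  n <- nrow(H); h <- ncol(H); C <- ncol(Y)
  if (is.null(W)) W <- with_seed(derive_seed(seed, 1),
                                 matrix(runif(C * h, -0.1, 0.1), C, h))
  if (is.null(b)) b <- numeric(C)
  loss_curve <- numeric(epochs)
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- H[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        m <- nrow(B)
        P <- softmax_rows(B %*% t(W) + rep(b, each = m))
        ep_loss <- ep_loss - mean(log(pmax(rowSums(P * Yb), 1e-300))); nb <- nb + 1
        D <- P - Yb
        W <- W - learning_rate * (t(D) %*% B / m + l2_weight * W)
        b <- b - learning_rate * colMeans(D)
      }
      loss_curve[ep] <- ep_loss / nb
    }
  })
  list(W = W, b = b, loss_curve = loss_curve)
}

sae_scale <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(model$scaler)) return(X)
  X <- sweep(X, 2, model$scaler$min, "-")
  X <- sweep(X, 2, ifelse(model$scaler$range > 0, model$scaler$range, 1), "/")
  X[, model$scaler$range == 0] <- 0
  X
}

# full forward pass up to `depth` layers, returning all activations
sae_forward <- function(layers, X, depth) {
  acts <- vector("list", depth + 1L)
  acts[[1]] <- X
  for (i in seq_len(depth)) acts[[i + 1]] <- encode_layer(layers[[i]], acts[[i]])
  acts
}

#' Fit a stacked autoencoder sleep-stage classifier
#'
#' Three training phases: (1) greedy layerwise pretraining -- each sigmoid
#' autoencoder is trained to reconstruct the codes of the layer below;
#' (2) a softmax head is trained by cross-entropy on the final codes;
#' (3) optional end-to-end fine-tuning of the encoder stack and head by
#' cross-entropy. All phases are plain seeded mini-batch SGD, so the fit is
#' fully deterministic given `(x, y, config, seed)`.
#'
#' @param x numeric feature matrix, one epoch per row.
#' @param y stage labels (coerced by [sleep_stages()]; at least 2 classes),
#'   or any factor for non-sleep data.
#' @param hidden_sizes hidden layer widths, default `c(32, 2)`: the final
#'   2-unit code is the abstract feature pool used for both visualization
#'   and classification.
#' @param pretrain_epochs,head_epochs,finetune_epochs epochs per phase
#'   (`finetune_epochs = 0` freezes the pretrained encoders).
#' @param learning_rate,l2_weight,batch_size SGD controls, shared by phases.
#' @param sparsity_target,sparsity_weight optional KL sparsity penalty for
#'   pretraining (weight 0 = off, the default).
#' @param head_from `"last"` (default; classify from the final code) or
#'   `"penultimate"` (attach the head one layer below, for problems where
#'   the terminal bottleneck is too narrow).
#' @param scale apply internal min-max scaling fit on `x` (default `TRUE`);
#'   set `FALSE` if features were already scaled with [normalize_features()].
#' @param seed integer master seed.
#' @return object of class `sae`.
#' @export
sae_fit <- function(x, y, hidden_sizes = c(32, 2),
                    pretrain_epochs = 60, head_epochs = 200,
                    finetune_epochs = 300,
                    learning_rate = 0.5, l2_weight = 1e-5,
                    sparsity_target = 0.1, sparsity_weight = 0,
                    batch_size = 32,
                    head_from = c("last", "penultimate"),
                    scale = TRUE, seed = 1) {
  head_from <- match.arg(head_from)
  x <- as.matrix(x)
  check_finite(x, "x")
  y <- if (all(as.character(y) %in% STAGE_LEVELS)) sleep_stages(y) else factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes to fit a classifier")
  if (length(y) != nrow(x)) stop("x and y disagree in length")
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1))

  scaler <- NULL
  if (scale) {
    nf <- normalize_features(x)
    scaler <- list(min = nf$min, range = nf$range)
    x <- nf$train
  }

  # phase 1: greedy layerwise pretraining
  layers <- vector("list", length(hidden_sizes))
  H <- x
  for (i in seq_along(hidden_sizes)) {
    layers[[i]] <- train_autoencoder(
      H, hidden_sizes[i], epochs = pretrain_epochs,
      learning_rate = learning_rate, l2_weight = l2_weight,
      sparsity_target = sparsity_target, sparsity_weight = sparsity_weight,
      batch_size = batch_size, seed = derive_seed(seed, 100 + i))
    H <- encode_layer(layers[[i]], H)
  }

  head_depth <- if (head_from == "last") length(hidden_sizes)
                else max(1L, length(hidden_sizes) - 1L)
  Hc <- if (head_depth == length(hidden_sizes)) H
        else sae_forward(layers, x, head_depth)[[head_depth + 1L]]
  Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]

  # phase 2: softmax head on the codes
  head <- train_softmax(Hc, Y, epochs = head_epochs,
                        learning_rate = learning_rate, l2_weight = l2_weight,
                        batch_size = batch_size, seed = derive_seed(seed, 200))

  # phase 3: end-to-end fine-tuning (encoders up to head_depth + head)
  finetune_curve <- numeric(0)
  if (finetune_epochs > 0) {
    W <- head$W; b <- head$b
    n <- nrow(x)
    finetune_curve <- numeric(finetune_epochs)
    with_seed(derive_seed(seed, 300), {
      for (ep in seq_len(finetune_epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0; nb <- 0
        for (start in seq(1, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, n)]
          acts <- sae_forward(layers, x[idx, , drop = FALSE], head_depth)
          m <- length(idx)
          Htop <- acts[[head_depth + 1L]]
          P <- softmax_rows(Htop %*% t(W) + rep(b, each = m))
          Yb <- Y[idx, , drop = FALSE]
          ep_loss <- ep_loss - mean(log(pmax(rowSums(P * Yb), 1e-300))); nb <- nb + 1
          D <- P - Yb
          gW <- t(D) %*% Htop / m + l2_weight * W
          gb <- colMeans(D)
          delta <- (D %*% W) * Htop * (1 - Htop)
          W <- W - learning_rate * gW
          b <- b - learning_rate * gb
          for (i in rev(seq_len(head_depth))) {
            A_in <- acts[[i]]
            gWi <- t(delta) %*% A_in / m + l2_weight * layers[[i]]$W_enc
            gbi <- colMeans(delta)
            if (i > 1)
              delta <- (delta %*% layers[[i]]$W_enc) * A_in * (1 - A_in)
            layers[[i]]$W_enc <- layers[[i]]$W_enc - learning_rate * gWi
            layers[[i]]$b_enc <- layers[[i]]$b_enc - learning_rate * gbi
          }
        }
        finetune_curve[ep] <- ep_loss / nb
      }
    })
    head$W <- W; head$b <- b
  }

  structure(
    list(layers = layers, softmax_W = head$W, softmax_b = head$b,
         class_order = levels(y), head_depth = head_depth, scaler = scaler,
         train_meta = list(
           seed = seed, hidden_sizes = hidden_sizes,
           pretrain_epochs = pretrain_epochs, head_epochs = head_epochs,
           finetune_epochs = finetune_epochs, learning_rate = learning_rate,
           l2_weight = l2_weight, sparsity_target = sparsity_target,
           sparsity_weight = sparsity_weight, batch_size = batch_size,
           head_from = head_from, n_train = nrow(x),
           pretrain_loss = lapply(layers, `[[`, "loss_curve"),
           head_loss = head$loss_curve, finetune_loss = finetune_curve)),
    class = "sae")
}

#' Predict sleep stages with a fitted stacked autoencoder
#'
#' @param object an [sae_fit()] model.
#' @param newdata feature matrix on the training feature layout.
#' @param type `"class"` (default) for labels or `"prob"` for the
#'   row-normalized softmax probability matrix.
#' @param ... unused.
#' @return factor of predicted labels (`"class"`; ties broken towards the
#'   lowest class index) or a probability matrix (`"prob"`).
#' @export
predict.sae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  H <- encode(object, newdata, depth = object$head_depth)
  P <- softmax_rows(H %*% t(object$softmax_W) +
                    rep(object$softmax_b, each = nrow(H)))
  colnames(P) <- object$class_order
  if (type == "prob") return(P)
  factor(object$class_order[apply(P, 1, which.max)], levels = object$class_order)
}

#' @export
print.sae <- function(x, ...) {
  cat(sprintf("<sae> stacked autoencoder classifier: %d -> %s -> %d classes\n",
              ncol(x$layers[[1]]$W_enc),
              paste(x$train_meta$hidden_sizes, collapse = " -> "),
              length(x$class_order)))
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  cat(sprintf("  head at depth %d; trained on %d samples (seed %d)\n",
              x$head_depth, x$train_meta$n_train, x$train_meta$seed))
  invisible(x)
}

#' @export
summary.sae <- function(object, ...) {
  m <- object$train_meta
  print(object)
  for (i in seq_along(object$layers)) {
    lc <- m$pretrain_loss[[i]]
    cat(sprintf("  AE layer %d (%d units): reconstruction loss %.5f -> %.5f over %d epochs\n",
                i, m$hidden_sizes[i], lc[1], lc[length(lc)], length(lc)))
  }
  hl <- m$head_loss
  cat(sprintf("  softmax head: cross-entropy %.5f -> %.5f\n", hl[1], hl[length(hl)]))
  if (length(m$finetune_loss))
    cat(sprintf("  fine-tuning: cross-entropy %.5f -> %.5f over %d epochs\n",
                m$finetune_loss[1], m$finetune_loss[length(m$finetune_loss)],
                length(m$finetune_loss)))
  invisible(object)
}

#' @export
coef.sae <- function(object, ...) {
  c(lapply(seq_along(object$layers), function(i)
      list(W_enc = object$layers[[i]]$W_enc, b_enc = object$layers[[i]]$b_enc)),
    list(softmax = list(W = object$softmax_W, b = object$softmax_b)))
}

#' Plot the abstract feature pool of a fitted model
#'
#' Scatter of the first two dimensions of the stacked-encoder code, coloured
#' by class -- the low-dimensional pool in which the stages should form
#' near-disjoint clusters.
#'
#' @param x an `sae` model.
#' @param newdata feature matrix to encode.
#' @param y optional true labels for colouring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sae <- function(x, newdata, y = NULL, ...) {
  H <- encode(x, newdata)
  if (ncol(H) < 2) H <- cbind(H, 0)
  cls <- if (is.null(y)) predict(x, newdata) else factor(y)
  cols <- hcl.colors(nlevels(cls), "Dark 2")
  plot(H[, 1], H[, 2], col = cols[as.integer(cls)], pch = 19,
       xlab = "abstract feature 1", ylab = "abstract feature 2", ...)
  legend("topright", legend = levels(cls), col = cols, pch = 19, cex = 0.8)
  invisible(H)
}

#' Serialize a fitted model to a single portable file
#'
#' Layout: one JSON header line (shapes, class order, training metadata)
#' followed by all weight matrices as little-endian float64 in header order.
#'
#' @param model an `sae` model.
#' @param path output file.
#' @return `path` (write) or the restored `sae` model (read).
#' @export
write_sae <- function(model, path) {
  stopifnot(inherits(model, "sae"))
  mats <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    mats[[paste0("layer", i, "_W_enc")]] <- l$W_enc
    mats[[paste0("layer", i, "_b_enc")]] <- l$b_enc
    mats[[paste0("layer", i, "_W_dec")]] <- l$W_dec
    mats[[paste0("layer", i, "_b_dec")]] <- l$b_dec
  }
  mats$softmax_W <- model$softmax_W
  mats$softmax_b <- model$softmax_b
  if (!is.null(model$scaler)) {
    mats$scaler_min <- model$scaler$min
    mats$scaler_range <- model$scaler$range
  }
  header <- list(
    format = "emdsleep-sae-1",
    class_order = model$class_order, head_depth = model$head_depth,
    has_scaler = !is.null(model$scaler),
    train_meta = model$train_meta[setdiff(names(model$train_meta),
                                          c("pretrain_loss", "head_loss", "finetune_loss"))],
    shapes = lapply(mats, function(m) if (is.matrix(m)) dim(m) else length(m)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), "\n"),
            con, eos = NULL)
  for (m in mats) writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_sae
#' @export
read_sae <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b) || b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  header <- jsonlite::fromJSON(rawToChar(bytes), simplifyVector = TRUE)
  mats <- list()
  for (nm in names(header$shapes)) {
    sh <- header$shapes[[nm]]
    v <- readBin(con, "numeric", prod(sh), size = 8L, endian = "little")
    mats[[nm]] <- if (length(sh) == 2) matrix(v, sh[1], sh[2]) else v
  }
  n_layers <- sum(grepl("^layer\\d+_W_enc$", names(mats)))
  layers <- lapply(seq_len(n_layers), function(i) {
    structure(list(W_enc = mats[[paste0("layer", i, "_W_enc")]],
                   b_enc = mats[[paste0("layer", i, "_b_enc")]],
                   W_dec = mats[[paste0("layer", i, "_W_dec")]],
                   b_dec = mats[[paste0("layer", i, "_b_dec")]],
                   activation = "sigmoid"),
              class = "ae_layer")
  })
  structure(
    list(layers = layers, softmax_W = mats$softmax_W, softmax_b = mats$softmax_b,
         class_order = header$class_order, head_depth = header$head_depth,
         scaler = if (isTRUE(header$has_scaler))
           list(min = mats$scaler_min, range = mats$scaler_range),
         train_meta = header$train_meta),
    class = "sae")
}
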