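# 1D convolutional network for mel-spectrogram classification.
#
# Tensors are R arrays (batch, time, channels); convolutions run along the
# time (frame) axis with mel bands as input channels and are evaluated as
# im2col matrix products so all heavy lifting is BLAS. Everything is
# seeded and single-threaded-deterministic.

#' Model configuration for the 1D CNN classifier
#'
#' Three convolutional blocks (Conv1D + ReLU + MaxPooling1D + Dropout)
#' with 32/64/128 filters, then Flatten, a ReLU dense layer, and a
#' softmax output over the six call classes.
#'
#' @param conv_filters Filter counts per block (default `c(32, 64, 128)`).
#' @param kernel_size Convolution kernel length along time (default 3).
#' @param pool_size Max-pooling factor (default 2).
#' @param dropout_rates Per-block dropout fractions in [0, 1).
#' @param dense_units Hidden dense width (default 64).
#' @param n_classes Number of output classes (default 6).
#' @param input_shape `c(frames, bands)` of the feature matrices.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(32L, 64L, 128L), kernel_size = 3L,
                         pool_size = 2L, dropout_rates = c(0.25, 0.25, 0.5),
                         dense_units = 64L, n_classes = 6L,
                         input_shape = c(198L, 40L)) {
  stopifnot(length(conv_filters) == length(dropout_rates),
            all(dropout_rates >= 0), all(dropout_rates < 1),
            kernel_size >= 1, pool_size >= 1, n_classes >= 2,
            length(input_shape) == 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dropout_rates = dropout_rates,
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before stopping (0 stops at the first non-improving
#'   epoch); the best-validation weights are restored.
#' @param seed Seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 12L, batch_size = 32L, learning_rate = 1e-3,
                         early_stop_patience = 3L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# time-axis length after each block: conv (valid) then pool (floor)
.block_dims <- function(config) {
  t <- config$input_shape[1]
  c_in <- config$input_shape[2]
  dims <- list()
  for (i in seq_along(config$conv_filters)) {
    p <- t - config$kernel_size + 1L
    if (p < config$pool_size) {
      # invert the recurrence to name the minimum input frames
      need <- config$pool_size
      for (j in rev(seq_len(i))) need <- need * config$pool_size + config$kernel_size - 1L
      stopf("input of %d frames is too short for %d conv/pool blocks (need >= %d frames)",
            config$input_shape[1], length(config$conv_filters), need)
    }
    t_out <- p %/% config$pool_size
    dims[[i]] <- list(c_in = c_in, p = p, t_out = t_out,
                      f = config$conv_filters[i])
    c_in <- config$conv_filters[i]
    t <- t_out
  }
  list(blocks = dims, flat = t * c_in)
}

#' Build an (untrained) 1D CNN
#'
#' Weights use Glorot-uniform initialization from `seed`; the
#' architecture and parameter count are pure functions of the config.
#'
#' @param config A [model_config()].
#' @param classes Class label ordering for the output layer (default
#'   [vocal_classes()]).
#' @param seed Initialization seed.
#' @return A `cnn_model` list (config, parameter tensors, class order).
#' @export
build_model <- function(config = model_config(), classes = unname(vocal_classes()),
                        seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (length(classes) != config$n_classes) {
    stopf("config has %d classes but %d labels supplied",
          config$n_classes, length(classes))
  }
  dims <- .block_dims(config)
  glorot <- function(fan_in, fan_out, nr, nc) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- with_seed(seed, {
    p <- list()
    for (i in seq_along(dims$blocks)) {
      b <- dims$blocks[[i]]
      fan_in <- config$kernel_size * b$c_in
      p[[sprintf("conv%d_W", i)]] <- glorot(fan_in, b$f, fan_in, b$f)
      p[[sprintf("conv%d_b", i)]] <- numeric(b$f)
    }
    p$dense_W <- glorot(dims$flat, config$dense_units, dims$flat,
                        config$dense_units)
    p$dense_b <- numeric(config$dense_units)
    p$out_W <- glorot(config$dense_units, config$n_classes,
                      config$dense_units, config$n_classes)
    p$out_b <- numeric(config$n_classes)
    p
  })
  structure(list(config = config, params = params, classes = classes,
                 dims = dims, norm = NULL, history = NULL),
            class = "cnn_model")
}

#' Number of trainable parameters
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# ---- layer primitives (arrays are (batch, time, channels)) ----

.im2col <- function(X, k) {
  d <- dim(X)  # (B, T, C)
  p <- d[2] - k + 1L
  cols <- vector("list", k)
  for (o in seq_len(k)) {
    sl <- X[, o:(p + o - 1L), , drop = FALSE]
    dim(sl) <- c(d[1] * p, d[3])
    cols[[o]] <- sl
  }
  out <- do.call(cbind, cols)  # (B*P) x (k*C), offset-major column blocks
  attr(out, "B") <- d[1]; attr(out, "P") <- p; attr(out, "C") <- d[3]
  out
}

.conv_fwd <- function(X, W, b, k) {
  Xc <- .im2col(X, k)
  Y <- Xc %*% W
  Y <- sweep(Y, 2, b, `+`)
  dim(Y) <- c(attr(Xc, "B"), attr(Xc, "P"), ncol(W))
  list(Y = Y, Xc = Xc)
}

.conv_bwd <- function(dY, cache, W, k, in_dim) {
  B <- in_dim[1]; C <- in_dim[3]
  p <- dim(dY)[2]
  dYm <- dY; dim(dYm) <- c(B * p, dim(dY)[3])
  dW <- crossprod(cache$Xc, dYm)
  db <- colSums(dYm)
  dXc <- tcrossprod(dYm, W)            # (B*P) x (k*C)
  dX <- array(0, in_dim)
  for (o in seq_len(k)) {
    blk <- dXc[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dim(blk) <- c(B, p, C)
    dX[, o:(p + o - 1L), ] <- dX[, o:(p + o - 1L), , drop = FALSE] + blk
  }
  list(dX = dX, dW = dW, db = db)
}

.pool_fwd <- function(Y, pool) {
  d <- dim(Y)
  t_out <- d[2] %/% pool
  M <- Y[, seq(1, t_out * pool, by = pool), , drop = FALSE]
  arg <- array(1L, dim(M))
  if (pool > 1) {
    for (o in 2:pool) {
      cand <- Y[, seq(o, t_out * pool, by = pool), , drop = FALSE]
      upd <- cand > M
      M[upd] <- cand[upd]
      arg[upd] <- o
    }
  }
  list(Y = M, arg = arg, in_dim = d)
}

.pool_bwd <- function(dY, cache, pool) {
  dX <- array(0, cache$in_dim)
  t_out <- dim(dY)[2]
  for (o in seq_len(pool)) {
    sel <- (cache$arg == o) * dY
    dX[, seq(o, t_out * pool, by = pool), ] <- sel
  }
  dX
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass. `training` enables dropout (caller must have seeded
# the RNG). `act_quant` optionally fake-quantizes post-block activations
# (see quantize_ptq); `collect_ranges=TRUE` instead records per-stage
# activation min/max for calibration.
.forward <- function(model, X, training = FALSE, act_quant = NULL,
                     collect_ranges = FALSE) {
  cfg <- model$config
  caches <- list()
  ranges <- list()
  qa <- function(A, stage) {
    if (collect_ranges) {
      ranges[[stage]] <<- range(A)
    } else if (!is.null(act_quant) && !is.null(act_quant[[stage]])) {
      q <- act_quant[[stage]]
      A[] <- .fake_quant_affine(A, q$scale, q$zero_point)
    }
    A
  }
  A <- X
  for (i in seq_along(cfg$conv_filters)) {
    cv <- .conv_fwd(A, model$params[[sprintf("conv%d_W", i)]],
                    model$params[[sprintf("conv%d_b", i)]], cfg$kernel_size)
    R <- pmax(cv$Y, 0)
    pl <- .pool_fwd(R, cfg$pool_size)
    P <- qa(pl$Y, sprintf("block%d", i))
    if (training && cfg$dropout_rates[i] > 0) {
      keep <- 1 - cfg$dropout_rates[i]
      mask <- array(stats::runif(length(P)) < keep, dim(P)) / keep
      P <- P * mask
    } else {
      mask <- NULL
    }
    caches[[i]] <- list(in_dim = dim(A), conv = cv, relu_in = cv$Y,
                        pool = pl, mask = mask)
    A <- P
  }
  d <- dim(A)
  Xf <- A; dim(Xf) <- c(d[1], d[2] * d[3])
  H <- sweep(Xf %*% model$params$dense_W, 2, model$params$dense_b, `+`)
  Hr <- qa(pmax(H, 0), "dense")
  Z <- sweep(Hr %*% model$params$out_W, 2, model$params$out_b, `+`)
  probs <- .softmax(Z)
  list(probs = probs, caches = caches, Xf = Xf, H = H, Hr = Hr,
       flat_dim = d, ranges = ranges)
}

# Backward pass; y is an integer class-index vector (1-based).
.backward <- function(model, fwd, y) {
  cfg <- model$config
  B <- nrow(fwd$probs)
  dZ <- fwd$probs
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  g <- list()
  g$out_W <- crossprod(fwd$Hr, dZ)
  g$out_b <- colSums(dZ)
  dHr <- tcrossprod(dZ, model$params$out_W)
  dH <- dHr * (fwd$H > 0)
  g$dense_W <- crossprod(fwd$Xf, dH)
  g$dense_b <- colSums(dH)
  dXf <- tcrossprod(dH, model$params$dense_W)
  dA <- dXf; dim(dA) <- fwd$flat_dim
  for (i in rev(seq_along(cfg$conv_filters))) {
    cache <- fwd$caches[[i]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dR <- .pool_bwd(dA, cache$pool, cfg$pool_size)
    dC <- dR * (cache$relu_in > 0)
    cb <- .conv_bwd(dC, cache$conv, model$params[[sprintf("conv%d_W", i)]],
                    cfg$kernel_size, cache$in_dim)
    g[[sprintf("conv%d_W", i)]] <- cb$dW
    g[[sprintf("conv%d_b", i)]] <- cb$db
    dA <- cb$dX
  }
  g
}

.xent <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# Stack a list of frames x bands matrices into a (B, T, C) array,
# applying per-band standardization if `norm` is given.
.stack_features <- function(feats, norm = NULL) {
  mats <- lapply(feats, function(f) if (inherits(f, "mel_spectrogram")) f$values else f)
  d1 <- dim(mats[[1]])
  X <- array(0, c(length(mats), d1[1], d1[2]))
  for (i in seq_along(mats)) {
    if (!identical(dim(mats[[i]]), d1)) {
      stopf("feature %d has shape %dx%d, expected %dx%d", i,
            nrow(mats[[i]]), ncol(mats[[i]]), d1[1], d1[2])
    }
    X[i, , ] <- mats[[i]]
  }
  if (!is.null(norm)) {
    for (cc in seq_len(d1[2])) {
      X[, , cc] <- (X[, , cc] - norm$mean[cc]) / norm$sd[cc]
    }
  }
  X
}

#' Train the CNN on extracted features
#'
#' Minimizes categorical cross-entropy with Adam (the adaptive-rate
#' optimizer), with per-band z-score standardization computed from the
#' training split only, seeded shuffling and dropout, and early stopping
#' on validation loss (best weights restored). With a fixed seed and
#' single-threaded BLAS, reruns reproduce the history exactly.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param features List of frames x bands matrices (or
#'   `mel_spectrogram`s), one per clip.
#' @param labels Character vector of class codes, parallel to `features`.
#' @param split Character vector `"train"`/`"val"`, parallel to
#'   `features`.
#' @param tc A [train_config()].
#' @return The trained `cnn_model` with `$history` (per-epoch loss and
#'   accuracy) and `$norm` filled in.
#' @export
train_model <- function(model, features, labels, split, tc = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(tc, "train_config"),
            length(features) == length(labels),
            length(labels) == length(split))
  if (!any(split == "train") || !any(split == "val")) {
    stopf("both 'train' and 'val' splits must be nonempty")
  }
  bad <- setdiff(unique(labels), model$classes)
  if (length(bad)) stopf("labels outside model classes: %s", paste(bad, collapse = ", "))
  tr <- which(split == "train")
  va <- which(split == "val")
  Xtr_raw <- .stack_features(features[tr])
  mu <- apply(Xtr_raw, 3, mean)
  sd_ <- apply(Xtr_raw, 3, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  model$norm <- list(mean = mu, sd = sd_)
  Xtr <- .stack_features(features[tr], model$norm)
  Xva <- .stack_features(features[va], model$norm)
  ytr <- match(labels[tr], model$classes)
  yva <- match(labels[va], model$classes)

  opt <- list(m = lapply(model$params, function(p) p * 0),
              v = lapply(model$params, function(p) p * 0), t = 0)
  adam_step <- function(params, grads) {
    opt$t <<- opt$t + 1
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (k in names(params)) {
      opt$m[[k]] <<- b1 * opt$m[[k]] + (1 - b1) * grads[[k]]
      opt$v[[k]] <<- b2 * opt$v[[k]] + (1 - b2) * grads[[k]]^2
      mhat <- opt$m[[k]] / (1 - b1^opt$t)
      vhat <- opt$v[[k]] / (1 - b2^opt$t)
      params[[k]] <- params[[k]] - tc$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    params
  }

  n_tr <- length(tr)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  hist <- list()
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_hit <- 0
      for (s in seq(1, n_tr, by = tc$batch_size)) {
        bi <- ord[s:min(s + tc$batch_size - 1L, n_tr)]
        fwd <- .forward(model, Xtr[bi, , , drop = FALSE], training = TRUE)
        g <- .backward(model, fwd, ytr[bi])
        model$params <- adam_step(model$params, g)
        ep_loss <- ep_loss + .xent(fwd$probs, ytr[bi]) * length(bi)
        ep_hit <- ep_hit + sum(max.col(fwd$probs) == ytr[bi])
      }
      vf <- .forward(model, Xva, training = FALSE)
      v_loss <- .xent(vf$probs, yva)
      v_acc <- mean(max.col(vf$probs) == yva)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n_tr,
                               train_acc = ep_hit / n_tr,
                               val_loss = v_loss, val_acc = v_acc)
      if (v_loss < best$loss - 1e-8) {
        best <- list(loss = v_loss, params = model$params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > tc$early_stop_patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

#' Predict class probabilities for clips
#'
#' Deterministic inference (dropout disabled). Features are standardized
#' with the statistics stored at training time.
#'
#' @param model A trained `cnn_model`.
#' @param features List of frames x bands matrices or `mel_spectrogram`s.
#' @return List with `probs` (clips x classes matrix, rows sum to 1) and
#'   `labels` (argmax class codes).
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "cnn_model"))
  X <- .stack_features(features, model$norm)
  if (!identical(dim(X)[2:3], as.integer(model$config$input_shape))) {
    stopf("feature shape %dx%d does not match model input %dx%d",
          dim(X)[2], dim(X)[3],
          model$config$input_shape[1], model$config$input_shape[2])
  }
  fwd <- .forward(model, X, training = FALSE, act_quant = model$act_quant)
  probs <- fwd$probs
  colnames(probs) <- model$classes
  list(probs = probs, labels = model$classes[max.col(probs)])
}

#' Save / load a trained model archive
#'
#' Serializes the architecture echo, weights, class order, normalization
#' statistics and training history as one RDS archive.
#'
#' @param model A `cnn_model`.
#' @param path Archive path.
#' @return `path` invisibly (`save_model`); a `cnn_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
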