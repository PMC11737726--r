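test_that("an untrained model emits valid probabilities of the right shape", {
  ts <- tiny_setup()
  m <- build_model(ts$cfg, classes = ts$classes, seed = 1)
  pr <- predict_model(m, ts$feats[1:5])
  expect_equal(dim(pr$probs), c(5L, 3L))
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
  expect_equal(rowSums(pr$probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pr$labels %in% ts$classes))
})

test_that("parameter count is a pure function of the config", {
  ts <- tiny_setup()
  m1 <- build_model(ts$cfg, classes = ts$classes, seed = 1)
  m2 <- build_model(ts$cfg, classes = ts$classes, seed = 99)
  expect_identical(n_params(m1), n_params(m2))
  # default config: conv stacks 3*40*32 + 32 etc., deterministic
  md <- build_model(model_config(), seed = 1)
  expect_identical(n_params(md), n_params(build_model(model_config(), seed = 2)))
  # int8 deployment footprint: one byte per parameter fits in 1 MB
  expect_lt(n_params(md), 2^20)
})

test_that("inputs too short for three conv/pool blocks raise a sizing error", {
  cfg <- model_config(input_shape = c(8L, 40L))
  expect_error(build_model(cfg), "need >= \\d+ frames")
})

test_that("seeded training is reproducible and learns a separable task", {
  ts <- tiny_setup()
  tc <- train_config(epochs = 25, batch_size = 8, learning_rate = 5e-3,
                     early_stop_patience = 25, seed = 11)
  m1 <- train_model(build_model(ts$cfg, classes = ts$classes, seed = 11),
                    ts$feats, ts$labels, ts$split, tc)
  m2 <- train_model(build_model(ts$cfg, classes = ts$classes, seed = 11),
                    ts$feats, ts$labels, ts$split, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  va <- ts$split == "val"
  pr <- predict_model(m1, ts$feats[va])
  expect_gt(mean(pr$labels == ts$labels[va]), 0.6)
  # inference is deterministic and dropout-free
  expect_identical(pr$probs, predict_model(m1, ts$feats[va])$probs)
})

test_that("patience 0 stops at the first non-improving epoch", {
  ts <- tiny_setup()
  # zero learning rate: the validation loss can never improve after epoch 1
  tc <- train_config(epochs = 10, batch_size = 8, learning_rate = 0,
                     early_stop_patience = 0, seed = 2)
  m <- train_model(build_model(ts$cfg, classes = ts$classes, seed = 2),
                   ts$feats, ts$labels, ts$split, tc)
  expect_equal(nrow(m$history), 2L)
  expect_equal(m$best_epoch, 1L)
})

test_that("analytic gradients match finite differences", {
  ts <- tiny_setup(n_clips = 6)
  m <- build_model(ts$cfg, classes = ts$classes, seed = 3)
  # jitter the zero-initialized biases: with b = 0, receptive fields that
  # are all zero put ReLU exactly at its kink, where finite differences
  # and the subgradient legitimately disagree
  set.seed(30)
  for (k in grep("_b$", names(m$params), value = TRUE)) {
    m$params[[k]] <- m$params[[k]] + rnorm(length(m$params[[k]]), sd = 0.05)
  }
  X <- poulvoc:::.stack_features(ts$feats[1:6])
  y <- match(ts$labels[1:6], ts$classes)
  fwd <- poulvoc:::.forward(m, X, training = FALSE)
  g <- poulvoc:::.backward(m, fwd, y)
  loss_at <- function(model) {
    poulvoc:::.xent(poulvoc:::.forward(model, X, training = FALSE)$probs, y)
  }
  set.seed(4)
  eps <- 1e-6
  for (k in c("conv1_W", "conv2_b", "conv3_W", "dense_W", "out_W", "out_b")) {
    for (rep in 1:3) {
      i <- sample(length(m$params[[k]]), 1)
      mp <- m; mp$params[[k]][i] <- mp$params[[k]][i] + eps
      mm <- m; mm$params[[k]][i] <- mm$params[[k]][i] - eps
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(g[[k]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training rejects malformed inputs", {
  ts <- tiny_setup()
  m <- build_model(ts$cfg, classes = ts$classes)
  expect_error(train_model(m, ts$feats, ts$labels, rep("train", 40),
                           train_config()), "splits must be nonempty")
  bad_labels <- ts$labels; bad_labels[1] <- "C9"
  expect_error(train_model(m, ts$feats, bad_labels, ts$split, train_config()),
               "outside model classes")
  expect_error(predict_model(m, list(matrix(0, 5, 6))), "does not match")
})

test_that("model archives round-trip through save/load", {
  ts <- tiny_setup()
  tc <- train_config(epochs = 2, batch_size = 8, seed = 1)
  m <- train_model(build_model(ts$cfg, classes = ts$classes, seed = 1),
                   ts$feats, ts$labels, ts$split, tc)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_model(m, ts$feats[1:3])$probs,
                   predict_model(m2, ts$feats[1:3])$probs)
})
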