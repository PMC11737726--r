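# Independent oracles, deliberately naive: direct evaluation of the
# defining summations, no reuse of the package's computation paths.

# One Haar analysis level by direct evaluation of
# a1[n] = sum_k h[k - 2n] a0[k], d1[n] = sum_k g[k - 2n] a0[k],
# h = (1/sqrt(2), 1/sqrt(2)), g = (1/sqrt(2), -1/sqrt(2)).
oracle_haar_level <- function(a0) {
  if (length(a0) %% 2 == 1) a0 <- c(a0, 0)
  s <- 1 / sqrt(2)
  n_out <- length(a0) / 2
  a1 <- numeric(n_out)
  d1 <- numeric(n_out)
  for (n in 0:(n_out - 1)) {
    acc_a <- 0
    acc_d <- 0
    for (k in 0:(length(a0) - 1)) {
      off <- k - 2 * n
      if (off == 0) { acc_a <- acc_a + s * a0[k + 1]; acc_d <- acc_d + s * a0[k + 1] }
      if (off == 1) { acc_a <- acc_a + s * a0[k + 1]; acc_d <- acc_d - s * a0[k + 1] }
    }
    a1[n + 1] <- acc_a
    d1[n + 1] <- acc_d
  }
  list(approx = a1, detail = d1)
}

oracle_haar_multilevel <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    lv <- oracle_haar_level(a)
    details[[j]] <- lv$detail
    a <- lv$approx
  }
  list(approx = a, details = details)
}

# E_m = sum_k P[k] H_m[k] by explicit double loop.
oracle_mel_energies <- function(power, bank) {
  out <- matrix(0, nrow(power), nrow(bank))
  for (fr in seq_len(nrow(power))) {
    for (m in seq_len(nrow(bank))) {
      acc <- 0
      for (k in seq_len(ncol(power))) acc <- acc + power[fr, k] * bank[m, k]
      out[fr, m] <- acc
    }
  }
  out
}

# Spectral centroid of a signal segment via a plain FFT.
oracle_centroid <- function(x, sample_rate) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2)]^2
  f <- (0:(n %/% 2 - 1)) * sample_rate / n
  sum(f * p) / sum(p)
}

# One-vs-rest 2x2 collapse metrics for class i of a count matrix.
oracle_ovr_metrics <- function(cm, i) {
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0)
}

# Mean log-mel spectrum of a clip (40-vector), for the nearest-class-mean
# separability oracle.
mean_mel_profile <- function(clip) {
  colMeans(extract_mfe(clip)$values)
}

# Tiny model + random features for classifier unit tests.
tiny_setup <- function(n_clips = 40, frames = 24, bands = 6, n_classes = 3,
                       seed = 5) {
  set.seed(seed)
  classes <- paste0("C", seq_len(n_classes))
  labels <- rep(classes, length.out = n_clips)
  # class-dependent mean shift so the task is learnable
  feats <- lapply(seq_len(n_clips), function(i) {
    matrix(rnorm(frames * bands, mean = match(labels[i], classes)), frames, bands)
  })
  split <- rep(c("train", "train", "train", "val"), length.out = n_clips)
  cfg <- model_config(conv_filters = c(4L, 4L, 4L), kernel_size = 2L,
                      dropout_rates = c(0.1, 0.1, 0.1), dense_units = 8L,
                      n_classes = n_classes, input_shape = c(frames, bands))
  list(feats = feats, labels = labels, split = split, cfg = cfg,
       classes = classes)
}
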