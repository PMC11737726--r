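test_that("mel mapping follows its formula and inverts cleanly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700, mel_break = 700), 2595 * log10(2))
  expect_error(hz_to_mel(-1), ">= 0")
  f <- seq(0, 8000, by = 50)
  m <- hz_to_mel(f)
  expect_true(all(diff(m) > 0))
  expect_equal(mel_to_hz(m), f, tolerance = 1e-9)
  # the alternative printed break constant is selectable
  expect_gt(hz_to_mel(1000, mel_break = 100), hz_to_mel(1000, mel_break = 700))
})

test_that("STFT power spectrum isolates a bin-centered tone", {
  sr <- 16000
  fr <- frame_params(0.032, 0.016, window = "rect", fft_size = 512L)
  f0 <- 1000  # 1000 = 32 * sr/512, exactly bin-centered
  x <- sin(2 * pi * f0 * (0:15999) / sr)
  p <- stft_power(x, sr, fr)
  peaks <- apply(p, 1, which.max)
  expect_true(all(peaks == 33))  # bin index 32 (0-based) + 1
  off_peak <- p[1, -c(33)]
  expect_lt(max(off_peak), 1e-12 * p[1, 33])
})

test_that("STFT satisfies Parseval per frame and handles degenerate input", {
  sr <- 8000
  fr <- frame_params(0.032, 0.032, window = "rect", fft_size = 256L)
  set.seed(2)
  x <- rnorm(1024)
  p <- stft_power(x, sr, fr)
  n <- 256
  for (i in seq_len(nrow(p))) {
    seg <- x[((i - 1) * n + 1):(i * n)]
    # reassemble the full two-sided spectrum from the one-sided power
    full <- c(p[i, ], rev(p[i, 2:(n / 2)]))
    expect_equal(sum(seg^2), sum(full) / n, tolerance = 1e-9)
  }
  expect_true(all(stft_power(numeric(600), sr, fr) == 0))
  expect_error(stft_power(rnorm(100), sr, fr), "shorter than one frame")
})

test_that("mel filter bank is triangular with mel-equispaced centers", {
  bp <- melbank_params(n_filters = 40L, f_min = 0, f_max = 8000,
                       sample_rate = 16000)
  bank <- mel_filterbank(bp, 512L)
  expect_equal(dim(bank), c(40L, 257L))
  expect_true(all(bank >= 0))
  # one interior maximum per row
  expect_true(all(apply(bank, 1, function(r) sum(r == max(r))) == 1))
  centers <- attr(bank, "center_freqs")
  mels <- hz_to_mel(centers)
  expect_lt(max(abs(diff(mels) - diff(mels)[1])), 1e-6)
  # coverage between the first and last center
  bin_freqs <- (0:256) * 16000 / 512
  interior <- bin_freqs > centers[1] & bin_freqs < centers[40]
  expect_true(all(colSums(bank)[interior] > 0))
  expect_error(mel_filterbank(melbank_params(n_filters = 200L,
                                             sample_rate = 16000), 64L),
               "too large")
})

test_that("mel energies equal the brute-force summation oracle", {
  set.seed(7)
  power <- matrix(runif(4 * 3), 4, 3)        # 4 frames, 3 bins
  bank <- matrix(runif(2 * 3), 2, 3)         # 2 filters
  expect_equal(mel_energies(power, bank), oracle_mel_energies(power, bank),
               tolerance = 1e-12)
  # larger random instance
  power <- matrix(runif(6 * 33), 6, 33)
  bp <- melbank_params(n_filters = 8L, sample_rate = 8000)
  bank2 <- mel_filterbank(bp, 64L)
  expect_equal(mel_energies(power, bank2), oracle_mel_energies(power, bank2),
               tolerance = 1e-12)
  expect_true(all(mel_energies(power * 0, bank2) == 0))
  # single-bin impulse picks out that bank column
  imp <- matrix(0, 1, 33); imp[1, 17] <- 1
  expect_equal(as.numeric(mel_energies(imp, bank2)), bank2[, 17])
  expect_error(mel_energies(matrix(0, 2, 5), matrix(0, 2, 4)), "mismatch")
})

test_that("log compression floors at eps and preserves order", {
  E <- matrix(c(0, exp(1) - 1e-10, 5), 1, 3)
  out <- log_compress(E, floor_eps = 1e-10)
  expect_equal(out[1, 1], log(1e-10))
  expect_equal(out[1, 2], 1.0)
  expect_error(log_compress(matrix(-1)), "nonnegative")
  E2 <- E + 0.5
  expect_true(all(log_compress(E2) >= log_compress(E)))
})

test_that("a 2-s clip at 16 kHz with 25 ms / 10 ms framing yields 198 frames", {
  clip <- synth_call(default_callspec("C1"), duration = 2,
                     sample_rate = 16000, seed = 1)
  m <- extract_mfe(clip)
  expect_equal(dim(m$values), c(198L, 40L))
  expect_equal(nrow(m$values), floor((32000 - 400) / 160) + 1)
  m2 <- extract_mfe(clip)
  expect_identical(m$values, m2$values)
})

test_that("feature extraction is shift-covariant at hop granularity", {
  set.seed(8)
  sr <- 16000
  x <- rnorm(4000)
  hop <- 160
  fr <- frame_params()
  a <- stft_power(x, sr, fr)
  b <- stft_power(x[(hop + 1):length(x)], sr, fr)
  k <- nrow(b)
  expect_equal(a[2:(k + 1), ], b, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("high-pitched calls concentrate energy in higher mel bands", {
  c1 <- extract_mfe(synth_call(default_callspec("C1"), seed = 3))
  c2 <- extract_mfe(synth_call(default_callspec("C2"), seed = 3))
  centroid <- function(m) {
    w <- exp(colMeans(m$values))  # back to energy scale
    sum(seq_along(w) * w) / sum(w)
  }
  expect_gt(centroid(c2), centroid(c1))
})

test_that("features persist to TSV with a faithful sidecar", {
  clip <- synth_call(default_callspec("C3"), seed = 4)
  m <- extract_mfe(clip)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mfe(m, f)
  m2 <- read_mfe(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$frame_times, m$frame_times)
  expect_equal(m2$params$bank$n_filters, 40L)
})
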