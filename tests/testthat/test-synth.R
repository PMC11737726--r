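test_that("built-in call specs honor their qualitative contracts", {
  expect_error(default_callspec("C9"), "unknown vocalization class")
  expect_identical(default_callspec("C2"), default_callspec("C2"))
  c1 <- default_callspec("C1")
  c2 <- default_callspec("C2")
  expect_lt(mean(c1$f0_range), 700)          # mellow, low-pitched
  expect_gt(mean(c2$f0_range), 2000)         # high-pitched piping
  expect_lt(c2$syllable_duration, c1$syllable_duration + 0.1)
  # class-mean fundamentals pairwise separated by >= 150 Hz
  # (C4 is broadband, C5 a long FM sweep; both excluded by design)
  tonal <- c("C1", "C2", "C3", "C6")
  means <- vapply(tonal, function(cl) mean(default_callspec(cl)$f0_range), 0)
  gaps <- abs(outer(means, means, `-`))
  expect_true(all(gaps[upper.tri(gaps)] >= 150))
  expect_identical(default_callspec("C4")$n_harmonics, 0L)  # broadband pulses
  expect_gt(default_callspec("C5")$fm_sweep, 0)             # upward crow sweep
})

test_that("synth_call is bit-deterministic and peak-normalized", {
  spec <- default_callspec("C1")
  a <- synth_call(spec, seed = 7)
  b <- synth_call(spec, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, synth_call(spec, seed = 8)$samples))
  expect_equal(max(abs(a$samples)), 10^(spec$amplitude_db / 20))
  expect_equal(a$duration, 2)
  expect_equal(length(a$samples), 32000)
})

test_that("a degenerate spec produces a pure tone with its FFT peak at f0", {
  spec <- callspec(c(1000, 1000), syllable_duration = 0.5, repetition_rate = 2,
                   n_harmonics = 1, amplitude_db = -6, fm_sweep = 0,
                   am_depth = 0)
  clip <- synth_call(spec, duration = 2, sample_rate = 16000, seed = 3)
  p <- Mod(stats::fft(clip$samples))[1:16000]
  peak_hz <- (which.max(p) - 1) * 16000 / 32000
  expect_lt(abs(peak_hz - 1000), 16000 / 32000 + 1e-9)  # within one bin
})

test_that("the crow's FM sweep raises the spectral centroid over the clip", {
  clip <- synth_call(default_callspec("C5"), seed = 11)
  n <- length(clip$samples)
  c1 <- oracle_centroid(clip$samples[1:(n / 2)], clip$sample_rate)
  c2 <- oracle_centroid(clip$samples[(n / 2 + 1):n], clip$sample_rate)
  expect_gt(c2, c1)
})

test_that("harmonics above Nyquist are clipped with a warning", {
  spec <- callspec(c(3000, 3000), 0.2, 2, n_harmonics = 6, amplitude_db = -6)
  expect_warning(clip <- synth_call(spec, sample_rate = 16000, seed = 1),
                 "Nyquist")
  p <- Mod(stats::fft(clip$samples))
  f <- (seq_along(p) - 1) * 16000 / length(p)
  above <- p[f > 8000 & f < 16000 - 8000]
  expect_lt(sum(above), 1e-6 * sum(p))
})

test_that("barn noise hits the requested SNR and preserves determinism", {
  clip <- synth_call(default_callspec("C1"), seed = 5)
  ns <- noisespec(snr_db = 10)
  noisy1 <- add_barn_noise(clip, ns, seed = 2)
  noisy2 <- add_barn_noise(clip, ns, seed = 2)
  expect_identical(noisy1$samples, noisy2$samples)
  expect_identical(noisy1$label, clip$label)
  # recompute the power ratio from the two addends
  nz <- noisy1$samples - clip$samples
  snr <- 10 * log10(mean(clip$samples^2) / mean(nz^2))
  expect_lt(abs(snr - 10), 0.1)
  # near-clean: +60 dB noise perturbs the RMS by < 0.2%
  hi <- add_barn_noise(clip, noisespec(snr_db = 60), seed = 2)
  rel <- sqrt(mean((hi$samples - clip$samples)^2)) / sqrt(mean(clip$samples^2))
  expect_lt(rel, 0.002)
  expect_error(add_barn_noise(audio_clip(numeric(100), 16000), ns, 1),
               "zero-power")
})

test_that("generate_dataset writes the requested composition with 4:1 splits", {
  out <- withr::local_tempdir()
  man <- generate_dataset(c(C1 = 10L, C6 = 5L), out_dir = out, seed = 3)
  expect_equal(nrow(man), 15)
  expect_equal(sum(man$label == "C1"), 10)
  expect_equal(sum(man$label == "C1" & man$split == "train"), 8)
  expect_equal(sum(man$label == "C1" & man$split == "val"), 2)
  expect_equal(sum(man$label == "C6" & man$split == "val"), 1)
  expect_false(anyDuplicated(man$file) > 0)
  expect_true(all(file.exists(man$file)))
  # manifest CSV round-trips
  csv <- read.csv(file.path(out, "manifest.csv"))
  expect_equal(csv$label, man$label)
  # clips on disk are exactly the seeded synthesis after 16-bit quantization
  w <- read_wav(man$file[1])
  ref <- synth_call(default_callspec("C1"), seed = man$seed[1])
  expect_identical(w$samples, round(ref$samples * 32767) / 32767)
  # regeneration is bit-identical
  out2 <- withr::local_tempdir()
  man2 <- generate_dataset(c(C1 = 10L, C6 = 5L), out_dir = out2, seed = 3)
  expect_identical(man$split, man2$split)
  expect_identical(read_wav(man$file[7])$samples, read_wav(man2$file[7])$samples)
})

test_that("empty composition yields an empty manifest and no files", {
  out <- withr::local_tempdir()
  man <- generate_dataset(stats::setNames(integer(0), character(0)),
                          out_dir = out, seed = 1)
  expect_equal(nrow(man), 0)
  expect_length(list.files(out, pattern = "\\.wav$"), 0)
})

test_that("full composition preset matches the study's class sizes", {
  comp <- composition_preset("full")
  expect_identical(comp, c(C1 = 1200L, C2 = 480L, C3 = 360L, C4 = 720L,
                           C5 = 600L, C6 = 240L))
  expect_identical(composition_preset("mini") * 12L, comp)
})

test_that("the six classes are separable by a nearest-class-mean oracle", {
  # mini preset, clean clips: a trivial classifier on average mel spectra
  # must exceed 80% accuracy, so the synthetic task is learnable
  out <- withr::local_tempdir()
  man <- generate_dataset("mini", out_dir = out, seed = 42)
  clips <- read_manifest_audio(man)
  prof <- t(vapply(clips, mean_mel_profile, numeric(40)))
  tr <- man$split == "train"
  centroids <- sapply(sort(unique(man$label)),
                      function(cl) colMeans(prof[tr & man$label == cl, , drop = FALSE]))
  pred <- colnames(centroids)[apply(prof[!tr, ], 1, function(v) {
    which.min(colSums((centroids - v)^2))
  })]
  expect_gt(mean(pred == man$label[!tr]), 0.80)
})
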