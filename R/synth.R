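#' The six vocalization classes
#'
#' Class codes for the call repertoire modelled by this package:
#' C1 contentment clucks, C2 hunger piping, C3 exploratory peeping,
#' C4 prelaying crackles, C5 rooster crowing, C6 alarm/distress calls.
#'
#' @return Character vector of the six class codes, named by a short
#'   description of each call.
#' @export
vocal_classes <- function() {
  c(contentment_cluck = "C1",
    hunger_piping     = "C2",
    exploratory_peeping = "C3",
    prelaying_crackle = "C4",
    rooster_crow      = "C5",
    alarm_distress    = "C6")
}

#' Construct a call specification
#'
#' Parametric description of one call type: fundamental-frequency band,
#' syllable timing, harmonic content, level, frequency-modulation sweep
#' and amplitude-modulation depth. `n_harmonics = 0` denotes a broadband
#' (noise-excited) call whose energy is band-limited to `f0_range`
#' instead of carried by a harmonic stack.
#'
#' @param f0_range Length-2 numeric, Hz. Fundamental band (per-syllable
#'   jitter is uniform in this interval); for broadband calls, the
#'   passband.
#' @param syllable_duration Seconds, length of one syllable.
#' @param repetition_rate Hz, syllable repetition rate.
#' @param n_harmonics Number of harmonic partials (0 = broadband).
#' @param amplitude_db Peak level in dBFS (must be <= 0).
#' @param fm_sweep Hz/s linear frequency sweep within each syllable.
#' @param am_depth Amplitude-modulation depth in [0, 1]; 0 yields a
#'   continuous sound, 1 fully gates the signal between syllables.
#' @return A `callspec` list.
#' @export
callspec <- function(f0_range, syllable_duration, repetition_rate,
                     n_harmonics, amplitude_db, fm_sweep = 0, am_depth = 1) {
  stopifnot(length(f0_range) == 2, f0_range[1] <= f0_range[2], f0_range[1] >= 0)
  if (syllable_duration <= 0) stopf("syllable_duration must be > 0")
  if (amplitude_db > 0) stopf("amplitude_db must be <= 0 dBFS")
  if (am_depth < 0 || am_depth > 1) stopf("am_depth must be in [0, 1]")
  structure(list(f0_range = as.numeric(f0_range),
                 syllable_duration = syllable_duration,
                 repetition_rate = repetition_rate,
                 n_harmonics = as.integer(n_harmonics),
                 amplitude_db = amplitude_db,
                 fm_sweep = fm_sweep,
                 am_depth = am_depth),
            class = "callspec")
}

# Built-in acoustic parameterization of the six call types. Qualitative
# contracts: C1 mellow/low/steady, C2 high-pitched short repeated, C3 quiet
# mid-high peeping, C4 broadband pulse train (no f0), C5 long loud upward
# FM sweep, C6 loud harsh (harmonic-rich) repetitive calls. Mean f0 of
# C1/C2/C3/C6 are pairwise >= 150 Hz apart so classes stay separable.
.callspec_table <- function() {
  list(
    C1 = callspec(c(300, 600),  0.15, 3.0, 5L, -6,  fm_sweep = 0,    am_depth = 1),
    C2 = callspec(c(2500, 3500), 0.08, 6.0, 2L, -6,  fm_sweep = 0,    am_depth = 1),
    C3 = callspec(c(1600, 2000), 0.10, 2.5, 2L, -20, fm_sweep = 800,  am_depth = 1),
    C4 = callspec(c(800, 4000), 0.05, 8.0, 0L, -8,  fm_sweep = 0,    am_depth = 1),
    C5 = callspec(c(550, 650),  1.60, 0.5, 6L, -3,  fm_sweep = 400,  am_depth = 0.9),
    C6 = callspec(c(1050, 1350), 0.12, 4.0, 5L, -3,  fm_sweep = -300, am_depth = 1)
  )
}

#' Built-in call specification for a vocalization class
#'
#' @param class One of the codes from [vocal_classes()].
#' @return A [callspec()] object; identical on every call for the same
#'   class.
#' @export
default_callspec <- function(class) {
  tab <- .callspec_table()
  if (!class %in% names(tab)) {
    stopf("unknown vocalization class '%s' (expected one of %s)",
          class, paste(names(tab), collapse = ", "))
  }
  tab[[class]]
}

#' Construct a noise specification for barn background noise
#'
#' Models the continuous background of a ventilated barn: a ventilation-
#' fan hum (fundamental plus harmonics at 1/k amplitude) mixed at equal
#' power with a broadband (white or pink) component, scaled to a target
#' signal-to-noise ratio.
#'
#' @param hum_freq Fan fundamental, Hz.
#' @param hum_harmonics Number of hum partials.
#' @param broadband_color `"pink"` (1/f power) or `"white"`.
#' @param snr_db Target SNR in dB (signal power over total noise power).
#' @return A `noisespec` list.
#' @export
noisespec <- function(hum_freq = 120, hum_harmonics = 4L,
                      broadband_color = c("pink", "white"), snr_db = 10) {
  broadband_color <- match.arg(broadband_color)
  stopifnot(is.finite(snr_db), hum_freq > 0)
  structure(list(hum_freq = hum_freq, hum_harmonics = as.integer(hum_harmonics),
                 broadband_color = broadband_color, snr_db = snr_db),
            class = "noisespec")
}

#' Construct an audio clip object
#'
#' @param samples Numeric samples in [-1, 1].
#' @param sample_rate Hz.
#' @param label Class code or NA.
#' @param seed Generating seed (NA for external audio).
#' @return An `audio_clip` list with `duration = length(samples)/sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate, label = NA_character_,
                       seed = NA_integer_) {
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 label = label,
                 seed = seed,
                 duration = length(samples) / sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %d Hz, label=%s, peak=%.3f\n",
              x$duration, as.integer(x$sample_rate),
              x$label, max(abs(x$samples))))
  invisible(x)
}

#' Synthesize one vocalization clip
#'
#' Renders a call as a train of raised-cosine syllables at
#' `repetition_rate`. Harmonic calls carry an `n_harmonics`-partial stack
#' (partial amplitudes 1/h) whose fundamental is jittered per syllable
#' within `f0_range` and swept linearly at `fm_sweep` Hz/s across the
#' syllable; broadband calls (`n_harmonics = 0`) use noise band-limited
#' to `f0_range`. The syllable envelope is mixed with a constant floor
#' controlled by `am_depth`, and the result is peak-normalized to
#' `amplitude_db`. Output is bit-identical for identical
#' (spec, duration, sample_rate, seed).
#'
#' @param spec A [callspec()].
#' @param duration Clip length in seconds (default 2).
#' @param sample_rate Hz (default 16000).
#' @param seed Integer seed.
#' @param label Optional class label stored on the clip.
#' @return An [audio_clip()].
#' @export
synth_call <- function(spec, duration = 2, sample_rate = 16000, seed = 1,
                       label = NA_character_) {
  stopifnot(inherits(spec, "callspec"), duration > 0)
  n <- round(duration * sample_rate)
  dt <- 1 / sample_rate
  nyq <- sample_rate / 2
  with_seed(seed, {
    period <- 1 / spec$repetition_rate
    onsets <- seq(0, duration - 1e-9, by = period)
    syl_len <- min(spec$syllable_duration, period)
    syl_n <- max(2L, round(syl_len * sample_rate))
    env <- numeric(n)
    f_track <- rep(mean(spec$f0_range), n)
    for (on in onsets) {
      i0 <- floor(on * sample_rate) + 1L
      i1 <- min(n, i0 + syl_n - 1L)
      m <- i1 - i0 + 1L
      win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(syl_n) - 1) / (syl_n - 1))
      env[i0:i1] <- pmax(env[i0:i1], win[seq_len(m)])
      f0 <- stats::runif(1, spec$f0_range[1], spec$f0_range[2])
      tau <- (seq_len(m) - 1L) * dt
      f_track[i0:i1] <- f0 + spec$fm_sweep * tau
    }
    f_track <- pmax(f_track, 0)
    if (spec$n_harmonics >= 1L) {
      phase <- 2 * pi * cumsum(f_track) * dt
      n_h <- spec$n_harmonics
      f_top <- max(f_track)
      keep <- which(seq_len(n_h) * f_top < nyq)
      if (length(keep) < n_h) {
        warning(sprintf("clipping harmonics above Nyquist: keeping %d of %d",
                        length(keep), n_h), call. = FALSE)
        if (length(keep) == 0) keep <- 1L
      }
      carrier <- numeric(n)
      for (h in keep) carrier <- carrier + sin(h * phase) / h
    } else {
      # broadband excitation: white noise band-limited to f0_range
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      freqs <- (seq_len(n) - 1L) * sample_rate / n
      freqs <- pmin(freqs, sample_rate - freqs)  # mirror for negative bins
      mask <- as.numeric(freqs >= spec$f0_range[1] & freqs <= spec$f0_range[2])
      carrier <- Re(stats::fft(W * mask, inverse = TRUE)) / n
    }
    x <- carrier * ((1 - spec$am_depth) + spec$am_depth * env)
    peak <- max(abs(x))
    if (peak > 0) x <- x * (10^(spec$amplitude_db / 20) / peak)
    audio_clip(x, sample_rate, label = label, seed = as.integer(seed))
  })
}

#' Add barn background noise to a clip at a target SNR
#'
#' The noise is a ventilation-fan hum (fundamental plus harmonics at
#' amplitude 1/k, random phases) mixed at equal power with a broadband
#' component (white or pink), then scaled so that
#' `10*log10(P_signal/P_noise)` equals `noise$snr_db` exactly. If the
#' mixture exceeds full scale it is renormalized to peak 1 (the SNR is a
#' ratio, so it is preserved). The label is preserved.
#'
#' @param clip An [audio_clip()].
#' @param noise A [noisespec()].
#' @param seed Integer seed for the noise realization.
#' @return A new [audio_clip()] with identical metadata.
#' @export
add_barn_noise <- function(clip, noise, seed = 1) {
  stopifnot(inherits(clip, "audio_clip"), inherits(noise, "noisespec"))
  x <- clip$samples
  n <- length(x)
  p_sig <- mean(x^2)
  if (p_sig == 0) stopf("zero-power clip: SNR is undefined")
  if (noise$hum_freq >= clip$sample_rate / 2) {
    stopf("hum_freq must be below Nyquist")
  }
  nz <- with_seed(seed, {
    t <- (seq_len(n) - 1L) / clip$sample_rate
    hum <- numeric(n)
    for (k in seq_len(noise$hum_harmonics)) {
      f <- k * noise$hum_freq
      if (f >= clip$sample_rate / 2) break
      hum <- hum + sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) / k
    }
    w <- stats::rnorm(n)
    if (noise$broadband_color == "pink") {
      W <- stats::fft(w)
      freqs <- (seq_len(n) - 1L) * clip$sample_rate / n
      freqs <- pmin(freqs, clip$sample_rate - freqs)
      g <- ifelse(freqs > 0, 1 / sqrt(freqs), 0)
      w <- Re(stats::fft(W * g, inverse = TRUE)) / n
    }
    hum <- hum / sqrt(mean(hum^2))
    w <- w / sqrt(mean(w^2))
    hum + w
  })
  alpha <- sqrt(p_sig / (mean(nz^2) * 10^(noise$snr_db / 10)))
  y <- x + alpha * nz
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  out <- audio_clip(y, clip$sample_rate, label = clip$label, seed = clip$seed)
  out
}

#' Dataset composition presets
#'
#' `"full"` is the full study composition (1200/480/360/720/600/240
#' clips for C1..C6); `"mini"` scales it down by 12 (100/40/30/60/50/20)
#' for desk-scale runs.
#'
#' @param preset `"full"` or `"mini"`.
#' @return Named integer vector of per-class clip counts.
#' @export
composition_preset <- function(preset = c("mini", "full")) {
  preset <- match.arg(preset)
  full <- c(C1 = 1200L, C2 = 480L, C3 = 360L, C4 = 720L, C5 = 600L, C6 = 240L)
  if (preset == "full") full else full %/% 12L
}

#' Generate a labeled synthetic vocalization dataset
#'
#' Writes one 2-second mono 16-bit PCM WAV per clip plus a manifest CSV
#' (`file,label,split,seed,snr_db`) and a key-value record of the
#' generator parameters. Clips are deterministic functions of
#' (composition, seed); each class is independently shuffled (seeded)
#' and split train:val at 4:1 with `floor(n/5)` clips on the validation
#' side.
#'
#' @param composition Named integer vector of clip counts per class
#'   code, or a preset name understood by [composition_preset()].
#' @param out_dir Output directory (created if needed).
#' @param sample_rate Hz (default 16000).
#' @param noise Optional [noisespec()]; `NULL` generates clean clips.
#' @param seed Integer master seed.
#' @param duration Clip length in seconds (default 2).
#' @return A `data.frame` manifest with columns
#'   `file, label, split, seed, snr_db` (also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(composition = "mini", out_dir,
                             sample_rate = 16000, noise = NULL, seed = 1,
                             duration = 2) {
  if (is.character(composition) && length(composition) == 1) {
    composition <- composition_preset(composition)
  }
  stopifnot(all(composition >= 0), !is.null(names(composition)))
  bad <- setdiff(names(composition), vocal_classes())
  if (length(bad)) stopf("unknown class code(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  rows <- list()
  for (cls in names(composition)) {
    n_cls <- composition[[cls]]
    if (n_cls == 0) next
    ci <- match(cls, vocal_classes())
    spec <- default_callspec(cls)
    files <- character(n_cls)
    seeds <- integer(n_cls)
    for (j in seq_len(n_cls)) {
      clip_seed <- derive_seed(seed, ci, j)
      clip <- synth_call(spec, duration = duration, sample_rate = sample_rate,
                         seed = clip_seed, label = cls)
      if (!is.null(noise)) {
        clip <- add_barn_noise(clip, noise, seed = derive_seed(seed, ci, j, 99))
      }
      f <- file.path(out_dir, sprintf("%s_%04d.wav", cls, j))
      write_wav(clip$samples, f, sample_rate)
      files[j] <- f
      seeds[j] <- clip_seed
    }
    split <- rep("train", n_cls)
    n_val <- floor(n_cls / 5)
    if (n_val > 0) {
      ord <- with_seed(derive_seed(seed, ci, 0), sample.int(n_cls))
      split[ord[seq_len(n_val)]] <- "val"
    }
    rows[[cls]] <- data.frame(file = files, label = cls, split = split,
                              seed = seeds,
                              snr_db = if (is.null(noise)) Inf else noise$snr_db,
                              stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(file = character(), label = character(), split = character(),
               seed = integer(), snr_db = numeric(), stringsAsFactors = FALSE)
  }
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  params <- c(sprintf("sample_rate=%d", as.integer(sample_rate)),
              sprintf("duration=%g", duration),
              sprintf("seed=%d", as.integer(seed)),
              sprintf("snr_db=%s", if (is.null(noise)) "clean" else noise$snr_db),
              sprintf("composition.%s=%d", names(composition),
                      as.integer(composition)))
  writeLines(params, file.path(out_dir, "params.txt"))
  manifest
}

#' Read all clips listed in a manifest
#'
#' @param manifest Manifest data frame from [generate_dataset()].
#' @return List of [audio_clip()] objects in manifest row order.
#' @export
read_manifest_audio <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    w <- read_wav(manifest$file[i])
    audio_clip(w$samples, w$sample_rate, label = manifest$label[i],
               seed = manifest$seed[i])
  })
}
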