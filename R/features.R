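#' Hertz to mel conversion
#'
#' `m = 2595 * log10(1 + f / mel_break)`. The canonical pairing with the
#' 2595 coefficient uses a 700 Hz break; 100 is selectable for the
#' alternative corner sometimes seen in print.
#'
#' @param f Frequency in Hz (vectorized, must be >= 0).
#' @param mel_break Break constant inside the logarithm, Hz.
#' @return Mel value(s); strictly increasing in `f`, 0 at `f = 0`.
#' @export
hz_to_mel <- function(f, mel_break = 700) {
  if (any(f < 0)) stopf("frequency must be >= 0")
  2595 * log10(1 + f / mel_break)
}

#' Mel to Hertz conversion (inverse of [hz_to_mel()])
#' @param m Mel value(s), >= 0.
#' @param mel_break Break constant, Hz.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m, mel_break = 700) {
  mel_break * (10^(m / 2595) - 1)
}

#' Framing parameters for the short-time Fourier transform
#'
#' @param frame_length Frame length, seconds (default 25 ms).
#' @param hop Hop between frame starts, seconds (default 10 ms).
#' @param window `"hamming"`, `"hann"`, or `"rect"`.
#' @param fft_size FFT length; `NULL` picks the next power of two at or
#'   above the frame length in samples.
#' @return A `frame_params` list.
#' @export
frame_params <- function(frame_length = 0.025, hop = 0.010,
                         window = c("hamming", "hann", "rect"),
                         fft_size = NULL) {
  window <- match.arg(window)
  if (hop <= 0 || hop > frame_length) stopf("require 0 < hop <= frame_length")
  structure(list(frame_length = frame_length, hop = hop, window = window,
                 fft_size = fft_size),
            class = "frame_params")
}

#' Mel filter-bank parameters
#'
#' @param n_filters Number of triangular filters (default 40).
#' @param f_min,f_max Band edges, Hz; `f_max = NULL` means Nyquist.
#' @param sample_rate Hz.
#' @param mel_break Mel-scale break constant (see [hz_to_mel()]).
#' @return A `melbank_params` list.
#' @export
melbank_params <- function(n_filters = 40L, f_min = 0, f_max = NULL,
                           sample_rate = 16000, mel_break = 700) {
  if (is.null(f_max)) f_max <- sample_rate / 2
  stopifnot(f_min >= 0, f_min < f_max, f_max <= sample_rate / 2, n_filters >= 2)
  structure(list(n_filters = as.integer(n_filters), f_min = f_min,
                 f_max = f_max, sample_rate = sample_rate,
                 mel_break = mel_break),
            class = "melbank_params")
}

.window_vec <- function(type, n) {
  k <- seq_len(n) - 1L
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann    = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         rect    = rep(1, n))
}

#' Short-time power spectrum
#'
#' Slices the signal into frames of `frame$frame_length` seconds every
#' `frame$hop` seconds (frame count `floor((n - frame)/hop) + 1`, no
#' tail padding), applies the window, and returns the one-sided power
#' spectrum `|X[k]|^2` for bins `k = 0..fft_size/2` of the DFT
#' `X[k] = sum_n x[n] exp(-i 2 pi k n / N)`.
#'
#' @param signal Numeric vector.
#' @param sample_rate Hz.
#' @param frame A [frame_params()].
#' @return Matrix of dimension frames x (fft_size/2 + 1) with attribute
#'   `frame_times` (frame start times, seconds) and `fft_size`.
#' @export
stft_power <- function(signal, sample_rate, frame = frame_params()) {
  stopifnot(inherits(frame, "frame_params"))
  flen <- round(frame$frame_length * sample_rate)
  hop <- round(frame$hop * sample_rate)
  n <- length(signal)
  if (n < flen) stopf("signal (%d samples) shorter than one frame (%d)", n, flen)
  nfft <- frame$fft_size %||% (2^ceiling(log2(flen)))
  if (nfft < flen) stopf("fft_size must be >= frame length in samples")
  n_frames <- floor((n - flen) / hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(flen), starts, `+`)   # flen x n_frames sample indices
  fr <- matrix(signal[idx], nrow = flen)
  fr <- fr * .window_vec(frame$window, flen)
  if (nfft > flen) fr <- rbind(fr, matrix(0, nfft - flen, n_frames))
  spec <- stats::mvfft(fr)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  p <- t(Mod(spec)^2)
  attr(p, "frame_times") <- starts / sample_rate
  attr(p, "fft_size") <- nfft
  p
}

#' Triangular mel filter bank
#'
#' `n_filters` triangular responses with peaks equally spaced on the mel
#' scale between `f_min` and `f_max`, evaluated at the FFT bin
#' frequencies. Filter m rises linearly from center m-1 to center m and
#' falls to center m+1 (band edges serve as the outer shoulders), so
#' adjacent filters overlap and all weights are nonnegative.
#'
#' @param params A [melbank_params()].
#' @param fft_size FFT length used for the power spectrum.
#' @return Matrix n_filters x (fft_size/2 + 1) with attribute
#'   `center_freqs` (Hz).
#' @export
mel_filterbank <- function(params, fft_size) {
  stopifnot(inherits(params, "melbank_params"))
  n_bins <- fft_size %/% 2L + 1L
  bin_freqs <- (seq_len(n_bins) - 1L) * params$sample_rate / fft_size
  mel_pts <- seq(hz_to_mel(params$f_min, params$mel_break),
                 hz_to_mel(params$f_max, params$mel_break),
                 length.out = params$n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts, params$mel_break)
  bank <- matrix(0, params$n_filters, n_bins)
  for (m in seq_len(params$n_filters)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    bank[m, ] <- pmax(0, pmin(up, dn))
  }
  if (any(rowSums(bank) == 0)) {
    stopf("n_filters = %d too large for the FFT bin resolution", params$n_filters)
  }
  attr(bank, "center_freqs") <- hz_pts[2:(params$n_filters + 1L)]
  bank
}

#' Per-frame mel filter energies
#'
#' `E_m = sum_k |X[k]|^2 H_m[k]` for each frame: the matrix product of
#' the power spectrogram with the transposed filter bank.
#'
#' @param power Frames x bins power matrix from [stft_power()].
#' @param bank Filters x bins weight matrix from [mel_filterbank()].
#' @return Frames x filters energy matrix.
#' @export
mel_energies <- function(power, bank) {
  if (ncol(power) != ncol(bank)) {
    stopf("bin mismatch: power has %d bins, bank has %d", ncol(power), ncol(bank))
  }
  power %*% t(bank)
}

#' Logarithmic compression of filter energies
#'
#' `log(E + floor_eps)` elementwise; the floor bounds the dynamic range
#' of silent frames without affecting voiced ones.
#'
#' @param E Nonnegative energy matrix.
#' @param floor_eps Additive floor (default 1e-10).
#' @return Matrix of log-energies.
#' @export
log_compress <- function(E, floor_eps = 1e-10) {
  if (any(E < 0)) stopf("energies must be nonnegative")
  log(E + floor_eps)
}

#' Extract log mel filter-bank energy (MFE) features from a clip
#'
#' The package's feature front end: short-time power spectrum, mel
#' filter-bank energies, log compression. Deterministic.
#'
#' @param clip An [audio_clip()] (or numeric vector with `sample_rate`).
#' @param frame A [frame_params()].
#' @param bank A [melbank_params()]; its `sample_rate` is overridden by
#'   the clip's.
#' @param floor_eps Log floor (see [log_compress()]).
#' @param sample_rate Required when `clip` is a bare numeric vector.
#' @return A `mel_spectrogram`: list with `values` (frames x filters),
#'   `frame_times`, and `params`.
#' @export
extract_mfe <- function(clip, frame = frame_params(), bank = melbank_params(),
                        floor_eps = 1e-10, sample_rate = NULL) {
  if (inherits(clip, "audio_clip")) {
    x <- clip$samples
    sr <- clip$sample_rate
  } else {
    if (is.null(sample_rate)) stopf("sample_rate required for bare signals")
    x <- as.numeric(clip)
    sr <- sample_rate
  }
  bank$sample_rate <- sr
  if (bank$f_max > sr / 2) bank$f_max <- sr / 2
  p <- stft_power(x, sr, frame)
  B <- mel_filterbank(bank, attr(p, "fft_size"))
  v <- log_compress(mel_energies(p, B), floor_eps)
  structure(list(values = v, frame_times = attr(p, "frame_times"),
                 params = list(frame = frame, bank = bank,
                               floor_eps = floor_eps)),
            class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d frames x %d bands, t in [0, %.3f] s\n",
              nrow(x$values), ncol(x$values), max(x$frame_times)))
  invisible(x)
}

#' Write / read a feature matrix with its sidecar metadata
#'
#' Tab-separated values plus a `.meta` key-value sidecar recording the
#' framing and filter-bank parameters, so features persisted to disk are
#' self-describing.
#'
#' @param m A `mel_spectrogram`.
#' @param path Output TSV path (sidecar written at `<path>.meta`).
#' @return `path` invisibly (`write_mfe`); a `mel_spectrogram`
#'   (`read_mfe`).
#' @export
write_mfe <- function(m, path) {
  stopifnot(inherits(m, "mel_spectrogram"))
  utils::write.table(m$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  fp <- m$params$frame; bp <- m$params$bank
  writeLines(c(sprintf("frame_length=%.17g", fp$frame_length),
               sprintf("hop=%.17g", fp$hop),
               sprintf("window=%s", fp$window),
               sprintf("n_filters=%d", bp$n_filters),
               sprintf("f_min=%.17g", bp$f_min),
               sprintf("f_max=%.17g", bp$f_max),
               sprintf("sample_rate=%.17g", bp$sample_rate),
               sprintf("mel_break=%.17g", bp$mel_break),
               sprintf("floor_eps=%.17g", m$params$floor_eps),
               sprintf("frame_times=%s", paste(sprintf("%.17g", m$frame_times),
                                               collapse = ","))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_mfe
#' @export
read_mfe <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(v) <- NULL
  kv <- strsplit(readLines(paste0(path, ".meta")), "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  num <- function(k) as.numeric(meta[[k]])
  structure(list(
    values = v,
    frame_times = as.numeric(strsplit(meta$frame_times, ",")[[1]]),
    params = list(
      frame = frame_params(num("frame_length"), num("hop"), meta$window),
      bank = melbank_params(as.integer(num("n_filters")), num("f_min"),
                            num("f_max"), num("sample_rate"),
                            num("mel_break")),
      floor_eps = num("floor_eps"))),
    class = "mel_spectrogram")
}
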