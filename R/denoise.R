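#' Multilevel discrete wavelet transform (db1/Haar)
#'
#' Decomposes a signal with the orthonormal Daubechies db1 (Haar) filter
#' pair, low-pass `h = (1/sqrt(2), 1/sqrt(2))` and high-pass
#' `g = (1/sqrt(2), -1/sqrt(2))`: at each level
#' `a[j+1][n] = sum_k h[k-2n] a[j][k]` and
#' `d[j+1][n] = sum_k g[k-2n] a[j][k]`, halving the length. Odd-length
#' bands are zero-padded by one sample before pairing (the pre-pad
#' length is recorded so reconstruction is exact). The transform is
#' orthonormal, so total coefficient energy equals signal energy.
#'
#' @param signal Numeric vector, length >= 2^levels.
#' @param wavelet Wavelet name; only `"db1"` (alias `"haar"`) is
#'   supported.
#' @param levels Decomposition depth J >= 1.
#' @return A `wavelet_coeffs` object: `approx` (coarsest a_J), `details`
#'   (list d_1..d_J, finest first), `levels`, `wavelet`,
#'   `original_length`, and the per-level pre-pad lengths.
#' @export
dwt_decompose <- function(signal, wavelet = "db1", levels = 1L) {
  wavelet <- tolower(wavelet)
  if (!wavelet %in% c("db1", "haar")) {
    stopf("unsupported wavelet '%s' (only db1/Haar)", wavelet)
  }
  n <- length(signal)
  levels <- as.integer(levels)
  if (levels < 1) stopf("levels must be >= 1")
  max_lev <- floor(log2(max(n, 1)))
  if (n < 2^levels) {
    stopf("signal of length %d supports at most %d level(s)", n, max_lev)
  }
  s <- 1 / sqrt(2)
  a <- as.numeric(signal)
  details <- vector("list", levels)
  lens <- integer(levels)
  for (j in seq_len(levels)) {
    lens[j] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, 0)
    ev <- a[seq(1, length(a), by = 2)]
    od <- a[seq(2, length(a), by = 2)]
    details[[j]] <- (ev - od) * s
    a <- (ev + od) * s
  }
  structure(list(approx = a, details = details, levels = levels,
                 wavelet = "db1", original_length = n, band_lengths = lens),
            class = "wavelet_coeffs")
}

#' Inverse multilevel db1 transform
#'
#' Exact inverse of [dwt_decompose()]: at each level,
#' `a[j][2n] = (a[j+1][n] + d[j+1][n])/sqrt(2)` and
#' `a[j][2n+1] = (a[j+1][n] - d[j+1][n])/sqrt(2)`, trimming any
#' zero-padding recorded during decomposition.
#'
#' @param coeffs A `wavelet_coeffs` object.
#' @return Numeric vector of length `coeffs$original_length`.
#' @export
dwt_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  s <- 1 / sqrt(2)
  a <- coeffs$approx
  for (j in rev(seq_len(coeffs$levels))) {
    d <- coeffs$details[[j]]
    if (length(d) != length(a)) {
      stopf("level %d size mismatch: approx %d vs detail %d",
            j, length(a), length(d))
    }
    up <- numeric(2L * length(a))
    up[seq(1, length(up), by = 2)] <- (a + d) * s
    up[seq(2, length(up), by = 2)] <- (a - d) * s
    a <- up[seq_len(coeffs$band_lengths[j])]
  }
  a
}

#' Robust noise-level estimate from detail coefficients
#'
#' The standard median-absolute-deviation estimator for Gaussian noise:
#' `sigma = median(|d|) / 0.6745`.
#'
#' @param detail Numeric vector of detail coefficients.
#' @return Nonnegative scalar sigma estimate.
#' @export
estimate_sigma <- function(detail) {
  if (length(detail) == 0) stopf("empty detail sequence")
  stats::median(abs(detail)) / 0.6745
}

#' Construct a wavelet thresholding policy
#'
#' @param mode `"hard"` (zero coefficients with |d| <= T) or `"soft"`
#'   (shrink all coefficients toward zero by T).
#' @param rule `"universal"` (T = sigma * sqrt(2 log N), N the original
#'   signal length) or `"fixed"` (T = `fixed_value`).
#' @param fixed_value Threshold for `rule = "fixed"`; must be >= 0.
#' @param sigma_estimator `"mad_finest"` (one sigma from the finest
#'   detail band) or `"per_level_mad"` (sigma per band).
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(mode = c("soft", "hard"),
                             rule = c("universal", "fixed"),
                             fixed_value = NULL,
                             sigma_estimator = c("mad_finest", "per_level_mad")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  sigma_estimator <- match.arg(sigma_estimator)
  if (rule == "fixed") {
    if (is.null(fixed_value) || fixed_value < 0) {
      stopf("rule='fixed' requires fixed_value >= 0")
    }
  } else if (!is.null(fixed_value)) {
    stopf("fixed_value is only meaningful with rule='fixed'")
  }
  structure(list(mode = mode, rule = rule, fixed_value = fixed_value,
                 sigma_estimator = sigma_estimator),
            class = "threshold_policy")
}

.shrink <- function(d, t, mode) {
  if (mode == "hard") d * (abs(d) > t) else sign(d) * pmax(abs(d) - t, 0)
}

#' Threshold the detail bands of a wavelet decomposition
#'
#' Applies hard or soft thresholding to every detail band; the
#' approximation band is never thresholded. Under the universal rule the
#' threshold is `sigma * sqrt(2 log N)` with N the original signal
#' length and sigma estimated by [estimate_sigma()] from the finest band
#' (or per band, per the policy).
#'
#' @param coeffs A `wavelet_coeffs` object.
#' @param policy A [threshold_policy()].
#' @return A new `wavelet_coeffs` object with shrunk details.
#' @export
apply_threshold <- function(coeffs, policy) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"),
            inherits(policy, "threshold_policy"))
  out <- coeffs
  n <- coeffs$original_length
  if (policy$rule == "fixed") {
    t_global <- policy$fixed_value
  } else {
    sigma <- estimate_sigma(coeffs$details[[1]])
    t_global <- sigma * sqrt(2 * log(n))
  }
  for (j in seq_len(coeffs$levels)) {
    t_j <- t_global
    if (policy$rule == "universal" && policy$sigma_estimator == "per_level_mad") {
      t_j <- estimate_sigma(coeffs$details[[j]]) * sqrt(2 * log(n))
    }
    out$details[[j]] <- .shrink(coeffs$details[[j]], t_j, policy$mode)
  }
  out
}

#' Wavelet-shrinkage denoising of an audio signal
#'
#' Decompose with db1 to `levels` scales, threshold the detail bands,
#' reconstruct. Because thresholding only shrinks coefficients of an
#' orthonormal transform, output energy never exceeds input energy.
#'
#' @param signal Numeric vector (or an [audio_clip()], whose samples are
#'   replaced).
#' @param wavelet Only `"db1"`.
#' @param levels Depth J; default 4, capped at the maximum the signal
#'   length permits.
#' @param policy A [threshold_policy()]; default soft universal
#'   thresholding with MAD sigma from the finest band.
#' @return Denoised signal of the same length (or an [audio_clip()] if
#'   one was given).
#' @export
dwt_denoise <- function(signal, wavelet = "db1", levels = 4L,
                        policy = threshold_policy()) {
  clip_in <- inherits(signal, "audio_clip")
  x <- if (clip_in) signal$samples else as.numeric(signal)
  if (all(x == 0)) return(signal)
  levels <- min(as.integer(levels), floor(log2(length(x))))
  cf <- dwt_decompose(x, wavelet = wavelet, levels = levels)
  y <- dwt_reconstruct(apply_threshold(cf, policy))
  if (clip_in) {
    audio_clip(y, signal$sample_rate, label = signal$label, seed = signal$seed)
  } else {
    y
  }
}
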