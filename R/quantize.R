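# Deployment-readiness transforms: simulated ("fake") int8 quantization
# and unstructured magnitude pruning. Simulated quantization rounds
# through the int8 grid and dequantizes, so accuracy-after-quantization
# is measured without integer kernels.

.fake_quant_affine <- function(A, scale, zero_point) {
  q <- pmin(pmax(round(A / scale) + zero_point, -128), 127)
  (q - zero_point) * scale
}

#' int8 quantization scheme
#'
#' Weights: symmetric per-tensor, scale only, range [-127, 127].
#' Activations: affine per-tensor (scale + zero point) over [-128, 127],
#' calibrated from observed min/max.
#'
#' @param bit_width Only 8 is supported.
#' @return A `quant_scheme` list.
#' @export
quant_scheme <- function(bit_width = 8L) {
  if (bit_width != 8L) stopf("only 8-bit quantization is supported")
  structure(list(bit_width = 8L, weight_mode = "symmetric_per_tensor",
                 activation_mode = "affine_per_tensor"),
            class = "quant_scheme")
}

#' Post-training int8 quantization
#'
#' Weight tensors are quantized per-tensor symmetrically
#' (`q = clamp(round(w/s), -127, 127)`, `s = max|w|/127`, with `s = 1`
#' guarding all-zero tensors) and dequantized for simulated inference.
#' Activation ranges are calibrated as the min/max of each block output
#' over the calibration clips, and inference fake-quantizes activations
#' through the affine int8 grid. If an evaluation set is supplied, a
#' before/after metric report is computed via the evaluation module.
#'
#' @param model A trained `cnn_model`.
#' @param calibration_features Nonempty list of feature matrices used to
#'   calibrate activation ranges.
#' @param scheme A [quant_scheme()].
#' @param eval_features,eval_labels Optional evaluation set for the
#'   accuracy report.
#' @return List with `model` (quantized `cnn_model`), `weight_scales`,
#'   and `report` (data frame `metric, before, after, delta`, or NULL).
#' @export
quantize_ptq <- function(model, calibration_features, scheme = quant_scheme(),
                         eval_features = NULL, eval_labels = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(scheme, "quant_scheme"))
  if (length(calibration_features) == 0) stopf("empty calibration set")
  qm <- model
  scales <- list()
  for (k in names(qm$params)) {
    if (!grepl("_W$", k)) next  # biases stay in float, standard int8 practice
    w <- qm$params[[k]]
    s <- max(abs(w)) / 127
    if (s == 0) s <- 1
    qm$params[[k]] <- pmin(pmax(round(w / s), -127), 127) * s
    scales[[k]] <- s
  }
  Xc <- .stack_features(calibration_features, model$norm)
  rng <- .forward(qm, Xc, training = FALSE, collect_ranges = TRUE)$ranges
  qm$act_quant <- lapply(rng, function(r) {
    s <- (r[2] - r[1]) / 255
    if (s <= 0) s <- 1
    zp <- round(-128 - r[1] / s)
    list(scale = s, zero_point = zp)
  })
  report <- NULL
  if (!is.null(eval_features)) {
    stopifnot(!is.null(eval_labels))
    before <- .model_eval_metrics(model, eval_features, eval_labels)
    after <- .model_eval_metrics(qm, eval_features, eval_labels)
    report <- data.frame(metric = names(before),
                         before = unlist(before), after = unlist(after),
                         delta = unlist(after) - unlist(before),
                         row.names = NULL)
  }
  list(model = qm, weight_scales = scales, report = report)
}

#' Unstructured magnitude pruning
#'
#' Zeroes the smallest-magnitude fraction `sparsity` of each weight
#' tensor (per layer, biases untouched). Realized per-layer sparsity is
#' `floor(sparsity * n)/n`, within `1/n` of the request.
#'
#' @param model A trained `cnn_model`.
#' @param sparsity Fraction in [0, 1).
#' @param eval_features,eval_labels Optional evaluation set for a
#'   before/after metric report.
#' @return List with `model` (pruned), `realized_sparsity`, and `report`.
#' @export
prune_magnitude <- function(model, sparsity,
                            eval_features = NULL, eval_labels = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (sparsity < 0 || sparsity >= 1) stopf("sparsity must be in [0, 1)")
  pm <- model
  zeroed <- 0; total <- 0
  for (k in names(pm$params)) {
    if (!grepl("_W$", k)) next
    w <- pm$params[[k]]
    n <- length(w)
    kz <- floor(sparsity * n)
    if (kz > 0) {
      idx <- order(abs(w))[seq_len(kz)]  # exact count, ties broken by order
      w[idx] <- 0
      pm$params[[k]] <- w
    }
    zeroed <- zeroed + kz
    total <- total + n
  }
  report <- NULL
  if (!is.null(eval_features)) {
    stopifnot(!is.null(eval_labels))
    before <- .model_eval_metrics(model, eval_features, eval_labels)
    after <- .model_eval_metrics(pm, eval_features, eval_labels)
    report <- data.frame(metric = names(before),
                         before = unlist(before), after = unlist(after),
                         delta = unlist(after) - unlist(before),
                         row.names = NULL)
  }
  list(model = pm, realized_sparsity = zeroed / total, report = report)
}

# accuracy/macro-F1 via the evaluation module (never reimplemented here)
.model_eval_metrics <- function(model, features, labels) {
  pr <- predict_model(model, features)
  cm <- build_confusion(labels, pr$labels, model$classes)
  m <- class_metrics(cm)
  list(accuracy = m$overall$accuracy, macro_f1 = m$overall$macro_f1)
}
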