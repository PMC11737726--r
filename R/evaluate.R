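#' Build a confusion matrix
#'
#' Counts with actual classes in rows and predicted classes in columns,
#' in the order given by `class_order`.
#'
#' @param labels Actual class codes.
#' @param predictions Predicted class codes (same length).
#' @param class_order Class codes fixing row/column order (default
#'   C1..C6).
#' @return Integer matrix with `dimnames` = (actual, predicted) and
#'   class `confusion_matrix`.
#' @export
build_confusion <- function(labels, predictions,
                            class_order = unname(vocal_classes())) {
  if (length(labels) != length(predictions)) {
    stopf("labels and predictions differ in length")
  }
  bad <- setdiff(unique(c(labels, predictions)), class_order)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  la <- factor(labels, levels = class_order)
  pr <- factor(predictions, levels = class_order)
  cm <- table(actual = la, predicted = pr)
  m <- matrix(as.integer(cm), nrow = length(class_order),
              dimnames = list(actual = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class and aggregate classification metrics
#'
#' One-vs-rest metrics per class i:
#' `TP = cm[i,i]`, `FN = rowsum_i - TP`, `FP = colsum_i - TP`,
#' `TN = total - TP - FN - FP`, then precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and false positive rate
#' `FP/(FP+TN)`. A zero denominator yields 0 with the class flagged in
#' `degenerate`. Aggregates: micro accuracy `trace/total` and unweighted
#' macro precision/recall/F1.
#'
#' @param cm A `confusion_matrix` (any square count matrix works).
#' @return List with `per_class` (data frame: class, precision, recall,
#'   f1, fpr, support), `overall` (accuracy, macro_precision,
#'   macro_recall, macro_f1), and `degenerate` (character vector of
#'   flagged classes).
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  degenerate <- character()
  safe_div <- function(num, den, cls) {
    if (den == 0) {
      degenerate <<- union(degenerate, cls)
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    p <- safe_div(tp, tp + fp, classes[i])
    r <- safe_div(tp, tp + fn, classes[i])
    f1 <- if (p + r == 0) {
      degenerate <<- union(degenerate, classes[i]); 0
    } else 2 * p * r / (p + r)
    fpr <- safe_div(fp, fp + tn, classes[i])
    data.frame(class = classes[i], precision = p, recall = r, f1 = f1,
               fpr = fpr, support = sum(cm[i, ]))
  })
  per_class <- do.call(rbind, rows)
  overall <- list(
    accuracy = if (total > 0) sum(diag(cm)) / total else 0,
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1))
  list(per_class = per_class, overall = overall, degenerate = degenerate)
}

# round half away from zero, the convention of the reference tables
round_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compare computed metrics against a reference metric table
#'
#' Computed values are rounded half away from zero to 3 decimals and
#' compared cellwise against the reference; a cell passes when the
#' absolute difference is at most `tolerance`.
#'
#' @param computed Data frame with `class` plus metric columns (as from
#'   `class_metrics()$per_class`).
#' @param reference Data frame in the same layout; only metric columns
#'   present in both are compared.
#' @param tolerance Per-cell tolerance after rounding (default 5e-4).
#' @return Data frame with one row per (class, metric): computed,
#'   reference, difference, and a logical `pass`.
#' @export
compare_to_reference <- function(computed, reference, tolerance = 5e-4) {
  stopifnot("class" %in% names(computed), "class" %in% names(reference))
  metrics <- intersect(setdiff(names(reference), c("class", "support")),
                       names(computed))
  if (!setequal(computed$class, reference$class)) {
    stopf("class sets differ between computed and reference")
  }
  out <- list()
  for (m in metrics) {
    for (cl in reference$class) {
      cv <- round_away(computed[[m]][computed$class == cl], 3)
      rv <- reference[[m]][reference$class == cl]
      out[[length(out) + 1L]] <- data.frame(
        class = cl, metric = m, computed = cv, reference = rv,
        diff = cv - rv, pass = abs(cv - rv) <= tolerance)
    }
  }
  do.call(rbind, out)
}

#' Write / read a confusion matrix as CSV
#'
#' CSV with a `class` column of actual-class codes and one column per
#' predicted class.
#'
#' @param cm A `confusion_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (`write_confusion`); a `confusion_matrix`
#'   (`read_confusion`).
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(class = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = df$class, predicted = colnames(df)[-1])
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}
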