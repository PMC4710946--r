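#' Gather classifier features from significant voxels
#'
#' One row per subject, one column per voxel in the significance mask, in
#' column-major voxel order (the package-wide fixed ordering; linear voxel
#' indices are attached as attribute `"voxel_index"`). Several maps per
#' subject (e.g. FCS plus two seed maps) can be concatenated by calling this
#' per map family and `cbind`-ing the results.
#'
#' @param maps List of per-subject maps ([compute_fcs()], [seed_fc_map()] or
#'   3D arrays).
#' @param significant_voxel_mask Non-empty 3D logical array.
#' @return subjects x voxels numeric matrix.
#' @export
extract_features <- function(maps, significant_voxel_mask) {
  .assert(sum(significant_voxel_mask) >= 1L, "significance mask is empty")
  X <- .stack_maps(maps, significant_voxel_mask)
  out <- matrix(X, nrow = nrow(X))
  attr(out, "voxel_index") <- attr(X, "voxel_index")
  out
}

#' Confusion-matrix performance metrics
#'
#' Exact ratios: accuracy = (TP + TN) / (TP + FN + TN + FP),
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), where TP/FN
#' count positive-class (converter) subjects predicted right/wrong and TN/FP
#' count negative-class (nonconverter) subjects predicted right/wrong.
#'
#' @param counts Named list or vector with tp, fn, tn, fp (nonnegative
#'   integers, total > 0).
#' @return List: `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(list(tp = 18, fn = 3, tn = 7, fp = 3))
confusion_metrics <- function(counts) {
  counts <- as.list(counts)
  v <- unlist(counts[c("tp", "fn", "tn", "fp")])
  .assert(all(!is.na(v)) && all(v >= 0), "counts must name nonnegative tp, fn, tn, fp")
  total <- sum(v)
  .assert(total > 0, "empty confusion matrix")
  .assert(counts$tp + counts$fn > 0, "no positive-class subjects: sensitivity undefined")
  .assert(counts$tn + counts$fp > 0, "no negative-class subjects: specificity undefined")
  list(accuracy = (counts$tp + counts$tn) / total,
       sensitivity = counts$tp / (counts$tp + counts$fn),
       specificity = counts$tn / (counts$tn + counts$fp))
}

#' Leave-one-out cross-validated SVM classification
#'
#' For each subject, the SVM is trained on the remaining N - 1 subjects and
#' predicts the held-out one. Feature standardization (z-score per feature)
#' is fit on each training fold only and applied to the held-out subject, so
#' no test information leaks into training. The procedure is deterministic
#' for fixed inputs.
#'
#' @param features subjects x features numeric matrix.
#' @param labels Factor or character vector; exactly two classes, each with
#'   >= 2 subjects.
#' @param positive Label of the positive class (default `"converter"` if
#'   present, else the first level).
#' @param kernel SVM kernel, default `"linear"`.
#' @param cost Soft-margin cost C, default 1.
#' @param balanced Use inverse-frequency class weights (default FALSE: no
#'   reweighting).
#' @return List of class `classification_result`: `predicted` (per-subject
#'   labels), `confusion` (list tp, fn, tn, fp), `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
loocv_svm <- function(features, labels, positive = NULL, kernel = "linear",
                      cost = 1, balanced = FALSE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  .assert(length(classes) == 2L, "exactly two classes required")
  .assert(all(table(labels) >= 2L), "each class needs at least 2 subjects")
  .assert(nrow(features) == length(labels), "one label per feature row required")
  positive <- positive %||% if ("converter" %in% classes) "converter" else classes[1]
  .assert(positive %in% classes, "`positive` is not one of the labels")
  n <- nrow(features)
  predicted <- character(n)
  wts <- if (balanced) {
    tb <- table(labels)
    stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  } else NULL
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- factor(labels[-i], levels = classes)
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    tr_z <- sweep(sweep(tr_x, 2, mu, "-"), 2, sdv, "/")
    te_z <- (features[i, ] - mu) / sdv
    fit <- e1071::svm(tr_z, tr_y, kernel = kernel, cost = cost,
                      scale = FALSE, class.weights = wts)
    predicted[i] <- as.character(stats::predict(fit, matrix(te_z, nrow = 1)))
  }
  is_pos <- labels == positive
  pred_pos <- predicted == positive
  confusion <- list(tp = sum(is_pos & pred_pos), fn = sum(is_pos & !pred_pos),
                    tn = sum(!is_pos & !pred_pos), fp = sum(!is_pos & pred_pos))
  metrics <- confusion_metrics(confusion)
  structure(c(list(predicted = predicted, confusion = confusion,
                   positive = positive), metrics),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(paste0("<classification_result> accuracy %.1f%%, sensitivity ",
                     "%.1f%%, specificity %.1f%% (tp %d, fn %d, tn %d, fp %d)\n"),
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$confusion$tp, x$confusion$fn, x$confusion$tn, x$confusion$fp))
  invisible(x)
}
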