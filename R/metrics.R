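#' Confusion counts between a truth and a predicted mask
#'
#' @param truth,pred integer matrices of identical shape with class indices
#'   in `0:(n_classes - 1)`.
#' @param n_classes number of classes (2 for background/aperture).
#' @return an `n_classes` x `n_classes` integer matrix of class
#'   `confusion_counts`; rows index the true class, columns the prediction.
#' @export
confusion <- function(truth, pred, n_classes = 2L) {
  if (!all(dim(truth) == dim(pred))) stop("mask shape mismatch")
  cls <- 0:(n_classes - 1L)
  if (!all(truth %in% cls) || !all(pred %in% cls)) {
    stop("mask values outside the class index range")
  }
  counts <- matrix(tabulate(as.integer(truth) * n_classes +
                              as.integer(pred) + 1L,
                            nbins = n_classes * n_classes),
                   nrow = n_classes, byrow = TRUE)
  dimnames(counts) <- list(truth = cls, pred = cls)
  structure(counts, class = c("confusion_counts", "matrix"))
}

#' Segmentation metrics from confusion counts
#'
#' Computes pixel accuracy (PA), per-class pixel accuracy (CPA), mean pixel
#' accuracy (MPA = mean of CPA), per-class intersection-over-union (IoU) and
#' mean IoU (MIoU = mean of IoU). A class absent from the ground truth has an
#' undefined CPA (and an empty-union class an undefined IoU); such classes
#' are reported as `NA` and excluded from the means.
#'
#' @param counts a `confusion_counts` matrix (true class in rows).
#' @return a `metrics_report` list: `pa`, `cpa`, `mpa`, `iou`, `miou`,
#'   `total`.
#' @export
compute_metrics <- function(counts) {
  counts <- unclass(counts)
  total <- sum(counts)
  if (total <= 0) stop("empty confusion counts")
  diagc <- diag(counts)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  cpa <- ifelse(row_tot > 0, diagc / row_tot, NA_real_)
  union <- row_tot + col_tot - diagc
  iou <- ifelse(union > 0, diagc / union, NA_real_)
  structure(list(pa = sum(diagc) / total,
                 cpa = cpa,
                 mpa = mean(cpa, na.rm = TRUE),
                 iou = iou,
                 miou = mean(iou, na.rm = TRUE),
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PA %.4f  MPA %.4f  MIoU %.4f  (n = %d px)\n",
              x$pa, x$mpa, x$miou, x$total))
  cat("  CPA:", paste(sprintf("%.4f", x$cpa), collapse = " "), "\n")
  cat("  IoU:", paste(sprintf("%.4f", x$iou), collapse = " "), "\n")
  invisible(x)
}

#' Micro-aggregated metrics over a test set
#'
#' Pools the confusion counts of all items (micro-aggregation: every pixel
#' counts once, matching the "ratio of correct pixel count to total pixel
#' count" definitions) and computes one report.
#'
#' @param items list of `confusion_counts`, or of `list(truth =, pred =)`
#'   mask pairs.
#' @param n_classes number of classes when mask pairs are given.
#' @return a `metrics_report`.
#' @export
aggregate_metrics <- function(items, n_classes = 2L) {
  if (length(items) == 0) stop("empty evaluation set")
  counts <- lapply(items, function(it) {
    if (inherits(it, "confusion_counts")) unclass(it)
    else unclass(confusion(it$truth, it$pred, n_classes))
  })
  compute_metrics(structure(Reduce(`+`, counts),
                            class = c("confusion_counts", "matrix")))
}
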