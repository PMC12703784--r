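# Pixel-level segmentation metrics: per-class IoU and its mean, micro
# precision/recall/F1 over foreground classes, and the merged weed IoU used
# to judge weeding-operation relevance. All counts are accumulated from a
# full K x K confusion matrix so class-merging metrics are exact.

#' Class table for a segmentation task
#'
#' @param names character vector of class names, in id order starting at 0.
#' @param roles character vector of the same length, each one of
#'   `"background"`, `"crop"`, `"weed"`. Exactly one background class is
#'   required.
#' @return A data frame with columns `id`, `name`, `role`, of class
#'   `"class_map"`.
#' @examples
#' paddy_class_map(2)
#' @export
class_map <- function(names, roles) {
  roles <- match.arg(roles, c("background", "crop", "weed"),
                     several.ok = TRUE)
  if (length(names) != length(roles))
    stop("`names` and `roles` must have equal length", call. = FALSE)
  if (sum(roles == "background") != 1L)
    stop("exactly one background class is required", call. = FALSE)
  structure(data.frame(id = seq_along(names) - 1L, name = names,
                       role = roles, stringsAsFactors = FALSE),
            class = c("class_map", "data.frame"))
}

#' Default class table: background, one crop, `n_weeds` weed classes
#' @param n_weeds number of weed classes (>= 1).
#' @rdname class_map
#' @export
paddy_class_map <- function(n_weeds = 2L) {
  class_map(c("background", "crop", paste0("weed_", seq_len(n_weeds))),
            c("background", "crop", rep("weed", n_weeds)))
}

#' Pixel confusion counts between predicted and true label masks
#'
#' Pixels whose ground-truth label is the ignore value (255) are excluded.
#' Counts accumulate over the full confusion matrix, so
#' `sum(TP + FN) = number of evaluated pixels`.
#'
#' @param pred,gt integer label masks of identical shape (matrices or
#'   arrays); values in `0 .. n_classes - 1`, plus 255 in `gt` for ignore.
#' @param n_classes number of classes K.
#' @return An object of class `"confusion_counts"`: the `K x K` matrix
#'   `conf` (rows = truth, cols = prediction) and vectors `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, gt, n_classes) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("`pred` and `gt` must have identical shapes", call. = FALSE)
  K <- as.integer(n_classes)
  p <- as.integer(pred); g <- as.integer(gt)
  keep <- g != 255L
  p <- p[keep]; g <- g[keep]
  if (length(p) && (any(p < 0L | p >= K) || any(g < 0L | g >= K)))
    stop(sprintf("labels outside 0..%d encountered", K - 1L), call. = FALSE)
  conf <- matrix(tabulate(g * K + p + 1L, nbins = K * K), K, K, byrow = TRUE)
  tp <- diag(conf)
  new_confusion(conf, tp, colSums(conf) - tp, rowSums(conf) - tp, K)
}

new_confusion <- function(conf, tp, fp, fn, K) {
  structure(list(conf = conf, tp = tp, fp = fp, fn = fn, n_classes = K),
            class = "confusion_counts")
}

#' Accumulate confusion counts
#' @param a,b `"confusion_counts"` objects over the same classes.
#' @rdname confusion_counts
#' @export
add_confusion <- function(a, b) {
  stopifnot(inherits(a, "confusion_counts"), inherits(b, "confusion_counts"),
            a$n_classes == b$n_classes)
  conf <- a$conf + b$conf
  tp <- diag(conf)
  new_confusion(conf, tp, colSums(conf) - tp, rowSums(conf) - tp,
                a$n_classes)
}

#' Mean intersection over union
#'
#' Mean over classes of `TP_c / (TP_c + FP_c + FN_c)`, in percent. Classes
#' absent from both prediction and ground truth are excluded from the mean;
#' small evaluations would otherwise be distorted by arbitrary 0/0
#' conventions. The background class participates unless
#' `exclude_background` is set.
#'
#' @param counts a [confusion_counts()] object.
#' @param exclude_background drop class id `background_id` from the mean.
#' @param background_id id of the background class. Default 0.
#' @return Percentage in `[0, 100]`.
#' @export
miou <- function(counts, exclude_background = FALSE, background_id = 0L) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fp + counts$fn
  use <- denom > 0
  if (exclude_background) use[background_id + 1L] <- FALSE
  if (!any(use))
    stop("no class is present in either prediction or ground truth",
         call. = FALSE)
  100 * mean(counts$tp[use] / denom[use])
}

#' Micro-averaged precision, recall and F1 over foreground classes
#'
#' Counts are pooled over every non-background class before the ratios:
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1` their harmonic mean.
#' A zero denominator defines the affected metric as 0 with a warning.
#'
#' @param counts a [confusion_counts()] object.
#' @param background_id id of the background class excluded from pooling.
#' @return Named numeric vector `c(precision, recall, f1)` in percent.
#' @export
micro_prf <- function(counts, background_id = 0L) {
  stopifnot(inherits(counts, "confusion_counts"))
  fg <- setdiff(seq_len(counts$n_classes), background_id + 1L)
  TP <- sum(counts$tp[fg]); FP <- sum(counts$fp[fg]); FN <- sum(counts$fn[fg])
  P <- if (TP + FP > 0) TP / (TP + FP) else {
    warning("no predicted foreground pixels; precision defined as 0")
    0
  }
  R <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("no true foreground pixels; recall defined as 0")
    0
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = 100 * P, recall = 100 * R, f1 = 100 * F1)
}

#' IoU of all weed classes merged into one category
#'
#' Weed classes are merged before counting -- equivalently, the rows and
#' columns of the confusion matrix belonging to weed classes are pooled --
#' so a pixel of one weed species predicted as another weed species counts
#' as a true positive of the merged category.
#'
#' @param counts a [confusion_counts()] object.
#' @param cmap a [class_map()] with at least one `"weed"` role.
#' @return Percentage in `[0, 100]`.
#' @export
weed_iou <- function(counts, cmap) {
  stopifnot(inherits(counts, "confusion_counts"), inherits(cmap, "class_map"))
  weed <- cmap$id[cmap$role == "weed"] + 1L
  if (!length(weed)) stop("no class has the weed role", call. = FALSE)
  conf <- counts$conf
  TP <- sum(conf[weed, weed, drop = FALSE])
  FP <- sum(conf[-weed, weed, drop = FALSE])
  FN <- sum(conf[weed, -weed, drop = FALSE])
  if (TP + FP + FN == 0) return(NA_real_)
  100 * TP / (TP + FP + FN)
}

#' Full metrics report from accumulated confusion counts
#'
#' @param counts a [confusion_counts()] object.
#' @param cmap a [class_map()] describing the classes.
#' @return An object of class `"metrics_report"`: per-class IoU, mIoU with
#'   and without background, micro precision/recall/F1, and the merged weed
#'   IoU, all in percent.
#' @export
metrics_report <- function(counts, cmap) {
  stopifnot(inherits(counts, "confusion_counts"), inherits(cmap, "class_map"))
  denom <- counts$tp + counts$fp + counts$fn
  per_class <- ifelse(denom > 0, 100 * counts$tp / denom, NA_real_)
  names(per_class) <- cmap$name
  prf <- suppressWarnings(micro_prf(counts))
  structure(list(
    per_class_iou = per_class,
    miou = miou(counts),
    miou_foreground = miou(counts, exclude_background = TRUE),
    precision = unname(prf["precision"]),
    recall = unname(prf["recall"]),
    f1 = unname(prf["f1"]),
    weed_iou = weed_iou(counts, cmap),
    counts = counts, class_map = cmap
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("Segmentation metrics (pixel level, %)\n")
  cat(sprintf("  mIoU (all classes):  %.*f\n", digits, x$miou))
  cat(sprintf("  mIoU (foreground):   %.*f\n", digits, x$miou_foreground))
  cat(sprintf("  Precision / Recall / F1 (micro, foreground): %.*f / %.*f / %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f1))
  cat(sprintf("  Weed IoU (merged):   %.*f\n", digits, x$weed_iou))
  cat("  Per-class IoU:\n")
  for (i in seq_along(x$per_class_iou))
    cat(sprintf("    %-12s %s\n", names(x$per_class_iou)[i],
                ifelse(is.na(x$per_class_iou[i]), "absent",
                       sprintf("%.*f", digits, x$per_class_iou[i]))))
  invisible(x)
}

#' Write a metrics report as TSV and JSON
#'
#' The TSV holds the per-class breakdown plus the summary rows; the JSON
#' mirrors the report's numeric fields.
#'
#' @param report a `"metrics_report"` object.
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the report.
#' @export
write_metrics_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(tsv_path)) {
    df <- data.frame(
      metric = c(paste0("iou_", names(report$per_class_iou)),
                 "miou", "miou_foreground", "precision", "recall", "f1",
                 "weed_iou"),
      value = c(report$per_class_iou, report$miou, report$miou_foreground,
                report$precision, report$recall, report$f1, report$weed_iou))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_class_iou = as.list(report$per_class_iou),
           miou = report$miou, miou_foreground = report$miou_foreground,
           precision = report$precision, recall = report$recall,
           f1 = report$f1, weed_iou = report$weed_iou),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
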