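#' @name boxes
#' @title Bounding-box tables
#' @description Ground truth and detections are plain data frames of
#' axis-aligned boxes in 0-based half-open pixel coordinates
#' (`[xmin, xmax) x [ymin, ymax)`, so width is `xmax - xmin`). Ground-truth
#' tables carry `image_id`, `class`, `xmin`, `ymin`, `xmax`, `ymax`;
#' detection tables additionally carry `confidence` in `[0, 1]`. Conversion
#' from the 1-based inclusive Pascal VOC convention is done by
#' [voc_to_internal()].
NULL

gt_columns <- c("image_id", "class", "xmin", "ymin", "xmax", "ymax")
det_columns <- c(gt_columns, "confidence")

check_boxes <- function(df, what = c("gt", "det")) {
  what <- match.arg(what)
  need <- if (what == "det") det_columns else gt_columns
  if (!all(need %in% names(df))) {
    stop("box table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(df$xmax <= df$xmin) || any(df$ymax <= df$ymin)) {
      stop("degenerate box: xmax must exceed xmin and ymax exceed ymin")
    }
    if (what == "det" && (any(df$confidence < 0) || any(df$confidence > 1))) {
      stop("confidence must lie in [0, 1]")
    }
  }
  invisible(df)
}

#' Intersection-over-union between two sets of boxes
#'
#' @param a,b box tables (or any data frames with `xmin`, `ymin`, `xmax`,
#'   `ymax` in half-open coordinates).
#' @return An `nrow(a)` by `nrow(b)` matrix of IoU values in `[0, 1]`; 0 for
#'   disjoint boxes.
#' @examples
#' b1 <- data.frame(xmin = 0, ymin = 0, xmax = 10, ymax = 10)
#' b2 <- data.frame(xmin = 5, ymin = 5, xmax = 15, ymax = 15)
#' box_iou(b1, b2) # 25 / 175
#' @export
box_iou <- function(a, b) {
  for (df in list(a, b)) {
    if (nrow(df) && (any(df$xmax <= df$xmin) || any(df$ymax <= df$ymin))) {
      stop("degenerate box passed to box_iou")
    }
  }
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (!n || !m) return(out)
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  un <- outer(area_a, area_b, `+`) - inter
  out[] <- ifelse(un > 0, inter / un, 0)
  out
}

#' Greedily match single-class detections to ground truth
#'
#' Detections are processed in descending confidence (ties keep input
#' order). Each detection claims its best-IoU ground-truth box on the same
#' image provided the IoU reaches the threshold and that ground truth is
#' still unmatched (IoU ties go to the lowest ground-truth index); it is
#' then a true positive, otherwise a false positive. Matching never crosses
#' image boundaries.
#'
#' @param det detection table for one class (may span several images).
#' @param gt ground-truth table for the same class.
#' @param iou_threshold minimum IoU for a match (0.5 by default).
#' @return A list: `detections` (the detections sorted in match order with
#'   logical column `tp`), `n_gt`, and `fn_by_image` (unmatched ground-truth
#'   counts per image).
#' @export
match_detections <- function(det, gt, iou_threshold = 0.5) {
  check_boxes(det, "det")
  check_boxes(gt, "gt")
  ord <- order(-det$confidence)
  det <- det[ord, , drop = FALSE]
  n_gt <- nrow(gt)
  matched <- logical(n_gt)
  tp <- logical(nrow(det))
  if (nrow(det) && n_gt) {
    iou_all <- box_iou(det, gt)
    same_img <- outer(as.character(det$image_id),
                      as.character(gt$image_id), `==`)
    iou_all[!same_img] <- 0
    for (i in seq_len(nrow(det))) {
      cand <- which(!matched & iou_all[i, ] >= iou_threshold)
      if (length(cand)) {
        best <- cand[which.max(iou_all[i, cand])]
        matched[best] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  det$tp <- tp
  fn_by_image <- if (n_gt) {
    tapply(!matched, as.character(gt$image_id), sum)
  } else integer(0)
  list(detections = det, n_gt = n_gt,
       fn_by_image = fn_by_image)
}

#' Cumulative precision-recall curve from ordered match flags
#'
#' @param tp logical vector of true-positive flags in descending-confidence
#'   order (as produced by [match_detections()]).
#' @param n_gt number of ground-truth positives.
#' @return A `pr_curve` data frame with cumulative `tp`, `fp`, `precision`
#'   and `recall`, plus attribute `n_gt`.
#' @export
pr_curve <- function(tp, n_gt) {
  tp_cum <- cumsum(tp)
  fp_cum <- cumsum(!tp)
  out <- data.frame(
    tp = tp_cum, fp = fp_cum,
    precision = if (length(tp)) tp_cum / (tp_cum + fp_cum) else numeric(0),
    recall = if (n_gt > 0) tp_cum / n_gt else rep(NaN, length(tp))
  )
  attr(out, "n_gt") <- n_gt
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Average precision from ordered match flags
#'
#' Computes the area under the precision-recall curve after applying the
#' monotone precision envelope (precision at recall r is replaced by the
#' maximum precision at any recall >= r), integrating exactly over all
#' recall points. The classic 11-point interpolation (mean of enveloped
#' precision sampled at recall 0, 0.1, ..., 1) is available for sensitivity
#' checks.
#'
#' @param tp logical true-positive flags in descending-confidence order.
#' @param n_gt number of ground-truth positives; when 0 the AP is undefined
#'   and `NA` is returned.
#' @param method `"envelope"` (exact area, default) or `"elevenpoint"`.
#' @return AP in `[0, 1]`, or `NA_real_` when `n_gt == 0`.
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), n_gt = 2) # 0.8333
#' @export
average_precision <- function(tp, n_gt, method = c("envelope", "elevenpoint")) {
  method <- match.arg(method)
  if (n_gt == 0) return(NA_real_)
  if (!length(tp) || !any(tp)) return(0)
  curve <- pr_curve(tp, n_gt)
  mrec <- c(0, curve$recall)
  mpre <- c(0, curve$precision)
  # monotone envelope, right to left
  for (i in rev(seq_len(length(mpre) - 1L))) {
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  }
  if (method == "envelope") {
    sum(diff(mrec) * mpre[-1L])
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- mrec >= r
      if (any(ok)) max(mpre[ok]) else 0
    }, numeric(1)))
  }
}

#' Mean average precision over classes
#'
#' @param aps named or unnamed numeric vector of per-class APs; `NA` entries
#'   (classes with no ground truth) are excluded.
#' @return The unweighted mean of the defined APs.
#' @examples
#' mean_ap(c(WBC = 0.9766, RBC = 0.7627, Platelets = 0.5895)) # 0.7763
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  if (!length(aps)) stop("no class has a defined AP")
  mean(aps)
}

#' Score detections against ground truth: per-class AP and mAP
#'
#' Runs [match_detections()] and [average_precision()] class by class.
#' Classes present only among the detections (no ground truth) get an
#' undefined AP, are excluded from the mAP, and are flagged.
#'
#' @param det detection table (all classes).
#' @param gt ground-truth table.
#' @param iou_threshold IoU matching threshold.
#' @param ap_method passed to [average_precision()].
#' @return A `detection_eval` list: `per_class` data frame (`class`, `n_gt`,
#'   `n_det`, `ap`), `map`, `curves` (per-class [pr_curve()]s),
#'   `undefined_classes`.
#' @export
evaluate_detections <- function(det, gt, iou_threshold = 0.5,
                                ap_method = "envelope") {
  check_boxes(det, "det")
  check_boxes(gt, "gt")
  classes <- sort(unique(c(as.character(det$class), as.character(gt$class))))
  rows <- list(); curves <- list()
  for (cl in classes) {
    d <- det[det$class == cl, , drop = FALSE]
    g <- gt[gt$class == cl, , drop = FALSE]
    m <- match_detections(d, g, iou_threshold)
    ap <- average_precision(m$detections$tp, m$n_gt, method = ap_method)
    curves[[cl]] <- pr_curve(m$detections$tp, m$n_gt)
    rows[[cl]] <- data.frame(class = cl, n_gt = m$n_gt, n_det = nrow(d),
                             ap = ap, stringsAsFactors = FALSE)
  }
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  structure(list(
    per_class = per_class,
    map = mean_ap(per_class$ap),
    curves = curves,
    undefined_classes = per_class$class[is.na(per_class$ap)],
    iou_threshold = iou_threshold
  ), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU threshold %.2f)\n", x$iou_threshold))
  tab <- x$per_class
  tab$ap <- round(tab$ap, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("mAP: %.4f\n", x$map))
  if (length(x$undefined_classes)) {
    cat("Classes without ground truth (excluded from mAP):",
        paste(x$undefined_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-class cell counts and counting accuracy
#'
#' Counting accuracy is `100 * n_detected / n_gt` percent, where
#' `n_detected` is the number of detections at or above the confidence
#' threshold. Accuracy above 100% is reported as-is with an over-count flag
#' (detectors can legitimately find cells the annotations under-label).
#'
#' @param det detection table.
#' @param gt ground-truth table.
#' @param confidence_threshold detections below this confidence are ignored.
#' @return A `count_report` data frame: `class`, `n_gt`, `n_detected`,
#'   `accuracy` (percent, `NA` when a class has no ground truth),
#'   `over_count`, `undefined`.
#' @examples
#' # 57 platelets found out of 75 annotated: 76% counting accuracy
#' @export
count_cells <- function(det, gt, confidence_threshold) {
  stopifnot(length(confidence_threshold) == 1L,
            confidence_threshold >= 0, confidence_threshold <= 1)
  check_boxes(det, "det")
  check_boxes(gt, "gt")
  det <- det[det$confidence >= confidence_threshold, , drop = FALSE]
  classes <- sort(unique(c(as.character(det$class), as.character(gt$class))))
  n_gt <- vapply(classes, function(cl) sum(gt$class == cl), integer(1))
  n_det <- vapply(classes, function(cl) sum(det$class == cl), integer(1))
  acc <- ifelse(n_gt > 0, 100 * n_det / n_gt, NA_real_)
  out <- data.frame(
    class = classes, n_gt = n_gt, n_detected = n_det, accuracy = acc,
    over_count = !is.na(acc) & acc > 100,
    undefined = n_gt == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("count_report", "data.frame")
  out
}

#' Read or write a detection table as delimited text
#'
#' Columns: `image_id`, `class`, `xmin`, `ymin`, `xmax`, `ymax`,
#' `confidence` (0-based half-open coordinates).
#'
#' @param det detection table.
#' @param path file path.
#' @param sep field separator.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns the validated table.
#' @export
write_detections <- function(det, path, sep = "\t") {
  check_boxes(det, "det")
  utils::write.table(det[det_columns], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, sep = "\t") {
  det <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  det$image_id <- as.character(det$image_id)
  check_boxes(det, "det")
  det
}
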