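# Evaluation: one-vs-rest precision/recall/accuracy from a confusion matrix,
# IoU on half-open boxes, per-class average precision by all-point
# precision-recall integration with greedy IoU matching, and mAP at a fixed
# IoU threshold (0.75 by default).

#' Classification metrics from a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Per-class
#' (one-vs-rest) precision `TP/(TP+FP)` and recall `TP/(TP+FN)`; overall
#' accuracy `trace/total`; macro precision/recall are unweighted class means.
#' `0/0` is defined as 0 (with a message) rather than NaN.
#'
#' @param confusion square count matrix (true x predicted).
#' @return list with `per_class` (data.frame of precision/recall per class),
#'   `macro` (precision, recall, accuracy), and the `confusion` matrix.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix entries must be non-negative")
  C <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / pmax(den, 1))
    if (any(den == 0)) {
      message("classification_metrics: 0/0 in ", what,
              " for class(es) ", paste(which(den == 0) - 1, collapse = ", "),
              "; defined as 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  list(
    per_class = data.frame(class = seq_len(C) - 1L, precision = precision,
                           recall = recall, row.names = NULL),
    macro = c(precision = mean(precision), recall = mean(recall),
              accuracy = sum(tp) / sum(confusion)),
    confusion = confusion
  )
}

#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open `(x0, y0, x1, y1)`; disjoint boxes score 0.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Create a detection record
#'
#' @param image_id image identifier.
#' @param class_id predicted class (0-based).
#' @param box `(x0, y0, x1, y1)` box.
#' @param score confidence in `[0, 1]`.
#' @return a `detection` list.
#' @export
detection <- function(image_id, class_id, box, score) {
  if (!(box[1] < box[3] && box[2] < box[4])) {
    stop("malformed detection box (need x0 < x1 and y0 < y1)")
  }
  if (score < 0 || score > 1) stop("score must be in [0, 1]")
  structure(list(image_id = image_id, class_id = as.integer(class_id),
                 box = as.numeric(box), score = score),
            class = "detection")
}

# Greedy matching for one class: detections sorted by score (desc), ties by
# higher IoU to their best ground truth then lexicographic image_id; each
# ground truth is matched at most once. Returns the TP/FP flag sequence.
match_detections <- function(dets, gts, iou_thresh) {
  if (length(dets) == 0) return(logical(0))
  best_iou <- vapply(dets, function(d) {
    cand <- gts[vapply(gts, function(g) g$image_id == d$image_id, logical(1))]
    if (length(cand) == 0) return(0)
    max(vapply(cand, function(g) iou(d$box, g$box), numeric(1)))
  }, numeric(1))
  scores <- vapply(dets, function(d) d$score, numeric(1))
  ids <- vapply(dets, function(d) d$image_id, character(1))
  ord <- order(-scores, -best_iou, ids)
  used <- rep(FALSE, length(gts))
  tp <- logical(length(dets))
  for (k in ord) {
    d <- dets[[k]]
    best <- 0; best_j <- 0L
    for (j in seq_along(gts)) {
      if (used[j] || gts[[j]]$image_id != d$image_id) next
      ov <- iou(d$box, gts[[j]]$box)
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (best_j > 0L && best >= iou_thresh) {
      used[best_j] <- TRUE
      tp[k] <- TRUE
    }
  }
  tp[ord]
}

#' Average precision for one class
#'
#' All-point interpolation of the precision-recall curve: detections are
#' sorted by descending score, greedily matched to ground truths at
#' `iou_thresh`, and the area under the precision envelope is accumulated
#' over recall increments.
#'
#' @param dets list of [detection()]s for one class.
#' @param gts list of ground truths for the same class: each a list with
#'   `image_id` and `box`.
#' @param iou_thresh IoU threshold for a match.
#' @param interpolation `"all"` (all-point envelope integration, the default
#'   and the form matched against the brute-force oracle), or `"11point"` /
#'   `"101point"` (fixed recall grids, for cross-tool comparison).
#' @return AP in `[0, 1]`; `NA` with a warning when there are no ground
#'   truths (the class is then excluded from mAP).
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.75,
                              interpolation = c("all", "11point", "101point")) {
  interpolation <- match.arg(interpolation)
  if (length(gts) == 0) {
    warning("average_precision: no ground truths for class; AP undefined")
    return(NA_real_)
  }
  tp <- match_detections(dets, gts, iou_thresh)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / length(gts)
  # precision envelope (running max from the right)
  env <- rev(cummax(rev(precision)))
  if (interpolation == "all") {
    return(sum(diff(c(0, recall)) * env))
  }
  grid <- seq(0, 1, length.out = if (interpolation == "11point") 11L else 101L)
  mean(vapply(grid, function(t) {
    idx <- which(recall >= t - 1e-12)
    if (length(idx) == 0) 0 else env[idx[1]]
  }, numeric(1)))
}

#' Mean average precision at an IoU threshold
#'
#' Unweighted mean of the per-class APs; classes without ground truths are
#' excluded (with a warning) rather than scored 0.
#'
#' @param dets list of [detection()]s (all classes).
#' @param gts list of ground truths: each a list with `image_id`, `class_id`,
#'   `box`.
#' @param iou_thresh IoU threshold (default 0.75).
#' @param n_classes total number of classes (default 5).
#' @return list with `map` and `per_class` (named AP vector, NA = excluded).
#' @export
map_at <- function(dets, gts, iou_thresh = 0.75, n_classes = 5) {
  ap <- setNames(rep(NA_real_, n_classes), seq_len(n_classes) - 1L)
  for (c in seq_len(n_classes) - 1L) {
    g <- gts[vapply(gts, function(x) x$class_id == c, logical(1))]
    if (length(g) == 0) {
      message("map_at: class ", c, " has no ground truths; excluded from mAP")
      next
    }
    d <- dets[vapply(dets, function(x) x$class_id == c, logical(1))]
    ap[as.character(c)] <- average_precision(d, g, iou_thresh)
  }
  if (all(is.na(ap))) stop("map_at: no class has ground truths")
  list(map = mean(ap, na.rm = TRUE), per_class = ap)
}
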