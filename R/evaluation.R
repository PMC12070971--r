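# COCO-style precision/recall/AP evaluation with occlusion-stratified
# reporting. AP uses the 101-point interpolated area under the
# precision-recall envelope; every report labels the rule used.

#' Match detections of one image against ground truth
#'
#' Greedy matching in descending score order: each detection takes the
#' unmatched ground truth with the highest IoU, and is a true positive iff
#' that IoU reaches `iou_thr`. Each ground truth matches at most once.
#'
#' @param dets List with `boxes` (n x 4) and `scores` (length n).
#' @param gts m x 4 matrix of ground-truth boxes.
#' @param iou_thr Matching threshold.
#' @return List: `tp` (logical per detection, score-sorted order), `scores`
#'   (sorted), `fn` (unmatched ground truths).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  gts <- as_box_matrix(gts)
  nb <- if (is.null(dets$boxes)) 0L else nrow(as_box_matrix(dets$boxes))
  if (nb == 0L)
    return(list(tp = logical(), scores = numeric(), fn = nrow(gts)))
  boxes <- as_box_matrix(dets$boxes)
  ord <- order(dets$scores, decreasing = TRUE)
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nb)
  M <- if (nrow(gts)) iou_mat(boxes, gts) else NULL
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (nrow(gts) == 0L) break
    ious <- M[i, ]
    ious[used] <- -1
    best <- which.max(ious)
    if (length(best) == 1L && ious[best] >= iou_thr) {
      tp[k] <- TRUE
      used[best] <- TRUE
    }
  }
  list(tp = tp, scores = dets$scores[ord], fn = sum(!used))
}

#' Precision-recall curve across a dataset
#'
#' Pools score-sorted matches from all images.
#'
#' @param det_list List of per-image detection sets.
#' @param gt_list List of per-image ground-truth box matrices.
#' @param iou_thr Matching threshold.
#' @return Object of class `pr_curve`: `precision`, `recall` (cumulative,
#'   confidence-sorted), `n_gt`, `iou_threshold`.
#' @export
pr_curve <- function(det_list, gt_list, iou_thr = 0.5) {
  scores <- numeric(); tp <- logical(); n_gt <- 0L
  for (i in seq_along(det_list)) {
    m <- match_detections(det_list[[i]], gt_list[[i]], iou_thr)
    scores <- c(scores, m$scores)
    tp <- c(tp, m$tp)
    n_gt <- n_gt + nrow(as_box_matrix(gt_list[[i]]))
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  structure(list(precision = if (length(tp)) ctp / (ctp + cfp) else numeric(),
                 recall = if (length(tp) && n_gt > 0) ctp / n_gt else numeric(),
                 n_gt = n_gt, iou_threshold = iou_thr,
                 interpolation = "coco-101pt"),
            class = "pr_curve")
}

#' Average precision from a precision-recall curve
#'
#' 101-point interpolation: the precision envelope (running maximum from the
#' right) is sampled at recalls 0, 0.01, ..., 1 and averaged.
#'
#' @param curve A [pr_curve].
#' @return AP in `[0, 1]`; `NaN` when the dataset has no ground truths.
#' @export
average_precision <- function(curve) {
  if (curve$n_gt == 0L) return(NaN)
  if (length(curve$precision) == 0L) return(0)
  rec <- curve$recall; prec <- curve$precision
  env <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(r) {
    i <- which(rec >= r)
    if (length(i)) env[i[1]] else 0
  }, 0)
  mean(vals)
}

#' AP over the COCO threshold range
#'
#' Evaluates IoU thresholds 0.50 to 0.95 in steps of 0.05 and averages.
#'
#' @param det_list,gt_list Per-image detections and ground truths.
#' @return Object of class `ap_result`: `ap50`, `ap75`, `ap_range`,
#'   `per_threshold` (named vector of the ten APs).
#' @export
ap_range <- function(det_list, gt_list) {
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t)
    average_precision(pr_curve(det_list, gt_list, t)), 0)
  names(aps) <- sprintf("ap%g", thrs * 100)
  structure(list(ap50 = aps[["ap50"]], ap75 = aps[["ap75"]],
                 ap_range = mean(aps), per_threshold = aps,
                 interpolation = "coco-101pt"),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("AP50 %.4f  AP75 %.4f  AP50:95 %.4f (%s)\n",
              x$ap50, x$ap75, x$ap_range, x$interpolation))
  invisible(x)
}

#' Full evaluation report with optional occlusion stratification
#'
#' @param det_list,gt_list Per-image detections and ground truths.
#' @param anns Optional list of [annotated_image] used to compute the dense
#'   subset (OR > `or_thr`, objects > `min_objects`).
#' @param or_thr,min_objects Dense-subset thresholds.
#' @return List with the full-set `ap_result` under `all`, the number of
#'   dense images under `n_dense`, and (when any exist) a `dense_subset`
#'   `ap_result` block.
#' @export
evaluate_detections <- function(det_list, gt_list, anns = NULL,
                                or_thr = 0.5, min_objects = 40L) {
  out <- list(all = ap_range(det_list, gt_list))
  if (!is.null(anns)) {
    keep <- vapply(anns, function(a) {
      r <- image_or(a)
      r$image_or > or_thr && r$n_objects > min_objects
    }, TRUE)
    out$n_dense <- sum(keep)
    if (any(keep))
      out$dense_subset <- ap_range(det_list[keep], gt_list[keep])
  }
  out
}
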