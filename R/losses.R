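# Occlusion-aware composite loss: CIoU attraction plus RepGT/RepBox repulsion
# with a smoothed-log penalty. Every term comes with a hand-derived gradient
# w.r.t. the predicted box corners so the training loop needs no autodiff;
# the gradients are validated against finite differences in the test suite.

#' Loss weight configuration
#'
#' @param alpha RepGT weight (default 0.4).
#' @param beta RepBox weight (default 0.6).
#' @param sigma_repgt,sigma_repbox Smooth-ln switch points in `[0, 1)`.
#' @param epsilon Small constant guarding the RepBox denominator.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.4, beta = 0.6,
                         sigma_repgt = 0.5, sigma_repbox = 0.5,
                         epsilon = 1e-7) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  if (sigma_repgt < 0 || sigma_repgt >= 1 || sigma_repbox < 0 || sigma_repbox >= 1)
    stop("sigma values must lie in [0, 1)")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(alpha = alpha, beta = beta, sigma_repgt = sigma_repgt,
                 sigma_repbox = sigma_repbox, epsilon = epsilon),
            class = "loss_weights")
}

#' Smoothed logarithmic penalty
#'
#' `-ln(1 - x)` for `x <= sigma`, linearized with matched value and slope
#' above (`(x - sigma)/(1 - sigma) - ln(1 - sigma)`), so the function is C1 at
#' the switch point.
#'
#' @param x Overlap fraction(s) in `[0, 1)`.
#' @param sigma Switch point in `[0, 1)`.
#' @return Nonnegative penalty, same length as `x`.
#' @export
smooth_ln <- function(x, sigma = 0.5) {
  if (any(x >= 1)) stop("smooth_ln undefined for x >= 1 (infinite repulsion)")
  if (any(x < 0)) stop("smooth_ln requires x >= 0")
  ifelse(x <= sigma, -log(1 - x), (x - sigma) / (1 - sigma) - log(1 - sigma))
}

smooth_ln_grad <- function(x, sigma = 0.5) {
  ifelse(x <= sigma, 1 / (1 - x), 1 / (1 - sigma))
}

# -- vectorized internals -----------------------------------------------------
# Row-aligned vector forms of the box overlap quantities and their gradients;
# these carry the training loop, while the scalar exported functions remain
# the reference implementations.

# Pairwise IoU matrix between two box sets (n x 4, m x 4) -> n x m.
iou_mat <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- outer(A[, 1], B[, 1], pmax); iy1 <- outer(A[, 2], B[, 2], pmax)
  ix2 <- outer(A[, 3], B[, 3], pmin); iy2 <- outer(A[, 4], B[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  u <- outer((A[, 3] - A[, 1]) * (A[, 4] - A[, 2]),
             (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]), `+`) - inter
  ifelse(u > 0, inter / u, 0)
}

# Row-aligned intersection area and gradient w.r.t. the rows of A.
inter_vec <- function(A, B) {
  ix1 <- pmax(A[, 1], B[, 1]); iy1 <- pmax(A[, 2], B[, 2])
  ix2 <- pmin(A[, 3], B[, 3]); iy2 <- pmin(A[, 4], B[, 4])
  iw <- ix2 - ix1; ih <- iy2 - iy1
  pos <- iw > 0 & ih > 0
  area <- ifelse(pos, iw * ih, 0)
  g <- cbind(-(A[, 1] > B[, 1]) * ih, -(A[, 2] > B[, 2]) * iw,
             (A[, 3] < B[, 3]) * ih, (A[, 4] < B[, 4]) * iw)
  g[!pos, ] <- 0
  list(area = area, grad = g)
}

iou_vec_grad <- function(A, B) {
  ig <- inter_vec(A, B)
  aa <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  ab <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  u <- aa + ab - ig$area
  ok <- u > 0
  val <- ifelse(ok, ig$area / u, 0)
  dA <- cbind(-(A[, 4] - A[, 2]), -(A[, 3] - A[, 1]),
              A[, 4] - A[, 2], A[, 3] - A[, 1])
  dU <- dA - ig$grad
  g <- (ig$grad * u - ig$area * dU) / u^2
  g[!ok, ] <- 0
  list(value = val, grad = g)
}

iog_vec_grad <- function(P, G) {
  ig <- inter_vec(P, G)
  ag <- (G[, 3] - G[, 1]) * (G[, 4] - G[, 2])
  list(value = ig$area / ag, grad = ig$grad / ag)
}

# Row-aligned CIoU and gradient w.r.t. the rows of P.
ciou_vec_grad <- function(P, G) {
  w <- P[, 3] - P[, 1]; h <- P[, 4] - P[, 2]
  wg <- G[, 3] - G[, 1]; hg <- G[, 4] - G[, 2]
  io <- iou_vec_grad(P, G)
  u <- 1 - io$value
  dx <- (P[, 1] + P[, 3]) / 2 - (G[, 1] + G[, 3]) / 2
  dy <- (P[, 2] + P[, 4]) / 2 - (G[, 2] + G[, 4]) / 2
  rho2 <- dx^2 + dy^2
  cw <- pmax(P[, 3], G[, 3]) - pmin(P[, 1], G[, 1])
  ch <- pmax(P[, 4], G[, 4]) - pmin(P[, 2], G[, 2])
  c2 <- cw^2 + ch^2
  delta <- atan(wg / hg) - atan(w / h)
  v <- (4 / pi^2) * delta^2
  tden <- u + v
  aspect <- ifelse(tden > 1e-12, v^2 / tden, 0)
  value <- u + rho2 / c2 + aspect
  drho2 <- cbind(dx, dy, dx, dy)
  dc2 <- cbind(2 * cw * -(P[, 1] < G[, 1]), 2 * ch * -(P[, 2] < G[, 2]),
               2 * cw * (P[, 3] > G[, 3]), 2 * ch * (P[, 4] > G[, 4]))
  dterm2 <- (drho2 * c2 - rho2 * dc2) / c2^2
  dv_dw <- -(8 / pi^2) * delta * h / (w^2 + h^2)
  dv_dh <- (8 / pi^2) * delta * w / (w^2 + h^2)
  dv <- cbind(-dv_dw, -dv_dh, dv_dw, dv_dh)
  dT_dv <- ifelse(tden > 1e-12, (2 * v * tden - v^2) / tden^2, 0)
  dT_du <- ifelse(tden > 1e-12, -v^2 / tden^2, 0)
  grad <- -io$grad + dterm2 + dv * dT_dv + (-io$grad) * dT_du
  list(value = value, grad = grad)
}

# Gradient of the plain intersection area w.r.t. the first box's corners.
inter_grad <- function(a, b) {
  ix1 <- max(a[1], b[1]); iy1 <- max(a[2], b[2])
  ix2 <- min(a[3], b[3]); iy2 <- min(a[4], b[4])
  iw <- ix2 - ix1; ih <- iy2 - iy1
  if (iw <= 0 || ih <= 0) return(list(area = 0, grad = numeric(4)))
  g <- c(-(a[1] > b[1]) * ih, -(a[2] > b[2]) * iw,
         (a[3] < b[3]) * ih, (a[4] < b[4]) * iw)
  list(area = iw * ih, grad = g)
}

iou_with_grad <- function(a, b) {
  ig <- inter_grad(a, b)
  aa <- box_area(a); ab <- box_area(b)
  u <- aa + ab - ig$area
  if (u <= 0) return(list(value = 0, grad = numeric(4)))
  dA <- c(-(a[4] - a[2]), -(a[3] - a[1]), a[4] - a[2], a[3] - a[1])
  dU <- dA - ig$grad
  list(value = ig$area / u, grad = (ig$grad * u - ig$area * dU) / u^2)
}

iog_with_grad <- function(p, g) {
  ig <- inter_grad(p, g)
  ag <- box_area(g)
  list(value = ig$area / ag, grad = ig$grad / ag)
}

#' Complete-IoU loss between a predicted and a ground-truth box
#'
#' `1 - IoU + rho^2/c^2 + omega * v`, where `rho` is the centre distance, `c`
#' the diagonal of the smallest enclosing box, `v` the squared arctan
#' aspect-ratio difference and `omega = v / ((1 - IoU) + v)`.
#'
#' @param pred,gt Boxes with positive width and height.
#' @param gradient If `TRUE`, also return the analytic gradient w.r.t. `pred`.
#' @return Loss value, or `list(value, grad)` when `gradient = TRUE`.
#' @export
ciou_loss <- function(pred, gt, gradient = FALSE) {
  validate_box(pred); validate_box(gt)
  w <- pred[3] - pred[1]; h <- pred[4] - pred[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  if (w <= 0 || h <= 0 || wg <= 0 || hg <= 0)
    stop("ciou_loss requires boxes with positive width and height")
  io <- iou_with_grad(pred, gt)
  u <- 1 - io$value
  dx <- (pred[1] + pred[3]) / 2 - (gt[1] + gt[3]) / 2
  dy <- (pred[2] + pred[4]) / 2 - (gt[2] + gt[4]) / 2
  rho2 <- dx^2 + dy^2
  cw <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  ch <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  c2 <- cw^2 + ch^2
  delta <- atan(wg / hg) - atan(w / h)
  v <- (4 / pi^2) * delta^2
  tden <- u + v
  aspect <- if (tden > 1e-12) v^2 / tden else 0
  value <- u + rho2 / c2 + aspect
  if (!gradient) return(value)

  drho2 <- c(dx, dy, dx, dy)
  dc2 <- c(2 * cw * -(pred[1] < gt[1]), 2 * ch * -(pred[2] < gt[2]),
           2 * cw * (pred[3] > gt[3]), 2 * ch * (pred[4] > gt[4]))
  dterm2 <- (drho2 * c2 - rho2 * dc2) / c2^2
  dv_dw <- -(8 / pi^2) * delta * h / (w^2 + h^2)
  dv_dh <- (8 / pi^2) * delta * w / (w^2 + h^2)
  dv <- c(-dv_dw, -dv_dh, dv_dw, dv_dh)
  if (tden > 1e-12) {
    dT_dv <- (2 * v * tden - v^2) / tden^2
    dT_du <- -v^2 / tden^2
  } else {
    dT_dv <- 0; dT_du <- 0
  }
  grad <- -io$grad + dterm2 + dT_dv * dv + dT_du * (-io$grad)
  list(value = value, grad = grad)
}

#' Assignment table for the repulsion losses
#'
#' One row per positive prediction: the index of its attraction ground truth,
#' the index of its repulsion ground truth (the non-assigned ground truth with
#' maximal IoU with the prediction, or `NA`), and its group id (defaults to
#' the attraction index).
#'
#' @param attr_idx Integer vector of assigned ground-truth indices.
#' @param rep_idx Integer vector (or `NA`) of repulsion ground-truth indices.
#' @param group Group ids partitioning the positives.
#' @return Object of class `assignment_table`.
#' @export
assignment_table <- function(attr_idx, rep_idx = rep(NA_integer_, length(attr_idx)),
                             group = attr_idx) {
  attr_idx <- as.integer(attr_idx)
  rep_idx <- as.integer(rep_idx)
  if (length(rep_idx) != length(attr_idx) || length(group) != length(attr_idx))
    stop("assignment table columns must have equal length")
  bad <- !is.na(rep_idx) & rep_idx == attr_idx
  if (any(bad)) stop("repulsion ground truth must differ from the attraction ground truth")
  structure(list(attr_idx = attr_idx, rep_idx = rep_idx, group = as.integer(group)),
            class = "assignment_table")
}

# Clamp an overlap fraction away from 1 so smooth_ln stays finite during
# optimization (duplicate boxes would otherwise produce infinite repulsion).
clamp_frac <- function(x, hi = 1 - 1e-9) pmin(x, hi)

#' RepGT repulsion loss
#'
#' Mean over all positives of `smooth_ln(IoG(P, G_Rep(P)))`; positives without
#' a repulsion ground truth contribute 0. Division is by the total number of
#' positives.
#'
#' @param preds n x 4 matrix of positive predicted boxes (rows align with `table`).
#' @param gts m x 4 matrix of ground-truth boxes.
#' @param table [assignment_table].
#' @param w [loss_weights].
#' @param gradient If `TRUE`, also return d(loss)/d(pred) as an n x 4 matrix.
#' @return Loss value, or `list(value, grad)`.
#' @export
repgt_loss <- function(preds, gts, table, w = loss_weights(), gradient = FALSE) {
  preds <- as_box_matrix(preds); gts <- as_box_matrix(gts)
  n <- length(table$attr_idx)
  if (nrow(preds) != n) stop("assignment table inconsistent with predictions")
  grad <- matrix(0, n, 4)
  if (n == 0L) {
    warning("repgt_loss: empty positive set")
    return(if (gradient) list(value = 0, grad = grad) else 0)
  }
  has_rep <- which(!is.na(table$rep_idx))
  value <- 0
  if (length(has_rep)) {
    P <- preds[has_rep, , drop = FALSE]
    G <- gts[table$rep_idx[has_rep], , drop = FALSE]
    ig <- iog_vec_grad(P, G)
    x <- clamp_frac(ig$value)
    value <- sum(smooth_ln(x, w$sigma_repgt)) / n
    grad[has_rep, ] <- (smooth_ln_grad(x, w$sigma_repgt) * ig$grad) / n
  }
  if (gradient) list(value = value, grad = grad) else value
}

#' RepBox repulsion loss
#'
#' Unordered pairs of positive predictions assigned to different ground
#' truths: `sum smooth_ln(IoU) / (count(IoU > 0) + epsilon)`.
#'
#' @inheritParams repgt_loss
#' @return Loss value, or `list(value, grad)`.
#' @export
repbox_loss <- function(preds, table, w = loss_weights(), gradient = FALSE) {
  preds <- as_box_matrix(preds)
  n <- nrow(preds)
  grad <- matrix(0, n, 4)
  if (n < 2L) return(if (gradient) list(value = 0, grad = grad) else 0)
  cross <- outer(table$group, table$group, `!=`) & upper.tri(matrix(0, n, n))
  im <- iou_mat(preds, preds)
  sel <- which(cross & im > 0, arr.ind = TRUE)
  cnt <- nrow(sel)
  den <- cnt + w$epsilon
  if (cnt == 0L) return(if (gradient) list(value = 0, grad = grad) else 0)
  x <- clamp_frac(im[sel])
  value <- sum(smooth_ln(x, w$sigma_repbox)) / den
  if (!gradient) return(value)
  sg <- smooth_ln_grad(x, w$sigma_repbox)
  Pi <- preds[sel[, 1], , drop = FALSE]
  Pj <- preds[sel[, 2], , drop = FALSE]
  gi <- iou_vec_grad(Pi, Pj)$grad * sg / den
  gj <- iou_vec_grad(Pj, Pi)$grad * sg / den
  agg_i <- rowsum(gi, sel[, 1])
  grad[as.integer(rownames(agg_i)), ] <- grad[as.integer(rownames(agg_i)), ] + agg_i
  agg_j <- rowsum(gj, sel[, 2])
  grad[as.integer(rownames(agg_j)), ] <- grad[as.integer(rownames(agg_j)), ] + agg_j
  list(value = value, grad = grad)
}

#' Composite occlusion loss
#'
#' `mean CIoU + alpha * RepGT + beta * RepBox` over the positive predictions.
#'
#' @inheritParams repgt_loss
#' @return `list(total, components)` where components holds `ciou`, `repgt`,
#'   `repbox`; with `gradient = TRUE` also `grad` (n x 4).
#' @export
occlusion_loss <- function(preds, gts, table, w = loss_weights(), gradient = FALSE) {
  preds <- as_box_matrix(preds); gts <- as_box_matrix(gts)
  n <- nrow(preds)
  if (n == 0L) {
    res <- list(total = 0, components = list(ciou = 0, repgt = 0, repbox = 0))
    if (gradient) res$grad <- matrix(0, 0, 4)
    return(res)
  }
  G <- gts[table$attr_idx, , drop = FALSE]
  if (any(preds[, 3] <= preds[, 1]) || any(preds[, 4] <= preds[, 2]) ||
      any(G[, 3] <= G[, 1]) || any(G[, 4] <= G[, 2]))
    stop("occlusion_loss requires boxes with positive width and height")
  cv <- ciou_vec_grad(preds, G)
  ciou_mean <- mean(cv$value)
  cgrad <- cv$grad
  rg <- repgt_loss(preds, gts, table, w, gradient = gradient)
  rb <- repbox_loss(preds, table, w, gradient = gradient)
  if (gradient) {
    total <- ciou_mean + w$alpha * rg$value + w$beta * rb$value
    list(total = total,
         components = list(ciou = ciou_mean, repgt = rg$value, repbox = rb$value),
         grad = cgrad / n + w$alpha * rg$grad + w$beta * rb$grad)
  } else {
    total <- ciou_mean + w$alpha * rg + w$beta * rb
    list(total = total, components = list(ciou = ciou_mean, repgt = rg, repbox = rb))
  }
}

#' Binary cross-entropy classification loss
#'
#' Mean BCE between sigmoid scores and targets, computed in a numerically
#' stable form from the raw logits.
#'
#' @param logits Numeric array of raw scores.
#' @param targets Numeric array of targets in `[0, 1]`, same shape.
#' @return Mean BCE (nonnegative scalar).
#' @export
classification_loss <- function(logits, targets) {
  if (length(logits) != length(targets) ||
      !identical(dim(logits), dim(targets)))
    stop("logits and targets must have identical shape")
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}
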