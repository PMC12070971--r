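# Box algebra and the Overlap Ratio occlusion statistic.
#
# A box is a length-4 numeric vector (x1, y1, x2, y2) in continuous pixel
# coordinates, corner convention, area = (x2-x1)*(y2-y1) with no +1. Sets of
# boxes are n x 4 matrices, one box per row.

#' Construct and validate a bounding box
#'
#' @param x1,y1,x2,y2 Corner coordinates in pixels; `x2 >= x1`, `y2 >= y1`.
#' @return A length-4 numeric vector `c(x1, y1, x2, y2)`.
#' @export
box <- function(x1, y1, x2, y2) {
  b <- c(x1, y1, x2, y2)
  validate_box(b)
  b
}

validate_box <- function(b) {
  if (length(b) != 4L || !is.numeric(b) || any(!is.finite(b)))
    stop("a box must be 4 finite numbers (x1, y1, x2, y2)")
  if (b[3] < b[1] || b[4] < b[2]) stop("box must satisfy x2 >= x1 and y2 >= y1")
  invisible(b)
}

as_box_matrix <- function(boxes) {
  if (is.null(boxes) || length(boxes) == 0L) return(matrix(numeric(), 0L, 4L))
  if (is.numeric(boxes) && is.null(dim(boxes))) boxes <- matrix(boxes, 1L, 4L)
  boxes <- as.matrix(boxes)
  if (ncol(boxes) != 4L) stop("box set must have 4 columns")
  boxes
}

#' Box area
#' @param b A box or n x 4 matrix of boxes.
#' @return Numeric vector of areas.
#' @export
box_area <- function(b) {
  b <- as_box_matrix(b)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

intersect_box <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[3], b[3]); y2 <- min(a[4], b[4])
  if (x2 <= x1 || y2 <= y1) return(NULL)
  c(x1, y1, x2, y2)
}

#' Intersection over union of two boxes
#'
#' Degenerate pairs (both boxes of zero area) return 0 with a warning.
#'
#' @param a,b Boxes (`c(x1, y1, x2, y2)`).
#' @return Fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  validate_box(a); validate_box(b)
  inter <- intersect_box(a, b)
  ia <- if (is.null(inter)) 0 else box_area(inter)
  u <- box_area(a) + box_area(b) - ia
  if (u <= 0) {
    warning("both boxes degenerate (zero union area); IoU defined as 0")
    return(0)
  }
  ia / u
}

#' Intersection over ground-truth area
#'
#' `iog(p, g) = area(p intersect g) / area(g)`; the denominator is the ground
#' truth's own area, so covering a foreign ground truth is penalized no matter
#' how large the prediction is.
#'
#' @param p Predicted box.
#' @param g Ground-truth box; must have positive area.
#' @return Fraction in `[0, 1]`.
#' @export
iog <- function(p, g) {
  validate_box(p); validate_box(g)
  ag <- box_area(g)
  if (ag <= 0) stop("degenerate ground-truth box (zero area) in iog()")
  inter <- intersect_box(p, g)
  if (is.null(inter)) 0 else box_area(inter) / ag
}

# Exact area of a union of axis-aligned rectangles via coordinate compression.
union_area <- function(rects) {
  if (length(rects) == 0L) return(0)
  m <- do.call(rbind, rects)
  xs <- sort(unique(c(m[, 1], m[, 3])))
  ys <- sort(unique(c(m[, 2], m[, 4])))
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  dx <- diff(xs); dy <- diff(ys)
  xm <- (xs[-length(xs)] + xs[-1]) / 2
  ym <- (ys[-length(ys)] + ys[-1]) / 2
  covered <- matrix(FALSE, length(xm), length(ym))
  for (r in rects)
    covered <- covered | outer(xm > r[1] & xm < r[3], ym > r[2] & ym < r[4], `&`)
  sum(outer(dx, dy) * covered)
}

#' Overlap Ratio of a box against its neighbours
#'
#' The fraction of `target`'s area covered by the union of its intersections
#' with all other boxes. The union is computed exactly (coordinate-compression
#' sweep), so overlapping neighbours are never double counted.
#'
#' @param target Box with positive area.
#' @param others n x 4 matrix (or list) of neighbour boxes.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(target, others) {
  validate_box(target)
  at <- box_area(target)
  if (at <= 0) stop("overlap_ratio: target box has zero area")
  others <- if (is.list(others)) do.call(rbind, others) else as_box_matrix(others)
  if (nrow(others) == 0L) return(0)
  rects <- list()
  for (i in seq_len(nrow(others))) {
    r <- intersect_box(target, others[i, ])
    if (!is.null(r)) rects[[length(rects) + 1L]] <- r
  }
  min(1, union_area(rects) / at)
}

#' Annotated image container
#'
#' Boxes are clipped to the image extent on construction (annotations are
#' amodal but cannot extend beyond the frame).
#'
#' @param image_id Identifier.
#' @param width,height Image extent in pixels.
#' @param boxes n x 4 matrix of boxes.
#' @param class_ids Integer class labels (all equal in single-class mode).
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, boxes, class_ids = NULL) {
  boxes <- as_box_matrix(boxes)
  if (is.null(class_ids)) class_ids <- rep(0L, nrow(boxes))
  if (length(class_ids) != nrow(boxes)) stop("class_ids length mismatch")
  if (any(class_ids < 0)) stop("class_ids must be nonnegative")
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), width)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), height)
  structure(list(image_id = image_id, width = width, height = height,
                 boxes = boxes, class_ids = as.integer(class_ids)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %s: %dx%d, %d boxes>\n",
              x$image_id, x$width, x$height, nrow(x$boxes)))
  invisible(x)
}

#' Per-image occlusion report
#'
#' Computes each box's Overlap Ratio against all other boxes of the image and
#' their arithmetic mean. An empty image has image OR 0 by convention.
#'
#' @param img An [annotated_image].
#' @return List with `per_box_or`, `image_or`, `n_objects`.
#' @export
image_or <- function(img) {
  stopifnot(inherits(img, "annotated_image"))
  n <- nrow(img$boxes)
  if (n == 0L)
    return(list(per_box_or = numeric(), image_or = 0, n_objects = 0L))
  per <- vapply(seq_len(n), function(i)
    overlap_ratio(img$boxes[i, ], img$boxes[-i, , drop = FALSE]), 0)
  list(per_box_or = per, image_or = mean(per), n_objects = n)
}

#' Dense-subset filter
#'
#' Keeps images whose mean Overlap Ratio strictly exceeds `or_thr` AND whose
#' object count strictly exceeds `min_objects` (both thresholds strict).
#'
#' @param dataset List of [annotated_image] objects.
#' @param or_thr Occlusion threshold (default 0.5).
#' @param min_objects Object-count threshold (default 40).
#' @return The filtered list, order preserved.
#' @export
dense_subset <- function(dataset, or_thr = 0.5, min_objects = 40L) {
  keep <- vapply(dataset, function(img) {
    rep <- image_or(img)
    rep$image_or > or_thr && rep$n_objects > min_objects
  }, TRUE)
  dataset[keep]
}
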