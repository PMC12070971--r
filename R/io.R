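# Annotation I/O: YOLO txt labels (class cx cy w h, normalized) and COCO
# JSON, plus COCO-results export for detections.

#' Write YOLO-format labels
#'
#' One line per object: `class cx cy w h`, centre/size normalized by the
#' image extent.
#'
#' @param ann An [annotated_image].
#' @param path Output txt path.
#' @export
write_yolo_labels <- function(ann, path) {
  stopifnot(inherits(ann, "annotated_image"))
  b <- ann$boxes
  if (nrow(b) == 0L) { writeLines(character(), path); return(invisible(path)) }
  cx <- (b[, 1] + b[, 3]) / 2 / ann$width
  cy <- (b[, 2] + b[, 4]) / 2 / ann$height
  w <- (b[, 3] - b[, 1]) / ann$width
  h <- (b[, 4] - b[, 2]) / ann$height
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", ann$class_ids, cx, cy, w, h), path)
  invisible(path)
}

#' Read YOLO-format labels
#'
#' @param path Label txt path.
#' @param width,height Image extent in pixels (YOLO labels are normalized).
#' @param image_id Identifier (defaults to the file name).
#' @return An [annotated_image].
#' @export
read_yolo_labels <- function(path, width, height,
                             image_id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(annotated_image(image_id, width, height, matrix(numeric(), 0, 4)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 5L) stop("YOLO label lines must have 5 fields: class cx cy w h")
  cx <- m[, 2] * width; cy <- m[, 3] * height
  w <- m[, 4] * width; h <- m[, 5] * height
  annotated_image(image_id, width, height,
                  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2),
                  class_ids = as.integer(m[, 1]))
}

#' Read a COCO-format annotation file
#'
#' @param path COCO JSON path.
#' @return List of [annotated_image], one per image entry.
#' @export
read_coco_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  imgs <- j$images
  anns <- j$annotations
  lapply(seq_len(nrow(imgs)), function(i) {
    im <- imgs[i, ]
    sel <- anns[anns$image_id == im$id, , drop = FALSE]
    boxes <- if (nrow(sel)) {
      bb <- do.call(rbind, sel$bbox)  # COCO xywh
      cbind(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4])
    } else matrix(numeric(), 0, 4)
    annotated_image(im$id, im$width, im$height, boxes,
                    class_ids = if (nrow(sel)) sel$category_id else NULL)
  })
}

#' Export detections as COCO-results JSON
#'
#' @param det_list Per-image detection sets.
#' @param image_ids Matching image identifiers.
#' @param path Output path.
#' @export
write_coco_results <- function(det_list, image_ids, path) {
  rows <- list()
  for (i in seq_along(det_list)) {
    d <- det_list[[i]]
    nb <- if (is.null(d$boxes)) 0L else nrow(as_box_matrix(d$boxes))
    if (nb == 0L) next
    b <- as_box_matrix(d$boxes)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = image_ids[[i]],
      category_id = if (length(d$class_ids)) d$class_ids else 0L,
      bbox_x = b[, 1], bbox_y = b[, 2],
      bbox_w = b[, 3] - b[, 1], bbox_h = b[, 4] - b[, 2],
      score = d$scores)
  }
  flat <- if (length(rows)) do.call(rbind, rows) else data.frame()
  recs <- lapply(seq_len(nrow(flat)), function(i)
    list(image_id = flat$image_id[i], category_id = flat$category_id[i],
         bbox = c(flat$bbox_x[i], flat$bbox_y[i], flat$bbox_w[i], flat$bbox_h[i]),
         score = flat$score[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a generated dataset from its manifest
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return List of scenes: `list(image, ann)` per entry.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- png::readPNG(file.path(dir, row$file))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    ann <- read_yolo_labels(file.path(dir, row$labels), row$width, row$height,
                            image_id = row$id)
    list(image = img[, , 1:3, drop = FALSE], ann = ann)
  })
}

#' Occlusion statistics report for a dataset
#'
#' Computes per-image OR and dense-subset membership.
#'
#' @param anns List of [annotated_image].
#' @param or_thr,min_objects Dense-subset thresholds.
#' @return Data frame: id, n_objects, image_or, dense.
#' @export
or_stats <- function(anns, or_thr = 0.5, min_objects = 40L) {
  rows <- lapply(anns, function(a) {
    r <- image_or(a)
    data.frame(id = a$image_id, n_objects = r$n_objects,
               image_or = r$image_or,
               dense = r$image_or > or_thr && r$n_objects > min_objects)
  })
  do.call(rbind, rows)
}
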