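# Deterministic generator of dense occluded scenes.
#
# The generator emulates the statistical regime of crowded poultry imagery:
# 10-80 mutually occluding convex bodies per image, per-image mean Overlap
# Ratio spanning 0-0.8, a fraction of edge-truncated instances, motion blur
# and illumination variation. Annotations are amodal boxes clipped at the
# image border, written in YOLO txt format.

#' Scene specification
#'
#' @param n_objects Number of objects.
#' @param image_size Square image side in pixels.
#' @param size_range Object bounding-box size interval (pixels); defaults to
#'   7.5--20 percent of the image side.
#' @param target_or Desired per-image mean Overlap Ratio in `[0, 1)`.
#' @param edge_fraction Fraction of objects forced to straddle the border.
#' @param blur_sigma Gaussian motion-blur sigma in pixels (0 = none).
#' @param illumination_gain Interval of the global illumination gain.
#' @param texture "ellipse" (smooth body) or "blob" (speckled body).
#' @param seed Integer seed; fully determines the scene.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_objects = 40L, image_size = 320L,
                       size_range = image_size * c(0.075, 0.2), target_or = 0.3,
                       edge_fraction = 0.15, blur_sigma = 0.8,
                       illumination_gain = c(0.7, 1.3),
                       texture = c("ellipse", "blob"), seed = 0L) {
  texture <- match.arg(texture)
  if (n_objects < 0L) stop("n_objects must be >= 0")
  if (target_or < 0 || target_or >= 1) stop("target_or must lie in [0, 1)")
  structure(list(n_objects = as.integer(n_objects),
                 image_size = as.integer(image_size),
                 size_range = size_range, target_or = target_or,
                 edge_fraction = edge_fraction, blur_sigma = blur_sigma,
                 illumination_gain = illumination_gain, texture = texture,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Sample object sizes and (amodal) boxes for a given cluster spread; returns
# an n x 4 box matrix. Smaller `spread` packs the boxes tighter.
place_boxes <- function(spec, spread) {
  n <- spec$n_objects
  S <- spec$image_size
  sz <- matrix(stats::runif(2 * n, spec$size_range[1], spec$size_range[2]), n, 2)
  n_edge <- round(spec$edge_fraction * n)
  k <- max(1L, round(n / 15))
  centers <- matrix(stats::runif(2 * k, 0.25 * S, 0.75 * S), k, 2)
  boxes <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    if (i <= n_edge) {
      # edge-truncated: centre within half a body of the border
      side <- sample(4L, 1L)
      off <- stats::runif(1, 0, sz[i, 1] / 2)
      cx <- switch(side, off, S - off, stats::runif(1, 0, S), stats::runif(1, 0, S))
      cy <- switch(side, stats::runif(1, 0, S), stats::runif(1, 0, S), off, S - off)
    } else {
      cl <- centers[sample(k, 1L), ]
      cx <- stats::rnorm(1, cl[1], spread)
      cy <- stats::rnorm(1, cl[2], spread)
      cx <- min(max(cx, sz[i, 1] / 2), S - sz[i, 1] / 2)
      cy <- min(max(cy, sz[i, 2] / 2), S - sz[i, 2] / 2)
    }
    boxes[i, ] <- c(cx - sz[i, 1] / 2, cy - sz[i, 2] / 2,
                    cx + sz[i, 1] / 2, cy + sz[i, 2] / 2)
  }
  boxes
}

# Rejection placement for fully disjoint layouts (target OR = 0).
place_disjoint <- function(spec, tries = 300L) {
  n <- spec$n_objects
  S <- spec$image_size
  boxes <- matrix(0, 0, 4)
  for (i in seq_len(n)) {
    for (t in seq_len(tries)) {
      w <- stats::runif(1, spec$size_range[1], spec$size_range[2])
      h <- stats::runif(1, spec$size_range[1], spec$size_range[2])
      cx <- stats::runif(1, w / 2, S - w / 2)
      cy <- stats::runif(1, h / 2, S - h / 2)
      b <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
      ok <- nrow(boxes) == 0L ||
        all(apply(boxes, 1, function(o) is.null(intersect_box(b, o))))
      if (ok) { boxes <- rbind(boxes, b); break }
    }
  }
  unname(boxes)
}

mean_or_of_boxes <- function(boxes, S) {
  ann <- annotated_image("tmp", S, S, boxes)
  image_or(ann)$image_or
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  xs <- -r:r
  k1 <- exp(-xs^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  d <- dim(img)
  cpp_dwconv(as.double(img), d[1], d[2], d[3],
             matrix(rep(as.vector(k2), d[3]), ncol = d[3]),
             2L * r + 1L, 1L, r)
}

#' Generate one synthetic dense scene
#'
#' Objects are placed by rejection-and-relax sampling: cluster spread starts
#' wide and shrinks until the achieved image Overlap Ratio lands within 0.05
#' of the target (best effort after a bounded number of attempts, flagged).
#' Later objects occlude earlier ones in render z-order; labels are amodal
#' boxes clipped to the image.
#'
#' @param spec A [scene_spec].
#' @return List: `image` (`(S, S, 3)` array in `[0, 1]`), `annotations`
#'   ([annotated_image]), `achieved_or`, `converged` flag.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    S <- spec$image_size
    if (spec$n_objects == 0L) {
      boxes <- matrix(numeric(), 0, 4); converged <- TRUE
    } else if (spec$target_or == 0) {
      boxes <- place_disjoint(spec); converged <- TRUE
    } else {
      spread0 <- S / 2
      best <- NULL; best_err <- Inf; converged <- FALSE
      for (t in 0:14) {
        cand <- place_boxes(spec, spread0 * 0.78^t)
        err <- abs(mean_or_of_boxes(cand, S) - spec$target_or)
        if (err < best_err) { best <- cand; best_err <- err }
        if (best_err <= 0.05) { converged <- TRUE; break }
      }
      if (!converged)
        warning(sprintf("scene %d: achieved OR misses target by %.3f",
                        spec$seed, best_err))
      boxes <- best
    }
    ann <- annotated_image(sprintf("scene_%d", spec$seed), S, S, boxes)

    # low-frequency background
    coarse <- matrix(stats::runif(64, 0.15, 0.45), 8, 8)
    gx <- seq(1, 8, length.out = S)
    bg1 <- coarse[pmin(floor(gx), 7), ][, pmin(floor(gx), 7)]
    img <- array(0, dim = c(S, S, 3))
    tint <- stats::runif(3, 0.8, 1.2)
    for (c in 1:3) img[, , c] <- pmin(bg1 * tint[c], 1)

    # render ellipses, later objects on top
    ys <- seq_len(S) - 0.5
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      a <- (b[3] - b[1]) / 2; bb <- (b[4] - b[2]) / 2
      col <- stats::runif(3, 0.45, 0.9)
      rows <- which(ys > cy - bb & ys < cy + bb)  # image rows = y
      cols <- which(ys > cx - a & ys < cx + a)
      if (!length(rows) || !length(cols)) next
      dy2 <- ((ys[rows] - cy) / bb)^2
      dx2 <- ((ys[cols] - cx) / a)^2
      mask <- outer(dy2, dx2, `+`) <= 1
      if (spec$texture == "blob") {
        speck <- matrix(stats::runif(length(mask)) > 0.08, nrow(mask))
        mask <- mask & speck
      }
      shade <- 1 - 0.3 * outer(dy2, dx2, `+`)
      for (c in 1:3) {
        patch <- img[rows, cols, c]
        patch[mask] <- (col[c] * shade)[mask]
        img[rows, cols, c] <- patch
      }
    }

    img <- gaussian_blur(img, spec$blur_sigma)
    gain <- stats::runif(1, spec$illumination_gain[1], spec$illumination_gain[2])
    ramp <- matrix(seq(0.92, 1.08, length.out = S), S, S, byrow = TRUE)
    for (c in 1:3) img[, , c] <- pmin(pmax(img[, , c] * gain * ramp, 0), 1)

    list(image = img, annotations = ann,
         achieved_or = image_or(ann)$image_or, converged = converged)
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes PNG images, YOLO txt labels and a JSON manifest with per-image
#' achieved OR and object counts. Fully reproducible from `seed`.
#'
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created).
#' @param seed Master seed; scene i uses `seed * 10000 + i`.
#' @param n_objects Interval of object counts to sample per image.
#' @param target_or Interval of target ORs to sample per image.
#' @param image_size,size_range,edge_fraction,blur_sigma,illumination_gain,texture
#'   Passed to [scene_spec].
#' @return The manifest as a data frame (invisibly also written to
#'   `manifest.json`).
#' @export
generate_dataset <- function(n_images, out_dir, seed = 0L,
                             n_objects = c(10L, 60L), target_or = c(0.05, 0.6),
                             image_size = 320L,
                             size_range = image_size * c(0.075, 0.2),
                             edge_fraction = 0.15, blur_sigma = 0.8,
                             illumination_gain = c(0.7, 1.3),
                             texture = "ellipse") {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_images)
  pars <- with_seed(seed, list(
    n = sample(seq(n_objects[1], n_objects[2]), n_images, replace = TRUE),
    or = stats::runif(n_images, target_or[1], target_or[2])))
  for (i in seq_len(n_images)) {
    spec <- scene_spec(n_objects = pars$n[i], image_size = image_size,
                       size_range = size_range, target_or = pars$or[i],
                       edge_fraction = edge_fraction, blur_sigma = blur_sigma,
                       illumination_gain = illumination_gain, texture = texture,
                       seed = seed * 10000L + i)
    sc <- suppressWarnings(generate_scene(spec))
    id <- sprintf("img_%04d", i)
    png::writePNG(sc$image, file.path(out_dir, "images", paste0(id, ".png")))
    write_yolo_labels(sc$annotations, file.path(out_dir, "labels", paste0(id, ".txt")))
    rows[[i]] <- data.frame(id = id, file = file.path("images", paste0(id, ".png")),
                            labels = file.path("labels", paste0(id, ".txt")),
                            width = image_size, height = image_size,
                            n_objects = nrow(sc$annotations$boxes),
                            achieved_or = sc$achieved_or,
                            target_or = pars$or[i])
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  manifest
}
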