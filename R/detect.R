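## Face and eye localization. Two routes share one contract:
##   * bypass mode: ground-truth regions (from the fixture generator or a
##     regions CSV) are injected and returned verbatim, so every bespoke
##     downstream stage is exercised independently of any detector;
##   * heuristic mode: a deterministic luminance/chroma detector designed for
##     the synthetic frontal faces (face = bounding box of bright pixels; eyes
##     = the two low-chroma bright sclera clusters, searched inside the face
##     box when one was found and over the whole frame otherwise).
## In both routes a frame where the two eyes are not simultaneously found is
## classified DISTRACTION downstream.

#' Rectangular image region (0-based pixel coordinates)
#'
#' @param x,y Top-left corner, 0-based.
#' @param w,h Width and height in pixels (> 0).
#' @return List with class `region`.
#' @export
region <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) gp_stop("region width/height must be > 0", "gp_validation")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)), class = "region")
}

#' Intersection-over-union of two regions
#'
#' @param a,b [region()] objects.
#' @return IoU in \[0, 1\].
#' @export
region_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Detector tuning parameters
#'
#' @param face_lum_threshold Luminance above which a pixel counts as
#'   foreground for the face bounding box (0-255).
#' @param sclera_lum_threshold Minimum luminance of a sclera pixel.
#' @param sclera_chroma_max Maximum channel spread (max - min) of a sclera
#'   pixel; the sclera is bright and nearly neutral, skin is not.
#' @param min_gap Minimum horizontal gap (pixels) separating the two eye
#'   clusters.
#' @param min_pixels Minimum pixel count for a cluster to count as an eye.
#' @param margin Pixels added around each detected eye cluster's bounding box.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(face_lum_threshold = 90,
                          sclera_lum_threshold = 150,
                          sclera_chroma_max = 40,
                          min_gap = 10, min_pixels = 12, margin = 4) {
  structure(list(face_lum_threshold = face_lum_threshold,
                 sclera_lum_threshold = sclera_lum_threshold,
                 sclera_chroma_max = sclera_chroma_max,
                 min_gap = min_gap, min_pixels = min_pixels, margin = margin),
            class = "detect_config")
}

## 3x3 binary erosion: keeps a pixel only when its full 8-neighborhood is in
## the mask, which strips isolated noise pixels while solid sclera regions
## survive
erode3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  out <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1)
    out <- out & pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  out
}

mask_bbox <- function(mask, margin = 0) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  x0 <- max(0, min(idx[, 2]) - 1 - margin)
  y0 <- max(0, min(idx[, 1]) - 1 - margin)
  x1 <- min(ncol(mask) - 1, max(idx[, 2]) - 1 + margin)
  y1 <- min(nrow(mask) - 1, max(idx[, 1]) - 1 + margin)
  region(x0, y0, x1 - x0 + 1, y1 - y0 + 1)
}

#' Locate the face in a frame
#'
#' Heuristic: the face is the bounding box of pixels brighter than the
#' background. Returns `NULL` when no such pixels exist (blank frame, subject
#' out of view).
#'
#' @param frame RGB array (0-255).
#' @param config A [detect_config()].
#' @return A [region()] or `NULL`.
#' @export
detect_face <- function(frame, config = detect_config()) {
  assert_frame(frame)
  mask_bbox(luminance(frame) > config$face_lum_threshold)
}

crop_region <- function(frame, reg) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rows <- clamp(round(reg$y) + seq_len(round(reg$h)), 1, h)
  cols <- clamp(round(reg$x) + seq_len(round(reg$w)), 1, w)
  frame[unique(rows), unique(cols), , drop = FALSE]
}

#' Locate the two eyes in a frame
#'
#' The search is restricted to the face region when one is supplied and falls
#' back to the whole frame otherwise, so a failed face detection never
#' prevents eye detection from being attempted. Sclera pixels (bright and
#' nearly neutral in color) are clustered along x; the two largest clusters
#' separated by a horizontal gap become the eye boxes, named in image
#' coordinates (left = smaller x). `both_eyes_found` is `TRUE` only when both
#' single-eye boxes are present.
#'
#' @param frame RGB array (0-255).
#' @param face A [region()] or `NULL`.
#' @param config A [detect_config()].
#' @return List with `face`, `eye_pair`, `left_eye`, `right_eye` (regions or
#'   `NULL`) and `both_eyes_found`.
#' @export
detect_eyes <- function(frame, face = NULL, config = detect_config()) {
  assert_frame(frame)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (!is.null(face)) {
    x0 <- clamp(round(face$x), 0, w - 1); y0 <- clamp(round(face$y), 0, h - 1)
  } else {
    x0 <- 0; y0 <- 0
  }
  sub <- if (is.null(face)) frame else crop_region(frame, face)
  lum <- luminance(sub)
  chroma <- do.call(pmax, lapply(1:3, function(ch) sub[, , ch])) -
    do.call(pmin, lapply(1:3, function(ch) sub[, , ch]))
  mask <- erode3(lum > config$sclera_lum_threshold &
                   chroma < config$sclera_chroma_max)
  idx <- which(mask, arr.ind = TRUE)
  result <- list(face = face, eye_pair = NULL, left_eye = NULL,
                 right_eye = NULL, both_eyes_found = FALSE)
  if (nrow(idx) < config$min_pixels) return(result)

  ## cluster sclera pixels by gaps along x
  xs <- sort(unique(idx[, 2]))
  breaks <- which(diff(xs) > config$min_gap)
  starts <- c(1, breaks + 1); ends <- c(breaks, length(xs))
  clusters <- lapply(seq_along(starts), function(k) {
    cols <- xs[starts[k]]:xs[ends[k]]
    sel <- idx[idx[, 2] %in% cols, , drop = FALSE]
    sel
  })
  clusters <- Filter(function(s) nrow(s) >= config$min_pixels, clusters)
  if (length(clusters) == 0L) return(result)
  sizes <- vapply(clusters, nrow, integer(1))
  keep <- order(-sizes, vapply(clusters, function(s) min(s[, 2]), numeric(1)))[
    seq_len(min(2L, length(clusters)))]
  clusters <- clusters[keep]
  boxes <- lapply(clusters, function(sel) {
    m <- matrix(FALSE, nrow(sub), ncol(sub))
    m[sel] <- TRUE
    b <- mask_bbox(m, margin = config$margin)
    region(b$x + x0, b$y + y0, b$w, b$h)     # back to frame coordinates
  })
  if (length(boxes) == 2L) {
    ord <- order(vapply(boxes, function(b) b$x, numeric(1)))
    result$left_eye <- boxes[[ord[1]]]
    result$right_eye <- boxes[[ord[2]]]
    result$both_eyes_found <- TRUE
    x0p <- min(result$left_eye$x, result$right_eye$x)
    y0p <- min(result$left_eye$y, result$right_eye$y)
    result$eye_pair <- region(x0p, y0p,
                              max(result$left_eye$x + result$left_eye$w,
                                  result$right_eye$x + result$right_eye$w) - x0p,
                              max(result$left_eye$y + result$left_eye$h,
                                  result$right_eye$y + result$right_eye$h) - y0p)
  } else {
    ## single cluster: assign a side by its position within the search region
    b <- boxes[[1]]
    mid <- x0 + (if (is.null(face)) w else face$w) / 2
    side <- if (b$x + b$w / 2 < mid) "left_eye" else "right_eye"
    result[[side]] <- b
  }
  result
}

regions_from_truth_row <- function(row) {
  getreg <- function(prefix) {
    x <- row[[paste0(prefix, "_x")]]
    if (is.na(x)) return(NULL)
    region(x, row[[paste0(prefix, "_y")]],
           row[[paste0(prefix, "_w")]], row[[paste0(prefix, "_h")]])
  }
  getiris <- function(prefix) {
    cx <- row[[paste0(prefix, "_cx")]]
    if (is.na(cx)) return(NULL)
    list(center_x = cx, center_y = row[[paste0(prefix, "_cy")]],
         radius = row[[paste0(prefix, "_r")]])
  }
  list(face = getreg("face"), left_eye = getreg("left_eye"),
       right_eye = getreg("right_eye"),
       left_iris = getiris("left_iris"), right_iris = getiris("right_iris"))
}

#' Detect face and eyes, or accept injected ground-truth regions
#'
#' With `regions` supplied (bypass mode) the injected regions are returned
#' verbatim and no pixel-based detection runs, making downstream
#' classification a deterministic function of pixel content only.
#'
#' @param frame RGB array (0-255).
#' @param config A [detect_config()].
#' @param regions Optional list with `face`, `left_eye`, `right_eye` regions
#'   (each a [region()] or `NULL`), e.g. from the fixture ground truth.
#' @return Detection result as in [detect_eyes()].
#' @export
detect_frame <- function(frame, config = detect_config(), regions = NULL) {
  if (!is.null(regions)) {
    res <- list(face = regions$face, eye_pair = NULL,
                left_eye = regions$left_eye, right_eye = regions$right_eye,
                both_eyes_found = !is.null(regions$left_eye) &&
                  !is.null(regions$right_eye))
    return(res)
  }
  face <- detect_face(frame, config)
  detect_eyes(frame, face = face, config = config)
}
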