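## The bespoke core: Prewitt edge map, iris localization by a circular
## accumulator, the horizontal brightness profile through the iris center,
## sclera peak brightnesses (LR, RR) and the threshold rule that turns their
## ratio into a gaze label.
##
## Rule (threshold t, default 0.85): LR/RR <= t  -> RIGHT gaze;
## RR/LR <= t -> LEFT gaze; min(LR, RR)/max(LR, RR) > t -> CENTER. A subject
## gazing to their right rotates the iris toward image-left, shrinking the
## left sclera region and leaving the right one wide and bright, so LR < RR.

#' Prewitt gradient magnitude
#'
#' 3x3 un-normalized Prewitt kernels; magnitude `sqrt(Gx^2 + Gy^2)`; image
#' borders handled by reflection. An ideal vertical step of height h gives an
#' interior magnitude of 3h.
#'
#' @param raster Single-channel numeric matrix, at least 3x3.
#' @return Matrix of gradient magnitudes, same size.
#' @export
prewitt_edges <- function(raster) {
  if (!is.matrix(raster) || nrow(raster) < 3L || ncol(raster) < 3L)
    gp_stop("raster must be a matrix of at least 3x3", "gp_validation")
  h <- nrow(raster); w <- ncol(raster)
  pad <- raster[c(1, 1:h, h), c(1, 1:w, w)]      # reflect borders
  sh <- function(dy, dx) pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  gx <- (sh(-1, 1) + sh(0, 1) + sh(1, 1)) - (sh(-1, -1) + sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + sh(1, 0) + sh(1, 1)) - (sh(-1, -1) + sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

## summed-area table lookup: mean of raster over the (2r+1)-square centered
## at each pixel, windows clipped at the borders
box_mean <- function(raster, r) {
  h <- nrow(raster); w <- ncol(raster)
  sat <- apply(apply(raster, 2, cumsum), 1, cumsum)   # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))                      # (h+1) x (w+1), 1-padded
  y0 <- pmax(0, (1:h) - r - 1); y1 <- pmin(h, (1:h) + r)
  x0 <- pmax(0, (1:w) - r - 1); x1 <- pmin(w, (1:w) + r)
  sums <- sat[y1 + 1, x1 + 1] - sat[y0 + 1, x1 + 1] -
    sat[y1 + 1, x0 + 1] + sat[y0 + 1, x0 + 1]
  areas <- outer(y1 - y0, x1 - x0)
  sums / areas
}

ring_points <- function(cx, cy, r, h, w) {
  n <- max(16L, ceiling(2 * pi * r))
  th <- 2 * pi * (seq_len(n) - 1) / n
  px <- round(cx + r * cos(th)); py <- round(cy + r * sin(th))
  keep <- px >= 1 & px <= w & py >= 1 & py <= h
  unique(cbind(py[keep], px[keep]))
}

#' Locate the iris in an eye crop
#'
#' Operates on the black-region-enhanced raster (iris bright, sclera/skin
#' dark). For each candidate radius, the best-supported center is the argmax
#' of the box-filtered raster (centroid of ties, so a flat dark disc resolves
#' to its geometric center); the winning radius maximizes the mean Prewitt
#' edge magnitude on the circle of that radius (ties -> smaller radius).
#' Deterministic given its input.
#'
#' @param eye_raster Single-channel matrix (black-enhanced eye crop, 0-255).
#' @param radii Candidate radii in pixels; default spans 15-45% of the crop
#'   height.
#' @param edge_threshold Minimum mean ring edge magnitude for a detection;
#'   below it a `gp_no_iris` error is raised (the frame becomes DISTRACTION
#'   downstream).
#' @return List `center_x`, `center_y` (0-based crop coordinates), `radius`.
#' @export
locate_iris <- function(eye_raster, radii = NULL, edge_threshold = 10) {
  if (!is.matrix(eye_raster) || nrow(eye_raster) < 8L || ncol(eye_raster) < 8L)
    gp_stop("eye raster too small", "gp_validation")
  h <- nrow(eye_raster); w <- ncol(eye_raster)
  if (is.null(radii)) {
    r0 <- max(2L, round(0.15 * h)); r1 <- max(r0, round(0.45 * h))
    radii <- r0:r1
  }
  edges <- prewitt_edges(eye_raster)
  best <- list(score = -Inf, cx = NA, cy = NA, r = NA)
  for (r in radii) {
    bm <- box_mean(eye_raster, r)
    mx <- which(bm == max(bm), arr.ind = TRUE)
    cy <- round(mean(mx[, 1])); cx <- round(mean(mx[, 2]))
    pts <- ring_points(cx, cy, r, h, w)
    if (nrow(pts) == 0L) next
    score <- mean(edges[pts])
    if (score > best$score + 1e-9) best <- list(score = score, cx = cx, cy = cy, r = r)
  }
  if (!is.finite(best$score) || best$score < edge_threshold)
    gp_stop("no iris-like blob with sufficient edge support", "gp_no_iris")
  list(center_x = best$cx - 1, center_y = best$cy - 1, radius = best$r)
}

#' Horizontal brightness profile through the iris center
#'
#' Samples the (remapped) L channel along the horizontal line through the
#' iris center, extending `half_length = round(half_length_factor * radius)`
#' pixels to each side (clipped at the crop borders, with the center index
#' adjusted accordingly). The profile is dark over the iris and bright over
#' the flanking sclera. With `band_rows > 1` each profile value is the
#' vertical mean over a band of rows centered on the iris center: sclera
#' brightness varies slowly vertically, so the band leaves a clean profile
#' essentially unchanged while averaging down single-pixel sensor noise.
#'
#' @param l_raster Single-channel matrix (remapped L of the eye crop).
#' @param iris Iris location from [locate_iris()].
#' @param half_length_factor Profile half-length as a multiple of the iris
#'   radius (>= 1, default 2).
#' @param band_rows Odd number of rows averaged per profile value (default 3).
#' @return List `values`, `center_index` (0-based position of the iris center
#'   within `values`), `half_length`.
#' @export
brightness_profile <- function(l_raster, iris, half_length_factor = 2,
                               band_rows = 3) {
  if (half_length_factor < 1)
    gp_stop("half_length_factor must be >= 1", "gp_validation")
  if (!is_gp_count(band_rows, min = 1) || band_rows %% 2 != 1)
    gp_stop("band_rows must be a positive odd integer", "gp_validation")
  h <- nrow(l_raster); w <- ncol(l_raster)
  cx <- round(iris$center_x); cy <- round(iris$center_y)
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    gp_stop("iris center outside the raster", "gp_validation")
  half <- round(half_length_factor * iris$radius)
  x0 <- max(0, cx - half); x1 <- min(w - 1, cx + half)
  rows <- clamp(cy + seq(-(band_rows %/% 2), band_rows %/% 2), 0, h - 1) + 1
  band <- l_raster[unique(rows), (x0 + 1):(x1 + 1), drop = FALSE]
  list(values = as.numeric(colMeans(band)),
       center_index = cx - x0,
       half_length = half)
}

#' Brightest sclera pixel on each side of the iris
#'
#' Excludes the iris span `[center - radius, center + radius]` and takes the
#' maximum of the remaining profile on each side: `LR` for the left region,
#' `RR` for the right. Also records each peak's pixel distance from the iris
#' center (used by the optional distance-ratio mode).
#'
#' @param profile A [brightness_profile()].
#' @param iris_radius Iris radius in pixels.
#' @return List `LR`, `RR`, `dist_LR`, `dist_RR`.
#' @export
sclera_peaks <- function(profile, iris_radius) {
  n <- length(profile$values)
  ci <- profile$center_index                       # 0-based
  left_idx <- seq_len(max(0, ci - iris_radius))    # 0-based < ci - radius
  right_lo <- ci + iris_radius + 2                 # 1-based index of first right pixel
  right_idx <- if (right_lo <= n) right_lo:n else integer(0)
  if (length(left_idx) == 0L || length(right_idx) == 0L)
    gp_stop("profile too short to contain sclera on both sides of the iris",
            "gp_degenerate")
  lv <- profile$values[left_idx]; rv <- profile$values[right_idx]
  li <- left_idx[which.max(lv)]; ri <- right_idx[which.max(rv)]
  list(LR = max(lv), RR = max(rv),
       dist_LR = ci - (li - 1), dist_RR = (ri - 1) - ci)
}

#' Classify gaze from the sclera brightness pair
#'
#' The threshold rule on the pair `(LR, RR)`: `LR/RR <= t` means the gaze is
#' to the right, `RR/LR <= t` to the left, and `min/max > t` is a central
#' gaze. The boundary is inclusive; for `t < 1` the three cases partition all
#' positive pairs, and an exact tie `LR == RR` with `t = 1` resolves to
#' CENTER.
#'
#' @param sb [sclera_peaks()] result (or any list with `LR`, `RR`).
#' @param threshold Ratio threshold in (0, 1\]; default 0.85.
#' @param mode `"brightness"` compares the peak brightness values (default);
#'   `"distance"` compares the peaks' pixel distances from the iris center.
#' @return One of `"LEFT"`, `"RIGHT"`, `"CENTER"`.
#' @export
classify_gaze <- function(sb, threshold = 0.85,
                          mode = c("brightness", "distance")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1)
    gp_stop("threshold must be in (0, 1]", "gp_validation")
  pair <- if (mode == "brightness") c(sb$LR, sb$RR) else c(sb$dist_LR, sb$dist_RR)
  if (any(!is.finite(pair)) || all(pair == 0))
    gp_stop("degenerate sclera measurements (LR = RR = 0)", "gp_degenerate")
  lr <- pair[1]; rr <- pair[2]
  if (lr == rr) return("CENTER")
  if (min(lr, rr) / max(lr, rr) > threshold) return("CENTER")
  if (lr < rr) "RIGHT" else "LEFT"
}

#' Pipeline configuration for per-frame classification
#'
#' @param threshold Gaze ratio threshold in (0, 1\] (default 0.85, the value
#'   selected by concordance calibration).
#' @param half_length_factor Brightness-profile half-length as a multiple of
#'   the iris radius.
#' @param ratio_mode `"brightness"` or `"distance"` (see [classify_gaze()]).
#' @param enhance An [enhance_config()].
#' @param detect A [detect_config()].
#' @param iris_edge_threshold Passed to [locate_iris()].
#' @return An object of class `gaze_config`.
#' @export
gaze_config <- function(threshold = 0.85, half_length_factor = 2,
                        ratio_mode = "brightness",
                        enhance = enhance_config(), detect = detect_config(),
                        iris_edge_threshold = 10) {
  if (threshold <= 0 || threshold > 1)
    gp_stop("threshold must be in (0, 1]", "gp_validation")
  if (half_length_factor < 1)
    gp_stop("half_length_factor must be >= 1", "gp_validation")
  structure(list(threshold = threshold,
                 half_length_factor = half_length_factor,
                 ratio_mode = ratio_mode, enhance = enhance, detect = detect,
                 iris_edge_threshold = iris_edge_threshold),
            class = "gaze_config")
}

## run enhancement + iris + profile + peaks on one eye crop;
## returns measurements without applying the threshold
measure_eye <- function(frame, eye_region, config) {
  crop <- crop_region(frame, eye_region)
  enh <- enhance_frame(crop, config$enhance)
  iris <- locate_iris(enh$k_enhanced,
                      edge_threshold = config$iris_edge_threshold)
  prof <- brightness_profile(enh$l_remap, iris, config$half_length_factor)
  sb <- sclera_peaks(prof, iris$radius)
  list(iris = iris, sb = sb)
}

combine_eye_labels <- function(left_label, right_label) {
  if (is.na(left_label) || is.na(right_label))
    return(list(label = "DISTRACTION", reason = "eye_measurement_failed"))
  if (left_label == right_label) return(list(label = left_label, reason = NA_character_))
  list(label = "DISTRACTION", reason = "eyes_disagree")
}

#' Classify a single frame
#'
#' Full pipeline: detection (or injected ground-truth regions), per-eye
#' enhancement, iris localization, brightness profile, sclera peaks, and the
#' threshold rule; the frame label is the common per-eye label, and any
#' failure (eyes not simultaneously detected, no iris, degenerate profile,
#' disagreement between the eyes) folds into DISTRACTION with a recorded
#' reason.
#'
#' @param frame RGB array (0-255).
#' @param config A [gaze_config()].
#' @param regions Optional injected regions for [detect_frame()] bypass mode.
#' @return List with `label`, `reason` (`NA` unless DISTRACTION), and `eyes`,
#'   a two-row data.frame of per-eye diagnostics (LR, RR, ratio, label, iris
#'   location, failure reason).
#' @export
classify_frame <- function(frame, config = gaze_config(), regions = NULL) {
  assert_frame(frame)
  det <- detect_frame(frame, config$detect, regions = regions)
  diag_row <- function(eye) data.frame(
    eye = eye, LR = NA_real_, RR = NA_real_, ratio = NA_real_,
    label = NA_character_, iris_cx = NA_real_, iris_cy = NA_real_,
    iris_r = NA_real_, reason = NA_character_)
  eyes <- rbind(diag_row("left"), diag_row("right"))
  if (!det$both_eyes_found)
    return(list(label = "DISTRACTION", reason = "eyes_not_detected", eyes = eyes))
  for (i in 1:2) {
    side <- c("left", "right")[i]
    reg <- det[[paste0(side, "_eye")]]
    m <- tryCatch(measure_eye(frame, reg, config), gazepref_error = identity)
    if (inherits(m, "condition")) {
      eyes$reason[i] <- conditionMessage(m)
      next
    }
    lab <- tryCatch(classify_gaze(m$sb, config$threshold, config$ratio_mode),
                    gazepref_error = identity)
    if (inherits(lab, "condition")) {
      eyes$reason[i] <- conditionMessage(lab)
      next
    }
    pair <- if (config$ratio_mode == "brightness") c(m$sb$LR, m$sb$RR)
            else c(m$sb$dist_LR, m$sb$dist_RR)
    eyes$LR[i] <- pair[1]; eyes$RR[i] <- pair[2]
    eyes$ratio[i] <- min(pair) / max(pair)
    eyes$label[i] <- lab
    eyes$iris_cx[i] <- reg$x + m$iris$center_x
    eyes$iris_cy[i] <- reg$y + m$iris$center_y
    eyes$iris_r[i] <- m$iris$radius
  }
  res <- combine_eye_labels(eyes$label[1], eyes$label[2])
  list(label = res$label, reason = res$reason, eyes = eyes)
}

#' Classify every frame of a session
#'
#' @param frames List of RGB arrays (e.g. `generate_session()$frames` or
#'   [extract_frames()] output).
#' @param config A [gaze_config()].
#' @param truth Optional ground-truth table (as produced by
#'   [generate_session()] or read from a regions CSV); when supplied, its
#'   regions are injected per frame (detection bypass).
#' @param frame_indices 0-based indices of `frames`; defaults to
#'   `truth$frame_index` or `0:(n-1)`.
#' @return List with `annotations` (data.frame `frame_index`, `label`, with
#'   `source = "AUTO"` attribute) and `diagnostics` (per-frame, per-eye
#'   data.frame).
#' @export
classify_session <- function(frames, config = gaze_config(), truth = NULL,
                             frame_indices = NULL) {
  n <- length(frames)
  if (n == 0L) gp_stop("empty session: no frames", "gp_empty_session")
  if (is.null(frame_indices))
    frame_indices <- if (!is.null(truth)) truth$frame_index else 0:(n - 1)
  labels <- character(n)
  diags <- vector("list", n)
  for (i in seq_len(n)) {
    regions <- if (!is.null(truth)) regions_from_truth_row(truth[i, ]) else NULL
    res <- classify_frame(frames[[i]], config, regions = regions)
    labels[i] <- res$label
    d <- res$eyes
    d$frame_index <- frame_indices[i]
    d$frame_label <- res$label
    d$frame_reason <- res$reason
    diags[[i]] <- d
  }
  ann <- data.frame(frame_index = frame_indices, label = labels)
  attr(ann, "source") <- "AUTO"
  list(annotations = ann, diagnostics = do.call(rbind, diags))
}
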