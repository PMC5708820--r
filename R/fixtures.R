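## Synthetic fixtures: eyes, faces, sessions and cohorts with exact ground
## truth. These stand in for recorded video of a child's face: the only signal
## the downstream pipeline needs is a bright sclera flanking a dark iris whose
## lateral offset encodes the gaze direction.

#' Specification of a rendered synthetic eye
#'
#' Describes one eye region: a bright sclera ellipse on skin, with a dark iris
#' disc displaced laterally by `iris_offset` pixels. The sclera is shaded so
#' that brightness falls off toward the eye corners (as it does in real eyes,
#' where the lids shadow the corners); this falloff is what makes the lateral
#' iris position recoverable from the brightness profile.
#'
#' Gaze convention (un-mirrored camera image): a subject gazing to *their*
#' left rotates the iris toward increasing x in the image, so
#' `iris_offset > 0` encodes a LEFT gaze, `iris_offset < 0` a RIGHT gaze and
#' `0` a CENTER gaze.
#'
#' @param width,height Eye-region size in pixels.
#' @param sclera_color,iris_color,skin_color RGB triples on 0-255.
#' @param iris_radius Iris radius in pixels.
#' @param iris_offset Signed lateral displacement of the iris center from the
#'   eye center, pixels (positive = toward increasing x).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (gray levels; 0 = noise free).
#' @param seed Integer seed for the noise.
#' @param sclera_semi_axes Horizontal/vertical semi-axes of the sclera
#'   ellipse, pixels; defaults scale with the region size.
#' @param corner_shading Fraction by which sclera brightness drops at the
#'   lateral extremes of the ellipse (0 = flat sclera).
#' @return An object of class `eye_render_spec`.
#' @export
eye_render_spec <- function(width = 51, height = 30,
                            sclera_color = c(245, 245, 245),
                            iris_color = c(40, 30, 25),
                            skin_color = c(190, 150, 120),
                            iris_radius = 8, iris_offset = 0,
                            noise_sd = 0, seed = 1L,
                            sclera_semi_axes = c(round(0.46 * width), round(0.40 * height)),
                            corner_shading = 0.5) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               sclera_color = sclera_color, iris_color = iris_color,
               skin_color = skin_color,
               iris_radius = iris_radius, iris_offset = iris_offset,
               noise_sd = noise_sd, seed = as.integer(seed),
               sclera_semi_axes = as.integer(sclera_semi_axes),
               corner_shading = corner_shading)
  class(spec) <- "eye_render_spec"
  validate_eye_spec(spec)
  spec
}

validate_eye_spec <- function(spec) {
  a <- spec$sclera_semi_axes[1]; b <- spec$sclera_semi_axes[2]
  if (spec$width < 8 || spec$height < 8)
    gp_stop("eye region too small", "gp_validation")
  if (!is.numeric(spec$iris_radius) || spec$iris_radius <= 0)
    gp_stop("iris_radius must be > 0", "gp_validation")
  if (spec$iris_radius > min(a, b))
    gp_stop("iris does not fit inside the sclera ellipse", "gp_validation")
  if (abs(spec$iris_offset) > a - spec$iris_radius)
    gp_stop("|iris_offset| must be <= sclera half-width - iris_radius",
            "gp_validation")
  if (spec$noise_sd < 0) gp_stop("noise_sd must be >= 0", "gp_validation")
  for (col in c("sclera_color", "iris_color", "skin_color"))
    if (length(spec[[col]]) != 3L || any(spec[[col]] < 0 | spec[[col]] > 255))
      gp_stop(sprintf("%s must be an RGB triple on 0-255", col), "gp_validation")
  invisible(spec)
}

## deterministic paint of one eye into a w x h raster (no noise)
paint_eye <- function(spec) {
  w <- spec$width; h <- spec$height
  a <- spec$sclera_semi_axes[1]; b <- spec$sclera_semi_axes[2]
  cx <- floor(w / 2); cy <- floor(h / 2)           # 0-based eye center
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1), h, w)
  inside <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  shade <- 1 - spec$corner_shading * ((x - cx) / a)^2
  icx <- cx + round(spec$iris_offset)
  iris <- (x - icx)^2 + (y - cy)^2 <= spec$iris_radius^2
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$skin_color[ch], h, w)
    plane[inside] <- (spec$sclera_color[ch] * shade)[inside]
    plane[iris] <- spec$iris_color[ch]
    img[, , ch] <- plane
  }
  list(image = img,
       iris = list(center_x = icx, center_y = cy, radius = spec$iris_radius))
}

#' Render a synthetic eye with ground truth
#'
#' @param spec An [eye_render_spec()].
#' @return List with `image` (height x width x 3 array, 0-255) and `iris`
#'   (list `center_x`, `center_y`, `radius` in 0-based eye-local pixels).
#' @export
render_eye <- function(spec) {
  validate_eye_spec(spec)
  out <- paint_eye(spec)
  if (spec$noise_sd > 0) {
    out$image <- with_seed(spec$seed, {
      clamp(out$image + array(stats::rnorm(length(out$image), 0, spec$noise_sd),
                              dim = dim(out$image)), 0, 255)
    })
  }
  out
}

#' Face layout for the synthetic frame compositor
#'
#' @param width,height Frame size, pixels.
#' @param face 0-based region `list(x, y, w, h)` of the face box.
#' @param left_eye_origin,right_eye_origin 0-based `(x, y)` of the top-left
#'   corner of each eye box ("left" = smaller x, image coordinates).
#' @param skin_color,background_color RGB triples on 0-255.
#' @return An object of class `face_layout`.
#' @export
face_layout <- function(width = 160, height = 120,
                        face = region(20, 10, 120, 100),
                        left_eye_origin = c(29, 35),
                        right_eye_origin = c(80, 35),
                        skin_color = c(190, 150, 120),
                        background_color = c(30, 30, 35)) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 face = face, left_eye_origin = as.integer(left_eye_origin),
                 right_eye_origin = as.integer(right_eye_origin),
                 skin_color = skin_color, background_color = background_color),
            class = "face_layout")
}

region_inside <- function(inner, outer) {
  inner$x >= outer$x && inner$y >= outer$y &&
    inner$x + inner$w <= outer$x + outer$w &&
    inner$y + inner$h <= outer$y + outer$h
}

regions_disjoint <- function(a, b) {
  a$x + a$w <= b$x || b$x + b$w <= a$x || a$y + a$h <= b$y || b$y + b$h <= a$y
}

#' Render a synthetic frontal face with ground-truth regions
#'
#' Composites a skin-colored face ellipse on a dark background and paints one
#' eye per non-`NULL` spec. Omitting an eye (spec `NULL`) leaves skin over
#' that eye box, which the downstream pipeline must report as DISTRACTION.
#'
#' @param left_spec,right_spec [eye_render_spec()] for the image-left and
#'   image-right eye, or `NULL` to omit that eye.
#' @param layout A [face_layout()].
#' @param noise_sd Frame-wide additive Gaussian noise (gray levels); defaults
#'   to the maximum `noise_sd` of the eye specs.
#' @param seed Seed for the frame noise; defaults to a combination of the eye
#'   spec seeds.
#' @param face_present If `FALSE`, only the background is rendered (subject
#'   out of frame).
#' @return List with `image` and `truth`; `truth` holds 0-based regions
#'   `face`, `left_eye`, `right_eye` (`NULL` when absent), iris locations in
#'   frame coordinates, and `face_present`.
#' @export
render_face <- function(left_spec = eye_render_spec(),
                        right_spec = eye_render_spec(),
                        layout = face_layout(),
                        noise_sd = NULL, seed = NULL, face_present = TRUE) {
  eye_boxes <- list()
  for (side in c("left", "right")) {
    spec <- if (side == "left") left_spec else right_spec
    if (is.null(spec)) next
    validate_eye_spec(spec)
    org <- layout[[paste0(side, "_eye_origin")]]
    eye_boxes[[side]] <- region(org[1], org[2], spec$width, spec$height)
  }
  for (box in eye_boxes)
    if (!region_inside(box, layout$face))
      gp_stop("eye region extends outside the face box", "gp_validation")
  if (length(eye_boxes) == 2L &&
      !regions_disjoint(eye_boxes$left, eye_boxes$right))
    gp_stop("eye regions overlap", "gp_validation")

  if (is.null(noise_sd))
    noise_sd <- max(0, left_spec$noise_sd %||% 0, right_spec$noise_sd %||% 0)
  if (is.null(seed))
    seed <- ((left_spec$seed %||% 0) * 131 + (right_spec$seed %||% 1)) %% .Machine$integer.max

  h <- layout$height; w <- layout$width
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- layout$background_color[ch]
  truth <- list(face = NULL, left_eye = NULL, right_eye = NULL,
                left_iris = NULL, right_iris = NULL, face_present = face_present)
  if (face_present) {
    fb <- layout$face
    fcx <- fb$x + (fb$w - 1) / 2; fcy <- fb$y + (fb$h - 1) / 2
    x <- matrix(0:(w - 1), h, w, byrow = TRUE)
    y <- matrix(0:(h - 1), h, w)
    inface <- ((x - fcx) / (fb$w / 2))^2 + ((y - fcy) / (fb$h / 2))^2 <= 1
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inface] <- layout$skin_color[ch]
      img[, , ch] <- plane
    }
    truth$face <- fb
    for (side in names(eye_boxes)) {
      spec <- if (side == "left") left_spec else right_spec
      spec$noise_sd <- 0                       # noise is applied frame-wide
      eye <- paint_eye(spec)
      box <- eye_boxes[[side]]
      rows <- box$y + seq_len(box$h); cols <- box$x + seq_len(box$w)
      img[rows, cols, ] <- eye$image
      truth[[paste0(side, "_eye")]] <- box
      truth[[paste0(side, "_iris")]] <-
        list(center_x = box$x + eye$iris$center_x,
             center_y = box$y + eye$iris$center_y,
             radius = eye$iris$radius)
    }
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, {
      clamp(img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img)),
            0, 255)
    })
  }
  list(image = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of a synthetic recording session
#'
#' @param true_labels Character vector of per-frame ground-truth labels from
#'   [gaze_labels()].
#' @param fps Frame rate, frames/second.
#' @param face_present Logical vector (recycled); `FALSE` renders the frame
#'   without a face. Frames labelled DISTRACTION with `face_present = TRUE`
#'   are rendered with one eye occluded instead.
#' @param noise_sd Frame noise standard deviation, gray levels.
#' @param offset_px Iris offset magnitude used to encode LEFT/RIGHT gazes.
#' @param seed Integer master seed for the session.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(true_labels, fps = 60, face_present = TRUE,
                         noise_sd = 0, offset_px = 10, seed = 1L) {
  true_labels <- as.character(true_labels)
  if (length(true_labels) < 1L) gp_stop("need at least one frame", "gp_validation")
  if (!all(true_labels %in% gaze_labels()))
    gp_stop("true_labels must be LEFT/RIGHT/CENTER/DISTRACTION", "gp_validation")
  face_present <- rep_len(as.logical(face_present), length(true_labels))
  if (any(!face_present & true_labels != "DISTRACTION"))
    gp_stop("face_present = FALSE is only valid on DISTRACTION frames",
            "gp_validation")
  structure(list(true_labels = true_labels, n_frames = length(true_labels),
                 fps = fps, face_present = face_present, noise_sd = noise_sd,
                 offset_px = offset_px, seed = as.integer(seed)),
            class = "session_spec")
}

offset_for_label <- function(label, offset_px) {
  switch(label, LEFT = offset_px, RIGHT = -offset_px, 0)
}

truth_to_row <- function(i, label, truth) {
  reg <- function(r) if (is.null(r)) c(NA, NA, NA, NA) else c(r$x, r$y, r$w, r$h)
  iri <- function(p) if (is.null(p)) c(NA, NA, NA) else c(p$center_x, p$center_y, p$radius)
  data.frame(frame_index = i, label = label, face_present = truth$face_present,
             face_x = reg(truth$face)[1], face_y = reg(truth$face)[2],
             face_w = reg(truth$face)[3], face_h = reg(truth$face)[4],
             left_eye_x = reg(truth$left_eye)[1], left_eye_y = reg(truth$left_eye)[2],
             left_eye_w = reg(truth$left_eye)[3], left_eye_h = reg(truth$left_eye)[4],
             right_eye_x = reg(truth$right_eye)[1], right_eye_y = reg(truth$right_eye)[2],
             right_eye_w = reg(truth$right_eye)[3], right_eye_h = reg(truth$right_eye)[4],
             left_iris_cx = iri(truth$left_iris)[1], left_iris_cy = iri(truth$left_iris)[2],
             left_iris_r = iri(truth$left_iris)[3],
             right_iris_cx = iri(truth$right_iris)[1], right_iris_cy = iri(truth$right_iris)[2],
             right_iris_r = iri(truth$right_iris)[3])
}

#' Generate a synthetic session: frames plus ground-truth table
#'
#' Renders one frame per true label (or, with `render = FALSE`, only the
#' ground-truth manifest — useful for protocol arithmetic on large sessions).
#' DISTRACTION frames are rendered with the image-right eye occluded by skin,
#' or with no face at all when `face_present` is `FALSE`.
#'
#' @param spec A [session_spec()].
#' @param layout A [face_layout()].
#' @param render If `FALSE`, skip pixel rendering; `frames` is `NULL`.
#' @return List with `frames` (list of RGB arrays, or `NULL`), `truth`
#'   (data.frame keyed by 0-based `frame_index` with label, face/eye boxes and
#'   iris locations), and `spec`.
#' @export
generate_session <- function(spec, layout = face_layout(), render = TRUE) {
  stopifnot(inherits(spec, "session_spec"))
  n <- spec$n_frames
  frames <- if (render) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    label <- spec$true_labels[i]
    fp <- spec$face_present[i]
    off <- offset_for_label(label, spec$offset_px)
    frame_seed <- (spec$seed * 7919 + i * 104729) %% .Machine$integer.max
    lspec <- eye_render_spec(iris_offset = off, noise_sd = 0)
    rspec <- if (label == "DISTRACTION") NULL else eye_render_spec(iris_offset = off, noise_sd = 0)
    if (render) {
      out <- render_face(lspec, rspec, layout = layout,
                         noise_sd = spec$noise_sd, seed = frame_seed,
                         face_present = fp)
      frames[[i]] <- out$image
      truth <- out$truth
    } else {
      out <- render_face(lspec, rspec, layout = layout, noise_sd = 0,
                         seed = frame_seed, face_present = fp)
      truth <- out$truth
    }
    rows[[i]] <- truth_to_row(i - 1L, label, truth)
  }
  truth <- do.call(rbind, rows)
  list(frames = frames, truth = truth, spec = spec)
}

#' Specification of a two-group preference cohort
#'
#' Emulates a preferential-looking study cohort: per-subject fractions of
#' looking time spent on the social scene, drawn from a Beta distribution
#' parameterized by group mean and a common dispersion. Defaults follow the
#' study conditions: 8 children with ASD averaging ~27% social preference and
#' 23 children without ASD averaging ~44%.
#'
#' @param n_per_group Named counts per group.
#' @param group_mean_social Named group means, fractions in (0, 1).
#' @param dispersion Beta precision `phi` (> 0): draws are
#'   `Beta(mean * phi, (1 - mean) * phi)`, giving group variance
#'   `mean (1 - mean) / (1 + phi)`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ASD = 8, NON_ASD = 23),
                        group_mean_social = c(ASD = 0.2696, NON_ASD = 0.4421),
                        dispersion = 6.5, seed = 1L) {
  if (is.null(names(n_per_group)) || is.null(names(group_mean_social)) ||
      !setequal(names(n_per_group), names(group_mean_social)))
    gp_stop("n_per_group and group_mean_social must share group names",
            "gp_validation")
  if (any(n_per_group < 1))
    gp_stop("every group needs n >= 1", "gp_validation")
  if (any(group_mean_social <= 0 | group_mean_social >= 1))
    gp_stop("group means must lie in (0, 1)", "gp_validation")
  if (dispersion <= 0) gp_stop("dispersion must be > 0", "gp_validation")
  structure(list(n_per_group = n_per_group,
                 group_mean_social = group_mean_social,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a per-subject preference cohort
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with `subject_id`, `group`, `social_pref` (fraction of
#'   left/right looking time on the social scene).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_per_group)
  with_seed(spec$seed, {
    out <- lapply(groups, function(g) {
      n <- spec$n_per_group[[g]]
      mu <- spec$group_mean_social[[g]]
      phi <- spec$dispersion
      data.frame(group = g,
                 social_pref = stats::rbeta(n, mu * phi, (1 - mu) * phi))
    })
    out <- do.call(rbind, out)
    out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
    out[, c("subject_id", "group", "social_pref")]
  })
}
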