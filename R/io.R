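## Reading frame sequences and reading/writing annotation, subject, result
## and ground-truth-region tables. Recorded sessions are consumed as numbered
## PNG frame series (one file per frame, lexicographic-numeric order), the
## output of any standard frame splitter; CSV throughout is comma-separated
## UTF-8 with a mandatory header row.

#' Stimulus/session protocol configuration
#'
#' Defaults follow the study protocol: five 50-second stimulus segments at
#' 60 fps (3,000 frames each, 15,000 per session), preceded by a 10-second
#' introductory scene that is excluded from analysis; social scene on the
#' right half of the screen, abstract scene on the left.
#'
#' @param segment_seconds Analysed segment duration per video, seconds.
#' @param fps Frame rate, frames/second.
#' @param n_videos Number of stimulus videos per session.
#' @param intro_seconds Introductory scene duration, seconds (excluded).
#' @param left_scene,right_scene Scene shown on each side of the screen, one
#'   of `"SOCIAL"`, `"ABSTRACT"`; must differ.
#' @param camera_mirrored If `TRUE`, the camera image is mirrored (as many
#'   front cameras do) and LEFT/RIGHT labels are swapped before mapping gaze
#'   side to scene.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(segment_seconds = 50, fps = 60, n_videos = 5,
                            intro_seconds = 10,
                            left_scene = "ABSTRACT", right_scene = "SOCIAL",
                            camera_mirrored = FALSE) {
  scenes <- c("SOCIAL", "ABSTRACT")
  if (!left_scene %in% scenes || !right_scene %in% scenes ||
      left_scene == right_scene)
    gp_stop("left_scene and right_scene must be distinct SOCIAL/ABSTRACT",
            "gp_validation")
  if (fps <= 0 || segment_seconds <= 0)
    gp_stop("fps and segment_seconds must be > 0", "gp_validation")
  structure(list(segment_seconds = segment_seconds, fps = fps,
                 n_videos = n_videos, intro_seconds = intro_seconds,
                 left_scene = left_scene, right_scene = right_scene,
                 camera_mirrored = camera_mirrored),
            class = "stimulus_config")
}

#' Frame counts implied by the protocol
#'
#' @param config A [stimulus_config()].
#' @return List with `per_video` and `total` frame counts.
#' @export
stimulus_frame_count <- function(config = stimulus_config()) {
  per <- round(config$segment_seconds * config$fps)
  list(per_video = per, total = per * config$n_videos)
}

#' Read a frame sequence from a directory of PNG files
#'
#' Files are ordered by the first integer in their names (falling back to
#' lexicographic order). With `has_intro = TRUE` the first
#' `intro_seconds * fps` frames are dropped, and at most
#' `segment_seconds * fps` frames are kept; short recordings are allowed.
#'
#' @param path Directory containing `.png` frames, or a character vector of
#'   PNG file paths.
#' @param config A [stimulus_config()].
#' @param has_intro Whether the series starts with the introductory scene.
#' @return List of RGB arrays (0-255) with attribute `frame_index` (0-based
#'   integer vector).
#' @export
extract_frames <- function(path, config = stimulus_config(), has_intro = FALSE) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.png$", full.names = TRUE)
  else as.character(path)
  if (length(path) == 1L && !dir.exists(path) && !file.exists(path))
    gp_stop(sprintf("cannot read frames from '%s'", path), "gp_io")
  num <- suppressWarnings(as.numeric(sub("^\\D*(\\d+).*$", "\\1", basename(files))))
  files <- files[order(is.na(num), num, basename(files))]
  if (has_intro) {
    skip <- round(config$intro_seconds * config$fps)
    files <- if (length(files) > skip) files[-seq_len(skip)] else character(0)
  }
  cap <- round(config$segment_seconds * config$fps)
  if (length(files) > cap) files <- files[seq_len(cap)]
  if (length(files) == 0L)
    gp_stop("empty session: no frames found", "gp_empty_session")
  frames <- lapply(files, read_frame_png)
  attr(frames, "frame_index") <- 0:(length(frames) - 1L)
  frames
}

read_frame_png <- function(file) {
  if (!file.exists(file)) gp_stop(sprintf("missing frame file '%s'", file), "gp_io")
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write frames as a numbered PNG series
#'
#' @param frames List of RGB arrays (0-255).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix><index>.png`, 0-based,
#'   zero-padded.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame_") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  width <- max(4L, nchar(length(frames) - 1L))
  paths <- file.path(dir, sprintf("%s%0*d.png", prefix, width,
                                  seq_along(frames) - 1L))
  for (i in seq_along(frames))
    png::writePNG(clamp(frames[[i]] / 255, 0, 1), paths[i])
  invisible(paths)
}

#' Keep every `stride`-th element
#'
#' Realizes the every-15th-frame manual annotation protocol: indices 0,
#' stride, 2*stride, ... are kept. Annotation tables are subsampled by their
#' `frame_index` values; plain sequences by position (first element = index
#' 0).
#'
#' @param x Annotation data.frame (with `frame_index`) or list/vector.
#' @param stride Positive integer step.
#' @return Subsampled object of the same type.
#' @export
subsample <- function(x, stride) {
  if (!is_gp_count(stride, min = 1)) gp_stop("stride must be >= 1", "gp_validation")
  if (is.data.frame(x)) return(x[x$frame_index %% stride == 0, , drop = FALSE])
  idx <- seq(1L, length(x), by = stride)
  x[idx]
}

#' Read / write per-frame annotation tables
#'
#' CSV with header `frame_index,label`; frame indices 0-based and strictly
#' increasing; labels restricted to [gaze_labels()]. A malformed row is
#' reported with its row number.
#'
#' @param path CSV file path.
#' @param source Provenance tag, `"MANUAL"` or `"AUTO"`, stored as an
#'   attribute.
#' @return data.frame with `frame_index` (integer) and `label` (character).
#' @export
read_annotations <- function(path, source = "MANUAL") {
  if (!file.exists(path)) gp_stop(sprintf("no such file '%s'", path), "gp_io")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character"))
  if (!identical(names(tab)[1:2], c("frame_index", "label")))
    gp_stop("annotation CSV must have header frame_index,label", "gp_parse")
  if (nrow(tab) == 0L) {
    out <- data.frame(frame_index = integer(0), label = character(0))
    attr(out, "source") <- source
    return(out)
  }
  idx <- suppressWarnings(as.numeric(tab$frame_index))
  bad <- which(is.na(idx) | idx != round(idx) | idx < 0)
  if (length(bad))
    gp_stop(sprintf("malformed frame_index at row %d", bad[1]), "gp_parse")
  bad <- which(!tab$label %in% gaze_labels())
  if (length(bad))
    gp_stop(sprintf("unknown label '%s' at row %d", tab$label[bad[1]], bad[1]),
            "gp_parse")
  if (any(diff(idx) <= 0))
    gp_stop("frame_index must be strictly increasing", "gp_parse")
  out <- data.frame(frame_index = as.integer(idx), label = tab$label)
  attr(out, "source") <- source
  out
}

#' @rdname read_annotations
#' @param table Annotation data.frame (`frame_index`, `label`).
#' @export
write_annotations <- function(table, path) {
  stopifnot(all(c("frame_index", "label") %in% names(table)))
  utils::write.csv(table[, c("frame_index", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' CSV with columns `subject_id, age_months, sex, weight, height, group`;
#' `sex` one of F/M, `group` one of ASD/NON_ASD, `age_months > 0`.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) gp_stop(sprintf("no such file '%s'", path), "gp_io")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_months", "sex", "weight", "height", "group")
  if (!all(need %in% names(tab)))
    gp_stop(paste("subject CSV must have columns", paste(need, collapse = ", ")),
            "gp_parse")
  if (any(!tab$group %in% c("ASD", "NON_ASD")))
    gp_stop("group must be ASD or NON_ASD", "gp_parse")
  if (any(!tab$sex %in% c("F", "M"))) gp_stop("sex must be F or M", "gp_parse")
  if (any(!is.finite(tab$age_months) | tab$age_months <= 0))
    gp_stop("age_months must be > 0", "gp_parse")
  tab
}

#' Write the ground-truth regions table of a synthetic session
#'
#' @param truth `generate_session()$truth` data.frame.
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth regions table (detection bypass format)
#'
#' @param path CSV written by [write_truth()].
#' @return data.frame keyed by 0-based `frame_index`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) gp_stop(sprintf("no such file '%s'", path), "gp_io")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
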