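#' @keywords internal
"_PACKAGE"

## Shared conventions: frames are numeric arrays dim = c(height, width, 3) with
## values on the 0-255 scale; all public pixel coordinates are 0-based with x
## increasing rightward (columns) and y downward (rows).

#' The four per-frame gaze categories
#'
#' @return Character vector `c("LEFT", "RIGHT", "CENTER", "DISTRACTION")`.
#' @export
gaze_labels <- function() c("LEFT", "RIGHT", "CENTER", "DISTRACTION")

gp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gazepref_error", "error", "condition")))
}

is_gp_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' Evaluate code with a private RNG stream
#'
#' Seeds the generator, runs `code`, and restores the caller's `.Random.seed`,
#' so seeded generators stay pure functions of (spec, seed) without disturbing
#' the surrounding RNG state.
#'
#' @param seed Single non-negative integer.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is_gp_count(seed)) gp_stop("'seed' must be a single non-negative integer", "gp_validation")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_frame <- function(frame, what = "frame") {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L ||
      !is.numeric(frame))
    gp_stop(sprintf("'%s' must be a numeric height x width x 3 RGB array", what),
            "gp_validation")
  invisible(frame)
}

#' Rec. 601 luma of an RGB frame
#'
#' @param frame RGB array (height x width x 3, 0-255).
#' @return Matrix of luminance values on the same scale.
#' @export
luminance <- function(frame) {
  assert_frame(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Mirror a frame or raster horizontally
#'
#' Flips the x axis (columns). For frames, all three channels are flipped.
#'
#' @param x RGB frame array or single-channel matrix.
#' @return Object of the same shape, horizontally mirrored.
#' @export
mirror_x <- function(x) {
  if (is.matrix(x)) return(x[, ncol(x):1, drop = FALSE])
  assert_frame(x)
  x[, dim(x)[2]:1, , drop = FALSE]
}

## round-half-up, used only when formatting report percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
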