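## Image enhancement chain: RGB -> CIELab, L-channel contrast remap with
## gamma 0.5, and a CMYK K-channel remap with gamma 3 that brightens dark
## (iris/pupil) regions. All operations are pixelwise and deterministic, so
## the chain commutes with horizontal mirroring.

#' Enhancement parameters
#'
#' @param l_gamma Gamma of the L-channel contrast remap (default 0.5, which
#'   lifts mid-tones and stretches the darks).
#' @param k_gamma Gamma of the K-channel remap (default 3, which suppresses
#'   mid-tones so only genuinely black regions stay bright in the output).
#' @param in_range Source intensity bounds `(low, high)` of the remap, or
#'   `NULL` to use the observed per-channel range (optionally clipped, see
#'   `clip_quantiles`).
#' @param out_range Target bounds, default `c(0, 255)`.
#' @param clip_quantiles Optional probabilities `(p_lo, p_hi)`: when
#'   `in_range` is `NULL`, use these channel quantiles instead of min/max
#'   (histogram-based clipping).
#' @return An object of class `enhance_config`.
#' @export
enhance_config <- function(l_gamma = 0.5, k_gamma = 3, in_range = NULL,
                           out_range = c(0, 255), clip_quantiles = NULL) {
  if (l_gamma <= 0 || k_gamma <= 0) gp_stop("gammas must be > 0", "gp_validation")
  if (!is.null(in_range) && (length(in_range) != 2L || in_range[1] >= in_range[2]))
    gp_stop("in_range must be (low, high) with low < high", "gp_validation")
  if (length(out_range) != 2L || out_range[1] >= out_range[2])
    gp_stop("out_range must be (low, high) with low < high", "gp_validation")
  structure(list(l_gamma = l_gamma, k_gamma = k_gamma, in_range = in_range,
                 out_range = out_range, clip_quantiles = clip_quantiles),
            class = "enhance_config")
}

#' Convert an RGB frame to CIELab channels
#'
#' sRGB companding, D65 illuminant (the standard convention).
#'
#' @param frame RGB array (0-255).
#' @return List of matrices `L` (0-100), `a`, `b` (signed).
#' @export
to_cielab <- function(frame) {
  assert_frame(frame)
  d <- dim(frame)
  rgb <- cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
               as.vector(frame[, , 3])) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

resolve_in_range <- function(channel, config) {
  if (!is.null(config$in_range)) return(config$in_range)
  r <- if (!is.null(config$clip_quantiles))
    stats::quantile(channel, config$clip_quantiles, names = FALSE)
  else range(channel)
  if (r[1] >= r[2])
    gp_stop("degenerate intensity range: channel is constant", "gp_degenerate")
  r
}

#' Gamma-shaped intensity remap
#'
#' Maps `in_range` onto `out_range` through a power curve:
#' `v -> out_lo + (out_hi - out_lo) * ((clip(v) - in_lo) / (in_hi - in_lo))^gamma`.
#' Monotone non-decreasing; the endpoints of `in_range` map exactly onto the
#' endpoints of `out_range`.
#'
#' @param channel Numeric matrix/vector of intensities.
#' @param config An [enhance_config()].
#' @param gamma Curve exponent; defaults to `config$l_gamma`.
#' @return Remapped values within `out_range`, same shape as `channel`.
#' @export
remap_intensity <- function(channel, config = enhance_config(),
                            gamma = config$l_gamma) {
  if (gamma <= 0) gp_stop("gamma must be > 0", "gp_validation")
  inr <- resolve_in_range(channel, config)
  outr <- config$out_range
  v <- clamp(channel, inr[1], inr[2])
  outr[1] + (outr[2] - outr[1]) * ((v - inr[1]) / (inr[2] - inr[1]))^gamma
}

#' K channel of a device-naive CMYK decomposition
#'
#' `K = 1 - max(R, G, B) / 255`: large where the image is dark.
#'
#' @param frame RGB array (0-255).
#' @return Matrix of K values in \[0, 1\].
#' @export
cmyk_k <- function(frame) {
  assert_frame(frame)
  1 - do.call(pmax, lapply(1:3, function(ch) frame[, , ch])) / 255
}

#' Black-region enhancement via the CMYK K channel
#'
#' Remaps the K channel with `k_gamma` over the fixed source range (0, 1):
#' output is bright where the image is dark (iris, pupil), and the gamma of 3
#' suppresses mid-tones so moderately dark skin/shadow stays low.
#'
#' @param frame RGB array (0-255).
#' @param config An [enhance_config()].
#' @return Matrix on the `out_range` scale (default 0-255).
#' @export
black_region_enhance <- function(frame, config = enhance_config()) {
  k <- cmyk_k(frame)
  cfg <- config
  cfg$in_range <- c(0, 1)
  remap_intensity(k, cfg, gamma = config$k_gamma)
}

#' Run the full enhancement chain on a frame or eye crop
#'
#' @param frame RGB array (0-255).
#' @param config An [enhance_config()].
#' @return List with `l_remap` (contrast-remapped L channel, for the sclera
#'   brightness profile) and `k_enhanced` (black-region-enhanced raster, for
#'   iris localization).
#' @export
enhance_frame <- function(frame, config = enhance_config()) {
  lab <- to_cielab(frame)
  list(l_remap = remap_intensity(lab$L, config, gamma = config$l_gamma),
       k_enhanced = black_region_enhance(frame, config))
}
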