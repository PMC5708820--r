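## shared fixture helpers: tiny sessions and mirrored ground truth

label_cycle <- function(n, labels = gaze_labels()) rep_len(labels, n)

quick_session <- function(n = 12, labels = NULL, noise_sd = 0, seed = 1L,
                          offset_px = 10) {
  if (is.null(labels)) labels <- label_cycle(n)
  generate_session(session_spec(labels, noise_sd = noise_sd, seed = seed,
                                offset_px = offset_px))
}

## mirror the injected regions of a render_face() truth for a frame of width
## W: flip x coordinates and swap the eye sides
mirror_regions <- function(truth, W = 160) {
  flip <- function(b) {
    if (is.null(b)) return(NULL)
    region(W - b$x - b$w, b$y, b$w, b$h)
  }
  list(face = flip(truth$face), left_eye = flip(truth$right_eye),
       right_eye = flip(truth$left_eye))
}

mirror_swap_label <- function(l) {
  if (l == "LEFT") "RIGHT" else if (l == "RIGHT") "LEFT" else l
}
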