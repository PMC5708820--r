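## brute-force 3x3 convolution oracle with reflected borders
prewitt_oracle <- function(m) {
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)   # columns -1, 0, +1
  ky <- t(kx)
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) pmin(pmax(i, 1), n)
  out <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    gx <- 0; gy <- 0
    for (dy in -1:1) for (dx in -1:1) {
      v <- m[refl(y + dy, h), refl(x + dx, w)]
      gx <- gx + v * kx[dy + 2, dx + 2]
      gy <- gy + v * ky[dy + 2, dx + 2]
    }
    out[y, x] <- sqrt(gx^2 + gy^2)
  }
  out
}

test_that("Prewitt magnitude matches a hand convolution and its symmetries", {
  set.seed(7)
  m <- matrix(runif(8 * 10, 0, 255), 8, 10)
  expect_equal(prewitt_edges(m), prewitt_oracle(m), tolerance = 1e-12)

  expect_true(all(prewitt_edges(matrix(42, 6, 6)) == 0))

  # ideal vertical step of height h: interior magnitude 3h on both flanks
  step <- cbind(matrix(0, 6, 4), matrix(10, 6, 4))
  e <- prewitt_edges(step)
  expect_equal(e[3, 4], 30)
  expect_equal(e[3, 5], 30)
  expect_true(all(e[, c(1:3, 6:8)] == 0))

  expect_equal(prewitt_edges(mirror_x(m)), mirror_x(prewitt_edges(m)),
               tolerance = 1e-12)
  expect_error(prewitt_edges(matrix(1, 2, 5)), class = "gp_validation")
})

eye_k_raster <- function(offset = 0, noise_sd = 0, seed = 1) {
  e <- render_eye(eye_render_spec(iris_offset = offset, noise_sd = noise_sd,
                                  seed = seed))
  list(k = enhance_frame(e$image)$k_enhanced, truth = e$iris)
}

test_that("iris localization recovers the ground-truth circle", {
  for (off in c(-10, -4, 0, 4, 10)) {
    r <- eye_k_raster(off)
    iris <- locate_iris(r$k)
    expect_lte(abs(iris$center_x - r$truth$center_x), 2)
    expect_lte(abs(iris$center_y - r$truth$center_y), 2)
    expect_lte(abs(iris$radius - r$truth$radius), 0.2 * r$truth$radius)
  }
  # mirrored eye -> mirrored center_x
  r <- eye_k_raster(6)
  i1 <- locate_iris(r$k)
  i2 <- locate_iris(mirror_x(r$k))
  expect_lte(abs((ncol(r$k) - 1 - i1$center_x) - i2$center_x), 1)

  expect_error(locate_iris(matrix(100, 30, 50)), class = "gp_no_iris")
})

test_that("brightness profile is centered on the iris with the right extent", {
  iris <- list(center_x = 20, center_y = 10, radius = 10)
  m <- matrix(128, 21, 41)
  p <- brightness_profile(m, iris, half_length_factor = 2)
  expect_length(p$values, 41)
  expect_equal(p$center_index, 20)
  expect_true(all(p$values == 128))

  # dark center / bright flanks: minimum lands on the center index
  prof_raster <- matrix(rep(c(200, 200, 50, 200, 200), each = 3), 3, 5)
  p2 <- brightness_profile(prof_raster, list(center_x = 2, center_y = 1, radius = 1),
                           half_length_factor = 2)
  expect_equal(which.min(p2$values) - 1, p2$center_index)

  # clipping at the raster border adjusts the center index
  p3 <- brightness_profile(m, list(center_x = 3, center_y = 10, radius = 10), 2)
  expect_equal(p3$center_index, 3)
  expect_error(brightness_profile(m, list(center_x = 100, center_y = 10, radius = 5), 2),
               class = "gp_validation")
})

test_that("sclera peaks equal the brute-force maxima outside the iris span", {
  prof <- list(values = c(180, 200, 120, 40, 30, 40, 90, 100, 95),
               center_index = 4, half_length = 4)
  sb <- sclera_peaks(prof, iris_radius = 2)
  expect_equal(sb$LR, 200)
  expect_equal(sb$RR, 100)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(9:41, 1)
    ci <- (n - 1) %/% 2
    r <- sample(1:max(1, ci - 1), 1)
    vals <- runif(n, 0, 255)
    p <- list(values = vals, center_index = ci, half_length = ci)
    left <- vals[seq_len(ci - r)]
    right <- vals[(ci + r + 2):n]
    if (length(left) && length(right)) {
      sb <- sclera_peaks(p, r)
      expect_equal(sb$LR, max(left))
      expect_equal(sb$RR, max(right))
    }
  }

  sym <- list(values = c(100, 90, 10, 90, 100), center_index = 2, half_length = 2)
  sbs <- sclera_peaks(sym, 1)
  expect_equal(sbs$LR, sbs$RR)

  short <- list(values = c(1, 2, 3), center_index = 1, half_length = 1)
  expect_error(sclera_peaks(short, 1), class = "gp_degenerate")
})

test_that("the threshold rule follows the worked examples and boundary", {
  expect_equal(classify_gaze(list(LR = 100, RR = 200), 0.85), "RIGHT")
  expect_equal(classify_gaze(list(LR = 100, RR = 100), 0.85), "CENTER")
  expect_equal(classify_gaze(list(LR = 170, RR = 200), 0.85), "RIGHT") # 0.85 inclusive
  expect_equal(classify_gaze(list(LR = 200, RR = 170), 0.85), "LEFT")
  expect_equal(classify_gaze(list(LR = 171, RR = 200), 0.85), "CENTER")
  expect_equal(classify_gaze(list(LR = 5, RR = 5), 1), "CENTER")     # tie at t = 1
  expect_error(classify_gaze(list(LR = 0, RR = 0), 0.85), class = "gp_degenerate")
  expect_error(classify_gaze(list(LR = 1, RR = 1), 1.2), class = "gp_validation")

  # distance mode compares the peaks' pixel offsets instead of brightness
  sb <- list(LR = 90, RR = 90, dist_LR = 5, dist_RR = 10)
  expect_equal(classify_gaze(sb, 0.85, mode = "distance"), "RIGHT")
  expect_equal(classify_gaze(sb, 0.85, mode = "brightness"), "CENTER")
  expect_equal(classify_gaze(list(LR = 1, RR = 1, dist_LR = 7, dist_RR = 7),
                             0.85, mode = "distance"), "CENTER")
})

test_that("exactly one rule fires for every positive pair and threshold", {
  g <- expand.grid(a = seq(1, 397, by = 7), b = seq(1, 397, by = 7))
  for (t in c(0.5, 0.85, 0.99)) {
    fired <- cbind(RIGHT = g$a / g$b <= t, LEFT = g$b / g$a <= t,
                   CENTER = pmin(g$a, g$b) / pmax(g$a, g$b) > t)
    expect_true(all(rowSums(fired) == 1))
    got <- mapply(function(a, b) classify_gaze(list(LR = a, RR = b), t),
                  g$a, g$b)
    expect_identical(got, colnames(fired)[max.col(fired)])
  }
})

test_that("frame classification decodes fixture gazes and folds failures into DISTRACTION", {
  for (case in list(list(d = 10, lab = "LEFT"), list(d = -10, lab = "RIGHT"),
                    list(d = 0, lab = "CENTER"))) {
    f <- render_face(eye_render_spec(iris_offset = case$d),
                     eye_render_spec(iris_offset = case$d))
    res <- classify_frame(f$image, regions = f$truth)
    expect_equal(res$label, case$lab)
    expect_equal(nrow(res$eyes), 2)
    expect_true(all(res$eyes$label == case$lab))
  }

  f1 <- render_face(eye_render_spec(), NULL)
  res1 <- classify_frame(f1$image, regions = f1$truth)
  expect_equal(res1$label, "DISTRACTION")
  expect_equal(res1$reason, "eyes_not_detected")

  f2 <- render_face(NULL, NULL, face_present = FALSE)
  expect_equal(classify_frame(f2$image, regions = f2$truth)$label, "DISTRACTION")

  # disagreeing eyes: inject mismatched offsets
  f3 <- render_face(eye_render_spec(iris_offset = 10),
                    eye_render_spec(iris_offset = -10))
  res3 <- classify_frame(f3$image, regions = f3$truth)
  expect_equal(res3$label, "DISTRACTION")
  expect_equal(res3$reason, "eyes_disagree")
})

test_that("label sweeps monotonically across the offset range without oscillation", {
  labs <- vapply(seq(-14, 14, by = 2), function(d) {
    f <- render_face(eye_render_spec(iris_offset = d),
                     eye_render_spec(iris_offset = d))
    classify_frame(f$image, regions = f$truth)$label
  }, character(1))
  runs <- rle(labs)$values
  expect_equal(runs, c("RIGHT", "CENTER", "LEFT"))
})
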