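toy_table <- function(counts) {
  # counts: named vector over the four labels
  labs <- rep(names(counts), counts)
  data.frame(frame_index = seq_along(labs) - 1L, label = labs)
}

test_that("aggregation reproduces the reference manual-evaluation percentages", {
  # 2,559 left/right frames: 1,123 social (right side) vs 1,436 abstract
  tab <- toy_table(c(RIGHT = 1123, LEFT = 1436))
  res <- aggregate_session(tab)
  expect_equal(res$scene_pct[["SOCIAL"]], 100 * 1123 / 2559)
  expect_lt(abs(res$scene_pct[["SOCIAL"]] - 43.88), 0.01)
  expect_lt(abs(res$scene_pct[["ABSTRACT"]] - 56.11), 0.01)
  expect_equal(res$lr_total, 2559)

  # camera mirroring swaps the side-to-scene mapping
  res_m <- aggregate_session(tab, stimulus_config(camera_mirrored = TRUE))
  expect_equal(res_m$scene_pct[["SOCIAL"]], res$scene_pct[["ABSTRACT"]])
})

test_that("aggregation handles uniform and degenerate label mixes", {
  res <- aggregate_session(toy_table(c(LEFT = 1, RIGHT = 1, CENTER = 1,
                                       DISTRACTION = 1)))
  expect_true(all(res$pct == 25))
  expect_equal(unname(res$pct_lr_only), c(50, 50))

  resd <- aggregate_session(toy_table(c(DISTRACTION = 5)))
  expect_equal(resd$pct[["DISTRACTION"]], 100)
  expect_false(resd$lr_defined)
  expect_true(all(is.na(resd$pct_lr_only)))

  expect_error(aggregate_session(data.frame(frame_index = integer(0),
                                            label = character(0))),
               class = "gp_empty_session")
})

test_that("four-way percentages always sum to 100", {
  set.seed(21)
  for (i in 1:25) {
    labs <- sample(gaze_labels(), sample(1:500, 1), replace = TRUE)
    res <- aggregate_session(data.frame(frame_index = seq_along(labs) - 1,
                                        label = labs))
    expect_equal(sum(res$pct), 100)
    if (res$lr_defined) expect_equal(sum(res$pct_lr_only), 100)
  }
})

test_that("binomial standard error matches the reference value and its maximum", {
  expect_lt(abs(binomial_se(1123, 2559) - 0.98), 0.01)
  expect_equal(binomial_se(0, 100), 0)
  expect_equal(binomial_se(100, 100), 0)
  n <- 200
  se <- vapply(0:n, binomial_se, numeric(1), n = n)
  expect_equal(which.max(se) - 1, n / 2)
  expect_error(binomial_se(5, 0), class = "gp_validation")
  expect_error(binomial_se(6, 5), class = "gp_validation")
})

test_that("pooled proportion z-test agrees with the chi-square cross-check", {
  pz <- prop_z_test(1436, 2559, 1397, 2559)
  expect_lt(abs(pz$z - 1.09), 0.01)
  ct <- prop.test(c(1436, 1397), c(2559, 2559), correct = FALSE)
  expect_equal(pz$z^2, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(pz$p_value, ct$p.value, tolerance = 1e-10)
  # one-sided value halves the two-sided one here
  pz1 <- prop_z_test(1436, 2559, 1397, 2559, alternative = "greater")
  expect_lt(abs(pz1$p_value - 0.136), 0.001)
})

test_that("concordance of identical annotations is perfect", {
  ses <- toy_table(c(LEFT = 10, RIGHT = 8, CENTER = 3, DISTRACTION = 2))
  rep <- concordance_report(ses, ses)
  expect_equal(rep$frame_spearman_rho, 1)
  expect_equal(rep$agreement, 1)
  expect_equal(rep$n_frames_compared, 18)
  expect_equal(rep$proportion_z, 0)

  per <- data.frame(manual_pct = c(40, 55, 62), auto_pct = c(40, 55, 62))
  rep2 <- concordance_report(ses, ses, per_subject = per)
  expect_equal(rep2$paired_t, 0)
  expect_equal(rep2$paired_p, 1)
  expect_equal(rep2$subject_pearson_r, 1)
})

test_that("binary Spearman equals the phi coefficient and joins are robust", {
  set.seed(33)
  manual <- data.frame(frame_index = 0:199,
                       label = sample(gaze_labels(), 200, TRUE))
  auto <- data.frame(frame_index = 0:199,
                     label = sample(gaze_labels(), 200, TRUE))
  rep <- concordance_report(manual, auto)
  keep <- manual$label %in% c("LEFT", "RIGHT") & auto$label %in% c("LEFT", "RIGHT")
  phi <- cor(as.integer(manual$label[keep] == "RIGHT"),
             as.integer(auto$label[keep] == "RIGHT"))
  expect_equal(rep$frame_spearman_rho, phi, tolerance = 1e-10)
  expect_equal(rep$n_frames_compared, sum(keep))

  disjoint <- data.frame(frame_index = 1000:1010, label = rep("LEFT", 11))
  expect_error(concordance_report(manual, disjoint), class = "gp_insufficient")
})

test_that("distraction removal commutes with the frame join", {
  set.seed(34)
  manual <- data.frame(frame_index = 0:99, label = sample(gaze_labels(), 100, TRUE))
  auto <- data.frame(frame_index = 0:99, label = sample(gaze_labels(), 100, TRUE))
  # remove-then-join
  m1 <- manual[manual$label %in% c("LEFT", "RIGHT"), ]
  a1 <- auto[auto$label %in% c("LEFT", "RIGHT"), ]
  j1 <- merge(m1, a1, by = "frame_index")
  # join-then-remove
  j2 <- merge(manual, auto, by = "frame_index")
  j2 <- j2[j2$label.x %in% c("LEFT", "RIGHT") & j2$label.y %in% c("LEFT", "RIGHT"), ]
  expect_equal(j1$frame_index, j2$frame_index)
  rep <- concordance_report(manual, auto)
  expect_equal(rep$n_frames_compared, nrow(j2))
})

test_that("threshold calibration maximizes concordance and honors tie-breaks", {
  set.seed(3)
  labs <- sample(c("LEFT", "RIGHT", "CENTER"), 30, replace = TRUE)
  ses <- generate_session(session_spec(labs, offset_px = 8, seed = 11))
  manual <- data.frame(frame_index = ses$truth$frame_index,
                       label = ses$truth$label)

  cal <- calibrate_threshold(ses$frames, manual, truth = ses$truth)
  expect_equal(cal$threshold, 0.85)
  expect_equal(cal$concordance, 1)
  # the generating model is among the concordance maximizers
  gen <- cal$grid$concordance[cal$grid$threshold == 0.85 &
                                cal$grid$half_length_factor == 2.0]
  expect_equal(gen, max(cal$grid$concordance))

  single <- data.frame(threshold = 0.7, half_length_factor = 2)
  cal1 <- calibrate_threshold(ses$frames, manual, grid = single,
                              truth = ses$truth)
  expect_equal(cal1$threshold, 0.7)
  expect_equal(cal1$half_length_factor, 2)

  expect_error(calibrate_threshold(ses$frames, manual,
                                   grid = data.frame(threshold = numeric(0),
                                                     half_length_factor = numeric(0)),
                                   truth = ses$truth),
               class = "gp_validation")
  no_lr <- data.frame(frame_index = 0:4, label = rep("CENTER", 5))
  expect_error(calibrate_threshold(ses$frames[1:5], no_lr,
                                   truth = ses$truth[1:5, ]),
               class = "gp_validation")
})

test_that("group comparison reports means, intervals and the t-test", {
  same <- data.frame(group = rep(c("A", "B"), each = 4),
                     social_pref = rep(c(0.2, 0.3, 0.4, 0.5), 2))
  cmp <- compare_groups(same, group = "group")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p_value, 1)

  co <- generate_cohort(cohort_spec(n_per_group = c(ASD = 200, NON_ASD = 200),
                                    seed = 6))
  cmp2 <- compare_groups(co)
  for (g in c("ASD", "NON_ASD")) {
    row <- cmp2$groups[cmp2$groups$group == g, ]
    truth <- c(ASD = 0.2696, NON_ASD = 0.4421)[[g]]
    expect_lt(abs(row$mean - truth), 3 * row$se)
  }
  expect_lt(cmp2$p_value, 0.01)
  # cross-check against the base t-test
  tt <- t.test(social_pref ~ group, data = co, var.equal = TRUE)
  expect_equal(cmp2$t, unname(tt$statistic), tolerance = 1e-12)

  lone <- data.frame(group = c("A", "B", "B"), social_pref = c(0.5, 0.4, 0.3))
  expect_error(compare_groups(lone, group = "group"), class = "gp_insufficient")
})
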