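## Session-level aggregation, threshold calibration against manual labels,
## and the manual-vs-automatic validation statistics (frame-level Spearman,
## pooled two-sample proportion z, paired t) plus the two-group comparison
## of social-scene preference.

#' Aggregate per-frame labels into a session result
#'
#' Computes counts and percentages over the four categories, the LEFT/RIGHT
#' percentages after excluding DISTRACTION and CENTER frames (only frames
#' attributable to one of the two scenes enter the preference denominator),
#' and the social/abstract scene percentages via the side-to-scene mapping of
#' the stimulus configuration (swapped when `camera_mirrored`).
#'
#' @param labels Annotation data.frame (`frame_index`, `label`).
#' @param stim A [stimulus_config()].
#' @return Object of class `session_result`: list with `counts`, `total_frames`,
#'   `pct`, `pct_lr_only` (NA when no LEFT/RIGHT frames; see `lr_defined`),
#'   `scene_pct`, `lr_total`, `lr_defined`.
#' @export
aggregate_session <- function(labels, stim = stimulus_config()) {
  if (is.null(labels) || nrow(labels) == 0L)
    gp_stop("empty session: no labelled frames", "gp_empty_session")
  if (!all(labels$label %in% gaze_labels()))
    gp_stop("labels outside the four-category taxonomy", "gp_validation")
  counts <- vapply(gaze_labels(), function(l) sum(labels$label == l), numeric(1))
  total <- sum(counts)
  pct <- 100 * counts / total
  lr <- counts[["LEFT"]] + counts[["RIGHT"]]
  lr_defined <- lr > 0
  pct_lr_only <- if (lr_defined)
    c(LEFT = 100 * counts[["LEFT"]] / lr, RIGHT = 100 * counts[["RIGHT"]] / lr)
  else c(LEFT = NA_real_, RIGHT = NA_real_)
  side_scene <- c(LEFT = stim$left_scene, RIGHT = stim$right_scene)
  if (isTRUE(stim$camera_mirrored))
    side_scene <- c(LEFT = stim$right_scene, RIGHT = stim$left_scene)
  scene_pct <- c(SOCIAL = NA_real_, ABSTRACT = NA_real_)
  for (side in c("LEFT", "RIGHT"))
    scene_pct[[side_scene[[side]]]] <- pct_lr_only[[side]]
  structure(list(counts = counts, total_frames = total, pct = pct,
                 pct_lr_only = pct_lr_only, scene_pct = scene_pct,
                 lr_total = lr, lr_defined = lr_defined),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("Session:", x$total_frames, "frames\n")
  for (l in gaze_labels())
    cat(sprintf("  %-11s %6d  %6.2f%%\n", l, x$counts[[l]],
                round_half_up(x$pct[[l]], 2)))
  if (x$lr_defined) {
    cat(sprintf("  Left/Right frames only (n = %d):\n", x$lr_total))
    cat(sprintf("    social   %6.2f%%\n    abstract %6.2f%%\n",
                round_half_up(x$scene_pct[["SOCIAL"]], 2),
                round_half_up(x$scene_pct[["ABSTRACT"]], 2)))
  } else cat("  No LEFT/RIGHT frames: preference undefined\n")
  invisible(x)
}

#' Binomial standard error of a percentage
#'
#' `100 * sqrt(p (1 - p) / n)` with `p = k / n`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @return Standard error in percentage points.
#' @export
binomial_se <- function(k, n) {
  if (!is_gp_count(n, min = 1) || !is_gp_count(k) || k > n)
    gp_stop("need 0 <= k <= n with n > 0", "gp_validation")
  p <- k / n
  100 * sqrt(p * (1 - p) / n)
}

#' Pooled two-sample proportion z-test
#'
#' Compares `k1/n1` against `k2/n2` with the pooled-variance z statistic
#' (no continuity correction).
#'
#' @param k1,n1,k2,n2 Counts.
#' @param alternative `"two.sided"` (default), `"greater"` (p1 > p2) or
#'   `"less"`.
#' @return List with `z`, `p_value`, `estimate` (the two proportions) and
#'   `alternative`.
#' @export
prop_z_test <- function(k1, n1, k2, n2,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  for (v in list(k1, k2)) if (!is_gp_count(v)) gp_stop("counts must be non-negative integers", "gp_validation")
  if (!is_gp_count(n1, 1) || !is_gp_count(n2, 1) || k1 > n1 || k2 > n2)
    gp_stop("need 0 <= k <= n with n > 0", "gp_validation")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) gp_stop("degenerate pooled proportion (0 or 1)", "gp_degenerate")
  z <- (p1 - p2) / se
  p_value <- switch(alternative,
                    two.sided = 2 * stats::pnorm(-abs(z)),
                    greater = stats::pnorm(z, lower.tail = FALSE),
                    less = stats::pnorm(z))
  list(z = z, p_value = p_value, estimate = c(p1 = p1, p2 = p2),
       alternative = alternative)
}

join_left_right <- function(manual, auto) {
  m <- manual[manual$label %in% c("LEFT", "RIGHT"), c("frame_index", "label")]
  a <- auto[auto$label %in% c("LEFT", "RIGHT"), c("frame_index", "label")]
  names(m)[2] <- "manual"; names(a)[2] <- "auto"
  merge(m, a, by = "frame_index")
}

#' Manual-versus-automatic concordance report
#'
#' Joins the two annotation tables on `frame_index`, keeps only frames
#' labelled LEFT or RIGHT in both (distraction and center frames are removed
#' from both sides before joining — equivalently after, the operation
#' commutes), then computes: frame-level Spearman correlation on the binary
#' LEFT/RIGHT coding; a pooled two-sample proportion z-test comparing the
#' manual and automatic scene proportions; and, when per-subject percentage
#' pairs are supplied, the Pearson correlation and a paired t-test across
#' subjects.
#'
#' @param manual,auto Annotation data.frames (`frame_index`, `label`).
#' @param per_subject Optional data.frame with columns `manual_pct`,
#'   `auto_pct` (one row per subject or per subject/video).
#' @param alternative Sidedness of the proportion test.
#' @return Object of class `concordance_report`.
#' @export
concordance_report <- function(manual, auto, per_subject = NULL,
                               alternative = "two.sided") {
  j <- join_left_right(manual, auto)
  if (nrow(j) < 3L)
    gp_stop("insufficient data: fewer than 3 jointly labelled LEFT/RIGHT frames",
            "gp_insufficient")
  mb <- as.integer(j$manual == "RIGHT")
  ab <- as.integer(j$auto == "RIGHT")
  if (stats::var(mb) == 0 || stats::var(ab) == 0) {
    rho <- if (all(mb == ab)) 1 else NA_real_
    rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(mb, ab, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  pz <- prop_z_test(sum(mb), length(mb), sum(ab), length(ab),
                    alternative = alternative)
  pearson_r <- pearson_p <- paired_t <- paired_p <- NA_real_
  if (!is.null(per_subject)) {
    stopifnot(all(c("manual_pct", "auto_pct") %in% names(per_subject)))
    if (nrow(per_subject) >= 3L &&
        stats::var(per_subject$manual_pct) > 0 &&
        stats::var(per_subject$auto_pct) > 0) {
      pt <- stats::cor.test(per_subject$manual_pct, per_subject$auto_pct)
      pearson_r <- unname(pt$estimate); pearson_p <- pt$p.value
    }
    d <- per_subject$manual_pct - per_subject$auto_pct
    if (nrow(per_subject) >= 2L) {
      if (stats::var(d) == 0) {
        paired_t <- 0; paired_p <- 1
      } else {
        tt <- stats::t.test(per_subject$manual_pct, per_subject$auto_pct,
                            paired = TRUE)
        paired_t <- unname(tt$statistic); paired_p <- tt$p.value
      }
    }
  }
  structure(list(frame_spearman_rho = rho, frame_spearman_p = rho_p,
                 subject_pearson_r = pearson_r, subject_pearson_p = pearson_p,
                 proportion_z = pz$z, proportion_p = pz$p_value,
                 paired_t = paired_t, paired_p = paired_p,
                 n_frames_compared = nrow(j),
                 agreement = mean(j$manual == j$auto)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d jointly labelled LEFT/RIGHT frames\n",
              x$n_frames_compared))
  cat(sprintf("  frame agreement     %.4f\n", x$agreement))
  cat(sprintf("  Spearman rho        %.4f (p = %.3g)\n",
              x$frame_spearman_rho, x$frame_spearman_p))
  cat(sprintf("  proportion z        %.3f (p = %.3g)\n",
              x$proportion_z, x$proportion_p))
  if (!is.na(x$subject_pearson_r))
    cat(sprintf("  subject Pearson r   %.4f (p = %.3g)\n",
                x$subject_pearson_r, x$subject_pearson_p))
  if (!is.na(x$paired_t))
    cat(sprintf("  paired t            %.3f (p = %.3g)\n",
                x$paired_t, x$paired_p))
  invisible(x)
}

#' Default calibration model grid
#'
#' 18 candidate models: thresholds 0.55-0.95 in steps of 0.05 crossed with
#' profile half-length factors 1.5 and 2.0.
#'
#' @return data.frame with `threshold` and `half_length_factor`.
#' @export
default_model_grid <- function() {
  expand.grid(threshold = round(seq(0.55, 0.95, by = 0.05), 2),
              half_length_factor = c(1.5, 2.0))
}

## per-eye ratio collection: classify-independent measurements, so a whole
## threshold sweep costs one pipeline pass per half_length_factor
collect_eye_pairs <- function(frames, truth, config) {
  n <- length(frames)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    regions <- if (!is.null(truth)) regions_from_truth_row(truth[i, ]) else NULL
    det <- detect_frame(frames[[i]], config$detect, regions = regions)
    row <- data.frame(frame_index = if (!is.null(truth)) truth$frame_index[i] else i - 1,
                      ok = FALSE, lLR = NA_real_, lRR = NA_real_,
                      rLR = NA_real_, rRR = NA_real_)
    if (det$both_eyes_found) {
      ml <- tryCatch(measure_eye(frames[[i]], det$left_eye, config),
                     gazepref_error = function(e) NULL)
      mr <- tryCatch(measure_eye(frames[[i]], det$right_eye, config),
                     gazepref_error = function(e) NULL)
      if (!is.null(ml) && !is.null(mr)) {
        pick <- function(sb) if (config$ratio_mode == "brightness")
          c(sb$LR, sb$RR) else c(sb$dist_LR, sb$dist_RR)
        row$ok <- TRUE
        row[, c("lLR", "lRR")] <- pick(ml$sb)
        row[, c("rLR", "rRR")] <- pick(mr$sb)
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

label_from_pairs <- function(pairs, threshold) {
  lab_one <- function(LR, RR) {
    if (!is.finite(LR) || !is.finite(RR) || (LR == 0 && RR == 0)) return(NA_character_)
    if (LR == RR) return("CENTER")
    if (min(LR, RR) / max(LR, RR) > threshold) return("CENTER")
    if (LR < RR) "RIGHT" else "LEFT"
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    if (!pairs$ok[i]) return("DISTRACTION")
    l <- lab_one(pairs$lLR[i], pairs$lRR[i])
    r <- lab_one(pairs$rLR[i], pairs$rRR[i])
    if (is.na(l) || is.na(r) || l != r) "DISTRACTION" else l
  }, character(1))
}

#' Calibrate the gaze threshold against manual labels
#'
#' Evaluates every candidate model on the frames, scoring each by its
#' concordance: the fraction of manually LEFT/RIGHT-labelled frames whose
#' automatic label matches. The best model wins; ties resolve to the smaller
#' threshold, then the smaller half-length factor.
#'
#' @param frames List of RGB frames.
#' @param manual Manual annotation data.frame (`frame_index`, `label`) with at
#'   least one LEFT/RIGHT frame.
#' @param grid data.frame of candidates (`threshold`,
#'   `half_length_factor`); default [default_model_grid()].
#' @param config Base [gaze_config()] supplying everything the grid does not
#'   vary.
#' @param truth Optional ground-truth regions table (detection bypass).
#' @return List with `threshold`, `half_length_factor`, `concordance`,
#'   `n_frames` and the full scored `grid`.
#' @export
calibrate_threshold <- function(frames, manual, grid = default_model_grid(),
                                config = gaze_config(), truth = NULL) {
  if (is.null(grid) || nrow(grid) == 0L)
    gp_stop("empty calibration grid", "gp_validation")
  keep <- manual$label %in% c("LEFT", "RIGHT")
  if (!any(keep))
    gp_stop("manual labels contain no LEFT/RIGHT frames", "gp_validation")
  manual_lr <- manual[keep, ]
  frame_idx <- if (!is.null(truth)) truth$frame_index else 0:(length(frames) - 1)
  grid$concordance <- NA_real_
  for (hlf in unique(grid$half_length_factor)) {
    cfg <- config
    cfg$half_length_factor <- hlf
    pairs <- collect_eye_pairs(frames, truth, cfg)
    sel <- match(manual_lr$frame_index, pairs$frame_index)
    if (any(is.na(sel)))
      gp_stop("manual annotations reference frames not supplied", "gp_validation")
    rows <- which(grid$half_length_factor == hlf)
    for (g in rows) {
      auto <- label_from_pairs(pairs[sel, ], grid$threshold[g])
      grid$concordance[g] <- mean(auto == manual_lr$label)
    }
  }
  ord <- order(-grid$concordance, grid$threshold, grid$half_length_factor)
  best <- grid[ord[1], ]
  list(threshold = best$threshold,
       half_length_factor = best$half_length_factor,
       concordance = best$concordance,
       n_frames = nrow(manual_lr), grid = grid)
}

#' Two-group comparison of scene preference
#'
#' Per-group mean, standard error and t-based 95% confidence interval of the
#' preference value, plus a two-sample t-test (Student's equal-variance by
#' default, Welch via `var_equal = FALSE`).
#'
#' @param cohort data.frame with a grouping column and a numeric value column.
#' @param value,group Column names (defaults `"social_pref"`, `"group"`).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @param conf_level Confidence level for the per-group intervals.
#' @return Object of class `group_comparison`: list with `groups` (per-group
#'   data.frame: n, mean, se, ci_lo, ci_hi), `t`, `df`, `p_value`.
#' @export
compare_groups <- function(cohort, value = "social_pref", group = "group",
                           var_equal = TRUE, conf_level = 0.95) {
  stopifnot(all(c(value, group) %in% names(cohort)))
  v <- cohort[[value]]; g <- as.character(cohort[[group]])
  lev <- unique(g)
  if (length(lev) != 2L) gp_stop("need exactly two groups", "gp_validation")
  ns <- table(factor(g, levels = lev))
  if (any(ns < 2L))
    gp_stop("insufficient data: every group needs n >= 2", "gp_insufficient")
  per <- do.call(rbind, lapply(lev, function(l) {
    x <- v[g == l]
    n <- length(x); m <- mean(x); se <- stats::sd(x) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
    data.frame(group = l, n = n, mean = m, se = se,
               ci_lo = m - tq * se, ci_hi = m + tq * se)
  }))
  tt <- stats::t.test(v[g == lev[1]], v[g == lev[2]], var.equal = var_equal)
  structure(list(groups = per, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (mean (SE), 95% CI):\n")
  for (i in seq_len(nrow(x$groups))) {
    r <- x$groups[i, ]
    cat(sprintf("  %-8s (N = %2d)  %.2f (%.2f)  [%.2f, %.2f]\n",
                r$group, r$n, r$mean, r$se, r$ci_lo, r$ci_hi))
  }
  cat(sprintf("  t = %.3f, df = %.1f, p = %.4g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Write a session result as JSON
#'
#' @param result A `session_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_session_result <- function(result, path) {
  jsonlite::write_json(list(counts = as.list(result$counts),
                            total_frames = result$total_frames,
                            pct = as.list(result$pct),
                            pct_lr_only = as.list(result$pct_lr_only),
                            scene_pct = as.list(result$scene_pct),
                            lr_total = result$lr_total,
                            lr_defined = result$lr_defined),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
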