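# gazepref

Calibration-free gaze-preference analysis for tablet-based preferential-looking
sessions.

A child watches a split-screen stimulus — a **social** scene (children
performing an activity) on one side, an **abstract** scene (moving non-social
shapes) on the other — while the front camera records their face. Children
with autism spectrum disorder tend to spend less time on the social scene, so
the fraction of looking time per scene is a candidate screening signal.
Conventional eye trackers need per-subject calibration or head restraint,
which rarely works with toddlers. `gazepref` implements a deliberately simple
frame-by-frame alternative that needs neither, plus the session statistics and
manual-versus-automatic validation around it, and a synthetic face/session/
cohort generator with exact ground truth so the whole pipeline is testable
without any recorded video.

## The classifier

Each webcam frame is assigned one of four labels: `LEFT`, `RIGHT`, `CENTER`,
`DISTRACTION`. The pipeline per frame:

1. locate the face and both eyes (any failure to find both eyes
   simultaneously → `DISTRACTION`);
2. per eye crop: convert RGB → CIELab, contrast-remap the L channel onto
   0–255 with gamma 0.5, and compute a black-region-enhanced raster from the
   CMYK K channel with gamma 3;
3. localize the iris as the best-supported dark disc (circular accumulator on
   a Prewitt edge map);
4. sample the horizontal brightness profile of the remapped L channel through
   the iris center, extending twice the iris radius to each side;
5. let `LR` and `RR` be the brightest profile values left and right of the
   iris span, and with threshold `t = 0.85`:

   | condition | label | reading |
   |---|---|---|
   | `LR / RR ≤ t` | `RIGHT` | left sclera dimmed → gaze right |
   | `RR / LR ≤ t` | `LEFT`  | right sclera dimmed → gaze left |
   | `min/max > t` | `CENTER` | balanced sclera |

   The frame label is the common label of the two eyes; disagreement folds
   into `DISTRACTION`. For `t < 1` the three cases partition every positive
   `(LR, RR)` pair.

Session aggregation maps the `LEFT`/`RIGHT` labels to scenes (side mapping
and camera mirroring are explicit configuration), computes preference
percentages with binomial standard errors, calibrates the threshold against
manual annotations by concordance, and reports the validation statistics:
frame-level Spearman correlation, pooled two-sample proportion z-test,
paired t-test across subjects, and the two-group comparison of social-scene
preference. See the methods vignette
(`vignettes/gaze-preference-methods.Rmd`) for assumptions, parameter
rationale, and limitations.

## Worked example

Simulate a noisy 120-frame session with known ground truth, classify it with
detection bypassed to the ground-truth regions, and aggregate:

```r
library(gazepref)
set.seed(1)
labels <- sample(gaze_labels(), 120, replace = TRUE, prob = c(.25, .4, .15, .2))
ses    <- generate_session(session_spec(labels, noise_sd = 10, seed = 42))
auto   <- classify_session(ses$frames, truth = ses$truth)
aggregate_session(auto$annotations)
#> Session: 120 frames
#>   LEFT            27   22.50%
#>   RIGHT           45   37.50%
#>   CENTER          16   13.33%
#>   DISTRACTION     32   26.67%
#>   Left/Right frames only (n = 72):
#>     social    62.50%
#>     abstract  37.50%
```

Of 120 frames, 72 are attributable to a scene; 62.5 % of those looked at the
social scene (the right half of the screen under the default mapping).
Against the generator's ground truth this run classifies 97.5 % of frames
correctly — the three residual errors are lateral frames whose noisy ratio
landed marginally above the threshold in one eye, which demotes the frame to
`DISTRACTION` rather than crediting the wrong scene.

Validation against a manual annotation table (here: the ground truth at
every 5th frame) and a simulated two-group cohort:

```r
manual <- subsample(data.frame(frame_index = ses$truth$frame_index,
                               label = ses$truth$label), 5)
concordance_report(manual, auto$annotations)
#> Concordance over 14 jointly labelled LEFT/RIGHT frames
#>   frame agreement     1.0000
#>   Spearman rho        1.0000 (p = 0)
#>   proportion z        0.000 (p = 1)

co <- generate_cohort(cohort_spec(seed = 3))
compare_groups(transform(co, social_pct = 100 * social_pref),
               value = "social_pct")
#> Group comparison (mean (SE), 95% CI):
#>   ASD      (N =  8)  21.32 (3.63)  [12.73, 29.90]
#>   NON_ASD  (N = 23)  41.49 (3.74)  [33.74, 49.24]
#>   t = -2.995, df = 29.0, p = 0.005565
```

The 8-versus-23 cohort with group means of ~27 % and ~44 % social preference
is the default study condition of the generator; the t-test recovers the
group difference.

A command-line launcher wrapping the same functions ships at
`inst/scripts/gazepref` (subcommands `simulate`, `classify`, `calibrate`,
`validate`, `compare`).

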