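# wcebleed

Automatic bleeding **frame** and bleeding **region** detection for wireless
capsule endoscopy (WCE) images.

A capsule endoscopy exam yields tens of thousands of frames that a
clinician must screen for bleeding, which is fundamentally a colour
phenomenon. wcebleed implements a complete colour-based screening pipeline:

1. **Preprocessing** — crop the meaningless peripheral black border and
   mask the circular informative field (`strip_border()`), then map to
   normalized RGB chromaticity, r = R/(R+G+B) etc., discarding brightness
   while keeping hue (`normalize_rgb()`).
2. **ROI extraction** — keep the valid pixels satisfying two sequential
   linear chromaticity conditions, r ≥ m·b then r ≥ n·g, with calibrated
   defaults (m, n) = (2.8, 2.0) (`extract_roi()`); the surviving pixels are
   the candidate bleeding pixels. `sweep_slope()` re-derives the slopes
   from ground-truth masks by a grid sweep over pixel accuracy.
3. **Features** — the 64-bin histogram of the normalized-g plane restricted
   to the ROI, raw counts on fixed [0,1] bin edges (`feature_vector()`);
   histogram summary statistics are available as a baseline
   (`histogram_stats()`).
4. **Classification** — K-nearest-neighbour vote (Euclidean, K = 5) with
   stratified k-fold cross-validation and frame metrics sensitivity
   T_b/(T_b+F_nb), specificity T_nb/(T_nb+F_b) and accuracy
   (`knn_predict()`, `cross_validate()`, `frame_metrics()`).
5. **Region refinement** — morphological erosion then dilation (opening by
   default, disk radius 2) of the ROI on frames classified bleeding,
   scored by pixel-level FNR, FPR and precision (`refine_region()`,
   `region_metrics()`).
6. **Video smoothing** — an isolated nonbleeding label between two
   bleeding labels is relabelled bleeding (`postprocess_labels()`).

Because clinical WCE data with pixel ground truth is not freely
redistributable, the package includes a seeded **phantom generator**
(`generate_frame()`, `generate_dataset()`, `generate_video()`) producing
WCE-like frames — circular field, black border, mucosa background, red
bleeding blobs — with exact pixel ground truth, so the entire pipeline is
testable end to end. See the methods vignette
(`vignettes/wce-bleeding-detection.Rmd`) for the model, parameter and
design rationale.

## Worked example

```r
library(wcebleed)

# 300 phantom frames: 60 bleeding, 240 nonbleeding, 160x160 px
ds  <- generate_dataset(phantom_config(image_size = 160, border_band = 10),
                        n_bleeding = 60, n_nonbleeding = 240, seed = 1)
run <- run_pipeline(ds$frames, config = pipeline_config(seed = 1))

unclass(run$cv$counts)
#> $t_b:  60    $f_nb: 0    $t_nb: 240    $f_b: 0
run$cv$metrics
#> $sensitivity: 1    $specificity: 1    $accuracy: 1
run$region[c("fnr", "fpr", "precision")]
#> $fnr: 0.0035    $fpr: 0    $precision: 1
```

All 60 bleeding phantoms are recovered by the tenfold cross-validated
classifier with no false alarms, and the opened ROI covers the ground-truth
blobs almost exactly (0.35% of bleeding pixels lost to boundary smoothing,
no false-positive pixels). The phantom colour models are separable by
construction — this validates the machinery, not clinical performance.

A single frame looks like:

```r
fr  <- generate_frame(phantom_config(image_size = 160, border_band = 10),
                      bleeding = TRUE, seed = 2)
st  <- strip_border(fr$frame)          # 160x160 -> 140x140 crop
ch  <- normalize_rgb(st$frame, st$validity)
roi <- extract_roi(ch)                 # candidate bleeding pixels
sum(roi)                               # 623 of 15380 valid pixels
region <- refine_region(roi)           # smoothed bleeding region
```

A thin command-line front end over the same functions lives at
`inst/cli/wcebleed.R` (subcommands `synth`, `roi`, `features`, `classify`,
`video`; YAML configuration via `read_pipeline_config()`).

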