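#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end bleeding detection
#' pipeline with its calibrated default: ROI slopes m = 2.8 and n = 2.0,
#' g-plane 64-bin histogram features, K = 5 nearest neighbours with tenfold
#' stratified cross-validation, disk-radius-2 opening for region refinement
#' and a black threshold of 10 for border stripping. All randomness (fold
#' shuffling) flows from `seed`.
#'
#' @param m,n ROI slopes (see [roi_params()]).
#' @param planes,bins histogram feature configuration (see
#'   [feature_vector()]).
#' @param k,folds classifier configuration (see [cross_validate()]).
#' @param black_threshold border stripping threshold (see [strip_border()]).
#' @param erode_radius,dilate_radius,se_shape morphology configuration (see
#'   [structuring_element()]).
#' @param postprocess smooth the per-frame label sequence (video mode).
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(m = 2.8, n = 2.0, planes = "g", bins = 64,
                            k = 5, folds = 10, black_threshold = 10,
                            erode_radius = 2, dilate_radius = 2,
                            se_shape = "disk", postprocess = FALSE, seed = 1) {
  params <- roi_params(m, n)  # validates slopes
  if (bins < 2) stop("bins must be at least 2", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  if (folds < 2) stop("folds must be at least 2", call. = FALSE)
  structure(
    list(roi = params, planes = planes, bins = bins, k = k, folds = folds,
         black_threshold = black_threshold,
         erode_se = structuring_element(se_shape, erode_radius),
         dilate_se = structuring_element(se_shape, dilate_radius),
         postprocess = isTRUE(postprocess), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML mapping whose keys are the arguments of
#' [pipeline_config()]; unknown keys are an error so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  # keep the bare keys y/n as strings (YAML 1.1 would read them as booleans,
  # clobbering the slope parameter n) while still parsing true/false values
  as_bool <- function(x) {
    if (x %in% c("y", "Y", "n", "N")) x else tolower(x) %in% c("true", "yes", "on")
  }
  cfg <- yaml::yaml.load_file(path,
                              handlers = list("bool#yes" = as_bool,
                                              "bool#no" = as_bool))
  if (!is.list(cfg)) stop("config file must contain a YAML mapping", call. = FALSE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, cfg)
}

# strip + normalize + ROI + feature for one frame; truth cropped alongside
process_frame <- function(frame, truth, config) {
  st <- strip_border(frame, config$black_threshold)
  ch <- normalize_rgb(st$frame, st$validity)
  roi <- extract_roi(ch, config$roi)
  list(
    chrom = ch, roi = roi,
    truth = if (is.null(truth)) NULL else crop_mask(truth, st),
    features = feature_vector(ch, roi, planes = config$planes,
                              bins = config$bins)
  )
}

#' Run the full bleeding-detection pipeline on a labelled frame set
#'
#' Executes border stripping, chromaticity normalization, ROI extraction and
#' feature extraction on every frame; classifies the frames by seeded
#' stratified cross-validated KNN; refines the ROI of every frame the
#' classifier labels bleeding by morphological opening and (when ground
#' truth is available) pools the pixel-level region confusion over those
#' frames; in video mode additionally smooths the predicted label sequence
#' and reports metrics before and after smoothing.
#'
#' @param frames list of [rgb_frame()]s, of `generate_frame()` results, or a
#'   character vector of image paths.
#' @param labels character label vector (`"bleeding"` / `"nonbleeding"`);
#'   taken from the frame objects when omitted and available.
#' @param truths optional list of ground-truth masks on the uncropped frame
#'   grid (taken from frame objects when available).
#' @param config a [pipeline_config()].
#' @return A list of class `wce_run`: `features` (matrix), `cv`
#'   ([cross_validate()] result), `region` (pooled [region_metrics()] or
#'   `NULL`), `labels_raw`/`labels_post` (video mode), `metrics_post`
#'   (video mode), `config`, `n`.
#' @export
run_pipeline <- function(frames, labels = NULL, truths = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(frames)) frames <- lapply(frames, read_frame)
  # unpack generate_frame()-style bundles
  if (length(frames) && is.list(frames[[1]]) && !inherits(frames[[1]], "rgb_frame")) {
    if (is.null(labels))
      labels <- vapply(frames, function(f) f$label, character(1))
    if (is.null(truths)) truths <- lapply(frames, function(f) f$truth)
    frames <- lapply(frames, function(f) f$frame)
  }
  n <- length(frames)
  if (n == 0L) stop("no frames to process", call. = FALSE)
  if (is.null(labels)) stop("labels are required for classification", call. = FALSE)
  if (length(labels) != n) stop("one label per frame is required", call. = FALSE)
  if (config$folds > n)
    stop("configuration error: folds exceed the number of frames", call. = FALSE)

  processed <- lapply(seq_len(n), function(i)
    process_frame(frames[[i]],
                  if (is.null(truths)) NULL else truths[[i]], config))
  features <- do.call(rbind, lapply(processed, `[[`, "features"))

  cv <- cross_validate(features, labels, folds = config$folds, k = config$k,
                       seed = config$seed)

  region <- NULL
  detected <- which(cv$predictions == "bleeding")
  if (length(detected) && !is.null(truths)) {
    conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in detected) {
      p <- processed[[i]]
      if (is.null(p$truth)) next
      refined <- refine_region(p$roi, config$erode_se, config$dilate_se)
      rm_i <- region_metrics(refined, p$truth, p$chrom$valid)
      conf <- conf + unlist(rm_i$confusion)
    }
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    region <- structure(
      list(fnr = ratio(conf["fn"], conf["fn"] + conf["tp"]),
           fpr = ratio(conf["fp"], conf["fp"] + conf["tn"]),
           precision = ratio(conf["tp"], conf["tp"] + conf["fp"]),
           confusion = as.list(conf)),
      class = "region_metrics"
    )
  }

  out <- list(features = features, cv = cv, region = region,
              config = config, n = n)
  if (config$postprocess) {
    out$labels_raw <- cv$predictions
    out$labels_post <- postprocess_labels(cv$predictions)
    out$metrics_post <- frame_metrics(confusion_counts(out$labels_post, labels))
  }
  class(out) <- "wce_run"
  out
}

#' Machine-readable summary of a pipeline run
#'
#' Everything needed to reproduce the run: the configuration, seed, sample
#' size and pooled results, as a plain list serializable with
#' [jsonlite::toJSON()].
#'
#' @param object a `wce_run` from [run_pipeline()].
#' @param ... unused.
#' @return A named list.
#' @export
summary.wce_run <- function(object, ...) {
  cfg <- object$config
  list(
    n = object$n,
    config = list(m = cfg$roi$m, n = cfg$roi$n, planes = cfg$planes,
                  bins = cfg$bins, k = cfg$k, folds = cfg$folds,
                  black_threshold = cfg$black_threshold,
                  postprocess = cfg$postprocess, seed = cfg$seed),
    counts = unclass(object$cv$counts),
    metrics = object$cv$metrics,
    region = if (is.null(object$region)) NULL else
      list(fnr = unname(object$region$fnr), fpr = unname(object$region$fpr),
           precision = unname(object$region$precision)),
    metrics_post = object$metrics_post
  )
}
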