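#' Chromaticity colour model for phantom tissue
#'
#' Two parameterizations are supported. A *chromaticity* model samples each
#' pixel's (r, g, b) as `mean` plus independent uniform jitter of half-width
#' `jitter` per component, renormalized to sum 1 (renormalization preserves
#' the r/b and r/g ratios, so the jitter bounds directly bound the ratios).
#' A *ratio* model samples the ratios u = r/b and v = r/g uniformly on the
#' given ranges and solves r = 1 / (1 + 1/u + 1/v); it gives exact control
#' over where pixels fall relative to the ROI separating lines and is used
#' by the calibration phantom.
#'
#' @param mean length-3 chromaticity mean summing to 1 (chromaticity model).
#' @param jitter uniform jitter half-width per component.
#' @param rb,rg length-2 ranges for the r/b and r/g ratios (ratio model).
#' @return A list of class `color_model`.
#' @export
color_model <- function(mean = NULL, jitter = 0.05, rb = NULL, rg = NULL) {
  if (!is.null(mean)) {
    if (length(mean) != 3L || abs(sum(mean) - 1) > 1e-9)
      stop("chromaticity mean must have 3 components summing to 1", call. = FALSE)
    if (jitter < 0 || jitter >= min(mean))
      stop("jitter must be nonnegative and smaller than every mean component",
           call. = FALSE)
    structure(list(type = "chromaticity", mean = mean, jitter = jitter),
              class = "color_model")
  } else {
    if (is.null(rb) || is.null(rg) || length(rb) != 2L || length(rg) != 2L ||
        any(c(rb, rg) <= 0) || rb[1] > rb[2] || rg[1] > rg[2])
      stop("ratio model needs increasing positive rb and rg ranges", call. = FALSE)
    structure(list(type = "ratio", rb = rb, rg = rg), class = "color_model")
  }
}

# ratio bounds (r/b, r/g) attainable under a colour model
model_ratio_bounds <- function(model) {
  if (model$type == "ratio") {
    list(rb = model$rb, rg = model$rg)
  } else {
    m <- model$mean; j <- model$jitter
    list(rb = c((m[1] - j) / (m[3] + j), (m[1] + j) / max(m[3] - j, 1e-9)),
         rg = c((m[1] - j) / (m[2] + j), (m[1] + j) / max(m[2] - j, 1e-9)))
  }
}

# n x 3 chromaticity samples from a colour model (rows sum to 1)
sample_chrom <- function(model, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (model$type == "chromaticity") {
    x <- matrix(rep(model$mean, each = n), n, 3) +
      matrix(stats::runif(3 * n, -model$jitter, model$jitter), n, 3)
    x <- pmax(x, 1e-3)
    x / rowSums(x)
  } else {
    u <- stats::runif(n, model$rb[1], model$rb[2])
    v <- stats::runif(n, model$rg[1], model$rg[2])
    r <- 1 / (1 + 1 / u + 1 / v)
    cbind(r, r / v, r / u)
  }
}

#' Phantom frame generator configuration
#'
#' Describes synthetic WCE-like frames: a circular informative field inside a
#' square black border band, mucosa-coloured background, and (on bleeding
#' frames) red blobs with pixel ground truth. Defaults mirror the structure
#' of clinical capsule frames: 576 x 576 pixels with a 32-pixel black band,
#' a bleeding colour model that satisfies the ROI conditions
#' (r >= 2.8 b, r >= 2.0 g) with margin and a mucosa model that violates the
#' r--g condition with margin. Blob radii are given as fractions of the
#' informative-field radius so one configuration remains valid at any frame
#' size.
#'
#' @param image_size side length of the square frame, pixels.
#' @param border_band width of the black margin on each side, pixels.
#' @param mucosa,bleeding [color_model()]s for background tissue and blood.
#' @param blob_count integer range (min, max) of blobs per bleeding frame.
#' @param blob_radius_frac range of blob radius as a fraction of the field
#'   radius, in (0, 1].
#' @param speck_count integer range of isolated single bleeding-like pixels
#'   added outside the ground truth (below any credible blob size; they
#'   exercise the morphological cleanup).
#' @param brightness range of per-pixel total intensity R+G+B before
#'   quantization; the default keeps every channel below 255 for both colour
#'   models.
#' @param radial_falloff optional brightness attenuation at the field edge in
#'   \[0, 1\) (0 disables).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 576, border_band = 32,
                           mucosa = color_model(c(0.45, 0.33, 0.22), 0.05),
                           bleeding = color_model(c(0.65, 0.20, 0.15), 0.05),
                           blob_count = c(1, 3),
                           blob_radius_frac = c(0.10, 0.35),
                           speck_count = c(0, 5),
                           brightness = c(210, 330),
                           radial_falloff = 0) {
  if (image_size - 2 * border_band < 8)
    stop("informative field too small for the given border band", call. = FALSE)
  if (any(blob_radius_frac <= 0) || any(blob_radius_frac > 1))
    stop("blob_radius_frac must lie in (0, 1]", call. = FALSE)
  if (blob_count[1] > blob_count[2] || blob_count[1] < 1)
    stop("blob_count must be an increasing range with min >= 1", call. = FALSE)
  if (radial_falloff < 0 || radial_falloff >= 1)
    stop("radial_falloff must lie in [0, 1)", call. = FALSE)
  bb <- model_ratio_bounds(bleeding)
  if (!(bb$rb[1] > 2.8 && bb$rg[1] > 2.0))
    stop("bleeding colour model must satisfy r > 2.8 b and r > 2.0 g with margin",
         call. = FALSE)
  mb <- model_ratio_bounds(mucosa)
  if (!(mb$rb[2] < 2.8 || mb$rg[2] < 2.0))
    stop("mucosa colour model must violate at least one ROI condition with margin",
         call. = FALSE)
  structure(
    list(image_size = as.integer(image_size),
         border_band = as.integer(border_band),
         mucosa = mucosa, bleeding = bleeding,
         blob_count = as.integer(blob_count),
         blob_radius_frac = blob_radius_frac,
         speck_count = as.integer(speck_count),
         brightness = brightness, radial_falloff = radial_falloff),
    class = "phantom_config"
  )
}

#' Calibration phantom configuration for slope recovery
#'
#' A configuration whose colour models straddle the (m, n) = (2.8, 2.0)
#' separating lines: mucosa r/b is uniform on \[2.1, 3.4\] (overlapping the
#' bleeding range \[2.85, 3.2\]) while mucosa r/g stays below 2.0 and
#' bleeding r/g above it, and blobs cover roughly 40--55% of the field so
#' bleeding and mucosa pixel counts are comparable. Under these densities
#' the pixel-accuracy objective of [sweep_slope()] has its maximum at
#' m = 2.8 and, with m fixed there, at n = 2.0 (see the methods vignette for
#' the derivation).
#'
#' @param image_size,border_band as in [phantom_config()].
#' @return A [phantom_config()].
#' @export
phantom_calibration_config <- function(image_size = 192, border_band = 12) {
  phantom_config(
    image_size = image_size, border_band = border_band,
    mucosa = color_model(rb = c(2.1, 3.4), rg = c(1.3, 1.95)),
    bleeding = color_model(rb = c(2.85, 3.2), rg = c(2.05, 2.7)),
    blob_count = c(1, 1),
    blob_radius_frac = c(0.75, 0.85),
    speck_count = c(0, 0)
  )
}

# one blob geometry: union of 3 jittered ellipses around a common center
sample_blob_geometry <- function(config, field_radius, center) {
  frac <- stats::runif(1, config$blob_radius_frac[1], config$blob_radius_frac[2])
  rad <- frac * field_radius
  if (rad > field_radius)
    stop("blob radius exceeds the field radius", call. = FALSE)
  slack <- field_radius - rad
  ang <- stats::runif(1, 0, 2 * pi)
  dist <- slack * sqrt(stats::runif(1))
  cy <- center[1] + dist * sin(ang)
  cx <- center[2] + dist * cos(ang)
  ellipses <- lapply(1:3, function(e) {
    list(cy = cy + stats::runif(1, -0.25, 0.25) * rad,
         cx = cx + stats::runif(1, -0.25, 0.25) * rad,
         a = stats::runif(1, 0.65, 1) * rad * 0.75,
         b = stats::runif(1, 0.65, 1) * rad * 0.75,
         theta = stats::runif(1, 0, pi))
  })
  list(cy = cy, cx = cx, radius = rad, ellipses = ellipses)
}

rasterize_blob <- function(geom, rowg, colg) {
  out <- matrix(FALSE, nrow(rowg), ncol(rowg))
  for (el in geom$ellipses) {
    dy <- rowg - el$cy
    dx <- colg - el$cx
    u <- dx * cos(el$theta) + dy * sin(el$theta)
    v <- -dx * sin(el$theta) + dy * cos(el$theta)
    out <- out | ((u / el$a)^2 + (v / el$b)^2 <= 1)
  }
  out
}

# small positional/size jitter for temporal coherence in videos
jitter_blob_geometry <- function(geoms, field_radius, center) {
  lapply(geoms, function(g) {
    dy <- stats::runif(1, -2, 2)
    dx <- stats::runif(1, -2, 2)
    sc <- stats::runif(1, 0.95, 1.05)
    g$cy <- g$cy + dy; g$cx <- g$cx + dx
    g$ellipses <- lapply(g$ellipses, function(el) {
      el$cy <- el$cy + dy; el$cx <- el$cx + dx
      el$a <- el$a * sc; el$b <- el$b * sc
      el
    })
    g
  })
}

gen_frame_impl <- function(config, bleeding, geometry = NULL) {
  S <- config$image_size
  w <- config$border_band
  C <- S - 2L * w
  R0 <- C / 2
  center <- c(w + (C + 1) / 2, w + (C + 1) / 2)
  rowg <- matrix(seq_len(S), S, S)
  colg <- matrix(seq_len(S), S, S, byrow = TRUE)
  d2 <- (rowg - center[1])^2 + (colg - center[2])^2
  field <- d2 <= R0^2

  truth <- matrix(FALSE, S, S)
  geoms <- NULL
  if (bleeding) {
    if (is.null(geometry)) {
      k <- if (config$blob_count[1] == config$blob_count[2]) config$blob_count[1]
           else sample(config$blob_count[1]:config$blob_count[2], 1)
      geoms <- lapply(seq_len(k), function(i)
        sample_blob_geometry(config, R0, center))
    } else {
      geoms <- geometry
    }
    for (g in geoms) truth <- truth | rasterize_blob(g, rowg, colg)
    truth <- truth & field
  }

  chrom <- matrix(0, S * S, 3)
  muc_idx <- which(field & !truth)
  chrom[muc_idx, ] <- sample_chrom(config$mucosa, length(muc_idx))
  blood_idx <- which(truth)
  chrom[blood_idx, ] <- sample_chrom(config$bleeding, length(blood_idx))

  # isolated bleeding-like specks, never part of the ground truth
  ns <- if (config$speck_count[2] == 0) 0L
        else sample(config$speck_count[1]:config$speck_count[2], 1)
  if (ns > 0L && length(muc_idx) > ns) {
    sp <- sample(muc_idx, ns)
    chrom[sp, ] <- sample_chrom(config$bleeding, ns)
  }

  bright <- stats::runif(S * S, config$brightness[1], config$brightness[2])
  if (config$radial_falloff > 0)
    bright <- bright * (1 - config$radial_falloff * pmin(d2 / R0^2, 1))
  inside <- as.vector(field)
  mk <- function(col) {
    v <- numeric(S * S)
    v[inside] <- round(chrom[inside, col] * bright[inside])
    matrix(pmin(pmax(v, 0), 255), S, S)
  }
  list(frame = rgb_frame(mk(1), mk(2), mk(3)),
       truth = truth,
       label = if (bleeding) "bleeding" else "nonbleeding",
       geometry = geoms)
}

#' Generate one synthetic WCE-like frame with ground truth
#'
#' Produces an 8-bit RGB frame with a circular informative field inside a
#' black border band, mucosa-coloured background and, for bleeding frames,
#' red blobs whose pixels form the ground-truth mask. Nonbleeding frames may
#' carry a few isolated bleeding-like pixels (ground truth stays empty).
#' Chromaticity is sampled per pixel from the configured colour models,
#' scaled by a per-pixel brightness, and quantized last, so recovered
#' chromaticity is exact only up to quantization noise (about 2/255 per
#' component at the default brightness).
#'
#' @param config a [phantom_config()].
#' @param bleeding logical: generate a bleeding frame?
#' @param seed optional integer; identical seeds give bit-identical frames.
#' @return A list with `frame` ([rgb_frame()]), `truth` (logical matrix on
#'   the full frame grid; use [crop_mask()] after [strip_border()]), `label`,
#'   and the internal blob `geometry`.
#' @export
generate_frame <- function(config, bleeding = TRUE, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(seed)) gen_frame_impl(config, bleeding)
  else withr::with_seed(as.integer(seed), gen_frame_impl(config, bleeding))
}

#' Generate a labelled phantom dataset
#'
#' Reproducible set of bleeding and nonbleeding frames with per-frame seeds
#' derived from the master seed, mirroring the class structure of a frame
#' collection at arbitrary scale.
#'
#' @param config a [phantom_config()].
#' @param n_bleeding,n_nonbleeding class counts (>= 0).
#' @param seed master integer seed.
#' @return A list with `frames` (list of [generate_frame()] results) and
#'   `manifest` (data.frame: `frame_id`, `label`, `seed`).
#' @export
generate_dataset <- function(config, n_bleeding, n_nonbleeding, seed = 1) {
  n <- n_bleeding + n_nonbleeding
  labels <- rep(c("bleeding", "nonbleeding"), c(n_bleeding, n_nonbleeding))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, max(n, 1L)))
  frames <- lapply(seq_len(n), function(i)
    generate_frame(config, labels[i] == "bleeding", seed = seeds[i]))
  manifest <- data.frame(
    frame_id = sprintf("frame_%04d", seq_len(n)),
    label = labels,
    seed = seeds[seq_len(n)],
    stringsAsFactors = FALSE
  )
  list(frames = frames, manifest = manifest)
}

#' Generate a temporally coherent phantom video
#'
#' One frame per entry of `label_pattern`; consecutive bleeding frames share
#' their blob geometry up to a small positional/size jitter, emulating a
#' continuous bleed seen across neighbouring frames. Appearance (mucosa
#' texture, brightness) is resampled every frame.
#'
#' @param config a [phantom_config()].
#' @param label_pattern character vector of `"bleeding"` / `"nonbleeding"`
#'   (or the shorthands `"B"` / `"N"`), length >= 1.
#' @param seed master integer seed.
#' @return A list with `frames` (list of per-frame results) and `labels`
#'   (normalized pattern).
#' @export
generate_video <- function(config, label_pattern, seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(label_pattern) < 1L) stop("pattern must be nonempty", call. = FALSE)
  lab <- ifelse(label_pattern %in% c("B", "bleeding"), "bleeding",
         ifelse(label_pattern %in% c("N", "nonbleeding"), "nonbleeding", NA))
  if (anyNA(lab)) stop("pattern entries must be bleeding/nonbleeding (B/N)",
                       call. = FALSE)
  withr::with_seed(as.integer(seed), {
    S <- config$image_size
    w <- config$border_band
    R0 <- (S - 2L * w) / 2
    center <- c(w + (S - 2L * w + 1) / 2, w + (S - 2L * w + 1) / 2)
    geoms <- NULL
    frames <- vector("list", length(lab))
    for (i in seq_along(lab)) {
      if (lab[i] == "bleeding") {
        geoms <- if (is.null(geoms)) NULL else jitter_blob_geometry(geoms, R0, center)
        frames[[i]] <- gen_frame_impl(config, TRUE, geometry = geoms)
        geoms <- frames[[i]]$geometry
      } else {
        frames[[i]] <- gen_frame_impl(config, FALSE)
        # a nonbleeding gap ends the current bleed; a new one gets new geometry
        geoms <- NULL
      }
    }
    list(frames = frames, labels = lab)
  })
}
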