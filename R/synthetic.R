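#' Scenario configuration for the synthetic generator
#'
#' Describes the scenes and the simulated binary-network outputs. Scenes
#' contain 0-3 classes of smooth elongated tubular structures (emulating
#' vessels, ureters and nerves, which may co-occur in one frame) on a
#' textured background. Probability maps are corrupted versions of the
#' per-class ground truth: Gaussian blur softens structure boundaries, a
#' logistic calibration curve pushes interiors towards 1 and background
#' towards 0, cross-class confusion leaks confident responses onto
#' visually similar classes, speckle flips isolated pixels, and false
#' blobs add spurious high-confidence background responses.
#'
#' Default presence probabilities (0.80, 0.43, 0.25) reproduce the class
#' imbalance typical of surgical scenes where the artery is visible in most
#' frames and nerves only rarely.
#'
#' @param width,height Scene dimensions in pixels.
#' @param class_ids Class ids rendered, ascending.
#' @param presence Per-class probability that the class occurs in a scene.
#' @param tube_count_range Min/max tubular structures per present class.
#' @param tube_width_range Min/max structure thickness in pixels.
#' @param curvature Wiggliness of the structures (0 = straight, 1 = very
#'   curved); scales the lateral spread of the spline control points.
#' @param blur_sigma Gaussian blur sigma in pixels applied to each binary
#'   support (0 disables).
#' @param speckle_rate Per-pixel probability of a confidence flip
#'   `p -> 1 - p`.
#' @param confusion_rate Fraction of another class's support that leaks a
#'   confidently wrong response into each map; scalar or one value per
#'   class (the rate at which *that* class's map picks up leaks).
#' @param false_blob_rate Expected count of spurious high-confidence blobs
#'   per map; scalar or per class.
#' @param calibration_sharpness Slope of the logistic calibration curve;
#'   `Inf` yields hard 0/1 maps (the noiseless limit).
#' @param seed Optional integer seed; identical configurations with the
#'   same seed produce bit-identical outputs.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(width = 192, height = 192, class_ids = 1:3,
                            presence = c(0.80, 0.43, 0.25),
                            tube_count_range = c(1, 2),
                            tube_width_range = c(6, 14),
                            curvature = 0.5,
                            blur_sigma = 1.5,
                            speckle_rate = 0.002,
                            confusion_rate = 0.1,
                            false_blob_rate = 1,
                            calibration_sharpness = 8,
                            seed = NULL) {
  nc <- length(class_ids)
  presence <- rep_len(presence, nc)
  confusion_rate <- rep_len(confusion_rate, nc)
  false_blob_rate <- rep_len(false_blob_rate, nc)
  stopifnot(
    width > 0, height > 0,
    all(presence >= 0 & presence <= 1),
    all(confusion_rate >= 0 & confusion_rate <= 1),
    all(speckle_rate >= 0 & speckle_rate <= 1),
    all(false_blob_rate >= 0),
    blur_sigma >= 0, calibration_sharpness > 0,
    tube_width_range[1] >= 1, tube_count_range[1] >= 0
  )
  if (max(tube_width_range) >= min(width, height)) {
    stop("structure width exceeds the image size")
  }
  structure(
    list(width = width, height = height, class_ids = as.integer(class_ids),
         presence = presence, tube_count_range = tube_count_range,
         tube_width_range = tube_width_range, curvature = curvature,
         blur_sigma = blur_sigma, speckle_rate = speckle_rate,
         confusion_rate = confusion_rate, false_blob_rate = false_blob_rate,
         calibration_sharpness = calibration_sharpness, seed = seed),
    class = "scenario_config"
  )
}

#' Noise-free scenario configuration
#'
#' Convenience wrapper: all corruption channels off and a hard calibration
#' curve, so simulated probability maps equal the binarized ground truth
#' exactly and every fusion operator recovers the ground truth.
#'
#' @param ... Passed to [scenario_config()] (e.g. `width`, `seed`).
#' @return A `scenario_config`.
#' @export
noiseless_config <- function(...) {
  scenario_config(blur_sigma = 0, speckle_rate = 0, confusion_rate = 0,
                  false_blob_rate = 0, calibration_sharpness = Inf, ...)
}

# Smooth open spline of control points across the image; returns dense
# (x, y) samples. Used for tubular structure centerlines.
tube_centerline <- function(config, base = NULL, jitter = 0) {
  w <- config$width
  h <- config$height
  n_ctrl <- 5L
  if (is.null(base)) {
    # a path crossing the frame with lateral wander set by curvature
    t0 <- runif(1, 0, 2 * pi)
    cx <- seq(runif(1, 0, 0.25), runif(1, 0.75, 1), length.out = n_ctrl)
    lat <- runif(1, 0.2, 0.8) +
      cumsum(rnorm(n_ctrl, 0, 0.12 * config$curvature + 0.01))
    base <- cbind(cx, pmin(0.95, pmax(0.05, lat)))
    # random orientation: maybe swap axes
    if (runif(1) < 0.5) base <- base[, 2:1]
    attr(base, "angle") <- t0
  }
  ctrl <- base + matrix(rnorm(length(base), 0, jitter), nrow(base))
  ctrl[, 1] <- pmin(1, pmax(0, ctrl[, 1]))
  ctrl[, 2] <- pmin(1, pmax(0, ctrl[, 2]))
  tt <- seq(0, 1, length.out = nrow(ctrl))
  dense <- seq(0, 1, length.out = 40L * max(w, h) %/% 10L)
  sx <- stats::spline(tt, ctrl[, 1], xout = dense)$y
  sy <- stats::spline(tt, ctrl[, 2], xout = dense)$y
  list(x = sx * (w - 1), y = sy * (h - 1), base = base)
}

# Stamp a thick curve onto a mask: union of discs along the centerline.
stamp_tube <- function(mask, line, radius) {
  h <- nrow(mask)
  w <- ncol(mask)
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  cyx <- cbind(round(line$y) + 1L, round(line$x) + 1L)
  cyx <- unique(cyx)
  rows <- rep(cyx[, 1L], each = nrow(off)) + off$dy
  cols <- rep(cyx[, 2L], each = nrow(off)) + off$dx
  ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  mask[cbind(rows[ok], cols[ok])] <- 1L
  mask
}

# Draw the per-scene geometry: which classes occur and their tube
# centerline control points / widths. Shared within a synthetic "video".
# Distinct anatomical structures co-occur in a frame but occupy disjoint
# pixel supports, so each new tube is redrawn (up to 25 attempts) until it
# clears the already placed structures by at least a one-pixel margin; a
# structure that cannot be placed is dropped (the scene simply holds fewer
# organs, as a crowded frame would).
scene_geometry <- function(config) {
  geom <- list()
  occupied <- matrix(FALSE, config$height, config$width)
  for (i in seq_along(config$class_ids)) {
    if (runif(1) >= config$presence[i]) next
    n_tubes <- sample(seq(config$tube_count_range[1],
                          config$tube_count_range[2]), 1L)
    tubes <- list()
    margin <- dilate1(occupied)
    for (j in seq_len(n_tubes)) {
      placed <- FALSE
      for (att in seq_len(25L)) {
        radius <- runif(1, config$tube_width_range[1],
                        config$tube_width_range[2]) / 2
        line <- tube_centerline(config)
        cand <- stamp_tube(matrix(0L, config$height, config$width),
                           line, radius) == 1L
        if (!any(cand & margin)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      occupied <- occupied | cand
      margin <- margin | dilate1(cand)
      tubes[[length(tubes) + 1L]] <- list(base = line$base, radius = radius)
    }
    if (length(tubes) > 0L) {
      geom[[as.character(config$class_ids[i])]] <- tubes
    }
  }
  geom
}

# one-step 8-neighbourhood dilation
dilate1 <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  out <- m
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      ys <- max(1, 1 + dy):min(h, h + dy)
      xs <- max(1, 1 + dx):min(w, w + dx)
      sub <- matrix(FALSE, h, w)
      sub[ys, xs] <- m[ys - dy, xs - dx]
      out <- out | sub
    }
  }
  out
}

render_scene <- function(geom, config, jitter = 0) {
  w <- config$width
  h <- config$height
  masks <- list()
  present <- names(geom)
  for (cid in as.character(config$class_ids)) {
    m <- matrix(0L, h, w)
    for (tube in geom[[cid]]) {
      line <- tube_centerline(config, base = tube$base, jitter = jitter)
      m <- stamp_tube(m, line, tube$radius)
    }
    masks[[cid]] <- m
  }
  labels <- merge_class_masks(masks, config$class_ids)
  attr(labels, "overlap_pixels") <- NULL
  # textured background + per-class tint, loosely endoscopic-looking
  base <- matrix(runif(h * w, 0.25, 0.45), h, w)
  if (config$blur_sigma > 0) base <- EBImage::gblur(base, sigma = 2)
  img <- array(rep(base, 3L), dim = c(h, w, 3L))
  tint <- rbind(c(0.8, 0.2, 0.2), c(0.2, 0.7, 0.3), c(0.9, 0.9, 0.5))
  for (i in seq_along(config$class_ids)) {
    sel <- labels == config$class_ids[i]
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[sel] <- tint[(i - 1L) %% 3L + 1L, ch]
      img[, , ch] <- pl
    }
  }
  list(image = img, labels = labels)
}

#' Generate one synthetic scene
#'
#' Renders 0-3 families of smooth tubular structures (one family per
#' present class; classes co-occur independently with their presence
#' probabilities) on a textured background and returns the RGB frame
#' together with its exact multi-class label map. Deterministic under
#' `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list with `image` (`H x W x 3` array in `[0,1]`) and `labels`
#'   (integer label map).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  render_scene(scene_geometry(config), config)
}

#' Simulate binary-network probability maps from a ground truth
#'
#' Stands in for a bank of trained one-vs-all segmentation networks: for
#' each class, the binarized ground-truth support is blurred, squashed
#' through a logistic calibration curve, and corrupted with cross-class
#' confusion (confidently wrong responses on other classes' structures),
#' speckle flips, and spurious false-positive blobs on the background.
#' All outputs lie in `[0, 1]`. With every corruption disabled and
#' infinite calibration sharpness (see [noiseless_config()]) each map
#' equals its binarized ground truth exactly.
#'
#' @param gt Integer ground-truth label map.
#' @param config A [scenario_config()]; its `seed`, when non-`NULL`, makes
#'   the corruption reproducible.
#' @return A [prob_maps] object over `config$class_ids`.
#' @export
simulate_probability_maps <- function(gt, config) {
  stopifnot(inherits(config, "scenario_config"))
  gt <- validate_label_map(gt, config$class_ids)
  if (!is.null(config$seed)) set.seed(config$seed)
  h <- nrow(gt)
  w <- ncol(gt)
  s <- config$calibration_sharpness
  maps <- vector("list", length(config$class_ids))
  for (i in seq_along(config$class_ids)) {
    cid <- config$class_ids[i]
    base <- (gt == cid) * 1
    raw <- if (config$blur_sigma > 0) {
      pmin(1, pmax(0, EBImage::gblur(base, sigma = config$blur_sigma)))
    } else {
      base
    }
    p <- if (is.finite(s)) stats::plogis(s * (raw - 0.5)) else (raw >= 0.5) * 1
    # confusion: other classes' structures elicit confidently wrong responses
    if (config$confusion_rate[i] > 0) {
      others <- which(gt != 0L & gt != cid)
      if (length(others) > 0L) {
        sel <- others[runif(length(others)) < config$confusion_rate[i]]
        p[sel] <- pmax(p[sel], runif(length(sel), 0.96, 1))
      }
    }
    # speckle: isolated confidence flips in either direction
    if (config$speckle_rate > 0) {
      sel <- which(runif(h * w) < config$speckle_rate)
      p[sel] <- 1 - p[sel]
    }
    # false blobs: compact spurious activations on the background
    nb <- if (config$false_blob_rate[i] > 0) {
      stats::rpois(1, config$false_blob_rate[i])
    } else 0L
    for (b in seq_len(nb)) {
      m <- matrix(0L, h, w)
      ctr <- list(x = runif(1, 0, w - 1), y = runif(1, 0, h - 1))
      m <- stamp_tube(m, ctr, radius = runif(1, 3, 8))
      conf <- runif(1, 0.55, 0.8)
      sel <- which(m == 1L & gt == 0L)
      p[sel] <- pmax(p[sel], conf)
    }
    maps[[i]] <- matrix(pmin(1, pmax(0, p)), h, w)
  }
  prob_maps(maps, config$class_ids)
}

#' Generate a synthetic multi-video dataset
#'
#' Emits a full fixture set: RGB frames, ground-truth masks, simulated
#' probability maps and a dataset index. Frames of one synthetic "video"
#' share their structure geometry (same organs, slightly jittered
#' centerlines frame to frame), reproducing the within-video frame
#' similarity that motivates video-grouped splitting. Optionally writes
#' the tree to disk (PNG frames and masks, 16-bit TIFF probability maps,
#' CSV index).
#'
#' @param n_videos,frames_per_video Positive counts.
#' @param config A [scenario_config()]; `config$seed` drives the whole
#'   dataset deterministically.
#' @param dir Optional output directory; created if missing.
#' @return A list with `index` (data frame: `image_id`, `video_id`),
#'   `images`, `masks`, `map_sets` (named lists keyed by image id).
#' @export
generate_dataset <- function(n_videos, frames_per_video, config,
                             dir = NULL) {
  stopifnot(n_videos >= 1, frames_per_video >= 1,
            inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  images <- masks <- map_sets <- list()
  rows <- list()
  inner <- config
  inner$seed <- NULL   # one RNG stream for the whole dataset
  for (v in seq_len(n_videos)) {
    geom <- scene_geometry(inner)
    vid <- sprintf("video%03d", v)
    for (f in seq_len(frames_per_video)) {
      iid <- sprintf("%s_frame%03d", vid, f)
      scn <- render_scene(geom, inner, jitter = 0.015)
      pm <- simulate_probability_maps(scn$labels, inner)
      images[[iid]] <- scn$image
      masks[[iid]] <- scn$labels
      map_sets[[iid]] <- pm
      rows[[length(rows) + 1L]] <- data.frame(image_id = iid, video_id = vid)
    }
  }
  index <- do.call(rbind, rows)
  out <- list(index = index, images = images, masks = masks,
              map_sets = map_sets)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}
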