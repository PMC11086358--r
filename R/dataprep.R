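#' Rasterize a closed boundary polygon to a binary mask
#'
#' Fills the interior of a closed annotation polygon under the even-odd
#' rule, testing pixel centers at integer coordinates; pixels whose center
#' lies exactly on a polygon edge count as foreground. Coordinates are
#' 0-based with x = column and y = row, so a mask of width W spans centers
#' x = 0..W-1.
#'
#' @param polygon Numeric matrix with two columns (x, y), one vertex per
#'   row, at least 3 vertices; the polygon is implicitly closed. Vertex
#'   order (clockwise or counter-clockwise) does not matter.
#' @param width,height Output mask dimensions in pixels.
#' @return An integer 0/1 matrix of `height` rows by `width` columns.
#' @examples
#' rect <- cbind(c(1, 4, 4, 1), c(1, 1, 3, 3))
#' sum(rasterize_boundary(rect, 6, 5))  # 12 covered pixel centers
#' @export
rasterize_boundary <- function(polygon, width, height) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must have at least 3 (x, y) vertices")
  }
  if (anyNA(polygon)) stop("polygon contains missing coordinates")
  px <- polygon[, 1L]
  py <- polygon[, 2L]
  if (any(px < 0 | px > width - 1 | py < 0 | py > height - 1)) {
    stop("polygon vertices fall outside the image bounds")
  }
  # shoelace area; zero-area polygons are degenerate annotations
  nx <- c(px[-1L], px[1L])
  ny <- c(py[-1L], py[1L])
  if (abs(sum(px * ny - nx * py)) / 2 < .Machine$double.eps^0.5) {
    stop("degenerate polygon: zero area")
  }
  x0 <- max(0L, floor(min(px)))
  x1 <- min(width - 1L, ceiling(max(px)))
  y0 <- max(0L, floor(min(py)))
  y1 <- min(height - 1L, ceiling(max(py)))
  gx <- x0:x1
  gy <- y0:y1
  cx <- rep(gx, each = length(gy))   # column-major over (gy, gx) grid
  cy <- rep(gy, times = length(gx))
  crossings <- integer(length(cx))
  on_edge <- logical(length(cx))
  eps <- 1e-9
  for (e in seq_len(nrow(polygon))) {
    x1e <- px[e]; y1e <- py[e]
    x2e <- nx[e]; y2e <- ny[e]
    # even-odd crossing test for a rightward ray from the pixel center
    straddles <- (y1e > cy) != (y2e > cy)
    if (any(straddles)) {
      xi <- (x2e - x1e) * (cy[straddles] - y1e) / (y2e - y1e) + x1e
      hit <- cx[straddles] < xi
      idx <- which(straddles)[hit]
      crossings[idx] <- crossings[idx] + 1L
    }
    # centers lying on the edge segment are foreground by convention
    dxe <- x2e - x1e; dye <- y2e - y1e
    len2 <- dxe^2 + dye^2
    t <- ((cx - x1e) * dxe + (cy - y1e) * dye) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (cx - (x1e + t * dxe))^2 + (cy - (y1e + t * dye))^2
    on_edge <- on_edge | d2 < eps
  }
  inside <- (crossings %% 2L == 1L) | on_edge
  mask <- matrix(0L, height, width)
  mask[cbind(cy + 1L, cx + 1L)[inside, , drop = FALSE]] <- 1L
  mask
}

#' Merge per-class binary masks into one ground-truth label map
#'
#' Stacks the filled per-class masks into a single multi-class label map.
#' Background wherever every mask is 0; where masks overlap, the lowest
#' class id takes precedence (deterministic), and the number of overlapping
#' pixels is recorded in the `"overlap_pixels"` attribute so annotation
#' conflicts are visible rather than silent.
#'
#' @param masks List of 0/1 matrices sharing dimensions, one per class.
#' @param class_ids Integer class id of each mask; default `seq_along`.
#' @return Integer label map with attribute `overlap_pixels`.
#' @export
merge_class_masks <- function(masks, class_ids = seq_along(masks)) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("`masks` must be a non-empty list")
  }
  class_ids <- as.integer(class_ids)
  ref <- dim(as.matrix(masks[[1L]]))
  for (i in seq_along(masks)) {
    if (!identical(dim(as.matrix(masks[[i]])), ref)) {
      stop(sprintf("mask for class %d has mismatched dimensions", class_ids[i]))
    }
  }
  cover <- Reduce(`+`, lapply(masks, function(m) (as.matrix(m) != 0) * 1L))
  out <- matrix(0L, ref[1L], ref[2L])
  for (i in order(class_ids, decreasing = TRUE)) {  # lowest id written last
    out[as.matrix(masks[[i]]) != 0] <- class_ids[i]
  }
  attr(out, "overlap_pixels") <- sum(cover > 1L)
  out
}

#' Binarize one class of a label map
#'
#' One-vs-all decomposition of a multi-class label map: 1 where the map
#' equals class `c`, 0 elsewhere. Summed over all classes the binarized
#' masks reconstruct the foreground indicator.
#'
#' @param labels Integer label map.
#' @param c A single declared class id.
#' @param class_ids Admissible class ids.
#' @return Integer 0/1 matrix.
#' @export
binarize_mask <- function(labels, c, class_ids = 1:3) {
  check_class_id(c, class_ids)
  labels <- validate_label_map(labels, class_ids)
  m <- (labels == c) * 1L
  dim(m) <- dim(labels)
  m
}

#' Constrained random-crop augmentation
#'
#' Draws `n` square sub-images from an annotated frame, each required to
#' contain at least `min_fraction` of the frame's total labeled
#' (non-background) pixels. Windows are sampled by seeded rejection
#' sampling of uniform top-left corners; if `max_attempts` draws are all
#' rejected, a deterministic fallback is used: the window centered on the
#' foreground centroid (clamped to the image), or, should that window also
#' fail the constraint, the window with maximum labeled coverage. If no
#' window at all can satisfy the constraint, an error reports the best
#' achievable fraction. Duplicate windows are permitted.
#'
#' @param image Numeric matrix or `H x W x C` array (the frame).
#' @param labels Integer label map of the frame (same height/width).
#' @param n Number of crops; default 24.
#' @param side Square window side in pixels; default 512.
#' @param min_fraction Minimum fraction of the frame's labeled pixels each
#'   crop must contain; default 1/3.
#' @param seed Optional RNG seed for reproducible windows.
#' @param max_attempts Rejection-sampling budget per crop; default 1000.
#' @param class_ids Admissible class ids.
#' @return A list of `n` crops; each a list with `image`, `labels`, and
#'   `window` (0-based `x`, `y` of the top-left corner, `side`, and the
#'   labeled `fraction` retained).
#' @export
slice_crops <- function(image, labels, n = 24, side = 512,
                        min_fraction = 1 / 3, seed = NULL,
                        max_attempts = 1000, class_ids = 1:3) {
  labels <- validate_label_map(labels, class_ids)
  h <- nrow(labels)
  w <- ncol(labels)
  img_dim <- dim(image)
  if (img_dim[1L] != h || img_dim[2L] != w) {
    stop("image and label dimensions differ")
  }
  if (h < side || w < side) {
    stop(sprintf("image %dx%d is smaller than the %d-pixel window", h, w, side))
  }
  total_fg <- sum(labels != 0L)
  if (total_fg == 0L) {
    stop("label map is entirely background; the crop constraint is unsatisfiable")
  }
  counts <- window_fg_counts(labels, side)      # (h-side+1) x (w-side+1)
  best <- which.max(counts)
  best_frac <- counts[best] / total_fg
  if (best_frac < min_fraction) {
    stop(sprintf(
      "no %dx%d window contains %.4f of the labeled pixels (best achievable: %.4f)",
      side, side, min_fraction, best_frac
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  need <- min_fraction * total_fg
  fg_idx <- which(labels != 0L)
  cen_r <- round(mean(((fg_idx - 1L) %% h) + 1L))
  cen_c <- round(mean(((fg_idx - 1L) %/% h) + 1L))
  fall_r <- min(max(cen_r - side %/% 2L, 1L), h - side + 1L)
  fall_c <- min(max(cen_c - side %/% 2L, 1L), w - side + 1L)
  if (counts[fall_r, fall_c] < need) {
    bi <- arrayInd(best, dim(counts))
    fall_r <- bi[1L]
    fall_c <- bi[2L]
  }
  crops <- vector("list", n)
  for (k in seq_len(n)) {
    r0 <- fall_r
    c0 <- fall_c
    for (a in seq_len(max_attempts)) {
      rr <- sample.int(h - side + 1L, 1L)
      cc <- sample.int(w - side + 1L, 1L)
      if (counts[rr, cc] >= need) {
        r0 <- rr
        c0 <- cc
        break
      }
    }
    rows <- r0:(r0 + side - 1L)
    cols <- c0:(c0 + side - 1L)
    crop_img <- if (length(img_dim) == 3L) {
      image[rows, cols, , drop = FALSE]
    } else {
      image[rows, cols, drop = FALSE]
    }
    crops[[k]] <- list(
      image = crop_img,
      labels = labels[rows, cols, drop = FALSE],
      window = list(x = c0 - 1L, y = r0 - 1L, side = side,
                    fraction = counts[r0, c0] / total_fg)
    )
  }
  crops
}

# labeled-pixel count of every side x side window via a summed-area table
window_fg_counts <- function(labels, side) {
  h <- nrow(labels)
  w <- ncol(labels)
  s <- apply(apply((labels != 0L) * 1L, 2L, cumsum), 1L, cumsum)
  s <- t(s)                                     # h x w integral image
  s <- rbind(0, cbind(0, s))                    # zero-padded
  ri <- seq_len(h - side + 1L)
  ci <- seq_len(w - side + 1L)
  s[ri + side, ci + side, drop = FALSE] -
    s[ri, ci + side, drop = FALSE] -
    s[ri + side, ci, drop = FALSE] +
    s[ri, ci, drop = FALSE]
}

#' Video-grouped cross-validation split
#'
#' Assigns whole videos to folds so that frames of one video — which are
#' near-duplicates of each other — never leak between training and
#' validation. Designated test videos are held out entirely. The remaining
#' videos are shuffled (seeded), then assigned largest-first to the
#' currently smallest fold, greedily balancing image counts.
#'
#' @param index Data frame with columns `image_id` and `video_id`.
#' @param k Number of folds; default 5.
#' @param test_videos Character/integer vector of video ids held out as the
#'   test split (may be empty).
#' @param seed Optional RNG seed for the shuffle.
#' @return The index with an added `split` column: `"test"` or
#'   `"fold1"`..`"foldk"`.
#' @export
group_split <- function(index, k = 5, test_videos = character(),
                        seed = NULL) {
  if (!all(c("image_id", "video_id") %in% names(index))) {
    stop("`index` needs columns image_id and video_id")
  }
  if (k < 2L) stop("`k` must be at least 2")
  vids <- unique(as.character(index$video_id))
  test_videos <- as.character(test_videos)
  unknown <- setdiff(test_videos, vids)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown test video(s): %s", paste(unknown, collapse = ", ")))
  }
  rest <- setdiff(vids, test_videos)
  if (length(rest) < k) {
    stop(sprintf("only %d non-test video(s) for %d folds", length(rest), k))
  }
  sizes <- table(as.character(index$video_id))
  if (!is.null(seed)) set.seed(seed)
  ord <- if (length(rest) > 1L) sample(rest) else rest
  ord <- ord[order(-as.integer(sizes[ord]))]    # stable: ties keep shuffle order
  load <- numeric(k)
  fold_of <- integer(0)
  for (v in ord) {
    f <- which.min(load)
    load[f] <- load[f] + sizes[[v]]
    fold_of[v] <- f
  }
  split <- ifelse(
    as.character(index$video_id) %in% test_videos, "test",
    paste0("fold", fold_of[as.character(index$video_id)])
  )
  index$split <- split
  index
}
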