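#' Pixel-wise ensemble fusion
#'
#' Fuses one-vs-all binary probability maps into a single multi-class label
#' map, one pixel at a time. A pixel is background (0) when every class
#' confidence falls strictly below the gate (`threshold`); otherwise it
#' receives the class id with the highest confidence. A confidence exactly
#' equal to the gate counts as positive. Argmax ties are broken
#' deterministically in favour of the lowest class id; the background never
#' competes in the argmax.
#'
#' @param maps A [prob_maps] object (or a list of matrices coercible to
#'   one).
#' @param threshold Confidence gate in `(0, 1)`; default 0.5.
#' @return An integer label map with the dimensions of the input maps.
#' @seealso [fuse_pixelwise_weighted()], [fuse_regionwise()]
#' @examples
#' p1 <- matrix(c(0.9, 0.3), 1, 2)
#' p2 <- matrix(c(0.6, 0.2), 1, 2)
#' fuse_pixelwise(prob_maps(list(p1, p2)))  # 1, 0
#' @export
fuse_pixelwise <- function(maps, threshold = 0.5) {
  maps <- as_prob_maps(maps)
  fuse_pixel_matrix(stack_maps(maps), maps$class_ids, dim(maps), threshold)
}

#' Weighted pixel-wise ensemble fusion
#'
#' As [fuse_pixelwise()], but each class confidence is first multiplied by
#' that member's weight (typically its held-out accuracy, e.g. a Dice
#' score). The weighting applies both to the background gate and to the
#' argmax, so down-weighting a member both shrinks its foreground support
#' and weakens it in class competitions. With all weights equal to 1 the
#' result is bit-identical to the unweighted operator.
#'
#' @inheritParams fuse_pixelwise
#' @param weights Numeric vector of per-class weights in `(0, 1]`, in
#'   ascending class-id order.
#' @return An integer label map.
#' @export
fuse_pixelwise_weighted <- function(maps, weights, threshold = 0.5) {
  maps <- as_prob_maps(maps)
  weights <- validate_weights(weights, maps)
  m <- sweep(stack_maps(maps), 2L, weights, `*`)
  fuse_pixel_matrix(m, maps$class_ids, dim(maps), threshold)
}

# pixels x classes matrix, columns in ascending class-id order
stack_maps <- function(maps) {
  matrix(unlist(maps$maps, use.names = FALSE), ncol = length(maps$maps))
}

fuse_pixel_matrix <- function(m, class_ids, dims, threshold) {
  if (!is.matrix(m)) m <- matrix(m, ncol = length(class_ids))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single value in (0, 1)")
  }
  # ties.method = "first" realizes the lowest-class-id tie break because
  # columns are stored in ascending id order
  win <- max.col(m, ties.method = "first")
  conf <- m[cbind(seq_len(nrow(m)), win)]
  lab <- ifelse(conf >= threshold, class_ids[win], 0L)
  matrix(as.integer(lab), dims[1L], dims[2L])
}

#' Connected foreground components of a label map
#'
#' Binarizes the label map into foreground (any class) versus background
#' and returns its maximal connected components. Components are
#' class-agnostic: a region may span pixels of several classes, which is
#' exactly what the region-based ensemble's majority vote resolves.
#'
#' @param labels Integer label map (0 = background).
#' @param connectivity Pixel adjacency, 8 (default; includes diagonals) or
#'   4.
#' @param class_ids Admissible class ids for validation.
#' @return A `region_set`: a list of integer vectors of linear
#'   (column-major) pixel indices, pairwise disjoint, whose union is the
#'   foreground support; carries the map dimensions and connectivity as
#'   attributes. Empty for an all-background map.
#' @export
extract_foreground_regions <- function(labels, connectivity = 8,
                                       class_ids = 1:3) {
  labels <- validate_label_map(labels, class_ids)
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  connectivity <- as.integer(connectivity)
  h <- nrow(labels)
  w <- ncol(labels)
  fg <- which(labels != 0L)
  if (length(fg) == 0L) {
    return(structure(list(), dims = c(h, w), connectivity = connectivity,
                     class = "region_set"))
  }
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  co <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))               # down, right
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))   # down-right, up-right
  }
  edges <- lapply(offs, function(o) {
    ok <- r + o[1L] >= 1L & r + o[1L] <= h & co + o[2L] <= w
    nb <- fg[ok] + o[1L] + o[2L] * h
    ok2 <- vid[nb] > 0L
    cbind(vid[fg[ok]][ok2], vid[nb][ok2])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  regions <- unname(split(fg, memb))
  structure(regions, dims = c(h, w), connectivity = connectivity,
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf(
    "<region_set> %d region(s) on a %d x %d map (%d-connectivity)\n",
    length(x), d[1L], d[2L], attr(x, "connectivity")
  ))
  invisible(x)
}

#' Majority class label of one region
#'
#' Returns the class id occurring most frequently among a region's pixels,
#' with ties broken in favour of the lowest class id. Used by the
#' region-based ensembles to relabel each connected component.
#'
#' @param region Integer vector of linear pixel indices into `labels`.
#' @param labels Integer label map the region was extracted from.
#' @return A single integer class id.
#' @export
region_majority_label <- function(region, labels) {
  if (length(region) == 0L) stop("region is empty")
  vals <- as.vector(labels)[region]
  if (anyNA(vals) || any(vals == 0L)) {
    stop("region contains background pixels; regions must cover foreground only")
  }
  ids <- sort(unique(vals))
  counts <- tabulate(match(vals, ids))
  ids[which.max(counts)]   # first max = lowest class id on ties
}

#' Region-based ensemble fusion
#'
#' Runs the pixel-wise ensemble, extracts the connected components of its
#' foreground, and rewrites every component with its majority class label.
#' The foreground/background support is untouched; only class labels inside
#' the foreground change, so each output component carries exactly one
#' class. This removes the pixel-level class inconsistencies that the plain
#' argmax leaves inside a single anatomical structure.
#'
#' @inheritParams fuse_pixelwise
#' @param connectivity Component adjacency, 8 (default) or 4.
#' @return An integer label map.
#' @export
fuse_regionwise <- function(maps, threshold = 0.5, connectivity = 8) {
  maps <- as_prob_maps(maps)
  relabel_regions(fuse_pixelwise(maps, threshold), connectivity,
                  maps$class_ids)
}

#' Weighted region-based ensemble fusion
#'
#' As [fuse_regionwise()], but the underlying pixel map is the weighted
#' pixel-wise fusion, and the components are therefore extracted from the
#' weighted map's foreground. With all weights equal to 1 the result is
#' bit-identical to [fuse_regionwise()].
#'
#' @inheritParams fuse_pixelwise_weighted
#' @param connectivity Component adjacency, 8 (default) or 4.
#' @return An integer label map.
#' @export
fuse_regionwise_weighted <- function(maps, weights, threshold = 0.5,
                                     connectivity = 8) {
  maps <- as_prob_maps(maps)
  relabel_regions(fuse_pixelwise_weighted(maps, weights, threshold),
                  connectivity, maps$class_ids)
}

relabel_regions <- function(labels, connectivity, class_ids) {
  regions <- extract_foreground_regions(labels, connectivity, class_ids)
  for (reg in regions) {
    labels[reg] <- region_majority_label(reg, labels)
  }
  labels
}
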