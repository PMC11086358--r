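#' Per-class probability map set
#'
#' Bundles one confidence grid per organ class, as produced by a bank of
#' one-vs-all binary segmentation models. Each map is a numeric matrix of
#' the same height and width with values in `[0, 1]`; rows index the image
#' y-axis and columns the x-axis.
#'
#' @param maps A named or unnamed list of numeric matrices (one per class),
#'   or a 3-d array whose third dimension indexes classes. If the list is
#'   named, names are parsed as integer class ids.
#' @param class_ids Integer vector of positive class ids, one per map.
#'   Defaults to the list names, or `seq_along(maps)`. Id 0 is reserved for
#'   the background and rejected. Maps are stored in ascending id order.
#' @return An object of class `prob_maps`: a list with elements `maps`
#'   (named list of matrices, ascending class id) and `class_ids`.
#' @examples
#' m <- matrix(runif(12), 3, 4)
#' pm <- prob_maps(list(m, 1 - m), class_ids = c(1, 2))
#' dim(pm)
#' @export
prob_maps <- function(maps, class_ids = NULL) {
  if (is.array(maps) && length(dim(maps)) == 3L) {
    maps <- lapply(seq_len(dim(maps)[3L]), function(i) maps[, , i])
  }
  if (!is.list(maps) || length(maps) == 0L) {
    stop("`maps` must be a non-empty list of matrices or a 3-d array")
  }
  if (is.null(class_ids)) {
    nm <- names(maps)
    class_ids <- if (!is.null(nm) && all(nzchar(nm))) {
      suppressWarnings(as.integer(nm))
    } else {
      seq_along(maps)
    }
  }
  class_ids <- as.integer(class_ids)
  if (length(class_ids) != length(maps) || anyNA(class_ids)) {
    stop("`class_ids` must supply one integer id per map")
  }
  if (any(class_ids <= 0L)) {
    stop("class ids must be positive; 0 is reserved for the background")
  }
  if (anyDuplicated(class_ids)) stop("class ids must be distinct")
  ord <- order(class_ids)
  class_ids <- class_ids[ord]
  maps <- maps[ord]
  ref <- dim(as.matrix(maps[[1L]]))
  maps <- lapply(maps, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (i in seq_along(maps)) {
    d <- dim(maps[[i]])
    if (!identical(d, ref)) {
      stop(sprintf(
        "map for class %d has dimensions %dx%d; expected %dx%d",
        class_ids[i], d[1L], d[2L], ref[1L], ref[2L]
      ))
    }
    v <- maps[[i]]
    if (anyNA(v) || any(v < 0) || any(v > 1)) {
      stop(sprintf(
        "map for class %d contains confidences outside [0, 1]", class_ids[i]
      ))
    }
  }
  names(maps) <- as.character(class_ids)
  structure(list(maps = maps, class_ids = class_ids), class = "prob_maps")
}

#' @export
dim.prob_maps <- function(x) dim(x$maps[[1L]])

#' @export
print.prob_maps <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<prob_maps> %d class map(s) [%s], %d x %d pixels\n",
    length(x$class_ids), paste(x$class_ids, collapse = ", "), d[1L], d[2L]
  ))
  invisible(x)
}

as_prob_maps <- function(x) {
  if (inherits(x, "prob_maps")) x else prob_maps(x)
}

#' Validate a multi-class label map
#'
#' A label map is an integer matrix whose entries are 0 (background) or one
#' of the declared class ids. Fusion operators, ground-truth masks and mask
#' readers all use this representation.
#'
#' @param labels An integer (or coercible) matrix.
#' @param class_ids Integer vector of admissible non-background labels.
#' @return The validated integer matrix, invisibly unchanged apart from
#'   storage mode.
#' @export
validate_label_map <- function(labels, class_ids = 1:3) {
  labels <- as.matrix(labels)
  if (anyNA(labels)) stop("label map contains missing values")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, as.integer(class_ids)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "label map contains values outside {0, %s}: {%s}",
      paste(class_ids, collapse = ", "),
      paste(sort(bad), collapse = ", ")
    ))
  }
  labels
}

#' Validate per-class ensemble weights
#'
#' Weights are the member accuracies used by the weighted ensembles; each
#' must lie in `(0, 1]`. Values above 1 are rejected because they would
#' lower the effective confidence gate below its nominal threshold.
#'
#' @param weights Numeric vector, one weight per class of `maps`.
#' @param maps The `prob_maps` object the weights will be applied to.
#' @return Numeric weight vector named by class id.
#' @export
validate_weights <- function(weights, maps) {
  maps <- as_prob_maps(maps)
  weights <- as.numeric(weights)
  if (length(weights) != length(maps$class_ids)) {
    stop(sprintf(
      "%d weight(s) supplied for %d class map(s)",
      length(weights), length(maps$class_ids)
    ))
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop("weights must be strictly positive")
  }
  if (any(weights > 1)) {
    stop("weights above 1 are rejected: they would lower the 0.5 gate")
  }
  names(weights) <- as.character(maps$class_ids)
  weights
}
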