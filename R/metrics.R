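#' Image-level Jaccard score of two label maps
#'
#' Treats ground truth and prediction as sets of (pixel, label) pairs over
#' all pixels, background included. With `a` pixels in agreement over `N`
#' total pixels, the intersection of the two sets has size `a` and the
#' union `2N - a`, giving `a / (2N - a)`. Counting background agreement
#' reflects that an empty scene correctly predicted empty scores 1, not
#' 0/0.
#'
#' @param gt,pred Integer label maps of identical dimensions.
#' @return A score in `[0, 1]`; 1 for identical maps.
#' @export
jaccard_global <- function(gt, pred) {
  check_pair_dims(gt, pred)
  n <- length(gt)
  a <- sum(gt == pred)
  a / (2 * n - a)
}

#' Image-level Dice coefficient of two label maps
#'
#' Same (pixel, label) set formalization as [jaccard_global()]:
#' `2a / 2N = a / N`, i.e. the pixel agreement rate.
#'
#' @inheritParams jaccard_global
#' @return A score in `[0, 1]`.
#' @export
dice_global <- function(gt, pred) {
  check_pair_dims(gt, pred)
  sum(gt == pred) / length(gt)
}

#' Class-level Jaccard score
#'
#' Intersection over union of the binary supports of class `c` in ground
#' truth and prediction. When the class is absent from both maps the score
#' is undefined (0/0) and `NA` is returned; dataset aggregation excludes
#' such images rather than crediting them.
#'
#' @inheritParams jaccard_global
#' @param c A single declared class id.
#' @param class_ids Admissible class ids.
#' @return A score in `[0, 1]`, or `NA` when class `c` is absent from both
#'   maps.
#' @export
jaccard_class <- function(gt, pred, c, class_ids = 1:3) {
  check_pair_dims(gt, pred)
  check_class_id(c, class_ids)
  g <- gt == c
  p <- pred == c
  u <- sum(g | p)
  if (u == 0L) return(NA_real_)
  sum(g & p) / u
}

#' Class-level Dice coefficient
#'
#' Twice the intersection of the binary supports of class `c` over the sum
#' of their sizes; `NA` when the class is absent from both maps. Satisfies
#' `D = 2J / (1 + J)` exactly against [jaccard_class()].
#'
#' @inheritParams jaccard_class
#' @return A score in `[0, 1]`, or `NA` when undefined.
#' @export
dice_class <- function(gt, pred, c, class_ids = 1:3) {
  check_pair_dims(gt, pred)
  check_class_id(c, class_ids)
  g <- gt == c
  p <- pred == c
  s <- sum(g) + sum(p)
  if (s == 0L) return(NA_real_)
  2 * sum(g & p) / s
}

check_pair_dims <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) {
    stop(sprintf(
      "dimension mismatch: ground truth %s vs prediction %s",
      paste(dim(gt), collapse = "x"), paste(dim(pred), collapse = "x")
    ))
  }
  invisible(NULL)
}

check_class_id <- function(c, class_ids) {
  if (length(c) != 1L || !(c %in% class_ids)) {
    stop(sprintf(
      "unknown class id %s; declared classes: %s",
      paste(c, collapse = ","), paste(class_ids, collapse = ", ")
    ))
  }
  invisible(NULL)
}

#' Evaluate a dataset of ground-truth / prediction pairs
#'
#' Computes the global and per-class Jaccard and Dice scores for every
#' image, then aggregates by the unweighted mean over the images where each
#' metric is defined. Per-class defined-image counts are reported alongside
#' the means because rare classes may be absent from (and hence undefined
#' on) many images. A pooled-pixel aggregation over the concatenation of
#' all images is available as an alternative.
#'
#' @param pairs A list; each element a list with components `gt` and `pred`
#'   (label maps of matching dimensions).
#' @param class_ids Class ids to evaluate per class.
#' @param ids Optional character vector of image ids (defaults to
#'   `img1..imgN`).
#' @param aggregation `"mean"` (default; per-image metrics averaged over
#'   defined images) or `"pooled"` (metrics of the pixel-pooled maps).
#' @return A `metric_report`: list with `per_image` (data frame of one row
#'   per image), `aggregate` (named means), `defined_n` (images per metric
#'   entering each mean), and `aggregation`.
#' @export
evaluate_dataset <- function(pairs, class_ids = 1:3, ids = NULL,
                             aggregation = c("mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (!is.list(pairs) || length(pairs) == 0L) {
    stop("`pairs` must be a non-empty list of gt/pred pairs")
  }
  if (is.null(ids)) ids <- paste0("img", seq_along(pairs))
  metric_names <- c(
    "jaccard", "dice",
    paste0("jaccard_", class_ids), paste0("dice_", class_ids)
  )
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    res <- tryCatch({
      vals <- c(
        jaccard_global(p$gt, p$pred),
        dice_global(p$gt, p$pred),
        vapply(class_ids, function(cc)
          jaccard_class(p$gt, p$pred, cc, class_ids), numeric(1)),
        vapply(class_ids, function(cc)
          dice_class(p$gt, p$pred, cc, class_ids), numeric(1))
      )
      names(vals) <- metric_names
      vals
    }, error = function(e) {
      stop(sprintf("image '%s': %s", ids[i], conditionMessage(e)))
    })
    res
  })
  per_image <- as.data.frame(do.call(rbind, rows))
  per_image <- cbind(image = ids, per_image)
  rownames(per_image) <- NULL
  if (aggregation == "mean") {
    aggregate <- vapply(metric_names, function(m)
      mean(per_image[[m]], na.rm = TRUE), numeric(1))
    aggregate[is.nan(aggregate)] <- NA_real_
  } else {
    gt_all <- matrix(unlist(lapply(pairs, function(p) as.vector(p$gt))), ncol = 1)
    pr_all <- matrix(unlist(lapply(pairs, function(p) as.vector(p$pred))), ncol = 1)
    aggregate <- c(
      jaccard_global(gt_all, pr_all), dice_global(gt_all, pr_all),
      vapply(class_ids, function(cc)
        jaccard_class(gt_all, pr_all, cc, class_ids), numeric(1)),
      vapply(class_ids, function(cc)
        dice_class(gt_all, pr_all, cc, class_ids), numeric(1))
    )
    names(aggregate) <- metric_names
  }
  defined_n <- vapply(metric_names, function(m)
    sum(!is.na(per_image[[m]])), integer(1))
  structure(
    list(per_image = per_image, aggregate = aggregate,
         defined_n = defined_n, aggregation = aggregation),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_report> %d image(s), aggregation = %s\n",
              nrow(x$per_image), x$aggregation))
  tab <- data.frame(
    metric = names(x$aggregate),
    value = round(unname(x$aggregate), digits),
    defined_images = unname(x$defined_n)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
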