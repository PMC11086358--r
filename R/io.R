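#' Read / write label masks as 8-bit PNG
#'
#' Label maps are stored as single-channel 8-bit PNG with literal label
#' values (0 = background). The round trip is lossless. On read, any pixel
#' value outside `{0} U class_ids` is rejected with the set of offending
#' values, so corrupted or mislabeled masks fail loudly.
#'
#' @param labels Integer label map.
#' @param path PNG file path.
#' @param class_ids Admissible class ids.
#' @return `write_label_mask()` returns `path` invisibly;
#'   `read_label_mask()` returns the integer label map.
#' @export
write_label_mask <- function(labels, path, class_ids = 1:3) {
  labels <- validate_label_map(labels, class_ids)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, class_ids = 1:3) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    stop(sprintf("%s is not a single-channel mask (%d channels)",
                 path, dim(img)[3L]))
  }
  labels <- round(img * 255)
  storage.mode(labels) <- "integer"
  validate_label_map(labels, class_ids)
}

#' Read / write probability map sets as 16-bit TIFF
#'
#' Each class map is stored as one single-channel 16-bit grayscale TIFF
#' named `<stem>.class<k>.prob.tif` (pixel value v stands for confidence
#' v / 65535), a lossless, portable container; the quantization round trip
#' is accurate to within 1/65535 per pixel, and confidences 0 and 1
#' survive exactly.
#'
#' @param maps A [prob_maps] object.
#' @param dir Directory holding the per-class files.
#' @param stem File-name stem (typically the image id).
#' @param class_ids Class ids to read.
#' @return `write_probability_maps()` returns the written paths invisibly;
#'   `read_probability_maps()` returns a [prob_maps].
#' @export
write_probability_maps <- function(maps, dir, stem) {
  maps <- as_prob_maps(maps)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s.class%d.prob.tif", stem,
                                  maps$class_ids))
  for (i in seq_along(paths)) {
    tiff::writeTIFF(maps$maps[[i]], paths[i], bits.per.sample = 16L)
  }
  invisible(paths)
}

#' @rdname write_probability_maps
#' @export
read_probability_maps <- function(dir, stem, class_ids = 1:3) {
  paths <- file.path(dir, sprintf("%s.class%d.prob.tif", stem, class_ids))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf("missing probability map file(s): %s",
                 paste(basename(paths[missing]), collapse = ", ")))
  }
  maps <- lapply(paths, tiff::readTIFF)
  prob_maps(maps, class_ids)
}

#' Read / write boundary annotations as JSON
#'
#' An annotation document records, per image, the closed boundary polygons
#' drawn for each class: a JSON object with `image_id` and `classes`, the
#' latter mapping class ids to lists of polygons (each an array of `[x, y]`
#' vertex pairs, 0-based pixel coordinates).
#'
#' @param annotation List with `image_id` and `classes` (named list of
#'   lists of two-column vertex matrices).
#' @param path JSON file path.
#' @return `read_annotation()` returns the annotation list with polygon
#'   matrices; `write_annotation()` returns `path` invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(is.list(annotation), !is.null(annotation$image_id))
  doc <- list(
    image_id = annotation$image_id,
    classes = lapply(annotation$classes, function(polys) {
      lapply(polys, function(p) unname(as.matrix(p)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(doc$classes, function(cl) {
    lapply(cl, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
  })
  list(image_id = doc$image_id, classes = polys)
}

#' Read / write a dataset index as CSV
#'
#' The index has one row per image: `image_id`, `video_id`, and, after
#' splitting, the `split` assignment.
#'
#' @param index Data frame.
#' @param path CSV file path.
#' @return `read_dataset_index()` returns the data frame;
#'   `write_dataset_index()` returns `path` invisibly.
#' @export
write_dataset_index <- function(index, path) {
  utils::write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_index
#' @export
read_dataset_index <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
}

# Write a generated dataset fixture tree: images/, masks/, probs/, index.csv
write_dataset <- function(ds, dir, class_ids = NULL) {
  for (sub in c("images", "masks", "probs")) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  for (iid in names(ds$masks)) {
    cids <- if (is.null(class_ids)) ds$map_sets[[iid]]$class_ids else class_ids
    png::writePNG(ds$images[[iid]], file.path(dir, "images",
                                              paste0(iid, ".png")))
    write_label_mask(ds$masks[[iid]], file.path(dir, "masks",
                                                paste0(iid, ".png")), cids)
    write_probability_maps(ds$map_sets[[iid]], file.path(dir, "probs"), iid)
  }
  write_dataset_index(ds$index, file.path(dir, "index.csv"))
  invisible(dir)
}
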