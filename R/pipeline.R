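#' Run configuration for the fusion pipeline
#'
#' Bundles the options of a pipeline run: which fusion method to apply,
#' the class ids, optional per-class weights (required by the weighted
#' methods), the confidence gate, component connectivity, directories and
#' seed.
#'
#' @param method One of `"pixel"`, `"pixel-weighted"`, `"region"`,
#'   `"region-weighted"`.
#' @param class_ids Integer class ids.
#' @param weights Per-class weights in `(0, 1]`; required iff `method` is
#'   weighted.
#' @param threshold Confidence gate in `(0, 1)`.
#' @param connectivity Component adjacency, 8 or 4.
#' @param in_dir,out_dir Input and output directories.
#' @param seed Optional integer seed.
#' @param force Overwrite existing outputs (default `FALSE`: refuse).
#' @return A validated `run_config` list.
#' @export
run_config <- function(method = c("pixel", "pixel-weighted", "region",
                                  "region-weighted"),
                       class_ids = 1:3, weights = NULL, threshold = 0.5,
                       connectivity = 8, in_dir = NULL, out_dir = NULL,
                       seed = NULL, force = FALSE) {
  method <- match.arg(method)
  weighted <- grepl("weighted", method)
  if (weighted && is.null(weights)) {
    stop(sprintf("method '%s' requires `weights`", method))
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)")
  }
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(
    list(method = method, class_ids = as.integer(class_ids),
         weights = weights, threshold = threshold,
         connectivity = as.integer(connectivity),
         in_dir = in_dir, out_dir = out_dir, seed = seed, force = force),
    class = "run_config"
  )
}

#' Apply the configured fusion operator to one probability map set
#'
#' @param maps A [prob_maps] object.
#' @param config A [run_config()].
#' @return An integer label map.
#' @export
fuse <- function(maps, config) {
  stopifnot(inherits(config, "run_config"))
  switch(config$method,
    "pixel" = fuse_pixelwise(maps, config$threshold),
    "pixel-weighted" = fuse_pixelwise_weighted(maps, config$weights,
                                               config$threshold),
    "region" = fuse_regionwise(maps, config$threshold,
                               config$connectivity),
    "region-weighted" = fuse_regionwise_weighted(maps, config$weights,
                                                 config$threshold,
                                                 config$connectivity)
  )
}

#' Fuse every probability map set in a directory
#'
#' Reads `<stem>.class<k>.prob.tif` sets from `in_dir` for every stem in
#' `stems`, applies the configured fusion operator and writes one label
#' mask PNG per stem to `out_dir`. Existing outputs are never silently
#' overwritten: set `force = TRUE` in the config to replace them.
#'
#' @param config A [run_config()] with `in_dir` and `out_dir` set.
#' @param stems Character vector of image ids; default: all stems found in
#'   `in_dir`.
#' @return Invisibly, the written mask paths.
#' @export
fuse_directory <- function(config, stems = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$in_dir) || is.null(config$out_dir)) {
    stop("config must set in_dir and out_dir")
  }
  if (is.null(stems)) {
    files <- list.files(config$in_dir, pattern = "\\.class\\d+\\.prob\\.tif$")
    stems <- unique(sub("\\.class\\d+\\.prob\\.tif$", "", files))
  }
  if (length(stems) == 0L) stop("no probability map sets found")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- file.path(config$out_dir, paste0(stems, ".png"))
  clash <- file.exists(out)
  if (any(clash) && !config$force) {
    stop(sprintf("output exists (use force = TRUE): %s",
                 paste(basename(out[clash]), collapse = ", ")))
  }
  for (i in seq_along(stems)) {
    maps <- read_probability_maps(config$in_dir, stems[i], config$class_ids)
    write_label_mask(fuse(maps, config), out[i], config$class_ids)
  }
  invisible(out)
}

#' Evaluate predicted masks against ground-truth masks on disk
#'
#' Pairs masks by file name between the two directories and runs
#' [evaluate_dataset()].
#'
#' @param gt_dir,pred_dir Directories of label-mask PNGs with matching
#'   names.
#' @param class_ids Class ids.
#' @param report Optional path; when set, the metric report is written
#'   there as JSON.
#' @return A `metric_report`.
#' @export
evaluate_directory <- function(gt_dir, pred_dir, class_ids = 1:3,
                               report = NULL) {
  gt_files <- sort(list.files(gt_dir, pattern = "\\.png$"))
  if (length(gt_files) == 0L) stop("no ground-truth masks found")
  missing <- !file.exists(file.path(pred_dir, gt_files))
  if (any(missing)) {
    stop(sprintf("prediction missing for: %s",
                 paste(gt_files[missing], collapse = ", ")))
  }
  pairs <- lapply(gt_files, function(f) {
    list(gt = read_label_mask(file.path(gt_dir, f), class_ids),
         pred = read_label_mask(file.path(pred_dir, f), class_ids))
  })
  rep <- evaluate_dataset(pairs, class_ids,
                          ids = sub("\\.png$", "", gt_files))
  if (!is.null(report)) {
    jsonlite::write_json(
      list(aggregation = rep$aggregation,
           aggregate = as.list(rep$aggregate),
           defined_images = as.list(rep$defined_n),
           per_image = rep$per_image),
      report, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  rep
}

#' Run the simulate / fuse / evaluate pipeline end to end
#'
#' Generates a synthetic dataset under `work_dir`, fuses its probability
#' maps with the configured operator, evaluates the fused masks against
#' the ground truth, and writes a JSON run manifest (configuration echo,
#' seed, per-stage timings and warnings). Any stage error aborts with a
#' nonzero-status condition while retaining partial outputs; the manifest
#' records the failure point.
#'
#' @param config A [run_config()].
#' @param work_dir Directory for all artifacts.
#' @param n_videos,frames_per_video Synthetic dataset size.
#' @param scenario A [scenario_config()]; its seed defaults to
#'   `config$seed`.
#' @return Invisibly, a list with the `metric_report` and the manifest
#'   path.
#' @export
run_pipeline <- function(config, work_dir, n_videos = 3,
                         frames_per_video = 2, scenario = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(work_dir)) dir.create(work_dir, recursive = TRUE)
  if (is.null(scenario)) {
    scenario <- scenario_config(class_ids = config$class_ids,
                                seed = config$seed)
  }
  manifest <- list(
    package = as.character(utils::packageVersion("segfuse")),
    config = config[c("method", "class_ids", "weights", "threshold",
                      "connectivity", "seed")],
    scenario = scenario[setdiff(names(scenario), "seed")],
    scenario_seed = scenario$seed,
    stages = list(), warnings = list()
  )
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(work_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  ds <- stage("simulate", function()
    generate_dataset(n_videos, frames_per_video, scenario,
                     dir = file.path(work_dir, "data")))
  stage("fuse", function() {
    cfg <- config
    cfg$in_dir <- file.path(work_dir, "data", "probs")
    cfg$out_dir <- file.path(work_dir, "fused")
    fuse_directory(cfg)
  })
  rep <- stage("eval", function()
    evaluate_directory(file.path(work_dir, "data", "masks"),
                       file.path(work_dir, "fused"), config$class_ids,
                       report = file.path(work_dir, "metrics.json")))
  write_manifest()
  invisible(list(report = rep, manifest = file.path(work_dir,
                                                    "manifest.json")))
}
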