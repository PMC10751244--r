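# End-to-end orchestration: simulate (optional) -> segment -> shape ->
# classify -> junction metrics -> clearance fits, with every stage's output
# written as CSV and a machine-readable run manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param scene a [scene_spec()] to simulate, or NULL to analyse a supplied
#'   image.
#' @param image optional `calibrated_image` to analyse instead of simulating.
#' @param polygons cell perimeters for junction metrics (taken from ground
#'   truth when simulating).
#' @param block_size_um segmentation block size (default 20 um).
#' @param segment segmentation parameters, a [segment_config()].
#' @param classify_scope,classify_mode quartile scope and binning mode.
#' @param tolerance_um junction assignment tolerance.
#' @param clearance optional clearance table (time_h, intensity, is_baseline).
#' @param seed integer seed recorded (and used for any simulation).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, scene = scene_spec(), image = NULL,
                       polygons = NULL, block_size_um = 20,
                       segment = segment_config(),
                       classify_scope = "cohort", classify_mode = "lenient",
                       tolerance_um = 1, clearance = NULL, seed = 1L) {
  structure(list(out_dir = out_dir, scene = scene, image = image,
                 polygons = polygons, block_size_um = block_size_um,
                 segment = segment, classify_scope = classify_scope,
                 classify_mode = classify_mode, tolerance_um = tolerance_um,
                 clearance = clearance, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when a scene spec is given) -> block segmentation ->
#' shape measurement -> four-category classification -> junction metrics ->
#' optional clearance fitting, writing `fragments.csv`, `shapes.csv`,
#' `classification.csv`, `junction_metrics.csv`, `length_cdf.csv`,
#' (`clearance_fit.csv`), `cells.csv` and `manifest.json` to the output
#' directory.  A failing stage aborts with the stage name in the error.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage outputs and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(config$scene)) {
    scene <- stage("simulate", simulate_scene(config$scene))
    image <- scene$image
    polygons <- scene$truth$cell_polygons
    truth <- scene$truth
  } else {
    if (is.null(config$image)) stop("pipeline stage 'input' failed: no scene spec and no image")
    image <- config$image
    polygons <- config$polygons
    truth <- NULL
  }
  seg <- stage("segment", segment_fov(image, config$block_size_um,
                                      config$segment))
  shapes <- stage("shape", shape_table(seg))
  q <- stage("classify", compute_quartiles(shapes$aspect_ratio,
                                           config$classify_scope))
  classified <- stage("classify",
                      classify_fragments(shapes, q, config$classify_mode))
  fovp <- stage("classify",
                fov_percentages(classified$category, fov = 1L,
                                discordant = classified$discordant))
  jm <- NULL
  cdf <- NULL
  if (!is.null(polygons)) {
    jm <- stage("junction-metrics",
                junction_metrics(classified, polygons, config$tolerance_um))
    cdf <- stage("junction-metrics",
                 cumulative_length_frequency(classified$length_um))
  }
  cfit <- NULL
  if (!is.null(config$clearance)) {
    cfit <- stage("clearance-fit",
                  fit_decay(as_clearance_series(config$clearance)))
  }
  write_out <- function(df, file) {
    utils::write.csv(df, file.path(config$out_dir, file), row.names = FALSE)
  }
  write_out(shapes[, setdiff(names(shapes), c("circ_bin", "ar_bin"))],
            "shapes.csv")
  write_out(seg$table, "fragments.csv")
  write_out(cbind(fovp, q1 = q$q1, q2 = q$q2, q3 = q$q3),
            "classification.csv")
  if (!is.null(jm)) write_out(jm, "junction_metrics.csv")
  if (!is.null(cdf)) write_out(cdf, "length_cdf.csv")
  if (!is.null(cfit)) {
    write_out(data.frame(k = cfit$k, half_life_h = cfit$half_life_h,
                         rss = cfit$rss, converged = cfit$converged),
              "clearance_fit.csv")
  }
  if (!is.null(polygons)) {
    polydf <- do.call(rbind, lapply(seq_along(polygons), function(i)
      data.frame(cell_id = i, vertex = seq_len(nrow(polygons[[i]])),
                 x_um = polygons[[i]][, 1], y_um = polygons[[i]][, 2])))
    write_out(polydf, "cells.csv")
  }
  manifest <- list(
    package = "junctmorph",
    version = as.character(utils::packageVersion("junctmorph")),
    seed = config$seed,
    block_size_um = config$block_size_um,
    classify_scope = config$classify_scope,
    classify_mode = config$classify_mode,
    tolerance_um = config$tolerance_um,
    quartiles = list(q1 = q$q1, q2 = q$q2, q3 = q$q3, n = q$n),
    n_fragments = nrow(shapes))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, segmentation = seg,
                 shapes = classified, quartiles = q, fov = fovp,
                 junction = jm, cdf = cdf, clearance_fit = cfit,
                 truth = truth))
}
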