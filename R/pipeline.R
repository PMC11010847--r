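#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end chain
#' filter -> segment -> trim -> pose -> measure -> predict. Loadable from
#' and dumpable to a plain-text YAML file; unknown keys are rejected.
#'
#' @param edgelength voxel edge for the filter stage, meters.
#' @param k cluster count for segmentation, or `"auto"` for elbow selection.
#' @param k_min,k_max candidate range when `k = "auto"`.
#' @param n_restarts K-means restarts.
#' @param camera_axis,camera_sign camera geometry for pig-cluster picking
#'   (see [extract_pig_cluster()]).
#' @param trim a [trim_params()].
#' @param bins x bins per section for [measure_widths()].
#' @param angle_threshold pose-correction threshold, degrees.
#' @param model_path optional MACNN checkpoint; `NULL` = measurement-only.
#' @param feature_mode feature mode for prediction.
#' @param n_points resampling size for prediction features.
#' @param seed master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(edgelength = 0.03, k = "auto", k_min = 1L,
                            k_max = 8L, n_restarts = 10L, camera_axis = "z",
                            camera_sign = "+", trim = trim_params(),
                            bins = 20L, angle_threshold = 1.0,
                            model_path = NULL, feature_mode = "xyz",
                            n_points = 1024L, seed = 1L,
                            log_level = "info") {
  if (!identical(k, "auto")) k <- as.integer(k)
  structure(list(edgelength = edgelength, k = k, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
                 camera_axis = camera_axis, camera_sign = camera_sign,
                 trim = trim, bins = as.integer(bins),
                 angle_threshold = angle_threshold, model_path = model_path,
                 feature_mode = feature_mode, n_points = as.integer(n_points),
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Flat YAML key/value files; trim parameters are nested under `trim:`.
#' Unknown keys raise an error rather than being silently dropped.
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return a `pipeline_config` (read) or `path` (write).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  defaults <- pipeline_config()
  trim_args <- list()
  if (!is.null(vals$trim)) {
    known_trim <- c("block_side", "dbscan_eps", "dbscan_min_samples",
                    "trim_extent", "density_percentile")
    bad <- setdiff(names(vals$trim), known_trim)
    if (length(bad))
      stop("unknown trim config keys: ", paste(bad, collapse = ", "))
    trim_args <- vals$trim
    vals$trim <- NULL
  }
  known <- setdiff(names(formals(pipeline_config)), "trim")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, c(vals, list(trim = do.call(trim_params, trim_args))))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$trim <- unclass(out$trim)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

pipe_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet")) message(sprintf(fmt, ...))
}

#' Run the full measurement / weight pipeline on one PLY file
#'
#' Executes voxel down-sampling, K-means segmentation (with elbow selection
#' of K when configured), pig-cluster extraction, head/tail removal, pose
#' correction, three-section width measurement and — when a model checkpoint
#' is configured — MACNN weight prediction. Per-stage point counts and wall
#' times are recorded.
#'
#' @param ply_path input PLY file (or an in-memory [point_cloud()]).
#' @param config a [pipeline_config()].
#' @param model optional pre-loaded `macnn_model` (overrides
#'   `config$model_path`).
#' @return object of class `pipeline_report`: list with `source`, `counts`
#'   (named per-stage point counts), `k_used`, `measurements`
#'   (`body_measurements`), `weight` (kg or NA), `stage_seconds`,
#'   `total_seconds`.
#' @export
run_pipeline <- function(ply_path, config = pipeline_config(), model = NULL) {
  t_all <- proc.time()[["elapsed"]]
  stage_t <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stage_t[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  cloud <- if (inherits(ply_path, "point_cloud")) ply_path else
    tick("read", read_ply(ply_path))
  src <- cloud$source_id
  counts <- c(input = n_points(cloud))

  filtered <- tick("filter", voxel_downsample(cloud, config$edgelength))
  counts["filter"] <- n_points(filtered)
  pipe_log(config, "filter: %d -> %d points (edgelength %.3g m)",
           counts["input"], counts["filter"], config$edgelength)

  k_used <- config$k
  if (identical(config$k, "auto")) {
    sel <- tick("elbow", elbow_select_k(filtered, config$k_min:config$k_max,
                                        seed = config$seed,
                                        n_restarts = config$n_restarts))
    k_used <- sel$K
    pipe_log(config, "elbow: chose K = %d", k_used)
  }
  seg <- tick("segment", kmeans_cluster(filtered, k_used, seed = config$seed,
                                        n_restarts = config$n_restarts))
  pig <- extract_pig_cluster(filtered, seg, config$camera_axis,
                             config$camera_sign)
  counts["segment"] <- n_points(pig)
  pipe_log(config, "segment: K = %d, pig cluster %d points", k_used,
           counts["segment"])

  tr <- tick("trim", remove_head_tail(pig, config$trim))
  counts["trim"] <- n_points(tr$trimmed)
  pipe_log(config, "trim: kept %d, removed %d points", counts["trim"],
           n_points(tr$removed))

  pose <- tick("pose", correct_pose(tr$trimmed, config$angle_threshold))
  head_pt <- if (!is.null(tr$head_point)) apply_pose(pose, tr$head_point)
  meas <- tick("measure", measure_widths(pose$corrected, config$bins,
                                         head_point = head_pt))
  pipe_log(config, "measure: shoulder %.3f, abdomen %.3f, hip %.3f m",
           meas$shoulder, meas$abdomen, meas$hip)

  weight <- NA_real_
  if (is.null(model) && !is.null(config$model_path))
    model <- load_weight_model(config$model_path)
  if (!is.null(model)) {
    feats <- assemble_features(tr$trimmed, mode = model$config$feature_mode,
                               n_points = model$config$n_points,
                               seed = config$seed)
    weight <- tick("predict", predict(model, feats))
    pipe_log(config, "predict: %.1f kg", weight)
  }
  structure(list(source = src, counts = counts, k_used = k_used,
                 measurements = meas, weight = weight,
                 pose_applied_deg = pose$applied_deg,
                 stage_seconds = unlist(stage_t),
                 total_seconds = proc.time()[["elapsed"]] - t_all),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report [%s]\n", x$source))
  cat("  points:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                         collapse = " "), "\n")
  cat(sprintf("  widths (m): shoulder %.3f, abdomen %.3f, hip %.3f\n",
              x$measurements$shoulder, x$measurements$abdomen,
              x$measurements$hip))
  if (is.finite(x$weight)) cat(sprintf("  weight: %.1f kg\n", x$weight))
  cat(sprintf("  total time: %.3f s\n", x$total_seconds))
  invisible(x)
}

#' Run the pipeline over many files
#'
#' Per-file failures are isolated: a failing input yields an error entry and
#' the batch continues. An error is raised only if every input fails.
#'
#' @param paths character vector of PLY paths, or a directory containing
#'   `.ply` files.
#' @param config a [pipeline_config()].
#' @param model optional pre-loaded `macnn_model`.
#' @return list with `reports` (per successful file), `failures` (named
#'   error messages), `summary` (data frame of widths/weights).
#' @export
batch_pipeline <- function(paths, config = pipeline_config(), model = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.ply$", full.names = TRUE)
  if (length(paths) < 1L) stop("batch_pipeline: no input files")
  if (is.null(model) && !is.null(config$model_path))
    model <- load_weight_model(config$model_path)
  reports <- list(); failures <- character(0)
  for (p in paths) {
    r <- tryCatch(run_pipeline(p, config, model = model),
                  error = function(e) e)
    if (inherits(r, "error")) failures[basename(p)] <- conditionMessage(r)
    else reports[[basename(p)]] <- r
  }
  if (!length(reports)) stop("batch_pipeline: all inputs failed: ",
                             paste(failures, collapse = "; "))
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(id = nm, shoulder = r$measurements$shoulder,
               abdomen = r$measurements$abdomen, hip = r$measurements$hip,
               weight = r$weight, seconds = r$total_seconds)
  }))
  list(reports = reports, failures = failures, summary = summary)
}
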