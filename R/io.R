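# File formats: trial CSV, scene JSON + cloud CSV, cohort parameter and
# property CSVs, and the YAML run configuration. All writers have matching
# readers so every artifact round-trips through the package.

TRIAL_COLUMNS <- c("frame", "time_s", "thickness_mm", "force_N", "area_cm2")

#' Write / read a stance-phase trial CSV
#'
#' Columns: `frame`, `time_s`, `thickness_mm`, `force_N`, `area_cm2`.
#'
#' @param trial a `heel_trial` data frame.
#' @param path output CSV path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `heel_trial` data frame.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(is.data.frame(trial))
  missing <- setdiff(TRIAL_COLUMNS, names(trial))
  if (length(missing))
    stopf("trial is missing columns: %s", paste(missing, collapse = ", "),
          class = "schema_error")
  write.csv(as.data.frame(trial)[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  out <- read.csv(path)
  missing <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing))
    stopf("'%s' is not a trial CSV; missing columns: %s", path,
          paste(missing, collapse = ", "), class = "schema_error")
  class(out) <- c("heel_trial", "data.frame")
  out
}

#' Write / read a geometry scene (JSON header + XYZ cloud CSV)
#'
#' The header JSON carries the ball centers, ball radius and plate tilt; the
#' cloud CSV holds one row per point with columns `frame`, `time_s`, `x`,
#' `y`, `z` (mm).
#'
#' @param scene a `geometry_scene`.
#' @param json_path header JSON path.
#' @param cloud_path point-cloud CSV path; defaults to the JSON path with
#'   extension `.csv`.
#' @return `write_scene` returns `json_path` invisibly; `read_scene` a
#'   `geometry_scene`.
#' @export
write_scene <- function(scene, json_path,
                        cloud_path = sub("\\.json$", ".csv", json_path)) {
  stopifnot(inherits(scene, "geometry_scene"))
  header <- list(ball_centers = unname(apply(scene$ball_centers, 1L,
                                             as.numeric, simplify = FALSE)),
                 ball_radius = scene$ball_radius,
                 plate_tilt_deg = scene$plate_tilt_deg,
                 n_frames = length(scene$frames),
                 cloud_csv = basename(cloud_path))
  jsonlite::write_json(header, json_path, auto_unbox = TRUE, digits = NA)
  pts <- do.call(rbind, lapply(seq_along(scene$frames), function(i) {
    f <- scene$frames[[i]]
    data.frame(frame = i, time_s = f$time, x = f$cloud[, 1L],
               y = f$cloud[, 2L], z = f$cloud[, 3L])
  }))
  write.csv(pts, cloud_path, row.names = FALSE)
  invisible(json_path)
}

#' @rdname write_scene
#' @export
read_scene <- function(json_path,
                       cloud_path = file.path(dirname(json_path),
                                              header$cloud_csv)) {
  header <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pts <- read.csv(cloud_path)
  missing <- setdiff(c("frame", "time_s", "x", "y", "z"), names(pts))
  if (length(missing))
    stopf("'%s' is not a scene cloud CSV; missing columns: %s", cloud_path,
          paste(missing, collapse = ", "), class = "schema_error")
  centers <- header$ball_centers
  centers <- if (is.list(centers)) do.call(rbind, lapply(centers, as.numeric))
  else unname(as.matrix(centers))
  frames <- lapply(seq_len(header$n_frames), function(i) {
    sub <- pts[pts$frame == i, ]
    list(time = sub$time_s[1L], cloud = as.matrix(sub[, c("x", "y", "z")]))
  })
  structure(list(ball_centers = centers, ball_radius = header$ball_radius,
                 plate_tilt_deg = header$plate_tilt_deg, frames = frames),
            class = "geometry_scene")
}

#' Write / read the cohort parameter table
#'
#' @param cohort a `heel_cohort` data frame from [sample_cohort()].
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("heel_cohort", "data.frame")
  out
}

#' Read and validate a YAML run configuration
#'
#' The configuration is a YAML document with blocks `seed`, `cohort`,
#' `gait` and `analysis`; block keys must match the fields of
#' [cohort_config()], [gait_config()] and [analysis_config()]. Unknown keys
#' are rejected with their full key path.
#'
#' @param path YAML file path.
#' @return List of class `run_config`: `seed`, `cohort` (cohort_config),
#'   `gait` (gait_config), `analysis` (analysis_config).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_blocks <- c("seed", "cohort", "gait", "analysis")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "),
          class = "invalid_config_error")
  check_block <- function(block, ctor, name) {
    block <- if (is.null(block)) list() else block
    bad <- setdiff(names(block), names(formals(ctor)))
    if (length(bad))
      stopf("unknown configuration key(s): %s",
            paste(paste0(name, ".", bad), collapse = ", "),
            class = "invalid_config_error")
    do.call(ctor, block)
  }
  structure(list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    cohort = check_block(raw$cohort, cohort_config, "cohort"),
    gait = check_block(raw$gait, gait_config, "gait"),
    analysis = check_block(raw$analysis, analysis_config, "analysis")
  ), class = "run_config")
}

# Write the resolved configuration back out so an analysis run can reuse
# the thresholds and gait settings the cohort was simulated with.
write_run_config <- function(config, path) {
  yaml::write_yaml(list(seed = config$seed,
                        cohort = unclass(config$cohort),
                        gait = unclass(config$gait),
                        analysis = unclass(config$analysis)), path)
  invisible(path)
}

# Manifest: one content hash per artifact, for byte-level reproducibility.
write_manifest <- function(dir, files) {
  files <- sort(files)
  hashes <- unname(tools::md5sum(file.path(dir, files)))
  manifest <- lapply(seq_along(files),
                     function(i) list(file = files[i], md5 = hashes[i]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
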