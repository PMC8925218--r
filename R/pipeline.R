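# Pipeline commands tying the stages together: simulate a cohort directory,
# analyze it into per-heel properties, and report summary / correlation /
# comparison tables. Thin wrappers over the module functions; also driven by
# the command-line script in inst/cli/heelpad.

trial_filename <- function(subject_id, side, condition)
  sprintf("trial_%s_%s_%s.csv", subject_id, side, condition)

msg <- function(fmt, ...) message(sprintf(fmt, ...))

#' Simulate a cohort directory
#'
#' Samples a cohort, simulates every heel's stance trial, and writes the
#' cohort parameter table, one trial CSV per heel, optional scene files, the
#' resolved configuration, and a manifest with an MD5 content hash per
#' artifact. Deterministic: identical `(config, seed)` produce identical
#' manifests.
#'
#' @param config a [read_run_config()] result, a path to a YAML config, or
#'   NULL for defaults.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; overrides the config's seed when given.
#' @param write_scenes also render and write 3D scenes per heel (larger
#'   outputs; off by default).
#' @return Invisibly, the cohort parameter table.
#' @export
cmd_simulate <- function(config = NULL, out_dir, seed = NULL,
                         write_scenes = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config))
    config <- structure(list(seed = 1L, cohort = cohort_config(),
                             gait = gait_config(),
                             analysis = analysis_config()),
                        class = "run_config")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  cohort <- sample_cohort(config$cohort, config$seed)
  files <- c("cohort_params.csv", "config_used.yaml")
  write_cohort_csv(cohort, file.path(out_dir, "cohort_params.csv"))
  write_run_config(config, file.path(out_dir, "config_used.yaml"))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    tr <- simulate_stance(row, config$gait)
    fn <- trial_filename(row$subject_id, row$side, row$condition)
    write_trial_csv(tr, file.path(out_dir, fn))
    files <- c(files, fn)
    if (isTRUE(write_scenes)) {
      sc <- render_scene(row, tr, config$gait)
      jfn <- sub("^trial_", "scene_", sub("\\.csv$", ".json", fn))
      cfn <- sub("\\.json$", ".csv", jfn)
      write_scene(sc, file.path(out_dir, jfn), file.path(out_dir, cfn))
      files <- c(files, jfn, cfn)
    }
  }
  write_manifest(out_dir, files)
  msg("simulate: %d heels written to %s [%.2f s]", nrow(cohort), out_dir,
      proc.time()[["elapsed"]] - t0)
  invisible(cohort)
}

#' Analyze a cohort directory into per-heel properties
#'
#' Reads the cohort parameter table and every trial in the directory, runs
#' [analyze_trial()] on each (from the thickness channel, or from rendered
#' scene geometry with `from = "geometry"`), and writes
#' `heel_properties.csv`: one row of covariates plus the six estimated
#' properties per heel. Per-trial failures are isolated, logged, and
#' summarized at exit rather than aborting the cohort.
#'
#' @param dir cohort directory produced by [cmd_simulate()] (or matching its
#'   schema).
#' @param from `"thickness"` (default) or `"geometry"`.
#' @param config optional run config; defaults to the directory's
#'   `config_used.yaml` when present.
#' @return Invisibly, the properties data frame.
#' @export
cmd_analyze <- function(dir, from = c("thickness", "geometry"),
                        config = NULL) {
  from <- match.arg(from)
  params_path <- file.path(dir, "cohort_params.csv")
  if (!file.exists(params_path))
    stopf("'%s' does not look like a cohort directory (no cohort_params.csv)",
          dir, class = "schema_error")
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) {
    cfg_path <- file.path(dir, "config_used.yaml")
    config <- if (file.exists(cfg_path)) read_run_config(cfg_path)
    else structure(list(seed = 1L, cohort = cohort_config(),
                        gait = gait_config(), analysis = analysis_config()),
                   class = "run_config")
  }
  cohort <- read_cohort_csv(params_path)
  rows <- vector("list", nrow(cohort))
  failures <- character(0)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    fn <- trial_filename(row$subject_id, row$side, row$condition)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      trial <- read_trial_csv(file.path(dir, fn))
      scene <- NULL
      if (from == "geometry") {
        jfn <- sub("^trial_", "scene_", sub("\\.csv$", ".json", fn))
        jp <- file.path(dir, jfn)
        if (!file.exists(jp))
          stopf("no scene file '%s'; rerun cmd_simulate(write_scenes = TRUE)",
                jfn, class = "schema_error")
        scene <- read_scene(jp)
      }
      analyze_trial(trial, config$analysis, scene = scene)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", fn, conditionMessage(res)))
      next
    }
    msg("analyze: %s [%.3f s]", fn, proc.time()[["elapsed"]] - t0)
    rows[[i]] <- cbind(row[, c("subject_id", "side", "condition", "age", "bmi")],
                       as.data.frame(res))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(failures)) {
    for (f in failures) msg("analyze: FAILED %s", f)
    warning(sprintf("%d of %d trials failed; see messages", length(failures),
                    nrow(cohort)), call. = FALSE)
  }
  if (!length(rows))
    stopf("no trial could be analyzed in '%s'", dir, class = "empty_input_error")
  props <- do.call(rbind, rows)
  rownames(props) <- NULL
  write.csv(props, file.path(dir, "heel_properties.csv"), row.names = FALSE)
  invisible(props)
}

#' Read a heel-properties CSV
#'
#' @param path CSV written by [cmd_analyze()].
#' @return Cohort record data frame.
#' @export
read_properties_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  check_records(out)
  out
}

fmt_cell <- function(x, digits) {
  digits <- rep_len(digits, length(x))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) "" else formatC(x[i], format = "f", digits = digits[i])
  }, character(1))
}

#' Report summary, correlation and comparison tables
#'
#' From a heel-properties table, writes: a formatted median (min ~ max)
#' summary table by side and condition (2 decimals for mm / kPa / %, 3 for
#' strain), Pearson correlation matrices (R and p layers) per condition, the
#' condition comparison with paired Wilcoxon p-values, and the standardized
#' per-heel values used for paired plotting. With only one condition present
#' the comparison and the missing condition's matrices are skipped with a
#' warning; summaries are still written.
#'
#' @param properties heel-properties data frame or CSV path.
#' @param out_dir output directory.
#' @return Invisibly, a list of the tables written.
#' @export
cmd_report <- function(properties, out_dir) {
  if (is.character(properties)) properties <- read_properties_csv(properties)
  check_records(properties)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list()
  summ <- summarize_cohort(properties)
  digits <- c(primary_thickness = 2, peak_strain = 3, peak_stress = 2,
              elastic_modulus = 2, viscous_modulus = 2, edr = 2)
  d <- digits[summ$property]
  summ_fmt <- data.frame(
    property = summ$property, condition = summ$condition, side = summ$side,
    n = summ$n,
    summary = ifelse(summ$n == 0, "absent",
                     sprintf("%s (%s ~ %s)", fmt_cell(summ$median, d),
                             fmt_cell(summ$min, d), fmt_cell(summ$max, d))),
    stringsAsFactors = FALSE)
  write.csv(summ_fmt, file.path(out_dir, "summary_table.csv"),
            row.names = FALSE)
  tabs$summary <- summ
  conds <- intersect(c("time_zero", "post_loading"),
                     unique(properties$condition))
  for (cond in conds) {
    pm <- tryCatch(pearson_matrix(properties, condition = cond),
                   insufficient_data_error = function(e) NULL)
    if (is.null(pm)) {
      warning(sprintf("too few records for the %s correlation matrix", cond),
              call. = FALSE)
      next
    }
    write.csv(round(pm$r, 4), file.path(out_dir,
                                        sprintf("correlation_%s_R.csv", cond)))
    write.csv(signif(pm$p, 4), file.path(out_dir,
                                         sprintf("correlation_%s_p.csv", cond)))
    tabs[[paste0("correlation_", cond)]] <- pm
  }
  if (length(conds) == 2L) {
    cmp <- compare_conditions(properties)
    write.csv(as.data.frame(cmp), file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    write.csv(attr(cmp, "standardized"),
              file.path(out_dir, "standardized_values.csv"), row.names = FALSE)
    tabs$comparison <- cmp
  } else {
    warning("only one loading condition present; comparison skipped",
            call. = FALSE)
  }
  msg("report: tables written to %s", out_dir)
  invisible(tabs)
}
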