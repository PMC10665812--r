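# Tidy-CSV writers with JSON metadata sidecars, and the run manifest.

.param_hash <- function(params) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_parameters(params, tf)
  unname(tools::md5sum(tf))
}

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a trajectory to CSV (+ JSON sidecar)
#'
#' One row per time point, one column per state and observable; the
#' sidecar records the schedule, a parameter-set hash, solver metadata
#' and the package version.
#'
#' @param traj a `t2d_trajectory`.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return the CSV path, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  df <- as.data.frame(traj)
  csv <- paste0(prefix, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  .write_sidecar(paste0(prefix, ".json"), list(
    schedule = list(times = traj$schedule$times, levels = traj$schedule$levels,
                    horizon = traj$schedule$horizon),
    params_md5 = .param_hash(traj$params),
    solver = traj$solver,
    package_version = as.character(utils::packageVersion("t2dsim"))))
  invisible(csv)
}

#' Write an event log as JSON
#' @param events a `t2d_events` data frame.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(as.data.frame(unclass(events)), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a bifurcation diagram to CSV (+ JSON sidecar)
#' @param diagram a `t2d_bifurcation`.
#' @param prefix path prefix; writes `<prefix>.csv` (branches) and
#'   `<prefix>.json` (folds + metadata).
#' @export
write_diagram <- function(diagram, prefix) {
  csv <- paste0(prefix, ".csv")
  utils::write.csv(diagram$branches, csv, row.names = FALSE)
  .write_sidecar(paste0(prefix, ".json"), list(
    folds = diagram$folds, bmi_range = diagram$bmi_range,
    params_md5 = .param_hash(diagram$params),
    package_version = as.character(utils::packageVersion("t2dsim"))))
  invisible(csv)
}

#' Write a remission map to CSV (+ JSON sidecar)
#' @param map a `t2d_remission_map`.
#' @param prefix path prefix.
#' @export
write_map <- function(map, prefix) {
  csv <- paste0(prefix, ".csv")
  utils::write.csv(map$grid, csv, row.names = FALSE)
  .write_sidecar(paste0(prefix, ".json"), list(
    de_range = map$de_range,
    threshold_bmi_range = map$threshold$range,
    params_md5 = .param_hash(map$params),
    package_version = as.character(utils::packageVersion("t2dsim"))))
  invisible(csv)
}

#' Write a cohort in long format (+ summary CSVs)
#'
#' `<prefix>_long.csv`: individual, time, variable, value, label (on the
#' stored output grid, thinned to `every` months);
#' `<prefix>_summary.csv` and `<prefix>_duration.csv`: group summaries;
#' `<prefix>_tests.csv`: t-test table.
#'
#' @param cohort a `t2d_cohort`.
#' @param prefix path prefix.
#' @param every thinning interval for the long table, months.
#' @export
write_cohort <- function(cohort, prefix, every = 1) {
  rows <- lapply(cohort, function(ind) {
    tr <- ind$trajectory
    keep <- which(tr$time %% every < 1e-9 | tr$time == max(tr$time))
    vars <- c("G", "I", "FFA", "theta", "S_i", "beta", "sigma")
    long <- do.call(rbind, lapply(vars, function(v)
      data.frame(individual = ind$id, time = tr$time[keep], variable = v,
                 value = tr$state[keep, v], label = ind$label)))
    rbind(long, data.frame(individual = ind$id, time = tr$time[keep],
                           variable = "BMI", value = tr$obs$BMI[keep],
                           label = ind$label))
  })
  utils::write.csv(do.call(rbind, rows), paste0(prefix, "_long.csv"),
                   row.names = FALSE)
  sm <- summarize_cohort(cohort)
  utils::write.csv(sm$stats, paste0(prefix, "_summary.csv"), row.names = FALSE)
  utils::write.csv(sm$duration, paste0(prefix, "_duration.csv"), row.names = FALSE)
  utils::write.csv(sm$tests, paste0(prefix, "_tests.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Write a run manifest
#'
#' JSON record of the effective configuration: command, options,
#' parameter hash, seed, package version and timestamp. Timestamps are
#' confined to the manifest so repeated runs produce byte-identical
#' data files.
#'
#' @param path output path.
#' @param command subcommand name.
#' @param options named list of options.
#' @param params parameter set used.
#' @param seed seed used (or NA).
#' @export
write_manifest <- function(path, command, options, params, seed = NA) {
  .write_sidecar(path, list(
    command = command, options = options,
    params_md5 = .param_hash(params), seed = seed,
    package_version = as.character(utils::packageVersion("t2dsim")),
    timestamp = format(Sys.time(), tz = "UTC")))
}
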