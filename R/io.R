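# Plain-text trial container and report writers.
#
# A dataset is stored as a directory: `dataset.json` carries the format
# version, shared metadata and one record per trial (identifiers, target,
# sampling rate and the full stimulus schedule — schedules always travel
# with the data, so decoding never needs a side channel); each trial's
# sample x channel matrix lives in its own CSV file.

CONTAINER_VERSION <- 1L
REPORT_VERSION <- 1L

#' Write trials to a plain-text container
#'
#' @param trials A `trial_dataset` or list of `trial_data`.
#' @param dir Output directory (created, must not already contain a
#'   dataset).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  if (inherits(trials, "trial_dataset")) trials <- trials$trials
  if (length(trials) == 0L) stop_ccabci("no trials to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    file <- sprintf("trial_%04d.csv", i)
    data.table::fwrite(data.table::as.data.table(tr$X),
                       file.path(dir, file), col.names = FALSE)
    sched <- tr$schedule
    index[[i]] <- list(
      id = i, file = file, fs = tr$fs,
      subject_id = tr$subject_id, run_id = tr$run_id,
      target = tr$target, buffer = tr$buffer,
      channel_labels = tr$channel_labels, modality = tr$modality,
      schedule = list(
        n_objects = sched$n_objects, n_reps = sched$n_reps,
        soa = sched$soa, min_gap = sched$min_gap,
        truncated = sched$truncated, global_order = sched$global_order
      )
    )
  }
  meta <- list(format = "ccabci-trials", version = CONTAINER_VERSION,
               n_trials = length(trials), trials = index)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read trials back from a container directory
#'
#' @param dir Directory written by [write_trials()].
#' @return List of `trial_data`.
#' @export
read_trials <- function(dir) {
  meta_path <- file.path(dir, "dataset.json")
  if (!file.exists(meta_path)) {
    stop_ccabci("not a trial container: missing ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (is.null(meta$format) || meta$format != "ccabci-trials") {
    stop_ccabci("not a ccabci trial container")
  }
  if (meta$version > CONTAINER_VERSION) {
    stop_ccabci("container format version ", meta$version,
                " is newer than supported (", CONTAINER_VERSION, ")")
  }
  lapply(meta$trials, function(rec) {
    path <- file.path(dir, rec$file)
    if (!file.exists(path)) stop_ccabci("missing trial file ", rec$file)
    X <- as.matrix(data.table::fread(path, header = FALSE))
    dimnames(X) <- NULL
    sc <- rec$schedule
    sched <- new_stim_schedule(sc$n_objects, sc$n_reps, sc$soa, sc$min_gap,
                               unlist(sc$global_order),
                               truncated = isTRUE(sc$truncated))
    new_trial_data(
      X, rec$fs, sched,
      channel_labels = unlist(rec$channel_labels),
      modality = unlist(rec$modality),
      target = if (is.null(rec$target)) NA_integer_ else rec$target,
      run_id = if (is.null(rec$run_id)) NA_integer_ else rec$run_id,
      subject_id = if (is.null(rec$subject_id)) NA_integer_
                   else rec$subject_id,
      buffer = if (is.null(rec$buffer)) 0 else rec$buffer
    )
  })
}

#' Write an evaluation report to JSON (+ CSV curves)
#'
#' The summary (scheme, pooled accuracy, per-run / per-subject accuracies)
#' goes to `<path>.json`; per-trial results and any curve are written as
#' CSV next to it.
#'
#' @param report An `evaluation_report`.
#' @param path Output path prefix (without extension).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, path) {
  summary <- list(
    format = "ccabci-report", version = REPORT_VERSION,
    scheme = report$scheme, da = report$da, n_trials = nrow(report$results)
  )
  if (!is.null(report$per_run)) {
    summary$per_run <- as.list(report$per_run)
  }
  if (!is.null(report$per_subject)) {
    summary$per_subject <- as.list(report$per_subject)
  }
  json_path <- paste0(path, ".json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  data.table::fwrite(report$results, paste0(path, "_results.csv"))
  if (!is.null(report$curve)) {
    data.table::fwrite(report$curve, paste0(path, "_curve.csv"))
  }
  invisible(json_path)
}

#' Read an evaluation-report summary
#'
#' @param path The path prefix used in [write_report()].
#' @return The parsed summary list.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "ccabci-report") {
    stop_ccabci("not a ccabci report")
  }
  if (obj$version > REPORT_VERSION) {
    stop_ccabci("report version ", obj$version,
                " is newer than supported (", REPORT_VERSION, ")")
  }
  obj
}
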