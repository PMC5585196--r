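#' Write a cohort to a directory
#'
#' Layout: `cohort.yaml` (provenance and simulation config), `subjects.tsv`
#' (metadata with severity grades), and per-subject `sub-<id>_roi.tsv` /
#' `sub-<id>_confounds.tsv` tables (one row per time point).
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  prov <- attr(cohort, "provenance")
  yaml::write_yaml(list(config = unclass(cfg),
                        provenance = lapply(prov, unclass)),
                   file.path(dir, "cohort.yaml"))
  meta <- as.data.frame(cohort[, c("subject_id", "group", "gs_gait",
                                   "gs_cognition", "gs_urinary", "mmse")])
  write.table(meta, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rois <- attr(cohort, "rois")
  write.table(as.data.frame(rois), file.path(dir, "rois.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[k]
    write.table(as.data.frame(cohort$series[[k]]),
                file.path(dir, sprintf("sub-%s_roi.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(cohort$confounds[[k]]),
                file.path(dir, sprintf("sub-%s_confounds.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `fc_cohort`.
#' @export
read_cohort <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  cfg <- y$config
  cfg$confound_loading <- unlist(cfg$confound_loading)
  config <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
  meta <- read.delim(file.path(dir, "subjects.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  rois <- roi_table(read.delim(file.path(dir, "rois.tsv"), sep = "\t",
                               stringsAsFactors = FALSE))
  out <- validate_subject_spec(as_tibble(meta))
  out$series <- lapply(out$subject_id, function(id) {
    as.matrix(read.delim(file.path(dir, sprintf("sub-%s_roi.tsv", id)),
                         sep = "\t", check.names = FALSE))
  })
  out$confounds <- lapply(out$subject_id, function(id) {
    as.matrix(read.delim(file.path(dir, sprintf("sub-%s_confounds.tsv", id)),
                         sep = "\t", check.names = FALSE))
  })
  attr(out, "rois") <- rois
  attr(out, "config") <- config
  attr(out, "provenance") <- y$provenance
  class(out) <- unique(c("fc_cohort", class(out)))
  out
}

#' Run the full connectome-classification pipeline
#'
#' Simulate (or accept) a cohort, denoise it, compute connectivity features,
#' run leave-one-out classification for the diagnosis and the three severity
#' grades, and build the interpretation weight report per task. Deterministic
#' given the simulation seed.
#'
#' @param specs Subject specifications (default: the 22-subject cohort of
#'   [default_cohort_specs()]).
#' @param sim A [sim_config()].
#' @param band A [filter_band()].
#' @param classifier A [classifier_config()].
#' @param tasks Character vector of tasks to run.
#' @param cohort Optionally, a pre-built `fc_cohort` (raw, not denoised);
#'   when supplied, `specs` and `sim` are ignored.
#' @return A list of class `fc_pipeline` with `cohort` (denoised), `qc`,
#'   `features`, `cv` (named list of `fc_cv`), `weights` (named list of
#'   `fc_weights`), and `config`.
#' @examples
#' \donttest{
#' res <- run_fc_pipeline(sim = sim_config(n_rois = 20, seed = 42))
#' glance(res$cv$diagnosis)
#' }
#' @export
run_fc_pipeline <- function(specs = default_cohort_specs(),
                            sim = sim_config(),
                            band = filter_band(),
                            classifier = classifier_config(),
                            tasks = c("diagnosis", "gs_gait", "gs_cognition",
                                      "gs_urinary"),
                            cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(specs, sim)
  # QC assesses the confound-removal step on its own, before filtering
  qc <- qc_correlation_shift(cohort, regress_cohort(cohort))
  denoised <- denoise_cohort(cohort, band)
  features <- cohort_features(denoised)
  cv <- lapply(tasks, function(tk) loocv(features, tk, classifier))
  names(cv) <- tasks
  weights <- lapply(tasks, function(tk) weight_report(features, tk, classifier))
  names(weights) <- tasks
  structure(list(cohort = denoised, qc = qc, features = features,
                 cv = cv, weights = weights,
                 config = list(sim = attr(cohort, "config"), band = band,
                               classifier = classifier)),
            class = "fc_pipeline")
}

#' @export
print.fc_pipeline <- function(x, ...) {
  cat("<fc_pipeline>\n")
  cat(sprintf("  QC: mean %0.3f -> %0.3f, SD %0.3f -> %0.3f\n",
              x$qc$mean_before, x$qc$mean_after, x$qc$sd_before, x$qc$sd_after))
  for (tk in names(x$cv)) print(x$cv[[tk]])
  invisible(x)
}

#' One-row-per-task pipeline summary
#'
#' @param x An `fc_pipeline` object.
#' @param ... Unused.
#' @return Tibble combining each task's cross-validation and weight-report
#'   summaries.
#' @method glance fc_pipeline
#' @export
glance.fc_pipeline <- function(x, ...) {
  cvs <- bind_rows(lapply(x$cv, glance))
  ws <- bind_rows(lapply(x$weights, glance))
  left_join(cvs, ws, by = "task")
}

#' Serialize a pipeline report to JSON
#'
#' @param x An `fc_pipeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(x, path) {
  report <- list(
    schema_version = 1L,
    qc = as.list(x$qc),
    tasks = lapply(names(x$cv), function(tk) {
      c(as.list(glance(x$cv[[tk]])), as.list(glance(x$weights[[tk]])))
    }),
    config = list(sim = unclass(x$config$sim),
                  band = unclass(x$config$band),
                  classifier = unclass(x$config$classifier)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
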