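# Trace bundle I/O: full session traces as JSON plus a per-session CSV
# summary, with a matching reader so bundles round-trip losslessly.

#' Per-session summary table
#'
#' @param traces List of `ebbs_trace` objects.
#' @return Data frame with one row per session: `subject_id`, `n_tasks`,
#'   `prediction`, `confidence`, `stop_reason`, `task_order` (comma-joined).
#' @export
trace_summary <- function(traces) {
  data.frame(
    subject_id = vapply(traces, function(t) t$subject_id, character(1)),
    n_tasks = vapply(traces, function(t) t$n_tasks_used, integer(1)),
    prediction = vapply(traces, function(t) t$final_prediction, character(1)),
    confidence = vapply(traces, function(t) t$final_confidence, numeric(1)),
    stop_reason = vapply(traces, function(t) t$stop_reason, character(1)),
    task_order = vapply(traces, function(t) paste(t$task_order, collapse = ","),
                        character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a trace bundle
#'
#' Writes `traces.json` (full traces) and `summary.csv` to a directory.
#'
#' @param traces List of `ebbs_trace` objects (may be empty).
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_trace_bundle <- function(traces, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  payload <- lapply(traces, function(t) {
    list(subject_id = t$subject_id, task_order = t$task_order,
         evaluations = t$evaluations, final_prediction = t$final_prediction,
         final_confidence = t$final_confidence, n_tasks_used = t$n_tasks_used,
         stop_reason = t$stop_reason)
  })
  jsonlite::write_json(payload, file.path(path, "traces.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.csv(trace_summary(traces), file.path(path, "summary.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a trace bundle
#'
#' @param path Directory written by [write_trace_bundle()].
#' @return List of `ebbs_trace` objects.
#' @export
read_trace_bundle <- function(path) {
  f <- file.path(path, "traces.json")
  if (!file.exists(f)) stop("no traces.json under ", path, call. = FALSE)
  payload <- jsonlite::read_json(f, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    ev <- p$evaluations
    structure(list(
      subject_id = if (is.null(p$subject_id)) NA_character_ else p$subject_id,
      task_order = as.integer(unlist(p$task_order)),
      evaluations = data.frame(n_tasks = as.integer(unlist(ev$n_tasks)),
                               prediction = as.character(unlist(ev$prediction)),
                               confidence = as.numeric(unlist(ev$confidence)),
                               stringsAsFactors = FALSE),
      final_prediction = p$final_prediction,
      final_confidence = as.numeric(p$final_confidence),
      n_tasks_used = as.integer(p$n_tasks_used),
      stop_reason = p$stop_reason
    ), class = "ebbs_trace")
  })
}
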