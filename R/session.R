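# Adaptive administration engine.
#
# A session seeds with an initial task subset, predicts the risk category
# with the subset predictor after every administered task, and stops as soon
# as the prediction confidence reaches the threshold (or the battery is
# exhausted).  The subject's scores are read strictly on demand — a
# prediction never sees a score for a task that has not been administered.

#' Session configuration
#'
#' @param initial_subset Non-empty initial task subset (typically size 1-3,
#'   chosen via [optimal_initial_subset()]).
#' @param selector A `selector_config`; its `ct` is the stopping threshold.
#' @param max_tasks Cap on administered tasks (default: battery size).
#' @param stop_rule `"geq"` (stop when confidence >= CT; default) or `"gt"`
#'   (strictly exceeds).
#' @return A `session_config` list.
#' @export
session_config <- function(initial_subset, selector = selector_config(),
                           max_tasks = NULL, stop_rule = c("geq", "gt")) {
  stop_rule <- match.arg(stop_rule)
  initial_subset <- sort(as.integer(initial_subset))
  if (length(initial_subset) == 0L) {
    stop("initial_subset must be non-empty", call. = FALSE)
  }
  structure(list(initial_subset = initial_subset, selector = selector,
                 max_tasks = max_tasks, stop_rule = stop_rule),
            class = "session_config")
}

stop_reached <- function(conf, ct, stop_rule) {
  if (stop_rule == "geq") conf >= ct else conf > ct
}

administer <- function(subject, task_id, battery, trace) {
  v <- as_score_vector(subject, battery)
  s <- v[task_cols(task_id)]
  if (is.na(s)) {
    stop(structure(class = c("ebbs_missing_administration", "error", "condition"),
                   list(message = paste0("subject has no score for administered task ",
                                         task_id),
                        call = NULL, task_id = task_id, partial_trace = trace)))
  }
  unname(s)
}

new_trace <- function(subject_id) {
  list(subject_id = subject_id, task_order = integer(0),
       evaluations = data.frame(n_tasks = integer(0), prediction = character(0),
                                confidence = numeric(0), stringsAsFactors = FALSE),
       final_prediction = NA_character_, final_confidence = NA_real_,
       n_tasks_used = 0L, stop_reason = NA_character_)
}

record_eval <- function(trace, css, pred) {
  trace$evaluations <- rbind(trace$evaluations, data.frame(
    n_tasks = length(css), prediction = as.character(pred$category),
    confidence = pred$confidence, stringsAsFactors = FALSE))
  trace$final_prediction <- as.character(pred$category)
  trace$final_confidence <- pred$confidence
  trace$n_tasks_used <- length(css)
  trace
}

finish_trace <- function(trace, reason) {
  trace$stop_reason <- reason
  class(trace) <- "ebbs_trace"
  trace
}

#' Run one adaptive E-BBS session
#'
#' @param subject Score vector (named `task_<id>` or one-row cohort) holding
#'   a score for every task the session may request.
#' @param bank A `predictor_bank` built on the training cohort.
#' @param config A `session_config`.
#' @return An `ebbs_trace`: `task_order` (administration order),
#'   `evaluations` (prediction + confidence after the initial subset and
#'   after each added task), `final_prediction`, `final_confidence`,
#'   `n_tasks_used`, and `stop_reason` (`confidence_reached` or
#'   `tasks_exhausted`).
#' @export
run_session <- function(subject, bank, config) {
  battery <- bank$battery
  ct <- config$selector$ct
  max_tasks <- if (is.null(config$max_tasks)) nrow(battery) else
    min(config$max_tasks, nrow(battery))
  sid <- if (is.data.frame(subject) && "subject_id" %in% names(subject)) {
    as.character(subject$subject_id[1L])
  } else NA_character_
  trace <- new_trace(sid)
  css <- config$initial_subset
  if (!all(css %in% battery$task_id)) {
    stop("initial subset outside the battery", call. = FALSE)
  }
  if (length(css) > max_tasks) {
    stop("initial subset larger than max_tasks", call. = FALSE)
  }
  administered <- stats::setNames(rep(NA_real_, nrow(battery)),
                                  task_cols(battery$task_id))
  for (tt in css) {
    administered[task_cols(tt)] <- administer(subject, tt, battery, trace)
  }
  trace$task_order <- css
  pred <- predict_risk(bank, css, administered[task_cols(css)])
  trace <- record_eval(trace, css, pred)
  repeat {
    if (stop_reached(pred$confidence, ct, config$stop_rule)) {
      return(finish_trace(trace, "confidence_reached"))
    }
    ut <- setdiff(battery$task_id, css)
    if (length(ut) == 0L || length(css) >= max_tasks) {
      return(finish_trace(trace, "tasks_exhausted"))
    }
    patient <- if (config$selector$method >= 3L) {
      administered[task_cols(css)]
    } else NULL
    nt <- select_next_task(bank, css, ut, config$selector, patient)
    administered[task_cols(nt)] <- administer(subject, nt, battery, trace)
    css <- sort(c(css, nt))
    trace$task_order <- c(trace$task_order, as.integer(nt))
    pred <- predict_risk(bank, css, administered[task_cols(css)])
    trace <- record_eval(trace, css, pred)
  }
}

#' Replay a session in a fixed task order
#'
#' Administers tasks in a constant order (e.g. the standard 1-14 sequence,
#' or the constant order produced by a patient-independent selector) with
#' the same stopping rule as [run_session()].
#'
#' @param subject Score vector.
#' @param bank A `predictor_bank`.
#' @param order Permutation of the battery task numbers.
#' @param ct Confidence threshold in (0, 1].
#' @param stop_rule `"geq"` or `"gt"`.
#' @return An `ebbs_trace`.
#' @export
fixed_order_session <- function(subject, bank, order, ct,
                                stop_rule = c("geq", "gt")) {
  stop_rule <- match.arg(stop_rule)
  battery <- bank$battery
  order <- as.integer(order)
  if (length(order) != nrow(battery) || !setequal(order, battery$task_id) ||
      anyDuplicated(order)) {
    stop("order must be a permutation of the battery task numbers", call. = FALSE)
  }
  sid <- if (is.data.frame(subject) && "subject_id" %in% names(subject)) {
    as.character(subject$subject_id[1L])
  } else NA_character_
  trace <- new_trace(sid)
  administered <- stats::setNames(rep(NA_real_, nrow(battery)),
                                  task_cols(battery$task_id))
  css <- integer(0)
  for (tt in order) {
    administered[task_cols(tt)] <- administer(subject, tt, battery, trace)
    css <- sort(c(css, tt))
    trace$task_order <- c(trace$task_order, tt)
    pred <- predict_risk(bank, css, administered[task_cols(css)])
    trace <- record_eval(trace, css, pred)
    if (stop_reached(pred$confidence, ct, stop_rule)) {
      return(finish_trace(trace, "confidence_reached"))
    }
  }
  finish_trace(trace, "tasks_exhausted")
}

#' @export
print.ebbs_trace <- function(x, ...) {
  cat(sprintf("E-BBS session%s: %d task(s) [%s] -> %s (confidence %.2f, %s)\n",
              if (is.na(x$subject_id)) "" else paste0(" ", x$subject_id),
              x$n_tasks_used, paste(x$task_order, collapse = ", "),
              x$final_prediction, x$final_confidence, x$stop_reason))
  invisible(x)
}
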