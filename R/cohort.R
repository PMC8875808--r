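# Cohort container and CSV score-table I/O.
#
# A cohort is a data frame with columns subject_id, task_<id> ... (one per
# battery task, NA = task not performed/scored), and risk_label (factor
# high/medium/low).  For the standard 14-task battery a missing risk_label is
# derived from the total score when all 14 scores are present.

#' Validate (and label) a cohort data frame
#'
#' @param df Data frame with `subject_id`, one `task_<id>` column per battery
#'   task, and optionally `risk_label`.
#' @param battery A `bbs_battery`.
#' @return The validated cohort, class `ebbs_cohort`.
#' @export
as_cohort <- function(df, battery = bbs_battery()) {
  if (!is.data.frame(df)) stop("cohort must be a data frame", call. = FALSE)
  cols <- task_cols(battery$task_id)
  if (!"subject_id" %in% names(df)) {
    stop("cohort must have a subject_id column", call. = FALSE)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop("cohort is missing task column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  for (j in cols) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.na(df[[j]]) & (is.na(x) | x < 0 | x > 4 | x != round(x)))
    if (length(bad) > 0L) {
      stop(sprintf("invalid score in column %s, row(s) %s (scores are integers 0-4)",
                   j, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[j]] <- as.integer(x)
  }
  if (!"risk_label" %in% names(df)) {
    df$risk_label <- NA_character_
  }
  lab <- as.character(df$risk_label)
  bad <- which(!is.na(lab) & !lab %in% risk_levels())
  if (length(bad) > 0L) {
    stop("unknown risk label in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0L && anyNA(lab)) {
    sm <- as.matrix(df[cols])
    complete <- !apply(sm, 1L, anyNA)
    derivable <- is.na(lab) & complete & length(cols) == 14L
    if (any(derivable)) {
      lab[derivable] <- as.character(classify_risk(rowSums(sm[derivable, , drop = FALSE])))
    }
    if (anyNA(lab)) {
      stop("risk_label missing and not derivable (need all 14 scores) in row(s): ",
           paste(which(is.na(lab)), collapse = ", "), call. = FALSE)
    }
  }
  df$risk_label <- risk_factor(lab)
  attr(df, "battery") <- battery
  class(df) <- unique(c("ebbs_cohort", class(df)))
  df
}

#' Read a cohort score table from CSV
#'
#' Expected header: `subject_id,task_1,...,task_14[,risk_label]` (task columns
#' follow the battery).  Blank cells are missing scores; `risk_label` values,
#' when present, must be `high`, `medium`, or `low`, and when absent are
#' derived from the total score for subjects with all 14 scores.
#'
#' @param path CSV file path.
#' @param battery A `bbs_battery`.
#' @return An `ebbs_cohort` data frame.
#' @export
read_score_table <- function(path, battery = bbs_battery()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = c("", "NA"))
  cols <- c("subject_id", task_cols(battery$task_id))
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop("malformed header; missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as_cohort(df, battery)
}

#' Write a cohort score table to CSV
#'
#' @param cohort An `ebbs_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(cohort, path) {
  battery <- cohort_battery(cohort)
  cols <- c("subject_id", task_cols(battery$task_id), "risk_label")
  out <- as.data.frame(cohort)[cols]
  out$risk_label <- as.character(out$risk_label)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

cohort_battery <- function(cohort) {
  b <- attr(cohort, "battery")
  if (is.null(b)) bbs_battery() else b
}

#' Score matrix of a cohort
#'
#' @param cohort An `ebbs_cohort`.
#' @return Numeric matrix (subjects x battery tasks), NA = missing, with
#'   `task_<id>` column names and subject ids as row names.
#' @export
score_matrix <- function(cohort) {
  battery <- cohort_battery(cohort)
  m <- as.matrix(as.data.frame(cohort)[task_cols(battery$task_id)])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$subject_id
  m
}

# Row indices of subjects with no missing score on the given tasks.
complete_on <- function(cohort, task_ids) {
  if (length(task_ids) == 0L) return(seq_len(nrow(cohort)))
  m <- as.matrix(as.data.frame(cohort)[task_cols(task_ids)])
  which(!apply(m, 1L, anyNA))
}
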