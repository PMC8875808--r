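# Core domain model: the Berg Balance Scale battery, score vectors,
# total score, and the three-band fall-risk mapping.

#' Standard BBS task descriptions
#'
#' Short descriptions of the 14 Berg Balance Scale motor tasks, in standard
#' task-number order.
#'
#' @return Character vector of length 14, named by task number.
#' @export
bbs_task_names <- function() {
  nm <- c(
    "Sitting to Standing",
    "Standing Unsupported",
    "Sitting with Back Unsupported",
    "Standing to Sitting",
    "Transfers",
    "Standing Unsupported, Eyes Closed",
    "Standing Unsupported, Feet Together",
    "Reaching Forward",
    "Pick up Object from the Floor",
    "Look Behind Shoulders",
    "Turn 360 Degrees",
    "Alternate Feet on Step",
    "Standing Unsupported, One Foot in Front",
    "Standing on One Leg"
  )
  names(nm) <- as.character(1:14)
  nm
}

#' Construct a BBS battery
#'
#' A battery is an ordered registry of scored motor tasks.  The standard Berg
#' Balance Scale has exactly 14 tasks, numbered 1-14, each scored on the
#' five-level 0 (unable) to 4 (independent) scale.  Truncated batteries (a
#' subset of the standard tasks, in standard numbering) are supported for
#' small-scale experiments.
#'
#' @param task_ids Integer task numbers drawn from 1-14 (default: the full
#'   standard battery).
#' @return A data frame of class `bbs_battery` with columns `task_id`,
#'   `name`, `max_score`.
#' @export
bbs_battery <- function(task_ids = 1:14) {
  task_ids <- as.integer(task_ids)
  if (length(task_ids) == 0L) {
    stop("a battery must contain at least one task", call. = FALSE)
  }
  if (anyNA(task_ids) || any(task_ids < 1L | task_ids > 14L)) {
    stop("task ids must be integers in 1-14", call. = FALSE)
  }
  if (anyDuplicated(task_ids)) {
    stop("task ids must be unique within a battery", call. = FALSE)
  }
  out <- data.frame(
    task_id = task_ids,
    name = unname(bbs_task_names()[as.character(task_ids)]),
    max_score = 4L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bbs_battery", "data.frame")
  out
}

#' Short-form BBS comparator battery
#'
#' The short-form BBS (SFBBS) administers seven of the fourteen standard
#' tasks.  The published membership is configuration here: only the size
#' constraint (exactly seven distinct standard task numbers) is enforced.
#'
#' @param member_ids Exactly 7 distinct task numbers from 1-14.
#' @return A `bbs_battery` of size 7.
#' @export
sfbbs_battery <- function(member_ids) {
  member_ids <- as.integer(member_ids)
  if (anyNA(member_ids) || any(member_ids < 1L | member_ids > 14L)) {
    stop("SFBBS member ids must be integers in 1-14", call. = FALSE)
  }
  member_ids <- unique(member_ids)
  if (length(member_ids) != 7L) {
    stop("the SFBBS comparator battery must contain exactly 7 distinct tasks",
         call. = FALSE)
  }
  bbs_battery(sort(member_ids))
}

#' Risk category labels
#'
#' The three fall-risk bands, ordered by decreasing risk.  The ordinal codes
#' used throughout (for MSE and threshold adjustment) are high = 0,
#' medium = 1, low = 2.
#'
#' @return Character vector `c("high", "medium", "low")`.
#' @export
risk_levels <- function() c("high", "medium", "low")

#' Ordinal code of a risk category
#'
#' @param label Character or factor of risk labels.
#' @return Integer codes: high = 0, medium = 1, low = 2.
#' @export
risk_code <- function(label) {
  label <- as.character(label)
  bad <- !label %in% risk_levels()
  if (any(bad)) {
    stop("unknown risk label(s): ", paste(unique(label[bad]), collapse = ", "),
         call. = FALSE)
  }
  match(label, risk_levels()) - 1L
}

risk_factor <- function(label) factor(as.character(label), levels = risk_levels())

task_cols <- function(task_ids) paste0("task_", as.integer(task_ids))

#' Total BBS score
#'
#' Sum of the scores over the battery tasks (0-56 for the standard 14-task
#' battery).  All battery scores must be present; missing tasks are an error
#' naming the offending task numbers.
#'
#' @param v Named numeric score vector with names `task_<id>` (or a one-row
#'   data frame holding those columns); each present score an integer in 0-4.
#' @param battery A `bbs_battery` (default: the standard 14-task battery).
#' @return Integer total score.
#' @export
total_score <- function(v, battery = bbs_battery()) {
  v <- as_score_vector(v, battery)
  missing_ids <- battery$task_id[is.na(v)]
  if (length(missing_ids) > 0L) {
    stop("cannot compute total score; missing scores for task(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  as.integer(sum(v))
}

#' Map a total BBS score to a fall-risk category
#'
#' Totals 0-20 are high risk, 21-40 medium risk, and 41-56 low risk.
#'
#' @param total Integer total score(s) in 0-56.
#' @return Factor with levels `high`, `medium`, `low`.
#' @export
classify_risk <- function(total) {
  total <- as.numeric(total)
  if (anyNA(total) || any(total < 0 | total > 56)) {
    stop("total score must lie in 0-56", call. = FALSE)
  }
  lab <- ifelse(total <= 20, "high", ifelse(total <= 40, "medium", "low"))
  risk_factor(lab)
}

#' Restrict a score vector to a task subset
#'
#' Returns the scores for exactly the tasks in `task_ids` (ascending task
#' number), unchanged.  An empty subset yields an empty vector.  A requested
#' task with a missing score is an error.
#'
#' @param v Named score vector (names `task_<id>`) or one-row data frame.
#' @param task_ids Task numbers to keep (must belong to the battery).
#' @param battery A `bbs_battery`.
#' @return Named numeric vector over `task_ids`.
#' @export
restrict <- function(v, task_ids, battery = bbs_battery()) {
  task_ids <- sort(as.integer(task_ids))
  if (length(task_ids) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (!all(task_ids %in% battery$task_id)) {
    stop("subset contains task(s) outside the battery: ",
         paste(setdiff(task_ids, battery$task_id), collapse = ", "),
         call. = FALSE)
  }
  v <- as_score_vector(v, battery)
  out <- v[task_cols(task_ids)]
  if (anyNA(out)) {
    stop("missing score(s) for requested task(s): ",
         paste(task_ids[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

# Coerce a score container (named vector or one-row data frame) to a numeric
# vector over the battery tasks, NA marking missing scores.
as_score_vector <- function(v, battery = bbs_battery()) {
  cols <- task_cols(battery$task_id)
  if (is.data.frame(v)) {
    if (nrow(v) != 1L) {
      stop("expected a single subject (one row)", call. = FALSE)
    }
    present <- intersect(cols, names(v))
    out <- stats::setNames(rep(NA_real_, length(cols)), cols)
    out[present] <- as.numeric(v[1L, present])
  } else {
    if (is.null(names(v))) {
      if (length(v) != length(cols)) {
        stop("unnamed score vector must cover the whole battery", call. = FALSE)
      }
      names(v) <- cols
    }
    out <- stats::setNames(rep(NA_real_, length(cols)), cols)
    keep <- intersect(cols, names(v))
    out[keep] <- as.numeric(v[keep])
  }
  ok <- is.na(out) | (out >= 0 & out <= 4 & out == round(out))
  if (!all(ok)) {
    stop("scores must be integers in 0-4; offending task(s): ",
         paste(battery$task_id[!ok], collapse = ", "), call. = FALSE)
  }
  out
}
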