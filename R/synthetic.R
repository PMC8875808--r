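# Synthetic score-cohort generator.
#
# Scores follow a binomial-logistic latent-ability model: subject i draws a
# latent balance ability theta_i from a three-component normal mixture (one
# component per intended risk stratum); the score on task t is a binomial
# count with 4 trials and success probability plogis(a_t * (theta_i - b_t)),
# i.e. an integer in 0-4 whose expectation rises with ability and falls with
# task difficulty b_t.  Risk labels are computed from the complete (pre-
# masking) totals, then missingness is applied per task, so stored labels are
# always sum-consistent with the unmasked scores.

#' Synthetic cohort generator configuration
#'
#' @param n_subjects Number of subjects to simulate.
#' @param ability_mixture Data frame with columns `weight`, `mean`, `sd` — one
#'   row per ability stratum; weights must sum to 1.
#' @param task_difficulty Numeric vector `b_t`, one per battery task (latent
#'   ability at which the expected task score is 2).
#' @param task_discrimination Positive numeric vector `a_t`, one per task
#'   (slope of the score-ability relationship).
#' @param missing_rate Per-task probability in [0, 1) that a score is masked
#'   as not administered.  Scalar or one value per task.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @param battery A `bbs_battery`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects,
                             ability_mixture,
                             task_difficulty,
                             task_discrimination,
                             missing_rate = 0,
                             seed = 1L,
                             battery = bbs_battery()) {
  n_tasks <- nrow(battery)
  stopifnot(is.data.frame(ability_mixture),
            all(c("weight", "mean", "sd") %in% names(ability_mixture)))
  if (length(n_subjects) != 1L || n_subjects < 1 || n_subjects != round(n_subjects)) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  if (abs(sum(ability_mixture$weight) - 1) > 1e-8 || any(ability_mixture$weight < 0)) {
    stop("ability mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(ability_mixture$sd <= 0)) {
    stop("ability mixture sds must be positive", call. = FALSE)
  }
  if (length(task_difficulty) != n_tasks) {
    stop("task_difficulty must have one value per battery task", call. = FALSE)
  }
  if (length(task_discrimination) == 1L) {
    task_discrimination <- rep(task_discrimination, n_tasks)
  }
  if (length(task_discrimination) != n_tasks || any(task_discrimination <= 0)) {
    stop("task_discrimination must be positive, one value per task", call. = FALSE)
  }
  if (length(missing_rate) == 1L) missing_rate <- rep(missing_rate, n_tasks)
  if (length(missing_rate) != n_tasks || any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1), scalar or one per task", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    ability_mixture = ability_mixture,
    task_difficulty = as.numeric(task_difficulty),
    task_discrimination = as.numeric(task_discrimination),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed),
    battery = battery
  ), class = "generator_config")
}

#' Default synthetic BBS cohort profile
#'
#' A 14-task profile calibrated qualitatively to the difficulty structure of
#' a mixed geriatric in-patient cohort: task 3 (sitting unsupported) is by
#' far the easiest and is almost always scored 4; tasks 12-14 (stepping and
#' single-leg stances) are the hardest, with substantial mass on low scores.
#' The three ability strata centre the expected totals near 12, 30, and 47
#' points — the middles of the high-, medium-, and low-risk bands — with
#' more low-risk than high-risk subjects (weights 0.15 / 0.35 / 0.50),
#' echoing a screening population enriched with ambulatory controls.
#'
#' @param n_subjects Number of subjects (default 130, a typical single-site
#'   pilot cohort size).
#' @param seed Integer seed.
#' @param missing_rate Per-task masking probability (default 0.05, a light
#'   rate of unperformed/unscorable tasks).
#' @return A `generator_config`.
#' @export
default_bbs_profile <- function(n_subjects = 130L, seed = 1L, missing_rate = 0.05) {
  generator_config(
    n_subjects = n_subjects,
    ability_mixture = data.frame(
      weight = c(0.15, 0.35, 0.50),
      mean = c(-2.7, -0.7, 1.5),
      sd = c(0.6, 0.55, 0.7)
    ),
    task_difficulty = c(-2.5, -1.8, -4.0, -2.3, -1.2, -1.5, -1.0,
                        -0.8, -1.0, -0.6, 0.6, 1.2, 1.4, 1.6),
    task_discrimination = c(1.2, 1.1, 1.0, 1.2, 1.0, 1.1, 1.0,
                            0.9, 1.0, 0.8, 1.1, 1.0, 0.9, 0.9),
    missing_rate = missing_rate,
    seed = seed,
    battery = bbs_battery()
  )
}

#' Generate a synthetic score cohort
#'
#' @param cfg A `generator_config`.
#' @return An `ebbs_cohort` with attributes `theta` (latent abilities),
#'   `true_total` (pre-masking totals), and `config`.
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "generator_config")) {
    stop("cfg must be a generator_config", call. = FALSE)
  }
  battery <- cfg$battery
  n <- cfg$n_subjects
  k <- nrow(battery)
  cohort <- local_seed(cfg$seed, {
    comp <- sample.int(nrow(cfg$ability_mixture), n, replace = TRUE,
                       prob = cfg$ability_mixture$weight)
    theta <- stats::rnorm(n, cfg$ability_mixture$mean[comp],
                          cfg$ability_mixture$sd[comp])
    scores <- matrix(NA_integer_, n, k, dimnames = list(NULL, task_cols(battery$task_id)))
    for (t in seq_len(k)) {
      p <- stats::plogis(cfg$task_discrimination[t] * (theta - cfg$task_difficulty[t]))
      scores[, t] <- stats::rbinom(n, 4L, p)
    }
    true_total <- rowSums(scores)
    label <- classify_risk(true_total)
    mask <- matrix(stats::runif(n * k), n, k) <
      matrix(cfg$missing_rate, n, k, byrow = TRUE)
    scores[mask] <- NA_integer_
    df <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(scores))
    df$risk_label <- label
    out <- as_cohort(df, battery)
    attr(out, "theta") <- theta
    attr(out, "true_total") <- true_total
    out
  })
  attr(cohort, "config") <- cfg
  cohort
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
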