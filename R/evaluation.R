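# Cross-validated evaluation of the adaptive battery: accuracy vs. mean
# number of administered tasks across confidence thresholds, occurrence
# matrices of the produced task sequences, and the short-form comparator.

# Stratified fold assignment; errors if any fold would lose a class.
stratified_folds <- function(y, n_folds, seed = 1L) {
  y <- as.character(y)
  n <- length(y)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  assign_f <- integer(n)
  local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign_f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  tab <- table(factor(assign_f, levels = seq_len(n_folds)), factor(y))
  if (any(tab == 0)) {
    stop("stratification failed: a fold lost a risk class (cohort too small?)",
         call. = FALSE)
  }
  assign_f
}

#' Cross-validated accuracy vs. mean-tasks curve
#'
#' For each fold, a predictor bank (and, when requested, the optimal initial
#' subset) is trained on the training split only; adaptive sessions are then
#' run on the held-out subjects that are complete on the battery, once per
#' confidence threshold.  Accuracy is the pooled proportion of correct final
#' risk predictions; `mean_tasks` the pooled average number of administered
#' tasks.
#'
#' @param cohort An `ebbs_cohort` spanning at least two risk classes.
#' @param selector A `selector_config` (its `ct` is overridden by
#'   `thresholds`).
#' @param thresholds Confidence thresholds to sweep (default the 0.90-1.00
#'   ladder).
#' @param initial Either an integer size (the optimal subset of that size is
#'   re-searched within each fold) or a fixed vector of task numbers.
#' @param n_folds Stratified folds (default 5).
#' @param bank_cfg A `bank_config` template; per-fold seeds are derived from
#'   `seed`.
#' @param seed Integer seed controlling folds and per-fold bank seeds.
#' @param return_traces Keep all session traces (for occurrence matrices)?
#' @return Data frame of class `ebbs_curve` with columns `ct`, `accuracy`,
#'   `mean_tasks`, `n_eval`; attributes `traces` (per threshold, if
#'   requested) and `pooled` (per-threshold truth/predicted factors).
#' @export
crossval_curve <- function(cohort, selector = selector_config(),
                           thresholds = c(0.90, 0.92, 0.94, 0.96, 0.98, 1.00),
                           initial = 3L, n_folds = 5L,
                           bank_cfg = bank_config(), seed = 1L,
                           return_traces = FALSE) {
  battery <- cohort_battery(cohort)
  y <- as.character(cohort$risk_label)
  assign_f <- stratified_folds(y, n_folds, seed)
  res <- lapply(thresholds, function(ct) {
    list(truth = character(0), pred = character(0), n_tasks = integer(0),
         traces = list())
  })
  names(res) <- as.character(thresholds)
  for (f in seq_len(n_folds)) {
    train <- cohort[assign_f != f, , drop = FALSE]
    attr(train, "battery") <- battery
    class(train) <- class(cohort)
    test_rows <- intersect(which(assign_f == f), complete_on(cohort, battery$task_id))
    if (length(test_rows) == 0L) next
    bank <- predictor_bank(train, bank_config(
      ensemble_size = bank_cfg$ensemble_size, max_depth = bank_cfg$max_depth,
      enumeration_mode = "lazy_on_demand",
      seed = subset_seed(seed, c(f, 99L))))
    # length-1 initial = subset size (re-optimized per fold);
    # longer vectors = a fixed initial subset
    init <- if (length(initial) == 1L) {
      optimal_initial_subset(bank, as.integer(initial))
    } else {
      sort(as.integer(initial))
    }
    for (ct in thresholds) {
      scfg <- session_config(
        initial_subset = init,
        selector = selector_config(selector$method, ct, selector$sigma2))
      key <- as.character(ct)
      for (i in test_rows) {
        tr <- run_session(cohort[i, , drop = FALSE], bank, scfg)
        res[[key]]$truth <- c(res[[key]]$truth, y[i])
        res[[key]]$pred <- c(res[[key]]$pred, tr$final_prediction)
        res[[key]]$n_tasks <- c(res[[key]]$n_tasks, tr$n_tasks_used)
        if (return_traces) res[[key]]$traces <- c(res[[key]]$traces, list(tr))
      }
    }
  }
  out <- data.frame(
    ct = thresholds,
    accuracy = vapply(res, function(r) mean(r$pred == r$truth), numeric(1)),
    mean_tasks = vapply(res, function(r) mean(r$n_tasks), numeric(1)),
    n_eval = vapply(res, function(r) length(r$truth), integer(1))
  )
  rownames(out) <- NULL
  class(out) <- c("ebbs_curve", "data.frame")
  attr(out, "pooled") <- lapply(res, function(r)
    list(truth = risk_factor(r$truth), predicted = risk_factor(r$pred)))
  if (return_traces) attr(out, "traces") <- lapply(res, `[[`, "traces")
  out
}

#' Occurrence matrix of task sequences
#'
#' Entry (i, j) is the proportion of sessions in which battery task i was
#' administered in sequence position j.  Column j therefore sums to the
#' fraction of sessions that reached position j, and the column sums are
#' non-increasing.
#'
#' @param traces List of `ebbs_trace` objects over one battery.
#' @param battery The `bbs_battery` the traces were produced on.
#' @return k x k matrix (rows = task numbers, columns = positions) of
#'   proportions.
#' @export
occurrence_matrix <- function(traces, battery = bbs_battery()) {
  if (length(traces) == 0L) stop("need at least one trace", call. = FALSE)
  k <- nrow(battery)
  ids <- battery$task_id
  om <- matrix(0, k, k, dimnames = list(task = ids, position = seq_len(k)))
  for (tr in traces) {
    ord <- tr$task_order
    if (!all(ord %in% ids) || length(ord) > k) {
      stop("trace uses tasks outside the battery", call. = FALSE)
    }
    for (j in seq_along(ord)) {
      om[match(ord[j], ids), j] <- om[match(ord[j], ids), j] + 1
    }
  }
  om / length(traces)
}

#' Cross-validated accuracy of the short-form comparator
#'
#' Trains the single subset predictor for the configured 7-task short-form
#' battery within each fold and evaluates it on held-out subjects complete
#' on those tasks — the fixed-subset analogue of the adaptive curve.
#'
#' @param cohort An `ebbs_cohort`.
#' @param member_ids The 7 short-form task numbers.
#' @param n_folds Stratified folds (default 5).
#' @param bank_cfg A `bank_config` template.
#' @param seed Integer seed.
#' @return List with `accuracy`, `n_tasks` (7), `truth`, `predicted`.
#' @export
sfbbs_cv <- function(cohort, member_ids, n_folds = 5L,
                     bank_cfg = bank_config(), seed = 1L) {
  sf <- sfbbs_battery(member_ids)
  battery <- cohort_battery(cohort)
  y <- as.character(cohort$risk_label)
  assign_f <- stratified_folds(y, n_folds, seed)
  truth <- pred <- character(0)
  for (f in seq_len(n_folds)) {
    train <- cohort[assign_f != f, , drop = FALSE]
    attr(train, "battery") <- battery
    class(train) <- class(cohort)
    bank <- predictor_bank(train, bank_config(
      ensemble_size = bank_cfg$ensemble_size, max_depth = bank_cfg$max_depth,
      seed = subset_seed(seed, c(f, 99L))))
    test_rows <- intersect(which(assign_f == f), complete_on(cohort, sf$task_id))
    for (i in test_rows) {
      p <- predict_risk(bank, sf$task_id, cohort[i, , drop = FALSE])
      truth <- c(truth, y[i])
      pred <- c(pred, as.character(p$category))
    }
  }
  list(accuracy = mean(pred == truth), n_tasks = 7L,
       truth = risk_factor(truth), predicted = risk_factor(pred))
}
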