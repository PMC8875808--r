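# Full-battery fall-risk classifier: an RBF-kernel SVM on the 14 task
# scores, gamma = 1/(number of features), cost C = 3, evaluated by
# leave-one-out (or k-fold) cross-validation.  Per-class scores are the
# one-vs-one vote fractions, which feed the false-negative threshold
# adjustment in the evaluation module.

#' Full-battery classifier configuration
#'
#' @param regularization_C SVM cost parameter (default 3).
#' @param kernel_gamma RBF width; `"1/nf"` (default) resolves to one over the
#'   number of features (1/14 for the standard battery), or a positive number.
#' @param cv_scheme `"loo"` (leave-one-out, default) or an integer number of
#'   stratified folds.
#' @return A `full_battery_config` list.
#' @export
full_battery_config <- function(regularization_C = 3, kernel_gamma = "1/nf",
                                cv_scheme = "loo") {
  structure(list(regularization_C = regularization_C,
                 kernel_gamma = kernel_gamma,
                 cv_scheme = cv_scheme),
            class = "full_battery_config")
}

resolve_gamma <- function(cfg, nf) {
  if (identical(cfg$kernel_gamma, "1/nf")) 1 / nf else as.numeric(cfg$kernel_gamma)
}

#' Train the full-battery risk classifier
#'
#' @param cohort Training `ebbs_cohort`; only subjects complete on every
#'   battery task are used, and at least two risk classes must be present.
#' @param cfg A `full_battery_config`.
#' @return A `full_battery_classifier` with the fitted SVM, the resolved
#'   gamma, and the training rows used.
#' @export
train_full_battery_classifier <- function(cohort, cfg = full_battery_config()) {
  battery <- cohort_battery(cohort)
  idx <- complete_on(cohort, battery$task_id)
  y <- as.character(cohort$risk_label)[idx]
  if (length(idx) < 2L || length(unique(y)) < 2L) {
    stop(structure(class = c("ebbs_degenerate_training", "error", "condition"),
                   list(message = "full-battery training needs >= 2 risk classes",
                        call = NULL)))
  }
  x <- score_matrix(cohort)[idx, , drop = FALSE]
  gamma <- resolve_gamma(cfg, ncol(x))
  fit <- e1071::svm(x, factor(y, levels = risk_levels()),
                    kernel = "radial", gamma = gamma,
                    cost = cfg$regularization_C)
  structure(list(fit = fit, gamma = gamma, C = cfg$regularization_C,
                 battery = battery, train_idx = idx,
                 levels = risk_levels()),
            class = "full_battery_classifier")
}

#' Predicted classes and per-class scores of the full-battery classifier
#'
#' Per-class scores are the one-vs-one vote fractions (each of the three
#' pairwise decision values casts one vote; scores sum to 1 per subject).
#'
#' @param clf A `full_battery_classifier`.
#' @param newdata Score matrix / cohort rows complete on the battery.
#' @return List with `class` (factor) and `scores` (n x 3 matrix, columns
#'   `high`, `medium`, `low`).
#' @export
full_battery_scores <- function(clf, newdata) {
  if (inherits(newdata, "ebbs_cohort") || is.data.frame(newdata)) {
    newdata <- as.matrix(as.data.frame(newdata)[task_cols(clf$battery$task_id)])
    storage.mode(newdata) <- "double"
  }
  pr <- predict(clf$fit, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lev <- clf$levels
  votes <- matrix(0, nrow(newdata), length(lev), dimnames = list(NULL, lev))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    win <- ifelse(dv[, j] > 0, pair[1], pair[2])
    for (cl in pair) votes[win == cl, cl] <- votes[win == cl, cl] + 1
  }
  list(class = risk_factor(as.character(pr)),
       scores = votes / ncol(dv))
}

#' Cross-validated accuracy of the full-battery classifier
#'
#' Retrains the SVM within each fold (leave-one-out or stratified k-fold) on
#' the subjects complete on the whole battery and pools held-out predictions.
#'
#' @param cohort An `ebbs_cohort`.
#' @param cfg A `full_battery_config`; its `cv_scheme` picks the scheme
#'   unless `folds` is given.
#' @param folds `"loo"` or an integer fold count (overrides `cfg`).
#' @param seed Seed for fold assignment (ignored for leave-one-out).
#' @return List with `accuracy`, `truth`, `predicted` (pooled held-out), and
#'   `n` (complete subjects used).
#' @export
full_battery_cv <- function(cohort, cfg = full_battery_config(), folds = NULL,
                            seed = 1L) {
  battery <- cohort_battery(cohort)
  idx <- complete_on(cohort, battery$task_id)
  x <- score_matrix(cohort)[idx, , drop = FALSE]
  y <- as.character(cohort$risk_label)[idx]
  n <- length(idx)
  if (is.null(folds)) folds <- cfg$cv_scheme
  assign_f <- if (identical(folds, "loo")) {
    seq_len(n)
  } else {
    stratified_folds(y, as.integer(folds), seed)
  }
  gamma <- resolve_gamma(cfg, ncol(x))
  pred <- character(n)
  for (f in unique(assign_f)) {
    test <- which(assign_f == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L) {
      stop("a cross-validation fold lost all but one risk class", call. = FALSE)
    }
    fit <- e1071::svm(x[train, , drop = FALSE],
                      factor(y[train], levels = risk_levels()),
                      kernel = "radial", gamma = gamma,
                      cost = cfg$regularization_C)
    pred[test] <- as.character(predict(fit, x[test, , drop = FALSE]))
  }
  list(accuracy = mean(pred == y),
       truth = risk_factor(y),
       predicted = risk_factor(pred),
       n = n)
}
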