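# Predictor bank: one fall-risk classifier per subset of BBS tasks.
#
# Each subset predictor is a 100-tree random forest (depth-capped) trained on
# the subjects with no missing score in the subset; its prediction for a
# score vector is the ensemble's modal vote and its confidence the modal vote
# share, with ties broken toward the higher-risk category.  The bank caches
# predictors by subset so that lazily enumerated greedy sessions and an
# eagerly enumerated bank train identical models (per-subset seeds are
# derived deterministically from the master seed and the subset membership).

#' Bank configuration
#'
#' @param ensemble_size Number of trees per subset predictor (default 100).
#' @param max_depth Maximum tree depth (default 10).
#' @param enumeration_mode `"lazy_on_demand"` (train-and-cache on first
#'   query; default) or `"all_subsets"` (train every non-empty subset up
#'   front — intended for small toy batteries).
#' @param seed Master seed; per-subset training seeds are derived from it.
#' @return A `bank_config` list.
#' @export
bank_config <- function(ensemble_size = 100L, max_depth = 10L,
                        enumeration_mode = c("lazy_on_demand", "all_subsets"),
                        seed = 1L) {
  enumeration_mode <- match.arg(enumeration_mode)
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1", call. = FALSE)
  if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 max_depth = as.integer(max_depth),
                 enumeration_mode = enumeration_mode,
                 seed = as.integer(seed)),
            class = "bank_config")
}

subset_key <- function(task_ids) paste(sort(as.integer(task_ids)), collapse = "+")

# Deterministic per-subset seed derived from the master seed and membership.
subset_seed <- function(master, task_ids) {
  p <- 2147483647
  h <- as.double(master) %% p
  for (id in sort(as.integer(task_ids))) h <- (h * 131 + id) %% p
  as.integer(h %% (p - 1)) + 1L
}

#' Build a predictor bank over a training cohort
#'
#' @param cohort Training `ebbs_cohort` (risk labels required).
#' @param config A `bank_config`.
#' @return A `predictor_bank` (environment-backed; predictors are cached as
#'   they are trained).
#' @export
predictor_bank <- function(cohort, config = bank_config()) {
  battery <- cohort_battery(cohort)
  if (!inherits(cohort, "ebbs_cohort")) cohort <- as_cohort(cohort, battery)
  bank <- new.env(parent = emptyenv())
  bank$cohort <- cohort
  bank$battery <- battery
  bank$config <- config
  bank$scores <- score_matrix(cohort)
  bank$y <- as.character(cohort$risk_label)
  bank$cache <- new.env(parent = emptyenv())
  bank$fingerprint <- digest::digest(list(bank$scores, bank$y, config))
  class(bank) <- "predictor_bank"
  if (config$enumeration_mode == "all_subsets") {
    k <- nrow(battery)
    if (k > 16L) {
      stop("all_subsets enumeration over ", k, " tasks (", 2^k - 1,
           " predictors) refused; use lazy_on_demand", call. = FALSE)
    }
    for (size in seq_len(k)) {
      combos <- utils::combn(battery$task_id, size, simplify = FALSE)
      for (ss in combos) bank_predictor(bank, ss)
    }
  }
  bank
}

#' @export
print.predictor_bank <- function(x, ...) {
  cat(sprintf("predictor bank: %d tasks, %d subjects, %d cached predictor(s)\n",
              nrow(x$battery), nrow(x$cohort), length(ls(x$cache))))
  invisible(x)
}

#' Train a single subset predictor
#'
#' Trains the ensemble on the subjects with no missing score in the subset
#' and records its training-set accuracy and mean vote confidence.  A subset
#' whose complete subjects span a single risk class raises a
#' `ebbs_degenerate_training` error; `bank_predictor()` falls back to a
#' constant predictor (confidence 1) in that case.
#'
#' @param cohort Training `ebbs_cohort`.
#' @param task_ids Non-empty subset of battery task numbers.
#' @param config A `bank_config`.
#' @return A `subset_predictor`.
#' @export
train_subset_predictor <- function(cohort, task_ids, config = bank_config()) {
  battery <- cohort_battery(cohort)
  task_ids <- sort(as.integer(task_ids))
  if (length(task_ids) == 0L) stop("subset must be non-empty", call. = FALSE)
  if (!all(task_ids %in% battery$task_id)) {
    stop("subset outside the battery: ",
         paste(setdiff(task_ids, battery$task_id), collapse = ", "),
         call. = FALSE)
  }
  sm <- score_matrix(cohort)
  y <- as.character(cohort$risk_label)
  idx <- complete_on(cohort, task_ids)
  if (length(idx) < 2L || length(unique(y[idx])) < 2L) {
    cls <- if (length(idx)) unique(y[idx]) else character(0)
    stop(structure(class = c("ebbs_degenerate_training", "error", "condition"),
                   list(message = paste0("degenerate training for subset {",
                                         subset_key(task_ids),
                                         "}: single class or too few subjects"),
                        call = NULL, task_ids = task_ids, classes = cls)))
  }
  cols <- task_cols(task_ids)
  df <- as.data.frame(sm[idx, cols, drop = FALSE])
  df$risk <- factor(y[idx], levels = risk_levels())
  seed <- subset_seed(config$seed, task_ids)
  fit <- ranger::ranger(risk ~ ., data = df,
                        num.trees = config$ensemble_size,
                        max.depth = config$max_depth,
                        seed = seed, num.threads = 1L)
  pv <- predictor_votes(fit, df[cols])
  pred <- structure(list(task_ids = task_ids,
                         fit = fit,
                         constant = NULL,
                         train_idx = idx,
                         train_pred = pv$pred,
                         train_conf = pv$conf,
                         train_accuracy = mean(pv$pred == y[idx]),
                         mean_confidence = mean(pv$conf),
                         n_train = length(idx),
                         seed = seed),
                    class = "subset_predictor")
  pred
}

# Modal vote + vote share for each row of newdata; ties go to the
# higher-risk (lower ordinal code) category.
predictor_votes <- function(fit, newdata) {
  pr <- predict(fit, data = newdata, predict.all = TRUE, num.threads = 1L)
  votes <- pr$predictions
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(newdata))
  lev <- fit$forest$levels
  ntree <- ncol(votes)
  counts <- t(apply(votes, 1L, tabulate, nbins = length(lev)))
  if (nrow(newdata) == 1L) counts <- matrix(counts, nrow = 1L)
  # order candidate classes by increasing risk code so which.max favours
  # the higher-risk class on ties
  ord <- order(risk_code(lev))
  counts_ord <- counts[, ord, drop = FALSE]
  pick <- apply(counts_ord, 1L, which.max)
  list(pred = lev[ord][pick],
       conf = counts_ord[cbind(seq_along(pick), pick)] / ntree)
}

#' Fetch (training on demand) the predictor for a subset
#'
#' @param bank A `predictor_bank`.
#' @param task_ids Subset of battery task numbers.
#' @return A `subset_predictor` (cached inside the bank).
#' @export
bank_predictor <- function(bank, task_ids) {
  key <- subset_key(task_ids)
  if (!is.null(bank$cache[[key]])) return(bank$cache[[key]])
  pred <- tryCatch(
    train_subset_predictor(bank$cohort, task_ids, bank$config),
    ebbs_degenerate_training = function(e) {
      idx <- complete_on(bank$cohort, task_ids)
      cls <- if (length(idx)) unique(bank$y[idx]) else risk_levels()[1L]
      cls <- cls[which.min(risk_code(cls))]
      message("subset {", key, "}: degenerate training; using constant predictor (",
              cls, ", confidence 1)")
      structure(list(task_ids = sort(as.integer(task_ids)),
                     fit = NULL, constant = cls,
                     train_idx = idx,
                     train_pred = rep(cls, length(idx)),
                     train_conf = rep(1, length(idx)),
                     train_accuracy = if (length(idx)) mean(bank$y[idx] == cls) else NA_real_,
                     mean_confidence = 1,
                     n_train = length(idx),
                     seed = NA_integer_),
                class = "subset_predictor")
    })
  bank$cache[[key]] <- pred
  pred
}

#' Predict fall risk from a task subset
#'
#' @param bank A `predictor_bank`.
#' @param task_ids Subset whose predictor should be used.
#' @param v Score vector (named `task_<id>` or one-row data frame) with all
#'   subset scores present.
#' @return List with `category` (factor high/medium/low) and `confidence`
#'   (modal vote share in [1/3, 1]).
#' @export
predict_risk <- function(bank, task_ids, v) {
  task_ids <- sort(as.integer(task_ids))
  x <- restrict(v, task_ids, bank$battery)
  pred <- bank_predictor(bank, task_ids)
  out <- predict_subset(pred, matrix(x, nrow = 1L,
                                     dimnames = list(NULL, task_cols(task_ids))))
  list(category = risk_factor(out$pred), confidence = out$conf)
}

# Vectorised prediction over a score matrix (columns = the subset's
# task_<id> columns).
predict_subset <- function(predictor, m) {
  if (!is.null(predictor$constant)) {
    return(list(pred = rep(predictor$constant, nrow(m)),
                conf = rep(1, nrow(m))))
  }
  predictor_votes(predictor$fit, as.data.frame(m))
}

#' Rank the bank's trained predictors
#'
#' Descending training accuracy; ties broken by descending mean confidence,
#' then smaller subset, then lexicographically by task numbers.
#'
#' @param bank A `predictor_bank` with at least one trained predictor.
#' @return Data frame with columns `subset` (key string), `size`,
#'   `train_accuracy`, `mean_confidence`, `n_train`, best first.
#' @export
rank_predictors <- function(bank) {
  keys <- ls(bank$cache)
  if (length(keys) == 0L) stop("bank has no trained predictors", call. = FALSE)
  preds <- lapply(keys, function(k) bank$cache[[k]])
  df <- data.frame(
    subset = vapply(preds, function(p) subset_key(p$task_ids), character(1)),
    size = vapply(preds, function(p) length(p$task_ids), integer(1)),
    train_accuracy = vapply(preds, function(p) p$train_accuracy, numeric(1)),
    mean_confidence = vapply(preds, function(p) p$mean_confidence, numeric(1)),
    n_train = vapply(preds, function(p) p$n_train, integer(1)),
    stringsAsFactors = FALSE
  )
  lex <- vapply(preds, function(p) paste(sprintf("%02d", p$task_ids), collapse = ""),
                character(1))
  ord <- order(-df$train_accuracy, -df$mean_confidence, df$size, lex)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Best subset of a given size
#'
#' Enumerates all subsets of exactly the given cardinality, trains any not
#' yet cached, and returns the top-ranked one (rank order as in
#' [rank_predictors()]).
#'
#' @param bank A `predictor_bank`.
#' @param size Subset cardinality, 1 to battery size.
#' @return Integer vector of task numbers.
#' @export
optimal_initial_subset <- function(bank, size) {
  k <- nrow(bank$battery)
  if (size < 1L || size > k) {
    stop("size must lie in 1-", k, call. = FALSE)
  }
  combos <- utils::combn(bank$battery$task_id, size, simplify = FALSE)
  preds <- lapply(combos, function(ss) bank_predictor(bank, ss))
  acc <- vapply(preds, function(p) p$train_accuracy, numeric(1))
  conf <- vapply(preds, function(p) p$mean_confidence, numeric(1))
  lex <- vapply(combos, function(ss) paste(sprintf("%02d", sort(ss)), collapse = ""),
                character(1))
  best <- order(-acc, -conf, lex)[1L]
  sort(as.integer(combos[[best]]))
}
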