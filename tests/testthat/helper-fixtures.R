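# Fixtures built in code: a 4-task toy battery with a 12-subject cohort
# whose scores separate the three risk bands, plus small generators.

toy_battery <- function() bbs_battery(1:4)

toy_cohort <- function() {
  scores <- rbind(
    c(0, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 1, 0), c(0, 0, 0, 2),   # high
    c(2, 2, 2, 1), c(2, 1, 3, 2), c(1, 2, 2, 2), c(3, 2, 1, 2),   # medium
    c(4, 4, 3, 4), c(3, 4, 4, 4), c(4, 3, 4, 3), c(4, 4, 4, 4)    # low
  )
  df <- data.frame(subject_id = sprintf("T%02d", 1:12))
  colnames(scores) <- paste0("task_", 1:4)
  df <- cbind(df, as.data.frame(scores))
  df$risk_label <- rep(c("high", "medium", "low"), each = 4)
  as_cohort(df, toy_battery())
}

toy_bank <- function(trees = 25L, seed = 5L,
                     mode = c("all_subsets", "lazy_on_demand")) {
  predictor_bank(toy_cohort(), bank_config(ensemble_size = trees,
                                           enumeration_mode = match.arg(mode),
                                           seed = seed))
}

# A separable 4-task cohort with each score pattern repeated, so every
# cross-validation fold sees every pattern.
separable_cohort <- function(reps = 6L) {
  pat <- rbind(c(0, 0, 0, 0), c(2, 2, 2, 2), c(4, 4, 4, 4))
  scores <- pat[rep(1:3, each = reps), ]
  colnames(scores) <- paste0("task_", 1:4)
  df <- data.frame(subject_id = sprintf("P%02d", seq_len(3 * reps)))
  df <- cbind(df, as.data.frame(scores))
  df$risk_label <- rep(c("high", "medium", "low"), each = reps)
  as_cohort(df, toy_battery())
}

random_score_vector <- function(task_ids = 1:4) {
  stats::setNames(as.numeric(sample(0:4, length(task_ids), replace = TRUE)),
                  paste0("task_", task_ids))
}

# Brute-force selector objective: assembles each method's weighted
# correct-prediction sum term by term, per training subject, using only
# predictor outputs and the similarity formula — independent of
# select_next_task()'s vectorised path.
oracle_next_task <- function(bank, css, ut, method, ct, patient = NULL,
                             sigma2 = NULL) {
  css <- sort(css)
  y <- as.character(bank$cohort$risk_label)
  if (method >= 2) {
    css_pred <- bank_predictor(bank, css)
    conf_lookup <- stats::setNames(css_pred$train_conf, css_pred$train_idx)
  }
  if (method >= 3 && is.null(sigma2)) sigma2 <- ebbs:::auto_sigma2(bank, css)
  if (method == 4) {
    at_pred <- bank_predictor(bank, bank$battery$task_id)
    yhat_lookup <- stats::setNames(at_pred$train_pred, at_pred$train_idx)
  }
  obj <- sapply(sort(ut), function(tt) {
    p <- bank_predictor(bank, sort(c(css, tt)))
    total <- 0
    for (pos in seq_along(p$train_idx)) {
      i <- p$train_idx[pos]
      term <- as.numeric(p$train_pred[pos] == y[i])
      if (method >= 2) {
        cv <- conf_lookup[as.character(i)]
        term <- term * as.numeric(!is.na(cv) && cv < ct)
      }
      if (method >= 3 && term > 0) {
        xi <- bank$cohort[i, , drop = FALSE]
        term <- term * similarity(xi, patient, css, sigma2, bank$battery)
      }
      if (method == 4) {
        yh <- yhat_lookup[as.character(i)]
        term <- term * as.numeric(!is.na(yh) && yh == y[i])
      }
      total <- total + term
    }
    total
  })
  if (all(obj == 0) && method > 1) {
    return(oracle_next_task(bank, css, ut, 1, ct))
  }
  sort(ut)[which.max(obj)]
}
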