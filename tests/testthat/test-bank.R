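test_that("confidence is the ensemble's modal vote share (per-member oracle)", {
  co <- toy_cohort()
  pred <- train_subset_predictor(co, c(1, 3), bank_config(ensemble_size = 5L,
                                                          seed = 21))
  v <- setNames(c(2, 2), c("task_1", "task_3"))
  newdf <- as.data.frame(matrix(v, 1, dimnames = list(NULL, names(v))))
  votes <- predict(pred$fit, data = newdf, predict.all = TRUE,
                   num.threads = 1)$predictions
  lev <- pred$fit$forest$levels
  tally <- table(factor(lev[as.vector(votes)], levels = risk_levels()))
  out <- ebbs:::predict_subset(pred, as.matrix(newdf))
  expect_equal(out$conf, max(tally) / 5)
  winners <- names(tally)[tally == max(tally)]
  expect_true(out$pred %in% winners)
  # tie-break favours the higher-risk winner
  expect_equal(out$pred, winners[which.min(risk_code(winners))])
})

test_that("training excludes subjects missing a subset score", {
  co <- toy_cohort()
  co$task_2[c(2, 5, 9)] <- NA
  pred <- train_subset_predictor(co, c(2, 4), bank_config(seed = 3))
  expect_equal(pred$n_train, 9L)
  expect_identical(pred$train_idx, setdiff(1:12, c(2, 5, 9)))
})

test_that("identical cohort, subset, and seed give identical predictors", {
  b1 <- toy_bank(trees = 50, seed = 8, mode = "lazy_on_demand")
  b2 <- toy_bank(trees = 50, seed = 8, mode = "lazy_on_demand")
  p1 <- bank_predictor(b1, c(1, 2, 4))
  p2 <- bank_predictor(b2, c(1, 2, 4))
  expect_identical(p1$train_pred, p2$train_pred)
  expect_identical(p1$train_conf, p2$train_conf)
  v <- random_score_vector(c(1, 2, 4))
  expect_identical(predict_risk(b1, c(1, 2, 4), v),
                   predict_risk(b2, c(1, 2, 4), v))
})

test_that("lazy and eager enumeration train the same predictor", {
  lazy <- toy_bank(trees = 30, seed = 4, mode = "lazy_on_demand")
  eager <- toy_bank(trees = 30, seed = 4, mode = "all_subsets")
  expect_identical(bank_predictor(lazy, c(2, 3))$train_pred,
                   bank_predictor(eager, c(2, 3))$train_pred)
})

test_that("all-subsets enumeration over k tasks yields 2^k - 1 predictors", {
  bank <- toy_bank(trees = 10, seed = 2, mode = "all_subsets")
  expect_equal(length(ls(bank$cache)), 2^4 - 1)
})

test_that("a separable cohort trains to perfect in-sample accuracy", {
  bank <- predictor_bank(separable_cohort(),
                         bank_config(ensemble_size = 50, seed = 6))
  pred <- bank_predictor(bank, 1:4)
  expect_equal(pred$train_accuracy, 1.0)
})

test_that("confidence is always a modal share of three classes: [1/3, 1]", {
  bank <- toy_bank(trees = 25, seed = 19, mode = "all_subsets")
  set.seed(99)
  for (i in 1:30) {
    ss <- sort(sample(1:4, sample(1:4, 1)))
    out <- predict_risk(bank, ss, random_score_vector(ss))
    expect_gte(out$confidence, 1 / 3)
    expect_lte(out$confidence, 1)
  }
})

test_that("ranking sorts by accuracy, then confidence, then size (sort oracle)", {
  co <- as_cohort(toy_cohort()[, c("subject_id", paste0("task_", 1:3), "risk_label")],
                  bbs_battery(1:3))
  bank <- predictor_bank(co, bank_config(ensemble_size = 40, seed = 13,
                                         enumeration_mode = "all_subsets"))
  rk <- rank_predictors(bank)
  expect_equal(nrow(rk), 7)
  keys <- ls(bank$cache)
  manual <- data.frame(
    subset = keys,
    acc = sapply(keys, function(k) bank$cache[[k]]$train_accuracy),
    conf = sapply(keys, function(k) bank$cache[[k]]$mean_confidence),
    size = sapply(keys, function(k) length(bank$cache[[k]]$task_ids))
  )
  manual <- manual[order(-manual$acc, -manual$conf, manual$size, manual$subset), ]
  expect_identical(rk$subset, manual$subset)
})

test_that("optimal_initial_subset is the exhaustive argmax at its size", {
  bank <- toy_bank(trees = 40, seed = 17, mode = "all_subsets")
  rk <- rank_predictors(bank)
  best1 <- optimal_initial_subset(bank, 1)
  expect_identical(subset_key <- paste(best1, collapse = "+"),
                   rk$subset[rk$size == 1][1])
  expect_identical(optimal_initial_subset(bank, 4), 1:4)
  expect_error(optimal_initial_subset(bank, 5), "size")
})

test_that("single-class training errors, and the bank falls back to a constant", {
  co <- toy_cohort()
  one_class <- co[co$risk_label == "low", , drop = FALSE]
  attr(one_class, "battery") <- toy_battery()
  class(one_class) <- class(co)
  expect_error(train_subset_predictor(one_class, 1:2, bank_config()),
               class = "ebbs_degenerate_training")
  bank <- predictor_bank(one_class, bank_config(seed = 1))
  expect_message(p <- bank_predictor(bank, 1:2), "constant")
  out <- predict_risk(bank, 1:2, random_score_vector(1:2))
  expect_equal(out$confidence, 1)
  expect_equal(as.character(out$category), "low")
})

test_that("the full battery beats any single task on the default profile", {
  co <- generate_cohort(default_bbs_profile(n_subjects = 130, seed = 1))
  bank <- predictor_bank(co, bank_config(seed = 31))
  full_acc <- bank_predictor(bank, 1:14)$train_accuracy
  singles <- sapply(1:14, function(t) bank_predictor(bank, t)$train_accuracy)
  expect_true(all(full_acc >= singles))
})
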