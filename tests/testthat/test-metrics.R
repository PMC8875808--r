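test_that("ordinal MSE worked cases", {
  perfect <- confusion_and_mse(c("high", "medium", "low"),
                               c("high", "medium", "low"))
  expect_equal(perfect$mse, 0)
  expect_equal(unname(diag(perfect$confusion)), c(1, 1, 1))
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  one_off <- confusion_and_mse(c("high", "high", "medium", "low"),
                               c("high", "medium", "medium", "low"))
  expect_equal(one_off$mse, 0.25)
  expect_equal(one_off$accuracy, 0.75)

  two_class_err <- confusion_and_mse(c("high", "low"), c("low", "low"))
  expect_equal(two_class_err$mse, 2.0)
})

test_that("confusion matrix rows are truth and its trace gives accuracy", {
  truth <- c("high", "medium", "low", "low", "medium")
  pred <- c("medium", "medium", "low", "high", "low")
  cm <- confusion_and_mse(truth, pred)
  expect_equal(cm$confusion["high", "medium"], 1)
  expect_equal(cm$confusion["low", "high"], 1)
  expect_equal(sum(diag(cm$confusion)) / length(truth), cm$accuracy)
})

test_that("weighted precision/recall/F1 match hand contingency arithmetic", {
  expect_equal(unname(weighted_prf(c("high", "medium", "low"),
                                   c("high", "medium", "low"))),
               c(1, 1, 1))
  # balanced 3-class truth, degenerate all-high predictions
  truth <- rep(c("high", "medium", "low"), each = 3)
  pred <- rep("high", 9)
  prf <- weighted_prf(truth, pred)
  expect_equal(unname(prf["recall"]), 1 / 3)
  expect_equal(unname(prf["precision"]), (1 / 3) * (1 / 3))
  # 9-subject mixed example, computed by hand:
  # truth: h h h m m m l l l ; pred: h h m m m h l m l
  truth <- c("high", "high", "high", "medium", "medium", "medium",
             "low", "low", "low")
  pred <- c("high", "high", "medium", "medium", "medium", "high",
            "low", "medium", "low")
  # per class (support 3 each):
  # high: tp=2 fp=1 fn=1  -> P=2/3 R=2/3 F1=2/3
  # medium: tp=2 fp=2 fn=1 -> P=1/2 R=2/3 F1=4/7
  # low: tp=2 fp=0 fn=1   -> P=1 R=2/3 F1=4/5
  prf <- weighted_prf(truth, pred)
  expect_equal(unname(prf["precision"]), (2/3 + 1/2 + 1) / 3)
  expect_equal(unname(prf["recall"]), 2 / 3)
  expect_equal(unname(prf["f1"]), (2/3 + 4/7 + 4/5) / 3)
})

test_that("threshold adjustment is vacuous at tau 0 and inert at tau 1", {
  sc <- rbind(c(high = 0.2, medium = 0.5, low = 0.3),
              c(high = 0.0, medium = 0.4, low = 0.6),
              c(high = 0.5, medium = 0.3, low = 0.2))
  expect_true(all(adjust_thresholds(sc, 0) == "high"))
  expect_equal(as.character(adjust_thresholds(sc, 1)),
               c("medium", "low", "high"))
})

test_that("false negatives are monotone under the tau sweep", {
  co <- generate_cohort(default_bbs_profile(n_subjects = 120, seed = 19,
                                            missing_rate = 0))
  clf <- train_full_battery_classifier(co)
  test_co <- generate_cohort(default_bbs_profile(n_subjects = 80, seed = 20,
                                                 missing_rate = 0))
  sc <- full_battery_scores(clf, score_matrix(test_co))$scores
  truth <- as.character(test_co$risk_label)
  taus <- seq(1, 0, by = -0.1)
  fn <- sapply(taus, function(tau) {
    pred <- as.character(adjust_thresholds(sc, tau))
    sum(truth == "high" & pred != "high")
  })
  n_high_calls <- sapply(taus, function(tau) {
    sum(adjust_thresholds(sc, tau) == "high")
  })
  expect_true(all(diff(fn) <= 0))          # tau decreasing along the sweep
  expect_true(all(diff(n_high_calls) >= 0))
})

test_that("ICC(3,1) equals a brute-force two-way mean-squares decomposition", {
  a <- c(12, 25, 33, 41, 50, 55)
  d <- c(15, 22, 36, 40, 47, 56)
  tab <- rater_table(a = a, d = d)
  # oracle: two-way ANOVA mean squares via aov
  df <- data.frame(score = c(a, d),
                   subject = factor(rep(1:6, 2)),
                   rater = factor(rep(c("a", "d"), each = 6)))
  ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(icc_3_1(tab), (msr - mse) / (msr + mse))
  expect_equal(icc_3_1(tab, type = "agreement"),
               (msr - mse) / (msr + mse + (2 / 6) * (msc - mse)))
})

test_that("ICC(3,1) invariances: duplicated raters and constant offsets", {
  x <- c(10, 20, 30, 44, 52)
  expect_equal(icc_3_1(cbind(x, x)), 1.0)
  tab <- cbind(a = x, b = x + c(1, -2, 2, 0, -1))
  expect_equal(icc_3_1(cbind(tab[, 1] + 4, tab[, 2])), icc_3_1(tab))
  expect_error(icc_3_1(cbind(c(5, 5, 5), c(5, 5, 5))), "variance")
})

test_that("the conservative min column takes the per-subject minimum", {
  tab <- rater_table(a = c(10, 30, 50), d = c(12, 28, 50),
                     include_min = c("a", "d"))
  expect_equal(unname(tab[, "min_a_d"]), c(10, 28, 50))
  expect_error(rater_table(a = c(10, 60), d = c(10, 20)), "0-56")
})
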