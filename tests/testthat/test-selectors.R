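test_that("similarity matches its closed form", {
  b <- toy_battery()
  vi <- setNames(c(4, 0, 2, 1), paste0("task_", 1:4))
  vj <- setNames(c(0, 0, 2, 1), paste0("task_", 1:4))
  expect_equal(similarity(vi, vi, 1:4, 5, b), 1.0)
  expect_equal(similarity(vi, vj, 1, 16, b), exp(-1))
  set.seed(31)
  for (rep in 1:20) {
    u <- random_score_vector(1:4)
    w <- random_score_vector(1:4)
    ss <- sort(sample(1:4, sample(1:3, 1)))
    s2 <- runif(1, 0.5, 30)
    expect_equal(similarity(u, w, ss, s2, b),
                 exp(-sum((u[paste0("task_", ss)] - w[paste0("task_", ss)])^2) / s2))
  }
  expect_error(similarity(vi, vj, 1:4, -1, b), "positive")
})

test_that("each selector method equals its brute-force objective", {
  bank <- toy_bank(trees = 25, seed = 5, mode = "all_subsets")
  co <- toy_cohort()
  set.seed(42)
  for (rep in 1:20) {
    css <- sort(sample(1:4, sample(1:2, 1)))
    ut <- setdiff(1:4, css)
    patient <- co[sample(1:12, 1), , drop = FALSE]
    ct <- sample(c(0.7, 0.9, 0.99), 1)
    for (method in 1:4) {
      cfg <- selector_config(method, ct, sigma2 = 8)
      got <- suppressMessages(
        select_next_task(bank, css, ut, cfg, patient = patient))
      want <- suppressMessages(
        oracle_next_task(bank, css, ut, method, ct, patient = patient, sigma2 = 8))
      expect_equal(as.integer(got), want,
                   info = sprintf("method %d, css {%s}, ct %.2f",
                                  method, paste(css, collapse = ","), ct))
    }
  }
})

test_that("method 2 collapses to method 1 when every confidence is below CT", {
  bank <- toy_bank(trees = 24, seed = 9, mode = "all_subsets")
  # the indicator I(Conf < CT) is identically 1 when every training
  # confidence sits strictly below CT = 1; scan for qualifying subsets
  found <- 0L
  for (size in 1:3) {
    for (css in utils::combn(1:4, size, simplify = FALSE)) {
      p <- bank_predictor(bank, css)
      if (!all(p$train_conf < 1)) next
      found <- found + 1L
      ut <- setdiff(1:4, css)
      m1 <- select_next_task(bank, css, ut, selector_config(1, 1.0))
      m2 <- select_next_task(bank, css, ut, selector_config(2, 1.0))
      expect_identical(as.integer(m1), as.integer(m2))
    }
  }
  expect_gte(found, 1L)
})

test_that("method 3 collapses to method 2 as the kernel flattens", {
  bank <- toy_bank(trees = 25, seed = 5, mode = "all_subsets")
  co <- toy_cohort()
  for (i in c(1, 6, 11)) {
    patient <- co[i, , drop = FALSE]
    m2 <- suppressMessages(
      select_next_task(bank, 2L, c(1L, 3L, 4L), selector_config(2, 0.9)))
    m3 <- suppressMessages(
      select_next_task(bank, 2L, c(1L, 3L, 4L),
                       selector_config(3, 0.9, sigma2 = 1e9), patient = patient))
    expect_identical(as.integer(m2), as.integer(m3))
  }
})

test_that("selection stays inside ut, and methods 1-2 ignore the patient", {
  bank <- toy_bank(trees = 25, seed = 7, mode = "all_subsets")
  co <- toy_cohort()
  set.seed(8)
  for (rep in 1:10) {
    css <- sort(sample(1:4, sample(1:2, 1)))
    ut <- setdiff(1:4, css)
    for (method in 1:2) {
      picks <- sapply(1:4, function(i) {
        as.integer(suppressMessages(select_next_task(
          bank, css, ut, selector_config(method, 0.95),
          patient = co[i, , drop = FALSE])))
      })
      expect_true(all(picks %in% ut))
      expect_false(any(picks %in% css))
      expect_equal(length(unique(picks)), 1L)
    }
  }
})

test_that("a single candidate is returned by every method", {
  bank <- toy_bank(trees = 20, seed = 3, mode = "all_subsets")
  patient <- toy_cohort()[5, , drop = FALSE]
  for (method in 1:4) {
    got <- suppressMessages(select_next_task(
      bank, c(1L, 2L, 3L), 4L, selector_config(method, 0.9), patient = patient))
    expect_identical(as.integer(got), 4L)
  }
})

test_that("annihilated objectives fall back to the method-1 choice, logged", {
  bank <- toy_bank(trees = 25, seed = 5, mode = "all_subsets")
  patient <- toy_cohort()[3, , drop = FALSE]
  # ct below every attainable confidence (confidence >= 1/3 always)
  expect_message(
    got <- select_next_task(bank, 1L, 2:4, selector_config(2, ct = 0.01)),
    "falling back")
  expect_true(attr(got, "fallback"))
  m1 <- select_next_task(bank, 1L, 2:4, selector_config(1, ct = 0.01))
  expect_identical(as.integer(got), as.integer(m1))
})

test_that("selector preconditions are enforced", {
  bank <- toy_bank(trees = 10, seed = 2, mode = "all_subsets")
  expect_error(select_next_task(bank, 1L, integer(0), selector_config(1, 0.9)),
               "no candidate")
  expect_error(select_next_task(bank, 1L, 2:4, selector_config(3, 0.9)),
               "patient")
  expect_error(select_next_task(bank, c(1L, 2L), 2:4, selector_config(1, 0.9)),
               "disjoint")
  expect_error(selector_config(5, 0.9), "method")
  expect_error(selector_config(1, 0), "ct")
})
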