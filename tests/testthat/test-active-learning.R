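test_that("surrogate training requires both classes and is reproducible", {
  set.seed(1)
  x <- cbind(runif(80, -1, 1), runif(80, -1, 1))
  y <- ifelse(x[, 1] > 0, "toxic", "nontoxic")
  expect_error(train_surrogate(x, rep("toxic", 80)), "both")
  m1 <- train_surrogate(x, y, seed = 5)
  m2 <- train_surrogate(x, y, seed = 5)
  grid <- cbind(seq(-1, 1, 0.05), 0)
  expect_identical(predict_toxicity(m1, grid), predict_toxicity(m2, grid))
  # a linearly separable problem with margin is learned perfectly
  sep <- x[abs(x[, 1]) > 0.2, ]
  ysep <- ifelse(sep[, 1] > 0, "toxic", "nontoxic")
  m <- train_surrogate(sep, ysep, seed = 5)
  expect_equal(unname(ifelse(predict_toxicity(m, sep) >= 0.5,
                             "toxic", "nontoxic")), ysep)
})

test_that("uncertainty selection picks probabilities nearest 0.5", {
  m <- fake_surrogate()
  pool <- matrix(qlogis(c(0.1, 0.5, 0.9)), ncol = 1)
  expect_equal(select_uncertain(m, pool, 1), 2L)
  expect_setequal(select_uncertain(m, pool, 3), 1:3)
  # ties broken by enumeration order
  tied <- matrix(qlogis(c(0.6, 0.4)), ncol = 1)
  expect_equal(select_uncertain(m, tied, 1), 1L)
  expect_error(select_uncertain(m, pool[0, , drop = FALSE], 1), "non-empty")
  expect_error(select_uncertain(m, pool, 4), "exceeds")
})

test_that("sensitivity and specificity follow the confusion matrix", {
  m <- fake_surrogate()
  x <- matrix(c(rep(3, 99), rep(-3, 1),    # toxic: 99 TP, 1 FN
                rep(-3, 98), rep(3, 2)),   # nontoxic: 98 TN, 2 FP
              ncol = 1)
  y <- c(rep("toxic", 100), rep("nontoxic", 100))
  expect_equal(evaluate_sens_spec(m, x, y),
               c(sensitivity = 99, specificity = 98))
  perfect <- matrix(c(rep(3, 10), rep(-3, 10)), ncol = 1)
  expect_equal(evaluate_sens_spec(m, perfect,
                                  rep(c("toxic", "nontoxic"), each = 10)),
               c(sensitivity = 100, specificity = 100))
  allneg <- matrix(rep(-3, 20), ncol = 1)
  expect_equal(evaluate_sens_spec(m, allneg,
                                  rep(c("toxic", "nontoxic"),
                                      each = 10))[["sensitivity"]], 0)
  expect_error(evaluate_sens_spec(m, allneg, rep("toxic", 20)), "both")
})

test_that("the active-learning loop labels exactly seed + k x batch", {
  toy <- toy_schedule_space(800, seed = 2)
  res <- run_active_learning(toy$features, toy$oracle, seed_size = 100,
                             batch_size = 40, stop_sens = 95,
                             stop_spec = 95, max_iter = 8, seed = 11)
  k <- nrow(res$history) - as.integer(res$converged)
  expect_equal(res$n_labeled, 100 + k * 40)
  expect_equal(anyDuplicated(res$labeled_idx), 0)
  expect_true(all(res$history$sensitivity >= 0 &
                    res$history$sensitivity <= 100))
  # evaluation points are never trained on, and both sets stay labeled
  expect_true(all(res$eval_idx %in% res$labeled_idx))
  # zero thresholds stop after the first iteration with no extra labels
  res0 <- run_active_learning(toy$features, toy$oracle, seed_size = 100,
                              batch_size = 40, stop_sens = 0,
                              stop_spec = 0, max_iter = 8, seed = 11)
  expect_true(res0$converged)
  expect_equal(res0$n_labeled, 100)
  # a single-class oracle is rejected
  expect_error(run_active_learning(toy$features,
                                   function(f) rep("nontoxic", nrow(f)),
                                   seed_size = 100, batch_size = 40,
                                   seed = 1),
               "single")
})
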