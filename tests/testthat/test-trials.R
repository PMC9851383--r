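test_that("replicate aggregation computes Table-style summaries", {
  all_cured <- replicate(50, fake_outcome(TRUE, time = 70, dose = 9.6),
                         simplify = FALSE)
  expect_equal(summarize_replicates(all_cured)$percent_cure, 100)
  part <- c(replicate(33, fake_outcome(TRUE, time = 300, dose = 50),
                      simplify = FALSE),
            replicate(17, fake_outcome(FALSE), simplify = FALSE))
  s <- summarize_replicates(part, untreated_mean_size = 400)
  expect_equal(s$percent_cure, 66)
  expect_equal(s$mean_time_to_cure_steps, 300)
  expect_equal(s$crypt_size_percent_untreated, 100 * 300 / 400)
  expect_equal(s$mean_accumulated_dose, 50)
  none <- replicate(5, fake_outcome(FALSE), simplify = FALSE)
  s0 <- summarize_replicates(none)
  expect_equal(s0$percent_cure, 0)
  expect_true(is.na(s0$mean_time_to_cure_steps))
  expect_error(summarize_replicates(list()), "non-empty")
})

test_that("percent cure is invariant under replicate order", {
  out <- c(replicate(7, fake_outcome(TRUE, time = 100), simplify = FALSE),
           replicate(3, fake_outcome(FALSE), simplify = FALSE))
  set.seed(9)
  shuffled <- out[sample(10)]
  expect_equal(summarize_replicates(shuffled)$percent_cure,
               summarize_replicates(out)$percent_cure)
})

test_that("toxicity classification follows extinguishment and the floor", {
  expect_true(classify_toxic(fake_outcome(FALSE, extinguished = TRUE)))
  expect_true(classify_toxic(fake_outcome(TRUE, min_size = 200,
                                          apoptotic_only = TRUE,
                                          floor = 280)))
  # the viability floor binds only for apoptotic-only dosing
  expect_false(classify_toxic(fake_outcome(TRUE, min_size = 200,
                                           apoptotic_only = FALSE,
                                           floor = 280)))
  expect_false(classify_toxic(fake_outcome(FALSE)))
})

test_that("trials are deterministic per seed and flag unreached triggers", {
  g <- test_geom()
  sched <- dose_schedule("cytotoxic", 2, 42, 12)
  o1 <- run_trial(sched, quick_protocol(), g, test_grad(), seed = 2)
  o2 <- run_trial(sched, quick_protocol(), g, test_grad(), seed = 2)
  keys <- c("cured", "time_to_cure_steps", "mean_treated_crypt_size",
            "min_treated_crypt_size", "accumulated_dose")
  expect_identical(o1[keys], o2[keys])
  expect_true(o1$evaluable)
  # cap reached before the mutant clone hits the trigger
  short <- trial_protocol(mutation_step = 100, max_steps = 115,
                          phenotype_label = "cancer")
  o3 <- run_trial(NULL, short, g, test_grad(), seed = 1)
  expect_false(o3$evaluable)
})

test_that("cure rate responds monotonically to lethality", {
  g <- test_geom()
  pr <- quick_protocol()
  cure <- sapply(c(4, 20), function(L) {
    out <- run_replicates(dose_schedule("cytotoxic", 1, 42, L), pr, g,
                          test_grad(), base_seed = 1)
    summarize_replicates(out)$percent_cure
  })
  expect_lte(cure[1], cure[2])
  expect_equal(cure[1], 0)
  expect_gt(cure[2], 0)
})
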