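test_that("dose schedules validate their invariants", {
  expect_error(dose_schedule("cytotoxic", 0, 42, 5), "duration")
  expect_error(dose_schedule("cytotoxic", 1, 41, 5), "even")
  expect_error(dose_schedule("cytotoxic", 4, 4, 5), "greater than")
  expect_error(dose_schedule("cytotoxic", 1, 42, 0), "positive")
  expect_error(combination_schedule(dose_schedule("apoptotic", 1, 84, 3.5),
                                    dose_schedule("apoptotic", 1, 84, 3.5)),
               "cytotoxic")
})

test_that("dose activity follows the duration/interval clock", {
  s <- dose_schedule("cytotoxic", 1, 42, 5.75)
  expect_true(is_dose_active(s, 0, 0))
  expect_false(is_dose_active(s, 1, 0))
  expect_true(is_dose_active(s, 42, 0))
  s84 <- dose_schedule("apoptotic", 1, 84, 3.5)
  expect_true(is_dose_active(s84, 84, 0))
  expect_false(is_dose_active(s84, 50, 60))  # before therapy start
})

test_that("dose activity is periodic with exact active fraction", {
  set.seed(1)
  for (k in 1:20) {
    i <- sample(seq(4L, 60L, 2L), 1)
    d <- sample(seq_len(i - 1L), 1)
    s <- dose_schedule("cytotoxic", d, i, 1)
    t0 <- sample(0:50, 1)
    steps <- t0 + 0:(i - 1)
    act <- is_dose_active(s, steps, t0)
    expect_identical(act, is_dose_active(s, steps + i, t0))
    expect_equal(mean(act), d / i)
  }
})

test_that("steps convert to days at 4 hours per step", {
  expect_equal(steps_to_days(71.01), 11.84)
  expect_equal(steps_to_days(194.56), 32.43)
  expect_equal(steps_to_days(133), 22.17)
  expect_equal(steps_to_days(0), 0)
  expect_error(steps_to_days(-1), "non-negative")
})

test_that("accumulated dose follows lethality x time / interval", {
  expect_equal(accumulated_dose(5.75, 71.01, 42), 5.75 * 71.01 / 42)
  expect_equal(round(accumulated_dose(5.75, 71.01, 42), 2), 9.72)
  expect_equal(accumulated_dose(7.5, 133, 42), 23.75)
  expect_equal(accumulated_dose(12, 0, 42), 0)
  expect_error(accumulated_dose(5, 10, 0), "positive")
  # linear in lethality and time, inverse in interval
  expect_equal(accumulated_dose(10, 50, 20), 2 * accumulated_dose(5, 50, 20))
  expect_equal(accumulated_dose(5, 100, 20), 2 * accumulated_dose(5, 50, 20))
  expect_equal(accumulated_dose(5, 50, 40), accumulated_dose(5, 50, 20) / 2)
})

test_that("practicality policy encodes clinic constraints", {
  combo <- combination_schedule(dose_schedule("cytotoxic", 1, 42, 7.5),
                                dose_schedule("apoptotic", 1, 84, 3.5))
  expect_true(is_practical(combo))
  expect_false(is_practical(dose_schedule("cytotoxic", 4, 42, 7.5)))
  expect_false(is_practical(dose_schedule("cytotoxic", 1, 34, 7.5)))
  loose <- practicality_policy(max_duration_steps = 6,
                               allowed_intervals = c(34, 42))
  expect_true(is_practical(dose_schedule("cytotoxic", 4, 34, 7.5), loose))
  expect_error(practicality_policy(allowed_intervals = integer(0)),
               "non-empty")
  expect_error(practicality_policy(allowed_intervals = c(42, 35)), "even")
})
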