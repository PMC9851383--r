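test_that("grid enumeration matches a brute-force product", {
  spec <- grid_spec(durations = 1:3, intervals = c(2L, 4L),
                    intensities = c(1, 2))
  g <- enumerate_grid(spec)
  expect_equal(nrow(g), 12)
  expect_equal(grid_size(spec), 12)
  brute <- list()
  k <- 0
  for (d in 1:3) for (i in c(2L, 4L)) for (x in c(1, 2)) {
    k <- k + 1
    brute[[k]] <- data.frame(duration = d, interval = i, intensity = x)
  }
  brute <- do.call(rbind, brute)
  expect_equal(g[, c("duration", "interval", "intensity")], brute)
  expect_identical(g$executable, g$interval > g$duration)
  expect_error(grid_spec(durations = integer(0)), "non-empty")
  expect_error(grid_spec(intervals = c(2L, 3L)), "even")
  expect_error(grid_spec(intensities = c(1, 1.25, 2)), "uniform")
})

test_that("combination sampling yields distinct seeded schedules", {
  cyto <- grid_spec(durations = 1:3, intervals = c(2L, 4L),
                    intensities = c(1, 2))
  full <- enumerate_combination_grid(cyto, cyto)
  expect_equal(nrow(full), 144)
  expect_equal(anyDuplicated(full), 0)
  smp <- enumerate_combination_grid(cyto, cyto, sample_n = 20, seed = 3)
  expect_equal(nrow(smp), 20)
  expect_equal(anyDuplicated(smp), 0)
  smp2 <- enumerate_combination_grid(cyto, cyto, sample_n = 20, seed = 3)
  expect_equal(smp, smp2)
  expect_error(enumerate_combination_grid(cyto, cyto, sample_n = 200),
               "exceeds")
  # sampled rows decode to members of the full product
  key <- function(d) do.call(paste, c(d, sep = "/"))
  expect_true(all(key(smp) %in% key(full)))
})

test_that("sweep execution skips non-executable rows and classifies", {
  g <- test_geom()
  scheds <- data.frame(duration = c(2L, 4L), interval = c(42L, 2L),
                       intensity = c(12, 12))
  res <- run_sweep(scheds, quick_protocol(n_replicates = 2L), g,
                   test_grad(), untreated_mean_size = 345,
                   base_seed = 1)
  expect_equal(nrow(res), 1L)  # interval 2 <= duration 4 dropped
  expect_true(all(c("percent_cure", "toxic", "practical",
                    "crypt_size_percent_untreated") %in% names(res)))
  expect_true(res$practical)  # duration 2, weekly interval
  expect_type(res$toxic, "logical")
})

test_that("curative filtering is strict, idempotent and order-preserving", {
  res <- data.frame(id = 1:4,
                    percent_cure = c(100, 98, 100, 100),
                    toxic = c(FALSE, FALSE, TRUE, FALSE),
                    practical = TRUE)
  kept <- filter_curative(res)
  expect_equal(kept$id, c(1, 4))
  expect_equal(filter_curative(kept), kept)
  empty <- res[0, ]
  expect_equal(nrow(filter_curative(empty)), 0)
})

test_that("optimal selection ranks by crypt size, dose, then time", {
  cur <- data.frame(id = 1:4,
                    percent_cure = 100, toxic = FALSE,
                    practical = c(TRUE, TRUE, TRUE, FALSE),
                    crypt_size_percent_untreated = c(60, 70, 70, 95),
                    mean_accumulated_dose = c(10, 9, 8, 1),
                    mean_time_to_cure_steps = c(100, 90, 120, 50))
  ranked <- select_optimal(cur)
  expect_equal(ranked$id, c(3, 2, 1))  # impractical id 4 removed
  expect_equal(ranked$rank, 1:3)
  # permuting the input does not change the ranking
  ranked2 <- select_optimal(cur[c(4, 2, 1, 3), ])
  expect_equal(ranked2$id, ranked$id)
  none <- cur[cur$id == 4, ]
  expect_message(out <- select_optimal(none), "practicality")
  expect_equal(nrow(out), 0)
  expect_error(select_optimal(cur[0, ]), "non-empty")
})
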