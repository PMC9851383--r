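test_that("constructors validate geometry and gradient invariants", {
  expect_error(crypt_geometry(10, 10, 2000), "capacity")
  expect_error(crypt_geometry(height = 2), "height")
  expect_error(crypt_geometry(25, 80, 1750, min_viable_cells = 1800),
               "min_viable_cells")
  expect_error(gradient_params(divide_max = 0.1, divide_min = 0.2),
               "divide_max")
  expect_error(gradient_params(die_max = 1.2), "\\[0, 1\\]")
  expect_error(gradient_params(niche_fraction = 0), "niche_fraction")
  expect_error(gradient_params(niche_fraction = 0.5, top_fraction = 0.6),
               "proliferative")
})

test_that("initialization fills the crypt to target and is reproducible", {
  g <- test_geom()
  cr <- init_crypt(g, test_grad(), seed = 7)
  expect_equal(length(cr$col), g$homeostatic_target)
  expect_true(all(cr$phen == 1L))
  expect_true(all(cr$ring <= g$height))
  cr2 <- init_crypt(g, test_grad(), seed = 7)
  expect_identical(cr[c("col", "ring", "phen")], cr2[c("col", "ring", "phen")])
  for (i in 1:5) {
    cr <- step_crypt(cr)
    cr2 <- step_crypt(cr2)
  }
  expect_identical(cr[c("col", "ring", "phen")], cr2[c("col", "ring", "phen")])
})

test_that("divide and die probabilities reflect phenotype kinetics exactly", {
  gr <- test_grad()
  h <- 0.4
  p_n <- divide_probability(h, "normal", gr, compartment = "proliferating")
  p_c <- divide_probability(h, "cancer", gr, compartment = "proliferating")
  p_r <- divide_probability(h, "resistant", gr, compartment = "proliferating")
  expect_equal(p_c / p_n, 1.16)
  expect_equal(p_r / p_n, 1.08)
  d_n <- die_probability(h, "normal", gr)
  d_c <- die_probability(h, "cancer", gr)
  d_r <- die_probability(h, "resistant", gr)
  expect_equal(d_c / d_n, 1.10)
  expect_equal(d_r / d_n, 1.05)
})

test_that("probabilities clamp to [0,1] and respect gradient endpoints", {
  gr <- test_grad()
  expect_equal(divide_probability(1, "normal", gr,
                                  compartment = "proliferating"), 0)
  hot <- gradient_params(divide_max = 0.9, die_max = 0.9)
  expect_equal(divide_probability(0, "cancer", hot,
                                  compartment = "proliferating"), 1)
  # sweep-range drug intensities never push probabilities out of [0,1]
  hs <- seq(0, 1, length.out = 21)
  for (L in c(0.25, 1, 5.75, 20)) {
    for (A in c(1, 3.5, 20)) {
      p <- die_probability(hs, "cancer", gr, lethality = L,
                           apoptotic_intensity = A)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
  expect_error(die_probability(0.5, lethality = -1), "non-negative")
})

test_that("quiescent stem cells divide only after release", {
  gr <- test_grad()
  expect_equal(divide_probability(0.05, "normal", gr), 0)
  expect_gt(divide_probability(0.05, "normal", gr, released = TRUE), 0)
  # cancer-lineage cells never enter quiescence
  expect_gt(divide_probability(0.05, "cancer", gr), 0)
  expect_identical(cell_compartment(0.05, "resistant", gr), "proliferating")
  expect_identical(cell_compartment(0.05, "normal", gr), "quiescent_stem")
  expect_identical(cell_compartment(0.9, "normal", gr), "differentiated")
})

test_that("die probability is monotone in both drug intensities", {
  gr <- test_grad()
  hs <- seq(0.05, 0.95, length.out = 10)
  for (ph in c("normal", "cancer", "resistant")) {
    prev <- rep(0, length(hs))
    for (L in c(1, 2, 5, 10, 20)) {
      p <- die_probability(hs, ph, gr, lethality = L)
      expect_true(all(p >= prev - 1e-12))
      prev <- p
    }
    prev <- rep(0, length(hs))
    for (A in c(1, 2, 5, 10, 20)) {
      p <- die_probability(hs, ph, gr, apoptotic_intensity = A)
      expect_true(all(p >= prev - 1e-12))
      prev <- p
    }
  }
})

test_that("per-step bookkeeping conserves cells", {
  cr <- init_crypt(test_geom(), test_grad(), seed = 3)
  for (i in 1:60) {
    before <- length(cr$col)
    L <- c(1, 1, 6)[(i %% 3) + 1]  # alternate untreated and dosed steps
    cr <- step_crypt(cr, lethality = L)
    ev <- cr$last_events
    expect_true(all(ev >= 0))
    expect_equal(length(cr$col),
                 before + ev[["births"]] - ev[["deaths"]] - ev[["removals"]])
    # stacks stay contiguous from the base
    expect_equal(length(cr$col),
                 sum(tabulate(cr$col, test_geom()$circumference)))
    expect_true(all(cr$ring >= 1 & cr$ring <= test_geom()$height))
  }
})

test_that("sustained extreme lethality extinguishes the crypt", {
  cr <- init_crypt(test_geom(), test_grad(), seed = 2)
  for (i in 1:400) {
    cr <- step_crypt(cr, lethality = 1e6)
    if (length(cr$col) == 0L) break
  }
  expect_equal(length(cr$col), 0L)
  # an extinguished crypt remains a legal state
  cr <- step_crypt(cr)
  expect_equal(length(cr$col), 0L)
  expect_equal(census(cr)$cancer_fraction, 0)
})

test_that("mutant seeding converts proliferating cells as configured", {
  cr <- init_crypt(test_geom(), test_grad(), seed = 5)
  for (i in 1:50) cr <- step_crypt(cr)
  cr2 <- introduce_mutants(cr, "cancer", n = 3, position = "lower_third")
  expect_equal(sum(cr2$phen == 2L), 3L)
  h <- (cr2$ring[cr2$phen == 2L] - 1) / (test_geom()$height - 1)
  expect_true(all(h <= 1 / 3))
  # scheduling guard: a mismatched at_step leaves the crypt unchanged
  cr3 <- introduce_mutants(cr, "resistant", at_step = cr$step_index + 10L)
  expect_identical(cr3$phen, cr$phen)
  # no proliferating cells -> warning, no-op
  empty <- cr
  empty$col <- integer(0); empty$ring <- integer(0)
  empty$phen <- integer(0); empty$lineage <- integer(0)
  expect_warning(introduce_mutants(empty, "cancer"), "no proliferating")
})

test_that("census counts are consistent", {
  cr <- init_crypt(test_geom(), test_grad(), seed = 1)
  cen <- census(cr)
  expect_equal(cen$cancer_fraction, 0)
  expect_equal(sum(cen$counts), cen$total)
  cr$phen <- rep(2L, length(cr$col))
  expect_equal(census(cr)$cancer_fraction, 1)
})

test_that("untreated crypt stays near its homeostatic target", {
  g <- test_geom()
  cr <- init_crypt(g, test_grad(), seed = 4)
  for (i in 1:100) cr <- step_crypt(cr)
  tot <- integer(400)
  for (i in 1:400) {
    cr <- step_crypt(cr)
    tot[i] <- length(cr$col)
  }
  expect_lt(abs(mean(tot) - g$homeostatic_target) / g$homeostatic_target,
            0.10)
})

test_that("a neutral crypt drifts toward monoclonality", {
  g <- crypt_geometry(6, 12, 50, 40)
  fixed <- logical(3)
  for (s in 1:3) {
    cr <- init_crypt(g, test_grad(), seed = s, tag_lineages = TRUE)
    for (i in 1:4000) {
      cr <- step_crypt(cr)
      if (i %% 100 == 0 && length(unique(cr$lineage)) == 1L) {
        fixed[s] <- TRUE
        break
      }
    }
  }
  expect_true(all(fixed))
})
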