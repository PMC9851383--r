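# Shared fixtures: a small desk-scale crypt for fast module tests
# (10 x 40 lattice; untreated equilibrium ~345 cells under the default
# gradients, so the 350 target is within 2%).

test_geom <- function() crypt_geometry(circumference = 10L, height = 40L,
                                       homeostatic_target = 350L,
                                       min_viable_cells = 280L)

test_grad <- function() gradient_params()

quick_protocol <- function(phenotype = "cancer", n_replicates = 4L,
                           max_steps = 1200L) {
  trial_protocol(mutation_step = 100L, n_replicates = n_replicates,
                 max_steps = max_steps, phenotype_label = phenotype,
                 n_mutants = 4L, mutant_position = "bottom")
}

# minimal hand-built trial outcome for aggregation tests
fake_outcome <- function(cured, time = NA_real_, size = 300,
                         dose = NA_real_, extinguished = FALSE,
                         evaluable = TRUE, min_size = size,
                         apoptotic_only = FALSE, floor = 280) {
  structure(list(cured = cured, extinguished = extinguished,
                 evaluable = evaluable, time_to_cure_steps = time,
                 mean_treated_crypt_size = size,
                 min_treated_crypt_size = min_size,
                 accumulated_dose = dose, apoptotic_only = apoptotic_only,
                 min_viable_cells = floor, seed = 1L),
            class = "trial_outcome")
}

# degenerate surrogate with fully controlled predictions: one feature,
# probability = plogis(x)
fake_surrogate <- function() {
  structure(list(fit = list(coefficients = c(0, 1)), center = 0,
                 scale = 1, is_nnet = FALSE),
            class = "surrogate_model")
}
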