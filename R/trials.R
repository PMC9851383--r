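# Simulated clinical trials: mutate at a protocol step, trigger therapy
# at a cancer-fraction threshold, run to cure / extinguishment / cap,
# replicate, aggregate.

#' Simulated-clinical-trial protocol
#'
#' @param mutation_step Step at which proliferating cells are mutated
#'   (default 200).
#' @param therapy_trigger_fraction Cancer fraction that triggers therapy
#'   (default 0.5).
#' @param n_replicates Stochastic replicates per dose schedule
#'   (default 50).
#' @param max_steps Cap on post-therapy steps before a replicate is
#'   declared uncured (default 2000 steps, about 333 days, far beyond
#'   any observed time to cure).
#' @param phenotype_label Mutant phenotype: `"cancer"` or
#'   `"resistant"`.
#' @param n_mutants Number of proliferating cells converted at the
#'   mutation step.
#' @param mutant_position Seeding position (see [introduce_mutants()]).
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(mutation_step = 200L,
                           therapy_trigger_fraction = 0.5,
                           n_replicates = 50L,
                           max_steps = 2000L,
                           phenotype_label = c("cancer", "resistant"),
                           n_mutants = 1L,
                           mutant_position = "lower_third") {
  phenotype_label <- match.arg(phenotype_label)
  if (therapy_trigger_fraction <= 0 || therapy_trigger_fraction > 1)
    stop("`therapy_trigger_fraction` must be in (0, 1]")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  if (max_steps <= mutation_step)
    stop("`max_steps` must exceed `mutation_step`")
  structure(list(mutation_step = as.integer(mutation_step),
                 therapy_trigger_fraction = therapy_trigger_fraction,
                 n_replicates = as.integer(n_replicates),
                 max_steps = as.integer(max_steps),
                 phenotype_label = phenotype_label,
                 n_mutants = as.integer(n_mutants),
                 mutant_position = mutant_position),
            class = "trial_protocol")
}

.schedule_parts <- function(schedule) {
  if (is.null(schedule)) return(list(cytotoxic = NULL, apoptotic = NULL))
  if (inherits(schedule, "combination_schedule"))
    return(list(cytotoxic = schedule$cytotoxic,
                apoptotic = schedule$apoptotic))
  if (inherits(schedule, "dose_schedule")) {
    if (schedule$drug_kind == "cytotoxic")
      return(list(cytotoxic = schedule, apoptotic = NULL))
    return(list(cytotoxic = NULL, apoptotic = schedule))
  }
  stop("`schedule` must be a dose_schedule, combination_schedule or NULL")
}

#' Run one simulated clinical trial replicate
#'
#' Simulates the full protocol on one crypt: initialize at homeostasis,
#' run to the mutation step, convert proliferating cells to the mutant
#' phenotype, let the mutant clone expand until it reaches the therapy
#' trigger fraction, then apply the dose schedule(s) (all drugs start
#' simultaneously) until cure (no cancer-lineage cells), extinguishment
#' (no cells at all) or the step cap. Deterministic for a fixed seed.
#'
#' @param schedule A [dose_schedule()], [combination_schedule()], or
#'   `NULL` for an untreated run.
#' @param protocol A [trial_protocol()].
#' @param geometry A [crypt_geometry()].
#' @param gradients A [gradient_params()].
#' @param seed Integer seed for this replicate's RNG stream.
#' @return An object of class `trial_outcome`: `evaluable`, `cured`,
#'   `extinguished`, `time_to_cure_steps` (`NA` unless cured),
#'   `mean_treated_crypt_size`, `min_treated_crypt_size`,
#'   `accumulated_dose`, `therapy_start_step`, `seed`, plus the
#'   schedule descriptors and toxicity-floor context used by
#'   [classify_toxic()].
#' @export
run_trial <- function(schedule, protocol = trial_protocol(),
                      geometry = crypt_geometry(),
                      gradients = gradient_params(), seed = 1L) {
  parts <- .schedule_parts(schedule)
  cyto <- parts$cytotoxic
  apo <- parts$apoptotic

  crypt <- init_crypt(geometry, gradients, seed = seed)
  for (i in seq_len(protocol$mutation_step)) crypt <- step_crypt(crypt)
  crypt <- introduce_mutants(crypt, protocol$phenotype_label,
                             n = protocol$n_mutants,
                             position = protocol$mutant_position)

  out <- list(schedule = schedule, seed = as.integer(seed),
              phenotype = protocol$phenotype_label,
              apoptotic_only = is.null(cyto) && !is.null(apo),
              min_viable_cells = geometry$min_viable_cells,
              evaluable = FALSE, cured = FALSE, extinguished = FALSE,
              time_to_cure_steps = NA_real_,
              mean_treated_crypt_size = NA_real_,
              min_treated_crypt_size = NA_real_,
              accumulated_dose = NA_real_,
              therapy_start_step = NA_integer_)
  class(out) <- "trial_outcome"

  # free growth until the mutant clone reaches the therapy trigger
  repeat {
    frac <- if (length(crypt$col)) mean(crypt$phen != 1L) else 0
    if (frac >= protocol$therapy_trigger_fraction) break
    if (crypt$step_index >= protocol$max_steps || frac == 0)
      return(out)  # clone lost or trigger never reached: not evaluable
    crypt <- step_crypt(crypt)
  }

  out$evaluable <- TRUE
  therapy_start <- crypt$step_index
  out$therapy_start_step <- therapy_start
  min_size <- Inf
  size_sum <- 0
  treated_steps <- 0L

  repeat {
    st <- crypt$step_index
    L <- if (!is.null(cyto) && is_dose_active(cyto, st, therapy_start))
      cyto$intensity else 1
    A <- if (!is.null(apo) && is_dose_active(apo, st, therapy_start))
      apo$intensity else 1
    crypt <- step_crypt(crypt, lethality = L, apoptotic_intensity = A)
    total <- length(crypt$col)
    min_size <- min(min_size, total)
    size_sum <- size_sum + total
    treated_steps <- treated_steps + 1L
    n_cancer <- sum(crypt$phen != 1L)

    if (total == 0L) {
      out$extinguished <- TRUE
      break
    }
    if (n_cancer == 0L) {
      out$cured <- TRUE
      out$time_to_cure_steps <- crypt$step_index - therapy_start
      break
    }
    if (crypt$step_index - therapy_start >= protocol$max_steps) break
  }

  out$min_treated_crypt_size <- min_size
  out$mean_treated_crypt_size <- size_sum / treated_steps
  if (out$cured && !is.null(cyto))
    out$accumulated_dose <- accumulated_dose(cyto$intensity,
                                             out$time_to_cure_steps,
                                             cyto$interval)
  out
}

#' Run all replicates of a trial
#'
#' Executes `protocol$n_replicates` independent replicates of
#' [run_trial()], each on its own RNG stream derived from `base_seed`.
#'
#' @inheritParams run_trial
#' @param base_seed First replicate seed; replicate `k` uses
#'   `base_seed + k - 1`.
#' @return A list of `trial_outcome` objects.
#' @export
run_replicates <- function(schedule, protocol = trial_protocol(),
                           geometry = crypt_geometry(),
                           gradients = gradient_params(),
                           base_seed = 1L) {
  lapply(seq_len(protocol$n_replicates) - 1L, function(k) {
    run_trial(schedule, protocol, geometry, gradients,
              seed = base_seed + k)
  })
}

#' Aggregate replicate outcomes
#'
#' Computes the per-schedule summary: percent cure over evaluable
#' replicates, mean time to cure (steps and days) over cured
#' replicates, mean treated crypt size as a percentage of the untreated
#' mean size, mean accumulated cytotoxic dose (computed per replicate,
#' then averaged), and whether any replicate extinguished its crypt.
#'
#' @param outcomes Non-empty list of `trial_outcome` objects.
#' @param untreated_mean_size Mean total cell count of a matched
#'   untreated crypt (see [untreated_crypt_size()]).
#' @return A one-row data frame of class `replicate_summary`.
#' @export
summarize_replicates <- function(outcomes, untreated_mean_size = NULL) {
  if (length(outcomes) == 0L) stop("`outcomes` must be non-empty")
  ev <- Filter(function(o) isTRUE(o$evaluable), outcomes)
  n_eval <- length(ev)
  if (n_eval == 0L)
    stop("no evaluable replicates (mutant clone never reached the trigger)")
  cured <- vapply(ev, function(o) isTRUE(o$cured), logical(1))
  times <- vapply(ev, function(o) o$time_to_cure_steps, numeric(1))
  sizes <- vapply(ev, function(o) o$mean_treated_crypt_size, numeric(1))
  doses <- vapply(ev, function(o) o$accumulated_dose, numeric(1))
  pct <- 100 * sum(cured) / n_eval
  mean_t <- if (any(cured)) mean(times[cured]) else NA_real_
  out <- data.frame(
    n_replicates = length(outcomes),
    n_evaluable = n_eval,
    percent_cure = pct,
    mean_time_to_cure_steps = mean_t,
    mean_time_to_cure_days = if (is.na(mean_t)) NA_real_
      else steps_to_days(mean_t),
    mean_treated_crypt_size = mean(sizes),
    crypt_size_percent_untreated = if (is.null(untreated_mean_size))
      NA_real_ else 100 * mean(sizes) / untreated_mean_size,
    mean_accumulated_dose = if (any(cured & !is.na(doses)))
      mean(doses[cured], na.rm = TRUE) else NA_real_,
    any_extinguished = any(vapply(ev, function(o) isTRUE(o$extinguished),
                                  logical(1))),
    min_crypt_size = min(vapply(ev, function(o) o$min_treated_crypt_size,
                                numeric(1)))
  )
  class(out) <- c("replicate_summary", class(out))
  out
}

#' Classify a trial outcome as toxic
#'
#' A schedule is toxic for a replicate if it extinguished the crypt, or
#' -- for apoptotic-only dosing -- if the crypt shrank below the
#' minimum viable size (the 1,399-cell floor at full scale, the lowest
#' count measured in biopsy crypts).
#'
#' @param outcome A `trial_outcome`.
#' @return Logical scalar.
#' @export
classify_toxic <- function(outcome) {
  if (isTRUE(outcome$extinguished)) return(TRUE)
  if (isTRUE(outcome$apoptotic_only) &&
      is.finite(outcome$min_treated_crypt_size) &&
      outcome$min_treated_crypt_size < outcome$min_viable_cells)
    return(TRUE)
  FALSE
}

#' Untreated mean crypt size
#'
#' Simulates an untreated, mutation-free crypt and returns the mean
#' total cell count after a burn-in, the reference size against which
#' treated crypt sizes are expressed.
#'
#' @param geometry A [crypt_geometry()].
#' @param gradients A [gradient_params()].
#' @param n_steps Steps to simulate after burn-in.
#' @param burn_in Steps discarded before averaging.
#' @param seed Integer RNG seed.
#' @return Mean total cell count (numeric scalar).
#' @export
untreated_crypt_size <- function(geometry = crypt_geometry(),
                                 gradients = gradient_params(),
                                 n_steps = 500L, burn_in = 200L,
                                 seed = 1L) {
  crypt <- init_crypt(geometry, gradients, seed = seed)
  for (i in seq_len(burn_in)) crypt <- step_crypt(crypt)
  tot <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    crypt <- step_crypt(crypt)
    tot[i] <- length(crypt$col)
  }
  mean(tot)
}
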