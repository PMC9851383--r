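# Dose-schedule grid enumeration, sweep execution and multi-objective
# filtering.

#' Dose-schedule grid specification
#'
#' The enumerable ranges of duration, interval and intensity for one
#' drug. The defaults reproduce the single-drug sweep: durations 1-48
#' in steps of 1, even intervals 2-96, and intensities 0.25-20.00 on a
#' 0.25 grid (80 values), for 48 x 48 x 80 = 184,320 schedules. The
#' requirement that the interval exceed the duration is applied at
#' execution time, not at enumeration.
#'
#' @param durations Integer vector of dose durations (steps).
#' @param intervals Integer vector of even dose intervals (steps).
#' @param intensities Numeric vector of intensities on a uniform grid.
#' @param enforce_interval_gt_duration Logical; mark rows violating
#'   interval > duration as non-executable when enumerating.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(durations = 1:48,
                      intervals = seq(2L, 96L, by = 2L),
                      intensities = seq(0.25, 20, by = 0.25),
                      enforce_interval_gt_duration = TRUE) {
  if (length(durations) == 0L || length(intervals) == 0L ||
      length(intensities) == 0L)
    stop("grid ranges must be non-empty")
  if (any(intervals %% 2L != 0L))
    stop("intervals must be even step counts")
  steps <- diff(sort(intensities))
  if (length(steps) > 1L && any(abs(steps - steps[1]) > 1e-8))
    stop("intensity grid must be uniform")
  structure(list(durations = as.integer(durations),
                 intervals = as.integer(intervals),
                 intensities = as.numeric(intensities),
                 enforce_interval_gt_duration =
                   isTRUE(enforce_interval_gt_duration)),
            class = "grid_spec")
}

#' Number of schedules in a grid
#' @param spec A [grid_spec()].
#' @return `|durations| * |intervals| * |intensities|` as a double.
#' @export
grid_size <- function(spec) {
  as.numeric(length(spec$durations)) * length(spec$intervals) *
    length(spec$intensities)
}

#' Enumerate a single-drug schedule grid
#'
#' Deterministic lexicographic enumeration of the Cartesian product
#' (duration outermost, then interval, then intensity). The full
#' product is returned; when the spec enforces interval > duration an
#' `executable` column marks the rows that satisfy it.
#'
#' @param spec A [grid_spec()].
#' @return A data frame with columns `duration`, `interval`,
#'   `intensity` and (if enforced) `executable`.
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  grid <- expand.grid(intensity = spec$intensities,
                      interval = spec$intervals,
                      duration = spec$durations,
                      KEEP.OUT.ATTRS = FALSE)[, 3:1]
  rownames(grid) <- NULL
  if (spec$enforce_interval_gt_duration)
    grid$executable <- grid$interval > grid$duration
  grid
}

#' Enumerate or sample a combination-schedule space
#'
#' The full product of a cytotoxic and an apoptotic grid is usually far
#' too large to materialize (184,320^2 combinations for the default
#' grids). When `sample_n` is given, a seeded uniform sample of exactly
#' `sample_n` distinct combinations is drawn by index arithmetic
#' without materializing the space; otherwise the full product is
#' materialized (only permitted for small spaces).
#'
#' @param cyto,apo [grid_spec()] objects for the two drugs.
#' @param sample_n Optional number of distinct combinations to sample.
#' @param seed Integer seed for the sample.
#' @param max_materialize Safety cap on full materialization.
#' @return A data frame with columns `cyto_duration`, `cyto_interval`,
#'   `cyto_intensity`, `apo_duration`, `apo_interval`, `apo_intensity`.
#' @export
enumerate_combination_grid <- function(cyto = grid_spec(),
                                       apo = grid_spec(),
                                       sample_n = NULL, seed = 1L,
                                       max_materialize = 1e6) {
  n_cyto <- grid_size(cyto)
  n_apo <- grid_size(apo)
  total <- n_cyto * n_apo
  decode <- function(idx0) {
    # mixed-radix decode of 0-based flat indices, cytotoxic outermost
    i_apo <- idx0 %% n_apo
    i_cyto <- (idx0 - i_apo) / n_apo
    dec1 <- function(i0, spec) {
      nL <- length(spec$intensities)
      nI <- length(spec$intervals)
      iL <- i0 %% nL
      i0 <- (i0 - iL) / nL
      iI <- i0 %% nI
      iD <- (i0 - iI) / nI
      data.frame(duration = spec$durations[iD + 1],
                 interval = spec$intervals[iI + 1],
                 intensity = spec$intensities[iL + 1])
    }
    cy <- dec1(i_cyto, cyto)
    ap <- dec1(i_apo, apo)
    data.frame(cyto_duration = cy$duration, cyto_interval = cy$interval,
               cyto_intensity = cy$intensity, apo_duration = ap$duration,
               apo_interval = ap$interval, apo_intensity = ap$intensity)
  }
  if (is.null(sample_n)) {
    if (total > max_materialize)
      stop("combination space has ", format(total, big.mark = ","),
           " schedules; pass `sample_n` to draw a seeded sample instead")
    return(decode(seq_len(total) - 1))
  }
  sample_n <- as.integer(sample_n)
  if (sample_n > total)
    stop("`sample_n` (", sample_n, ") exceeds the combination space (",
         format(total, big.mark = ","), ")")
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  set.seed(as.integer(seed))
  picked <- numeric(0)
  while (length(picked) < sample_n) {
    draw <- floor(stats::runif(2L * (sample_n - length(picked))) * total)
    draw <- pmin(draw, total - 1)
    picked <- unique(c(picked, draw))
  }
  decode(sort(picked[seq_len(sample_n)]))
}

#' Execute a sweep of dose schedules
#'
#' Runs the full replicate trial protocol for each schedule row and
#' returns one summary row per schedule, including the toxicity and
#' practicality classifications used by the downstream filters.
#' Schedule rows violating interval > duration are skipped (marked
#' non-executable).
#'
#' @param schedules A data frame of schedules: either single-drug
#'   columns (`duration`, `interval`, `intensity`, with `drug_kind`
#'   given by the argument) or combination columns as produced by
#'   [enumerate_combination_grid()].
#' @param protocol A [trial_protocol()].
#' @param geometry,gradients Model configuration.
#' @param untreated_mean_size Reference untreated crypt size; computed
#'   once via [untreated_crypt_size()] when `NULL`.
#' @param policy A [practicality_policy()].
#' @param drug_kind For single-drug schedule tables, which drug the
#'   columns describe.
#' @param base_seed Seed for the first replicate of the first schedule;
#'   each schedule gets a disjoint replicate seed block.
#' @param progress Logical; print one line per schedule to stderr.
#' @return A data frame (one row per schedule) of class
#'   `sweep_result`: the schedule columns plus the
#'   [summarize_replicates()] summary, `toxic` and `practical`.
#' @export
run_sweep <- function(schedules, protocol = trial_protocol(),
                      geometry = crypt_geometry(),
                      gradients = gradient_params(),
                      untreated_mean_size = NULL,
                      policy = practicality_policy(),
                      drug_kind = c("cytotoxic", "apoptotic"),
                      base_seed = 1L, progress = FALSE) {
  drug_kind <- match.arg(drug_kind)
  if (is.null(untreated_mean_size))
    untreated_mean_size <- untreated_crypt_size(geometry, gradients,
                                                seed = base_seed)
  is_combo <- "cyto_duration" %in% names(schedules)
  rows <- vector("list", nrow(schedules))
  for (i in seq_len(nrow(schedules))) {
    sched <- .row_to_schedule(schedules[i, ], is_combo, drug_kind)
    if (is.null(sched)) next  # non-executable (interval <= duration)
    seed_i <- base_seed + (i - 1L) * protocol$n_replicates
    outcomes <- run_replicates(sched, protocol, geometry, gradients,
                               base_seed = seed_i)
    smry <- summarize_replicates(outcomes, untreated_mean_size)
    toxic <- any(vapply(outcomes, classify_toxic, logical(1)))
    rows[[i]] <- cbind(schedules[i, , drop = FALSE], smry,
                       toxic = toxic,
                       practical = is_practical(sched, policy))
    if (progress)
      message("schedule ", i, "/", nrow(schedules), ": cure ",
              round(smry$percent_cure, 1), "%, toxic ", toxic)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

.row_to_schedule <- function(row, is_combo, drug_kind) {
  mk <- function(kind, d, i, x) {
    if (i <= d) return(NULL)
    dose_schedule(kind, d, i, x)
  }
  if (is_combo) {
    cy <- mk("cytotoxic", row$cyto_duration, row$cyto_interval,
             row$cyto_intensity)
    ap <- mk("apoptotic", row$apo_duration, row$apo_interval,
             row$apo_intensity)
    if (is.null(cy) || is.null(ap)) return(NULL)
    return(combination_schedule(cy, ap))
  }
  mk(drug_kind, row$duration, row$interval, row$intensity)
}

#' Keep curative, crypt-sparing schedules
#'
#' Filters sweep results to schedules that cured 100% of replicates
#' while retaining crypt function (no toxic replicate). The filter is
#' strict (a 49/50 cure rate is excluded), idempotent and
#' order-preserving.
#'
#' @param results A `sweep_result` data frame.
#' @return The filtered data frame.
#' @export
filter_curative <- function(results) {
  if (length(results) == 0L || nrow(results) == 0L) return(results)
  results[results$percent_cure == 100 & !results$toxic, , drop = FALSE]
}

#' Rank curative schedules by clinical desirability
#'
#' Applies the practicality policy and ranks the remaining schedules
#' lexicographically: highest crypt size (least perturbation of crypt
#' function), then lowest mean accumulated cytotoxic dose, then lowest
#' mean time to cure.
#'
#' @param curative A data frame from [filter_curative()].
#' @param policy A [practicality_policy()] (the `practical` column is
#'   recomputed if absent).
#' @return The ranked data frame with a `rank` column; zero rows (with
#'   a message) if every schedule is filtered out.
#' @export
select_optimal <- function(curative, policy = practicality_policy()) {
  if (nrow(curative) == 0L) stop("`curative` must be non-empty")
  keep <- curative[curative$practical, , drop = FALSE]
  if (nrow(keep) == 0L) {
    message("no curative schedule passes the practicality policy")
    keep$rank <- integer(0)
    return(keep)
  }
  ord <- order(-keep$crypt_size_percent_untreated,
               keep$mean_accumulated_dose,
               keep$mean_time_to_cure_steps)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}
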