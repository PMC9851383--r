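# Dose schedules, drug-activity timing, unit conversions and the
# clinical-practicality filter.

#' Dose schedule for a single drug
#'
#' A dose schedule is the triple (duration, interval, intensity): the
#' drug is active for `duration` consecutive steps starting at the
#' beginning of each `interval` (the interval is measured from the start
#' of one dose to the start of the next). Intensity is the cytotoxic
#' lethality factor for `"cytotoxic"` drugs and the apoptotic
#' PTreatment/CptDieMax factor for `"apoptotic"` drugs.
#'
#' @param drug_kind `"cytotoxic"` or `"apoptotic"`.
#' @param duration Integer steps (>= 1) of drug exposure per dose.
#' @param interval Even integer steps (>= 2) between dose starts; must
#'   exceed `duration` for an executable schedule.
#' @param intensity Positive multiplier on the positional death
#'   probability of the targeted compartment while the dose is active.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(drug_kind = c("cytotoxic", "apoptotic"),
                          duration, interval, intensity) {
  drug_kind <- match.arg(drug_kind)
  duration <- as.integer(duration)
  interval <- as.integer(interval)
  if (duration < 1L) stop("`duration` must be >= 1 step")
  if (interval < 2L || interval %% 2L != 0L)
    stop("`interval` must be an even integer >= 2 steps")
  if (interval <= duration)
    stop("`interval` must be greater than `duration`")
  if (intensity <= 0) stop("`intensity` must be positive")
  structure(list(drug_kind = drug_kind, duration = duration,
                 interval = interval, intensity = intensity),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("<dose_schedule> %s: duration %d, interval %d, intensity %g\n",
              x$drug_kind, x$duration, x$interval, x$intensity))
  invisible(x)
}

#' Combination schedule of one cytotoxic and one apoptotic drug
#'
#' Both drugs start simultaneously at `start_step`; thereafter each
#' follows its own interval.
#'
#' @param cytotoxic A cytotoxic [dose_schedule()].
#' @param apoptotic An apoptotic [dose_schedule()].
#' @param start_step Non-negative integer start step.
#' @return An object of class `combination_schedule`.
#' @export
combination_schedule <- function(cytotoxic, apoptotic, start_step = 0L) {
  if (!inherits(cytotoxic, "dose_schedule") ||
      cytotoxic$drug_kind != "cytotoxic")
    stop("`cytotoxic` must be a cytotoxic dose_schedule")
  if (!inherits(apoptotic, "dose_schedule") ||
      apoptotic$drug_kind != "apoptotic")
    stop("`apoptotic` must be an apoptotic dose_schedule")
  start_step <- as.integer(start_step)
  if (start_step < 0L) stop("`start_step` must be >= 0")
  structure(list(cytotoxic = cytotoxic, apoptotic = apoptotic,
                 start_step = start_step),
            class = "combination_schedule")
}

#' Is a dose active at a given step?
#'
#' A dose is active at `step` iff `step >= therapy_start` and
#' `(step - therapy_start) mod interval < duration`, i.e. the drug is on
#' for the first `duration` steps of every interval.
#'
#' @param schedule A [dose_schedule()].
#' @param step Non-negative integer step (vectorized).
#' @param therapy_start Step at which therapy begins.
#' @return Logical vector.
#' @export
is_dose_active <- function(schedule, step, therapy_start = 0L) {
  step >= therapy_start &
    ((step - therapy_start) %% schedule$interval) < schedule$duration
}

#' Convert simulation steps to days
#'
#' One step is estimated to be 4 hours of human time; days are reported
#' rounded to 2 decimals (71.01 steps -> 11.84 days).
#'
#' @param steps Non-negative numeric vector of steps.
#' @return Days, rounded to 2 decimal places.
#' @export
steps_to_days <- function(steps) {
  if (any(steps < 0)) stop("`steps` must be non-negative")
  round(steps * 4 / 24, 2)
}

#' Accumulated cytotoxic dose
#'
#' The surrogate for cumulative cytotoxic exposure:
#' `lethality * (time_to_cure / interval)`, i.e. intensity times the
#' number of doses delivered up to cure. When aggregating replicates the
#' formula is applied per replicate and then averaged.
#'
#' @param lethality Cytotoxic intensity factor.
#' @param time_to_cure_steps Time to cure in steps (>= 0).
#' @param interval Dose interval in steps (> 0).
#' @return Accumulated dose in lethality units.
#' @export
accumulated_dose <- function(lethality, time_to_cure_steps, interval) {
  if (any(interval <= 0)) stop("`interval` must be positive")
  if (any(time_to_cure_steps < 0)) stop("`time_to_cure_steps` must be >= 0")
  lethality * time_to_cure_steps / interval
}

#' Clinical-practicality policy
#'
#' Encodes which schedules an infusion clinic can realistically deliver:
#' dose durations short enough to fit a working day, and intervals that
#' stay in synch with the 7-day week. The default allows infusions of at
#' most 2 steps (8 hours) and intervals that are whole-week multiples of
#' 42 steps.
#'
#' @param max_duration_steps Longest acceptable dose duration, in steps.
#' @param allowed_intervals Set of acceptable intervals (even step
#'   counts).
#' @return An object of class `practicality_policy`.
#' @export
practicality_policy <- function(max_duration_steps = 2L,
                                allowed_intervals = c(42L, 84L)) {
  allowed_intervals <- as.integer(allowed_intervals)
  if (length(allowed_intervals) == 0L)
    stop("`allowed_intervals` must be non-empty")
  if (any(allowed_intervals %% 2L != 0L))
    stop("all allowed intervals must be even step counts")
  structure(list(max_duration_steps = as.integer(max_duration_steps),
                 allowed_intervals = allowed_intervals),
            class = "practicality_policy")
}

#' Is a schedule practical to administer in the clinic?
#'
#' `TRUE` iff every drug's duration is at most
#' `policy$max_duration_steps` and every interval is in
#' `policy$allowed_intervals`. A 4-step infusion (16 hours) fails the
#' default policy, as does a 34-step interval (5.7 days, out of synch
#' with the week).
#'
#' @param schedule A [dose_schedule()] or [combination_schedule()].
#' @param policy A [practicality_policy()].
#' @return Logical scalar.
#' @export
is_practical <- function(schedule, policy = practicality_policy()) {
  parts <- if (inherits(schedule, "combination_schedule"))
    list(schedule$cytotoxic, schedule$apoptotic) else list(schedule)
  all(vapply(parts, function(s) {
    s$duration <= policy$max_duration_steps &&
      s$interval %in% policy$allowed_intervals
  }, logical(1)))
}
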