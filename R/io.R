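# Configuration, schedule-table readers/writers, run manifests and
# report generation.

.single_cols <- c("duration", "interval", "intensity")
.combo_cols <- c("cyto_duration", "cyto_interval", "cyto_intensity",
                 "apo_duration", "apo_interval", "apo_intensity")

#' Read a dose-schedule table
#'
#' Reads a CSV/TSV schedule table (comma default, tab accepted; UTF-8,
#' "." decimal separator). Single-drug tables carry columns
#' `duration`, `interval`, `intensity`; combination tables carry
#' `cyto_*` and `apo_*` triples. Schedule invariants are validated row
#' by row (duration >= 1; even interval >= 2; interval > duration;
#' positive intensity); a malformed row raises an error naming the row
#' number. Unknown columns (e.g. outcome columns alongside the
#' schedule) are kept with a warning. Row order is preserved.
#'
#' @param path Path to the table.
#' @param sep Field separator; inferred from the extension when `NULL`
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @return A data frame of schedules (zero rows, with a warning, for an
#'   empty file).
#' @export
read_schedule_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) == 0L || !nzchar(trimws(first))) {
    warning("empty schedule table: ", path)
    return(data.frame())
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  is_combo <- all(.combo_cols %in% names(tab))
  is_single <- all(.single_cols %in% names(tab))
  if (!is_combo && !is_single)
    stop("schedule table must contain columns ",
         paste(.single_cols, collapse = ", "), " or ",
         paste(.combo_cols, collapse = ", "))
  core <- if (is_combo) .combo_cols else .single_cols
  extra <- setdiff(names(tab), core)
  if (length(extra))
    warning("ignoring unrecognized columns: ", paste(extra, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("schedule table has a header but no rows: ", path)
    return(tab)
  }
  triples <- if (is_combo)
    list(tab[, .combo_cols[1:3]], tab[, .combo_cols[4:6]])
  else list(tab[, .single_cols])
  for (tr in triples) {
    d <- tr[[1]]; i <- tr[[2]]; x <- tr[[3]]
    bad <- which(!is.finite(d) | !is.finite(i) | !is.finite(x) |
                   d < 1 | i < 2 | i %% 2 != 0 | i <= d | x <= 0)
    if (length(bad))
      stop("invalid schedule in row ", bad[1],
           " (need duration >= 1, even interval > duration, ",
           "positive intensity)")
  }
  tab
}

#' Write sweep results
#'
#' Writes a tidy CSV (stable column order, "." decimals, UTF-8) that
#' round-trips through [read_schedule_table()] without loss of the
#' schedule columns.
#'
#' @param results A data frame (e.g. a `sweep_result`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  utils::write.csv(results, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration digest and seeds that reproduce a run
#' bit-for-bit, as machine-readable JSON.
#'
#' @param config A list of configuration objects (coerced to JSON).
#' @param seeds Integer vector of seeds used.
#' @param path Output path (".json").
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(config, seeds, path) {
  payload <- list(
    package = "cryptsched",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.integer(seeds),
    config = config,
    config_digest = sum(utf8ToInt(jsonlite::toJSON(config,
                                                   auto_unbox = TRUE))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run configuration
#'
#' Reads a YAML or JSON model/protocol configuration and instantiates
#' the package objects. Recognized top-level blocks: `geometry`,
#' `gradients`, `protocol`, `policy`; each block's entries are passed
#' to the corresponding constructor, so defaults apply to omitted
#' entries.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `geometry`, `gradients`, `protocol`, `policy`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  build <- function(block, ctor) do.call(ctor, as.list(raw[[block]]))
  list(geometry = build("geometry", crypt_geometry),
       gradients = build("gradients", gradient_params),
       protocol = build("protocol", trial_protocol),
       policy = build("policy", practicality_policy))
}

#' Filter-funnel and timeline report
#'
#' Summarizes a completed sweep as the funnel of schedule counts at
#' each stage (enumerated, predicted nontoxic, executed, curative,
#' practical, optimal) and, when a schedule is supplied, a per-step
#' treatment timeline (total cells, cancer cells, dose-active flags)
#' from a single simulated trial.
#'
#' @param results A `sweep_result` data frame (may be empty).
#' @param n_enumerated Total schedules enumerated before any filter.
#' @param n_predicted_nontoxic Schedules the surrogate passed to
#'   execution (defaults to the number executed).
#' @param policy A [practicality_policy()].
#' @param timeline_schedule Optional [dose_schedule()] or
#'   [combination_schedule()] for the timeline.
#' @param protocol,geometry,gradients Model configuration for the
#'   timeline run.
#' @param seed Seed for the timeline replicate.
#' @return A list of class `sweep_report` with `funnel` (named integer
#'   vector) and optionally `timeline` (data frame).
#' @export
report <- function(results, n_enumerated = NROW(results),
                   n_predicted_nontoxic = NROW(results),
                   policy = practicality_policy(),
                   timeline_schedule = NULL,
                   protocol = trial_protocol(),
                   geometry = crypt_geometry(),
                   gradients = gradient_params(), seed = 1L) {
  n_exec <- NROW(results)
  has_outcomes <- all(c("percent_cure", "toxic") %in% names(results))
  curative <- if (n_exec && has_outcomes) filter_curative(results)
    else results[0, , drop = FALSE]
  n_cur <- NROW(curative)
  n_prac <- if (n_cur && "practical" %in% names(curative))
    sum(curative$practical) else 0L
  n_opt <- if (n_prac > 0) 1L else 0L
  funnel <- c(enumerated = as.integer(n_enumerated),
              predicted_nontoxic = as.integer(n_predicted_nontoxic),
              executed = as.integer(n_exec),
              curative = as.integer(n_cur),
              practical = as.integer(n_prac),
              optimal = as.integer(n_opt))
  out <- list(funnel = funnel)
  if (!is.null(timeline_schedule))
    out$timeline <- schedule_timeline(timeline_schedule, protocol,
                                      geometry, gradients, seed)
  class(out) <- "sweep_report"
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Schedule filter funnel:\n")
  for (nm in names(x$funnel))
    cat(sprintf("  %-20s %d\n", nm, x$funnel[[nm]]))
  if (!is.null(x$timeline))
    cat("Timeline recorded over", nrow(x$timeline), "treatment steps\n")
  invisible(x)
}

#' Per-step treatment timeline for one schedule
#'
#' Runs the trial protocol once and records, for every step from
#' therapy initiation, the total cell count, cancer-lineage count and
#' dose-active flags -- the data behind a treatment-timeline figure.
#'
#' @inheritParams report
#' @param schedule A [dose_schedule()] or [combination_schedule()].
#' @return A data frame with columns `step`, `total`, `cancer`,
#'   `cyto_active`, `apo_active` (empty if the replicate is not
#'   evaluable).
#' @export
schedule_timeline <- function(schedule, protocol = trial_protocol(),
                              geometry = crypt_geometry(),
                              gradients = gradient_params(), seed = 1L) {
  parts <- .schedule_parts(schedule)
  crypt <- init_crypt(geometry, gradients, seed = seed)
  for (i in seq_len(protocol$mutation_step)) crypt <- step_crypt(crypt)
  crypt <- introduce_mutants(crypt, protocol$phenotype_label,
                             n = protocol$n_mutants,
                             position = protocol$mutant_position)
  repeat {
    frac <- if (length(crypt$col)) mean(crypt$phen != 1L) else 0
    if (frac >= protocol$therapy_trigger_fraction) break
    if (crypt$step_index >= protocol$max_steps || frac == 0)
      return(data.frame())
    crypt <- step_crypt(crypt)
  }
  therapy_start <- crypt$step_index
  rows <- list()
  k <- 0L
  repeat {
    st <- crypt$step_index
    cy_on <- !is.null(parts$cytotoxic) &&
      is_dose_active(parts$cytotoxic, st, therapy_start)
    ap_on <- !is.null(parts$apoptotic) &&
      is_dose_active(parts$apoptotic, st, therapy_start)
    crypt <- step_crypt(crypt,
                        lethality = if (cy_on) parts$cytotoxic$intensity else 1,
                        apoptotic_intensity = if (ap_on)
                          parts$apoptotic$intensity else 1)
    k <- k + 1L
    rows[[k]] <- data.frame(step = st - therapy_start + 1L,
                            total = length(crypt$col),
                            cancer = sum(crypt$phen != 1L),
                            cyto_active = cy_on, apo_active = ap_on)
    done <- length(crypt$col) == 0L || sum(crypt$phen != 1L) == 0L ||
      (st - therapy_start) >= protocol$max_steps
    if (done) break
  }
  do.call(rbind, rows)
}
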