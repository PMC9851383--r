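# Agent-based crypt state and per-step update.
#
# The crypt is a cylinder of `circumference` columns; cells in each column
# form a contiguous stack from the base (ring 1) upward. Normalized height
# h = (ring - 1) / (height - 1) drives the positional divide/die
# gradients. One step corresponds to approximately 4 hours of human time.

# --- seeded per-crypt RNG stream ---------------------------------------

.capture_seed_state <- function(seed) {
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  set.seed(as.integer(seed))
  get(".Random.seed", envir = globalenv())
}

.save_ambient_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_ambient_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# --- positional gradients ----------------------------------------------

#' Positional base probabilities
#'
#' `positional_divide()` is flat at `divide_max` through the quiescent
#' niche and declines linearly to `divide_min` at the crypt top;
#' `positional_die()` rises linearly from `die_min` at the base to
#' `die_max` at the top. Both are per-step probabilities, vectorized over
#' normalized height.
#'
#' @param height_norm Numeric vector of normalized heights in `[0, 1]`.
#' @param gradients A [gradient_params()] object.
#' @return Numeric vector of probabilities.
#' @export
positional_divide <- function(height_norm, gradients = gradient_params()) {
  nf <- gradients$niche_fraction
  frac <- pmax(0, (height_norm - nf) / (1 - nf))
  gradients$divide_max + (gradients$divide_min - gradients$divide_max) * frac
}

#' @rdname positional_divide
#' @export
positional_die <- function(height_norm, gradients = gradient_params()) {
  gradients$die_min + (gradients$die_max - gradients$die_min) * height_norm
}

#' Compartment assignment by position and phenotype
#'
#' Normal cells within the bottom `niche_fraction` of the crypt are
#' quiescent stem cells unless the crypt has been depleted below 90% of
#' its homeostatic target, in which case they awaken and proliferate
#' (`released = TRUE`); normal cells above `1 - top_fraction` are
#' differentiated. Cancer-lineage cells neither enter quiescence nor
#' differentiate: they are proliferating at every height, which is what
#' makes them targets of an S-phase-specific drug wherever they sit.
#'
#' @param height_norm Numeric vector of normalized heights.
#' @param phenotype Character vector (recycled) of phenotype labels.
#' @param gradients A [gradient_params()] object.
#' @param released Logical; has the quiescence-release condition
#'   (crypt size < 90% of homeostatic target) been met?
#' @return Character vector: `"quiescent_stem"`, `"proliferating"` or
#'   `"differentiated"`.
#' @export
cell_compartment <- function(height_norm, phenotype = "normal",
                             gradients = gradient_params(),
                             released = FALSE) {
  n <- length(height_norm)
  phenotype <- rep_len(phenotype, n)
  comp <- rep("proliferating", n)
  normal <- phenotype == "normal"
  comp[normal & height_norm > 1 - gradients$top_fraction] <- "differentiated"
  comp[normal & height_norm <= gradients$niche_fraction &
         !released] <- "quiescent_stem"
  comp
}

#' Per-step division probability
#'
#' The positional base probability scaled by the phenotype's divide
#' multiplier and clamped to `[0, 1]`. Quiescent stem cells divide at
#' the basal `stem_self_renewal` rate (0 by default); they acquire
#' their full positional probability only when released from
#' quiescence by crypt depletion.
#'
#' @inheritParams cell_compartment
#' @param compartment Optional character vector of compartments; derived
#'   from position and phenotype when `NULL`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
divide_probability <- function(height_norm, phenotype = "normal",
                               gradients = gradient_params(),
                               released = FALSE, compartment = NULL) {
  n <- length(height_norm)
  phenotype <- rep_len(phenotype, n)
  if (is.null(compartment))
    compartment <- cell_compartment(height_norm, phenotype, gradients, released)
  mult <- .phenotypes$divide_multiplier[match(phenotype, .phenotypes$label)]
  p <- pmin(1, pmax(0, positional_divide(height_norm, gradients) * mult))
  p[compartment == "quiescent_stem"] <- gradients$stem_self_renewal
  p
}

#' Per-step death probability
#'
#' The positional base death probability scaled by the phenotype's die
#' multiplier and, during active dosing, by the drug terms. The
#' cytotoxic `lethality` raises the death probability of cells in the
#' proliferating compartment above the positional baseline by the
#' additive term `cytotoxic_gain * (lethality - 1) * cycling^2`. A
#' cell's cycling activity interpolates between a basal floor and its
#' full positional division rate
#' (`cycling = multiplier * (0.5 + 0.5 * positional fraction)`), and
#' enters squared because both the chance of being caught in S phase
#' and the chance of dying at the next division scale with cycle rate:
#' the 5-FU-like drug is S-phase specific, so fast-cycling sensitive
#' cancer cells are hit hardest, slow-cycling resistant cells escape
#' part of the kill, and quiescent stem cells are spared entirely.
#' `apoptotic_intensity` multiplies the death probability of every
#' cell in the top-of-crypt zone, whatever its phenotype (the
#' sulindac-like drug induces apoptosis at the crypt/lumen interface
#' and shrinks the crypt from the top). Inactive doses are encoded as
#' factor 1. The result is clamped to `[0, 1]`.
#'
#' With both factors at 1 the probability reduces to the positional
#' baseline times the phenotype multiplier, so the no-drug death ratio
#' of a cancer (resistant) cell to a normal cell at the same height is
#' exactly 1.10 (1.05).
#'
#' @inheritParams divide_probability
#' @param lethality Cytotoxic factor (>= 0); 1 when no cytotoxic dose is
#'   active.
#' @param apoptotic_intensity Apoptotic factor (>= 0); 1 when no
#'   apoptotic dose is active.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
die_probability <- function(height_norm, phenotype = "normal",
                            gradients = gradient_params(),
                            lethality = 1, apoptotic_intensity = 1,
                            released = FALSE, compartment = NULL) {
  if (lethality < 0 || apoptotic_intensity < 0)
    stop("drug intensity factors must be non-negative")
  n <- length(height_norm)
  phenotype <- rep_len(phenotype, n)
  if (is.null(compartment))
    compartment <- cell_compartment(height_norm, phenotype, gradients, released)
  mult <- .phenotypes$die_multiplier[match(phenotype, .phenotypes$label)]
  p <- positional_die(height_norm, gradients) * mult
  if (lethality != 1) {
    tgt <- compartment == "proliferating"
    posfrac <- positional_divide(height_norm, gradients) /
      gradients$divide_max
    dmult <- .phenotypes$divide_multiplier[match(phenotype,
                                                 .phenotypes$label)]
    cycling <- dmult * (0.5 + 0.5 * posfrac)
    # additive drug channel: identity at L = 1, continuous and
    # monotone in L, with no sanctuary anywhere in the crypt; the
    # basal floor keeps deep and high cancer cells exposed while the
    # positional part still concentrates the kill on the zone of
    # active division
    p[tgt] <- p[tgt] +
      gradients$cytotoxic_gain * (lethality - 1) * cycling[tgt]^2
  }
  if (apoptotic_intensity != 1) {
    top <- height_norm > 1 - gradients$top_fraction
    p[top] <- p[top] * apoptotic_intensity
  }
  pmin(1, pmax(0, p))
}

# --- crypt state --------------------------------------------------------

#' Initialize a homeostatic crypt
#'
#' Populates the crypt to its homeostatic target with normal-phenotype
#' cells stacked from the base of each column, and attaches an
#' independent seeded RNG stream that all subsequent stochastic updates
#' of this crypt consume. Identical seeds reproduce identical
#' trajectories.
#'
#' @param geometry A [crypt_geometry()] object.
#' @param gradients A [gradient_params()] object.
#' @param seed Integer seed for this crypt's private RNG stream.
#' @param tag_lineages Logical; if `TRUE` every initial cell receives a
#'   distinct lineage tag (for neutral-drift / monoclonal-conversion
#'   studies). Daughters inherit the parental tag.
#' @return An object of class `crypt_state`.
#' @export
init_crypt <- function(geometry = crypt_geometry(),
                       gradients = gradient_params(),
                       seed = 1L, tag_lineages = FALSE) {
  C <- geometry$circumference
  target <- geometry$homeostatic_target
  per <- target %/% C
  extra <- target %% C
  counts <- rep(per, C) + c(rep(1L, extra), rep(0L, C - extra))
  col <- rep.int(seq_len(C), counts)
  ring <- sequence(counts)
  n <- length(col)
  crypt <- structure(
    list(geometry = geometry, gradients = gradients,
         col = as.integer(col), ring = as.integer(ring),
         phen = rep(1L, n),
         lineage = if (tag_lineages) seq_len(n) else rep(1L, n),
         step_index = 0L,
         last_events = c(births = 0L, deaths = 0L, removals = 0L),
         rng_state = .capture_seed_state(seed),
         seed = as.integer(seed)),
    class = "crypt_state")
  crypt
}

#' @export
print.crypt_state <- function(x, ...) {
  cen <- census(x)
  cat("<crypt_state> step", x$step_index, "-", cen$total, "cells (",
      sprintf("%.1f%%", 100 * cen$total / x$geometry$capacity),
      "of capacity ), cancer fraction",
      sprintf("%.3f", cen$cancer_fraction), "\n")
  invisible(x)
}

.height_norm <- function(crypt) {
  (crypt$ring - 1) / (crypt$geometry$height - 1)
}

#' Advance the crypt by one 4-hour step
#'
#' Applies, in order: death draws for every cell, division draws for the
#' survivors (daughters are placed directly above their parent, pushing
#' the cells above up by one ring), downward compaction of each column
#' stack, and removal of cells pushed past the top ring into the lumen.
#' Drug factors of 1 denote inactive doses. An emptied crypt is a legal
#' (extinguished) state.
#'
#' @param crypt A `crypt_state`.
#' @param lethality Cytotoxic factor applied this step (1 = inactive).
#' @param apoptotic_intensity Apoptotic factor applied this step
#'   (1 = inactive).
#' @return The successor `crypt_state`; `last_events` records the
#'   births, deaths and top removals of the step.
#' @export
step_crypt <- function(crypt, lethality = 1, apoptotic_intensity = 1) {
  if (lethality < 0 || apoptotic_intensity < 0)
    stop("drug intensity factors must be non-negative")
  n <- length(crypt$col)
  if (n == 0L) {
    crypt$step_index <- crypt$step_index + 1L
    crypt$last_events <- c(births = 0L, deaths = 0L, removals = 0L)
    return(crypt)
  }
  geom <- crypt$geometry
  grad <- crypt$gradients
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  assign(".Random.seed", crypt$rng_state, envir = globalenv())

  h <- .height_norm(crypt)
  phen_lab <- .phen_label[crypt$phen]
  released <- n < 0.9 * geom$homeostatic_target
  comp <- cell_compartment(h, phen_lab, grad, released)

  pdie <- die_probability(h, phen_lab, grad, lethality, apoptotic_intensity,
                          released, compartment = comp)
  dead <- stats::runif(n) < pdie

  pdiv <- divide_probability(h, phen_lab, grad, released, compartment = comp)
  divides <- stats::runif(n) < pdiv
  divides[dead] <- FALSE

  keep <- which(!dead)
  parents <- keep[divides[keep]]
  nb <- length(parents)
  # daughters are placed just above the parent's ring, in the parent's own
  # or an adjacent column (circumferential neighbor, wrapped)
  dcol <- crypt$col[parents] +
    if (nb) sample(c(-1L, 0L, 1L), nb, replace = TRUE) else integer(0)
  dcol <- ((dcol - 1L) %% geom$circumference) + 1L
  allcol <- c(crypt$col[keep], dcol)
  allkey <- c(as.numeric(crypt$ring[keep]), crypt$ring[parents] + 0.5)
  src <- c(keep, parents)
  isparent <- c(divides[keep], rep(FALSE, nb))

  # niche rings: bulk compaction never crosses the niche boundary from
  # above; a stem vacancy is instead refilled by niche succession -- the
  # lowest cell above the boundary drops in, at most one per column per
  # step -- so niche occupancy turns over slowly and competitively
  k_niche <- floor(grad$niche_fraction * (geom$height - 1)) + 1L
  in_niche <- allkey <= k_niche
  ord <- order(allcol, !in_niche, allkey)
  colo <- allcol[ord]
  nicheo <- in_niche[ord]
  cnt_niche <- tabulate(colo[nicheo], nbins = geom$circumference)
  cnt_upper <- tabulate(colo[!nicheo], nbins = geom$circumference)
  ring2 <- integer(length(colo))
  ring2[nicheo] <- sequence(cnt_niche)
  succ <- as.integer(cnt_niche < k_niche)   # one succession slot if vacant
  col_u <- colo[!nicheo]
  pos_u <- sequence(cnt_upper)
  ring2[!nicheo] <- ifelse(
    pos_u <= succ[col_u],
    cnt_niche[col_u] + pos_u,
    pmax(cnt_niche, k_niche)[col_u] + pos_u - succ[col_u])
  inside <- ring2 <= geom$height

  births <- nb
  deaths <- n - length(keep)
  removals <- sum(!inside)

  src <- src[ord][inside]
  crypt$col <- colo[inside]
  crypt$ring <- as.integer(ring2[inside])
  crypt$phen <- crypt$phen[src]
  crypt$lineage <- crypt$lineage[src]
  crypt$divided_last_step <- isparent[ord][inside]
  crypt$step_index <- crypt$step_index + 1L
  crypt$last_events <- c(births = as.integer(births),
                         deaths = as.integer(deaths),
                         removals = as.integer(removals))
  crypt$rng_state <- get(".Random.seed", envir = globalenv())
  crypt
}

#' Seed mutant cancer cells into the crypt
#'
#' Converts `n` proliferating cells to the given cancer phenotype. The
#' seeding position may be the crypt bottom (the lowest proliferating
#' cells), the lower third, or the top third. If `at_step` is given and
#' does not equal the crypt's current step, the crypt is returned
#' unchanged; the trial runner uses this to schedule mutation at a fixed
#' protocol step.
#'
#' @param crypt A `crypt_state`.
#' @param phenotype `"cancer"` (drug-sensitive) or `"resistant"`
#'   (multidrug-resistant).
#' @param n Number of proliferating cells to convert.
#' @param position `"lower_third"`, `"bottom"` or `"top_third"`.
#' @param at_step Optional step index at which the mutation applies.
#' @return The updated `crypt_state`.
#' @export
introduce_mutants <- function(crypt, phenotype = c("cancer", "resistant"),
                              n = 1L, position = c("lower_third", "bottom",
                                                   "top_third"),
                              at_step = NULL) {
  phenotype <- match.arg(phenotype)
  position <- match.arg(position)
  if (!is.null(at_step) && crypt$step_index != at_step) return(crypt)
  h <- .height_norm(crypt)
  total <- length(crypt$col)
  released <- total < 0.9 * crypt$geometry$homeostatic_target
  comp <- cell_compartment(h, .phen_label[crypt$phen], crypt$gradients,
                           released)
  eligible <- which(comp == "proliferating")
  if (length(eligible) == 0L) {
    warning("no proliferating cells available; mutation skipped")
    return(crypt)
  }
  zone <- switch(position,
    lower_third = eligible[h[eligible] <= 1 / 3],
    top_third = eligible[h[eligible] > 2 / 3],
    bottom = eligible[order(h[eligible])][seq_len(min(n, length(eligible)))])
  if (length(zone) == 0L) zone <- eligible
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  assign(".Random.seed", crypt$rng_state, envir = globalenv())
  pick <- if (length(zone) <= n) zone else sample(zone, n)
  crypt$phen[pick] <- .phen_code[[phenotype]]
  crypt$rng_state <- get(".Random.seed", envir = globalenv())
  crypt
}

#' Census of the crypt
#'
#' Counts cells per compartment and phenotype, and computes the cancer
#' fraction (cancer plus resistant cells over total; 0 for an empty
#' crypt).
#'
#' @param crypt A `crypt_state`.
#' @return A list with `counts` (a compartment x phenotype data frame),
#'   `total` and `cancer_fraction`.
#' @export
census <- function(crypt) {
  n <- length(crypt$col)
  comps <- c("quiescent_stem", "proliferating", "differentiated")
  if (n == 0L) {
    counts <- as.data.frame(matrix(0L, 3, 3,
      dimnames = list(comps, .phen_label)))
    return(list(counts = counts, total = 0L, cancer_fraction = 0))
  }
  h <- .height_norm(crypt)
  released <- n < 0.9 * crypt$geometry$homeostatic_target
  comp <- cell_compartment(h, .phen_label[crypt$phen], crypt$gradients,
                           released)
  tab <- table(factor(comp, levels = comps),
               factor(.phen_label[crypt$phen], levels = .phen_label))
  counts <- as.data.frame.matrix(tab)
  n_cancer <- sum(crypt$phen != 1L)
  list(counts = counts, total = n, cancer_fraction = n_cancer / n)
}

#' Simulate a crypt trajectory
#'
#' Runs `n_steps` updates, optionally under dose schedules, and records
#' a tidy per-step trajectory (total cells, counts per phenotype and
#' compartment, dose-active flags, per-step event counts).
#'
#' @param crypt A `crypt_state`.
#' @param n_steps Number of steps to simulate.
#' @param cytotoxic,apoptotic Optional [dose_schedule()] objects.
#' @param therapy_start Step index at which both schedules start.
#' @param record Logical; collect the per-step trajectory?
#' @return A list with the final `crypt` and (if recorded) a
#'   `trajectory` data frame.
#' @export
simulate_crypt <- function(crypt, n_steps, cytotoxic = NULL, apoptotic = NULL,
                           therapy_start = 0L, record = TRUE) {
  rows <- if (record) vector("list", n_steps) else NULL
  for (k in seq_len(n_steps)) {
    step <- crypt$step_index
    cy_on <- !is.null(cytotoxic) && is_dose_active(cytotoxic, step, therapy_start)
    ap_on <- !is.null(apoptotic) && is_dose_active(apoptotic, step, therapy_start)
    crypt <- step_crypt(crypt,
                        lethality = if (cy_on) cytotoxic$intensity else 1,
                        apoptotic_intensity = if (ap_on) apoptotic$intensity else 1)
    if (record) {
      ph <- tabulate(crypt$phen, nbins = 3L)
      rows[[k]] <- c(step = crypt$step_index, total = length(crypt$col),
                     normal = ph[1], cancer = ph[2], resistant = ph[3],
                     cyto_active = as.integer(cy_on),
                     apo_active = as.integer(ap_on),
                     crypt$last_events)
    }
  }
  out <- list(crypt = crypt)
  if (record) {
    traj <- as.data.frame(do.call(rbind, rows))
    out$trajectory <- traj
  }
  out
}
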