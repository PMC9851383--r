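#' Crypt geometry
#'
#' Describes the cylindrical cell lattice of one colon crypt: a ring of
#' `circumference` cell columns, each `height` rings tall. The crypt is
#' modeled as a set of per-column cell stacks growing up from the base
#' toward the lumen; `capacity = circumference * height` bounds the total
#' cell count.
#'
#' @param circumference Integer, number of cell columns around the crypt
#'   axis (>= 1).
#' @param height Integer, number of cell rings from crypt base to lumen
#'   (>= 3, so that niche, proliferative and differentiated zones are all
#'   representable).
#' @param homeostatic_target Integer, the long-run mean total cell count
#'   of an untreated crypt under the calibrated gradients.
#' @param min_viable_cells Integer, the smallest crypt size regarded as
#'   biologically viable; apoptotic dosing that shrinks the crypt below
#'   this floor is classified as toxic. The full-size default of 1399
#'   cells is the lowest total measured in human biopsy crypts.
#' @return An object of class `crypt_geometry`.
#' @seealso [gradient_params()], [init_crypt()]
#' @export
crypt_geometry <- function(circumference = 25L, height = 80L,
                           homeostatic_target = 1750L,
                           min_viable_cells = 1399L) {
  circumference <- as.integer(circumference)
  height <- as.integer(height)
  homeostatic_target <- as.integer(homeostatic_target)
  min_viable_cells <- as.integer(min_viable_cells)
  if (circumference < 1L) stop("`circumference` must be >= 1")
  if (height < 3L) stop("`height` must be >= 3")
  if (min_viable_cells > homeostatic_target)
    stop("`min_viable_cells` must not exceed `homeostatic_target`")
  capacity <- circumference * height
  if (capacity < homeostatic_target)
    stop("crypt capacity (", capacity, ") is below `homeostatic_target` (",
         homeostatic_target, ")")
  structure(
    list(circumference = circumference, height = height,
         homeostatic_target = homeostatic_target,
         min_viable_cells = min_viable_cells, capacity = capacity),
    class = "crypt_geometry")
}

#' Positional divide/die gradient parameters
#'
#' Cell fate probabilities depend on normalized height `h` in `[0, 1]`
#' (0 = crypt base, 1 = lumen). Division probability is highest at the
#' base and declines linearly to `divide_min` at the top; death
#' probability rises linearly from `die_min` at the base to `die_max` at
#' the top. The bottom `niche_fraction` of the crypt is the quiescent
#' stem niche: normal cells there do not divide while the crypt is near
#' its homeostatic size, and they are not targeted by cytotoxic dosing.
#' The top `top_fraction` is the differentiated zone, the target of
#' apoptotic (sulindac-like) dosing.
#'
#' @param divide_max Division probability per 4-hour step at the base.
#' @param divide_min Division probability at the top.
#' @param die_max Death probability per step at the top.
#' @param die_min Death probability at the base.
#' @param niche_fraction Fraction of crypt height occupied by the
#'   quiescent stem niche (0 < f < 1).
#' @param top_fraction Fraction of crypt height forming the
#'   differentiated / apoptotic-target zone at the top.
#' @param stem_self_renewal Basal per-step division probability of
#'   quiescent stem cells (default 0: stem divide only when released
#'   from quiescence by crypt depletion; niche attrition is instead
#'   replaced by succession from the boundary).
#' @param cytotoxic_gain Death-probability gain per unit lethality
#'   above 1, for a maximally cycling cell during an active cytotoxic
#'   dose. The cytotoxic drug adds to the positional death probability
#'   rather than multiplying it, so no crypt position is a sanctuary;
#'   the added term scales with the square of the cell's cycling
#'   activity (S-phase specificity).
#' @return An object of class `gradient_params`.
#' @export
gradient_params <- function(divide_max = 0.2, divide_min = 0,
                            die_max = 0.20, die_min = 0.005,
                            niche_fraction = 0.1, top_fraction = 1 / 3,
                            stem_self_renewal = 0, cytotoxic_gain = 0.06) {
  probs <- c(divide_max, divide_min, die_max, die_min)
  if (any(probs < 0 | probs > 1))
    stop("all gradient probabilities must lie in [0, 1]")
  if (divide_max < divide_min) stop("`divide_max` must be >= `divide_min`")
  if (die_max < die_min) stop("`die_max` must be >= `die_min`")
  if (niche_fraction <= 0 || niche_fraction >= 1)
    stop("`niche_fraction` must be in (0, 1)")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("`top_fraction` must be in (0, 1)")
  if (niche_fraction + top_fraction >= 1)
    stop("niche and differentiated zones must leave room for a proliferative zone")
  if (stem_self_renewal < 0 || stem_self_renewal > 1)
    stop("`stem_self_renewal` must be in [0, 1]")
  if (cytotoxic_gain < 0 || cytotoxic_gain > 1)
    stop("`cytotoxic_gain` must be in [0, 1]")
  structure(
    list(divide_max = divide_max, divide_min = divide_min,
         die_max = die_max, die_min = die_min,
         niche_fraction = niche_fraction, top_fraction = top_fraction,
         stem_self_renewal = stem_self_renewal,
         cytotoxic_gain = cytotoxic_gain),
    class = "gradient_params")
}

# Phenotype kinetic multipliers, relative to a normal cell at the same
# crypt position: sensitive cancer cells divide 1.16x and die 1.10x,
# relatively drug-resistant cancer cells divide 1.08x and die 1.05x.
.phenotypes <- data.frame(
  label = c("normal", "cancer", "resistant"),
  divide_multiplier = c(1.00, 1.16, 1.08),
  die_multiplier = c(1.00, 1.10, 1.05),
  stringsAsFactors = FALSE
)

#' Cell phenotype kinetics
#'
#' Returns the kinetic multipliers a phenotype applies to the positional
#' divide and die probabilities. `cancer` models a drug-sensitive,
#' fast-cycling cancer cell; `resistant` a multidrug-resistant cancer
#' cell whose slower kinetics let it escape drugs that preferentially
#' remove fast-cycling cells.
#'
#' @param label One of `"normal"`, `"cancer"`, `"resistant"`.
#' @return A list with `label`, `divide_multiplier`, `die_multiplier`.
#' @export
cell_phenotype <- function(label = c("normal", "cancer", "resistant")) {
  label <- match.arg(label)
  row <- .phenotypes[.phenotypes$label == label, ]
  list(label = label,
       divide_multiplier = row$divide_multiplier,
       die_multiplier = row$die_multiplier)
}

# integer phenotype codes used in the crypt state vectors
.phen_code <- c(normal = 1L, cancer = 2L, resistant = 3L)
.phen_label <- names(.phen_code)
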