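# Surrogate toxicity classifier and the uncertainty-sampling loop.
#
# Labeling every combination schedule by simulation is intractable; a
# probabilistic classifier is trained on a seeded sample, the schedules
# whose predicted toxicity probability is closest to 0.5 are labeled
# next, and the loop stops once held-out sensitivity and specificity
# both exceed their thresholds.

#' Train the surrogate toxicity classifier
#'
#' Fits a single-hidden-layer feed-forward neural network (with a
#' logistic-regression fallback if the network fails to converge) on
#' standardized 6-vector schedule features. Deterministic for a fixed
#' seed.
#'
#' @param features Numeric matrix (rows = schedules, 6 columns:
#'   cytotoxic duration/interval/intensity, apoptotic
#'   duration/interval/intensity; any fixed feature set is accepted).
#' @param labels Factor or character vector with levels `"nontoxic"`
#'   and `"toxic"`; both classes must be present.
#' @param seed Integer seed for weight initialization.
#' @param size Hidden units.
#' @param decay Weight decay.
#' @param maxit Training iterations.
#' @return An object of class `surrogate_model`.
#' @export
train_surrogate <- function(features, labels, seed = 1L, size = 16L,
                            decay = 1e-4, maxit = 500L) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("nontoxic", "toxic"))
  if (anyNA(labels)) stop("labels must be 'nontoxic' or 'toxic'")
  if (nlevels(droplevels(labels)) < 2L)
    stop("both toxicity classes must be present in the training data")
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  std <- sweep(sweep(features, 2, center), 2, scale, "/")
  y <- as.integer(labels == "toxic")
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  set.seed(as.integer(seed))
  fit <- tryCatch(
    nnet::nnet(std, y, size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- stats::glm.fit(cbind(1, std), y,
                          family = stats::binomial())
  structure(list(fit = fit, center = center, scale = scale,
                 is_nnet = inherits(fit, "nnet")),
            class = "surrogate_model")
}

#' Predicted probability of toxicity
#'
#' @param model A `surrogate_model`.
#' @param features Numeric matrix of schedule features.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_toxicity <- function(model, features) {
  features <- as.matrix(features)
  std <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  if (model$is_nnet) {
    p <- as.numeric(stats::predict(model$fit, std))
  } else {
    beta <- model$fit$coefficients
    beta[is.na(beta)] <- 0
    eta <- drop(cbind(1, std) %*% beta)
    p <- stats::plogis(eta)
  }
  pmin(1, pmax(0, p))
}

#' Select the most uncertain schedules
#'
#' Returns the indices of the `batch` pool schedules whose predicted
#' toxicity probability is closest to 0.5, ties broken by enumeration
#' order.
#'
#' @param model A `surrogate_model`.
#' @param pool Numeric matrix of candidate features.
#' @param batch Number of schedules to select (<= pool size).
#' @return Integer vector of row indices into `pool`.
#' @export
select_uncertain <- function(model, pool, batch) {
  pool <- as.matrix(pool)
  if (nrow(pool) == 0L) stop("`pool` must be non-empty")
  if (batch > nrow(pool)) stop("`batch` exceeds the pool size")
  p <- predict_toxicity(model, pool)
  ord <- order(abs(p - 0.5), seq_along(p))
  ord[seq_len(batch)]
}

#' Held-out sensitivity and specificity
#'
#' Sensitivity is the percentage of toxic schedules predicted toxic,
#' specificity the percentage of nontoxic schedules predicted nontoxic,
#' at the 0.5 probability threshold.
#'
#' @param model A `surrogate_model`.
#' @param features Numeric matrix of evaluation features.
#' @param labels Labels (`"nontoxic"`/`"toxic"`); both classes must be
#'   present.
#' @return Named numeric vector `c(sensitivity, specificity)` in
#'   percent.
#' @export
evaluate_sens_spec <- function(model, features, labels) {
  labels <- factor(as.character(labels), levels = c("nontoxic", "toxic"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("evaluation set must contain both classes")
  pred <- predict_toxicity(model, features) >= 0.5
  truth <- labels == "toxic"
  c(sensitivity = 100 * sum(pred & truth) / sum(truth),
    specificity = 100 * sum(!pred & !truth) / sum(!truth))
}

#' Active-learning loop over a schedule space
#'
#' Iterates: train the surrogate on all labeled schedules, predict over
#' the full space, label the `batch_size` most uncertain unlabeled
#' schedules with the oracle, and repeat until both held-out
#' sensitivity and specificity exceed their thresholds (or the
#' iteration cap is reached). A stratified fraction of the initial
#' seed sample is diverted to a fixed held-out evaluation set and never
#' used for training. No schedule is labeled twice, so the number of
#' labeled schedules after k iterations is exactly
#' `seed_size + k * batch_size`.
#'
#' @param space Numeric matrix of features for the full enumerated
#'   schedule space.
#' @param oracle Function mapping a feature matrix to labels
#'   (`"toxic"`/`"nontoxic"`); in production this runs the replicate
#'   simulations and [classify_toxic()], in tests a cheap deterministic
#'   boundary.
#' @param seed_size Size of the initial random labeled sample.
#' @param batch_size Schedules labeled per iteration.
#' @param stop_sens,stop_spec Stopping thresholds in percent (strict
#'   inequalities, as in "exceeded 99%").
#' @param max_iter Iteration cap guaranteeing termination.
#' @param eval_fraction Fraction of the initial seed sample held out
#'   for evaluation (stratified by class). The evaluation set is fixed
#'   at initialization and drawn uniformly from the space, so the
#'   stopping metrics estimate space-wide generalization rather than
#'   accuracy on the deliberately hard uncertainty-sampled batches.
#' @param seed Master seed for sampling, training and stratification.
#' @return A list of class `al_result`: `model`, `history` (one row per
#'   iteration: labeled count, sensitivity, specificity), `converged`,
#'   `n_labeled`, `labeled_idx`, `eval_idx`, and `nontoxic_idx` (row
#'   indices of `space` predicted nontoxic by the final model, for
#'   downstream execution).
#' @export
run_active_learning <- function(space, oracle, seed_size = 100000L,
                                batch_size = 10000L, stop_sens = 99,
                                stop_spec = 99, max_iter = 50L,
                                eval_fraction = 0.1, seed = 1L) {
  space <- as.matrix(space)
  n <- nrow(space)
  if (seed_size > n) stop("`seed_size` exceeds the space")
  old <- .save_ambient_seed()
  on.exit(.restore_ambient_seed(old))
  set.seed(as.integer(seed))

  labeled_idx <- sample.int(n, seed_size)
  labels <- character(0)
  eval_flag <- logical(0)

  label_batch <- function(idx, hold_out) {
    new_labels <- as.character(oracle(space[idx, , drop = FALSE]))
    if (!all(new_labels %in% c("toxic", "nontoxic")))
      stop("oracle must return 'toxic' or 'nontoxic' labels")
    flag <- logical(length(idx))
    if (hold_out) {
      # stratified held-out assignment, fixed at initialization
      for (cl in unique(new_labels)) {
        members <- which(new_labels == cl)
        k <- round(eval_fraction * length(members))
        if (k > 0) flag[sample(members, k)] <- TRUE
      }
    }
    list(labels = new_labels, eval = flag)
  }

  first <- label_batch(labeled_idx, hold_out = TRUE)
  labels <- first$labels
  eval_flag <- first$eval
  if (length(unique(labels)) < 2L)
    stop("initial sample contains a single toxicity class; ",
         "enlarge `seed_size` or check the oracle")

  history <- list()
  converged <- FALSE
  model <- NULL
  for (it in seq_len(max_iter)) {
    train <- !eval_flag
    model <- train_surrogate(space[labeled_idx[train], , drop = FALSE],
                             labels[train], seed = seed + it)
    metrics <- evaluate_sens_spec(model,
                                  space[labeled_idx[eval_flag], ,
                                        drop = FALSE],
                                  labels[eval_flag])
    history[[it]] <- data.frame(iteration = it,
                                n_labeled = length(labeled_idx),
                                sensitivity = metrics[["sensitivity"]],
                                specificity = metrics[["specificity"]])
    if (metrics[["sensitivity"]] > stop_sens &&
        metrics[["specificity"]] > stop_spec) {
      converged <- TRUE
      break
    }
    pool_idx <- setdiff(seq_len(n), labeled_idx)
    if (length(pool_idx) == 0L) break
    b <- min(batch_size, length(pool_idx))
    pick <- pool_idx[select_uncertain(model,
                                      space[pool_idx, , drop = FALSE], b)]
    newly <- label_batch(pick, hold_out = FALSE)
    labeled_idx <- c(labeled_idx, pick)
    labels <- c(labels, newly$labels)
    eval_flag <- c(eval_flag, newly$eval)
  }
  p_space <- predict_toxicity(model, space)
  structure(list(model = model,
                 history = do.call(rbind, history),
                 converged = converged,
                 n_labeled = length(labeled_idx),
                 labeled_idx = labeled_idx,
                 eval_idx = labeled_idx[eval_flag],
                 nontoxic_idx = which(p_space < 0.5)),
            class = "al_result")
}

#' Toy combination-schedule space and toxicity oracle
#'
#' A fully enumerable stand-in for the combination-schedule space, used
#' to exercise the active-learning loop at desk scale: a seeded uniform
#' sample of combination schedules from reduced grids, with a smooth
#' deterministic toxicity boundary based on the delivered dose rate
#' (intensity x duration / interval) of the two drugs.
#'
#' @param n Number of schedules in the toy space.
#' @param seed Integer seed.
#' @return A list with `features` (n x 6 matrix) and `oracle`
#'   (a labeling function as required by [run_active_learning()]).
#' @export
toy_schedule_space <- function(n = 10000L, seed = 1L) {
  cyto <- grid_spec(durations = 1:16, intervals = seq(2L, 48L, 2L),
                    intensities = seq(0.5, 20, 0.5))
  apo <- grid_spec(durations = 1:16, intervals = seq(2L, 48L, 2L),
                   intensities = seq(0.5, 20, 0.5))
  df <- enumerate_combination_grid(cyto, apo, sample_n = n, seed = seed)
  features <- as.matrix(df)
  oracle <- function(f) {
    burden <- f[, "cyto_intensity"] * f[, "cyto_duration"] /
      f[, "cyto_interval"] +
      0.5 * f[, "apo_intensity"] * f[, "apo_duration"] / f[, "apo_interval"]
    ifelse(burden > 2, "toxic", "nontoxic")
  }
  list(features = features, oracle = oracle)
}
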