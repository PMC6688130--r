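## Cascaded fusion architectures.
##
## Four ways of combining the seven (task, mode) feature vectors into one
## session-level MCI probability:
##   feature_fusion -- early fusion: all vectors concatenated (116 features
##     at the default question count), one classifier;
##   mode_fusion    -- one classifier per (task, mode); the seven probability
##     scores are averaged;
##   task_fusion    -- mode-level scores feed per-task classifiers; the three
##     task scores are averaged;
##   session_fusion -- the task scores additionally feed one top classifier.
##
## Upper-level classifiers are trained on out-of-fold lower-level scores
## (seeded stratified k-fold stacking); training them on in-sample scores
## would let the meta-level overfit the lower levels' training optimism. An
## in-sample mode is retained for comparison.

CASCADE_ARCHITECTURES <- c("feature_fusion", "mode_fusion", "task_fusion",
                           "session_fusion")

#' Cascade configuration
#'
#' @param architecture One of `"feature_fusion"`, `"mode_fusion"`,
#'   `"task_fusion"`, `"session_fusion"`.
#' @param base A [base_classifier_spec()]; the same specification (including
#'   the regularization strength) is used by every component classifier.
#' @param stacking_folds Internal stratified folds used to generate
#'   out-of-fold lower-level scores for training upper levels (default 5).
#' @param seed Integer seed controlling all internal randomness.
#' @param threshold Classification threshold on the session probability
#'   (default 0.5; a probability equal to the threshold is called MCI).
#' @param stacking `"out_of_fold"` (default) or `"in_sample"` meta-features.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(architecture = "task_fusion",
                           base = base_classifier_spec(),
                           stacking_folds = 5L, seed = 1L, threshold = 0.5,
                           stacking = c("out_of_fold", "in_sample")) {
  architecture <- match.arg(architecture, CASCADE_ARCHITECTURES)
  stacking <- match.arg(stacking)
  stopifnot(inherits(base, "base_classifier_spec"),
            stacking_folds >= 2, threshold >= 0, threshold <= 1)
  structure(list(architecture = architecture, base = base,
                 stacking_folds = as.integer(stacking_folds),
                 seed = as.integer(seed), threshold = threshold,
                 stacking = stacking),
            class = "cascade_config")
}

task_of_slot <- function(slot_ids)
  vapply(strsplit(slot_ids, ".", fixed = TRUE), `[`, character(1), 1L)

# out-of-fold score matrix over a list of design matrices; in-sample scores
# when requested or when a class is too small to stratify (the logistic
# family runs the per-fold impute/standardize/fit/score loop in compiled
# code, with semantics identical to the generic path)
oof_scores <- function(x_list, y, config, seed) {
  n <- length(y)
  m <- length(x_list)
  scores <- matrix(NA_real_, n, m)
  folds <- if (config$stacking == "out_of_fold")
    stratified_folds(y, config$stacking_folds, seed) else NULL
  if (is.null(folds)) {
    for (j in seq_len(m)) {
      fit <- fit_base(x_list[[j]], y, config$base, seed)
      scores[, j] <- predict_base(fit, x_list[[j]])
    }
  } else if (config$base$family == "logistic") {
    for (j in seq_len(m))
      scores[, j] <- .ridge_logistic_oof_cpp(x_list[[j]], as.numeric(y),
                                             as.integer(folds),
                                             1 / config$base$C)
  } else {
    for (f in sort(unique(folds))) {
      tr <- folds != f
      for (j in seq_len(m)) {
        fit <- fit_base(x_list[[j]][tr, , drop = FALSE], y[tr], config$base,
                        seed)
        scores[!tr, j] <- predict_base(fit, x_list[[j]][!tr, , drop = FALSE])
      }
    }
  }
  scores
}

# cascade fit on pre-assembled design matrices (list keyed by slot id)
fit_cascade_matrices <- function(mats, y, config) {
  if (length(unique(y[!is.na(y)])) < 2)
    stop("cascade fitting needs at least one participant per class",
         call. = FALSE)
  slots <- names(mats)
  tasks <- task_of_slot(slots)
  base_fit <- function(x, yy, seed) fit_base(x, yy, config$base, seed)
  model <- list(config = config, slots = slots, tasks = tasks)

  if (config$architecture == "feature_fusion") {
    xall <- do.call(cbind, lapply(mats, `[[`, "x"))
    model$feature_model <- base_fit(xall, y, derive_seed(config$seed, 1L))
    class(model) <- "fitted_cascade"
    return(model)
  }

  x_list <- lapply(mats, `[[`, "x")
  model$mode_models <- lapply(seq_along(slots), function(j)
    base_fit(x_list[[j]], y, derive_seed(config$seed, 10L + j)))
  names(model$mode_models) <- slots

  if (config$architecture %in% c("task_fusion", "session_fusion")) {
    mode_oof <- oof_scores(x_list, y, config, derive_seed(config$seed, 2L))
    colnames(mode_oof) <- slots
    task_x <- lapply(task_kinds(), function(tk)
      mode_oof[, tasks == tk, drop = FALSE])
    names(task_x) <- task_kinds()
    model$task_models <- lapply(seq_along(task_x), function(j)
      base_fit(task_x[[j]], y, derive_seed(config$seed, 20L + j)))
    names(model$task_models) <- task_kinds()

    if (config$architecture == "session_fusion") {
      task_oof <- oof_scores(task_x, y, config, derive_seed(config$seed, 3L))
      colnames(task_oof) <- task_kinds()
      model$session_model <- base_fit(task_oof, y,
                                      derive_seed(config$seed, 30L))
    }
  }
  class(model) <- "fitted_cascade"
  model
}

# score a list of design matrices (same slots as training); returns
# mode (n x 7), task (n x 3) and session (n) probabilities as available
predict_cascade_matrices <- function(model, mats) {
  slots <- model$slots
  tasks <- model$tasks
  arch <- model$config$architecture
  n <- nrow(mats[[1]]$x)
  out <- list()
  if (arch == "feature_fusion") {
    xall <- do.call(cbind, lapply(mats, `[[`, "x"))
    out$session <- predict_base(model$feature_model, xall)
    return(out)
  }
  mode_scores <- vapply(slots, function(s)
    predict_base(model$mode_models[[s]], mats[[s]]$x), numeric(n))
  mode_scores <- matrix(mode_scores, nrow = n,
                        dimnames = list(NULL, slots))
  out$mode <- mode_scores
  if (arch == "mode_fusion") {
    out$task <- vapply(task_kinds(), function(tk)
      rowMeans(mode_scores[, tasks == tk, drop = FALSE]), numeric(n))
    out$task <- matrix(out$task, nrow = n, dimnames = list(NULL, task_kinds()))
    out$session <- rowMeans(mode_scores)
    return(out)
  }
  task_scores <- vapply(task_kinds(), function(tk)
    predict_base(model$task_models[[tk]],
                 mode_scores[, tasks == tk, drop = FALSE]), numeric(n))
  task_scores <- matrix(task_scores, nrow = n,
                        dimnames = list(NULL, task_kinds()))
  out$task <- task_scores
  out$session <- if (arch == "task_fusion") rowMeans(task_scores)
                 else predict_base(model$session_model, task_scores)
  out
}

#' Fit a cascaded classifier on a cohort
#'
#' Assembles the seven (task, mode) design matrices and fits the requested
#' fusion architecture. Features must have been extracted with
#' [extract_features()].
#'
#' @param cohort A [cohort_dataset()] with extracted features and at least
#'   one participant per diagnosis class.
#' @param config A [cascade_config()].
#' @return An object of class `fitted_cascade`.
#' @export
fit_cascade <- function(cohort, config = cascade_config()) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            inherits(config, "cascade_config"))
  mats <- assemble_all_matrices(cohort)
  fit_cascade_matrices(mats, cohort_labels(cohort), config)
}

#' @export
print.fitted_cascade <- function(x, ...) {
  cat(sprintf("<fitted_cascade> %s, base=%s (C=%g)\n",
              x$config$architecture, x$config$base$family, x$config$base$C))
  invisible(x)
}

#' Predict the probability tree for one session
#'
#' @param model A `fitted_cascade` from [fit_cascade()].
#' @param session A [session_record()] complete for the model's slots
#'   (features are extracted on the fly if absent).
#' @param lexicon Lexicon used if language features still need extraction.
#' @return An object of class `cascade_prediction` holding the session
#'   probability, per-task and per-(task, mode) probabilities as populated
#'   by the architecture, and the thresholded label.
#' @export
predict_session <- function(model, session, lexicon = default_iu_lexicon()) {
  stopifnot(inherits(model, "fitted_cascade"),
            inherits(session, "session_record"))
  if (length(session$features) == 0)
    session <- extract_features(session, lexicon = lexicon)
  missing <- setdiff(model$slots, names(session$features))
  if (length(missing))
    stop("session is missing slot(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mats <- lapply(setNames(model$slots, model$slots), function(s)
    list(x = matrix(as.numeric(session$features[[s]]), nrow = 1)))
  sc <- predict_cascade_matrices(model, mats)
  structure(list(
    participant_id = session$participant_id,
    architecture = model$config$architecture,
    session_probability = as.numeric(sc$session),
    task_probabilities = if (is.null(sc$task)) NULL else
      setNames(as.numeric(sc$task[1, ]), colnames(sc$task)),
    mode_probabilities = if (is.null(sc$mode)) NULL else
      setNames(as.numeric(sc$mode[1, ]), colnames(sc$mode)),
    threshold = model$config$threshold,
    predicted_label = classify_threshold(as.numeric(sc$session),
                                         model$config$threshold)
  ), class = "cascade_prediction")
}

#' @export
print.cascade_prediction <- function(x, ...) {
  cat(sprintf("<cascade_prediction> %s (%s)\n  p(MCI) = %.3f -> %s (threshold %.2f)\n",
              x$participant_id, x$architecture, x$session_probability,
              x$predicted_label, x$threshold))
  if (!is.null(x$task_probabilities)) {
    cat("  tasks: ",
        paste(sprintf("%s=%.3f", names(x$task_probabilities),
                      x$task_probabilities), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Unweighted average of probability scores
#'
#' The late-fusion voting rule: the fused prediction is the arithmetic mean
#' of the component probability scores.
#'
#' @param scores Non-empty numeric vector of probabilities in `[0, 1]`.
#' @return Single probability.
#' @examples
#' fuse_mean(c(0.2, 0.8))
#' @export
fuse_mean <- function(scores) {
  if (length(scores) == 0)
    stop("fuse_mean needs at least one score", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("scores must be probabilities in [0, 1]", call. = FALSE)
  mean(scores)
}

#' Threshold a probability into a diagnosis label
#'
#' MCI if the probability is greater than or equal to the threshold
#' (ties favor sensitivity), HC otherwise.
#'
#' @param probability,threshold Probabilities in `[0, 1]`.
#' @return Character vector of `"MCI"` / `"HC"`.
#' @export
classify_threshold <- function(probability, threshold = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1),
            threshold >= 0, threshold <= 1)
  ifelse(probability >= threshold, "MCI", "HC")
}
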