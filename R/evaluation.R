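## Leave-pair-out cross-validation (LPO-CV) and evaluation metrics.
##
## Every possible (MCI, HC) participant pair is held out once; the model is
## refit on the remainder and scores the pair. AUC is the mean over folds of
## the concordance indicator (1 if the MCI member outscores the HC member,
## 0.5 on ties, else 0), an unbiased AUC estimate for small samples; its
## dispersion is the standard deviation of the per-fold indicators.

#' Enumerate leave-pair-out folds
#'
#' @param labels Named 0/1 vector (names = participant ids, 1 = MCI).
#' @return List of folds, each a list with `pos_id`, `neg_id` and
#'   `train_ids`; exactly `n_MCI * n_HC` folds in deterministic (sorted-id)
#'   order. A cohort of exactly one participant per class yields a single
#'   degenerate fold with no training ids, flagged `degenerate = TRUE`.
#' @examples
#' enumerate_lpo_folds(c(a = 1, b = 1, c = 0, d = 0, e = 0))  # 6 folds
#' @export
enumerate_lpo_folds <- function(labels) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be uniquely named by participant id", call. = FALSE)
  pos <- sort(names(labels)[labels == 1])
  neg <- sort(names(labels)[labels == 0])
  if (length(pos) == 0 || length(neg) == 0)
    stop("leave-pair-out requires at least one participant per class",
         call. = FALSE)
  folds <- vector("list", length(pos) * length(neg))
  k <- 0L
  for (p in pos) for (n in neg) {
    k <- k + 1L
    train <- setdiff(names(labels), c(p, n))
    folds[[k]] <- list(pos_id = p, neg_id = n, train_ids = train,
                       degenerate = length(train) == 0)
  }
  folds
}

#' Pairwise concordance AUC
#'
#' Brute-force AUC over all (positive, negative) score pairs: the mean of
#' the indicator that the positive scores higher, counting ties as 0.5.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors for the
#'   positive (MCI) and negative (HC) class.
#' @return AUC in `[0, 1]`.
#' @examples
#' pairwise_auc(c(0.9, 0.7), c(0.2, 0.8))  # 0.75
#' @export
pairwise_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  ind <- outer(scores_pos, scores_neg,
               function(p, n) (p > n) + 0.5 * (p == n))
  mean(ind)
}

concordance_indicator <- function(pos, neg) (pos > neg) + 0.5 * (pos == neg)

#' Aggregate held-out scores per participant
#'
#' Averages the session scores a participant received over all LPO folds in
#' which it was held out, together with their standard deviation -- the
#' per-participant summary used for individual-level plots, threshold
#' shifting and correlation analysis.
#'
#' @param fold_scores Data frame with columns `participant_id` and `score`,
#'   one row per held-out scoring event.
#' @param ids Optional full id vector; an id never held out raises an error.
#' @return Data frame with `participant_id`, `mean_score`, `sd_score`,
#'   `n_folds`.
#' @export
aggregate_participant_scores <- function(fold_scores, ids = NULL) {
  stopifnot(all(c("participant_id", "score") %in% names(fold_scores)))
  sp <- split(fold_scores$score, fold_scores$participant_id)
  out <- data.frame(
    participant_id = names(sp),
    mean_score = vapply(sp, mean, numeric(1)),
    sd_score = vapply(sp, function(s) if (length(s) < 2) 0 else sd(s),
                      numeric(1)),
    n_folds = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(ids)) {
    missing <- setdiff(ids, out$participant_id)
    if (length(missing))
      stop("participant(s) never held out: ", paste(missing, collapse = ", "),
           call. = FALSE)
    out <- out[match(ids, out$participant_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Confusion metrics from aggregated scores
#'
#' @param scores Numeric scores per participant.
#' @param labels 0/1 labels aligned with `scores`.
#' @param threshold Classification threshold; a score `>= threshold` is
#'   called MCI.
#' @return Named vector with `accuracy`, `sensitivity` (true positive rate
#'   over MCI) and `specificity` (true negative rate over HC).
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  called_mci <- scores >= threshold
  tp <- sum(called_mci & labels == 1)
  fn <- sum(!called_mci & labels == 1)
  tn <- sum(!called_mci & labels == 0)
  fp <- sum(called_mci & labels == 0)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

subset_mats <- function(mats, idx) {
  lapply(mats, function(m) list(x = m$x[idx, , drop = FALSE]))
}

# model fitting/scoring dispatch used by run_lpo_evaluation
lpo_model_funs <- function(model, mats, np, config) {
  switch(model,
    cascade = list(
      fit = function(idx, y) fit_cascade_matrices(subset_mats(mats, idx), y,
                                                  config),
      score = function(fit, idx) predict_cascade_matrices(fit,
                                                          subset_mats(mats, idx))
    ),
    neuropsych = list(
      fit = function(idx, y) fit_base(np[idx, , drop = FALSE], y, config$base,
                                      derive_seed(config$seed, 40L)),
      score = function(fit, idx)
        list(session = predict_base(fit, np[idx, , drop = FALSE]))
    ),
    combined = {
      tf_config <- config
      tf_config$architecture <- "task_fusion"
      list(
        fit = function(idx, y) {
          list(cascade = fit_cascade_matrices(subset_mats(mats, idx), y,
                                              tf_config),
               np = fit_base(np[idx, , drop = FALSE], y, config$base,
                             derive_seed(config$seed, 40L)))
        },
        score = function(fit, idx) {
          sc <- predict_cascade_matrices(fit$cascade, subset_mats(mats, idx))
          np_score <- predict_base(fit$np, np[idx, , drop = FALSE])
          votes <- cbind(sc$task, np_score)
          list(session = rowMeans(votes), task = sc$task, mode = sc$mode,
               np = np_score)
        }
      )
    },
    stop("unknown model type: ", model, call. = FALSE))
}

#' Run a leave-pair-out evaluation
#'
#' For every (MCI, HC) pair, refits the model on the remaining participants
#' and scores the held-out pair. Reports the LPO concordance AUC with its
#' per-fold standard deviation; accuracy, sensitivity and specificity are
#' computed from the per-participant fold-averaged scores at the configured
#' threshold (set `per_fold_confusion = TRUE` to count per-fold decisions
#' instead). For cascaded models the per-participant averages of every mode
#' and task probability are also collected, for correlation analysis and
#' explanation reports.
#'
#' @param cohort A [cohort_dataset()] with extracted features.
#' @param config A [cascade_config()].
#' @param model `"cascade"` (the configured architecture), `"neuropsych"`
#'   (flat classifier on the neuropsychological battery) or `"combined"`
#'   (task fusion plus the neuropsychological score as a fourth vote).
#' @param per_fold_confusion Count confusion metrics per fold rather than
#'   from fold-averaged participant scores.
#' @return An object of class `lpo_result`: `auc`, `auc_sd`, `accuracy`,
#'   `sensitivity`, `specificity`, `fold_scores`, `participant_scores`, and
#'   (cascade/combined) `level_scores` -- per-participant mean probabilities
#'   at every mode/task/session level.
#' @export
run_lpo_evaluation <- function(cohort, config = cascade_config(),
                               model = c("cascade", "neuropsych", "combined"),
                               per_fold_confusion = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "cohort_dataset"))
  ids <- cohort_ids(cohort)
  labels <- setNames(cohort_labels(cohort), ids)
  if (anyNA(labels))
    stop("all participants need a diagnosis label for evaluation",
         call. = FALSE)

  mats <- if (model != "neuropsych") assemble_all_matrices(cohort) else NULL
  np <- if (model != "cascade") neuropsych_matrix(cohort) else NULL

  funs <- lpo_model_funs(model, mats, np, config)
  folds <- enumerate_lpo_folds(labels)
  if (any(vapply(folds, `[[`, logical(1), "degenerate")))
    stop("degenerate leave-pair-out fold (empty training set)", call. = FALSE)

  level_names <- c(names(mats), task_kinds(), "session")
  n_levels <- length(level_names)
  level_sum <- matrix(0, length(ids), n_levels,
                      dimnames = list(ids, level_names))
  level_n <- setNames(numeric(length(ids)), ids)

  nf <- length(folds)
  pos_score <- neg_score <- numeric(nf)
  pos_id <- neg_id <- character(nf)
  for (k in seq_len(nf)) {
    fold <- folds[[k]]
    tr_idx <- match(fold$train_ids, ids)
    te_ids <- c(fold$pos_id, fold$neg_id)
    te_idx <- match(te_ids, ids)
    fit <- tryCatch(funs$fit(tr_idx, labels[tr_idx]),
                    error = function(e)
                      stop(sprintf("fold %d (%s vs %s): %s", k, fold$pos_id,
                                   fold$neg_id, conditionMessage(e)),
                           call. = FALSE))
    sc <- funs$score(fit, te_idx)
    pos_id[k] <- fold$pos_id; neg_id[k] <- fold$neg_id
    pos_score[k] <- sc$session[1]; neg_score[k] <- sc$session[2]
    lv <- cbind(if (!is.null(sc$mode)) sc$mode,
                if (!is.null(sc$task)) sc$task,
                session = sc$session)
    present <- match(colnames(lv), level_names)
    level_sum[te_idx, present] <- level_sum[te_idx, present] + lv
    level_n[te_idx] <- level_n[te_idx] + 1
  }

  indicators <- concordance_indicator(pos_score, neg_score)
  fold_scores <- data.frame(
    fold = rep(seq_len(nf), 2L),
    participant_id = c(pos_id, neg_id),
    label = rep(c(1L, 0L), each = nf),
    score = c(pos_score, neg_score),
    stringsAsFactors = FALSE
  )
  participant_scores <- aggregate_participant_scores(fold_scores, ids)
  participant_scores$label <- as.integer(labels[participant_scores$participant_id])

  if (per_fold_confusion) {
    cm <- confusion_metrics(c(pos_score, neg_score),
                            rep(c(1L, 0L), each = nf), config$threshold)
  } else {
    cm <- confusion_metrics(participant_scores$mean_score,
                            participant_scores$label, config$threshold)
  }

  level_scores <- NULL
  if (model != "neuropsych") {
    keep <- colSums(level_sum != 0) > 0 | level_names == "session"
    level_scores <- sweep(level_sum, 1, pmax(level_n, 1), "/")
    level_scores <- level_scores[, keep, drop = FALSE]
  }

  structure(list(
    model = model, architecture = config$architecture,
    base_family = config$base$family, threshold = config$threshold,
    auc = mean(indicators), auc_sd = sd(indicators),
    accuracy = cm[["accuracy"]], sensitivity = cm[["sensitivity"]],
    specificity = cm[["specificity"]],
    n_folds = nf, n_mci = sum(labels == 1), n_hc = sum(labels == 0),
    fold_scores = fold_scores, participant_scores = participant_scores,
    level_scores = level_scores
  ), class = "lpo_result")
}

#' @export
print.lpo_result <- function(x, ...) {
  cat(sprintf("<lpo_result> %s%s, base=%s\n",
              x$model,
              if (x$model == "cascade") paste0("/", x$architecture) else "",
              x$base_family))
  cat(sprintf("  %d folds (%d MCI x %d HC)\n", x$n_folds, x$n_mci, x$n_hc))
  cat(sprintf("  AUC %.3f (sd %.3f)  acc %.3f  sens %.3f  spec %.3f\n",
              x$auc, x$auc_sd, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
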