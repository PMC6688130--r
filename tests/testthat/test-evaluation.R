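test_that("fold enumeration produces n_MCI x n_HC deterministic folds", {
  folds <- enumerate_lpo_folds(c(a = 1, b = 1, c = 0, d = 0, e = 0))
  expect_length(folds, 6)
  expect_identical(folds[[1]]$pos_id, "a")
  expect_identical(folds[[1]]$neg_id, "c")
  expect_identical(sort(c(folds[[1]]$pos_id, folds[[1]]$neg_id,
                          folds[[1]]$train_ids)), c("a", "b", "c", "d", "e"))

  big <- setNames(c(rep(1, 26), rep(0, 29)), sprintf("p%02d", 1:55))
  expect_length(enumerate_lpo_folds(big), 754)

  tiny <- enumerate_lpo_folds(c(x = 1, y = 0))
  expect_length(tiny, 1)
  expect_true(tiny[[1]]$degenerate)
  expect_error(enumerate_lpo_folds(c(x = 1, y = 1)), "per class")
})

test_that("pairwise AUC counts concordant pairs with half-credit ties", {
  expect_equal(pairwise_auc(c(0.9, 0.7), c(0.2, 0.8)), 0.75)
  expect_equal(pairwise_auc(rep(0.5, 4), rep(0.5, 3)), 0.5)
  expect_equal(pairwise_auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_error(pairwise_auc(numeric(0), 1), "non-empty")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(17, {
    pos <- runif(8); neg <- runif(11)
    a0 <- pairwise_auc(pos, neg)
    expect_equal(pairwise_auc(qlogis(pos), qlogis(neg)), a0)
    expect_equal(pairwise_auc(pos^3, neg^3), a0)
    expect_equal(pairwise_auc(5 * pos + 2, 5 * neg + 2), a0)
  })
})

test_that("a frozen scorer makes LPO concordance equal all-pairs AUC", {
  # when per-participant scores do not depend on the training split, the
  # matched-pair mean over the full MCI x HC enumeration is exactly the
  # brute-force pairwise AUC
  withr::with_seed(23, {
    for (rep in 1:20) {
      n_pos <- sample(2:6, 1); n_neg <- sample(2:6, 1)
      labels <- setNames(c(rep(1, n_pos), rep(0, n_neg)),
                         sprintf("s%02d", seq_len(n_pos + n_neg)))
      score <- setNames(runif(length(labels)), names(labels))
      folds <- enumerate_lpo_folds(labels)
      ind <- vapply(folds, function(f)
        mcicascade:::concordance_indicator(score[f$pos_id], score[f$neg_id]),
        numeric(1))
      expect_equal(mean(ind),
                   pairwise_auc(score[labels == 1], score[labels == 0]))
    }
  })
})

test_that("label-independent scores give a null AUC near one half", {
  withr::with_seed(29, {
    aucs <- replicate(50, {
      labels <- setNames(c(rep(1, 30), rep(0, 30)), sprintf("s%02d", 1:60))
      score <- setNames(runif(60), names(labels))
      pairwise_auc(score[labels == 1], score[labels == 0])
    })
    expect_gt(mean(aucs), 0.45)
    expect_lt(mean(aucs), 0.55)
  })
})

test_that("participant aggregation averages held-out scores", {
  fs <- data.frame(participant_id = c("a", "a", "b"),
                   score = c(0.6, 0.8, 0.3))
  agg <- aggregate_participant_scores(fs)
  expect_equal(agg$mean_score[agg$participant_id == "a"], 0.7)
  expect_equal(agg$sd_score[agg$participant_id == "b"], 0)
  expect_error(aggregate_participant_scores(fs, ids = c("a", "b", "zz")),
               "zz")
})

test_that("confusion metrics and the accuracy identity hold", {
  cm <- confusion_metrics(c(0.9, 0.4, 0.2, 0.6), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(cm), c(0.5, 0.5, 0.5))
  expect_equal(confusion_metrics(runif(10), rep(c(1, 0), 5), 0)[["sensitivity"]],
               1.0)
  withr::with_seed(31, {
    scores <- runif(20)
    labels <- rep(c(1, 0), c(8, 12))
    for (t in c(0.2, 0.5, 0.8)) {
      cm <- confusion_metrics(scores, labels, t)
      expect_equal(cm[["accuracy"]],
                   (cm[["sensitivity"]] * 8 + cm[["specificity"]] * 12) / 20)
    }
  })
})

test_that("sensitivity falls and specificity rises along a threshold sweep", {
  withr::with_seed(37, {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
  })
  sweep <- t(vapply(seq(0, 1, by = 0.05), function(t)
    confusion_metrics(scores, labels, t), numeric(3)))
  expect_true(all(diff(sweep[, "sensitivity"]) <= 1e-12))
  expect_true(all(diff(sweep[, "specificity"]) >= -1e-12))
})

test_that("LPO evaluation matches the brute-force enumeration of its folds", {
  coh <- small_cohort(n_hc = 4, n_mci = 3, d = 2, seed = 41)
  res <- run_lpo_evaluation(coh, cascade_config("task_fusion", seed = 41))
  expect_identical(res$n_folds, 12L)
  fs <- res$fold_scores
  pos <- fs[fs$label == 1, ]
  neg <- fs[fs$label == 0, ]
  ind <- vapply(seq_len(res$n_folds), function(k)
    pairwise_auc(pos$score[pos$fold == k], neg$score[neg$fold == k]),
    numeric(1))
  expect_equal(res$auc, mean(ind))
  expect_equal(res$auc_sd, sd(ind))
  # every participant is held out the expected number of times
  expect_true(all(res$participant_scores$n_folds ==
                    ifelse(res$participant_scores$label == 1, 4L, 3L)))
  expect_true(all(res$fold_scores$score >= 0 & res$fold_scores$score <= 1))
})

test_that("a perfectly separating scorer yields AUC 1 with zero spread", {
  labels <- setNames(c(1, 1, 0, 0), c("m1", "m2", "h1", "h2"))
  score <- c(m1 = 0.9, m2 = 0.8, h1 = 0.2, h2 = 0.1)
  folds <- enumerate_lpo_folds(labels)
  ind <- vapply(folds, function(f)
    mcicascade:::concordance_indicator(score[f$pos_id], score[f$neg_id]),
    numeric(1))
  expect_equal(mean(ind), 1.0)
  expect_equal(sd(ind), 0)
})
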