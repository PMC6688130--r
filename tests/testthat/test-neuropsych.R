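test_that("imputation fills with training means and is reusable", {
  m <- matrix(c(10, NA, 14, 5, 7, NA), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  imp <- impute_scores(m)
  expect_equal(imp$scores["b", "t1"], 12)
  expect_equal(imp$scores["c", "t2"], 6)

  complete <- matrix(1:6, ncol = 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(impute_scores(complete)$scores, complete)

  # held-out rows are imputed with the training fold's means, not their own
  m2 <- matrix(c(0, 2, 100, NA), ncol = 1,
               dimnames = list(c("a", "b", "c", "d"), "t1"))
  imp2 <- impute_scores(m2, training_ids = c("a", "b"))
  expect_equal(imp2$scores["d", "t1"], 1)  # mean(0, 2), not mean incl. 100

  all_na <- matrix(c(1, 2, NA, NA), ncol = 2,
                   dimnames = list(c("a", "b"), c("ok", "gone")))
  expect_error(impute_scores(all_na), "gone")
})

test_that("battery metadata marks the timed tests as higher-is-worse", {
  b <- neuropsych_battery()
  expect_identical(nrow(b), 25L)
  timed <- c("tmt_a", "tmt_b", "pasmo", "stroop_1", "stroop_2", "stroop_3",
             "stroop_effect")
  expect_true(all(!b$higher_is_better[b$test %in% timed]))
  expect_true(all(b$higher_is_better[!b$test %in% timed]))
  expect_setdiff <- setdiff(unique(b$domain),
                            c("global", "memory", "language", "attention",
                              "spatial", "executive"))
  expect_length(expect_setdiff, 0)
})

test_that("the neuropsych baseline recovers a strong group signal", {
  coh <- small_cohort(n_hc = 10, n_mci = 10, d = 3, seed = 51)
  fit <- fit_neuropsych_baseline(coh)
  p <- predict_base(fit, mcicascade:::neuropsych_matrix(coh))
  expect_true(all(p >= 0 & p <= 1))
  res <- run_lpo_evaluation(coh, cascade_config("task_fusion", seed = 51),
                            model = "neuropsych")
  expect_gt(res$auc, 0.9)
})

test_that("signed Spearman correlations flip higher-is-better tests", {
  profiles <- data.frame(participant_id = c("a", "b", "c"),
                         tmt_a = c(1, 2, 3),      # higher is worse
                         mmse = c(3, 2, 1))       # higher is better
  lv <- matrix(c(0.1, 0.2, 0.9), 3, 1,
               dimnames = list(c("a", "b", "c"), "session"))
  labels <- c(a = 0, b = 0, c = 1)
  sm <- signed_spearman_matrix(lv, profiles, labels)
  expect_equal(sm$rho["session", "tmt_a"], 1.0)
  expect_false(sm$flipped[["tmt_a"]])
  expect_equal(sm$rho["session", "mmse"], 1.0)  # raw -1, flipped
  expect_true(sm$flipped[["mmse"]])
  expect_identical(rownames(sm$rho), c("session", "diagnosis"))
})

test_that("tied scores use average ranks, checked against a manual oracle", {
  profiles <- data.frame(participant_id = c("a", "b", "c", "d"),
                         tmt_a = c(1, 1, 2, 3))
  lv <- matrix(c(0.2, 0.5, 0.4, 0.9), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), "session"))
  labels <- c(a = 0, b = 0, c = 1, d = 1)
  sm <- signed_spearman_matrix(lv, profiles, labels)
  manual <- cor(rank(c(0.2, 0.5, 0.4, 0.9)), rank(c(1, 1, 2, 3)))
  expect_equal(sm$rho["session", "tmt_a"], manual)
})

test_that("negating a direction flag exactly negates that column", {
  withr::with_seed(61, {
    profiles <- data.frame(participant_id = sprintf("p%d", 1:10),
                           ravlt_total = rnorm(10), tmt_b = rnorm(10))
    lv <- matrix(runif(20), 10, 2,
                 dimnames = list(profiles$participant_id,
                                 c("reading_silent", "session")))
    labels <- setNames(rbinom(10, 1, 0.5), profiles$participant_id)
    labels[1:2] <- c(0, 1)
  })
  battery <- neuropsych_battery()
  sm1 <- signed_spearman_matrix(lv, profiles, labels, battery)
  battery2 <- battery
  battery2$higher_is_better[battery2$test == "ravlt_total"] <-
    !battery2$higher_is_better[battery2$test == "ravlt_total"]
  sm2 <- signed_spearman_matrix(lv, profiles, labels, battery2)
  expect_equal(sm2$rho[, "ravlt_total"], -sm1$rho[, "ravlt_total"])
  expect_equal(sm2$rho[, "tmt_b"], sm1$rho[, "tmt_b"])
})

test_that("constant vectors give masked correlations", {
  profiles <- data.frame(participant_id = c("a", "b", "c"),
                         mmse = c(5, 5, 5))
  lv <- matrix(c(0.1, 0.5, 0.9), 3, 1,
               dimnames = list(c("a", "b", "c"), "session"))
  sm <- signed_spearman_matrix(lv, profiles, c(a = 0, b = 1, c = 1))
  expect_true(is.na(sm$rho["session", "mmse"]))
})

test_that("the combined vote is a four-way unweighted mean", {
  expect_equal(combined_vote(c(0.8, 0.8, 0.8, 0.0)), 0.6)
  expect_equal(combined_vote(rep(0.35, 4)), 0.35)
  expect_equal(combined_vote(c(0.1, 0.4, 0.6, 0.9)),
               fuse_mean(c(0.1, 0.4, 0.6, 0.9)))
  expect_error(combined_vote(c(0.5, 0.5, 0.5)), "four")
  coh <- small_cohort(n_hc = 4, n_mci = 4, d = 2, seed = 71)
  res <- run_lpo_evaluation(coh, cascade_config("task_fusion", seed = 71),
                            model = "combined")
  expect_true(res$auc >= 0 && res$auc <= 1)
})

make_control_stats <- function(mean = 10, sd = 2) {
  b <- neuropsych_battery()
  b <- b[b$domain != "global", ]
  expand.grid(test = b$test, age_group = c("50-64", "65-80"),
              stringsAsFactors = FALSE) |>
    transform(mean = mean, sd = sd)
}

normal_profile <- function() {
  b <- neuropsych_battery()
  b <- b[b$domain != "global", ]
  p <- setNames(rep(10, nrow(b)), b$test)
  c(p, age = 70)
}

test_that("subtype rules follow the impairment-pattern definitions", {
  cs <- make_control_stats()
  p <- normal_profile()

  p1 <- p; p1[["ravlt_delayed"]] <- 10 - 2 * 2  # 2 sd below, memory
  expect_identical(classify_mci_subtype(p1, cs)$label, "aMCI-sd")

  p2 <- p1; p2[["tmt_b"]] <- 10 + 4  # timed test: impaired tail is high
  expect_identical(classify_mci_subtype(p2, cs)$label, "aMCI-md")

  p3 <- p; p3[["silhouettes"]] <- 2; p3[["stroop_3"]] <- 18
  expect_identical(classify_mci_subtype(p3, cs)$label, "naMCI-md")

  p4 <- p; p4[["silhouettes"]] <- 2; p4[["rcf_copy"]] <- 2  # both spatial
  expect_identical(classify_mci_subtype(p4, cs)$label, "naMCI-sd")

  expect_identical(classify_mci_subtype(p, cs)$label, "unclassifiable")

  p5 <- p1; p5[["tmt_b"]] <- NA
  out <- classify_mci_subtype(p5, cs)
  expect_identical(out$label, "unclassifiable")
  expect_match(out$reason, "missing")

  # a high TMT-B alone must not read as impairment on the good side
  p6 <- p; p6[["tmt_b"]] <- 10 - 4
  expect_identical(classify_mci_subtype(p6, cs)$label, "unclassifiable")
})

test_that("control reference statistics stratify by age group", {
  profiles <- data.frame(
    participant_id = sprintf("p%d", 1:6),
    age = c(55, 60, 70, 75, 58, 72),
    ravlt_total = c(50, 54, 40, 44, 999, 999))
  labels <- setNames(c(0, 0, 0, 0, 1, 1), profiles$participant_id)
  cs <- control_reference_stats(profiles, labels)
  young <- cs[cs$test == "ravlt_total" & cs$age_group == "50-64", ]
  old <- cs[cs$test == "ravlt_total" & cs$age_group == "65-80", ]
  expect_equal(young$mean, 52)  # MCI rows (999) never contribute
  expect_equal(old$mean, 42)
  expect_equal(young$sd, sd(c(50, 54)))
})

test_that("every profile receives exactly one subtype label", {
  cs <- make_control_stats()
  valid <- c("aMCI-sd", "aMCI-md", "naMCI-sd", "naMCI-md", "unclassifiable")
  withr::with_seed(81, {
    for (rep in 1:40) {
      p <- normal_profile()
      idx <- sample(seq_len(length(p) - 1), sample(0:4, 1))
      p[idx] <- 10 + sample(c(-5, 5), length(idx), replace = TRUE)
      out <- classify_mci_subtype(p, cs)
      expect_length(out$label, 1)
      expect_true(out$label %in% valid)
    }
  })
})
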