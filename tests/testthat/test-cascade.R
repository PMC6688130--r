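coh <- small_cohort(n_hc = 5, n_mci = 5, d = 2, seed = 31)

test_that("ridge logistic matches the glmnet ridge solution", {
  skip_if_not_installed("glmnet")
  withr::with_seed(1, {
    n <- 40; p <- 6
    x <- matrix(rnorm(n * p), n)
    y <- rbinom(n, 1, plogis(x[, 1] - x[, 2]))
  })
  spec <- base_classifier_spec("logistic", C = 1.0)
  fit <- fit_base(x, y, spec)
  # same objective in glmnet's parameterization: lambda = 1 / (C * n),
  # fitted on the same standardized design
  xs <- fit$pp$x
  g <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                      lambda = 1 / n, standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(fit$beta[-1]), unname(as.numeric(g$beta)),
               tolerance = 1e-5)
  expect_equal(fit$beta[1], unname(g$a0), tolerance = 1e-5)
})

test_that("compiled out-of-fold stacking equals the R fit/predict path", {
  withr::with_seed(3, {
    n <- 30
    x <- matrix(rnorm(n * 5), n)
    x[sample(length(x), 10)] <- NA  # masked-missing entries on both paths
    y <- rep(c(0L, 1L), each = 15)
  })
  folds <- mcicascade:::stratified_folds(y, 5, seed = 7)
  fast <- mcicascade:::.ridge_logistic_oof_cpp(x, as.numeric(y),
                                               as.integer(folds), 1)
  slow <- numeric(n)
  spec <- base_classifier_spec("logistic")
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_base(x[tr, , drop = FALSE], y[tr], spec)
    slow[!tr] <- predict_base(fit, x[!tr, , drop = FALSE])
  }
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("feature fusion concatenates all mode vectors (width 116)", {
  fit <- fit_cascade(coh, cascade_config("feature_fusion", seed = 1))
  expect_length(fit$feature_model$pp$center, 26 + 12 + 22 + 11 + 22 + 11 + 12)
  pr <- predict_session(fit, coh$sessions[[1]])
  expect_true(pr$session_probability >= 0 && pr$session_probability <= 1)
  expect_null(pr$task_probabilities)
})

test_that("mode fusion averages exactly seven mode-level scores", {
  fit <- fit_cascade(coh, cascade_config("mode_fusion", seed = 1))
  expect_length(fit$mode_models, 7)
  pr <- predict_session(fit, coh$sessions[[3]])
  expect_length(pr$mode_probabilities, 7)
  expect_equal(pr$session_probability, fuse_mean(pr$mode_probabilities))
})

test_that("task fusion averages the three task scores and exposes the tree", {
  fit <- fit_cascade(coh, cascade_config("task_fusion", seed = 1))
  pr <- predict_session(fit, coh$sessions[[8]])
  expect_length(pr$task_probabilities, 3)
  expect_length(pr$mode_probabilities, 7)
  expect_equal(pr$session_probability, fuse_mean(pr$task_probabilities))
})

test_that("session fusion adds a top-level classifier over task scores", {
  fit <- fit_cascade(coh, cascade_config("session_fusion", seed = 1))
  expect_s3_class(fit$session_model, "fitted_base")
  pr <- predict_session(fit, coh$sessions[[2]])
  expect_true(all(c(pr$session_probability, pr$task_probabilities,
                    pr$mode_probabilities) >= 0))
  expect_true(all(c(pr$session_probability, pr$task_probabilities,
                    pr$mode_probabilities) <= 1))
})

test_that("cascade fitting is reproducible and rejects single-class cohorts", {
  cfg <- cascade_config("session_fusion", seed = 9)
  f1 <- fit_cascade(coh, cfg)
  f2 <- fit_cascade(coh, cfg)
  p1 <- predict_session(f1, coh$sessions[[1]])
  p2 <- predict_session(f2, coh$sessions[[1]])
  expect_identical(p1$session_probability, p2$session_probability)
  expect_identical(p1$mode_probabilities, p2$mode_probabilities)

  hc_only <- cohort_dataset(coh$sessions[1:5])
  expect_error(fit_cascade(hc_only, cfg), "per class")
})

test_that("missing slots are named at prediction time", {
  fit <- fit_cascade(coh, cascade_config("task_fusion", seed = 1))
  s <- coh$sessions[[1]]
  s$features[["reading_aloud.speech"]] <- NULL
  s$records[["reading_aloud.speech"]] <- NULL
  expect_error(predict_session(fit, s), "reading_aloud.speech")
})

test_that("label symmetry: swapping class coding complements probabilities", {
  withr::with_seed(8, {
    x <- matrix(rnorm(40 * 4), 40)
    y <- rep(c(0L, 1L), 20)
  })
  p <- predict_base(fit_base(x, y, base_classifier_spec("logistic")), x)
  q <- predict_base(fit_base(x, 1L - y, base_classifier_spec("logistic")), x)
  expect_equal(p, 1 - q, tolerance = 1e-6)
  expect_identical(classify_threshold(p, 0.5),
                   ifelse(classify_threshold(1 - p, 1 - 0.5 + 1e-12) == "MCI",
                          "HC", "MCI"))
})

test_that("fuse_mean and threshold classification follow their contracts", {
  expect_equal(fuse_mean(c(0.2, 0.8)), 0.5)
  expect_equal(fuse_mean(1.0), 1.0)
  expect_equal(fuse_mean(c(0.27, 0.86, 0.89)), mean(c(0.27, 0.86, 0.89)))
  expect_equal(fuse_mean(c(0.7, 0.9, 0.2, 0.6, 0.8, 0.5, 0.4)), 4.1 / 7)
  expect_error(fuse_mean(numeric(0)), "at least one")
  expect_error(fuse_mean(c(0.5, 1.2)), "probabilities")

  expect_identical(classify_threshold(0.82, 0.5), "MCI")
  expect_identical(classify_threshold(0.3, 0.5), "HC")
  expect_identical(classify_threshold(0.5, 0.5), "MCI")  # tie -> positive
  # raising the threshold can only flip MCI -> HC
  withr::with_seed(2, p <- runif(50))
  lab1 <- classify_threshold(p, 0.3)
  lab2 <- classify_threshold(p, 0.7)
  expect_false(any(lab1 == "HC" & lab2 == "MCI"))
})

test_that("Platt calibration is a monotone sigmoid with correct asymptotes", {
  dv <- c(-3, -2, -1, 1, 2, 3)
  labels <- c(0, 0, 0, 1, 1, 1)
  cal <- calibrate_probabilities(dv, labels)
  expect_lt(predict(cal, -0.5), 0.5)
  expect_gt(predict(cal, 0.5), 0.5)
  expect_equal(predict(cal, 0), 0.5, tolerance = 1e-6)  # symmetric midpoint
  expect_equal(predict(cal, 1e6), 1, tolerance = 1e-6)
  expect_equal(predict(cal, -1e6), 0, tolerance = 1e-6)
  expect_error(calibrate_probabilities(dv, rep(1, 6)), "both classes")

  withr::with_seed(13, {
    for (rep in 1:100) {
      f <- rnorm(20)
      y <- rbinom(20, 1, plogis(sample(c(-2, 2), 1) * f))
      if (length(unique(y)) < 2) next
      cal <- calibrate_probabilities(f, y)
      fs <- sort(rnorm(15))
      expect_true(!is.unsorted(predict(cal, fs)))
    }
  })
})

test_that("the RBF-SVM family honors the probability contract", {
  cfg <- cascade_config("mode_fusion", base = base_classifier_spec("rbf"),
                        seed = 4)
  fit <- fit_cascade(coh, cfg)
  pr <- predict_session(fit, coh$sessions[[6]])
  expect_true(all(pr$mode_probabilities >= 0 & pr$mode_probabilities <= 1))
  # separable data must be scored on the correct side
  withr::with_seed(21, {
    x <- rbind(matrix(rnorm(60, -2), 15), matrix(rnorm(60, 2), 15))
    y <- rep(c(0L, 1L), each = 15)
  })
  p <- predict_base(fit_base(x, y, base_classifier_spec("rbf")), x)
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})
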