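## Pluggable binary probabilistic base classifier.
##
## Every component classifier in the cascade follows the same contract: it
## is fit on a numeric matrix with 0/1 labels (1 = MCI, the positive class)
## and predicts a probability in [0, 1]. Two families are provided: L2
## regularized logistic regression (linear) and an RBF-kernel SVM whose
## decision values are mapped to probabilities by Platt calibration. The
## regularization strength C is shared across all component classifiers and
## is deliberately not tuned.

#' Base classifier specification
#'
#' @param family `"logistic"` (L2-regularized logistic regression) or
#'   `"rbf"` (support vector machine with radial basis function kernel and
#'   Platt-calibrated probabilities).
#' @param C Regularization strength; the penalty on the summed log-loss is
#'   `1/C` per the usual C parameterization. Default 1.0, used unchanged by
#'   every classifier in a cascade.
#' @param calibration_folds Internal folds used to obtain out-of-fold
#'   decision values for Platt calibration of the SVM family.
#' @return An object of class `base_classifier_spec`.
#' @export
base_classifier_spec <- function(family = c("logistic", "rbf"), C = 1.0,
                                 calibration_folds = 5L) {
  family <- match.arg(family)
  stopifnot(C > 0, calibration_folds >= 2)
  structure(list(family = family, C = C,
                 calibration_folds = as.integer(calibration_folds)),
            class = "base_classifier_spec")
}

# training-mean imputation + z-standardization parameters (hot path:
# vectorized, no apply/sweep)
preprocess_fit <- function(x) {
  n <- nrow(x)
  mu <- .colMeans(x, n, ncol(x), na.rm = TRUE)
  mu[!is.finite(mu)] <- 0  # feature missing for every training row
  if (anyNA(x)) {
    nas <- which(is.na(x))
    x[nas] <- mu[((nas - 1L) %/% n) + 1L]
  }
  center <- .colMeans(x, n, ncol(x))
  v <- (.colSums(x * x, n, ncol(x)) - n * center^2) / max(n - 1, 1)
  scl <- sqrt(pmax(v, 0))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- (x - rep(center, each = n)) / rep(scl, each = n)
  list(x = xs, impute = mu, center = center, scale = scl)
}

preprocess_apply <- function(x, pp) {
  n <- nrow(x)
  if (anyNA(x)) {
    nas <- which(is.na(x))
    x[nas] <- pp$impute[((nas - 1L) %/% n) + 1L]
  }
  (x - rep(pp$center, each = n)) / rep(pp$scale, each = n)
}

#' Fit a base classifier
#'
#' Features are imputed with training means (explicitly-masked missing
#' values only), z-standardized with training statistics, and passed to the
#' requested model family. For the SVM family, Platt calibration is fitted
#' on out-of-fold decision values within the training split.
#'
#' @param x Numeric matrix (rows = participants), `NA` allowed.
#' @param y 0/1 labels; both classes must be present.
#' @param spec A [base_classifier_spec()].
#' @param seed Seed for the internal calibration folds.
#' @return An object of class `fitted_base` with a [predict_base()] method.
#' @export
fit_base <- function(x, y, spec = base_classifier_spec(), seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("cannot fit a classifier on a single-class training set",
         call. = FALSE)
  pp <- preprocess_fit(x)
  fit <- list(spec = spec, pp = pp)
  if (spec$family == "logistic") {
    fit$beta <- .ridge_logistic_fit_cpp(pp$x, as.numeric(y), 1 / spec$C)
  } else {
    gamma <- 1 / (ncol(pp$x) * max(mean(apply(pp$x, 2, var)), 1e-12))
    svm_fit <- function(xs, ys) {
      e1071::svm(x = xs, y = factor(ys, levels = c(0, 1)), kernel = "radial",
                 cost = spec$C, gamma = gamma, scale = FALSE)
    }
    decision_of <- function(m, xs) {
      as.numeric(attr(predict(m, xs, decision.values = TRUE),
                      "decision.values"))
    }
    model <- svm_fit(pp$x, y)
    # libsvm's decision-value sign depends on training order; orient so
    # larger values mean more MCI-like
    dv_train <- decision_of(model, pp$x)
    flip <- mean(dv_train[y == 1]) < mean(dv_train[y == 0])
    sgn <- if (flip) -1 else 1
    folds <- stratified_folds(y, spec$calibration_folds,
                              derive_seed(seed, 77L))
    if (is.null(folds)) {
      dv_oof <- sgn * dv_train
    } else {
      dv_oof <- numeric(length(y))
      for (f in sort(unique(folds))) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) { dv_oof[!tr] <- 0; next }
        mf <- svm_fit(pp$x[tr, , drop = FALSE], y[tr])
        dvf <- decision_of(mf, pp$x[!tr, , drop = FALSE])
        flip_f <- mean(decision_of(mf, pp$x[tr, , drop = FALSE])[y[tr] == 1]) <
          mean(decision_of(mf, pp$x[tr, , drop = FALSE])[y[tr] == 0])
        dv_oof[!tr] <- if (flip_f) -dvf else dvf
      }
    }
    fit$model <- model
    fit$sign <- sgn
    fit$platt <- calibrate_probabilities(dv_oof, y)
  }
  class(fit) <- "fitted_base"
  fit
}

#' @rdname fit_base
#' @param fit A `fitted_base` object.
#' @param newx Matrix of new observations.
#' @return `predict_base()`: numeric vector of MCI probabilities in `[0, 1]`.
#' @export
predict_base <- function(fit, newx) {
  if (!inherits(fit, "fitted_base"))
    stop("fit must be a fitted_base object", call. = FALSE)
  newx <- as.matrix(newx)
  xs <- preprocess_apply(newx, fit$pp)
  if (fit$spec$family == "logistic") {
    as.numeric(.ridge_logistic_predict_cpp(xs, fit$beta))
  } else {
    dv <- fit$sign *
      as.numeric(attr(predict(fit$model, xs,
                                          decision.values = TRUE),
                      "decision.values"))
    predict(fit$platt, dv)
  }
}

#' Platt calibration of decision values
#'
#' Fits the sigmoid `p = 1 / (1 + exp(-(a f + b)))` to decision values `f`
#' by maximum likelihood with the usual smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)` and `t- = 1/(N- + 2)`, constrained to `a >= 0`
#' so that the map is monotone non-decreasing in the decision value.
#'
#' @param decision_values Numeric vector of classifier decision values.
#' @param labels 0/1 labels; both classes must be present.
#' @return An object of class `platt_calibration`; use `predict(obj, f)` to
#'   map decision values to probabilities.
#' @export
calibrate_probabilities <- function(decision_values, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("Platt calibration needs both classes present", call. = FALSE)
  stopifnot(length(decision_values) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  t <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  f <- decision_values
  nll <- function(par) {
    eta <- par[1] * f + par[2]
    # -sum t*log(p) + (1-t)*log(1-p), stable form
    sum((1 - t) * eta + log1p(exp(-abs(eta))) + pmax(-eta, 0))
  }
  opt <- optim(c(1, 0), nll, method = "L-BFGS-B",
               lower = c(0, -Inf), upper = c(Inf, Inf))
  structure(list(a = opt$par[1], b = opt$par[2]), class = "platt_calibration")
}

#' @export
predict.platt_calibration <- function(object, newdata, ...) {
  plogis(object$a * newdata + object$b)
}
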