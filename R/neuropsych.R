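## Neuropsychological battery: baseline classifier, correlation analysis
## and retrospective MCI subtyping.

#' Neuropsychological battery metadata
#'
#' The 25-test battery covering learning/memory, language, attention,
#' visuo-spatial and executive domains, plus the MMSE as a global screen.
#' `higher_is_better` records score direction: for the timed tests (TMT,
#' PaSMO, Stroop) a higher score is worse. Direction flags drive both the
#' sign adjustment of the correlation analysis and the direction-aware
#' impairment cut-offs of the subtype rules; MMSE (domain `global`) is not
#' used by the subtype rules.
#'
#' @return Data frame with columns `test`, `domain`, `higher_is_better`.
#' @export
neuropsych_battery <- function() {
  data.frame(
    test = c("mmse",
             "ravlt_total", "ravlt_delayed", "ravlt_immediate",
             "rcf_3min", "rcf_20min", "wlm_delayed", "wlm_immediate",
             "bnt", "verbal_fluency_fas", "similarities", "token_test_5",
             "digit_span", "digit_symbol", "tmt_a", "tmt_b",
             "block_design", "rcf_copy", "silhouettes",
             "letter_digit", "pasmo", "stroop_1", "stroop_2", "stroop_3",
             "stroop_effect"),
    domain = c("global",
               rep("memory", 7),
               rep("language", 4),
               rep("attention", 4),
               rep("spatial", 3),
               rep("executive", 6)),
    higher_is_better = c(TRUE,
                         rep(TRUE, 7), rep(TRUE, 4),
                         TRUE, TRUE, FALSE, FALSE,
                         rep(TRUE, 3),
                         TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# score matrix aligned to cohort order, columns = battery tests
neuropsych_matrix <- function(cohort) {
  if (is.null(cohort$neuropsych))
    stop("cohort has no neuropsychological profiles", call. = FALSE)
  np <- cohort$neuropsych
  tests <- neuropsych_battery()$test
  missing <- setdiff(tests, names(np))
  if (length(missing))
    stop("neuropsych table lacks test column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(cohort_ids(cohort), np$participant_id)
  if (anyNA(idx))
    stop("neuropsych profiles missing for some participants", call. = FALSE)
  as.matrix(np[idx, tests, drop = FALSE])
}

#' Training-mean imputation of test scores
#'
#' Missing entries are replaced by the mean of the observed values among the
#' training participants; the means are returned so held-out profiles can be
#' imputed with training statistics only.
#'
#' @param scores Numeric matrix or data frame (participants x tests), `NA`
#'   for missing; rownames or a `participant_id` column identify rows.
#' @param training_ids Ids of the training participants whose observed
#'   values define the imputation means (default: all rows).
#' @return List with `scores` (completed matrix) and `means` (named vector,
#'   reusable on new profiles). A test with no observed training value is an
#'   error.
#' @export
impute_scores <- function(scores, training_ids = NULL) {
  if (is.data.frame(scores)) {
    if ("participant_id" %in% names(scores)) {
      ids <- scores$participant_id
      scores <- as.matrix(scores[setdiff(names(scores), "participant_id")])
      rownames(scores) <- ids
    } else scores <- as.matrix(scores)
  }
  tr <- if (is.null(training_ids)) seq_len(nrow(scores))
        else match(training_ids, rownames(scores))
  if (anyNA(tr)) stop("unknown training id(s)", call. = FALSE)
  means <- colMeans(scores[tr, , drop = FALSE], na.rm = TRUE)
  bad <- names(means)[!is.finite(means)]
  if (length(bad))
    stop("test(s) fully missing in the training set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (j in seq_len(ncol(scores))) {
    nas <- is.na(scores[, j])
    if (any(nas)) scores[nas, j] <- means[j]
  }
  list(scores = scores, means = means)
}

#' Fit the flat neuropsychological baseline classifier
#'
#' A single (non-cascaded) classifier on the imputed, standardized test
#' score vector, under the same probability contract as the cascade
#' components. Evaluate it under LPO with
#' `run_lpo_evaluation(cohort, config, model = "neuropsych")`.
#'
#' @param cohort A [cohort_dataset()] with neuropsych profiles.
#' @param base A [base_classifier_spec()].
#' @param seed Seed for internal calibration folds.
#' @return A `fitted_base` object.
#' @export
fit_neuropsych_baseline <- function(cohort, base = base_classifier_spec(),
                                    seed = 1L) {
  np <- neuropsych_matrix(cohort)
  fit_base(np, cohort_labels(cohort), base, seed)
}

#' Sign-adjusted Spearman correlations between predictions and test scores
#'
#' Spearman rank correlations (average-rank tie handling, pairwise complete
#' observations) between each prediction level's fold-averaged probability
#' and each test score, plus each test's correlation with the diagnosis
#' label. For tests where a higher score indicates better function the sign
#' is flipped so every test correlates positively with MCI; flipped columns
#' are flagged. Correlations against a constant vector are masked `NA`.
#'
#' @param level_scores Numeric matrix (participants x prediction levels),
#'   e.g. the `level_scores` element of an [run_lpo_evaluation()] result.
#' @param profiles Neuropsych data frame with `participant_id` plus test
#'   columns, aligned by id with `level_scores` rownames.
#' @param labels Named 0/1 diagnosis vector.
#' @param battery Battery metadata (default [neuropsych_battery()]); its
#'   `higher_is_better` flags drive the sign adjustment.
#' @return Object of class `signed_spearman`: list with `rho` (matrix,
#'   levels + `diagnosis` x tests, sign-adjusted), `flipped` (named logical
#'   per test).
#' @export
signed_spearman_matrix <- function(level_scores, profiles, labels,
                                   battery = neuropsych_battery()) {
  ids <- rownames(level_scores)
  if (is.null(ids)) stop("level_scores needs participant rownames",
                         call. = FALSE)
  idx <- match(ids, profiles$participant_id)
  if (anyNA(idx)) stop("profiles missing for some participants", call. = FALSE)
  tests <- intersect(battery$test, names(profiles))
  sc <- as.matrix(profiles[idx, tests, drop = FALSE])
  lv <- cbind(level_scores, diagnosis = as.numeric(labels[ids]))

  rho_one <- function(a, b) {
    ok <- complete.cases(a, b)
    if (sum(ok) < 3) return(NA_real_)
    if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2)
      return(NA_real_)
    cor(a[ok], b[ok], method = "spearman")
  }
  rho <- matrix(NA_real_, ncol(lv), length(tests),
                dimnames = list(colnames(lv), tests))
  for (i in seq_len(ncol(lv)))
    for (j in seq_along(tests))
      rho[i, j] <- rho_one(lv[, i], sc[, j])

  flip <- setNames(battery$higher_is_better[match(tests, battery$test)], tests)
  rho[, flip] <- -rho[, flip]
  structure(list(rho = rho, flipped = flip), class = "signed_spearman")
}

#' @export
print.signed_spearman <- function(x, ...) {
  cat(sprintf("<signed_spearman> %d levels x %d tests (%d sign-flipped)\n",
              nrow(x$rho), ncol(x$rho), sum(x$flipped)))
  print(round(x$rho, 2))
  invisible(x)
}

#' Four-vote combined fusion
#'
#' Combines the three task-level probability scores with the
#' neuropsychological classifier's probability by an unweighted average --
#' task fusion with four votes instead of three.
#'
#' @param scores Numeric vector of exactly four probabilities (three task
#'   scores plus the neuropsych score).
#' @return Single probability.
#' @export
combined_vote <- function(scores) {
  if (length(scores) != 4)
    stop("combined_vote takes exactly four probability scores", call. = FALSE)
  fuse_mean(scores)
}

#' Control reference statistics for subtype cut-offs
#'
#' Per-test mean and standard deviation among healthy controls, stratified
#' by age group (50-64 and 65-80 years), as required by the impairment
#' cut-offs of [classify_mci_subtype()].
#'
#' @param profiles Neuropsych data frame with `participant_id`, `age` and
#'   test columns.
#' @param labels Named 0/1 diagnosis vector (controls = 0).
#' @return Data frame with `test`, `age_group`, `mean`, `sd`.
#' @export
control_reference_stats <- function(profiles, labels) {
  stopifnot("age" %in% names(profiles))
  hc <- profiles[labels[profiles$participant_id] == 0, , drop = FALSE]
  tests <- intersect(neuropsych_battery()$test, names(profiles))
  grp <- ifelse(hc$age < 65, "50-64", "65-80")
  out <- expand.grid(test = tests, age_group = c("50-64", "65-80"),
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- hc[grp == out$age_group[i], out$test[i]]
    v <- v[!is.na(v)]
    out$mean[i] <- masked_mean(v)
    out$sd[i] <- masked_sd(v)
  }
  out
}

age_stratum <- function(age) if (age < 65) "50-64" else "65-80"

#' Retrospective MCI subtype from neuropsychological impairment pattern
#'
#' A test is impaired when its score is worse than the age-stratified
#' control mean by more than 1.5 control standard deviations, direction
#' aware (for timed tests the impaired tail is the high side). Subtypes:
#' amnestic single-domain (memory impairment only), amnestic multi-domain
#' (memory plus any non-memory impairment), non-amnestic single-domain (all
#' impaired tests in exactly one non-memory domain), non-amnestic
#' multi-domain (impaired tests in at least two non-memory domains). A
#' profile whose missing scores leave the rule undecidable, or with no
#' impaired test, is unclassifiable, with the reason reported.
#'
#' @param profile Named numeric vector (or one-row data frame) of test
#'   scores with an `age` entry; `NA` for missing scores.
#' @param control_stats Reference statistics from
#'   [control_reference_stats()].
#' @param cutoff_sd Impairment cut-off in control standard deviations
#'   (default 1.5).
#' @return List with `label` (one of `aMCI-sd`, `aMCI-md`, `naMCI-sd`,
#'   `naMCI-md`, `unclassifiable`) and `reason`.
#' @export
classify_mci_subtype <- function(profile, control_stats, cutoff_sd = 1.5) {
  if (is.data.frame(profile)) profile <- unlist(profile[1, , drop = TRUE])
  if (!"age" %in% names(profile))
    stop("profile needs an age entry", call. = FALSE)
  stratum <- age_stratum(profile[["age"]])
  battery <- neuropsych_battery()
  battery <- battery[battery$domain != "global", , drop = FALSE]

  flags <- setNames(rep(NA, nrow(battery)), battery$test)
  for (i in seq_len(nrow(battery))) {
    test <- battery$test[i]
    score <- if (test %in% names(profile)) profile[[test]] else NA_real_
    cs <- control_stats[control_stats$test == test &
                          control_stats$age_group == stratum, , drop = FALSE]
    if (is.na(score) || nrow(cs) == 0 || is.na(cs$mean) || is.na(cs$sd)) next
    flags[test] <- if (battery$higher_is_better[i])
      score < cs$mean - cutoff_sd * cs$sd
    else
      score > cs$mean + cutoff_sd * cs$sd
  }

  mem <- flags[battery$domain == "memory"]
  nonmem_tests <- battery[battery$domain != "memory", , drop = FALSE]
  nonmem <- flags[nonmem_tests$test]
  mem_any <- any(mem)          # three-valued: TRUE / FALSE / NA
  nonmem_any <- any(nonmem)
  domains <- unique(nonmem_tests$domain)
  dom_flag <- vapply(domains, function(d)
    any(nonmem[nonmem_tests$domain == d]), logical(1))
  n_dom_impaired <- sum(dom_flag, na.rm = TRUE)

  unclass <- function(reason) list(label = "unclassifiable", reason = reason)
  if (is.na(mem_any))
    return(unclass("missing memory scores leave amnestic status undecidable"))
  if (mem_any) {
    if (isTRUE(nonmem_any))
      return(list(label = "aMCI-md",
                  reason = "memory and non-memory impairment"))
    if (is.na(nonmem_any))
      return(unclass("memory impairment present but missing non-memory scores"))
    return(list(label = "aMCI-sd", reason = "memory impairment only"))
  }
  if (n_dom_impaired >= 2)
    return(list(label = "naMCI-md",
                reason = "impairment in two or more non-memory domains"))
  if (n_dom_impaired == 1) {
    others_clear <- all(!nonmem[nonmem_tests$domain !=
                                  names(dom_flag)[which(dom_flag)]])
    if (is.na(others_clear))
      return(unclass("missing scores leave single-domain status undecidable"))
    return(list(label = "naMCI-sd",
                reason = sprintf("impairment confined to the %s domain",
                                 names(dom_flag)[which(dom_flag)])))
  }
  if (anyNA(nonmem))
    return(unclass("no observed impairment but missing scores remain"))
  unclass("no test score below the impairment cut-off")
}
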