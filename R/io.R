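## Readers and writers for the session-bundle formats, explanation reports,
## and the end-to-end experiment runner.
##
## Formats are plain text, UTF-8, decimal point: TSV for token/fixation
## tables (tabs never occur in fields), CSV elsewhere; `#`-prefixed header
## lines carry per-record scalars. Numerics are written with 17 significant
## digits so that write -> read round-trips are bit exact.

write_table_with_header <- function(df, path, header = list(), sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(header))
    writeLines(sprintf("# %s=%s", key, header[[key]]), con)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
}

read_table_with_header <- function(path, sep = "\t") {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_lines <- grep("^#", lines, value = TRUE)
  header <- list()
  for (hl in hdr_lines) {
    kv <- sub("^#\\s*", "", hl)
    key <- sub("=.*$", "", kv)
    header[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1)
    read.delim(text = body, sep = sep, stringsAsFactors = FALSE)
  else
    read.delim(text = body, sep = sep, stringsAsFactors = FALSE)[0, , drop = FALSE]
  list(header = header, data = df)
}

num_header <- function(parsed, key, path) {
  v <- parsed$header[[key]]
  if (is.null(v))
    stop(sprintf("%s: missing '# %s=' header", path, key), call. = FALSE)
  as.numeric(v)
}

# ---- per-mode writers/readers ---------------------------------------------

write_trial_gaze <- function(trial, fix_path, sac_path) {
  spans <- paste(sprintf("%d:%d", trial$sentence_spans$first_aoi,
                         trial$sentence_spans$last_aoi), collapse = ",")
  write_table_with_header(trial$fixations, fix_path,
                          list(n_words = trial$n_words,
                               sentence_spans = spans))
  write_table_with_header(trial$saccades, sac_path)
}

read_trial_gaze <- function(fix_path, sac_path) {
  fx <- read_table_with_header(fix_path)
  if (nrow(fx$data) && any(fx$data$aoi_index < 1))
    stop(sprintf("%s: aoi_index must be 1-based (word AOIs are indexed from 1)",
                 fix_path), call. = FALSE)
  spans <- strsplit(fx$header$sentence_spans %||%
                      stop(sprintf("%s: missing sentence_spans header", fix_path),
                           call. = FALSE), ",")[[1]]
  parts <- do.call(rbind, strsplit(spans, ":"))
  sc <- read_table_with_header(sac_path)
  trial_gaze(num_header(fx, "n_words", fix_path),
             data.frame(first_aoi = as.integer(parts[, 1]),
                        last_aoi = as.integer(parts[, 2])),
             fx$data, sc$data)
}

write_speech_timing <- function(timing, path) {
  write_table_with_header(timing$voiced_intervals, path,
                          list(total_duration_s = fmt_num(timing$total_duration_s),
                               syllable_count = timing$syllable_count),
                          sep = ",")
}

read_speech_timing <- function(path) {
  p <- read_table_with_header(path, sep = ",")
  speech_timing(num_header(p, "total_duration_s", path),
                num_header(p, "syllable_count", path),
                p$data)
}

write_transcript <- function(transcript, path) {
  write_table_with_header(
    transcript$tokens, path,
    list(sentence_count = transcript$sentence_count,
         incomplete_sentence_count = transcript$incomplete_sentence_count,
         sample_duration_s = fmt_num(transcript$sample_duration_s)))
}

read_transcript <- function(path) {
  p <- read_table_with_header(path)
  annotated_transcript(p$data,
                       sentence_count = num_header(p, "sentence_count", path),
                       incomplete_sentence_count =
                         num_header(p, "incomplete_sentence_count", path),
                       sample_duration_s =
                         num_header(p, "sample_duration_s", path))
}

write_comprehension <- function(responses, path) {
  df <- cbind(question_index = seq_len(nrow(responses$items)),
              responses$items)
  write_table_with_header(df, path, sep = ",")
}

read_comprehension <- function(path) {
  p <- read_table_with_header(path, sep = ",")
  d <- p$data[order(p$data$question_index), , drop = FALSE]
  comprehension_responses(d$correct, d$response_time_ms)
}

# ---- cohort bundle ---------------------------------------------------------

#' Write a cohort as a session bundle on disk
#'
#' One directory per participant with per-(task, mode) text files, a
#' neuropsych CSV, and a JSON manifest tying them together. The formats are
#' exactly what [load_session_bundle()] consumes, so written cohorts double
#' as round-trip fixtures.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  participants <- list()
  for (s in cohort$sessions) {
    pdir <- file.path(dir, s$participant_id)
    dir.create(pdir, showWarnings = FALSE)
    slots <- list()
    for (key in names(s$records)) {
      rec <- s$records[[key]]
      base <- file.path(s$participant_id, key)
      if (inherits(rec, "trial_gaze")) {
        write_trial_gaze(rec, file.path(dir, paste0(base, "_fixations.tsv")),
                         file.path(dir, paste0(base, "_saccades.tsv")))
        slots[[key]] <- list(fixations = paste0(base, "_fixations.tsv"),
                             saccades = paste0(base, "_saccades.tsv"))
      } else if (inherits(rec, "speech_timing")) {
        write_speech_timing(rec, file.path(dir, paste0(base, ".csv")))
        slots[[key]] <- list(timing = paste0(base, ".csv"))
      } else if (inherits(rec, "annotated_transcript")) {
        write_transcript(rec, file.path(dir, paste0(base, ".tsv")))
        slots[[key]] <- list(transcript = paste0(base, ".tsv"))
      } else if (inherits(rec, "comprehension_responses")) {
        write_comprehension(rec, file.path(dir, paste0(base, ".csv")))
        slots[[key]] <- list(responses = paste0(base, ".csv"))
      }
    }
    participants[[length(participants) + 1L]] <- list(
      participant_id = s$participant_id,
      diagnosis = if (is.na(s$diagnosis)) NULL else s$diagnosis,
      slots = slots)
  }
  manifest <- list(format = "mcicascade-session-bundle",
                   version = as.character(packageVersion("mcicascade")),
                   participants = participants)
  if (!is.null(cohort$neuropsych)) {
    np <- cohort$neuropsych
    num <- vapply(np, is.numeric, logical(1))
    out <- np
    for (j in which(num)) out[[j]] <- fmt_num(np[[j]])
    write.table(out, file.path(dir, "neuropsych.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    manifest$neuropsych <- "neuropsych.csv"
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a session bundle from its manifest
#'
#' Reads every referenced file, rebuilding the raw records; parse and
#' validation errors name the offending file.
#'
#' @param manifest_path Path to a manifest written by [write_cohort()].
#' @return A [cohort_dataset()].
#' @export
load_session_bundle <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  resolve <- function(rel) {
    p <- file.path(dir, rel)
    if (!file.exists(p))
      stop("manifest references a missing file: ", p, call. = FALSE)
    p
  }
  sessions <- lapply(manifest$participants, function(pt) {
    records <- list()
    for (key in names(pt$slots)) {
      slot <- pt$slots[[key]]
      mode <- strsplit(key, ".", fixed = TRUE)[[1]][2]
      records[[key]] <- tryCatch(switch(mode,
        eyes = read_trial_gaze(resolve(slot$fixations), resolve(slot$saccades)),
        speech = read_speech_timing(resolve(slot$timing)),
        language = read_transcript(resolve(slot$transcript)),
        comprehension = read_comprehension(resolve(slot$responses)),
        stop("unknown mode in slot key: ", key, call. = FALSE)),
        error = function(e) stop(sprintf("participant %s, slot %s: %s",
                                         pt$participant_id, key,
                                         conditionMessage(e)), call. = FALSE))
    }
    session_record(pt$participant_id, pt$diagnosis %||% NA, records)
  })
  np <- NULL
  if (!is.null(manifest$neuropsych))
    np <- read.csv(resolve(manifest$neuropsych), stringsAsFactors = FALSE)
  cohort_dataset(sessions, neuropsych = np)
}

# ---- explanation reports ---------------------------------------------------

pretty_task <- function(task) {
  c(picture_description = "the picture description",
    reading_silent = "reading silently",
    reading_aloud = "reading aloud")[task]
}

pretty_mode <- function(mode) {
  c(speech = "speech timing", language = "language use",
    eyes = "eye movements", comprehension = "comprehension responses")[mode]
}

#' Render a narrative explanation of a cascade prediction
#'
#' Produces the multi-level narrative report: the overall session
#' probability, each task's probability, and any mode-level probability at
#' or above the threshold. Every probability quoted in the narrative equals
#' the prediction tree's value rounded to two decimals.
#'
#' @param prediction A `cascade_prediction` from [predict_session()]
#'   populated to at least the task level.
#' @param threshold Decision threshold quoted in the report (defaults to the
#'   prediction's own).
#' @return Object of class `explanation_report` with fields
#'   `participant_id`, `probabilities`, `threshold`, `text`.
#' @export
render_explanation <- function(prediction, threshold = prediction$threshold) {
  stopifnot(inherits(prediction, "cascade_prediction"))
  if (is.null(prediction$task_probabilities))
    stop("explanation reports need task-level probabilities", call. = FALSE)
  p2 <- function(p) sprintf("%.2f", round(p, 2))
  sess <- prediction$session_probability
  lines <- sprintf(
    "This participant has an overall probability of %s of having MCI.",
    p2(sess))
  tp <- prediction$task_probabilities
  high_tasks <- names(tp)[tp >= threshold]
  low_tasks <- setdiff(names(tp), high_tasks)
  if (length(low_tasks))
    lines <- c(lines, sprintf(
      "Performance on %s was normal [p(MCI) = %s].",
      paste(pretty_task(low_tasks), collapse = " and "),
      paste(p2(tp[low_tasks]), collapse = " and ")))
  if (length(high_tasks)) {
    sentence <- sprintf(
      "%s suggest%s an elevated probability of impairment [p(MCI) = %s].",
      paste(pretty_task(high_tasks), collapse = " and "),
      if (length(high_tasks) == 1) "s" else "",
      paste(p2(tp[high_tasks]), collapse = " and "))
    substring(sentence, 1, 1) <- toupper(substring(sentence, 1, 1))
    lines <- c(lines, sentence)
  }
  mp <- prediction$mode_probabilities
  if (!is.null(mp)) {
    flagged <- names(mp)[mp >= threshold]
    for (slot in flagged) {
      parts <- strsplit(slot, ".", fixed = TRUE)[[1]]
      lines <- c(lines, sprintf(
        "Specifically, the %s during %s points to a possible impairment [p(MCI) = %s].",
        pretty_mode(parts[2]), pretty_task(parts[1]), p2(mp[[slot]])))
    }
    if (length(flagged) == 0 && length(high_tasks) == 0)
      lines <- c(lines,
                 "No task or mode reached the impairment threshold; performance appears normal at every level.")
  }
  structure(list(participant_id = prediction$participant_id,
                 probabilities = list(session = sess,
                                      task = prediction$task_probabilities,
                                      mode = prediction$mode_probabilities),
                 threshold = threshold,
                 text = paste(lines, collapse = " ")),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(sprintf("<explanation_report> %s\n%s\n", x$participant_id,
              paste(strwrap(x$text, 72), collapse = "\n")))
  invisible(x)
}

# ---- fitted-model container ------------------------------------------------

#' Save or load a fitted cascade
#'
#' Wraps the fitted model in a versioned container.
#'
#' @param model A `fitted_cascade`.
#' @param path File path.
#' @return `load_cascade()` returns the `fitted_cascade`.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "fitted_cascade"))
  saveRDS(list(format = "mcicascade-fitted-cascade",
               version = as.character(packageVersion("mcicascade")),
               model = model), path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mcicascade-fitted-cascade"))
    stop("not a fitted-cascade container: ", path, call. = FALSE)
  obj$model
}

# ---- experiment runner -----------------------------------------------------

read_experiment_config <- function(config_path) {
  if (grepl("\\.ya?ml$", config_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(config_path)
  } else {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  }
}

#' Run a full synthetic-cohort experiment from a config file
#'
#' Generates a cohort, extracts all features, runs leave-pair-out
#' evaluation for the requested architectures (plus the neuropsychological
#' baseline and the combined four-vote fusion when profiles are present),
#' and writes the result bundle: a metrics JSON and CSV (one row per
#' configuration plus per-mode and per-task rows), the per-participant
#' fold-averaged score table, the sign-adjusted correlation matrix, and a
#' log recording seed, config hash and package version.
#'
#' @param config_path JSON (or YAML) file with fields `seed`, `out_dir`, and
#'   optionally `n_hc`, `n_mci`, `effect_size`, `architectures`,
#'   `base_family`, `threshold`, `stacking_folds`, `run_neuropsych`,
#'   `run_combined`.
#' @return Invisibly, the list of `lpo_result` objects keyed by
#'   configuration name.
#' @export
run_experiment <- function(config_path) {
  cfg <- read_experiment_config(config_path)
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  architectures <- cfg$architectures %||% CASCADE_ARCHITECTURES
  base_family <- cfg$base_family %||% "logistic"
  threshold <- cfg$threshold %||% 0.5

  gen <- generator_config(n_hc = cfg$n_hc %||% 29L,
                          n_mci = cfg$n_mci %||% 26L,
                          effect_size = cfg$effect_size %||% 2,
                          seed = seed)
  cohort <- extract_features(generate_cohort(gen))

  results <- list()
  for (arch in architectures) {
    config <- cascade_config(architecture = arch,
                             base = base_classifier_spec(base_family),
                             stacking_folds = cfg$stacking_folds %||% 5L,
                             seed = seed, threshold = threshold)
    results[[arch]] <- run_lpo_evaluation(cohort, config)
  }
  ref_config <- cascade_config(architecture = "task_fusion",
                               base = base_classifier_spec(base_family),
                               stacking_folds = cfg$stacking_folds %||% 5L,
                               seed = seed, threshold = threshold)
  if (!is.null(cohort$neuropsych) && (cfg$run_neuropsych %||% TRUE))
    results[["neuropsych"]] <- run_lpo_evaluation(cohort, ref_config,
                                                  model = "neuropsych")
  if (!is.null(cohort$neuropsych) && (cfg$run_combined %||% TRUE))
    results[["combined"]] <- run_lpo_evaluation(cohort, ref_config,
                                                model = "combined")

  # metrics table: one row per configuration, plus mode/task rows taken
  # from the most detailed cascade available
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(configuration = nm, auc = r$auc, auc_sd = r$auc_sd,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity, stringsAsFactors = FALSE)
  })
  detailed <- results[[intersect(c("session_fusion", "task_fusion",
                                   "mode_fusion"), names(results))[1] %||%
                         names(results)[1]]]
  if (!is.null(detailed$level_scores)) {
    ls <- detailed$level_scores
    labels <- setNames(detailed$participant_scores$label,
                       detailed$participant_scores$participant_id)
    lv_rows <- lapply(setdiff(colnames(ls), "session"), function(lvl) {
      sc <- ls[, lvl]
      cm <- confusion_metrics(sc, labels[rownames(ls)], threshold)
      data.frame(configuration = paste0("level:", lvl),
                 auc = pairwise_auc(sc[labels[rownames(ls)] == 1],
                                    sc[labels[rownames(ls)] == 0]),
                 auc_sd = NA_real_, accuracy = cm[["accuracy"]],
                 sensitivity = cm[["sensitivity"]],
                 specificity = cm[["specificity"]], stringsAsFactors = FALSE)
    })
    rows <- c(rows, lv_rows)
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "evaluation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  write.csv(detailed$participant_scores,
            file.path(out_dir, "participant_scores.csv"), row.names = FALSE)

  if (!is.null(cohort$neuropsych) && !is.null(detailed$level_scores)) {
    labels <- setNames(cohort_labels(cohort), cohort_ids(cohort))
    corr <- signed_spearman_matrix(detailed$level_scores, cohort$neuropsych,
                                   labels)
    out <- as.data.frame(corr$rho)
    out <- cbind(level = rownames(corr$rho), out)
    write.csv(out, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    flags <- data.frame(test = names(corr$flipped),
                        sign_flipped = unname(corr$flipped))
    write.csv(flags, file.path(out_dir, "correlation_sign_flags.csv"),
              row.names = FALSE)
  }

  cfg_hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = ""))) %% 1e9
  writeLines(c(sprintf("mcicascade %s", packageVersion("mcicascade")),
               sprintf("seed: %d", as.integer(seed)),
               sprintf("config hash: %d", as.integer(cfg_hash)),
               sprintf("configurations: %s",
                       paste(names(results), collapse = ", "))),
             file.path(out_dir, "log.txt"))
  invisible(results)
}
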