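## Comprehension features from question responses.

#' Extract the comprehension features of one reading task
#'
#' Average accuracy, per-question binary correctness, and per-question
#' response time in ms. With the default five questions this yields the
#' standard 11 features; for `q` questions the dimensionality is `2q + 1`.
#'
#' @param responses A [comprehension_responses()] record.
#' @param task Task the responses belong to.
#' @param n_questions Expected question count (default 5).
#' @return A [feature_vector()] of mode `comprehension`.
#' @export
extract_comprehension_features <- function(responses, task = "reading_silent",
                                           n_questions = 5L) {
  stopifnot(inherits(responses, "comprehension_responses"))
  items <- responses$items
  if (nrow(items) != n_questions)
    stop(sprintf("expected %d question responses, got %d",
                 n_questions, nrow(items)), call. = FALSE)
  q <- seq_len(n_questions)
  vals <- c(mean(items$correct),
            items$correct,
            items$response_time_ms)
  names(vals) <- c("average_accuracy",
                   paste0("q", q, "_correct"),
                   paste0("q", q, "_response_time_ms"))
  feature_vector(vals, mode = "comprehension", task = task,
                 n_questions = n_questions)
}
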