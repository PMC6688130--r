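## Small shared helpers.

# mean/sd/max over possibly-empty sets: statistics over empty sets (or sd
# over a single value) are masked missing (NA), never 0 or an error.
masked_mean <- function(x) if (length(x) == 0) NA_real_ else mean(x)

# sample (n-1) standard deviation; NA when fewer than 2 values
masked_sd <- function(x) if (length(x) < 2) NA_real_ else sd(x)

masked_max <- function(x) if (length(x) == 0) NA_real_ else max(x)

# ratio with masked-missing denominator rule
masked_ratio <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic RNG scope: runs expr with the given seed and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# seeds derived from a user seed stay below 2^31 - 1
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 10007 + offset) %% 2147483629
}

# full-precision numeric formatting so text round-trips are bit exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# stratified k-fold assignment, deterministic under seed; k is reduced when
# a class has fewer members than k (minimum 2 usable folds)
stratified_folds <- function(y, k, seed) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  k_eff <- min(k, n_pos, n_neg)
  if (k_eff < 2) return(NULL)  # caller falls back to in-sample scores
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
  })
  fold
}
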