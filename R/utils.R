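# Internal helpers shared across modules.

# Deterministic per-stage seed derived from the master seed, kept below
# 2^31 so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 977L + h) %% 2147483629)
}

# Most frequent value; ties broken by sort order for determinism.
mode_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  out <- sort(best)[1L]
  if (is.numeric(x)) as.numeric(out) else out
}

# F1 of the positive class; zero-denominator convention returns 0.
f1_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

precision_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  pp <- sum(pred == 1)
  if (pp == 0) 0 else tp / pp
}

recall_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  ap <- sum(truth == 1)
  if (ap == 0) 0 else tp / ap
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin, so fold class counts never differ by more than one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

is_binary01 <- function(x) {
  v <- unique(x[!is.na(x)])
  length(v) <= 2 && all(v %in% c(0, 1))
}
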