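#' Configuration for the deep dropout network
#'
#' Fixes the stage-2 training contract: Adam optimizer at learning rate
#' 0.001, binary cross-entropy loss, 2 hidden ReLU layers of width
#' `ceil((I + O) / 2)` (with O = 1 output label), dropout after each
#' hidden layer, one sigmoid output unit, and stratified K-fold
#' cross-validation for subset scoring.
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs per fit (default 500; desk-scale
#'   experiments in this package use 100-200).
#' @param dropout_grid Candidate dropout rates for the grid search
#'   (default 0, 0.1, ..., 0.5).
#' @param k_folds Cross-validation folds K (default 5).
#' @param batch_size Mini-batch size, capped at the training size
#'   (default 16).
#' @param seed Integer seed controlling initialization, shuffling,
#'   dropout masks and fold assignment.
#' @return An object of class `ddn_config`.
#' @export
ddn_config <- function(learning_rate = 0.001, epochs = 500,
                       dropout_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                       k_folds = 5, batch_size = 16, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, k_folds >= 2, batch_size >= 1,
            length(dropout_grid) >= 1,
            all(dropout_grid >= 0 & dropout_grid < 1))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = "Adam", loss = "binary cross-entropy",
                 hidden_layers = 2L, hidden_activation = "ReLU",
                 output_activation = "sigmoid",
                 dropout_grid = sort(dropout_grid),
                 k_folds = as.integer(k_folds),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ddn_config")
}

# Hidden width rule: ceil((I + O) / 2) with a single output label.
hidden_width <- function(input_dim) as.integer(ceiling((input_dim + 1) / 2))

#' Describe the dropout network for a given input size
#'
#' @param input_dim Number of input features (>= 1).
#' @param dropout Dropout rate applied after each hidden layer.
#' @param config A [ddn_config()].
#' @return A list describing the architecture (layer widths, activations,
#'   dropout, training contract).
#' @export
build_ddn <- function(input_dim, dropout, config = ddn_config()) {
  stopifnot(input_dim >= 1, dropout >= 0, dropout < 1)
  list(input_dim = as.integer(input_dim),
       hidden_width = hidden_width(input_dim),
       hidden_layers = 2L, hidden_activation = "ReLU",
       dropout = dropout, output_units = 1L,
       output_activation = "sigmoid",
       optimizer = config$optimizer, learning_rate = config$learning_rate,
       loss = config$loss, epochs = config$epochs,
       batch_size = config$batch_size)
}

# Train the network on a numeric matrix; consumes the current R RNG
# stream (callers wrap in withr::with_seed for reproducibility).
# At the very small hidden widths the sizing rule yields for short
# feature lists, an unlucky initialization can leave every ReLU unit of
# a layer inactive for all inputs (a dead network with zero gradients);
# such degenerate fits are re-initialized deterministically from the
# continuing RNG stream, up to 3 times.
train_ddn <- function(X, y, dropout, config) {
  base_acc <- max(mean(y == 1), mean(y == 0))
  for (attempt in seq_len(4)) {
    params <- .ddn_train_cpp(X, as.numeric(y), hidden_width(ncol(X)), dropout,
                             config$learning_rate, config$epochs,
                             min(config$batch_size, nrow(X)))
    pr <- .ddn_predict_cpp(params, X)
    acc <- mean(as.numeric(pr > 0.5) == y)
    if (acc > base_acc || length(unique(y)) < 2) break
  }
  params
}

predict_ddn <- function(params, X) .ddn_predict_cpp(params, X)

#' Enumerate candidate feature subsets for the stage-2 search
#'
#' All non-empty subsets of the 2-metric feature set with size at most
#' `max_size` (N minus the size of F_3M+, so the combined list never
#' exceeds N), ordered by size and then lexicographically by feature
#' position. With 7 features and `max_size = 5` this yields 119 subsets
#' (of 128 possible including the empty set).
#'
#' @param f2m Character vector of 2-metric features (F_2M).
#' @param max_size Maximum subset size; 0 gives an empty list and
#'   stage 2 degenerates to the baseline.
#' @return A list of character vectors.
#' @export
enumerate_subsets <- function(f2m, max_size) {
  stopifnot(max_size >= 0)
  max_size <- min(max_size, length(f2m))
  if (max_size == 0 || !length(f2m)) return(list())
  unlist(lapply(seq_len(max_size), function(s) {
    m <- utils::combn(f2m, s, simplify = FALSE)
    m
  }), recursive = FALSE)
}

#' Mean cross-validated F1 of the dropout network
#'
#' Stratified, seeded K-fold cross-validation: per fold the network is
#' trained on the remaining folds and the held-out fold is predicted at
#' threshold 0.5; the unweighted mean of the per-fold F1 scores of class
#' 1 is returned. A held-out fold with no positive instances contributes
#' 0 with a warning.
#'
#' @param table Training data.frame (balanced, normalized).
#' @param features Character vector of feature columns to use.
#' @param outcome Name of the binary outcome column.
#' @param dropout Dropout rate.
#' @param config A [ddn_config()]; `config$seed` fixes folds and
#'   training randomness.
#' @return Mean F1 over the K folds.
#' @export
cv_f1 <- function(table, features, outcome, dropout, config = ddn_config()) {
  X <- as.matrix(table[features])
  storage.mode(X) <- "double"
  y <- table[[outcome]]
  k <- config$k_folds
  if (min(table(y)) < k)
    stop("k_folds (", k, ") exceeds the minority class count")
  withr::with_seed(config$seed, {
    fold <- stratified_folds(y, k)
    f1s <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      params <- train_ddn(X[tr, , drop = FALSE], y[tr], dropout, config)
      pred <- as.numeric(predict_ddn(params, X[!tr, , drop = FALSE]) > 0.5)
      if (!any(y[!tr] == 1)) {
        warning("fold ", f, " holds no positive instances; F1 set to 0")
        return(0)
      }
      f1_score(pred, y[!tr])
    }, numeric(1))
    mean(f1s)
  })
}

#' Grid-search the dropout rate by cross-validated F1
#'
#' Evaluates every rate in the grid on the 3-metric baseline feature set
#' with [cv_f1()] and returns the rate with the highest mean F1; ties go
#' to the smaller rate.
#'
#' @param table Training data.frame.
#' @param f3m Baseline feature set (F_3M+).
#' @param outcome Name of the binary outcome column.
#' @param config A [ddn_config()] supplying the grid.
#' @return The best dropout rate, with the per-rate F1s as attribute
#'   `"grid_f1"`.
#' @export
tune_dropout <- function(table, f3m, outcome, config = ddn_config()) {
  grid <- config$dropout_grid
  f1s <- vapply(grid, function(d) cv_f1(table, f3m, outcome, d, config),
                numeric(1))
  best <- grid[which.max(f1s)]  # grid sorted ascending: ties -> smaller
  structure(best, grid_f1 = stats::setNames(f1s, grid))
}

#' Stage 2: select the final feature list with the dropout network
#'
#' If F_3M+ already meets the expert target size `n`, stage 2 is skipped
#' and F_3M+ (trimmed to the `n` best average ranks if larger) is
#' returned. Otherwise the dropout rate is tuned once on F_3M+, the
#' baseline cross-validated F1 is computed, and every candidate list
#' F_3M+ with an F_2M subset appended (sizes up to `n - |F_3M+|`) is
#' evaluated with the same tuned rate. The final list is the candidate
#' with the highest mean CV F1 if it strictly exceeds the baseline;
#' otherwise the baseline features alone. Ties prefer the smaller
#' subset, then earlier enumeration order.
#'
#' @param table Training data.frame (balanced, normalized).
#' @param f3m,f2m Stage-1 outputs F_3M+ and F_2M.
#' @param outcome Name of the binary outcome column.
#' @param n Expert target feature count.
#' @param config A [ddn_config()].
#' @param rank Named average-rank vector from stage 1, used only for
#'   the skip-path trim.
#' @return An object of class `selection_result` with `final_features`,
#'   `baseline_f1`, `best_subset`, `best_dropout`, `subset_log` (one row
#'   per candidate subset with its mean CV F1) and `stage2_skipped`.
#' @export
select_final_features <- function(table, f3m, f2m, outcome, n,
                                  config = ddn_config(), rank = NULL) {
  empty_log <- data.frame(subset = character(), size = integer(),
                          cv_f1 = numeric(), stringsAsFactors = FALSE)
  if (length(f3m) >= n) {
    final <- f3m
    if (length(f3m) > n) {
      if (is.null(rank)) stop("rank table required to trim F_3M+ to n")
      final <- names(sort(rank[f3m]))[seq_len(n)]
      final <- f3m[f3m %in% final]
    }
    return(structure(list(final_features = final, baseline_f1 = NA_real_,
                          best_subset = character(), best_dropout = NA_real_,
                          subset_log = empty_log, stage2_skipped = TRUE,
                          best_f1 = NA_real_, log = "F_3M+ met the expert target; stage 2 skipped"),
                     class = "selection_result"))
  }
  best_dropout <- tune_dropout(table, f3m, outcome, config)
  baseline_f1 <- cv_f1(table, f3m, outcome, as.numeric(best_dropout), config)
  subsets <- enumerate_subsets(f2m, n - length(f3m))
  log_msg <- character()
  if (!length(subsets))
    log_msg <- "F_2M empty; stage 2 returns the baseline features"
  f1s <- vapply(subsets, function(z) {
    cv_f1(table, c(f3m, z), outcome, as.numeric(best_dropout), config)
  }, numeric(1))
  subset_log <- if (length(subsets)) {
    data.frame(subset = vapply(subsets, paste, character(1), collapse = "+"),
               size = lengths(subsets), cv_f1 = f1s,
               stringsAsFactors = FALSE)
  } else empty_log
  best_subset <- character()
  best_f1 <- NA_real_
  if (length(f1s) && max(f1s) > baseline_f1) {
    pick <- which.max(f1s)  # enumeration order = size then lexicographic
    best_subset <- subsets[[pick]]
    best_f1 <- f1s[pick]
  }
  structure(list(
    final_features = c(f3m, best_subset),
    baseline_f1 = baseline_f1,
    best_subset = best_subset,
    best_dropout = as.numeric(best_dropout),
    grid_f1 = attr(best_dropout, "grid_f1"),
    subset_log = subset_log,
    stage2_skipped = FALSE,
    best_f1 = best_f1,
    log = log_msg), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$final_features), " final feature(s)",
      if (x$stage2_skipped) " (stage 2 skipped)" else sprintf(
        "; baseline F1 %.3f, best dropout %.2f, %d subset(s) searched",
        x$baseline_f1, x$best_dropout, nrow(x$subset_log)), "\n", sep = "")
  invisible(x)
}
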