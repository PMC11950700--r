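# Baseline feature selectors: the four classical families (filter,
# wrapper, embedded, hybrid) used as comparators for the 2-stage method.
# These are behavioral contracts around standard algorithms; each
# selector returns exactly k distinct feature names.

# Mutual information (bits) between two variables, discretizing
# continuous inputs by equal-frequency binning.
mutual_info <- function(x, y, bins = 10) {
  xb <- discretize_ef(x, bins)
  yb <- discretize_ef(y, bins)
  entropy_bits(xb) + entropy_bits(yb) - entropy_bits(paste(xb, yb))
}

# Symmetrical uncertainty: 2 I(X;Y) / (H(X) + H(Y)).
symmetrical_uncertainty <- function(x, y, bins = 10) {
  hx <- entropy_bits(discretize_ef(x, bins))
  hy <- entropy_bits(discretize_ef(y, bins))
  if (hx + hy == 0) return(0)
  2 * mutual_info(x, y, bins) / (hx + hy)
}

baseline_candidates <- function(table, schema) {
  intersect(candidate_features(schema), names(table))
}

#' Filter-family baseline selectors
#'
#' Ranks candidate features by one of three filter criteria and returns
#' the top `k`: `CFS` (absolute Pearson correlation for continuous
#' features, symmetrical uncertainty for discrete ones), `IG`
#' (information gain), or `MRMR` (greedy maximum-relevance
#' minimum-redundancy, difference scheme, mutual-information based).
#'
#' @param table Preprocessed cohort data.frame.
#' @param schema A [feature_schema()].
#' @param outcome Name of the binary outcome column.
#' @param method `"CFS"`, `"IG"` or `"MRMR"`.
#' @param k Number of features to select.
#' @return Character vector of `k` feature names.
#' @export
filter_select <- function(table, schema, outcome, method = c("CFS", "IG", "MRMR"),
                          k) {
  method <- match.arg(method)
  feats <- baseline_candidates(table, schema)
  if (k > length(feats)) stop("k exceeds the number of candidate features")
  y <- table[[outcome]]
  if (method %in% c("CFS", "IG")) {
    crit <- vapply(feats, function(f) {
      x <- table[[f]]
      if (method == "IG") return(compute_info_gain(x, y))
      if (schema$columns[[f]] == "continuous") {
        suppressWarnings(compute_correlation_score(x, y, "continuous", "binary"))
      } else {
        symmetrical_uncertainty(x, y)
      }
    }, numeric(1))
    return(feats[order(-crit, seq_along(feats))][seq_len(k)])
  }
  # MRMR: greedy difference scheme
  rel <- vapply(feats, function(f) mutual_info(table[[f]], y), numeric(1))
  selected <- feats[which.max(rel)]
  while (length(selected) < k) {
    rest <- setdiff(feats, selected)
    score <- vapply(rest, function(f) {
      red <- mean(vapply(selected, function(s)
        mutual_info(table[[f]], table[[s]]), numeric(1)))
      rel[[f]] - red
    }, numeric(1))
    selected <- c(selected, rest[which.max(score)])
  }
  selected
}

# Cross-validated accuracy of an SVM on a feature subset; folds are
# fixed by the caller so subset comparisons are paired.
svm_cv_accuracy <- function(table, features, outcome, fold) {
  y <- factor(table[[outcome]], levels = c(0, 1))
  acc <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2)
      stop("degenerate single-class fold in wrapper search")
    fit <- e1071::svm(table[tr, features, drop = FALSE], y[tr], scale = FALSE)
    mean(stats::predict(fit, table[!tr, features, drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Wrapper-family baseline selectors
#'
#' Greedy subset search scored by the cross-validated accuracy of a
#' support vector machine: sequential forward selection (`SFS`),
#' sequential backward selection (`SBS`), or stepwise/bidirectional
#' selection (`SS`, a forward step optionally followed by a backward
#' removal when it improves the score). The search stops when a subset
#' of size `k` is reached.
#'
#' @inheritParams filter_select
#' @param method `"SFS"`, `"SBS"` or `"SS"`.
#' @param cv_folds Accuracy-scoring folds (default 3).
#' @param seed Seed fixing the fold assignment.
#' @return Character vector of `k` feature names.
#' @export
wrapper_select <- function(table, schema, outcome, method = c("SFS", "SBS", "SS"),
                           k, cv_folds = 3, seed = 1) {
  method <- match.arg(method)
  feats <- baseline_candidates(table, schema)
  if (k > length(feats)) stop("k exceeds the number of candidate features")
  fold <- withr::with_seed(seed, stratified_folds(table[[outcome]], cv_folds))
  score <- function(fs) svm_cv_accuracy(table, fs, outcome, fold)

  forward_step <- function(selected) {
    rest <- setdiff(feats, selected)
    sc <- vapply(rest, function(f) score(c(selected, f)), numeric(1))
    c(selected, rest[which.max(sc)])
  }
  backward_step <- function(selected) {
    sc <- vapply(selected, function(f) score(setdiff(selected, f)), numeric(1))
    setdiff(selected, selected[which.max(sc)])
  }

  if (method == "SFS") {
    selected <- character()
    while (length(selected) < k) selected <- forward_step(selected)
  } else if (method == "SBS") {
    selected <- feats
    while (length(selected) > k) selected <- backward_step(selected)
  } else {
    selected <- character()
    while (length(selected) < k) {
      selected <- forward_step(selected)
      if (length(selected) > 2 && length(selected) < k) {
        cand <- backward_step(selected)
        if (score(cand) > score(selected)) selected <- cand
      }
    }
  }
  selected
}

#' Embedded-family baseline selectors
#'
#' Fits a penalized logistic regression with glmnet — Lasso (`"L1"`),
#' Ridge (`"L2"`) or ElasticNet (`"L1+L2"`, alpha 0.5) — with the
#' penalty chosen by seeded cross-validation, and returns the `k`
#' features with the largest absolute coefficients.
#'
#' @inheritParams filter_select
#' @param method `"L1"`, `"L2"` or `"L1+L2"`.
#' @param seed Seed fixing the cross-validation folds.
#' @return Character vector of `k` feature names.
#' @export
embedded_select <- function(table, schema, outcome, method = c("L1", "L2", "L1+L2"),
                            k, seed = 1) {
  method <- match.arg(method)
  feats <- baseline_candidates(table, schema)
  if (k > length(feats)) stop("k exceeds the number of candidate features")
  alpha <- switch(method, L1 = 1, L2 = 0, `L1+L2` = 0.5)
  X <- as.matrix(table[feats])
  y <- table[[outcome]]
  cvfit <- withr::with_seed(seed, {
    foldid <- stratified_folds(y, min(5, min(table(y))))
    glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                      foldid = foldid)
  })
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
  feats[order(-abs(beta), seq_along(feats))][seq_len(k)]
}

#' Hybrid-family baseline selectors
#'
#' Filter-then-wrapper composition: a filter method reduces the
#' candidates to `pre_k` features, and a wrapper method selects the
#' final `k` from the reduced table. The 3 x 3 combinations of filter
#' and wrapper methods give the nine classical hybrid baselines.
#'
#' @inheritParams wrapper_select
#' @param filter_method Passed to [filter_select()].
#' @param wrapper_method Passed to [wrapper_select()].
#' @param pre_k Filter-stage size (default 30; must be >= `k`).
#' @return Character vector of `k` feature names (a subset of the
#'   filter stage's output).
#' @export
hybrid_select <- function(table, schema, outcome, filter_method, wrapper_method,
                          pre_k = 30, k = 15, cv_folds = 3, seed = 1) {
  if (pre_k < k) stop("pre_k must be at least k")
  pre <- filter_select(table, schema, outcome, filter_method,
                       min(pre_k, length(baseline_candidates(table, schema))))
  keep <- names(schema$columns) %in%
    c(pre, schema_columns(schema, c("outcome", "identifier")))
  sub_schema <- feature_schema(schema$columns[keep], character())
  wrapper_select(table[names(sub_schema$columns)], sub_schema, outcome,
                 wrapper_method, k, cv_folds = cv_folds, seed = seed)
}

#' Benchmark baseline selectors against the 2-stage method
#'
#' Runs each requested selector on the training data, evaluates its
#' feature list with the three downstream classifiers, and returns one
#' comparison table (method x precision/recall/F1 means).
#'
#' @param train,test Preprocessed train and test data.frames.
#' @param schema A [feature_schema()].
#' @param outcome Name of the binary outcome column.
#' @param k Target feature count.
#' @param methods Named list mapping method labels to functions
#'   `function(train, schema, outcome, k)` returning feature vectors;
#'   defaults to one representative per family.
#' @param seed Seed passed to the evaluators.
#' @return A data.frame with one row per method.
#' @export
benchmark_selectors <- function(train, test, schema, outcome, k,
                                methods = NULL, seed = 1) {
  if (is.null(methods)) {
    methods <- list(
      `filter/IG` = function(tr, sc, oc, k)
        filter_select(tr, sc, oc, "IG", k),
      `filter/MRMR` = function(tr, sc, oc, k)
        filter_select(tr, sc, oc, "MRMR", k),
      `wrapper/SFS` = function(tr, sc, oc, k)
        wrapper_select(tr, sc, oc, "SFS", k, seed = seed),
      `embedded/L1` = function(tr, sc, oc, k)
        embedded_select(tr, sc, oc, "L1", k, seed = seed),
      `hybrid/IG-SFS` = function(tr, sc, oc, k)
        hybrid_select(tr, sc, oc, "IG", "SFS", pre_k = 2 * k, k = k,
                      seed = seed))
  }
  rows <- lapply(names(methods), function(nm) {
    fs <- methods[[nm]](train, schema, outcome, k)
    rep <- suppressWarnings(
      evaluate_classifiers(train, test, fs, outcome, seed = seed))
    data.frame(method = nm, n_features = length(fs),
               precision = rep$mean[["precision"]],
               recall = rep$mean[["recall"]], f1 = rep$mean[["f1"]],
               f1_variance = rep$variance[["f1"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
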