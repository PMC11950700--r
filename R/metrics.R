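#' Maximal information coefficient (MIC)
#'
#' Measures the strength of any linear or nonlinear association between
#' two variables on a 0-1 scale, via the characteristic-matrix
#' approximation: one axis is equipartitioned, the other optimized by
#' dynamic programming over clumps, over all grids `p x q` with
#' `p * q <= n^alpha`. Both orientations are scanned, so the score is
#' exactly symmetric in its arguments and deterministic for fixed input.
#'
#' @param x,y Numeric vectors of equal length (at least 10).
#' @param alpha Grid-size exponent, bounding grids by `n^alpha`
#'   (default 0.6).
#' @param clump_factor Maximum clumps per axis bin before superclump
#'   merging (default 15).
#' @return MIC score in `[0, 1]`. A constant input yields 0 with a
#'   warning.
#' @examples
#' x <- seq(-1, 1, length.out = 100)
#' compute_mic(x, x^2)  # 1: noiseless functional relation
#' @export
compute_mic <- function(x, y, alpha = 0.6, clump_factor = 15) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("compute_mic requires at least 10 observations")
  if (length(unique(x)) <= 1 || length(unique(y)) <= 1) {
    warning("constant input; MIC undefined, returning 0")
    return(0)
  }
  .mic_cpp(as.numeric(x), as.numeric(y), alpha, as.integer(clump_factor))
}

# Gini impurity of a binary label vector.
gini_impurity <- function(y) {
  p <- mean(y == 1)
  1 - p^2 - (1 - p)^2
}

#' Gini-impurity relevance (1 - GI)
#'
#' Computes the split-weighted Gini impurity of the binary outcome under
#' the partition induced by the feature, and returns its complement so
#' that, like the other relevance metrics, higher means more relevant.
#' Features with at most two distinct values partition by value;
#' continuous features use the single best threshold over midpoints of
#' sorted unique values (a decision-stump split).
#'
#' @param x Numeric feature vector.
#' @param y Binary outcome vector coded 0/1.
#' @return `1 - GI` in `[0, 1]`. A constant feature induces no partition
#'   and returns `1 - impurity(y)` with a warning.
#' @export
compute_gini_relevance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ux <- sort(unique(x))
  n <- length(y)
  if (length(ux) <= 1) {
    warning("constant feature; uninformative partition")
    return(1 - gini_impurity(y))
  }
  weighted_gini <- function(groups) {
    sum(vapply(groups, function(idx) length(idx) / n * gini_impurity(y[idx]),
               numeric(1)))
  }
  gi <- if (length(ux) == 2) {
    weighted_gini(split(seq_len(n), x == ux[2]))
  } else {
    mids <- (ux[-1] + ux[-length(ux)]) / 2
    min(vapply(mids, function(th) {
      weighted_gini(split(seq_len(n), x > th))
    }, numeric(1)))
  }
  1 - gi
}

# Shannon entropy in bits of a discrete vector.
entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# Equal-frequency discretization used for information-theoretic metrics
# on continuous features; features with few unique values are kept as-is.
discretize_ef <- function(x, bins = 10) {
  ux <- unique(x)
  if (length(ux) <= bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Information gain of an outcome given a feature
#'
#' Expected reduction in outcome entropy (log base 2, so the result is in
#' bits and bounded by 1 for a binary outcome) from partitioning records
#' by the feature. Continuous features are discretized by equal-frequency
#' binning with `min(10, #unique)` bins.
#'
#' @param x Numeric feature vector.
#' @param y Binary outcome vector coded 0/1.
#' @param bins Maximum number of equal-frequency bins (default 10).
#' @return Information gain in bits, `0 <= IG <= H(y)`.
#' @export
compute_info_gain <- function(x, y, bins = 10) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) <= 1) return(0)
  xb <- discretize_ef(x, bins)
  hy <- entropy_bits(y)
  hy_given <- sum(vapply(split(y, xb, drop = TRUE), function(g) {
    length(g) / length(y) * entropy_bits(g)
  }, numeric(1)))
  max(hy - hy_given, 0)
}

#' Type-aware absolute correlation score
#'
#' Pearson correlation for two continuous variables, point-biserial
#' correlation for a continuous/binary pair, and the phi coefficient for
#' two binary variables — all three reduce to the Pearson correlation of
#' the suitably 0/1-coded vectors, and the absolute value is returned so
#' the score always lies in `[0, 1]`.
#'
#' @param x,y Numeric vectors (binary variables coded 0/1).
#' @param x_kind,y_kind `"continuous"` or `"binary"`; retained for
#'   interface clarity and validation.
#' @return `|r|` in `[0, 1]`; zero-variance input returns 0 with a
#'   warning (correlation undefined).
#' @export
compute_correlation_score <- function(x, y, x_kind = "continuous",
                                      y_kind = "binary") {
  stopifnot(length(x) == length(y))
  kinds <- c("continuous", "binary")
  if (!x_kind %in% kinds || !y_kind %in% kinds)
    stop("kinds must be 'continuous' or 'binary'")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance input; correlation undefined, returning 0")
    return(0)
  }
  abs(stats::cor(x, y))
}

#' Score every candidate feature against one outcome
#'
#' Computes the four stage-1A relevance metrics — MIC, 1-GI, IG and CS —
#' between each non-outcome, non-identifier feature and the named binary
#' outcome. Per-metric warnings are collected into a log attached as the
#' `"log"` attribute.
#'
#' @param table Preprocessed (imputed, encoded) cohort data.frame.
#' @param schema A [feature_schema()].
#' @param outcome Name of the outcome column.
#' @return A data.frame with columns `feature`, `mic`, `one_minus_gi`,
#'   `ig`, `cs`, one row per candidate feature in table column order.
#' @export
score_all_features <- function(table, schema, outcome) {
  if (length(schema_columns(schema, "categorical")))
    stop("categorical features present; run encode_categoricals() first")
  feats <- intersect(candidate_features(schema), names(table))
  y <- table[[outcome]]
  if (!is_binary01(y)) stop("outcome '", outcome, "' must be binary 0/1")
  log <- character()
  one <- function(f) {
    x <- table[[f]]
    kind <- if (schema$columns[[f]] == "binary") "binary" else "continuous"
    withCallingHandlers(
      c(mic = compute_mic(x, y),
        one_minus_gi = compute_gini_relevance(x, y),
        ig = compute_info_gain(x, y),
        cs = compute_correlation_score(x, y, kind, "binary")),
      warning = function(w) {
        log <<- c(log, paste0(f, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  sc <- t(vapply(feats, one, numeric(4)))
  out <- data.frame(feature = feats, sc, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "outcome") <- outcome
  attr(out, "log") <- log
  out
}
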