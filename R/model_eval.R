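#' Append clinically mandated features to a selected list
#'
#' Domain experts may mandate features (for example sex, current age and
#' age at diagnosis) that must appear in every final feature list. Any
#' mandated feature not already selected is appended in the given order;
#' the list may exceed the target size N after the overlay.
#'
#' @param features Selected feature list.
#' @param mandated Character vector of mandated features.
#' @param table The cohort table; every mandated feature must be one of
#'   its columns.
#' @return The feature list with absent mandated features appended; the
#'   appended names are recorded in the `"expert_added"` attribute.
#' @export
apply_expert_overlay <- function(features, mandated, table) {
  missing <- setdiff(mandated, names(table))
  if (length(missing))
    stop("mandated feature(s) not in table: ", paste(missing, collapse = ", "))
  added <- setdiff(mandated, features)
  structure(c(features, added), expert_added = added)
}

#' Evaluate a feature list with the three downstream classifiers
#'
#' Fits logistic regression, Gaussian naive Bayes and k-nearest
#' neighbors (k = 5) on the training data restricted to the selected
#' features, and reports precision, recall and F1 of the positive class
#' on the test data, plus the cross-classifier mean and variance of each
#' score. A classifier predicting no positives yields precision 0 by
#' convention (with a warning).
#'
#' @param train,test Data.frames sharing the feature columns.
#' @param features Feature columns to use.
#' @param outcome Name of the binary outcome column.
#' @param knn_k Neighbors for the kNN classifier (default 5).
#' @param seed Seed for kNN tie-breaking.
#' @return An object of class `evaluation_report`: a list with `scores`
#'   (data.frame classifier x precision/recall/f1), `mean`, `variance`,
#'   `outcome` and `features`.
#' @export
evaluate_classifiers <- function(train, test, features, outcome,
                                 knn_k = 5, seed = 1) {
  ytr <- train[[outcome]]
  yte <- test[[outcome]]
  if (length(unique(ytr)) < 2)
    stop("training outcome '", outcome, "' has a single class")
  Xtr <- train[features]
  Xte <- test[features]

  fit_df <- cbind(Xtr, .y = ytr)
  lr <- suppressWarnings(stats::glm(.y ~ ., data = fit_df,
                                    family = stats::binomial()))
  p_lr <- as.numeric(suppressWarnings(
    stats::predict(lr, newdata = Xte, type = "response")) > 0.5)

  nb <- e1071::naiveBayes(Xtr, factor(ytr, levels = c(0, 1)))
  p_nb <- as.numeric(as.character(stats::predict(nb, Xte)))

  p_knn <- withr::with_seed(seed, {
    as.numeric(as.character(
      class::knn(Xtr, Xte, factor(ytr, levels = c(0, 1)), k = knn_k)))
  })

  preds <- list(`logistic regression` = p_lr, `naive Bayes` = p_nb,
                `k-nearest neighbors` = p_knn)
  scores <- do.call(rbind, lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    if (!any(p == 1))
      warning(nm, " predicted no positives; precision set to 0")
    data.frame(classifier = nm,
               precision = precision_score(p, yte),
               recall = recall_score(p, yte),
               f1 = f1_score(p, yte),
               stringsAsFactors = FALSE)
  }))
  num <- c("precision", "recall", "f1")
  structure(list(scores = scores,
                 mean = vapply(scores[num], mean, numeric(1)),
                 variance = vapply(scores[num], stats::var, numeric(1)),
                 outcome = outcome, features = features),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> outcome:", x$outcome, "\n")
  print(x$scores, row.names = FALSE)
  cat(sprintf("mean F1 %.3f (variance %.4f) over %d classifiers\n",
              x$mean[["f1"]], x$variance[["f1"]], nrow(x$scores)))
  invisible(x)
}

# Flatten an evaluation report into the Table-1-style CSV layout.
report_to_df <- function(report, method = "2-stage") {
  data.frame(outcome = report$outcome, method = method,
             metric = c("precision", "recall", "f1"),
             logistic_regression = as.numeric(report$scores[1, -1]),
             naive_bayes = as.numeric(report$scores[2, -1]),
             knn = as.numeric(report$scores[3, -1]),
             mean = as.numeric(report$mean),
             variance = as.numeric(report$variance),
             stringsAsFactors = FALSE)
}
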