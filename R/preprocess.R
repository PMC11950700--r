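#' Impute missing cells by group-wise mean or mode
#'
#' Missing values are replaced by the mean (continuous features) or mode
#' (binary/categorical features) of the same feature among records that
#' share the schema's imputation-group key values (for example cancer
#' type, age range and biological sex). When a record's group has no
#' observed value for the feature, or when a record is missing one of its
#' own group-key values, the global mean/mode is used instead and a
#' warning is raised.
#'
#' @param table Cohort data.frame; missing cells are `NA`.
#' @param schema A [feature_schema()].
#' @return The table with no missing cells in feature columns.
#' @export
impute_missing <- function(table, schema) {
  keys <- intersect(schema$impute_groups, names(table))
  feats <- candidate_features(schema)
  feats <- setdiff(feats, keys)
  for (col in schema_columns(schema, "outcome"))
    if (anyNA(table[[col]]))
      stop("outcome column '", col, "' has missing values; records without ",
           "an observed outcome cannot be imputed")

  key_na <- if (length(keys)) {
    Reduce(`|`, lapply(keys, function(k) is.na(table[[k]])))
  } else rep(FALSE, nrow(table))
  if (any(key_na))
    warning(sum(key_na), " record(s) missing a group-key value; ",
            "falling back to global statistics for them")
  group_id <- if (length(keys)) {
    interaction(table[keys], drop = TRUE, lex.order = TRUE)
  } else factor(rep(1L, nrow(table)))

  for (col in feats) {
    v <- table[[col]]
    if (!anyNA(v)) next
    if (all(is.na(v)))
      stop("feature '", col, "' is entirely missing; cannot impute")
    continuous <- schema$columns[[col]] == "continuous"
    stat <- if (continuous) function(z) mean(z, na.rm = TRUE) else mode_value
    global <- stat(v)
    miss <- which(is.na(v))
    for (i in miss) {
      if (key_na[i]) {
        v[i] <- global
        next
      }
      donors <- v[group_id == group_id[i] & !is.na(v)]
      v[i] <- if (length(donors)) stat(donors) else global
    }
    table[[col]] <- v
  }
  table
}

#' One-hot encode categorical features
#'
#' Categorical columns with L > 2 levels are replaced by L binary
#' indicator columns named `<column>_<level>`; 2-level columns collapse
#' to a single 0/1 column whose sorted second level codes as 1 (so a
#' sex column with levels F/M codes M as 1 and F as 0). Single-level
#' columns carry no information and are dropped with a warning.
#'
#' @param table Imputed cohort data.frame.
#' @param schema A [feature_schema()].
#' @return A list with the encoded `table` and the updated `schema`.
#' @export
encode_categoricals <- function(table, schema) {
  cols <- schema$columns
  for (col in schema_columns(schema, "categorical")) {
    lev <- sort(unique(as.character(table[[col]])))
    if (length(lev) < 2) {
      warning("categorical feature '", col, "' has a single level; dropped")
      table[[col]] <- NULL
      cols <- cols[names(cols) != col]
      next
    }
    if (length(lev) == 2) {
      table[[col]] <- as.numeric(as.character(table[[col]]) == lev[2])
      cols[[col]] <- "binary"
      next
    }
    pos <- match(col, names(table))
    ind <- lapply(lev, function(l) as.numeric(as.character(table[[col]]) == l))
    names(ind) <- paste0(col, "_", gsub("[^[:alnum:]_]", "_", lev))
    table <- cbind(table[seq_len(pos - 1)], as.data.frame(ind),
                   table[seq_len(ncol(table))[-seq_len(pos)]])
    at <- match(col, names(cols))
    newk <- stats::setNames(rep("binary", length(ind)), names(ind))
    cols <- append(cols[-at], newk, after = at - 1)
  }
  list(table = table, schema = feature_schema(cols, schema$impute_groups))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-adjusted skewness and kurtosis z statistics
#' into K-squared = Z_skew^2 + Z_kurt^2, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires at least 8
#' observations for the skewness transformation to be defined.
#'
#' @param x Numeric vector.
#' @return A list with `statistic` (K-squared) and `p.value`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson_test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("constant input")
  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  yy <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(yy / alpha + sqrt((yy / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
               ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Assess normality of a continuous feature by a 2-of-3 vote
#'
#' Runs the Shapiro-Wilk test, a one-sample Kolmogorov-Smirnov test
#' against a Gaussian with the sample mean and SD, and the
#' D'Agostino-Pearson omnibus test. The verdict is `"normal"` when at
#' least 2 of the 3 tests fail to reject normality at `alpha`.
#'
#' @param values Numeric vector of continuous values.
#' @param alpha Per-test significance level (default 0.05).
#' @return A list with `verdict` (`"normal"`, `"non-normal"` or
#'   `"degenerate"`) and `p_values` (shapiro, ks, dagostino).
#' @export
assess_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  p <- c(shapiro = NA_real_, ks = NA_real_, dagostino = NA_real_)
  if (length(unique(values)) <= 1)
    return(list(verdict = "degenerate", p_values = p))
  if (length(values) < 8) {
    warning("fewer than 8 observations; treating feature as non-normal")
    return(list(verdict = "non-normal", p_values = p))
  }
  p["shapiro"] <- stats::shapiro.test(values)$p.value
  p["ks"] <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  p["dagostino"] <- dagostino_pearson_test(values)$p.value
  verdict <- if (sum(p >= alpha) >= 2) "normal" else "non-normal"
  list(verdict = verdict, p_values = p)
}

#' Normalize continuous features by normality verdict
#'
#' Continuous features judged normal by [assess_normality()] are z-scored
#' (mean removed, unit variance); all other continuous features are
#' min-max scaled to `[0, 1]`. Binary columns are left untouched
#' (min-max on 0/1 indicators is the identity). Constant features are
#' dropped with a warning. Scaling parameters are recorded so the same
#' transform can be replayed on held-out data with
#' [apply_normalization()].
#'
#' @param table Encoded cohort data.frame with no missing cells.
#' @param schema A [feature_schema()].
#' @param alpha Significance level passed to [assess_normality()].
#' @return A list with `table`, updated `schema`, and `params` — a named
#'   list per feature with `method` (`"z-score"` or `"min-max"`), its
#'   parameters, and the normality verdict and p-values.
#' @export
normalize_features <- function(table, schema, alpha = 0.05) {
  params <- list()
  cols <- schema$columns
  for (col in schema_columns(schema, "continuous")) {
    v <- table[[col]]
    res <- assess_normality(v, alpha = alpha)
    if (res$verdict == "degenerate") {
      warning("constant feature '", col, "' dropped during normalization")
      table[[col]] <- NULL
      cols <- cols[names(cols) != col]
      next
    }
    if (res$verdict == "normal") {
      ctr <- mean(v); scl <- stats::sd(v)
      table[[col]] <- (v - ctr) / scl
      params[[col]] <- list(method = "z-score", center = ctr, scale = scl,
                            verdict = res$verdict, p_values = res$p_values)
    } else {
      lo <- min(v); hi <- max(v)
      table[[col]] <- (v - lo) / (hi - lo)
      params[[col]] <- list(method = "min-max", min = lo, max = hi,
                            verdict = res$verdict, p_values = res$p_values)
    }
  }
  list(table = table, schema = feature_schema(cols, schema$impute_groups),
       params = params)
}

#' Replay recorded normalization parameters on new data
#'
#' @param table Data.frame sharing the columns the parameters were fit on.
#' @param params The `params` element returned by [normalize_features()].
#' @return The transformed table (values may fall outside `[0, 1]` for
#'   min-max features whose new values exceed the training range).
#' @export
apply_normalization <- function(table, params) {
  for (col in names(params)) {
    if (!col %in% names(table)) next
    p <- params[[col]]
    table[[col]] <- if (p$method == "z-score") {
      (table[[col]] - p$center) / p$scale
    } else {
      (table[[col]] - p$min) / (p$max - p$min)
    }
  }
  table
}

#' Balance classes with SMOTE-NC oversampling
#'
#' Oversamples the minority class of a binary outcome until both classes
#' have equal counts, using the mixed-type variant of synthetic minority
#' oversampling. Distances between minority records are Euclidean over
#' continuous features, plus `med^2` added once per differing nominal
#' feature, where `med` is the median of the minority-class standard
#' deviations of the continuous features. Each synthetic record
#' interpolates continuous values at a uniform random fraction along the
#' segment from a minority record to one of its `k` nearest minority
#' neighbors, and sets nominal values by majority vote among those `k`
#' neighbors. Original records are preserved verbatim.
#'
#' @param table Normalized cohort data.frame containing `outcome`.
#' @param schema A [feature_schema()].
#' @param outcome Name of the binary outcome column to balance on.
#' @param k_neighbors Number of minority nearest neighbors (default 5).
#' @param seed Integer seed controlling neighbor and gap draws.
#' @return The table with synthetic minority rows appended.
#' @export
balance_smote_nc <- function(table, schema, outcome, k_neighbors = 5, seed = 1) {
  y <- table[[outcome]]
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("outcome '", outcome, "' has a single class; cannot balance")
  minority <- as.numeric(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min == n_maj) return(table)
  if (n_min < 2) stop("minority class has fewer than 2 records")
  k <- k_neighbors
  if (n_min < k + 1) {
    k <- n_min - 1
    warning("minority class smaller than k+1; k reduced to ", k)
  }

  cont <- schema_columns(schema, "continuous")
  cont <- intersect(cont, names(table))
  nom <- setdiff(names(table), c(cont, schema_columns(schema, "identifier")))
  min_idx <- which(y == minority)
  Xc <- as.matrix(table[min_idx, cont, drop = FALSE])
  Xn <- as.matrix(as.data.frame(lapply(table[min_idx, nom, drop = FALSE], as.character)))

  med2 <- if (length(cont)) {
    stats::median(apply(Xc, 2, stats::sd))^2
  } else 1  # all-nominal table: unit mismatch penalty

  m <- length(min_idx)
  d2 <- matrix(0, m, m)
  for (i in seq_len(m)) {
    dc <- sweep(Xc, 2, Xc[i, ], "-")
    d2[i, ] <- rowSums(dc^2) + med2 * rowSums(Xn != rep(Xn[i, ], each = m))
  }
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))

  n_syn <- n_maj - n_min
  synth <- withr::with_seed(seed, {
    base <- sample.int(m, n_syn, replace = TRUE)
    rows <- vector("list", n_syn)
    for (s in seq_len(n_syn)) {
      b <- base[s]
      neigh <- nn[b, ]
      pick <- neigh[sample.int(k, 1)]
      u <- stats::runif(1)
      row <- table[min_idx[b], , drop = FALSE]
      row[cont] <- as.list(Xc[b, ] + u * (Xc[pick, ] - Xc[b, ]))
      for (cn in nom) {
        votes <- table[min_idx[neigh], cn]
        row[[cn]] <- mode_value(votes)
      }
      row[[outcome]] <- minority
      rows[[s]] <- row
    }
    do.call(rbind, rows)
  })
  ids <- schema_columns(schema, "identifier")
  for (id in intersect(ids, names(synth)))
    synth[[id]] <- paste0("syn_", seq_len(nrow(synth)))
  out <- rbind(table, synth)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Partitions records into disjoint, exhaustive train and test sets with
#' `round(n * train_fraction)` training records, stratified by the
#' binary outcome so both classes appear on each side whenever their
#' counts permit.
#'
#' @param table Cohort data.frame.
#' @param outcome Name of the binary outcome column to stratify on.
#' @param train_fraction Proportion of records assigned to training
#'   (strictly between 0 and 1; the motivating study used 0.696, i.e.
#'   71 of 102 records).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A list with data.frames `train` and `test`.
#' @export
split_train_test <- function(table, outcome, train_fraction, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  y <- table[[outcome]]
  n <- nrow(table)
  n_train <- round(n * train_fraction)
  classes <- sort(unique(y))
  # per-class allocation by largest remainder, summing exactly to n_train
  sizes <- vapply(classes, function(c) sum(y == c), numeric(1))
  exact <- sizes * n_train / n
  take <- floor(exact)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(y == classes[i])
      sample(idx, take[i])
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  for (c in classes) {
    if (!any(y[train_idx] == c) || !any(y[test_idx] == c))
      warning("class ", c, " absent from one side of the split")
  }
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}
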