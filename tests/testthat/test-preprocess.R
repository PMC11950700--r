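test_that("group-wise imputation fills means/modes within the record's group", {
  tab <- data.frame(
    type = c("ALL", "ALL", "ALL", "AML", "AML"),
    sex = c("M", "M", "M", "F", "F"),
    f = c(2, 4, NA, 10, NA),
    b = c(1, 1, NA, 0, 0),
    outcome = c(0, 1, 0, 1, 0))
  schema <- feature_schema(
    c(type = "categorical", sex = "categorical", f = "continuous",
      b = "binary", outcome = "outcome"),
    impute_groups = c("type", "sex"))
  out <- impute_missing(tab, schema)
  expect_equal(out$f[3], 3)   # mean of {2, 4} in group ALL/M
  expect_equal(out$f[5], 10)  # single donor in group AML/F
  expect_equal(out$b[3], 1)   # group mode
  expect_false(anyNA(out))
})

test_that("imputation is the identity on complete tables and errors on empty features", {
  tab <- toy_cohort(20)
  expect_identical(impute_missing(tab, toy_schema()), tab)
  tab$signal <- NA_real_
  expect_error(impute_missing(tab, toy_schema()), "signal")
})

test_that("imputed values match a brute-force per-group oracle under MCAR", {
  withr::with_seed(99, {
    n <- 100
    tab <- data.frame(
      grp = sample(c("a", "b", "c"), n, replace = TRUE),
      x1 = rnorm(n), x2 = rnorm(n),
      outcome = rbinom(n, 1, 0.5))
    full <- tab
    for (col in c("x1", "x2")) tab[[col]][runif(n) < 0.10] <- NA
  })
  schema <- feature_schema(c(grp = "categorical", x1 = "continuous",
                             x2 = "continuous", outcome = "outcome"),
                           impute_groups = "grp")
  out <- impute_missing(tab, schema)
  for (col in c("x1", "x2")) {
    for (i in which(is.na(tab[[col]]))) {
      donors <- tab[[col]][tab$grp == tab$grp[i]]
      expect_equal(out[[col]][i], mean(donors, na.rm = TRUE))
    }
  }
})

test_that("one-hot encoding maps 2-level to one 0/1 column and L levels to L indicators", {
  tab <- data.frame(sex = c("M", "F", "M"), grp = c("a", "b", "c"),
                    x = c(1, 2, 3), outcome = c(0, 1, 0))
  schema <- feature_schema(c(sex = "categorical", grp = "categorical",
                             x = "continuous", outcome = "outcome"))
  enc <- encode_categoricals(tab, schema)
  expect_equal(enc$table$sex, c(1, 0, 1))  # M -> 1, F -> 0
  expect_identical(unname(enc$schema$columns[["sex"]]), "binary")
  ind <- enc$table[c("grp_a", "grp_b", "grp_c")]
  expect_true(all(rowSums(ind) == 1))
  # no categoricals: unchanged
  tab2 <- toy_cohort(10)
  enc2 <- encode_categoricals(tab2, toy_schema())
  expect_identical(enc2$table, tab2)
  # single level dropped with warning
  tab$grp <- "only"
  expect_warning(enc3 <- encode_categoricals(tab, schema), "single level")
  expect_false("grp" %in% names(enc3$table))
})

test_that("D'Agostino-Pearson omnibus test matches the reference implementation", {
  x1 <- qnorm((1:50 - 0.5) / 50)
  x2 <- qexp((1:50 - 0.5) / 50)
  r1 <- dagostino_pearson_test(x1)
  r2 <- dagostino_pearson_test(x2)
  # frozen from an independent implementation of the omnibus K^2 test
  expect_equal(r1$statistic, 0.0055909308, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.9972084383, tolerance = 1e-8)
  expect_equal(r2$statistic, 24.6873001932, tolerance = 1e-8)
  expect_equal(r2$p.value, 4.3573e-06, tolerance = 1e-4)
})

test_that("the 2-of-3 normality vote has the stated size and power", {
  verdicts <- vapply(1:100, function(s) {
    withr::with_seed(s, assess_normality(rnorm(500))$verdict)
  }, character(1))
  expect_gte(mean(verdicts == "normal"), 0.95)
  verdicts <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, assess_normality(rexp(500))$verdict)
  }, character(1))
  expect_gte(mean(verdicts == "non-normal"), 0.95)
  expect_identical(assess_normality(rep(1, 20))$verdict, "degenerate")
  expect_warning(v <- assess_normality(c(1, 2, 3, 4, 5))$verdict, "non-normal")
  expect_identical(v, "non-normal")
})

test_that("normalization z-scores normal features and min-max scales the rest", {
  withr::with_seed(5, {
    tab <- data.frame(gauss = rnorm(200), unif = runif(200),
                      flag = rbinom(200, 1, 0.4),
                      konst = rep(2, 200),
                      outcome = rbinom(200, 1, 0.5))
  })
  schema <- schema_for(tab)
  schema$columns[["konst"]] <- "continuous"
  expect_warning(nor <- normalize_features(tab, schema), "constant")
  expect_false("konst" %in% names(nor$table))
  expect_equal(mean(nor$table$gauss), 0, tolerance = 1e-9)
  expect_equal(sd(nor$table$gauss), 1, tolerance = 1e-9)
  expect_identical(nor$params$gauss$method, "z-score")
  expect_equal(range(nor$table$unif), c(0, 1))
  expect_identical(nor$params$unif$method, "min-max")
  expect_identical(nor$table$flag, tab$flag)  # binary untouched
  # each continuous feature gets exactly one method, matching its verdict
  for (p in nor$params) {
    expect_identical(p$method,
                     if (p$verdict == "normal") "z-score" else "min-max")
  }
  # recorded parameters replay exactly on the same data
  replay <- apply_normalization(tab[names(nor$table)], nor$params)
  expect_equal(replay$gauss, nor$table$gauss)
  expect_equal(replay$unif, nor$table$unif)
})

test_that("SMOTE-NC balances classes, preserves originals, and respects parents", {
  withr::with_seed(8, {
    n <- 71
    tab <- data.frame(
      c1 = rnorm(n), c2 = runif(n),
      b1 = rbinom(n, 1, 0.3), b2 = rbinom(n, 1, 0.6),
      outcome = c(rep(0, 61), rep(1, 10)))
  })
  schema <- schema_for(tab)
  bal <- balance_smote_nc(tab, schema, "outcome", k_neighbors = 5, seed = 2)
  expect_equal(as.numeric(table(bal$outcome)), c(61, 61))
  # originals preserved verbatim, in order (rbind may promote int to dbl)
  expect_equal(bal[seq_len(nrow(tab)), ], tab, ignore_attr = TRUE)
  # synthetic continuous values lie within the minority coordinate range;
  # synthetic nominal values occur among minority values (vote of neighbors)
  syn <- bal[-seq_len(nrow(tab)), ]
  minod <- tab[tab$outcome == 1, ]
  for (col in c("c1", "c2")) {
    expect_true(all(syn[[col]] >= min(minod[[col]]) - 1e-12))
    expect_true(all(syn[[col]] <= max(minod[[col]]) + 1e-12))
  }
  for (col in c("b1", "b2"))
    expect_true(all(syn[[col]] %in% minod[[col]]))
  expect_true(all(syn$outcome == 1))
})

test_that("SMOTE-NC nominal votes agree with a brute-force neighbor search", {
  withr::with_seed(31, {
    tab <- data.frame(c1 = rnorm(40), c2 = rnorm(40),
                      b1 = rbinom(40, 1, 0.5),
                      outcome = c(rep(0, 30), rep(1, 10)))
  })
  schema <- schema_for(tab)
  k <- 3
  bal <- balance_smote_nc(tab, schema, "outcome", k_neighbors = k, seed = 7)
  syn <- bal[-seq_len(nrow(tab)), ]
  minod <- tab[tab$outcome == 1, ]
  med2 <- median(apply(minod[c("c1", "c2")], 2, sd))^2
  # brute-force: for each synthetic row, its continuous parent pair must be
  # a (base, one-of-k-nearest) pair, and b1 the majority among those k
  for (i in seq_len(nrow(syn))) {
    ok <- FALSE
    for (b in seq_len(nrow(minod))) {
      d2 <- sapply(seq_len(nrow(minod)), function(j) {
        sum((minod[j, c("c1", "c2")] - minod[b, c("c1", "c2")])^2) +
          med2 * (minod$b1[j] != minod$b1[b]) +
          med2 * (minod$outcome[j] != minod$outcome[b])
      })
      d2[b] <- Inf
      nn <- order(d2)[seq_len(k)]
      vote <- as.numeric(names(which.max(table(minod$b1[nn]))))
      for (p in nn) {
        lo <- pmin(minod[b, c("c1", "c2")], minod[p, c("c1", "c2")])
        hi <- pmax(minod[b, c("c1", "c2")], minod[p, c("c1", "c2")])
        if (all(syn[i, c("c1", "c2")] >= lo - 1e-9) &&
            all(syn[i, c("c1", "c2")] <= hi + 1e-9) &&
            syn$b1[i] %in% minod$b1[nn]) ok <- TRUE
      }
    }
    expect_true(ok)
  }
})

test_that("SMOTE-NC errors on degenerate class structure", {
  tab <- data.frame(c1 = rnorm(10), outcome = rep(1, 10))
  expect_error(balance_smote_nc(tab, schema_for(tab), "outcome"), "single class")
  tab$outcome <- c(rep(0, 9), 1)
  expect_error(balance_smote_nc(tab, schema_for(tab), "outcome"), "fewer than 2")
  tab$outcome <- c(rep(0, 7), 1, 1, 1)
  expect_warning(balance_smote_nc(tab, schema_for(tab), "outcome",
                                  k_neighbors = 5, seed = 1),
                 "k reduced to 2")
})

test_that("the stratified split reproduces the study arithmetic and is seeded", {
  tab <- data.frame(x = rnorm(102), outcome = rep(c(0, 1), c(76, 26)))
  sp <- split_train_test(tab, "outcome", 0.696, seed = 4)
  expect_equal(nrow(sp$train), 71)
  expect_equal(nrow(sp$test), 31)
  expect_equal(nrow(sp$train) + nrow(sp$test), 102)
  sp2 <- split_train_test(tab, "outcome", 0.696, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(tab, "outcome", 0.696, seed = 5)
  expect_false(identical(rownames(sp$train), rownames(sp3$train)))
  expect_error(split_train_test(tab, "outcome", 1.0), "strictly between")
  # partition property across n and fractions; both classes on both sides
  for (frac in c(0.5, 0.696, 0.8)) {
    sp <- split_train_test(tab, "outcome", frac, seed = 1)
    expect_equal(nrow(sp$train), round(102 * frac))
    expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(tab))
    expect_true(all(c(0, 1) %in% sp$train$outcome))
    expect_true(all(c(0, 1) %in% sp$test$outcome))
  }
})
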