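# Independent brute-force oracle for the MIC estimator at small n:
# same scheme (equipartition one axis, optimize the other, both
# orientations, grids bounded by n^0.6) but the optimized axis is
# searched exhaustively over all contiguous point partitions instead of
# the clump dynamic program. n must be divisible by every q and values
# distinct so the equipartition is unambiguous.
bf_mic <- function(x, y) {
  n <- length(x)
  B <- floor(n^0.6)
  H <- function(cnt) { p <- cnt[cnt > 0] / sum(cnt); -sum(p * log(p)) }
  best <- 0
  one_orient <- function(x, y) {
    for (q in 2:floor(B / 2)) {
      lmax <- floor(B / q)
      if (lmax < 2) next
      Q <- integer(n)
      Q[order(y)] <- rep(seq_len(q), each = n / q)
      hq <- H(table(Q))
      Qx <- Q[order(x)]
      for (l in 2:lmax) {
        cuts <- utils::combn(n - 1, l - 1)
        for (j in seq_len(ncol(cuts))) {
          bounds <- c(0, cuts[, j], n)
          hqp <- 0
          for (b in seq_len(l)) {
            idx <- (bounds[b] + 1):bounds[b + 1]
            hqp <- hqp + length(idx) / n * H(table(Qx[idx]))
          }
          best <<- max(best, (hq - hqp) / log(min(l, q)))
        }
      }
    }
  }
  one_orient(x, y)
  one_orient(y, x)
  min(best, 1)
}

test_that("MIC equals the exhaustive-partition oracle on small fixtures", {
  for (s in 1:6) {
    withr::with_seed(s, {
      x <- rnorm(24)
      y <- switch(1 + s %% 3, rnorm(24), x^2 + rnorm(24, sd = 0.3),
                  sin(3 * x) + rnorm(24, sd = 0.1))
    })
    expect_equal(compute_mic(x, y), bf_mic(x, y), tolerance = 1e-9,
                 label = paste("seed", s))
  }
})

test_that("MIC is 1 for deterministic relations and symmetric in its arguments", {
  x <- as.numeric(1:100)
  expect_equal(compute_mic(x, x), 1.0)
  xg <- seq(-1, 1, length.out = 100)
  expect_gte(compute_mic(xg, xg^2), 0.99)
  withr::with_seed(2, {
    a <- rnorm(80); b <- a^3 + rnorm(80, sd = 0.2)
  })
  expect_identical(compute_mic(a, b), compute_mic(b, a))
  expect_warning(v <- compute_mic(rep(1, 50), rnorm(50)), "constant")
  expect_identical(v, 0)
  expect_error(compute_mic(1:5, 1:5), "at least 10")
})

test_that("MIC of independent variables stays below 0.25 almost always", {
  v <- vapply(1:100, function(s) {
    withr::with_seed(s, compute_mic(runif(500), runif(500)))
  }, numeric(1))
  expect_gte(mean(v < 0.25), 0.95)
})

test_that("relevance metrics are invariant under order-preserving rescaling", {
  withr::with_seed(10, {
    x <- rnorm(100)
    y <- rbinom(100, 1, plogis(1.5 * x))
  })
  x2 <- 3 * x + 7  # strictly increasing affine
  expect_equal(compute_mic(x, y), compute_mic(x2, y), tolerance = 1e-9)
  expect_equal(compute_mic(x, y), compute_mic(exp(x), y), tolerance = 0.05)
  expect_equal(compute_gini_relevance(x, y), compute_gini_relevance(x2, y))
  expect_equal(compute_info_gain(x, y), compute_info_gain(x2, y))
  expect_equal(compute_correlation_score(x, y),
               compute_correlation_score(x2, y), tolerance = 1e-12)
})

test_that("Gini relevance matches analytic impurities", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(compute_gini_relevance(y, y), 1.0)        # pure partition
  x <- rep(c(0, 1, 0, 1), each = 25)                     # independent balanced
  expect_equal(compute_gini_relevance(x, y), 0.5)
  xc <- c(rnorm(50, -3), rnorm(50, 3))                   # separable threshold
  expect_equal(compute_gini_relevance(xc, y), 1.0)
  expect_warning(v <- compute_gini_relevance(rep(2, 100), y), "constant")
  expect_equal(v, 1 - 0.5)
})

test_that("information gain matches plug-in entropy hand-computations", {
  y <- rep(c(0, 1), each = 4)
  expect_equal(compute_info_gain(y, y), 1.0)             # IG = H(y) = 1 bit
  x <- rep(c(0, 1), 4)                                   # independent
  expect_equal(compute_info_gain(x, y), 0.0)
  # contingency [[3,1],[1,3]]: H(y)=1, H(y|x)=H(1/4)=0.8113 -> IG = 0.1887
  x <- c(0, 0, 0, 1, 0, 1, 1, 1)
  hand <- 1 - (-0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_equal(compute_info_gain(x, y), hand, tolerance = 1e-9)
  expect_equal(compute_info_gain(x, y), 0.18872, tolerance = 1e-4)
  # IG bounded by H(y) on random fixtures; 1-GI in [0.5, 1] for binary y
  for (s in 1:10) {
    withr::with_seed(s, {
      xr <- rnorm(60); yr <- rbinom(60, 1, 0.5)
    })
    p <- mean(yr)
    hy <- -p * log2(p) - (1 - p) * log2(1 - p)
    expect_lte(compute_info_gain(xr, yr), hy + 1e-12)
    g <- compute_gini_relevance(xr, yr)
    expect_gte(g, 0.5); expect_lte(g, 1)
  }
})

test_that("the correlation score covers all three type branches", {
  x <- rnorm(50)
  expect_equal(compute_correlation_score(x, x, "continuous", "continuous"), 1.0)
  b <- rep(c(0, 1), 25)
  expect_equal(compute_correlation_score(b, 1 - b, "binary", "binary"), 1.0)
  # point-biserial equals Pearson with the 0/1 dummy
  x <- as.numeric(1:6); y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(compute_correlation_score(x, y, "continuous", "binary"),
               0.8783101, tolerance = 1e-6)
  for (s in 1:10) {
    withr::with_seed(s, {
      xc <- rnorm(40); yb <- rbinom(40, 1, 0.5)
    })
    expect_identical(compute_correlation_score(xc, yb, "continuous", "binary"),
                     abs(cor(xc, yb)))
  }
  expect_warning(v <- compute_correlation_score(rep(1, 20), rnorm(20)), "zero-variance")
  expect_identical(v, 0)
  expect_error(compute_correlation_score(x, y, "ordinal", "binary"), "kinds")
})

test_that("score_all_features returns one deterministic row of 4 scores per candidate", {
  tab <- toy_cohort(60)
  sc <- score_all_features(tab, toy_schema(), "outcome")
  expect_identical(sc$feature, c("signal", "noise1", "noise2", "flag"))
  expect_identical(names(sc), c("feature", "mic", "one_minus_gi", "ig", "cs"))
  expect_true(all(sc$mic >= 0 & sc$mic <= 1))
  expect_true(all(sc$cs >= 0 & sc$cs <= 1))
  expect_true(all(sc$ig >= 0 & sc$ig <= 1))  # binary outcome: <= 1 bit
  # duplicated feature columns get identical rows
  tab$signal2 <- tab$signal
  schema <- toy_schema()
  schema$columns <- c(schema$columns, signal2 = "continuous")
  sc2 <- score_all_features(tab, schema, "outcome")
  expect_equal(unlist(sc2[sc2$feature == "signal2", -1]),
               unlist(sc2[sc2$feature == "signal", -1]))
  # the planted signal feature dominates noise on CS
  expect_identical(sc$feature[which.max(sc$cs)], "signal")
})

test_that("a planted linear effect outranks noise on CS across generator seeds", {
  hits <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(
      n = 500, n_continuous = 10, n_binary = 0,
      planted = data.frame(name = "rel", type = "linear", effect = 1.5,
                           partner = NA, stringsAsFactors = FALSE),
      redundant = default_redundant()[0, ], missing_rate = 0, seed = s))
    tab <- co$table
    cs <- vapply(setdiff(names(tab), c("id", "outcome")), function(f)
      abs(cor(tab[[f]], tab$outcome)), numeric(1))
    names(which.max(cs)) == "rel"
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
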