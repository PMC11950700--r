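# Build a metric score table directly, bypassing the metric computations,
# so voting and ranking bookkeeping can be checked against hand-derived
# membership patterns.
score_table <- function(features, mic, gi, ig, cs) {
  data.frame(feature = features, mic = mic, one_minus_gi = gi, ig = ig,
             cs = cs, stringsAsFactors = FALSE)
}

test_that("take_top_n keeps the n best per metric with column-order tie-breaks", {
  sc <- score_table(c("a", "b", "c"),
                    mic = c(0.9, 0.5, 0.1), gi = c(0.5, 0.9, 0.1),
                    ig = c(0.2, 0.1, 0.9), cs = c(0.9, 0.1, 0.5))
  top <- take_top_n(sc, 2)
  expect_identical(top$F_MIC, c("a", "b"))
  expect_identical(top$F_1_GI, c("b", "a"))
  expect_identical(top$F_IG, c("c", "a"))
  # tie: earlier column wins
  sc2 <- score_table(c("a", "b"), mic = c(0.5, 0.5), gi = c(0.5, 0.5),
                     ig = c(0.5, 0.5), cs = c(0.5, 0.5))
  expect_identical(take_top_n(sc2, 1)$F_MIC, "a")
  expect_error(take_top_n(sc2, 3), "exceeds")
  # four lists of 15 carry 60 entries with duplicates
  sc3 <- score_table(sprintf("f%02d", 1:40), runif(40), runif(40),
                     runif(40), runif(40))
  top3 <- take_top_n(sc3, 15)
  expect_length(unlist(top3[c("F_MIC", "F_1_GI", "F_CS", "F_IG")]), 60)
})

test_that("vote tallies match a brute-force membership scan on random lists", {
  for (s in 1:20) {
    withr::with_seed(s, {
      sc <- score_table(sprintf("f%02d", 1:30), runif(30), runif(30),
                        runif(30), runif(30))
    })
    top <- take_top_n(sc, 10)
    res <- tally_votes(top)
    lists <- top[c("F_MIC", "F_1_GI", "F_CS", "F_IG")]
    for (f in sc$feature) {
      cnt <- sum(vapply(lists, function(l) f %in% l, logical(1)))
      expect_identical(f %in% res$three_plus, cnt >= 3)
      expect_identical(f %in% res$two, cnt == 2)
    }
    expect_length(intersect(res$three_plus, res$two), 0)
    expect_setequal(res$pool, c(res$three_plus, res$two))
    expect_true(all(res$votes >= 2))
    expect_true(all(res$rank >= 1))
  }
})

test_that("average rank follows the worked bookkeeping", {
  sc <- score_table(sprintf("f%02d", 1:10), 10:1 / 10, 10:1 / 10,
                    10:1 / 10, 10:1 / 10)
  top <- take_top_n(sc, 9)
  # positions 1, 9, 1, 9 average to 5
  top$F_MIC <- c("x", top$F_MIC[-9])[c(2:9, 1)]  # craft positions directly
  top$F_MIC <- sc$feature[c(1, 3:9, 10)]  # f01 at 1, f10 at 9
  top$F_1_GI <- sc$feature[c(10, 2:8, 1)] # f10 at 1, f01 at 9
  top$F_CS <- top$F_MIC
  top$F_IG <- top$F_1_GI
  expect_equal(average_rank("f01", top), 5)
  expect_equal(average_rank("f10", top), 5)
  # a feature at position p in all four lists has rank p
  same <- top
  same$F_1_GI <- same$F_CS <- same$F_IG <- same$F_MIC
  expect_equal(average_rank("f03", same), match("f03", same$F_MIC))
  # mean over containing lists only
  top$F_CS <- sc$feature[2:10]
  expect_equal(average_rank("f02", top),
               mean(c(match("f02", top$F_MIC), match("f02", top$F_1_GI),
                      match("f02", top$F_CS), match("f02", top$F_IG)),
                    na.rm = TRUE))
  expect_error(average_rank("zz", top), "no top list")
  # all4 variant scores absences at N + 1
  top2 <- take_top_n(sc, 3)
  expect_equal(average_rank("f04", top2, rank_over = "all4"), 4)
})

test_that("exact duplicate columns are pruned down to a single survivor", {
  withr::with_seed(3, {
    y <- rep(c(0, 1), 50)
    x <- y + rnorm(100, sd = 0.4)
    tab <- data.frame(a = x, b = x, c = rnorm(100), d = rnorm(100),
                      e = rnorm(100), outcome = y)
  })
  s1 <- suppressWarnings(run_stage1(tab, schema_for(tab), "outcome", n = 3,
                                    max_retries = 0))
  expect_equal(sum(c("a", "b") %in% s1$pool), 1)
  expect_equal(nrow(s1$removals), 1)
})

test_that("pruning removes by votes, then by worse rank, deterministically", {
  withr::with_seed(9, {
    y <- rep(c(0, 1), 60)
    base <- y + rnorm(120, sd = 0.6)
    tab <- data.frame(a = base, b = base + rnorm(120, sd = 0.005),
                      c = rnorm(120), outcome = y)
  })
  schema <- schema_for(tab)
  sc <- score_all_features(tab, schema, "outcome")
  top <- take_top_n(sc, 2)
  res <- tally_votes(top)
  pruned <- prune_redundant(res, tab, schema)
  expect_equal(nrow(pruned$removals), 1)
  removed <- pruned$removals$removed
  kept <- pruned$removals$kept
  if (res$votes[[kept]] == res$votes[[removed]]) {
    expect_gte(res$rank[[removed]], res$rank[[kept]])
    expect_identical(pruned$removals$reason, "worse average rank")
  } else {
    expect_lt(res$votes[[removed]], res$votes[[kept]])
  }
  # identical inputs give identical removals
  pruned2 <- prune_redundant(res, tab, schema)
  expect_identical(pruned$removals, pruned2$removals)
  # no surviving pair is jointly redundant
  ps <- pruned$pair_stats
  surv <- ps[ps$a %in% pruned$pool & ps$b %in% pruned$pool, ]
  expect_false(any(surv$one_minus_mic < 0.05 & surv$one_minus_cs < 0.05))
})

test_that("planted copy pairs are detected and singly removed across seeds", {
  hits <- vapply(1:25, function(s) {
    co <- generate_cohort(cohort_spec(
      n = 100, n_continuous = 8, n_binary = 0,
      planted = data.frame(name = "rel", type = "linear", effect = 1.5,
                           partner = NA, stringsAsFactors = FALSE),
      redundant = data.frame(name = "rel_copy", source = "rel",
                             transform = "copy", noise_sd = 0.01,
                             stringsAsFactors = FALSE),
      missing_rate = 0, seed = 200 + s))
    s1 <- suppressWarnings(run_stage1(co$table, co$schema, "outcome", n = 4,
                                      max_retries = 0))
    sum(c("rel", "rel_copy") %in% s1$pool) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("run_stage1 trims oversized 3-metric sets and retries thin pools", {
  # several correlated informative features: many collect >= 3 votes, so
  # the 3-metric set exceeds n and must be trimmed to the n best ranks
  withr::with_seed(21, {
    y <- rep(c(0, 1), 60)
    tab <- data.frame(lapply(1:6, function(j) y * (7 - j) / 4 + rnorm(120)),
                      outcome = y)
    names(tab)[1:6] <- sprintf("g%d", 1:6)
  })
  s1 <- suppressWarnings(run_stage1(tab, schema_for(tab), "outcome", n = 3,
                                    max_retries = 0))
  expect_lte(length(s1$three_plus), 3)
  # degenerate 4-feature table with n = 3: depth retry fires and is logged
  withr::with_seed(22, {
    tab2 <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40),
                       d = rnorm(40), outcome = rep(c(0, 1), 20))
  })
  s2 <- suppressWarnings(run_stage1(tab2, schema_for(tab2), "outcome", n = 3))
  expect_gte(s2$depth, 3)
  expect_error(run_stage1(tab2, schema_for(tab2), "outcome", n = 10), "exceeds")
})

test_that("independent features are almost never flagged redundant", {
  flags <- vapply(1:100, function(s) {
    withr::with_seed(400 + s, {
      y <- rep(c(0, 1), 50)
      tab <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100),
                        d = rnorm(100), outcome = y)
    })
    schema <- schema_for(tab)
    sc <- score_all_features(tab, schema, "outcome")
    top <- take_top_n(sc, 4)
    res <- tally_votes(top)
    pr <- suppressWarnings(prune_redundant(res, tab, schema))
    nrow(pr$removals) > 0
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})
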