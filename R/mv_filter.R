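#' Top-N features per relevance metric
#'
#' Sorts the candidate features by each of the four stage-1A metrics in
#' descending score order and keeps the top `n` per metric. Score ties
#' are broken by original column order, so results are deterministic on
#' small cohorts where ties happen.
#'
#' @param scores A metric score table from [score_all_features()].
#' @param n Features to keep per metric (the domain experts' target
#'   count; the motivating study used 15).
#' @return An object of class `top_lists` with ordered character vectors
#'   `F_MIC`, `F_1_GI`, `F_CS`, `F_IG`, each of length `n`. Their
#'   concatenation with duplicates (`F_UNION`) has `4 * n` entries.
#' @export
take_top_n <- function(scores, n) {
  if (n > nrow(scores))
    stop("n (", n, ") exceeds the number of candidate features (",
         nrow(scores), ")")
  pick <- function(metric) {
    ord <- order(-scores[[metric]], seq_len(nrow(scores)))
    scores$feature[ord[seq_len(n)]]
  }
  structure(list(F_MIC = pick("mic"), F_1_GI = pick("one_minus_gi"),
                 F_CS = pick("cs"), F_IG = pick("ig"),
                 n = n, scores = scores),
            class = "top_lists")
}

#' @export
print.top_lists <- function(x, ...) {
  cat("<top_lists> top", x$n, "features per metric;",
      length(unique(unlist(x[c("F_MIC", "F_1_GI", "F_CS", "F_IG")]))),
      "distinct features overall\n")
  invisible(x)
}

top_list_names <- c("F_MIC", "F_1_GI", "F_CS", "F_IG")
metric_of_list <- c(F_MIC = "mic", F_1_GI = "one_minus_gi",
                    F_CS = "cs", F_IG = "ig")

#' Average rank position of a feature across the metric lists
#'
#' The mean 1-based position of the feature over the top-N lists that
#' contain it (`rank_over = "containing"`, the default), or over all
#' four lists with absent features counted at position `N + 1`
#' (`rank_over = "all4"`).
#'
#' @param feature Feature name.
#' @param top A [take_top_n()] result.
#' @param rank_over `"containing"` or `"all4"`.
#' @return The average position (>= 1). A feature in no list is an error.
#' @export
average_rank <- function(feature, top, rank_over = c("containing", "all4")) {
  rank_over <- match.arg(rank_over)
  pos <- vapply(top_list_names, function(l) {
    p <- match(feature, top[[l]])
    if (is.na(p) && rank_over == "all4") p <- top$n + 1
    as.numeric(p)
  }, numeric(1))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stop("feature '", feature, "' appears in no top list")
  mean(pos)
}

#' Tally metric votes into the stage-1 feature sets
#'
#' Partitions the features of the four top-N lists by how many metrics
#' selected them: `three_plus` (at least 3 of 4, highly likely relevant),
#' `two` (exactly 2, candidates for the stage-2 subset search), and their
#' duplicate-free union `pool`. Features selected by a single metric are
#' discarded (and logged). Also records per-feature vote counts, average
#' rank positions, and the scores of the selecting metrics (used later
#' for the unified metric values of the radial charts).
#'
#' @param top A [take_top_n()] result.
#' @param rank_over Passed to [average_rank()].
#' @return An object of class `stage1_result`.
#' @export
tally_votes <- function(top, rank_over = "containing") {
  lists <- top[top_list_names]
  all_feats <- unique(unlist(lists))
  votes <- vapply(all_feats, function(f) {
    sum(vapply(lists, function(l) f %in% l, logical(1)))
  }, integer(1))
  # keep the score-table order for determinism
  all_feats <- intersect(top$scores$feature, all_feats)
  votes <- votes[all_feats]
  three_plus <- all_feats[votes[all_feats] >= 3]
  two <- all_feats[votes[all_feats] == 2]
  dropped <- all_feats[votes[all_feats] == 1]
  pool <- c(three_plus, two)
  rank <- vapply(pool, average_rank, numeric(1), top = top,
                 rank_over = rank_over)
  selecting_scores <- lapply(stats::setNames(pool, pool), function(f) {
    sel <- vapply(top_list_names, function(l) f %in% top[[l]], logical(1))
    row <- top$scores[top$scores$feature == f, , drop = FALSE]
    vapply(metric_of_list[top_list_names[sel]], function(m) row[[m]],
           numeric(1))
  })
  structure(list(three_plus = three_plus, two = two, pool = pool,
                 votes = votes[pool], rank = rank,
                 selecting_scores = selecting_scores,
                 top = top,
                 removals = data.frame(kept = character(),
                                       removed = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE),
                 log = if (length(dropped))
                   paste0("discarded single-metric feature(s): ",
                          paste(dropped, collapse = ", "))
                 else character()),
            class = "stage1_result")
}

#' @export
print.stage1_result <- function(x, ...) {
  cat("<stage1_result>\n",
      " selected by >=3 metrics: ", length(x$three_plus), " feature(s)\n",
      " selected by exactly 2:   ", length(x$two), " feature(s)\n",
      " redundancy removals:     ", nrow(x$removals), "\n", sep = "")
  invisible(x)
}

#' Prune redundant feature pairs from the stage-1 pool
#'
#' For every unordered pair in the pool, computes `1 - MIC` and
#' `1 - CS`; a pair with both below `threshold` is redundant. Redundant
#' pairs are processed in ascending `(1-MIC) + (1-CS)` order (most
#' redundant first), skipping pairs whose member was already removed.
#' The member selected by fewer metrics is removed; on equal votes the
#' one with the worse (numerically larger) average rank; if still tied,
#' the later table column, with a warning.
#'
#' @param result A [tally_votes()] result.
#' @param table The preprocessed table the scores were computed on.
#' @param schema A [feature_schema()].
#' @param threshold Redundancy threshold on both complement scores
#'   (default 0.05, the value fixed by preliminary experimental
#'   analysis in the motivating study).
#' @return The updated `stage1_result` with disjoint `three_plus`
#'   (F_3M+) and `two` (F_2M) and a `removals` record.
#' @export
prune_redundant <- function(result, table, schema, threshold = 0.05) {
  pool <- result$pool
  if (!length(pool)) stop("empty stage-1 pool")
  if (length(pool) < 2) return(result)
  pairs <- utils::combn(pool, 2)
  kind <- function(f) if (schema$columns[[f]] == "binary") "binary" else "continuous"
  stats_df <- data.frame(a = pairs[1, ], b = pairs[2, ],
                         one_minus_mic = NA_real_, one_minus_cs = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    stats_df$one_minus_mic[i] <- 1 - compute_mic(table[[a]], table[[b]])
    stats_df$one_minus_cs[i] <-
      1 - suppressWarnings(compute_correlation_score(table[[a]], table[[b]],
                                                     kind(a), kind(b)))
  }
  red <- stats_df[stats_df$one_minus_mic < threshold &
                    stats_df$one_minus_cs < threshold, , drop = FALSE]
  red <- red[order(red$one_minus_mic + red$one_minus_cs), , drop = FALSE]

  removed <- character()
  removals <- result$removals
  col_pos <- match(pool, result$top$scores$feature)
  names(col_pos) <- pool
  for (i in seq_len(nrow(red))) {
    a <- red$a[i]; b <- red$b[i]
    if (a %in% removed || b %in% removed) next
    va <- result$votes[[a]]; vb <- result$votes[[b]]
    if (va != vb) {
      drop <- if (va < vb) a else b
      reason <- "fewer metric votes"
    } else if (result$rank[[a]] != result$rank[[b]]) {
      drop <- if (result$rank[[a]] > result$rank[[b]]) a else b
      reason <- "worse average rank"
    } else {
      drop <- if (col_pos[[a]] > col_pos[[b]]) a else b
      reason <- "tie on votes and rank; later column removed"
      warning("redundant pair (", a, ", ", b,
              ") tied on votes and rank; removing later column '", drop, "'")
    }
    keep <- setdiff(c(a, b), drop)
    removed <- c(removed, drop)
    removals <- rbind(removals,
                      data.frame(kept = keep, removed = drop, reason = reason,
                                 stringsAsFactors = FALSE))
  }
  result$three_plus <- setdiff(result$three_plus, removed)
  result$two <- setdiff(result$two, removed)
  result$pool <- c(result$three_plus, result$two)
  result$votes <- result$votes[result$pool]
  result$rank <- result$rank[result$pool]
  result$selecting_scores <- result$selecting_scores[result$pool]
  result$removals <- removals
  result$pair_stats <- stats_df
  result
}

#' Run the full stage-1 multimetric majority-voting filter
#'
#' Orchestrates [take_top_n()], [tally_votes()], the pool-size checks
#' and [prune_redundant()]. If the pool before pruning is smaller than
#' `min_pool`, or the nonredundant pool after pruning is smaller than
#' `n`, the per-metric list depth is increased by `depth_step` and the
#' selection re-run (at most `max_retries` times, then a warning). If
#' more than `n` features carry three or more votes, the set is trimmed
#' to the `n` best average ranks.
#'
#' @param table Preprocessed cohort data.frame.
#' @param schema A [feature_schema()].
#' @param outcome Name of the binary outcome column.
#' @param n Target feature count (default 15).
#' @param threshold Redundancy threshold (default 0.05).
#' @param min_pool Minimum pre-pruning pool size before a re-run is
#'   triggered; defaults to `n`. (The motivating study's narrative
#'   mentions 25 at this checkpoint but compares against N = 15; set
#'   `min_pool = 25` for the literal variant.)
#' @param rank_over Passed to [average_rank()].
#' @param depth_step Per-metric depth increment on re-run (default 5).
#' @param max_retries Maximum re-runs (default 3).
#' @return A `stage1_result` with fields `three_plus` (F_3M+), `two`
#'   (F_2M), rank table, vote counts, selecting-metric scores, removal
#'   log and the final per-metric depth used.
#' @export
run_stage1 <- function(table, schema, outcome, n = 15, threshold = 0.05,
                       min_pool = n, rank_over = "containing",
                       depth_step = 5, max_retries = 3) {
  scores <- score_all_features(table, schema, outcome)
  if (n > nrow(scores))
    stop("n (", n, ") exceeds the number of candidate features (",
         nrow(scores), ")")
  depth <- n
  retries <- 0
  repeat {
    top <- take_top_n(scores, min(depth, nrow(scores)))
    result <- tally_votes(top, rank_over = rank_over)
    if (length(result$pool) < min_pool && retries < max_retries &&
        depth < nrow(scores)) {
      depth <- depth + depth_step
      retries <- retries + 1
      result$log <- c(result$log, sprintf(
        "pool of %d < min_pool %d; re-running with per-metric depth %d",
        length(result$pool), min_pool, depth))
      next
    }
    if (length(result$pool) < min_pool)
      warning("stage-1 pool (", length(result$pool),
              ") below min_pool after ", retries, " retries; proceeding")
    result <- prune_redundant(result, table, schema, threshold)
    if (length(result$pool) < n && retries < max_retries &&
        depth < nrow(scores)) {
      depth <- depth + depth_step
      retries <- retries + 1
      result$log <- c(result$log, sprintf(
        "nonredundant pool of %d < n; re-running with per-metric depth %d",
        length(result$pool), depth))
      next
    }
    if (length(result$pool) < n)
      warning("nonredundant stage-1 pool (", length(result$pool),
              ") smaller than n after ", retries, " retries; proceeding")
    break
  }
  if (length(result$three_plus) > n) {
    keep <- names(sort(result$rank[result$three_plus]))[seq_len(n)]
    trimmed <- setdiff(result$three_plus, keep)
    result$three_plus <- intersect(result$three_plus, keep)
    result$pool <- c(result$three_plus, result$two)
    result$log <- c(result$log, paste0(
      "trimmed ", length(trimmed), " worst-ranked feature(s) from F_3M+: ",
      paste(trimmed, collapse = ", ")))
  }
  result$depth <- depth
  result$scores <- scores
  result
}
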