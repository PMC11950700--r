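#' Configuration for an end-to-end pipeline run
#'
#' @param data,schema Paths to the cohort CSV and schema YAML (may be
#'   `NULL` when a table is passed to [run_pipeline()] directly).
#' @param outcomes Character vector of outcome columns to run; features
#'   are selected independently per outcome.
#' @param n Target feature count N expected by the domain experts
#'   (default 15).
#' @param mandated Clinically mandated features appended to every final
#'   list when absent (default sex, current age and age at diagnosis,
#'   matching the motivating study; mandated names missing from a
#'   cohort are skipped with a warning at run time).
#' @param redundancy_threshold Stage-1B threshold (default 0.05).
#' @param train_fraction Training fraction for the split (default
#'   0.696, i.e. 71 of 102 records).
#' @param k_neighbors SMOTE-NC neighbor count (default 5).
#' @param balance_after_split If `TRUE`, balancing is applied to the
#'   training data only, after the split; the default `FALSE` follows
#'   the framework's module order (balancer before splitter), which
#'   leaks synthetic points into the test set but matches the original
#'   design.
#' @param balance_column Optional second balancing pass keyed on this
#'   binary column (for example a minority sex), applied after outcome
#'   balancing; disabled by default.
#' @param normal_alpha Per-test significance level for the normality
#'   vote (default 0.05).
#' @param ddn A [ddn_config()] block for stage 2.
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param out_dir Output directory for run artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data = NULL, schema = NULL, outcomes, n = 15,
                       mandated = c("gender", "current_age", "age_at_diagnosis"),
                       redundancy_threshold = 0.05, train_fraction = 0.696,
                       k_neighbors = 5, balance_after_split = FALSE,
                       balance_column = NULL, normal_alpha = 0.05,
                       ddn = ddn_config(), seed = 1, out_dir = "runs") {
  stopifnot(n >= 1, redundancy_threshold > 0, redundancy_threshold < 1,
            length(outcomes) >= 1)
  structure(list(data = data, schema = schema, outcomes = outcomes, n = n,
                 mandated = mandated,
                 redundancy_threshold = redundancy_threshold,
                 train_fraction = train_fraction, k_neighbors = k_neighbors,
                 balance_after_split = balance_after_split,
                 balance_column = balance_column, normal_alpha = normal_alpha,
                 ddn = ddn, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage1_to_json <- function(stage1, path) {
  jsonlite::write_json(
    list(three_plus = stage1$three_plus, two = stage1$two,
         rank = as.list(stage1$rank), votes = as.list(stage1$votes),
         unified_scores = lapply(stage1$selecting_scores, as.list),
         removals = stage1$removals, depth = stage1$depth,
         log = stage1$log),
    path, auto_unbox = TRUE, digits = NA)
}

selection_to_json <- function(sel, path) {
  jsonlite::write_json(
    list(final_features = sel$final_features, baseline_f1 = sel$baseline_f1,
         best_subset = sel$best_subset, best_dropout = sel$best_dropout,
         best_f1 = sel$best_f1, stage2_skipped = sel$stage2_skipped,
         log = sel$log),
    path, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Run the full data-driven, clinical domain-guided pipeline
#'
#' Executes, per outcome: impute, encode, normalize, balance, split,
#' stage-1 majority-voting filter, stage-2 dropout-network subset
#' search, expert overlay, downstream classifier evaluation, unified
#' metric values, and radial chart rendering. All randomness derives
#' deterministically from the master seed, so identical configurations
#' reproduce identical results.
#'
#' @param config A [run_config()].
#' @param table,schema Optional in-memory cohort (otherwise loaded from
#'   `config$data` / `config$schema`).
#' @return Invisibly, a named list (one element per outcome) with the
#'   stage-1 result, selection result, final features, evaluation
#'   report and unified metric values; artifacts are written under
#'   `config$out_dir/<outcome>/` when `out_dir` is non-NULL.
#' @export
run_pipeline <- function(config, table = NULL, schema = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) {
    ds <- load_dataset(config$data, config$schema)
    table <- ds$table
    schema <- ds$schema
  }
  missing_out <- setdiff(config$outcomes, names(table))
  if (length(missing_out))
    stop("outcome column(s) not in table: ", paste(missing_out, collapse = ", "))

  results <- list()
  for (outcome in config$outcomes) {
    stage <- function(name) stage_seed(config$seed, paste0(outcome, "/", name))
    run_step <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", label, "' failed for outcome '", outcome,
             "': ", conditionMessage(e), call. = FALSE)
      })
    }
    tab <- run_step("impute", impute_missing(table, schema))
    enc <- run_step("encode", encode_categoricals(tab, schema))
    nor <- run_step("normalize",
                    normalize_features(enc$table, enc$schema,
                                       alpha = config$normal_alpha))
    sch <- nor$schema
    if (!config$balance_after_split) {
      bal <- run_step("balance",
                      balance_smote_nc(nor$table, sch, outcome,
                                       k_neighbors = config$k_neighbors,
                                       seed = stage("balance")))
      if (!is.null(config$balance_column))
        bal <- run_step("balance_column",
                        balance_smote_nc(bal, sch, config$balance_column,
                                         k_neighbors = config$k_neighbors,
                                         seed = stage("balance_column")))
      parts <- run_step("split",
                        split_train_test(bal, outcome, config$train_fraction,
                                         seed = stage("split")))
    } else {
      parts <- run_step("split",
                        split_train_test(nor$table, outcome,
                                         config$train_fraction,
                                         seed = stage("split")))
      parts$train <- run_step("balance",
                              balance_smote_nc(parts$train, sch, outcome,
                                               k_neighbors = config$k_neighbors,
                                               seed = stage("balance")))
    }
    stage1 <- run_step("stage1",
                       run_stage1(parts$train, sch, outcome, n = config$n,
                                  threshold = config$redundancy_threshold))
    ddn_cfg <- config$ddn
    ddn_cfg$seed <- stage("ddn")
    sel <- run_step("stage2",
                    select_final_features(parts$train, stage1$three_plus,
                                          stage1$two, outcome, config$n,
                                          config = ddn_cfg,
                                          rank = stage1$rank))
    mandated <- config$mandated
    absent <- setdiff(mandated, names(parts$train))
    if (length(absent)) {
      warning("mandated feature(s) not in this cohort, skipped: ",
              paste(absent, collapse = ", "))
      mandated <- setdiff(mandated, absent)
    }
    final <- run_step("overlay",
                      apply_expert_overlay(sel$final_features, mandated,
                                           parts$train))
    report <- run_step("evaluate",
                       suppressWarnings(
                         evaluate_classifiers(parts$train, parts$test, final,
                                              outcome,
                                              seed = stage("evaluate"))))
    uni <- run_step("unified",
                    unified_metric_values(stage1, final))

    if (!is.null(config$out_dir)) {
      dir <- file.path(config$out_dir, outcome)
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      stage1_to_json(stage1, file.path(dir, "stage1.json"))
      selection_to_json(sel, file.path(dir, "selection.json"))
      utils::write.csv(sel$subset_log, file.path(dir, "subset_log.csv"),
                       row.names = FALSE)
      utils::write.csv(report_to_df(report), file.path(dir, "report.csv"),
                       row.names = FALSE)
      run_step("chart", render_chart(radial_chart_spec(
        outcome, uni, path = file.path(dir, paste0(outcome, "_radial.svg")))))
      manifest <- list(
        seed = config$seed, outcome = outcome, n = config$n,
        redundancy_threshold = config$redundancy_threshold,
        train_fraction = config$train_fraction,
        k_neighbors = config$k_neighbors,
        balance_after_split = config$balance_after_split,
        normal_alpha = config$normal_alpha,
        ddn = unclass(ddn_cfg), mandated = config$mandated,
        package_version = as.character(utils::packageVersion("ddnselect")),
        r_version = R.version.string)
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
    results[[outcome]] <- list(stage1 = stage1, selection = sel,
                               final_features = final, report = report,
                               unified = uni,
                               normalization = nor$params)
  }
  invisible(results)
}
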