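# End-to-end orchestration: simulate or load a two-session cohort, extract
# the enabled metric features per session, screen them by permutation
# tests (with the coherence-specific reduction rules), run the
# classification benchmark, and write all artifacts with logged
# parameters and derived seeds.

#' Extract the feature table of a cohort
#'
#' One row per session observation; columns are the concatenated feature
#' rows of the enabled metrics. For the study's 14-network panel the
#' counts are 91 (sfc) + 315 (gc) + 1820 (wcoh) + 42 (egn) = 2268.
#'
#' @param x a [cohort].
#' @param metrics subset of `c("sfc", "gc", "wcoh", "egn")`.
#' @param gc_order VAR order for the GC features (`NULL` = BIC-selected
#'   per session).
#' @param gc_max_order order-selection bound.
#' @param wcoh_n_surrogates,wcoh_alpha surrogate count and pointwise level
#'   for the coherence significance masks.
#' @param egn_lambda ridge penalty of the EGN fit.
#' @param seed integer seed for the surrogate thresholds.
#' @param cache optional [new_threshold_cache] environment shared across
#'   calls (created internally otherwise).
#' @return a feature table.
#' @export
extract_features <- function(x, metrics = c("sfc", "gc", "wcoh", "egn"),
                             gc_order = NULL, gc_max_order = 5,
                             wcoh_n_surrogates = 300, wcoh_alpha = 0.05,
                             egn_lambda = 1e-3, seed = 1, cache = NULL) {
  stopifnot(inherits(x, "cohort"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  cache <- cache %||% new_threshold_cache()
  rows <- lapply(x$sessions, function(s) {
    parts <- list()
    if ("sfc" %in% metrics) parts$sfc <- sfc_features(s)
    if ("gc" %in% metrics)
      parts$gc <- gc_features(s, order = gc_order, max_order = gc_max_order)
    if ("wcoh" %in% metrics)
      parts$wcoh <- wcoh_features(s, n_surrogates = wcoh_n_surrogates,
                                  alpha = wcoh_alpha, seed = seed,
                                  cache = cache)
    if ("egn" %in% metrics) parts$egn <- ep_features(s, lambda = egn_lambda)
    unlist(unname(parts))
  })
  keys <- data.frame(
    subject_id = vapply(x$sessions, function(s) s$subject_id, character(1)),
    session_id = vapply(x$sessions, function(s) s$session_id, character(1)),
    group = vapply(x$sessions, function(s) s$group, character(1)),
    stringsAsFactors = FALSE)
  feature_table(keys, do.call(rbind, rows))
}

is_wcoh_name <- function(x) grepl("^(ip|ap|lead|lag)_", x)

#' Session-consistency permutation test on controls
#'
#' Compares control subjects' RS1 vs RS2 values of the given features with
#' the same two-sided permutation test used for the group screening; used
#' as reduction rule (i) for the coherence features (a feature that
#' fluctuates between a control's own sessions is not a trustworthy group
#' marker).
#'
#' @param rs1,rs2 session feature tables.
#' @param features features to test.
#' @param n_perm,seed permutation parameters.
#' @return results data.frame (feature, statistic, p).
#' @export
controls_session_consistency <- function(rs1, rs2, features, n_perm = 5000,
                                         seed = 1) {
  c1 <- rs1[rs1$group == "CONTROL", , drop = FALSE]
  c2 <- rs2[rs2$group == "CONTROL", , drop = FALSE]
  X <- rbind(feature_matrix(c1, features), feature_matrix(c2, features))
  perm_test_matrix(X, rep(c(TRUE, FALSE), c(nrow(c1), nrow(c2))), n_perm,
                   seed)
}

default_pipeline_config <- function() {
  list(simulate = TRUE, seed = 1, out_dir = "rsndyn-output",
       metrics = c("sfc", "gc", "wcoh", "egn"),
       simulate_args = list(n_aca = 10, n_control = 14, T = 208, dt = 2,
                            effects = TRUE),
       cohort = list(manifest = NULL, dt = 2),
       gc = list(order = NULL, max_order = 5),
       wcoh = list(n_surrogates = 300, alpha = 0.05),
       egn = list(lambda = 1e-3),
       selection = list(alpha = 0.05, strict_alpha = 0.01, n_perm = 5000),
       classify = list(algorithms = c("SVM", "LDA", "KNN", "DT")))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' @param path YAML file; missing fields fall back to package defaults.
#' @return a config list.
#' @export
read_pipeline_config <- function(path) {
  merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 sprintf(fmt, ...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> extract -> select -> classify -> report. Every
#' stochastic stage receives a seed derived from the master seed by stage
#' name, so re-runs with an identical configuration are byte-identical.
#' Artifacts written to `config$out_dir`: per-session feature tables, the
#' selection report with rule traces, the validation report (long CSV and
#' a wide layout with acc/sens/spec triplets per algorithm), a JSON
#' summary, a plain-text log, and an MD5 manifest of the outputs.
#'
#' @param config a config list (see [read_pipeline_config]) or a YAML
#'   path.
#' @param seed optional master-seed override.
#' @param out_dir optional output-directory override.
#' @return invisibly, a list with the feature tables, selection results,
#'   selected features, the validation report, and the best set-ups.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line(log_con, "pipeline start: seed=%d metrics=%s", config$seed,
           paste(config$metrics, collapse = ","))

  if (isTRUE(config$simulate)) {
    sa <- config$simulate_args
    bench <- gen_benchmark_dataset(seed = derive_seed(config$seed, "simulate"),
                                   n_aca = sa$n_aca, n_control = sa$n_control,
                                   T = sa$T, dt = sa$dt,
                                   effects = isTRUE(sa$effects))
    rs1_cohort <- bench$rs1; rs2_cohort <- bench$rs2
    log_line(log_con, "simulated benchmark cohort: %d + %d sessions",
             length(rs1_cohort), length(rs2_cohort))
  } else {
    if (is.null(config$cohort$manifest))
      stop_rsndyn("config$cohort$manifest is required when simulate = FALSE")
    full <- load_cohort(config$cohort$manifest, dt = config$cohort$dt)
    rs1_cohort <- cohort_session(full, "RS1")
    rs2_cohort <- cohort_session(full, "RS2")
    log_line(log_con, "loaded cohort from %s", config$cohort$manifest)
  }

  cache <- new_threshold_cache()
  tabs <- list()
  for (ses in c("RS1", "RS2")) {
    co <- if (ses == "RS1") rs1_cohort else rs2_cohort
    tabs[[ses]] <- extract_features(
      co, metrics = config$metrics, gc_order = config$gc$order,
      gc_max_order = config$gc$max_order,
      wcoh_n_surrogates = config$wcoh$n_surrogates,
      wcoh_alpha = config$wcoh$alpha, egn_lambda = config$egn$lambda,
      seed = derive_seed(config$seed, "wcoh-threshold"), cache = cache)
    write_feature_table(tabs[[ses]],
                        file.path(config$out_dir,
                                  sprintf("features_%s.csv", tolower(ses))))
    log_line(log_con, "extracted %s: %d observations x %d features", ses,
             nrow(tabs[[ses]]), length(feature_names(tabs[[ses]])))
  }

  selcfg <- config$selection
  sel1 <- select_features(tabs$RS1, alpha = selcfg$alpha,
                          n_perm = selcfg$n_perm,
                          seed = derive_seed(config$seed, "select:RS1"))
  sel2 <- select_features(tabs$RS2, alpha = selcfg$alpha,
                          n_perm = selcfg$n_perm,
                          seed = derive_seed(config$seed, "select:RS2"))
  feats <- feature_names(tabs$RS1)
  wcoh_feats <- feats[is_wcoh_name(feats)]
  selected <- union(sel1$selected, sel2$selected)
  reduction_trace <- NULL
  if (length(wcoh_feats)) {
    ctrl <- controls_session_consistency(
      tabs$RS1, tabs$RS2, wcoh_feats, n_perm = selcfg$n_perm,
      seed = derive_seed(config$seed, "select:controls"))
    red <- reduce_wcoh(sel1$results[is_wcoh_name(sel1$results$feature), ],
                       sel2$results[is_wcoh_name(sel2$results$feature), ],
                       ctrl, alpha = selcfg$alpha,
                       strict_alpha = selcfg$strict_alpha)
    selected <- union(setdiff(selected, wcoh_feats), red$selected)
    reduction_trace <- red$trace
    utils::write.csv(red$trace,
                     file.path(config$out_dir, "wcoh_reduction.csv"),
                     row.names = FALSE)
  }
  selected <- feats[feats %in% selected] # canonical order
  sel_report <- merge(sel1$results, sel2$results, by = "feature",
                      suffixes = c("_rs1", "_rs2"))
  sel_report$selected <- sel_report$feature %in% selected
  utils::write.csv(sel_report, file.path(config$out_dir, "selection.csv"),
                   row.names = FALSE)
  log_line(log_con, "selection: %d of %d features survive", length(selected),
           length(feats))

  report <- NULL; best <- NULL
  if (length(selected) >= 1) {
    specs <- stats::setNames(
      lapply(config$classify$algorithms, classifier_spec,
             seed = derive_seed(config$seed, "classify")),
      config$classify$algorithms)
    report <- validation_suite(tabs$RS1, tabs$RS2, specs, selected)
    best <- select_best(report)
    utils::write.csv(report,
                     file.path(config$out_dir, "validation_report.csv"),
                     row.names = FALSE)
    utils::write.csv(report_wide(report),
                     file.path(config$out_dir, "validation_report_wide.csv"),
                     row.names = FALSE)
    log_line(log_con, "best average accuracy: %.3f (%s)",
             max(best$avg_accuracy),
             best$algorithm[which.max(best$avg_accuracy)])
    jsonlite::write_json(
      list(seed = config$seed, n_selected = length(selected),
           selected = selected, best = best),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA)
  } else {
    log_line(log_con, "no features selected; classification skipped")
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("(pipeline\\.log|manifest\\.md5)$", outputs)]
  hashes <- tools::md5sum(outputs)
  writeLines(sprintf("%s  %s", hashes, basename(names(hashes))),
             file.path(config$out_dir, "manifest.md5"))
  log_line(log_con, "pipeline done")
  invisible(list(config = config, tables = tabs, selection = sel_report,
                 selected = selected, reduction = reduction_trace,
                 report = report, best = best))
}

#' Wide layout of a validation report
#'
#' Rows are the validation schemes plus the average; columns are
#' accuracy/sensitivity/specificity triplets per algorithm.
#'
#' @param report a `validation_report`.
#' @return a data.frame.
#' @export
report_wide <- function(report) {
  schemes <- c(VALIDATION_SCHEMES, "Average")
  out <- data.frame(scheme = schemes, stringsAsFactors = FALSE)
  for (alg in unique(report$algorithm)) {
    sub <- report[report$algorithm == alg, ]
    sub <- sub[match(schemes, sub$scheme), ]
    out[[paste0(alg, "_acc")]] <- sub$accuracy
    out[[paste0(alg, "_sens")]] <- sub$sensitivity
    out[[paste0(alg, "_spec")]] <- sub$specificity
  }
  out
}
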