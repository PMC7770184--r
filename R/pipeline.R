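#' Load a pipeline run configuration
#'
#' YAML configuration driving the pipeline stages. Recognised keys:
#' `seed`, `alpha`, `correction`, `t_variant`, `efficiency_mode`,
#' `bonferroni_family`, `classifier` (`cost`, `gamma`), paths
#' (`cohort_dir`, `out_dir`) and a `simulate` block holding
#' [synth_config()] fields (including a `planted_edges` list of
#' `{i, j, state, direction, delta}` entries and a `delta_coupling`
#' list).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# build a synth_config from the `simulate` block of a run config
config_from_block <- function(block, seed = NULL) {
  pe <- NULL
  if (!is.null(block$planted_edges)) {
    pe <- do.call(rbind, lapply(block$planted_edges, function(e)
      planted_edge(e$i, e$j, e$state,
                   if (is.null(e$direction)) "increase" else e$direction,
                   if (is.null(e$delta)) 0.4 else e$delta,
                   if (is.null(e$nc_level)) NA_real_ else e$nc_level)))
  }
  synth_config(
    n_controls = block$n_controls %||% 23L,
    n_patients = block$n_patients %||% 24L,
    n_rois = block$n_rois %||% 116L,
    n_timepoints = block$n_timepoints %||% 200L,
    base_correlation = block$base_correlation %||% 0.1,
    planted_edges = pe,
    delta_coupling = block$delta_coupling %||% list(),
    seed = seed %||% block$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate stage: write a synthetic cohort bundle
#'
#' @param config A [synth_config()], or a run-config list with a
#'   `simulate` block, or a YAML path.
#' @param out_dir Output directory for the bundle.
#' @return Invisibly, the bundle.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "synth_config"))
    config <- config_from_block(config$simulate %||% config, config$seed)
  message(sprintf("simulate: seed %d, %d controls + %d patients x 2, R=%d, T=%d",
                  config$seed, config$n_controls, config$n_patients,
                  config$n_rois, config$n_timepoints))
  bundle <- generate_cohort(config, out_dir)
  message(sprintf("simulate: wrote %d session files to %s",
                  length(bundle$sessions), out_dir))
  invisible(bundle)
}

#' Analyze stage: cohort directory to full results directory
#'
#' Sequences the pipeline on a cohort bundle: weighted connectome per
#' session (written as TSV), binarized networks, node metric table,
#' edge-state and node-metric-state classification, delta-vs-clinical
#' correlations on the non-unchanged edges, per-group frequency
#' matrices with unconnected-edge counts, and a summary JSON tying the
#' outputs together.
#'
#' @param cohort_dir Directory holding a cohort bundle (see
#'   [generate_cohort()]), or an in-memory bundle list.
#' @param out_dir Results directory (created).
#' @param alpha Significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param variant Two-sample t variant.
#' @param efficiency_mode Local-efficiency mode (see
#'   [local_efficiency()]).
#' @param family_m Optional Bonferroni family-size override.
#' @param write_connectomes Write per-session connectome TSVs (default
#'   TRUE).
#' @return Invisibly, a list with all computed tables and the summary.
#' @export
run_analyze <- function(cohort_dir, out_dir, alpha = 0.05,
                        correction = "bonferroni", variant = "welch",
                        efficiency_mode = "literal", family_m = NULL,
                        write_connectomes = TRUE) {
  bundle <- if (is.list(cohort_dir)) cohort_dir else read_cohort(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- study_design(bundle$design)
  message(sprintf("analyze: %d sessions, %d ROIs",
                  length(bundle$sessions),
                  ncol(bundle$sessions[[1L]]$values)))
  conns <- lapply(bundle$sessions, function(ts) fisher_z(compute_fc(ts)))
  if (write_connectomes) {
    cdir <- file.path(out_dir, "connectomes")
    dir.create(cdir, showWarnings = FALSE)
    for (key in names(conns))
      write_connectome_tsv(conns[[key]], file.path(cdir, paste0(key, ".tsv")))
  }
  nets <- lapply(conns, binarize_positive)

  metrics <- node_metric_table(nets, bundle$design, efficiency_mode)
  utils::write.csv(metrics, file.path(out_dir, "node_metrics.csv"),
                   row.names = FALSE)

  groups <- split(names(nets),
                  bundle$design$group[match(names(nets),
                    paste0(bundle$design$subject_id, "_",
                           bundle$design$session))])
  freq <- lapply(groups, function(keys) frequency_matrix(nets[keys]))
  unconnected <- vapply(freq, count_unconnected_edges, numeric(1))

  weights <- edge_weight_matrix(conns, design)
  edge_states <- classify_edge_states(weights, design, alpha = alpha,
                                      correction = correction,
                                      family_m = family_m,
                                      variant = variant)
  utils::write.csv(edge_states, file.path(out_dir, "edge_states.csv"),
                   row.names = FALSE)
  node_states <- classify_node_metric_states(metrics, design, alpha = alpha,
                                             correction = correction,
                                             family_m = family_m,
                                             variant = variant)
  utils::write.csv(node_states, file.path(out_dir, "node_metric_states.csv"),
                   row.names = FALSE)

  selected <- edge_states$feature[edge_states$state != "unchanged"]
  deltas <- delta_correlations(if (length(selected)) selected else NULL,
                               weights$baseline, weights$post,
                               bundle$clinical, design)
  if (!length(selected))
    deltas <- deltas[0, , drop = FALSE]
  utils::write.csv(deltas, file.path(out_dir, "delta_correlations.csv"),
                   row.names = FALSE)

  summary <- list(
    schema_version = 1L,
    parameters = list(alpha = alpha, correction = correction,
                      t_variant = variant,
                      efficiency_mode = efficiency_mode,
                      bonferroni_family = family_m %||% ncol(weights$nc)),
    n_sessions = length(bundle$sessions),
    n_edges = ncol(weights$nc),
    edge_state_counts = as.list(table(edge_states$state)),
    node_state_counts = as.list(table(node_states$state)),
    unconnected_edges = as.list(unconnected),
    delta_correlations = deltas[, c("feature", "score", "r", "p", "n")],
    files = c("node_metrics.csv", "edge_states.csv",
              "node_metric_states.csv", "delta_correlations.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  message(sprintf("analyze: edge states %s",
                  paste(names(summary$edge_state_counts),
                        unlist(summary$edge_state_counts),
                        sep = "=", collapse = ", ")))
  invisible(list(connectomes = conns, networks = nets, metrics = metrics,
                 edge_states = edge_states, node_states = node_states,
                 delta_correlations = deltas, frequency = freq,
                 summary = summary))
}

#' Classify stage: biomarker verification across cohorts
#'
#' Builds connectomes for a training and a held-out test cohort,
#' extracts the given edge features for one binary comparison, and runs
#' the RBF support-vector verification, writing the report JSON and ROC
#' CSV.
#'
#' @param train_dir,test_dir Cohort bundle directories (or in-memory
#'   bundles).
#' @param edges Edge feature names (`"roiA|roiB"`) or data frame with
#'   `roi_i`, `roi_j`.
#' @param comparison Length-2 character: the two condition labels to
#'   classify (`"NC"`, `"IBSbs"`, `"IBS1st"`).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config Classifier hyperparameters (see [train_validate()]).
#' @return Invisibly, the `classification_report`.
#' @export
run_classify <- function(train_dir, test_dir, edges,
                         comparison = c("NC", "IBSbs"), out_dir = NULL,
                         config = list()) {
  stopifnot(length(comparison) == 2L)
  load_side <- function(d) {
    bundle <- if (is.list(d)) d else read_cohort(d)
    key <- paste0(bundle$design$subject_id, "_", bundle$design$session)
    keep <- bundle$design$group %in% comparison
    conns <- lapply(bundle$sessions[key[keep]],
                    function(ts) fisher_z(compute_fc(ts)))
    extract_features(conns, edges, bundle$design$group[keep])
  }
  train <- load_side(train_dir)
  test <- load_side(test_dir)
  report <- train_validate(train, test, config)
  message(sprintf("classify %s vs %s: accuracy %.3f, AUC %.3f",
                  comparison[1L], comparison[2L], report$accuracy,
                  report$auc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(comparison = paste(comparison, collapse = "_vs_"),
           accuracy = report$accuracy, auc = report$auc,
           hyperparameters = report$hyperparameters,
           seed = report$seed,
           per_class_counts = as.list(table(test$label))),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$roc, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
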