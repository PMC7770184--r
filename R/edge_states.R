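#' Study design for a three-condition paired cohort
#'
#' Validates and indexes a design table: unpaired control sessions
#' (group `NC`, session `single`) and patients with exactly one
#' `baseline` (group `IBSbs`) and one `post` (group `IBS1st`) session
#' each.
#'
#' @param design Data frame with columns `subject_id`, `group`
#'   (`NC|IBSbs|IBS1st`), `session` (`single|baseline|post`) and
#'   optionally `file`.
#' @return Object of class `study_design`: the table plus `nc_ids` and
#'   `patient_ids`.
#' @export
study_design <- function(design) {
  need <- c("subject_id", "group", "session")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  if (!all(design$group %in% c("NC", "IBSbs", "IBS1st")))
    stop("unknown group label(s)")
  nc_ids <- unique(design$subject_id[design$group == "NC"])
  pat <- design[design$group != "NC", , drop = FALSE]
  patient_ids <- unique(pat$subject_id)
  for (id in patient_ids) {
    ses <- pat$session[pat$subject_id == id]
    if (!setequal(ses, c("baseline", "post")) || length(ses) != 2L)
      stop("patient ", id, " must have exactly one baseline and one post session")
  }
  structure(list(table = design, nc_ids = nc_ids, patient_ids = patient_ids),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d controls, %d patients (paired baseline/post)\n",
              length(x$nc_ids), length(x$patient_ids)))
  invisible(x)
}

#' Per-condition edge-weight matrices
#'
#' Extracts every unordered ROI pair's Fisher-z weight from each
#' session's weighted connectome and splits the sessions into the three
#' conditions. Patients' baseline and post rows are aligned by subject
#' id, so paired statistics can be computed row-wise.
#'
#' @param connectomes Named list of weighted connectome matrices, names
#'   `<subject_id>_<session>`.
#' @param design A [study_design()] or its underlying data frame.
#' @return List with matrices `nc` (controls x edges), `baseline` and
#'   `post` (patients x edges, rows aligned); columns named
#'   `"<roi_i>|<roi_j>"` with i < j in atlas order.
#' @export
edge_weight_matrix <- function(connectomes, design) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  first <- connectomes[[1L]]
  labs <- rownames(first)
  if (is.null(labs)) labs <- paste0("ROI", seq_len(nrow(first)))
  ut <- upper.tri(first)
  idx <- which(ut, arr.ind = TRUE)
  feat <- paste0(labs[idx[, 1L]], "|", labs[idx[, 2L]])
  pull <- function(ids, session) {
    keys <- paste0(ids, "_", session)
    miss <- setdiff(keys, names(connectomes))
    if (length(miss))
      stop("missing connectome(s) for session(s): ", paste(miss, collapse = ", "))
    m <- t(vapply(keys, function(k) unclass(as.matrix(connectomes[[k]]))[ut],
                  numeric(length(feat))))
    dimnames(m) <- list(ids, feat)
    m
  }
  list(nc = pull(design$nc_ids, "single"),
       baseline = pull(design$patient_ids, "baseline"),
       post = pull(design$patient_ids, "post"))
}

# shared three-comparison decision engine used for both edges and node
# metrics. nc/bs/po: condition x feature matrices, bs/po row-aligned.
classify_feature_states <- function(nc, bs, po, alpha = 0.05,
                                    correction = c("bonferroni", "none"),
                                    family_m = NULL,
                                    variant = c("welch", "pooled"),
                                    compute_anova = TRUE) {
  correction <- match.arg(correction)
  variant <- match.arg(variant)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (nrow(bs) != nrow(po) || !identical(rownames(bs), rownames(po)))
    stop("baseline and post rows must be aligned by patient")
  nf <- ncol(nc)
  m <- if (is.null(family_m)) nf else family_m
  res <- data.frame(feature = colnames(nc),
                    t1 = NA_real_, p1 = NA_real_,
                    t2 = NA_real_, p2 = NA_real_,
                    t3 = NA_real_, p3 = NA_real_,
                    F = NA_real_, pF = NA_real_,
                    mean_nc = colMeans(nc), mean_bs = colMeans(bs),
                    mean_post = colMeans(po),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (j in seq_len(nf)) {
    r1 <- two_sample_t(nc[, j], bs[, j], variant)
    r2 <- paired_t(bs[, j], po[, j])
    r3 <- two_sample_t(nc[, j], po[, j], variant)
    res$t1[j] <- r1$statistic; res$p1[j] <- r1$p
    res$t2[j] <- r2$statistic; res$p2[j] <- r2$p
    res$t3[j] <- r3$statistic; res$p3[j] <- r3$p
    if (compute_anova) {
      rf <- one_way_anova(list(nc[, j], bs[, j], po[, j]))
      res$F[j] <- rf$statistic; res$pF[j] <- rf$p
    }
  }
  adj <- function(p) if (correction == "bonferroni") bonferroni_adjust(p, m) else p
  res$p1_corr <- adj(res$p1)
  res$p2_corr <- adj(res$p2)
  res$p3_corr <- adj(res$p3)
  s1 <- res$p1_corr < alpha
  s2 <- res$p2_corr < alpha
  s3 <- res$p3_corr < alpha
  state <- rep("unchanged", nf)
  state[s1 & !s2] <- "disorder"
  state[s1 & s2 & !s3] <- "cured"
  state[!s1 & s2 & s3] <- "activated"
  res$state <- state
  dir_ref <- ifelse(state == "activated", res$mean_post, res$mean_bs)
  res$direction <- ifelse(state == "unchanged", NA_character_,
                          ifelse(dir_ref > res$mean_nc, "increase", "decrease"))
  cols <- c("feature", "t1", "p1", "p1_corr", "t2", "p2", "p2_corr",
            "t3", "p3", "p3_corr", "F", "pF",
            "mean_nc", "mean_bs", "mean_post", "state", "direction")
  res[, cols]
}

#' Classify every edge into disorder / cured / activated / unchanged
#'
#' For each edge, three comparisons are run on the Fisher-z weights:
#' controls vs patient baseline (two-sample), patient baseline vs post
#' (paired), controls vs patient post (two-sample). After the chosen
#' multiple-comparison correction within each comparison family, with
#' S(p) meaning corrected p < alpha, the edge state is
#'
#' * cured: S(p1) and S(p2) and not S(p3) — abnormal at baseline,
#'   changed by the intervention, back at the control level after;
#' * disorder: S(p1) and not S(p2) — abnormal at baseline and not
#'   changed by the intervention;
#' * activated: not S(p1) and S(p2) and S(p3) — normal at baseline,
#'   moved away from both baseline and control level after;
#' * unchanged: any other pattern.
#'
#' The omnibus one-way ANOVA across the three conditions is computed and
#' stored per edge but takes no part in the decision; users wanting an
#' ANOVA gate can filter on its `pF` column.
#'
#' @param weights Output of [edge_weight_matrix()] (or any list with
#'   row-aligned `nc`, `baseline`, `post` matrices).
#' @param design A [study_design()]; only used for validation when
#'   `weights` rows carry subject ids.
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` (within each comparison family) or
#'   `"none"`.
#' @param family_m Bonferroni family size; defaults to the number of
#'   features tested.
#' @param variant Two-sample t variant, `"welch"` (default) or
#'   `"pooled"`.
#' @param compute_anova Store the omnibus F/p per edge (default TRUE).
#' @return Data frame, one row per edge: the three t/p/p_corrected
#'   triples, omnibus F and p, condition means, `state` and
#'   `direction`.
#' @export
classify_edge_states <- function(weights, design = NULL, alpha = 0.05,
                                 correction = c("bonferroni", "none"),
                                 family_m = NULL,
                                 variant = c("welch", "pooled"),
                                 compute_anova = TRUE) {
  if (!is.null(design) && !inherits(design, "study_design"))
    design <- study_design(design)
  classify_feature_states(weights$nc, weights$baseline, weights$post,
                          alpha = alpha, correction = correction,
                          family_m = family_m, variant = variant,
                          compute_anova = compute_anova)
}

#' Classify node metrics into disorder / cured / activated / unchanged
#'
#' Applies the decision table of [classify_edge_states()] to each node's
#' degree, clustering coefficient and local efficiency. The Bonferroni
#' family is the set of nodes within one metric.
#'
#' @param metrics A [node_metric_table()] with `group` annotation.
#' @param design A [study_design()].
#' @inheritParams classify_edge_states
#' @param metric_names Metrics to classify.
#' @return Data frame as in [classify_edge_states()] plus `roi` and
#'   `metric` columns.
#' @export
classify_node_metric_states <- function(metrics, design, alpha = 0.05,
                                        correction = c("bonferroni", "none"),
                                        family_m = NULL,
                                        variant = c("welch", "pooled"),
                                        metric_names = c("degree", "clustering",
                                                         "local_efficiency"),
                                        compute_anova = TRUE) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  rois <- unique(metrics$roi)
  out <- lapply(metric_names, function(v) {
    grab <- function(ids, session) {
      sub <- metrics[metrics$session == session & metrics$subject_id %in% ids,
                     c("subject_id", "roi", v)]
      m <- matrix(NA_real_, length(ids), length(rois),
                  dimnames = list(ids, rois))
      m[cbind(match(sub$subject_id, ids), match(sub$roi, rois))] <- sub[[v]]
      if (anyNA(m)) stop("incomplete ", v, " data for session ", session)
      m
    }
    res <- classify_feature_states(grab(design$nc_ids, "single"),
                                   grab(design$patient_ids, "baseline"),
                                   grab(design$patient_ids, "post"),
                                   alpha = alpha, correction = correction,
                                   family_m = family_m, variant = variant,
                                   compute_anova = compute_anova)
    data.frame(roi = res$feature, metric = v,
               res[, setdiff(names(res), "feature")],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlate feature changes with clinical-score changes
#'
#' For each selected feature (edge weight or node metric) the
#' per-patient change is the post-session value minus the baseline
#' value; the clinical change is defined the same way. Each
#' (feature, score) pair is tested with [pearson_r()] on the patients
#' with complete data.
#'
#' @param features Character vector of feature (column) names to test;
#'   default all columns.
#' @param baseline,post Patient x feature matrices with aligned rows
#'   (e.g. from [edge_weight_matrix()]).
#' @param clinical Data frame with columns `subject_id`, `session` and
#'   the score columns; missing scores may be `NA`.
#' @param design A [study_design()].
#' @param scores Score column names to test.
#' @return Data frame: feature, score, r, p, n, plus the per-patient
#'   deltas as a list column `deltas`.
#' @export
delta_correlations <- function(features = NULL, baseline, post, clinical,
                               design,
                               scores = c("ibs_sss", "ibs_qol", "hama")) {
  if (!inherits(design, "study_design")) design <- study_design(design)
  if (is.null(features)) features <- colnames(baseline)
  miss <- setdiff(features, colnames(baseline))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  ids <- design$patient_ids
  cl_delta <- function(score) {
    b <- clinical[[score]][match(paste0(ids, "_baseline"),
                                 paste0(clinical$subject_id, "_", clinical$session))]
    p <- clinical[[score]][match(paste0(ids, "_post"),
                                 paste0(clinical$subject_id, "_", clinical$session))]
    p - b
  }
  rows <- list()
  for (f in features) {
    dw <- post[ids, f] - baseline[ids, f]
    for (s in scores) {
      ds <- cl_delta(s)
      ok <- is.finite(dw) & is.finite(ds)
      if (sum(ok) < 3L) next
      ct <- pearson_r(dw[ok], ds[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, score = s, r = ct$estimate, p = ct$p,
                   n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature = character(), score = character(),
                      r = numeric(), p = numeric(), n = integer()))
  do.call(rbind, rows)
}
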