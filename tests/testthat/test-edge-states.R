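# build condition matrices whose p-value patterns force each state:
# columns are features, rows subjects
make_state_weights <- function(n_nc = 20, n_pat = 20, seed = 41) {
  set.seed(seed)
  noise <- function(n) rnorm(n, 0, 1)
  nc <- cbind(cured = noise(n_nc), disorder = noise(n_nc),
              activated = noise(n_nc), unchanged = noise(n_nc))
  bs <- cbind(cured = noise(n_pat) + 8, disorder = noise(n_pat) + 8,
              activated = noise(n_pat), unchanged = noise(n_pat))
  po <- cbind(cured = bs[, "cured"] - 8 + rnorm(n_pat, 0, 0.5),
              disorder = bs[, "disorder"] + rnorm(n_pat, 0, 0.5),
              activated = bs[, "activated"] + 8 + rnorm(n_pat, 0, 0.5),
              unchanged = bs[, "unchanged"] + rnorm(n_pat, 0, 0.5))
  rownames(bs) <- rownames(po) <- paste0("pt", seq_len(n_pat))
  rownames(nc) <- paste0("nc", seq_len(n_nc))
  list(nc = nc, baseline = bs, post = po)
}

test_that("the decision table assigns each planted pattern its state, exactly one per feature", {
  w <- make_state_weights()
  res <- classify_edge_states(w, alpha = 0.05, correction = "none")
  expect_equal(res$state, c("cured", "disorder", "activated", "unchanged"))
  expect_equal(nrow(res), 4L)
  # cured/disorder deviate upward at baseline; activated upward post
  expect_equal(res$direction, c("increase", "increase", "increase", NA))
  # pure function: identical inputs give identical labels
  res2 <- classify_edge_states(w, alpha = 0.05, correction = "none")
  expect_identical(res$state, res2$state)
  # p-triple semantics: cured means S(p1), S(p2), not S(p3)
  expect_true(res$p1[1] < 0.05 && res$p2[1] < 0.05 && res$p3[1] >= 0.05)
  expect_true(res$p1[2] < 0.05 && res$p2[2] >= 0.05)
  expect_true(res$p1[3] >= 0.05 && res$p2[3] < 0.05 && res$p3[3] < 0.05)
})

test_that("Bonferroni correction within family gates the states and p_corr >= p", {
  w <- make_state_weights()
  res <- classify_edge_states(w, alpha = 0.05, correction = "bonferroni",
                              family_m = 1000)
  expect_true(all(res$p1_corr >= res$p1))
  expect_equal(res$p1_corr, pmin(1, res$p1 * 1000))
  expect_error(classify_edge_states(w, alpha = 1.2), "alpha")
})

test_that("identical group distributions are overwhelmingly labeled unchanged", {
  set.seed(42)
  n <- 23
  w <- list(nc = matrix(rnorm(n * 30), n, 30,
                        dimnames = list(NULL, paste0("e", 1:30))),
            baseline = matrix(rnorm(24 * 30), 24, 30,
                              dimnames = list(paste0("pt", 1:24), paste0("e", 1:30))),
            post = matrix(rnorm(24 * 30), 24, 30,
                          dimnames = list(paste0("pt", 1:24), paste0("e", 1:30))))
  res <- classify_edge_states(w, correction = "bonferroni")
  expect_true(all(res$state == "unchanged"))
})

test_that("node-metric classification shares the edge decision table", {
  set.seed(43)
  cfg <- tiny_config(planted_edges = planted_edge(1, 2, "cured",
                                                  "increase", 0.6))
  bundle <- generate_cohort(cfg)
  nets <- lapply(bundle$sessions, function(s)
    binarize_positive(fisher_z(compute_fc(s))))
  metrics <- node_metric_table(nets, bundle$design)
  design <- study_design(bundle$design)
  res <- classify_node_metric_states(metrics, design, correction = "none")
  expect_setequal(unique(res$metric),
                  c("degree", "clustering", "local_efficiency"))
  expect_equal(nrow(res), 3L * cfg$n_rois)
  expect_true(all(res$state %in% c("disorder", "cured", "activated",
                                   "unchanged")))
  # same decision rule as edges: rebuild one metric as an edge problem
  deg <- metrics[, c("subject_id", "session", "roi", "degree")]
  grab <- function(ids, ses) {
    m <- with(deg[deg$session == ses & deg$subject_id %in% ids, ],
              tapply(degree, list(subject_id, roi), identity))
    m[ids, unique(deg$roi), drop = FALSE]
  }
  w <- list(nc = grab(design$nc_ids, "single"),
            baseline = grab(design$patient_ids, "baseline"),
            post = grab(design$patient_ids, "post"))
  res_edge <- classify_edge_states(w, correction = "none")
  expect_equal(res[res$metric == "degree", "state"], res_edge$state)
})

test_that("delta correlations: identity deltas give r = 1; default design has n = 24", {
  set.seed(44)
  n_pat <- 24
  ids <- sprintf("pt%02d", 1:n_pat)
  baseline <- matrix(rnorm(n_pat * 2), n_pat, 2,
                     dimnames = list(ids, c("A|B", "C|D")))
  post <- baseline + matrix(rnorm(n_pat * 2), n_pat, 2)
  design <- study_design(data.frame(
    subject_id = c(sprintf("nc%02d", 1:23), rep(ids, each = 2)),
    group = c(rep("NC", 23), rep(c("IBSbs", "IBS1st"), n_pat)),
    session = c(rep("single", 23), rep(c("baseline", "post"), n_pat))))
  clinical <- data.frame(
    subject_id = c(ids, ids), session = rep(c("baseline", "post"), each = n_pat),
    ibs_sss = c(rep(0, n_pat), post[, 1] - baseline[, 1]),
    ibs_qol = rnorm(2 * n_pat), hama = rnorm(2 * n_pat))
  res <- delta_correlations(NULL, baseline, post, clinical, design)
  row <- res[res$feature == "A|B" & res$score == "ibs_sss", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_equal(unique(res$n), 24)
  expect_error(delta_correlations("X|Y", baseline, post, clinical, design),
               "unknown feature")
})

test_that("study_design validates pairing and names offending patients", {
  bad <- data.frame(subject_id = c("nc01", "pt01", "pt01", "pt02"),
                    group = c("NC", "IBSbs", "IBS1st", "IBSbs"),
                    session = c("single", "baseline", "post", "baseline"))
  expect_error(study_design(bad), "pt02")
  ok <- study_design(bad[1:3, ])
  expect_equal(ok$nc_ids, "nc01")
  expect_equal(ok$patient_ids, "pt01")
})
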