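test_that("zero effect size gives three identical target matrices", {
  cfg <- tiny_config(planted_edges = planted_edge(1, 2, "cured",
                                                  "increase", 0))
  bt <- build_group_targets(cfg)
  expect_equal(bt$targets$NC, bt$targets$IBSbs)
  expect_equal(bt$targets$NC, bt$targets$IBS1st)
})

test_that("a cured edge at NC level 0.5 with baseline decrease 0.4 yields (0.5, 0.1, 0.5)", {
  cfg <- tiny_config(planted_edges = planted_edge(1, 2, "cured",
                                                  "decrease", 0.4,
                                                  nc_level = 0.5))
  bt <- build_group_targets(cfg)
  expect_equal(bt$targets$NC[1, 2], 0.5, tolerance = 0.04)
  expect_equal(bt$targets$IBSbs[1, 2], 0.1, tolerance = 0.04)
  expect_equal(bt$targets$IBS1st[1, 2], 0.5, tolerance = 0.04)
  # and the repair stayed well below the delta/10 contract
  expect_lt(abs(bt$targets$NC[1, 2] - 0.5), 0.04)
})

test_that("random planted configs match the direct-construction oracle entry-by-entry", {
  set.seed(51)
  for (rep in 1:5) {
    R <- 12
    edges <- data.frame(i = c(1, 3, 5, 7, 9), j = c(2, 4, 6, 8, 10),
                        state = sample(c("disorder", "cured", "activated"),
                                       5, replace = TRUE),
                        direction = sample(c("increase", "decrease"), 5,
                                           replace = TRUE),
                        delta = runif(5, 0.2, 0.4), nc_level = NA_real_,
                        stringsAsFactors = FALSE)
    cfg <- synth_config(n_rois = R, base_correlation = 0.1,
                        planted_edges = edges, seed = rep)
    bt <- build_group_targets(cfg)
    oracle <- oracle_targets(R, 0.1, edges)
    for (g in c("NC", "IBSbs", "IBS1st"))
      for (k in 1:5)
        expect_equal(bt$targets[[g]][edges$i[k], edges$j[k]],
                     oracle[[g]][edges$i[k], edges$j[k]],
                     tolerance = edges$delta[k] / 10)
    # truth records every planted edge with its state
    expect_equal(bt$truth$edge_states$state, edges$state)
    # PSD within tolerance
    for (g in c("NC", "IBSbs", "IBS1st"))
      expect_gt(min(eigen(bt$targets[[g]], symmetric = TRUE,
                          only.values = TRUE)$values), -1e-10)
  }
})

test_that("an unrepairable planted configuration fails naming the edges", {
  cfg <- synth_config(n_rois = 3, base_correlation = 0,
                      planted_edges = rbind(
                        planted_edge(1, 2, "disorder", "increase", 0.95),
                        planted_edge(1, 3, "disorder", "increase", 0.95),
                        planted_edge(2, 3, "disorder", "decrease", 0.95)))
  expect_error(build_group_targets(cfg), "planted edge")
  # an out-of-range level is caught before repair
  cfg2 <- tiny_config(planted_edges = planted_edge(1, 2, "cured",
                                                   "increase", 0.5,
                                                   nc_level = 0.6))
  expect_error(build_group_targets(cfg2), "range")
})

test_that("simulated series reproduce their target correlations at large T", {
  R <- 6
  cfg <- synth_config(n_controls = 2, n_patients = 2, n_rois = R,
                      n_timepoints = 5000, base_correlation = 0,
                      planted_edges = planted_edge(1, 2, "disorder",
                                                   "increase", 0.6),
                      seed = 52)
  bt <- build_group_targets(cfg)
  ses <- simulate_timeseries(bt$targets, cfg)
  # identity-like NC target: off-diagonal sample correlations near 0
  r_nc <- compute_fc(ses[["nc01_single"]])
  expect_lt(mean(abs(r_nc[upper.tri(r_nc)][-1])), 0.05)
  # planted 0.6 entry recovered in a patient baseline session
  r_bs <- compute_fc(ses[["pt01_baseline"]])
  expect_lt(abs(r_bs[1, 2] - 0.6), 0.05)
  # determinism: the same config draws bit-identical data
  ses2 <- simulate_timeseries(bt$targets, cfg)
  expect_identical(ses[["pt02_post"]]$values, ses2[["pt02_post"]]$values)
  expect_error(tiny_config(n_timepoints = 2), "n_timepoints")
  broken <- cfg
  broken$n_timepoints <- 2L
  expect_error(simulate_timeseries(bt$targets, broken), "invalid config")
})

test_that("clinical scores follow group parameters; zero SD collapses to the mean", {
  cp <- clinical_defaults()
  for (g in names(cp)) for (s in names(cp[[g]])) cp[[g]][[s]]["sd"] <- 0
  cfg <- tiny_config(clinical_params = cp)
  cl <- simulate_clinical(cfg)
  expect_equal(unique(cl$ibs_sss[cl$session == "baseline"]), 245.5)
  expect_equal(unique(cl$ibs_sss[cl$session == "post"]), 91.9)
  expect_equal(unique(cl$hama[cl$session == "single"]), 2.48)
  # controls carry HAMA only
  expect_true(all(is.na(cl$ibs_sss[cl$session == "single"])))
  expect_true(all(is.na(cl$ibs_qol[cl$session == "single"])))
  expect_false(any(is.na(cl$hama)))
})

test_that("clinical coupling demands a planted edge and recovers the planted rho", {
  cfg <- tiny_config(delta_coupling = list(list(i = 3, j = 4,
                                                score = "ibs_sss", rho = 0.5)))
  bt <- build_group_targets(cfg)
  ses <- simulate_timeseries(bt$targets, cfg)
  expect_error(simulate_clinical(cfg, bt$truth, ses), "unplanted")

  cfg2 <- synth_config(n_controls = 3, n_patients = 200, n_rois = 8,
                       n_timepoints = 200,
                       planted_edges = planted_edge(1, 2, "cured",
                                                    "increase", 0.4),
                       delta_coupling = list(list(i = 1, j = 2,
                                                  score = "ibs_sss",
                                                  rho = 0.9)),
                       seed = 53)
  bt2 <- build_group_targets(cfg2)
  ses2 <- simulate_timeseries(bt2$targets, cfg2)
  cl2 <- simulate_clinical(cfg2, bt2$truth, ses2)
  ids <- sprintf("pt%02d", 1:200)
  dz <- vapply(ids, function(id) {
    atanh(cor(ses2[[paste0(id, "_post")]]$values[, 1],
              ses2[[paste0(id, "_post")]]$values[, 2])) -
      atanh(cor(ses2[[paste0(id, "_baseline")]]$values[, 1],
                ses2[[paste0(id, "_baseline")]]$values[, 2]))
  }, numeric(1))
  ds <- cl2$ibs_sss[match(paste0(ids, "_post"),
                          paste0(cl2$subject_id, "_", cl2$session))] -
        cl2$ibs_sss[match(paste0(ids, "_baseline"),
                          paste0(cl2$subject_id, "_", cl2$session))]
  expect_lt(abs(cor(dz, ds) - 0.9), 0.08)
})

test_that("cohort bundles round-trip through disk and are byte-deterministic", {
  cfg <- tiny_config(planted_edges = planted_edge(2, 5, "activated",
                                                  "decrease", 0.3),
                     seed = 54)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_cohort(cfg, d1)
  b2 <- generate_cohort(cfg, d2)
  expect_equal(length(b1$sessions), cfg$n_controls + 2L * cfg$n_patients)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))

  back <- read_cohort(d1)
  expect_equal(names(back$sessions), names(b1$sessions))
  expect_equal(back$sessions[["pt03_post"]]$values,
               b1$sessions[["pt03_post"]]$values, tolerance = 1e-12)
  expect_equal(back$design, b1$design)
  expect_equal(back$clinical, b1$clinical, tolerance = 1e-12)
  expect_equal(back$truth$edge_states$i, b1$truth$edge_states$i)
  expect_equal(back$truth$edge_states$state, b1$truth$edge_states$state)
})

test_that("default-size cohort produces 23 + 24 x 2 = 71 session files", {
  cfg <- synth_config(n_rois = 10, n_timepoints = 20, seed = 55)
  d <- withr::local_tempdir()
  generate_cohort(cfg, d)
  expect_length(list.files(file.path(d, "timeseries")), 71L)
})

test_that("group-mean z ordering matches every planted direction", {
  cfg <- synth_config(n_controls = 100, n_patients = 100, n_rois = 8,
                      n_timepoints = 1000,
                      planted_edges = rbind(
                        planted_edge(1, 2, "cured", "decrease", 0.3),
                        planted_edge(3, 4, "disorder", "increase", 0.3),
                        planted_edge(5, 6, "activated", "increase", 0.3)),
                      seed = 56)
  bt <- build_group_targets(cfg)
  ses <- simulate_timeseries(bt$targets, cfg)
  conns <- lapply(ses, function(s) fisher_z(compute_fc(s)))
  w <- edge_weight_matrix(conns, cohort_design(cfg))
  mz <- function(mat, i, j) {
    labs <- rownames(bt$targets$NC)
    mean(mat[, paste0(labs[i], "|", labs[j])])
  }
  # cured decrease: baseline below NC, post back near NC
  expect_lt(mz(w$baseline, 1, 2), mz(w$nc, 1, 2))
  expect_lt(abs(mz(w$post, 1, 2) - mz(w$nc, 1, 2)), 0.05)
  # disorder increase: both patient sessions above NC
  expect_gt(mz(w$baseline, 3, 4), mz(w$nc, 3, 4))
  expect_gt(mz(w$post, 3, 4), mz(w$nc, 3, 4))
  # activated increase: baseline near NC, post above
  expect_lt(abs(mz(w$baseline, 5, 6) - mz(w$nc, 5, 6)), 0.05)
  expect_gt(mz(w$post, 5, 6), mz(w$nc, 5, 6))
})
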