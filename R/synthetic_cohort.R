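#' Default clinical-score parameters
#'
#' Group- and session-wise mean/SD of the three clinical instruments:
#' symptom severity (IBS-SSS, 0-500 points), quality of life (IBS-QOL
#' points) and Hamilton anxiety (HAMA points). Controls are assessed on
#' HAMA only. Values are the cohort summaries the generator emulates:
#' patients at baseline IBS-SSS 245.5 (100), IBS-QOL 132.46 (33.1),
#' HAMA 15.25 (7.9); after the intervention 91.9 (49), 150.33 (13.6),
#' 8.17 (2.9); controls HAMA 2.48 (2.9).
#'
#' @return Nested list `clinical_params[[group]][[score]] = c(mean, sd)`.
#' @export
clinical_defaults <- function() {
  list(
    NC = list(hama = c(mean = 2.48, sd = 2.9)),
    IBSbs = list(ibs_sss = c(mean = 245.5, sd = 100),
                 ibs_qol = c(mean = 132.46, sd = 33.1),
                 hama = c(mean = 15.25, sd = 7.9)),
    IBS1st = list(ibs_sss = c(mean = 91.9, sd = 49),
                  ibs_qol = c(mean = 150.33, sd = 13.6),
                  hama = c(mean = 8.17, sd = 2.9))
  )
}

#' Describe a planted edge effect
#'
#' @param i,j ROI indices of the edge, `i < j`.
#' @param state `"disorder"`, `"cured"` or `"activated"`.
#' @param direction `"increase"` or `"decrease"`: the direction of the
#'   abnormal deviation from the normal (control) level — at baseline
#'   for disorder/cured edges, after the intervention for activated
#'   edges.
#' @param delta Effect size in correlation units (shift applied to the
#'   target correlation).
#' @param nc_level Optional normal-level correlation of this edge in
#'   the control group; defaults to the base correlation.
#' @return One-row data frame.
#' @export
planted_edge <- function(i, j, state, direction = "increase", delta = 0.4,
                         nc_level = NA_real_) {
  stopifnot(state %in% c("disorder", "cured", "activated"),
            direction %in% c("increase", "decrease"))
  data.frame(i = as.integer(i), j = as.integer(j), state = state,
             direction = direction, delta = delta, nc_level = nc_level,
             stringsAsFactors = FALSE)
}

#' Synthetic-cohort configuration
#'
#' Defines a three-condition cohort: unpaired controls, and patients
#' measured at baseline and again after the intervention. Defaults
#' reproduce the study conditions the package emulates: 23 controls,
#' 24 patients scanned twice, 116 atlas ROIs, 200 retained time points
#' per scan, and the clinical parameters of [clinical_defaults()].
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_rois Number of ROIs (116 for the full atlas; smaller values
#'   use the first labels).
#' @param n_timepoints Time points per session.
#' @param base_correlation Scalar off-diagonal correlation of the base
#'   target matrix, or a full symmetric R x R target.
#' @param planted_edges Data frame of [planted_edge()] rows (possibly
#'   several rbind-ed).
#' @param clinical_params As [clinical_defaults()].
#' @param delta_coupling List of couplings, each
#'   `list(i =, j =, score =, rho =)`: the target correlation between a
#'   planted edge's per-patient Fisher-z weight change and the named
#'   clinical score's change.
#' @param seed Integer master seed; all randomness derives from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_controls = 23L, n_patients = 24L,
                         n_rois = 116L, n_timepoints = 200L,
                         base_correlation = 0.1,
                         planted_edges = NULL,
                         clinical_params = clinical_defaults(),
                         delta_coupling = list(),
                         seed = 1L) {
  stopifnot(n_controls >= 2L, n_patients >= 2L, n_rois >= 2L,
            n_timepoints >= 3L)
  if (is.matrix(base_correlation)) {
    stopifnot(nrow(base_correlation) == n_rois,
              isTRUE(all.equal(base_correlation, t(base_correlation))),
              all(diag(base_correlation) == 1))
  } else {
    stopifnot(length(base_correlation) == 1L, abs(base_correlation) < 1)
  }
  if (is.null(planted_edges))
    planted_edges <- planted_edge(1, 2, "cured")[0, ]
  if (nrow(planted_edges)) {
    with(planted_edges, stopifnot(all(i < j), all(i >= 1), all(j <= n_rois),
                                  all(delta >= 0)))
    if (anyDuplicated(planted_edges[, c("i", "j")]))
      stop("duplicate planted edges")
  }
  for (g in names(clinical_params))
    for (s in names(clinical_params[[g]]))
      if (clinical_params[[g]][[s]][["sd"]] < 0) stop("negative clinical SD")
  for (cp in delta_coupling) {
    stopifnot(all(c("i", "j", "score", "rho") %in% names(cp)))
    if (abs(cp$rho) >= 1) stop("|rho| must be < 1")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 base_correlation = base_correlation,
                 planted_edges = planted_edges,
                 clinical_params = clinical_params,
                 delta_coupling = delta_coupling,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# nearest-PSD repair: clip eigenvalues at a small positive floor and
# renormalize to unit diagonal
psd_repair <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  r <- e$vectors %*% (vals * t(e$vectors))
  r <- stats::cov2cor(r)
  (r + t(r)) / 2
}

#' Build the three group target correlation matrices
#'
#' Starting from the base correlation structure, plants each configured
#' edge effect: with "normal" the edge's control-group level and
#' "abnormal" = normal +/- delta (per the edge's direction),
#'
#' * disorder: baseline and post targets both abnormal;
#' * cured: baseline abnormal, post back at normal;
#' * activated: baseline normal, post abnormal.
#'
#' Each matrix is then repaired to the nearest positive semi-definite
#' correlation matrix by eigenvalue clipping. If the repair moves any
#' planted entry by delta/10 or more the configuration is rejected,
#' naming the offending edges.
#'
#' @param config A [synth_config()].
#' @return List with `targets` (named list `NC`, `IBSbs`, `IBS1st` of
#'   R x R correlation matrices) and `truth` (a `synthetic_truth` list:
#'   planted edge states, the targets actually used, clinical
#'   couplings, seed).
#' @export
build_group_targets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  R <- config$n_rois
  labs <- aal116_labels(min(R, 116L))
  if (R > 116L) labs <- c(labs, paste0("ROI", seq.int(117L, R)))
  base <- if (is.matrix(config$base_correlation)) config$base_correlation
          else matrix(config$base_correlation, R, R)
  diag(base) <- 1
  tg <- list(NC = base, IBSbs = base, IBS1st = base)
  pe <- config$planted_edges
  set_entry <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  if (nrow(pe)) for (k in seq_len(nrow(pe))) {
    i <- pe$i[k]; j <- pe$j[k]
    normal <- if (is.finite(pe$nc_level[k])) pe$nc_level[k] else base[i, j]
    sgn <- if (pe$direction[k] == "increase") 1 else -1
    abn <- normal + sgn * pe$delta[k]
    if (abs(normal) >= 1 || abs(abn) >= 1)
      stop("planted edge (", i, ",", j, ") leaves the valid correlation range")
    tg$NC <- set_entry(tg$NC, i, j, normal)
    tg$IBSbs <- set_entry(tg$IBSbs, i, j,
                          if (pe$state[k] == "activated") normal else abn)
    tg$IBS1st <- set_entry(tg$IBS1st, i, j,
                           if (pe$state[k] == "cured") normal else abn)
  }
  pre_repair <- tg
  tg <- lapply(tg, psd_repair)
  if (nrow(pe)) {
    bad <- character()
    for (k in seq_len(nrow(pe))) {
      if (pe$delta[k] == 0) next
      i <- pe$i[k]; j <- pe$j[k]
      drift <- max(vapply(names(tg), function(g)
        abs(tg[[g]][i, j] - pre_repair[[g]][i, j]), numeric(1)))
      if (drift >= pe$delta[k] / 10)
        bad <- c(bad, sprintf("(%d,%d)", i, j))
    }
    if (length(bad))
      stop("PSD repair distorted planted edge(s) ",
           paste(bad, collapse = ", "),
           "; reduce the number or size of planted effects")
  }
  tg <- lapply(tg, function(m) { dimnames(m) <- list(labs, labs); m })
  truth <- structure(list(
    edge_states = if (nrow(pe))
      data.frame(pe, roi_i = labs[pe$i], roi_j = labs[pe$j],
                 stringsAsFactors = FALSE)
    else pe,
    group_targets = tg,
    clinical_coupling = config$delta_coupling,
    seed = config$seed), class = "synthetic_truth")
  list(targets = tg, truth = truth)
}

# deterministic per-stream seed derivation from the master seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483629L + 1)
}

#' Simulate ROI time series for the whole cohort
#'
#' Each session's T x R matrix is drawn as a zero-mean stationary
#' multivariate normal with the session's group target as correlation
#' matrix: one session per control, two (baseline, post) per patient
#' with a shared subject id but independent noise. Every session uses
#' its own counter-derived seed, so the draw is reproducible
#' subject-by-subject.
#'
#' @param targets Named list `NC`, `IBSbs`, `IBS1st` of target
#'   correlation matrices (from [build_group_targets()]).
#' @param config A [synth_config()].
#' @return Named list of [roi_timeseries()], keyed
#'   `<subject>_<session>`.
#' @export
simulate_timeseries <- function(targets, config) {
  stopifnot(inherits(config, "synth_config"))
  R <- config$n_rois; T_ <- config$n_timepoints
  if (T_ < 3L || R < 2L) stop("invalid config: need T >= 3 and R >= 2")
  labs <- rownames(targets$NC)
  plan <- rbind(
    data.frame(subject_id = sprintf("nc%02d", seq_len(config$n_controls)),
               group = "NC", session = "single", target = "NC",
               stringsAsFactors = FALSE),
    data.frame(subject_id = rep(sprintf("pt%02d", seq_len(config$n_patients)),
                                each = 2L),
               group = rep(c("IBSbs", "IBS1st"), config$n_patients),
               session = rep(c("baseline", "post"), config$n_patients),
               target = rep(c("IBSbs", "IBS1st"), config$n_patients),
               stringsAsFactors = FALSE))
  out <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    set.seed(derive_seed(config$seed, k))
    x <- MASS::mvrnorm(T_, mu = rep(0, R), Sigma = targets[[plan$target[k]]])
    colnames(x) <- labs
    out[[k]] <- roi_timeseries(x, labs, plan$subject_id[k],
                               plan$group[k], plan$session[k])
  }
  names(out) <- paste0(plan$subject_id, "_", plan$session)
  out
}

#' Design table of a simulated cohort
#' @param config A [synth_config()].
#' @return Data frame with columns subject_id, group, session, file.
#' @export
cohort_design <- function(config) {
  d <- rbind(
    data.frame(subject_id = sprintf("nc%02d", seq_len(config$n_controls)),
               group = "NC", session = "single", stringsAsFactors = FALSE),
    data.frame(subject_id = rep(sprintf("pt%02d", seq_len(config$n_patients)),
                                each = 2L),
               group = rep(c("IBSbs", "IBS1st"), config$n_patients),
               session = rep(c("baseline", "post"), config$n_patients),
               stringsAsFactors = FALSE))
  d$file <- file.path("timeseries", paste0(d$subject_id, "_", d$session, ".tsv"))
  d
}

#' Simulate clinical scores
#'
#' Draws each subject-session's scores from the configured group
#' mean/SD. Controls receive HAMA only; patient scores without a
#' coupling are drawn independently at baseline and post. For a coupled
#' (edge, score) pair with target correlation rho, the patient's score
#' change is rho x (standardized realized Fisher-z change of that
#' edge) + sqrt(1 - rho^2) x noise, rescaled to the implied change
#' distribution (mean = post mean - baseline mean, SD =
#' sqrt(baseline SD^2 + post SD^2)); the post score is then baseline +
#' change.
#'
#' @param config A [synth_config()].
#' @param truth Output `truth` of [build_group_targets()]; required when
#'   couplings are configured.
#' @param sessions Output of [simulate_timeseries()]; required when
#'   couplings are configured (the realized edge changes are computed
#'   from it).
#' @return Data frame: subject_id, session, ibs_sss, ibs_qol, hama
#'   (`NA` = not assessed).
#' @export
simulate_clinical <- function(config, truth = NULL, sessions = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cp <- config$clinical_params
  couplings <- config$delta_coupling
  if (length(couplings)) {
    if (is.null(truth) || is.null(sessions))
      stop("couplings configured: truth and sessions are required")
    planted <- truth$edge_states
    for (c0 in couplings) {
      if (!nrow(planted) ||
          !any(planted$i == c0$i & planted$j == c0$j))
        stop("delta coupling requested for unplanted edge (",
             c0$i, ",", c0$j, ")")
    }
  }
  set.seed(derive_seed(config$seed, 10^6))
  scores <- c("ibs_sss", "ibs_qol", "hama")
  draw <- function(group, score, n) {
    par <- cp[[group]][[score]]
    if (is.null(par)) return(rep(NA_real_, n))
    stats::rnorm(n, par[["mean"]], par[["sd"]])
  }
  nc_ids <- sprintf("nc%02d", seq_len(config$n_controls))
  pt_ids <- sprintf("pt%02d", seq_len(config$n_patients))
  nc <- data.frame(subject_id = nc_ids, session = "single",
                   ibs_sss = draw("NC", "ibs_sss", length(nc_ids)),
                   ibs_qol = draw("NC", "ibs_qol", length(nc_ids)),
                   hama = draw("NC", "hama", length(nc_ids)),
                   stringsAsFactors = FALSE)
  bs <- data.frame(subject_id = pt_ids, session = "baseline",
                   stringsAsFactors = FALSE)
  po <- data.frame(subject_id = pt_ids, session = "post",
                   stringsAsFactors = FALSE)
  realized_dz <- function(i, j) {
    vapply(pt_ids, function(id) {
      zb <- atanh(stats::cor(sessions[[paste0(id, "_baseline")]]$values[, i],
                             sessions[[paste0(id, "_baseline")]]$values[, j]))
      zp <- atanh(stats::cor(sessions[[paste0(id, "_post")]]$values[, i],
                             sessions[[paste0(id, "_post")]]$values[, j]))
      zp - zb
    }, numeric(1))
  }
  for (s in scores) {
    coup <- Filter(function(c0) c0$score == s, couplings)
    b <- draw("IBSbs", s, length(pt_ids))
    if (length(coup)) {
      c0 <- coup[[1L]]
      pb <- cp$IBSbs[[s]]; pp <- cp$IBS1st[[s]]
      if (is.null(pb) || is.null(pp))
        stop("coupled score ", s, " lacks clinical parameters")
      dmean <- pp[["mean"]] - pb[["mean"]]
      dsd <- sqrt(pb[["sd"]]^2 + pp[["sd"]]^2)
      dz <- realized_dz(c0$i, c0$j)
      zs <- if (stats::sd(dz) > 0) (dz - mean(dz)) / stats::sd(dz)
            else rep(0, length(dz))
      u <- c0$rho * zs + sqrt(1 - c0$rho^2) * stats::rnorm(length(dz))
      p <- b + dmean + dsd * u
    } else {
      p <- draw("IBS1st", s, length(pt_ids))
    }
    bs[[s]] <- b
    po[[s]] <- p
  }
  rbind(nc, bs, po)
}

#' Generate and write a complete synthetic cohort
#'
#' Runs target construction, time-series simulation and clinical-score
#' simulation, and writes the cohort in its plain-text interchange
#' formats: one TSV per session under `timeseries/`, `design.csv`,
#' `clinical.csv` and `truth.json` (the planted ground truth for
#' recovery tests).
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed); `NULL` keeps the
#'   bundle in memory only.
#' @return Invisibly, the bundle: list with `sessions`, `design`,
#'   `clinical`, `truth`, `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  bt <- build_group_targets(config)
  sessions <- simulate_timeseries(bt$targets, config)
  clinical <- simulate_clinical(config, bt$truth, sessions)
  design <- cohort_design(config)
  bundle <- list(sessions = sessions, design = design, clinical = clinical,
                 truth = bt$truth, config = config)
  if (!is.null(dir)) write_cohort(bundle, dir)
  invisible(bundle)
}

#' @rdname generate_cohort
#' @param bundle A cohort bundle.
#' @export
write_cohort <- function(bundle, dir) {
  tsdir <- file.path(dir, "timeseries")
  dir.create(tsdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(bundle$sessions)) {
    path <- file.path(tsdir, paste0(key, ".tsv"))
    ok <- try(utils::write.table(bundle$sessions[[key]]$values, path,
                                 sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write ", path)
  }
  utils::write.csv(bundle$design, file.path(dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  tr <- bundle$truth
  jsonlite::write_json(
    list(edge_states = tr$edge_states,
         clinical_coupling = tr$clinical_coupling,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a cohort bundle back from disk
#'
#' @param dir Directory written by [generate_cohort()].
#' @return Bundle list with `sessions`, `design`, `clinical`, `truth`.
#' @export
read_cohort <- function(dir) {
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path)) stop("no design table at ", design_path)
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("no clinical table at ", clin_path)
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  sessions <- list()
  for (k in seq_len(nrow(design))) {
    path <- file.path(dir, design$file[k])
    if (!file.exists(path)) stop("missing time-series file ", path)
    x <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
    sessions[[paste0(design$subject_id[k], "_", design$session[k])]] <-
      roi_timeseries(x, colnames(x), design$subject_id[k],
                     design$group[k], design$session[k])
  }
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    class(truth) <- "synthetic_truth"
  }
  list(sessions = sessions, design = design, clinical = clinical,
       truth = truth)
}
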