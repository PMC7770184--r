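# fcstates

Three-condition functional connectome edge-state analysis for
longitudinal intervention studies.

## The problem

Resting-state fMRI studies of gastrointestinal disorders such as
diarrhea-predominant irritable bowel syndrome (IBS-D) compare a control
group (NC) with patients measured before (IBSbs) and after (IBS1st) an
intervention — for example a six-week acupuncture course — asking which
brain functional connections and network properties are abnormal at
baseline, which are restored by the intervention, and which are newly
changed by it. `fcstates` implements that whole analysis as a tested,
reusable R pipeline for anyone with ROI time series and a paired
three-condition design:

* **Connectome construction** — per session, the Pearson correlation
  between every pair of ROI mean time series (116 AAL parcels by
  default), Fisher z transform $z = \operatorname{arctanh}(r)$, removal
  of self-connections, and binarization keeping edges with $z > 0$.
* **Binary graph metrics** — degree $k_i = \sum_j a_{ij}$, clustering
  coefficient $C_i = E_i/\binom{k_i}{2}$, and local efficiency
  $E_{node}(i) = \frac{1}{N}\sum_{j\neq i} 1/L_{ij}$ (plus the
  conventional neighbourhood-subgraph variant behind a mode flag).
* **Edge/node state taxonomy** — per feature, three tests
  ($p_1$: NC vs IBSbs two-sample t; $p_2$: IBSbs vs IBS1st paired t;
  $p_3$: NC vs IBS1st two-sample t) with Bonferroni correction per
  family, then: *cured* = $S(p_1) \wedge S(p_2) \wedge \neg S(p_3)$,
  *disorder* = $S(p_1) \wedge \neg S(p_2)$, *activated* =
  $\neg S(p_1) \wedge S(p_2) \wedge S(p_3)$, else *unchanged*.
* **Clinical delta correlations** — Pearson r between per-patient
  changes in edge weight and changes in IBS-SSS / IBS-QOL / HAMA
  scores, $p$ from $t = r\sqrt{n-2}/\sqrt{1-r^2}$.
* **Biomarker verification** — an RBF-kernel support-vector machine
  (libsvm) trained on one cohort and evaluated on a held-out cohort,
  with accuracy, ROC curve and AUC.
* **A synthetic paired-cohort generator** — multivariate-normal ROI
  time series with planted disorder/cured/activated edges, Table-style
  clinical scores, and planted edge–clinical couplings, so the entire
  pipeline (and its calibration and power) is testable with no data
  download.

## Worked example

Simulate a study-sized cohort (23 controls, 24 patients scanned twice,
20 ROIs, 400 time points) with a planted cured edge, a planted disorder
edge, and a planted coupling of −0.6 between the cured edge's change
and the change in symptom severity, then analyze it:

```r
library(fcstates)
cfg <- synth_config(
  n_controls = 23, n_patients = 24, n_rois = 20, n_timepoints = 400,
  planted_edges = rbind(planted_edge(1, 2, "cured",    "increase", 0.4),
                        planted_edge(3, 4, "disorder", "decrease", 0.4)),
  delta_coupling = list(list(i = 1, j = 2, score = "ibs_sss", rho = -0.6)),
  seed = 11)
run_simulate(cfg, "demo/cohort")
res <- run_analyze("demo/cohort", "demo/results")
subset(res$edge_states, state != "unchanged",
       select = c(feature, p1_corr, p2_corr, p3_corr, state, direction))
```

```
            feature      p1_corr      p2_corr      p3_corr    state direction
1   PreCG.L|PreCG.R 8.659096e-26 3.474388e-18 1.000000e+00    cured  increase
6 SFGdor.L|SFGdor.R 3.377199e-29 1.000000e+00 1.258463e-30 disorder  decrease
```

Both planted effects are recovered with their directions: the cured
edge is significant against controls at baseline ($p_1$), changes under
the intervention ($p_2$), and is indistinguishable from controls
afterwards ($p_3 = 1$ after correction); the disorder edge stays
abnormal in both patient sessions. The remaining 188 of 190 edges are
labeled unchanged. The planted clinical coupling is also recovered:

```r
subset(res$delta_correlations, score == "ibs_sss")
```

```
            feature   score          r           p  n
1   PreCG.L|PreCG.R ibs_sss -0.5687873 0.003727709 24
4 SFGdor.L|SFGdor.R ibs_sss -0.1720599 0.421430376 24
```

i.e. patients whose cured-edge connectivity increased most showed the
largest drop in symptom severity (r = −0.57 against a planted −0.6,
n = 24 patients), while the disorder edge shows no coupling, as
planted. `demo/results/` also contains per-session connectome TSVs,
the tidy node-metric table, node-metric states, and a `summary.json`
with state counts and all delta correlations.

The same stages are scriptable from a shell via the thin CLI at
`inst/cli/fcstates` (`simulate`, `analyze`, `classify` subcommands
driven by a YAML config).

Published summary statistics can be checked directly:

```r
two_sample_t_from_summary(23, 41.96, 12.7, 24, 40.17, 10.6)$p  # 0.6033625
p_from_r(-0.54, 24)                                            # 0.006453914
```

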