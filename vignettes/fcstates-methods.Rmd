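---
title: "Methods: three-condition connectome edge-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-condition connectome edge-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcstates)
```

## The analysis problem

`fcstates` implements a longitudinal three-condition brain-network
analysis for studies with one control group (NC) measured once and one
patient group measured at baseline (IBSbs) and again after an
intervention (IBS1st), with the two patient sessions paired by subject.
The motivating application is resting-state fMRI of
diarrhea-predominant irritable bowel syndrome patients before and after
a six-week acupuncture course, with 23 controls and 24 patients, but
nothing in the code is specific to that cohort: any design table with
the NC/IBSbs/IBS1st structure is accepted.

The pipeline has five stages.

1. **Connectome construction.** Each session is an ROI-by-time matrix
   (by default the 116 parcels of the AAL atlas). Functional
   connectivity is the Pearson correlation between every pair of ROI
   mean time series; Fisher's z transform (`atanh`) is applied to
   improve normality, self-connections are removed (zero diagonal), and
   the binary network keeps an edge exactly when its weight is strictly
   positive — negative and zero correlations are treated as spurious
   and dropped. Because `atanh` is odd and strictly increasing, the
   sign rule gives the same adjacency whether applied to r or to z; the
   package binarizes z weights.

2. **Graph metrics** on the binary network, per node $i$:
   degree $k_i = \sum_j a_{ij}$; clustering coefficient
   $C_i = E_i / \binom{k_i}{2}$ with $E_i$ the number of edges among
   $i$'s neighbours; and local efficiency
   $E_{node}(i) = \frac{1}{N}\sum_{j \ne i} 1/L_{ij}$ with $L_{ij}$ the
   shortest hop distance. Unreachable pairs contribute $0$
   (the usual $1/\infty$ convention), and $C_i = 0$ when $k_i < 2$ so
   that group statistics never meet a NaN.

3. **Edge/node state taxonomy.** For each edge (or each node metric)
   three tests are run: NC vs IBSbs (two-sample t), IBSbs vs IBS1st
   (paired t), NC vs IBS1st (two-sample t). Writing $S(p)$ for
   "corrected $p < \alpha$", the label is

   | $S(p_1)$ | $S(p_2)$ | $S(p_3)$ | state |
   |---|---|---|---|
   | yes | yes | no  | cured |
   | yes | no  | —   | disorder |
   | no  | yes | yes | activated |
   | otherwise | | | unchanged |

   "Cured" operationalizes "returned to the control level" as
   non-significance of NC vs IBS1st — the only testable reading of that
   phrase. The Bonferroni family is the set of simultaneous hypotheses
   within one comparison: all tested edges, or all nodes for one
   metric; `family_m` can override it and `correction = "none"`
   reproduces uncorrected exploratory reporting. An omnibus one-way
   ANOVA across the three conditions is computed and stored per feature
   but deliberately excluded from the decision rule, which is purely
   pairwise; users who want an omnibus gate can filter on the stored
   `pF`.

4. **Clinical delta correlations.** For the features that received a
   non-unchanged label, the per-patient change (post minus baseline) in
   Fisher-z weight is correlated (Pearson) with the change in each
   clinical score (IBS-SSS, IBS-QOL, HAMA), with the p-value from
   $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df.

5. **Biomarker verification.** Selected edges feed a radial-basis
   support-vector machine (libsvm via `e1071`): features are z-scored
   with training-cohort statistics only, the classifier is fit on one
   cohort and evaluated on a held-out cohort, and the decision scores
   are swept into a ROC curve whose area equals the Mann–Whitney
   statistic divided by $n_1 n_2$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | significance level for all state decisions |
| `correction` | `"bonferroni"` | per-family multiple-comparison correction (`"none"` for exploratory runs) |
| `family_m` | number of features | Bonferroni family size |
| `variant` | `"welch"` | two-sample t form; `"pooled"` gives the classical equal-variance test |
| `efficiency_mode` | `"literal"` | local-efficiency normalization (see below) |
| SVM `cost`, `gamma` | 1, $1/p$ | libsvm hyperparameters on standardized features; no tuning is performed |

**Welch as default.** The source of every two-sample comparison is a
cohort with unequal group variances in several measures; Welch is the
robust default and reproduces the published demographic p-values
(0.603 for age, 0.718 within rounding for education) slightly more
closely than the pooled form. The pooled variant is retained for exact
classical behaviour (and for the $F = t^2$ identity with the ANOVA).

**Local-efficiency modes.** The printed nodal formula sums inverse
shortest-path lengths over the whole graph with prefactor $1/N$; the
conventional "local efficiency" of the literature instead scores the
subgraph induced by a node's neighbours with prefactor
$1/(k_i(k_i-1))$. The source text does not disambiguate which
subnetwork is meant, so both are implemented: `"literal"` reproduces
the formula as printed, `"neighborhood"` the standard variant; every
output row records which mode produced it.

## The synthetic cohort generator

Real scans for this design are not publicly deposited, so the package
ships a generator whose defaults are the study conditions: 23 controls
scanned once, 24 patients scanned twice, 116 ROIs, 200 retained time
points per session (210 acquired volumes minus 10 discarded for signal
equilibrium), and clinical parameters equal to the cohort table —
baseline IBS-SSS 245.5 (SD 100), post 91.9 (49); IBS-QOL 132.46 (33.1)
to 150.33 (13.6); HAMA 15.25 (7.9) to 8.17 (2.9); controls HAMA 2.48
(2.9) and no IBS instruments, mirroring the published table.

Each session is a zero-mean stationary multivariate normal time series
whose population correlation is the session's group target matrix —
the simplest generative model whose sample Pearson correlations
converge to a controllable target. Planted effects shift single target
entries by `delta` correlation units: a *disorder* edge is abnormal in
both patient targets, a *cured* edge abnormal at baseline only, an
*activated* edge abnormal post only, with "abnormal" = control level
± delta according to the planted direction. After planting, each target
is repaired to the nearest positive semi-definite correlation matrix by
symmetric eigenvalue clipping (floor $10^{-6}$) followed by
re-normalization to unit diagonal; the repair is deterministic and, for
the effect sizes of interest, leaves planted entries essentially
untouched — if it would move any planted entry by `delta`/10 or more
the configuration is rejected with the offending edges named, rather
than silently eroding the ground truth.

Clinical scores are plain normal draws at the configured group
mean/SD. Truncating at instrument bounds would bias the means the
generator is required to reproduce, so scores are left untruncated
(with SD 100 around mean 245.5 roughly 0.7% of baseline severities fall
below zero — harmless for the statistics exercised here). A
delta-coupling with target correlation $\rho$ between a planted edge
and a score generates the patient's score change as
$\rho \cdot \tilde{z} + \sqrt{1-\rho^2}\,\varepsilon$, where
$\tilde{z}$ is the standardized *realized* Fisher-z change of that edge
in the simulated series, rescaled to the implied change distribution.
The change SD is not stated anywhere, so it is taken as
$\sqrt{SD_{baseline}^2 + SD_{post}^2}$ (independence); the post score
is baseline + change.

Determinism: a single master seed expands into per-session substreams
through a counter-based derivation, so the same configuration always
yields byte-identical bundles and any subject's data can be regenerated
without drawing its predecessors.

**What the generator does *not* emulate** — and hence what passing
tests do and do not show about real data: there is no temporal
autocorrelation or hemodynamic smoothness within a session (sample
correlations of real BOLD have fewer effective degrees of freedom than
T suggests, so real-data power is lower than synthetic power at equal
T); no within-subject stability of connectivity across the six-week
interval (the two patient sessions share only their target, a modeling
choice — the source reports nothing about test–retest dependence);
no motion artifacts, scanner drift or physiological noise; and
group-level heterogeneity beyond sampling noise is absent. Recovery
results on synthetic cohorts therefore validate the *machinery*
(calibration of the taxonomy under the null, power under planted
effects, estimator consistency), not the anatomical findings of any
real cohort.

## Numerical choices and degenerate inputs

* Zero-variance ROI signals correlate as 0 with a warning (rather than
  propagating NaN), keeping binarization total.
* An off-diagonal correlation of exactly ±1 is rejected before the z
  transform rather than mapped to ±Inf.
* Zero-variance samples in the t tests are resolved as limits (p = 1
  for equal means, p = 0 otherwise) and flagged `degenerate`.
* Strict `> 0` binarization: an exactly-zero weight is not an edge.
* ROC ties are grouped (one threshold per distinct score), and the AUC
  uses the trapezoid rule, which equals the tie-corrected Mann–Whitney
  statistic.
* State labels are a pure function of the corrected p-triples and
  alpha; every feature receives exactly one label.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the sampling
behaviour visible while keeping runs routine on a laptop: calibration
of the family-wise error rate uses 500 null replicates at 20 ROIs and
200 time points with the default group sizes; power of cured-edge
recovery uses 100 replicates at effect size 0.4 and 400 time points;
coupling recovery uses 200 patients; generator fidelity uses 10,000
clinical draws. Oracle equivalence for graph metrics runs 200 random
graphs of up to 12 nodes against independent brute-force
implementations.

## Known limitations

* Negative-weight network analysis is out of scope; anti-correlations
  are discarded by design.
* No sparsity or density thresholding beyond the sign rule is offered.
* Families are corrected with Bonferroni only; permutation-based
  family-wise methods and FDR are not implemented.
* The SVM stage is a fixed-hyperparameter verification, not a tuned
  classifier; published held-out accuracies from real scans are not
  reproducible from synthetic data and are not targets of this
  package.
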