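---
title: "Methods: connectome-based prediction of longitudinal symptom severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of longitudinal symptom severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connpred)
```

## The problem

After an acute trauma, posttraumatic stress symptoms follow heterogeneous
longitudinal courses: most survivors remain at low severity, others remit,
and smaller groups follow moderate, chronically high, or delayed-worsening
trajectories. A question of clinical interest is whether whole-brain
functional connectivity measured early (about one month post trauma) carries
prognostic signal about symptom severity months later. `connpred` implements
the standard analysis for that question — connectome-based predictive
modeling (CPM) — as a reusable, tested pipeline, together with a synthetic
cohort generator that makes every stage verifiable against known ground
truth.

## The model

**Connectomes.** Each scan's node time series (T timepoints x N nodes) is
turned into an N x N matrix of pairwise Pearson correlations, Fisher
transformed edgewise, $z = \operatorname{artanh}(r)$. Correlations are
clipped to $\pm(1 - 10^{-7})$ first so numerically perfect correlations map
to large finite z rather than infinity; the diagonal is stored as 0 and
never enters any model. A subject's scans (rest and two task paradigms) are
combined by an unweighted elementwise mean — the number of scans averaged is
recorded for audit, but scans are not weighted by duration, since the
averaging is defined over valid scans, not timepoints. Edges are vectorized
in a fixed canonical order (upper triangle, row-major; `edge_pairs()`), so a
cohort is an n x E matrix with $E = N(N-1)/2$.

**Edge selection.** For a target outcome $y$ (CAPS-5 total or a cluster
score), every edge is correlated with $y$ by *partial* Pearson correlation
given the confounds (age, sex, mean head motion; plus the 1-month total for
follow-up targets, so that follow-up models predict something beyond initial
severity). Two-tailed p-values use the t distribution on $n - 2 - c$ degrees
of freedom. Edges with $p < \alpha$ (default 0.05) are split by sign into a
positive and a negative mask.

**Prediction.** For each subject the selected edge strengths are summed per
mask (`pos_sum`, `neg_sum`) and the outcome is regressed on
$[1, \text{pos\_sum}, \text{neg\_sum}]$ by ordinary least squares. The
combined two-feature form is the default because it yields a single
prediction per subject, matching one reported score per timepoint;
positive-only and negative-only variants are available via `variant=`. When
a mask is empty its column is dropped (coefficient 0); with no selected
edges at all the model degrades to the training mean.

**Cross-validation.** `run_cv()` repeats a k-fold split (default k = 10) over
100 random divisions. Fold sizes differ by at most one; repeat $r$ is seeded
`seed + r` so any repeat can be regenerated alone. Within a repeat, each
fold is predicted from a model whose *selection and coefficients* are fit on
the other folds only — the held-out outcomes are never touched, which the
test suite asserts directly by perturbing held-out labels. Performance per
repeat is the Spearman rank correlation (average ranks for ties) between
out-of-fold predictions and observed outcomes; the run's score is the median
across repeats.

**Significance.** `permutation_test()` shuffles the correspondence between
outcome and connectomes (covariates stay aligned with the connectomes, since
the shuffle targets the brain-behavior link, not the confound structure) and
reruns the full CPM per shuffle. The p-value is one-tailed with the add-one
rule $p = (1 + \#\{\rho_{null} \ge \rho_{obs}\})/(B + 1)$: only positive
predicted-observed association indicates prediction above chance, and the
add-one form is valid at finite $B$ and never exactly zero. Per-cluster
models (criteria B, C, D, E) are corrected across the four tests within a
timepoint by Benjamini-Hochberg FDR (`fdr_bh()`, backed by `p.adjust`).

**Virtual lesions.** `run_lesion_cpm()` reruns the whole pipeline once per
network with the edge universe restricted to edges having *at least one
endpoint* in the network of interest — i.e. its within-network plus
between-network connections, the only reading under which each network's
model retains its connectivity to the rest of the brain. All lesion runs and
the whole-brain run share identical fold assignments (same seed), so
"network outperforms whole brain" is a paired comparison free of
fold-assignment noise; networks whose median rho exceeds the whole-brain
median are flagged as driving. Attribution is completed by per-node degree
centrality of selected edges and a 10 x 10 network-pair contribution matrix
reported both as raw counts and as density (count divided by the number of
possible node pairs spanning the pair), because an "average contribution" is
not uniquely defined — plots should default to the density variant, which is
comparable across networks of different sizes.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` | 0.05 | edge-selection p threshold |
| `k`, `repeats` | 10, 100 | CV folds, random repeated divisions |
| `n_perm` | 1000 | label shuffles for the null |
| `perm_repeats` | 10 | CV repeats per shuffle |
| `variant` | combined | model form (also positive / negative) |
| `clip_margin` | 1e-7 | correlation clip before Fisher z |
| `consensus_threshold` | 1 | fraction of training fits an edge must be selected in |

`perm_repeats` defaults to 10 rather than the observed run's 100 because
1000 shuffles x 100 repeats x 10 folds is a cluster-scale job, and the null
distribution of the *median* rho is insensitive to the repeat count (the
type-I-error suite runs at `perm_repeats = 5` and is calibrated); full
fidelity is one argument away. How a "consensus predictive edge" should be
counted across folds and repeats is not uniquely defined either, so
`consensus_edges()` exposes the per-edge selection frequency and a
configurable threshold (default: selected in every training fit) rather than
hard-coding one rule.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
not the physiology of BOLD data:

* **Trajectories.** Subjects are drawn iid from five latent classes — low,
  remitting, moderate, high, delayed — with default prevalences 64.5 : 16.9 :
  6.7 : 6.5 : 5.5 (normalized; the printed percentages sum to 100.1).
  Each class has a mean latent-severity profile over 1/6/14 months whose
  shapes encode the class semantics (remitting decreases, delayed
  increases); the profile values, in latent SD units, are a modeling choice
  made once — they produce realistic score distributions (mostly
  low-severity, a chronic tail) rather than fitting any particular dataset.
  A subject-level Gaussian deviation (SD 0.3) is shared across timepoints.
* **CAPS-5 scores.** Each of 20 items per timepoint is an ordinal 0-4 from
  thresholding latent severity plus item noise; totals (0-80) and cluster
  scores are item sums, so cluster scores add to the total by construction.
  Item counts per cluster default to the standard 20-item structure
  (B = 5, C = 2, D = 7, E = 6) — the instrument convention, configurable.
* **Connectomes.** Each edge is a population mean (N(0.25, 0.1) across
  edges) plus subject noise (SD 0.1); three scans add independent scan noise
  (SD 0.2), and the averaged connectome is their mean. A planted set of 50
  edges, 90% concentrated in a target network (default aDMN), is shifted by
  `-beta` z per SD of standardized 1-month latent severity; 2% of planted
  edges get a positive effect instead, so both selection masks are
  exercised while the signal is overwhelmingly "less connectivity, more
  severe symptoms". `beta = 0.15` is a synthetic effect scale chosen so that
  recovery properties hold robustly at cohort sizes of 100-160; no empirical
  effect size is claimed for it.
* **Dropout.** Follow-up outcomes are masked missing-completely-at-random at
  marginal retention 84.0% (6 months) and 82.1% (14 months), 14-month
  completers nested within 6-month completers; an informative-dropout mode
  (retention log-odds decreasing in severity) exists for robustness studies.
  Subjects missing a target are excluded from that model, never imputed.
* **Scale.** The default 60 nodes in 10 networks of 6 keeps a full CPM with
  permutations at interactive speed; `n_nodes = 268` gives full-resolution
  connectomes when fidelity matters more than wall time.

What the generator does *not* emulate: hemodynamics and temporal
autocorrelation, head-motion artifacts, site effects, scanner differences,
or task structure. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under the assumed data-generating model — they
do not certify performance on real fMRI data.

## Numerical choices and degenerate inputs

* A zero-variance node is an error naming the node, not a silent NaN — it
  indicates corrupt input.
* Selection inside the compiled CV loop compares $|r|$ against the critical
  value $r_{crit} = t_{crit}/\sqrt{df + t_{crit}^2}$ (one t quantile per
  fold size) — algebraically identical to thresholding the two-tailed p,
  without an incomplete-beta evaluation per edge. The pure-R reference
  backend computes the p-values explicitly; tests assert the two paths give
  identical selections and predictions.
* Per-fold training statistics are whole-sample crossproduct blocks minus
  the held-out fold's block, so the edge matrix is never copied per fold.
* The small OLS on the summed features uses a pseudoinverse, so an exactly
  collinear feature pair degrades gracefully instead of erroring mid-run.
* A training fold with constant outcome (or collinear covariates) aborts
  that repeat with a warning and an `NA` rho; `cv_score()` takes the median
  over completed repeats. Constant out-of-fold predictions carry no rank
  information and score 0.
* Ties in Spearman use average ranks; the fold partition uses
  `rep(1:k, length.out = n)` shuffled, guaranteeing sizes differ by at most
  one.

## Validation suite sizes

The packaged acceptance checks run at sizes chosen to give stable
statistics in minutes on one core: type-I-error calibration uses 200
effect-free cohorts (n = 100, 60 nodes) at 200 shuffles x 5 repeats each;
planted-effect recovery uses the default cohort (n = 160) at full 100
repeats plus 20 reduced-repeat seeds for lesion localization; the
trajectory-mixture check draws 100,000 labels. The null-centering property
uses 200 runs at n = 100, E = 500.

## Known limitations

* The model form behind the original headline correlations (positive,
  negative, or combined) is not identifiable from the source; `combined` is
  the default and the others are options.
* Covariates act only at edge selection; the outcome is not residualized
  and covariates are not prediction features. This is the literal reading
  of "confound control through partial correlation"; other confound
  strategies would need to be added deliberately.
* Edge selection treats edges independently; no spatial or network prior
  enters selection.
* No regularized or nonlinear prediction models, no site harmonization, no
  graph metrics beyond degree.
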