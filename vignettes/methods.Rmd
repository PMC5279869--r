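---
title: "Methods: context-specific causal signaling networks from interventional RPPA time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific causal signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxcausal)
```

## The problem

Signaling networks differ between cell types and between environmental
conditions: an edge "mTOR influences S6K" may be active in one breast
cancer cell line under serum stimulation and absent in another. ctxcausal
implements an end-to-end pipeline for mapping such **context-specific
causal networks** from reverse-phase protein array (RPPA) time courses
collected under kinase inhibition. A *context* is a (cell line, stimulus)
pair; inhibitors are interventions applied within a context. The full
design this package targets has 4 cell lines x 8 stimuli = 32 contexts,
7 observation times (0--240 min), a vehicle (DMSO) control and five
inhibitor regimes, with ~16 replicates at t = 0 and duplicate vehicle
controls at later times.

The pipeline has four analysis stages plus a simulator:

1. **Preprocessing** (`preprocess_rppa()` and its components),
2. **Salient-change calling / causal descendancy matrices**
   (`call_salient_changes()`, `build_descendancy_matrix()`),
3. **Joint network learning** (`learn_networks()`),
4. **Held-out-inhibitor assessment** (`run_full_assessment()`),

with `sample_context_networks()` / `simulate_rppa_dataset()` generating
ground-truth interventional time courses so every stage can be validated
without access to the original assay.

## Preprocessing

**Loading normalization** corrects per-sample total-protein loading by
median centering on the log2 scale: center each antibody at its
cross-sample median, take the per-sample median of the centered values as
the correction factor (CF), and subtract the CF from the sample's original
values. The CF is reported on the linear scale (`2^CF`); samples with
`CF > 2.5` or `CF < 0.25` (strict inequalities) are flagged as loading
outliers. We interpret these bounds on the *linear* scale: they are
near-reciprocal multiplicative bounds, and log2-scale medians straddle 0
so a log2 reading could never reach 2.5 for sane data. The bound scale is
a config switch.

**Batch normalization** merges two batches that share vehicle-control
samples. Per antibody, the mean and SD of the control samples are
computed in each batch -- with t = 0 replicates averaged first so they do
not dominate -- and every individual batch-2 value `x` is mapped to
`mu1 + s1 * (x - mu2) / s2`. An antibody with `s2 = 0` falls back to
centering only, with a warning. The post-condition (batch-2 control
moments equal batch-1's to 1e-10) is asserted in the test suite.

**QC** additionally flags samples whose log2 variance across antibodies
exceeds 40, and computes per (cell line, phospho antibody, regime)
signal-to-noise ratios (mean / SD of the t = 0 replicates, on the linear
scale -- the statistic changes meaning on log2 values, so the scale is
configurable). SNR < 1 marks replicate groups for *review*, not automatic
exclusion. Every excluded sample carries exactly one primary reason code,
with CF bounds taking precedence over variance.

**Panel selection** keeps phospho antibodies observed in all cell lines
and collapses same-target antibody pairs whose Pearson correlation
exceeds 0.9 in *every* cell line (dropping the lexicographically later
name unless a priority order is given). **Replicate averaging** is the
log2 arithmetic mean, with replicate counts retained; **imputation** is
linear interpolation in real minutes for interior gaps and
nearest-observed-value fill at the boundaries (`stats::approx`,
`rule = 2`). The fixed order is: loading normalization (per batch) ->
batch normalization -> QC exclusions -> averaging -> panel selection ->
imputation.

## Salient changes and descendancy matrices

For each (phosphoprotein, context, inhibitor regime) a paired t test
compares the control and inhibitor time courses, paired by time point,
over all 7 times. Stimulus-responsive proteins whose control course is
"peak"-shaped get a retest restricted to the peak window, and the smaller
p-value is retained. The peak heuristic is fully specified here because
only its existence, not its constants, is standard: the maximum must lie
at an interior time index and exceed both endpoints by more than
`k_peak` (default 1) pooled replicate SDs; the window is the maximal
contiguous interior run above the half-height `(max + min(ends)) / 2`
containing the maximum, with minimum width 2. All constants are exposed.

P-values are corrected per (context, regime) across the protein panel
with the **two-stage adaptive linear step-up** procedure: stage 1 is the
linear step-up at `q' = q / (1 + q)`; if it rejects neither none nor all,
the null count is estimated as `m0 = m - r1` and stage 2 reruns the
step-up at `q' * m / m0`. One-stage BH is available behind a flag. A
change is **salient** iff its FDR value is below 5% *and* its absolute
effect (mean log2 control-vs-inhibitor ratio, recomputed over the peak
window when the retest was retained) is at least `tau` (default 1) times
the pooled replicate SD, itself df-weighted across both arms and averaged
over time points (window-matched when the retest is used). When no time
point carries replication the dataset-level median replicate SD is used
as a fallback. The procedure is heuristic by design; the FDR values are
not to be read as formal error rates.

Salient calls, signed by direction (-1 decrease, +1 increase under
inhibition), fill the **causal descendancy matrix** (phosphoproteins x
contexts, per regime): a nonzero entry marks the protein as a descendant
of the inhibited kinase in that context. `context_difference_stats()`
counts, per regime and unordered context pair, proteins salient in
exactly one of the two contexts, and reports the grand mean plus the
means over same-stimulus (cell-line comparison) and same-cell-line
(stimulus comparison) pairs.

## Joint interventional-DBN learning

Networks are learned per context as lag-1 dynamic Bayesian networks over
the sampled series (uneven real spacing is ignored: the DBN operates on
the 7 observation indices). For each child node, all parent sets up to
`d_max` are enumerated and scored in closed form; the intercept and the
child's own lag (self-persistence) are always included and never reported
as an edge. The score is the Gaussian marginal likelihood under a
unit-information Zellner g-prior (`g = n`) with a flat prior on the
intercept and reference prior on the noise variance; up to a constant,

```
log ML = (n - 1 - k)/2 * log(1 + g) - (n - 1)/2 * log(1 + g (1 - R^2)),
```

with `k` the rank of the centered predictor block. This choice makes
exact model averaging over parent sets cheap and fully reproducible; BIC
is offered as an alternative. Rank-deficient predictor sets are scored on
their reduced column space and flagged.

**Interventions** enter the likelihood: under the default `fix_baseline`
mode, rows belonging to a regime inhibiting node k have k's *predictor*
values clamped to the context's control t = 0 value -- the inhibitors are
catalytic, blocking the target's activity (outgoing influence) rather
than its abundance, and cells are pre-treated before stimulation, so the
blocked activity is pinned at its resting level. `drop_edges` removes the
target from parent sets for those rows instead; `none` disables masking
(used as a negative control -- the test suite shows masking strictly
improves directed-edge recovery).

**Joint learning** couples the contexts: the parent-set posterior in
context c is proportional to
`exp(log ML - eta_n |S delta priorParents| - lambda_n * D(S))`, where
`D(S)` is the expected edge disagreement with the other contexts under
their current marginals, `eta_n = eta * kappa_eta`, and
`lambda_n = lambda / (C - 1) * kappa_lambda` so the coupling pressure per
context does not grow with the number of contexts C. The coupled
posteriors are solved by mean-field iteration (prior-only
initialization, cyclic context updates in declared order, children in
node order, tolerance 1e-4 on the maximum edge-marginal change, at most
100 sweeps) -- exact joint inference over 32 coupled structures is
intractable, and the mean-field fixed point reproduces both analytic
limits (lambda -> infinity forces agreement; eta -> infinity concentrates
each child on the parent set closest to its prior parents), which the
test suite verifies by enumeration. The study-scale values lambda = 3,
eta = 15 are the defaults of `learning_config()`, but they belong to the
original parametrization of these penalties; the kappa scale constants
exist to absorb any difference, and all four numbers are reported in run
manifests.

Cell-line summary networks average the stimulus-specific edge-probability
matrices and list edges with mean probability strictly above 0.2, flagged
for prior membership.

## Held-out-inhibitor assessment

A test regime is held out; its targets must be network nodes, and
training keeps only regimes with disjoint targets (always maximal). With
the study's five regimes and a panel containing the mTOR/AKT/MEK readouts
but no FGFR or PI3K node, exactly three splits qualify -- the test suite
asserts this configuration. Gold-standard descendant sets are the salient
changes under the test regime per context; networks are re-learned from
the training regimes only, and predicted descendants of the test targets
are swept over the edge-probability threshold: at each threshold, nodes
reachable from a target through at least one kept edge count as
predicted descendants. TPR/FPR against the gold set trace an ROC curve
((0,0) and (1,1) appended, FPR-sorted with ties keeping maximal TPR,
monotonized, trapezoid-integrated). The node universe excludes the test
targets themselves by default: an activity-state readout of the inhibited
node responds trivially to its own inhibitor. Significance uses an
empirical null of uniform(0,1) edge-probability matrices with the add-one
estimator `p = (1 + #{null >= observed}) / (1 + n_null)`; `n_null`
defaults to 1000.

Reachability at a threshold is computed via widest-path bottleneck
probabilities (the maximal over paths of the minimal edge probability),
which reproduces breadth-first search on every thresholded graph at once;
the tests cross-check against an igraph BFS oracle.

## The synthetic-data generator

`sample_context_networks()` draws a base directed network at a given edge
density with signed weights, rewires a fraction of edges independently
per context, and rescales each weight matrix to a target spectral radius
(stable lag-1 dynamics; the diagonal holds a common self-persistence
term). `simulate_rppa_dataset()` then iterates

```
x(t+1) = baseline + W_eff' (x(t) - baseline) + basal + u(t+1) + process noise
```

with measurement noise on every observation, on the log2 scale.
Stimulus inputs are shaped per node: "sustained" is a step,
"peak" a difference of exponentials (rise 0.8, decay 2.5 step units,
normalized to unit maximum), reproducing the peak-vs-sustained dichotomy
the peak heuristic must detect. Inhibition scales the target's outgoing
row of W by an efficiency `alpha` (0 = complete blockade); the node's own
abundance is untouched, matching catalytic inhibitors. Because cells are
pre-treated before t = 0, every regime starts at the fixed point of its
*effective* dynamics under the basal drive, so blockade already shifts
descendant resting levels at the first time point. Replicate structure
mirrors the assay: many replicates at t = 0 (pure measurement
replicates), duplicate control trajectories at t > 0, single replicates
elsewhere. Batch effects (per-batch per-antibody affine maps on log2) and
outlier samples (global linear multipliers) can be injected to exercise
the normalization and QC stages.

What the simulator does *not* emulate: mechanistic (mass-action) kinetics,
saturation and feedback nonlinearity, single-cell heterogeneity, spatial
effects, antibody cross-reactivity, and the real assay's uneven
information content across antibodies. Passing tests on this generator
demonstrate that the pipeline's statistics and algorithms behave as
specified under the model class they assume (linear-Gaussian lag-1
dynamics with activity-blocking interventions); they cannot certify
performance on real lysate data.

## Benchmark scenarios and problem sizes

Two frozen scenarios (`benchmark_scenario()`) define the package's
validation studies; the test suite and `scripts/acceptance.R` both use
them.

* **Recovery** (directed-edge recovery): 10 nodes, 4 contexts, density
  0.15, rewiring 0.2, spectral radius 0.9, process SD 0.25 vs measurement
  SD 0.05, two stimulated nodes, three single-target inhibitors, 4
  replicates at t = 0. Process innovations dominate the excitation --
  this is the regime where lag-1 transitions identify directed edges.
  Evaluated over 20 seeds with interventional masking on, off, and on
  time-shuffled data (each node's series permuted independently, the
  negative control).
* **Assessment** (held-out-inhibitor evaluation): 20 nodes, 8 contexts,
  sparse strong-weight networks (density 0.06, weights 0.5--0.8,
  spectral radius at most 0.7, self-persistence 0.2), sustained
  stimulation (gain 3) with basal drive 1.5 on the three inhibitor
  targets, process SD 0.12. The sparsity keeps descendant sets compact
  and mid-sized -- with near-complete reachability or one-node gold sets
  the empirical null becomes too coarse to resolve significance -- and
  the basal drive plus sustained stimulation make inhibition effects
  persist across the full time course, the situation the 7-point paired
  test is designed for. Joint learning uses lambda = 2 across the 8
  contexts, pooling the shared structure exactly as joint learning is
  meant to.

These sizes keep parent-set enumeration exact (d_max = 2) and the whole
validation suite inside a desktop-scale run while preserving every
qualitative feature the analysis relies on.

## Numerical choices and degenerate inputs

* Paired test with zero-variance differences: p = 0 if the mean
  difference is nonzero (degenerate flag), p = 1 otherwise.
* `adaptive_fdr()` reports adjusted values on a scale where rejection is
  `q_fdr <= q`, consistent with the two-stage flags in all branches.
* SNR with zero replicate SD is flagged infinite; single-replicate groups
  are skipped with a warning.
* Imputation requires at least 2 observed points; series below that are
  left missing with a warning.
* Mean-field updates are damped only by the cyclic schedule; tie-breaks
  are fixed (contexts in declared order, children in node order) so runs
  are bit-reproducible. Non-convergence returns the last iterate with a
  warning and the final delta.
* All RNG flows through explicit integer seeds; no global state is
  consumed.

## Known limitations

The FDR-plus-effect-filter caller is heuristic (the peak retest takes a
minimum of two dependent p-values without correction); its family-wise
null-call rate is verified empirically, not guaranteed analytically. The
mean-field joint posterior is an approximation whose quality degrades at
intermediate coupling strengths. Edge probabilities are unsigned -- the
model does not distinguish activation from inhibition. Inhibitor targets
are assumed known and on-panel; off-panel targets contribute data without
interventional masking. The assessment metric scores global agreement
with held-out interventions, not the identification of context
*differences* specifically.
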