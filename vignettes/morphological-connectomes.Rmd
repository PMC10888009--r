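---
title: "Morphological connectomes from gray-matter intensity distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological connectomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`morphnet` treats each brain region of a single subject as a probability
distribution: the distribution of gray-matter (GM) intensity values over the
voxels of that region, under a 90-region non-cerebellar AAL parcellation.
Two regions are "connected" to the degree that their intensity distributions
are similar. For regions $i$ and $j$ with kernel-density-estimated
distributions $P_i$ and $P_j$ evaluated on a grid shared across the
subject's regions, the edge weight is the Kullback–Leibler-based similarity

$$\mathrm{KLS}(i,j) \;=\; \exp\!\big(-\big[\mathrm{KL}(P_i \,\|\, P_j) +
\mathrm{KL}(P_j \,\|\, P_i)\big]\big) \;\in\; (0, 1],$$

which is symmetric, equals 1 exactly when the two distributions coincide,
and tends to 0 as their supports separate. The 90×90 KLS matrix is the
subject's morphological connectome: it needs no tractography, no time
series, and no second subject (unlike group-level structural covariance).

Downstream, each connectome is binarized at a sweep of sparsity thresholds
$S = 0.10, 0.11, \dots, 0.34$ (fraction of the $N(N{-}1)/2$ possible edges
retained), and each binary graph is summarized by the standard small-world
and efficiency metrics — clustering coefficient $C_p$, characteristic path
length $L_p$, their normalized forms $\gamma = C_p/\langle C_p^{rand}
\rangle$ and $\lambda = L_p/\langle L_p^{rand}\rangle$ against
degree-preserving rewired references, small-worldness $\sigma =
\gamma/\lambda$, global and local efficiency — plus nodal degree, nodal
efficiency and betweenness centrality. A metric's trapezoidal area under its
curve over the sweep (AUC) is the unit of statistical comparison, removing
the arbitrariness of any single threshold.

Group differences in AUC are tested by label-permutation (mean difference,
two-tailed, $p = (1 + \#\{|\Delta_b| \ge |\Delta_{obs}|\})/(B+1)$), with
Benjamini–Hochberg FDR within each nodal family (one metric × one contrast
across the 90 nodes). Clinical associations use partial correlation with age
and a 0/1 sex indicator as covariates. Finally, connectome feature vectors
(the strict upper triangle; 4005 features, or 105 for the 15-region
BD-vs-MDD subset) feed a reducer × classifier cascade under stratified
5-fold cross-validation, with per-feature Gaussian-process regression on the
3-level medication code used to residualize medication effects.

## Numerical and design choices

**KDE.** Gaussian kernel, Silverman rule-of-thumb bandwidth per region, a
128-point grid spanning the subject's pooled sample range ± 3 pooled
bandwidths, shared across the subject's regions so every pairwise divergence
is computed on a common support. Densities are floored at $10^{-10}$ and
renormalized; this keeps $\log(p/q)$ finite where supports barely overlap
and bounds the worst-case divergence. Zero-variance input falls back to
bandwidth $10^{-3}$ with a warning.

**Divergence discretization.** KL is computed on bin masses
($p_i = \text{density} \times \Delta x$, renormalized), so `kl_divergence`
is the exact discrete KL of the gridded distributions; it is clipped at 0
against floating-point cancellation, making KLS ≤ 1 and KLS = 1 on
identical profiles exact.

**Thresholding.** The edge count at sparsity $S$ is round-half-up of
$S \cdot N(N-1)/2$ (at $S = 0.10$ on 90 nodes: 401 edges). Ties are broken
by weight descending, then (row, column) ascending, so the graph is a
deterministic function of the matrix.

**Metric conventions.** $C_p$ averages local clustering over *all* nodes
(degree < 2 contributes 0); $L_p$ averages shortest paths over connected
ordered pairs only (efficiency metrics handle disconnection through
$1/\infty = 0$, so no infinities propagate at sparse thresholds);
betweenness is unnormalized Brandes with even splitting over equal-length
geodesics, each unordered pair counted once. Local efficiency of a node is
the global efficiency of the subgraph induced by its neighbors (0 below 2
neighbors). Random references are Maslov–Sneppen double-edge swaps (10
attempts per edge, 100 references by default, seeded); every reference is
asserted to preserve the exact degree sequence. With `n_random_refs = 0`
the normalized metrics are reported as `NA` rather than silently computed
against nothing.

**Statistics.** Permutation $p$-values use +1 smoothing (minimum
$1/(B+1)$, never 0). The FDR family is one nodal metric × one contrast
(90 tests); global metrics are reported uncorrected, mirroring the
convention of applying FDR to nodal measures only. BH is implemented
directly (step-up with monotonicity enforcement) and is tested against both
a brute-force implementation and `stats::p.adjust`.

**Confound residualization.** One GP regression per feature maps the
medication code (1 = none, 2 = antidepressant, 3 = antidepressant +
antipsychotic) to the expected feature value; residuals replace features.
Because the code takes ≤ 3 distinct values, the $n \times n$ GP algebra
collapses onto the unique codes, so thousands of per-feature GPs cost
m×m solves. The RBF lengthscale is fixed at 1 on the code scale; signal and
noise variances are chosen per feature by maximizing the exact marginal
likelihood over a fixed grid (noise grid down to $10^{-4}$ so noise-free
relationships are interpolated). GPs are fitted on training folds only and
applied unchanged to held-out subjects; a constant training confound
degenerates to mean-centering with a warning. Fitting the residualization
inside the folds is a deliberate deviation from pipelines that residualize
before cross-validation: it avoids test-fold leakage.

**Learners.** The targeted R stack ships no SVM, random-forest or boosting
package, so the cascade is implemented in-package: an RBF-kernel SVM in
least-squares formulation ($C = 1$, median-heuristic kernel width; one
linear solve, deterministic), a 500-tree random forest (variance-reduction
trees, $\sqrt{p}$ features per node, bootstrap resampling), and
second-order gradient-boosted trees with logistic loss (depth 3, shrinkage
0.1, $\lambda = 1$, 150 rounds, 50% column subsampling per node — the
column subsampling is a small-$n$ generalization choice). All three share
one exact-greedy C++ tree learner driven by R's RNG, so `set.seed` governs
them. The reducers are a symmetric autoencoder (reconstruction loss;
bottleneck 64 for 4005-feature input, 16 for 105) and a supervised
feedforward network whose penultimate layer provides the reduced features;
both have one hidden layer per side with width geometric between input and
bottleneck, tanh activations, full-batch Adam, a fixed epoch budget (200 by
default), and seeded initialization, making them deterministic. Balanced
accuracy from pooled cross-validation confusion counts is the headline
number; the fold-mean is also reported for comparability with studies that
average folds. The positive class is the patient group (HC-vs-patients) or
BD (BD-vs-MDD).

## What the synthetic generator emulates — and what it does not

Each region $r$ draws intensity samples from a truncated normal on
$(10^{-4}, 1-10^{-4})$ with base mean
$\mu_r = 0.55 + 0.25\sin(2\pi (r-1)/R)$ (spanning [0.3, 0.8]), sd 0.08,
plus a per-subject jitter (sd 0.02), group effects (planted mean shifts and
sd scalings per region), and optionally an additive medication effect. The
smooth periodic mean profile is deliberate: regions adjacent in the profile
have similar distributions, so the KLS matrix has ring-lattice-like
structure whose subject-specific jitter adds shortcuts — graphs in the
small-world regime ($\sigma > 1$ across the whole sweep), which is what the
estimability validation expects of real gray-matter networks. Covariates
mirror a typical mood-disorder case-control sample: age ~ N(21.5, 10²)
truncated at 16, ~75% female, medication-code distributions with roughly
10% drug-naïve patients, HAMD/HAMA scores for patients and YMRS for BD
only. One global seed fans out to per-subject substreams, so enlarging a
cohort never perturbs existing subjects.

The generator does *not* emulate spatial voxel correlation, scanner noise,
partial-volume effects, registration error, or any longitudinal structure.
A green test therefore establishes that the pipeline's statistics behave
correctly on data with the assumed distributional structure — not that the
published effect sizes or accuracies would reproduce on real MRI.

Two lessons from designing the effect-recovery world are worth recording.
First, a *pure mean shift* of one region can be nearly invisible to the
connectome: it slides the region along the smooth base-mean profile into
another region's distributional neighborhood, changing *which* regions it
resembles but barely changing how many. Planted effects therefore perturb
both location (+0.1) and scale (×1.3), a shape change every neighbor sees.
Second, nodal degree under a fixed edge budget is zero-sum, so planting
effects in a large fraction of regions (e.g. 4 of 20) produces spillover
significance everywhere; recovery is assessed at the realistic 90-region
scale where spillover dilutes.

## Interpreting the calibration and recovery tests

The acceptance suite checks, at reduced but honest scale: KLS identity and
matrix geometry; $\sigma > 1$ at all 25 thresholds for the default
20-subject cohort (100 rewired references); oracle equivalence of the KDE
pipeline against Gaussian closed forms (within 10% at $n = 10^4$), of every
graph metric against igraph on 50 random graphs (to $10^{-9}$), and of BH
against brute force (exactly, 1000 vectors); permutation type-I error in
[0.03, 0.07] over 200 null cohorts; label-permutation rejection in
[0.02, 0.08] over 100 null classification tasks; all-4 planted-region FDR
recovery in ≥ 80% of 25 runs; partial-correlation recovery of $\rho = 0.5$
within ±0.12 in ≥ 90% of 100 seeds; ≥ 0.95 balanced accuracy for all nine
reducer × classifier cells on separable data; chance-level performance
after confound residualization on confounded-null tasks (10-seed mean in
[0.4, 0.6] — the band is read as a mean because a single 40-subject CV
estimate has sampling sd ≈ 0.08); and a no-leakage canary (noise features
with the supervised reducer and confound path must stay at chance).

## Known limitations

* Weighted-network variants, modularity/rich-club analyses and
  Jensen–Shannon or Wasserstein similarity kernels are out of scope.
* The permutation test permutes precomputed AUC values, not subject labels
  upstream of network construction; the two differ if network construction
  itself were group-dependent (it is not, here).
* The 15-region feature subset is a fixed list; with user data the region
  subset should come from the user's own nodal statistics.
* Hyperparameters of the learners are fixed defaults, not searched; the
  classification module measures separability under an honest protocol
  rather than maximizing accuracy.
* The NIfTI reader is deliberately minimal (scalar single-file NIfTI-1,
  both endiannesses, gzip); anything exotic should be converted upstream.
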