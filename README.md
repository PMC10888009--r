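# morphnet

Single-subject **morphological brain connectomes** from gray-matter (GM)
intensity distributions, and everything needed to analyze them: sparsity-swept
graph-theory metrics, permutation statistics with FDR control, clinical
partial correlations, and a reducer × classifier machine-learning cascade —
plus a synthetic cohort generator so the entire pipeline runs and is tested
without any imaging data.

## Who this is for

Researchers studying structural brain-network alterations in psychiatric or
neurological populations (e.g. distinguishing bipolar disorder from major
depressive disorder) from T1-weighted MRI, working from per-region GM
intensity samples under a 90-region non-cerebellar AAL parcellation — and
anyone who needs a tested, deterministic reference implementation of the
KLS-connectome methodology.

## The method in brief

Each region of one subject is a distribution of GM intensity values. For
regions *i*, *j* with KDE-estimated densities *Pᵢ*, *Pⱼ* on a shared grid,
the edge weight is the Kullback–Leibler-based similarity

    KLS(i,j) = exp(−[KL(Pᵢ‖Pⱼ) + KL(Pⱼ‖Pᵢ)])  ∈ (0,1],

giving a 90×90 symmetric connectome with unit diagonal per subject. Each
connectome is binarized at sparsities S = 0.10…0.34 (step 0.01), and each
graph summarized by Cp, Lp, γ, λ, σ = γ/λ (against 100 degree-preserving
rewired references), Eglob, Eloc, and nodal degree/efficiency/betweenness.
The area under each metric-vs-sparsity curve (AUC) is compared between
groups by permutation tests (10,000 by default) with Benjamini–Hochberg FDR
over nodal families; metric–symptom associations use partial correlation
with age/sex covariates; and connectome feature vectors (upper triangle:
4005 features, or 105 for a 15-region prefrontal/fronto-limbic subset)
are classified by {none, autoencoder, DNN} × {SVM, random forest, gradient
boosting} under stratified 5-fold CV with Gaussian-process residualization
of medication status.

## Worked example

```r
library(morphnet)

# a synthetic cohort: 15 controls, 15 patients with a planted distribution
# shift in the right middle frontal gyrus (region 8: mean +0.1, sd x1.3)
design <- cohort_design(
  n_per_group = c(HC = 15L, MDD = 15L),
  effects = data.frame(group = "MDD", region = 8L,
                       mean_shift = 0.1, sd_scale = 1.3),
  seed = 42L)
ch <- generate_cohort(design)

# one subject's KLS connectome
S <- build_similarity_matrix(ch$samples[[1L]])
S[1:3, 1:3]
#>               Precentral_L Precentral_R Frontal_Sup_L
#> Precentral_L     1.0000000    0.7867904     0.3769634
#> Precentral_R     0.7867904    1.0000000     0.6345675
#> Frontal_Sup_L    0.3769634    0.6345675     1.0000000

# threshold at 15% sparsity and summarize the graph
g <- sparsity_threshold(S, 0.15)
gm <- global_metrics(g, n_random_refs = 100L, seed = 1L)
round(unlist(gm), 3)
#>     Cp     Lp  gamma lambda  sigma  Eglob   Eloc
#>  0.761  5.918  4.730  3.001  1.576  0.328  0.879
```

σ = 1.58 > 1: the network is small-world (much more clustered than its
degree-matched rewired references, γ = 4.7, at a moderate path-length cost,
λ = 3.0). Now the group comparison on nodal degree AUC:

```r
met <- cohort_metrics(build_cohort_matrices(ch), n_random_refs = 0L, seed = 1L)
tab <- compare_groups(met$auc, ch$subjects$group, B = 999L, seed = 7L)
deg <- tab[tab$family == "degree", ]
head(deg[order(deg$p_perm), c("region", "observed_diff", "p_perm", "q_fdr")])
#>               region observed_diff p_perm   q_fdr
#> 15     Frontal_Mid_R     0.5623333  0.007 0.39000
#> 46 ParaHippocampal_L    -0.4326667  0.011 0.39000
#> 22 Frontal_Inf_Orb_L     0.3826667  0.013 0.39000
#> 28       Olfactory_L     0.5413333  0.024 0.41625
#> 13 Frontal_Sup_Orb_R    -0.3426667  0.026 0.41625
#> 73         Angular_R     0.7863333  0.028 0.41625
```

The planted region ranks first (uncorrected p = 0.007, MDD > HC in degree
AUC), but at n = 15/15 it does not survive FDR across 90 nodes
(q = 0.39) — at n = 30/30 the same effect is FDR-significant in ≥ 80% of
seeded runs (see the acceptance suite). This is the method working as
designed: nodal inference over 90 regions needs realistic sample sizes.

## Pipeline and CLI

```r
cfg <- default_run_config(seed = 1L, output_dir = "results")
res <- run_pipeline(cfg)   # cohort -> matrices -> metrics -> stats -> ML grid
```

or from the shell (after install):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","morphnet.R",package="morphnet"))')" \
    run-all --config cfg.yaml --seed 1 --out results
```

Commands: `simulate`, `build-networks`, `metrics`, `stats`, `classify`,
`run-all`. Intermediates are cached by content key; identical config + seed
reproduces a byte-identical results bundle.

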