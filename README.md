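# scExemplar

Cell-type **exemplar signatures** from single-cell RNA-seq compendia, and
what they reveal when used to deconvolve bulk tumors.

Bulk tumor RNA-seq mixes the transcriptomes of malignant cells with those
of an entire microenvironment — immune, stromal, vascular and other cell
types whose abundance can matter as much for a patient's outcome as the
tumor's own subtype. Public single-cell archives now hold enough datasets
to derive reference profiles for hundreds of cell types, but the datasets
come from different platforms, and naive concatenation makes batch the
dominant signal. scExemplar is a workflow for researchers who want to
quantify cell types in bulk cohorts using references assembled, unsupervised,
from many heterogeneous single-cell datasets, and to ask whether any of
those cell types stratify patient survival.

## The method

1. **Rank centroids.** Each dataset is clustered independently (Louvain on
   a shared-nearest-neighbor graph over the top principal components).
   Expression in every cell is replaced by within-cell ranks (average ranks
   on ties), and a cluster's profile is the per-gene mean rank across its
   cells. Ranks are invariant to any strictly monotone per-cell transform,
   which is precisely the class of distortions that separates platforms.
2. **Reciprocal top-K enrichment (RTKE).** Two centroids are similar when
   each one's top 10% of genes is enriched in the other's. The score is
   the hypergeometric upper-tail surprise of the top-k overlap on the
   shared gene universe G:

   `RTKE(a, b) = -log10 P(X >= |T_a ∩ T_b|)`, `X ~ Hypergeom(G, |T_a|, |T_b|)`

   computed in log space so strong matches never underflow.
3. **Meta-clustering.** Centroid pairs scoring above an empirical quantile
   of the score distribution (upper 0.006 tail by default) form a weighted
   graph; Louvain communities of that graph are the **exemplars** — one
   per inferred cell type, its signature the unweighted mean of member
   centroids' rank profiles.
4. **Signature matrix.** For each gene, the gap score is the highest
   exemplar value minus the second highest; the top 20% of genes by gap
   form the deconvolution reference.
5. **Deconvolution.** A CIBERSORT-style absolute-mode work-alike:
   per-sample z-scored non-negative least squares (optional nu-SVR), raw
   scores not forced to sum to one, detection at a normalized score of
   0.01 or greater.
6. **Patient stratification.** Per exemplar and cohort, scores are split
   by a decision tree: excluded if fewer than 10 positive scores; zeros
   vs positives if more than half the scores are zero; otherwise a
   two-component Student-t mixture (EM, BIC vs one component) splits at
   the component means; otherwise the median.
7. **Signature outcome separation (SOS).** Cox proportional hazards of
   up vs down groups — naive (univariate, log-rank p) and
   subtype-corrected (published subtype as covariate, Wald p) — with
   Benjamini-Hochberg FDR across exemplar-cohort pairs.
8. **Tumor cell-type map.** Samples are laid out in 2-D by the similarity
   of their exemplar score vectors (seeded force-directed layout over a
   kNN correlation graph), clustered spatially with HDBSCAN
   (min cluster size 20), compared against published groupings with the
   adjusted Rand index, and probed per disease with cluster-vs-main-cluster
   survival comparisons and differential exemplars (Student t).

Everything is testable offline: seeded generators produce multi-dataset
compendia with planted cell types under monotone platform distortions,
in-silico bulk mixtures with a dominant tumor component (integer
percentages, tumor fraction uniform on 50–90%), and survival tables with
planted hazard ratios.

## Worked example

```r
library(scExemplar)

comp <- simulate_compendium(seed = 1)          # 4 datasets, 3 planted types
centroids <- list()
for (d in names(comp$datasets)) {
  em <- comp$datasets[[d]]
  ca <- cluster_dataset(em, seed = 1)
  centroids <- c(centroids, dataset_centroids(em, ca, min_cells = 1))
}
res <- derive_exemplars(centroids, run_config(edge_quantile = 0.73), seed = 1)
vapply(res$exemplars, function(e) length(e$member_cluster_uids), integer(1))
#> X1 X2 X3
#>  4  4  4
```

Three exemplars, each assembled from one cluster per dataset — the planted
cell types, re-identified across the platform distortions. Build the
signature matrix and deconvolve simulated bulk mixtures:

```r
sig <- signature_matrix_from_exemplars(res$exemplars)   # 120 genes x 3
mx  <- simulate_mixtures(exemplar_matrix(res$exemplars), n = 200, seed = 1)
dr  <- detect(deconvolve(mx$bulk, sig))
round(dr$normalized_scores[1:3, ], 3)
#>            X1    X2    X3
#> mix0001 0.565 0.401 0.034
#> mix0002 0.639 0.178 0.182
#> mix0003 0.607 0.367 0.026
round(mx$truth$proportions[1:3, ] / 100, 3)
#>           X1   X2   X3
#> mix0001 0.53 0.42 0.05
#> mix0002 0.63 0.19 0.18
#> mix0003 0.59 0.38 0.03
```

Estimated fractions track the planted mixing proportions. Stratify the
mixtures by their X1 score and test outcome separation against survival
simulated with a true hazard ratio of 2 for the up group:

```r
scores <- setNames(dr$normalized_scores[, "X1"], rownames(dr$normalized_scores))
g  <- split_samples(scores, seed = 1)        # rule: "bimodal", 62 up / 44 down
sv <- simulate_survival(data.frame(sample_id = g$sample_ids,
                                   group = unname(g$label)),
                        hr = 2, censor_frac = 0.2, seed = 1)
fit_sos(g, sv, cohort = "synthetic", exemplar = "X1")
#>      cohort exemplar n_up n_down hazard_ratio           p      wald_p model
#> 1 synthetic       X1   62     44     2.090802 0.001263424 0.001566317 naive
```

The fitted hazard ratio (2.09) recovers the planted one, and the log-rank
p-value flags the separation.

A thin command-line dispatcher over the same functions is provided in
`exec/scexemplar` (subcommands: `cluster`, `rtke`, `exemplars`,
`sigmatrix`, `deconv`, `group`, `sos`, `simulate`).

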