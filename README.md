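# degnet

Multi-dataset differential-expression meta-analysis with
network-proximity extraction of a core gene neighborhood.

## The problem

Transcriptomic comparisons of normal tissue, primary tumors and metastatic
lesions are noisy and platform-dependent: a gene called differentially
expressed (DE) in one cohort frequently fails to replicate in the next.
One robust remedy is a *set-intersection meta-analysis*: run the same
two-group contrast (metastatic vs normal, primary vs normal, metastatic vs
primary — MvsN, PvsN, MvsP) in several independent **test** datasets, keep
only genes that are DE *with the same direction* in every one of them, and
then screen the survivors against further **validation** datasets.  The
consensus genes that separate metastatic from primary samples (the **core
genes**) are then used to interrogate a weighted protein–protein
interaction (PPI) network: genes topologically close to the core set are
candidate co-drivers even when they missed the expression cutoffs
themselves.

`degnet` implements that whole chain as composable, tested R functions:

1. **Preprocessing** per dataset: absent-call (P/A) filtering, quantile
   normalization, median-SD variance filtering, highest-IQR probe→gene
   collapse (or log2 preparation of pre-normalized matrices).
2. **Outlier QC**: per-group inter-sample Pearson correlation; each
   sample's mean correlation is standardized into a *Number-SD* score and
   samples scoring below −2 are removed.
3. **Differential expression**: empirical-Bayes moderated t-test (variance
   prior fitted by moment matching on log variances with trigamma
   inversion), Benjamini–Hochberg correction, DEG call at |log2FC| > 0.5
   and adjusted p < 0.05.
4. **Meta-integration**: direction-consistent intersections per comparison
   class, validation filtering, core-gene selection, and direction /
   concordance tables (uniform, one-discordant, heterogeneous).
5. **Core network**: STRING-style weighted graph → giant component →
   topological overlap similarity

   TOM(i,j) = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),
   l_ij = Σ_u a_iu a_uj,  k_i = Σ_u a_iu,

   1 − TOM distance, Dijkstra all-pairs shortest paths SP, and the
   proximity score

   D_j = ( Σ_{i∉C} SP_ij / NC − Σ_{i∈C} SP_ij / C ) / ( Σ_i SP_ij / (NC+C) ),

   where C and NC count core and non-core nodes.  D_j > 0 means node j is
   closer to the core set than to the network at large; the induced
   subgraph on {core} ∪ {D_j > 0} is the extracted core network, reported
   with descriptive statistics (diameter, transitivity, density, mean
   distance, degree, betweenness).
6. **Synthetic data**: generators for multi-dataset studies (planted DEGs
   with monotone progression trends, planted decorrelated outliers,
   probe-level duplication, intensity-dependent absent calls) and PPI edge
   lists with a planted dense module, so every stage is testable against a
   known ground truth without any downloads.

## Worked example

A fully synthetic study — 3 test and 2 validation datasets, 1000 genes,
three groups of 10 samples — through the entire chain:

```r
library(degnet)
cfg <- list(
  outdir = file.path(tempdir(), "demo"),
  simulation = list(seed = 42L, n_genes = 1000,
                    n_datasets_test = 3, n_datasets_validation = 2,
                    group_sizes = c(normal = 10, primary = 10, metastatic = 10)))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result>
#>   analyses:           15
#>   common MvsN:         61 genes
#>   common PvsN:         20 genes
#>   common MvsP:         84 genes
#>   final DEGs:         107
#>   core genes:         84
#>   core network:       28 nodes / 63 edges
```

15 analyses = 5 datasets × 3 comparisons.  The per-class "common" counts
are direction-consistent intersections across the three test datasets;
107 of their union survive the validation screen; the MvsP consensus
within that final set forms the 84 core genes, of which those present in
the simulated PPI seed the proximity scoring.  The top-scoring nodes:

```r
head(as.data.frame(res$scores[order(-res$scores$Dj), ]), 5)
#>      node        Dj is_core
#> 43 G00070 0.7869103    TRUE
#> 15 G00015 0.7770354    TRUE
#> 4  G00004 0.7672170    TRUE
#> 8  G00008 0.7575019    TRUE
#> 12 G00012 0.7158889    TRUE
str(res$descriptives[c("n_nodes", "n_edges", "transitivity",
                       "density", "mean_distance", "diameter")])
#> List of 6
#>  $ n_nodes      : num 28
#>  $ n_edges      : num 63
#>  $ transitivity : num 0.409
#>  $ density      : num 0.167
#>  $ mean_distance: num 2.26
#>  $ diameter     : num 4
```

All artifacts (clean matrices, per-analysis DE tables, gene lists, Dj
score table, core-network TSV/GraphML, direction table, md5 manifest) are
written under `cfg$outdir`; re-running the same config reproduces them
byte for byte.

Every stage is equally usable stand-alone — see `?quantile_normalize`,
`?number_sd_scores`, `?moderated_t_test`, `?intersect_class`,
`?tom_similarity`, `?dj_scores`, and the methods vignette
(`vignettes/degnet-methods.Rmd`) for the modelling details.

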