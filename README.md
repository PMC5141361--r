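# mirtopnet

Reconstruction of mixed transcriptional and post-transcriptional regulatory
networks from matched miRNA and gene expression profiles of two or more
sample classes — for instance, CD34+ cells of patients with a
myeloproliferative neoplasm compared in parallel against bone-marrow and
peripheral-blood healthy controls. The package is aimed at systems-biology
analysts who have log2 expression matrices, pathway topologies and regulation
catalogs in hand and want a single reproducible route from those inputs to a
provenance-tagged network of deregulated pathway paths wired together by
miRNAs and transcription-factor circuits.

## What it computes

The pipeline combines a knowledge-based and an *ab initio* arm:

1. **Filtering.** miRNAs weakly expressed (lowest 25% of average expression)
   and/or poorly variable (Shannon entropy `H < 1.4` bits over 10 equal-width
   bins) are removed; removal sets are computed on the original matrix and
   unioned.
2. **Expression-supported targeting.** For each predicted miRNA–target pair
   (prediction score ≥ 0.8), the Pearson correlation `r` between the two
   profiles is tested; pairs with `r < −0.5` at Benjamini–Hochberg
   `FDR < 0.1` (two-sided p from `t = r·sqrt((n−2)/(1−r²))`) are kept as
   *supported* interactions.
3. **Topological pathway analysis.** Pathway graphs are augmented with
   validated and supported miRNA edges (validated evidence takes precedence),
   moralized, min-fill triangulated and decomposed into a clique tree. The
   Gaussian graphical model the pathway defines is fitted by the decomposable
   maximum-likelihood formula (an iterative-proportional-scaling fitter is
   exported and tested against it). Two permutation statistics are computed
   per pathway — a mean statistic `(n_a n_b / n) · d' K d` (class mean
   difference `d` weighted by the pooled concentration `K`) and a variance
   statistic (log-likelihood ratio of class-specific versus pooled fits) —
   and BH-adjusted across pathways; a pathway is significant when
   `min(q_mean, q_var) ≤ 0.1`. Within significant pathways, the same
   statistics are evaluated per clique; *paths* (clique sequences between
   leaf cliques) are scored by the mean of `−log10 min(p_mean, p_var)`; the
   top 10 paths are merged into a *meta-pathway*, which is re-analyzed, and
   paths in the upper quartile of the re-analysis scores are reported.
4. **Feed-forward circuits.** TF–miRNA–gene triangles are enumerated in two
   topologies (TF master: TF regulates the miRNA and the gene, miRNA targets
   the gene; miRNA master: miRNA targets both the TF transcript and the
   gene, TF regulates the gene), kept when all three pairwise `|r| ≥ 0.5`,
   and classified as coherent/incoherent feed-forward loops from the edge
   signs (miRNA arms count as repression).
5. **Assembly.** Per-comparison networks are merged (union on node ids and
   `(src, dst, etype)` edges, provenance sets unioned), circuits sharing at
   least one node are nested onto the network, fold changes
   (`mean log2 A − mean log2 B`, optionally mutation-stratified) are attached
   per comparison, and the result exports to GraphML/SIF (Cytoscape-loadable)
   and lossless JSON.

A seeded synthetic-data generator (`simulateBundle`) emulates the assumed
statistical structure — a mean shift planted along one pathway path,
bivariate-normal anticorrelated miRNA–target pairs, latent-driver circuits —
so every stage is testable offline, with `evaluateRecovery` scoring
precision/recall against the planted truth.

## Worked example

```r
library(mirtopnet)

bundle <- simulateBundle(syntheticConfig(seed = 1))
result <- runPipeline(list(
  bundle = bundle, seed = 1,
  comparisons = list(bm = list(case = "case", control = "ctrlA"),
                     pb = list(case = "case", control = "ctrlB")),
  thresholds = list(nPerm = 499)))

result$network
#> RegulatoryNetwork: 28 nodes (3 miRNA), 31 edges
#> edge types: activation=16, inhibition=8, binding=4, mirna_validated=2, mirna_predicted=1

result$comparisons$bm$pathwayTests[, c("pathway_id", "p_mean", "p_var",
                                       "q_mean", "q_var", "significant")]
#>   pathway_id p_mean p_var q_mean q_var significant
#> 1        pw1  0.002 0.692  0.006 0.788        TRUE
#> 2        pw2  0.736 0.788  0.736 0.788       FALSE
#> 3        pw3  0.014 0.596  0.021 0.788        TRUE

head(result$circuits[, c("topology", "tf_id", "mirna_id", "gene_id",
                         "coherence", "comparison")], 2)
#>       topology tf_id mirna_id gene_id  coherence comparison
#> 1 mirna_master g0299   mir013   g0295   coherent         bm
#> 2 mirna_master g0300   mir014   g0296 incoherent         bm

evaluateRecovery(result, bundle$truth)
#>                component precision recall n_predicted n_truth
#> 1 supported_interactions 0.7142857      1          14      10
#> 2     meta_pathway_nodes 0.1785714      1          28       5
#> 3       final_path_nodes 0.1785714      1          28       5
#> 4               circuits 1.0000000      1           4       4
```

Reading the output: the merged network keeps the 5-node planted path (recall
1 for both the meta-pathway and the final path selection) inside pathway
`pw1`, correctly flagged by the whole-pathway mean test (`q_mean = 0.006`);
`pw3` is a borderline co-detection driven by two planted anticorrelated
targets sitting in its scaffold. All 10 planted miRNA–target pairs pass the
anticorrelation filter (supported recall 1); the extra "predicted" pairs
behind the 0.71 precision are the anticorrelated arms of the planted
circuits, which legitimately pass the same filter. All 4 planted circuits
are recovered with their expected coherence labels. At this desk scale
(25-node pathways) the meta-pathway spans most of a significant pathway,
hence the low node precision; on real pathway collections (hundreds of
nodes) the top-10-path merge is far more selective.

A small ready-made bundle ships with the package:

```r
bundle <- readBundle(system.file("extdata", "bundle_mini", package = "mirtopnet"))
```

Configurations can also live in YAML (`readPipelineConfig`), with a bundle
directory written by `writeBundle` as `input_dir`.

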