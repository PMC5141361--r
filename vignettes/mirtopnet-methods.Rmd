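---
title: "Methods: miRNA-integrated pathway topology and circuit discovery"
author: "mirtopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-integrated pathway topology and circuit discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtopnet)
```

## The model in brief

`mirtopnet` reconstructs a mixed regulatory network from matched miRNA and
gene log2 expression matrices profiled over one case class and one or more
control classes. Two arms feed one merged network. The knowledge-based arm
asks *which pathway subtopologies are deregulated* and *which miRNAs plug
into them*; the ab initio arm asks *which TF–miRNA–gene feed-forward circuits
are supported by strong pairwise correlations*. Both arms are run once per
case–control comparison; parallel comparisons (e.g. against bone-marrow and
peripheral-blood controls) are deliberately kept separate and merged only at
the end, because control populations can differ systematically from each
other.

### Expression filtering

miRNA features are dropped when weakly expressed (per-feature mean below the
0.25 empirical quantile of all means) and/or uninformative across samples.
"Poorly variable" is operationalized as Shannon entropy below 1.4 bits: each
feature's own range is split into 10 equal-width bins (right-open, last bin
closed) and `H = -sum(p_b * log2(p_b))` is computed over the bin occupancy
fractions, so `H` lies in `[0, log2 10 ≈ 3.32]` and is invariant to affine
rescaling. A constant profile has `H = 0` by convention. Nothing in the
filter's intent pins down the bin count or whether entropy should be taken on
the log2 or the linear scale; we fixed 10 bins on the log2 values (the scale
everything else uses) because it keeps the 1.4-bit threshold comfortably
inside the attainable range — a normal profile spanning ~5 standard
deviations scores about 3 bits, a near-constant one far below 1. Both removal
sets are computed on the *original* matrix and unioned, which makes the
composition of the two filters exactly order-insensitive (the quantile is not
recomputed after entropy removal).

### Supported miRNA–target interactions

Predicted pairs passing the score filter (`score >= 0.8` by default; a
top-quartile mode exists for score scales that are not comparable across
sources) and present in both matrices form the testing family. Pearson
correlations between miRNA and target profiles are converted to two-sided
p-values via the exact t transform and Benjamini–Hochberg adjusted across
exactly that family, so the family is reproducible from the inputs alone. A
pair is *supported* when `r < -0.5` and `q < 0.1`, both strict. Two-sided
p-values with a directional magnitude filter are the conservative choice when
sidedness is not otherwise specified; an anticorrelation this strong is
mechanistically consistent with target repression. BH is used because it is
the field default when only "FDR" is named.

### Pathway augmentation and the Gaussian graphical model

Pathway graphs are typed edge lists (activation, inhibition, undirected
binding). Augmentation adds, for each miRNA with at least one target already
annotated in the pathway, the miRNA node and one directed repressive edge per
such target; an edge is typed `mirna_validated` when the pair has reporter-
assay-grade evidence (precedence) and `mirna_predicted` when it is supported
only by anticorrelation. Genes are never added — the pathway's gene content
is the curator's statement, the miRNAs are the data-driven enrichment.

For testing, the augmented graph is moralized (directions dropped, co-parents
married; binding edges pass through as plain adjacencies) and triangulated
with the min-fill elimination heuristic, ties broken by lexicographic node
id so the output is deterministic. Maximal cliques of the chordal cover are
arranged in a junction tree by a deterministic maximum-weight (intersection
size) Kruskal pass; only cliques with non-empty intersections are joined, so
disconnected pathways yield a forest whose components are analyzed
separately. The Gaussian graphical model constrained to this chordal graph is
fitted in closed form from clique and separator blocks of the sample
covariance; the generic iterative-proportional-scaling fitter
(`ipsCovariance`) is exported and its agreement with the closed form (within
1e-6 on decomposable models) is part of the test suite. Edge signs play no
role in the Gaussian model — they are kept for reporting only.

### Permutation mean and variance tests

With classes `a` and `b` (ML covariances `S_a`, `S_b`, pooled within-class
`S_p`), two statistics are computed on the GGM fit:

* mean: `T_m = (n_a n_b / n) * d' K_p d`, with `d` the class mean difference
  and `K_p` the pooled fitted concentration matrix — a Mahalanobis-type form
  in the pathway's own metric;
* variance: the log-likelihood ratio of class-specific fits against the
  pooled fit, which for decomposable models reduces to
  `n_a (logdet S_p_hat - logdet S_a_hat) + n_b (logdet S_p_hat - logdet S_b_hat)`
  accumulated over cliques and separators.

Null distributions come from permuting class labels; both tests consume the
*same* permutation stream (one pre-drawn permutation matrix per seed), and
p-values use the add-one estimator `(1 + #{T_perm >= T_obs}) / (1 + nPerm)`,
hence are bounded below by `1/(1+nPerm)` and are valid by exchangeability.
Mean- and variance-test p-values are BH-adjusted separately across pathways;
a pathway is significant when `min(q_mean, q_var) <= 0.1` (non-strict). The
inclusive "either" reading matches the intent of flagging deregulation in
location *or* covariance; an "and" rule is available as
`adjustPathwayQvalues(rule = "both")`. Pathway nodes absent from the
expression matrix are dropped with a warning, not imputed — imputation would
manufacture covariance structure the test is meant to detect.

### Paths, meta-pathway, final selection

Within each significant pathway the same two statistics are evaluated per
clique under the saturated model (a single-clique tree reproduces the
whole-pathway test exactly, which the suite checks). A *path* is the clique
sequence between a pair of leaf cliques of the junction tree; its score is
the mean over its cliques of `-log10 min(p_mean, p_var)`. Since the upstream
machinery only fixes "top paths by score", this package fixes the remaining
choices explicitly: leaf-pair enumeration, the mean-of-min-p score, add-one
p-values and shared permutation streams are all documented package choices.
The top 10 paths across all significant pathways (overall, not per pathway;
ties broken by pathway id then path label) are merged — node union plus all
augmented-graph edges induced on it — into the meta-pathway, which is then
re-decomposed and re-tested, and the paths at or above the 75th percentile
(linear-interpolation quantile, ties kept) of the re-analysis scores are the
final result. Per-comparison networks are the meta-pathway edges induced on
the final paths' node union.

### Circuits

Candidate feed-forward loops come from a regulation catalog (TF→miRNA,
TF→gene) and the score-filtered prediction table, in two topologies: TF
master — `(tf, m)` and `(tf, g)` in the catalog, `(m, g)` predicted — and
miRNA master — `(m, tf)` and `(m, g)` predicted, `(tf, g)` in the catalog.
Circuits are retained when all three pairwise correlations satisfy
`|r| >= 0.5` (inclusive), computed on the same sample subset as the
comparison under analysis. For coherence classification the miRNA arms are
always treated as repressive regardless of the observed sign — that is the
mechanism — while TF arms take `sign(r)` because catalog TF–gene pairs carry
no sign. A circuit is coherent when the direct route's sign equals the
product of signs along the indirect route; a zero correlation has no sign and
is an error rather than a silent guess. Circuits sharing at least one node
with the merged pathway network are nested onto it.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `dropFraction` | 0.25 | proportion | lowest quarter of mean expression is noise-dominated on arrays |
| `entropyThreshold` | 1.4 | bits in [0, 3.32] | separates near-constant from informative profiles at 10 bins |
| `scoreMin` | 0.8 | prediction score in [0,1] | high-confidence predictions only |
| `rMax` | -0.5 | correlation, strict | strong anticorrelation consistent with repression |
| `qMax` | 0.1 | FDR, strict | tolerated false-discovery level for supported pairs |
| `pathwayQMax` | 0.1 | FDR, inclusive | pathway-level significance |
| `topK` | 10 | paths | size of the meta-pathway merge |
| `minAbsR` | 0.5 | correlation, inclusive | "at least 0.5" on all three circuit arms |
| `nPerm` | 1000 | permutations | p-value resolution 1/1001 |

## The synthetic generator: what it does and does not emulate

`simulateBundle` draws per-feature baseline means uniformly in log2 `[4, 12]`
with unit-variance Gaussian noise, mirroring the dynamic range and
class-conditional normality the Gaussian machinery assumes. It plants: a
`delta = 1.5` standard-deviation case-class shift along a 5-node path
attached as a pendant chain to one of three 25-gene pathways (a pendant chain
ends in a leaf clique, so the deregulated path is actually enumerable —
that attachment choice is the generator's, made once); 10 miRNA–target pairs
drawn bivariate normal at `rho = -0.8`, some targeting pathway scaffold
genes and some outside genes so augmentation is exercised both ways; and two
circuits per topology built from a latent driver with chosen sign loadings,
giving pairwise correlations near ±0.8. Planted regulator miRNAs get means
in `[8, 12]` so the abundance filter models dropout of weak features without
deleting planted signal. Decoy predictions (random pairs, uniform scores)
and decoy catalog rows keep the FDR step and the enumeration honest. Class
sizes default to 30/30/30 across one case and two control classes so the
two-comparison merge logic is always exercised.

What it does **not** emulate: array-level probe noise, normalization
artifacts, batch effects, correlated gene–gene background beyond the pathway
structure, heavy-tailed expression, or realistic pathway sizes. Passing the
recovery tests therefore demonstrates that the statistics detect exactly the
structure they model, at desk scale — not that real-data performance is
guaranteed. In particular, with 25-node pathways the top-10-path merge spans
most of a significant pathway, so node-level *precision* of the final paths
is structurally low here even when recall is perfect; with realistic pathway
collections the merge is far more selective.

The latent-driver circuits also produce genuinely anticorrelated
miRNA–target arms; these legitimately pass the supported-interaction filter,
which is why supported-interaction precision against the pairwise-planted
truth sits below 1 on default bundles.

## Numerical choices and degenerate inputs

* Quantiles (filter cutoff, upper-quartile selection) are linear-interpolation
  (type 7) throughout; removal below the cutoff is strict.
* Covariances are maximum-likelihood (1/n); positive definiteness is checked
  per clique via Cholesky and a degenerate clique is an error, not a silent
  regularization.
* IPS starts from the diagonal (so zero constraints hold from the first
  iterate), cycles cliques in canonical order and stops when every clique
  marginal matches within `tol = 1e-8`; non-convergence is an error carrying
  the last discrepancy.
* Determinism: min-fill ties break lexicographically, clique-tree ties by
  sorted clique labels, path ranking ties by pathway id then path label;
  every randomized stage takes an explicit seed and restores the caller's
  RNG state. Pipeline stage seeds are small deterministic offsets of the
  config seed.
* Matrix round-trips render doubles as `%.17g`, which reproduces IEEE
  doubles exactly from decimal text.
* `|r| = 1` maps to `p = 0` by convention; constant profiles are an error in
  `pearsonR`, a warned drop in the bulk selectors.

## Test-suite problem sizes

The suite and the acceptance script size their simulations for a single CPU:
null-uniformity uses 400 replicates of a 3-node pathway at 199 permutations;
type-I control uses 50 null bundles (3 pathways each, one comparison, 199
permutations); recovery uses one default bundle through the full
two-comparison pipeline at 499 permutations. These sizes are the package's
own choices for a quick, reproducible check; the statistics scale unchanged
to larger inputs.

## Known limitations

* Pathway inputs use the package's neutral edge-list dialect; KGML/BioPAX
  importers are out of scope (convert upstream, e.g. via existing pathway
  packages). KEGG compound/group nodes are not modeled.
* The FDR family for supported interactions is per comparison, matching the
  two-comparison design being independent analyses; a global family across
  comparisons is not offered.
* The mean/variance tests use permutation nulls only; no asymptotic
  approximation is provided.
* Node identities are taken at face value: no identifier translation
  (miRBase versions, gene aliases) is performed.
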