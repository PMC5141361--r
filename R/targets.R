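# Expression-supported miRNA-target selection: anticorrelation with FDR.

#' Read a predicted miRNA-target table
#'
#' TSV with header `mirna_id<TAB>gene_id<TAB>score`; scores are opaque
#' prediction confidences in `[0, 1]` (e.g. conservation-weighted sequence
#' scores). Duplicate (miRNA, gene) pairs are an error.
#'
#' @param path file path.
#' @return data.frame with columns mirna_id, gene_id, score.
#' @export
readPredictedTargets <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopIfNot(all(c("mirna_id", "gene_id", "score") %in% names(d)),
            "prediction table needs columns mirna_id, gene_id, score")
  if (anyDuplicated(paste(d$mirna_id, d$gene_id))) {
    stop("duplicate (mirna_id, gene_id) pairs in prediction table",
         call. = FALSE)
  }
  stopIfNot(all(is.finite(d$score)), "prediction scores must be finite")
  d
}

#' Read a validated miRNA-target table
#'
#' TSV with header `mirna_id<TAB>gene_id<TAB>source<TAB>assay`; rows are
#' interactions validated experimentally (e.g. by reporter assays). Pairs are
#' de-duplicated across sources.
#'
#' @param path file path.
#' @return data.frame with columns mirna_id, gene_id, source, assay.
#' @export
readValidatedTargets <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopIfNot(all(c("mirna_id", "gene_id", "source", "assay") %in% names(d)),
            "validated table needs columns mirna_id, gene_id, source, assay")
  d[!duplicated(paste(d$mirna_id, d$gene_id)), , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit preconditions: equal lengths of
#' at least 3 and non-constant inputs (zero variance makes the coefficient
#' undefined and is an error).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 3L, "need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant profile (zero variance)",
         call. = FALSE)
  }
  cor(x, y, method = "pearson")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. `|r| = 1` returns `p = 0` by convention. Vectorized
#' over `r`.
#'
#' @param r correlation coefficient(s).
#' @param n number of paired samples (>= 4).
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
correlationPValue <- function(r, n) {
  stopIfNot(n >= 4L, "need n >= 4 for a correlation p-value")
  stopIfNot(all(abs(r) <= 1), "correlations must lie in [-1, 1]")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  pmin(p, 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Monotone non-decreasing in sorted order, capped at 1; empty input yields
#' empty output. The adjusted value is never below the raw p-value.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (q-values) of the same length.
#' @export
bhFdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopIfNot(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Filter a prediction table by score
#'
#' `mode = "threshold"` keeps rows with `score >= scoreMin` (default 0.8);
#' `mode = "quantile"` keeps the top quarter of the score distribution
#' (score at or above the 75th percentile), an alternative phrasing of the
#' same idea when score scales are not comparable across sources.
#'
#' @param predictions data.frame as from [readPredictedTargets()].
#' @param scoreMin threshold used in `"threshold"` mode.
#' @param mode `"threshold"` or `"quantile"`.
#' @return the filtered prediction table.
#' @export
filterPredictions <- function(predictions, scoreMin = 0.8,
                              mode = c("threshold", "quantile")) {
  mode <- match.arg(mode)
  if (nrow(predictions) == 0L) return(predictions)
  cut <- switch(mode,
                threshold = scoreMin,
                quantile = quantile(predictions$score, 0.75, type = 7,
                                    names = FALSE))
  predictions[predictions$score >= cut, , drop = FALSE]
}

#' Select predicted miRNA-target interactions supported by anticorrelation
#'
#' For every predicted pair passing the score filter whose members are present
#' in both expression matrices, the Pearson correlation between the miRNA and
#' gene profiles is computed, two-sided p-values are derived and
#' Benjamini-Hochberg adjusted across exactly the tested pairs. A pair passes
#' when `r` falls strictly below `rMax` and `q` strictly below `qMax` (the
#' defaults encode
#' r < -0.5 with FDR < 0.1).
#'
#' @param predictions prediction table (mirna_id, gene_id, score).
#' @param mirnaExpr,geneExpr [ExpressionProfile-class] objects with identical
#'   sample sets and order.
#' @param scoreMin minimum prediction score (default 0.8).
#' @param rMax correlation upper bound; pairs must fall strictly below
#'   (default -0.5).
#' @param qMax FDR bound, strict (default 0.1).
#' @param samples optional sample-id subset on which correlations are
#'   computed (e.g. one comparison's cases plus controls); default all.
#' @param scoreMode passed to [filterPredictions()].
#' @return data.frame with one row per tested pair: mirna_id, gene_id, score,
#'   r, p, q, passed; sorted by (mirna_id, gene_id) so the result does not
#'   depend on prediction-table row order.
#' @export
selectSupported <- function(predictions, mirnaExpr, geneExpr,
                            scoreMin = 0.8, rMax = -0.5, qMax = 0.1,
                            samples = NULL,
                            scoreMode = c("threshold", "quantile")) {
  stopIfNot(identical(sampleIds(mirnaExpr), sampleIds(geneExpr)),
            "miRNA and gene matrices must share identical sample order")
  preds <- filterPredictions(predictions, scoreMin, match.arg(scoreMode))
  M <- exprValues(mirnaExpr)
  G <- exprValues(geneExpr)
  if (!is.null(samples)) {
    stopIfNot(all(samples %in% colnames(M)), "unknown sample ids in subset")
    M <- M[, samples, drop = FALSE]
    G <- G[, samples, drop = FALSE]
  }
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      score = numeric(), r = numeric(), p = numeric(),
                      q = numeric(), passed = logical(),
                      stringsAsFactors = FALSE)
  keep <- preds$mirna_id %in% rownames(M) & preds$gene_id %in% rownames(G)
  preds <- preds[keep, , drop = FALSE]
  if (nrow(preds) == 0L) {
    warning("no testable miRNA-target pairs", call. = FALSE)
    return(empty)
  }
  preds <- preds[order(preds$mirna_id, preds$gene_id), , drop = FALSE]
  n <- ncol(M)
  stopIfNot(n >= 4L, "need at least 4 samples for supported-interaction tests")
  zrow <- function(mat) {
    mu <- rowMeans(mat)
    s <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
    (mat - mu) / s
  }
  zm <- zrow(M[preds$mirna_id, , drop = FALSE])
  zg <- zrow(G[preds$gene_id, , drop = FALSE])
  r <- rowSums(zm * zg) / (n - 1)
  const <- !is.finite(r)
  if (any(const)) {
    warning(sum(const), " pair(s) dropped: constant expression profile",
            call. = FALSE)
    preds <- preds[!const, , drop = FALSE]
    r <- r[!const]
    if (nrow(preds) == 0L) {
      warning("no testable miRNA-target pairs", call. = FALSE)
      return(empty)
    }
  }
  r <- pmin(pmax(r, -1), 1)
  p <- correlationPValue(r, n)
  q <- bhFdr(p)
  data.frame(mirna_id = preds$mirna_id, gene_id = preds$gene_id,
             score = preds$score, r = r, p = p, q = q,
             passed = r < rMax & q < qMax,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Restrict supported interactions to a gene universe
#'
#' Keeps interactions whose target gene is annotated in the given universe
#' (typically the union of pathway gene ids), so that only pathway-relevant
#' miRNA edges enter the augmentation step.
#'
#' @param interactions data.frame as from [selectSupported()].
#' @param geneUniverse character vector of gene ids.
#' @return the filtered interaction table.
#' @export
restrictToPathwayGenes <- function(interactions, geneUniverse) {
  interactions[interactions$gene_id %in% geneUniverse, , drop = FALSE]
}
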