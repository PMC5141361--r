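# Expression-matrix IO, filtering, fold changes and sample clustering.

#' Read a log2 expression matrix with its sample annotation
#'
#' The matrix file is tab-separated, UTF-8, first header cell `feature_id`,
#' remaining header cells sample ids, decimal point `"."`. The annotation file
#' is tab-separated with header `sample_id<TAB>condition[<TAB>mutation]`.
#' Every sample in the matrix must be annotated; sample order follows the
#' matrix file.
#'
#' @param matrixPath path to the expression TSV.
#' @param annotationPath path to the sample-annotation TSV.
#' @param featureKind `"gene"` or `"mirna"`.
#' @return an [ExpressionProfile-class].
#' @export
readExpressionMatrix <- function(matrixPath, annotationPath,
                                 featureKind = c("gene", "mirna")) {
  featureKind <- match.arg(featureKind)
  raw <- read.delim(matrixPath, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA)
  if (ncol(raw) < 2L) stop("matrix file needs feature ids plus >=1 sample",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1)))
    stop("non-numeric cells in sample column(s): ",
         paste(names(raw)[-1L][bad], collapse = ", "), call. = FALSE)
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (anyDuplicated(colnames(vals))) {
    stop("duplicate sample ids in matrix header", call. = FALSE)
  }
  ann <- readSampleAnnotation(annotationPath)
  ExpressionProfile(vals, ann, featureKind)
}

#' @rdname readExpressionMatrix
#' @param path annotation file path.
#' @export
readSampleAnnotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(ann))) {
    stop("annotation needs columns sample_id and condition", call. = FALSE)
  }
  ann
}

#' Write an expression matrix (and optionally its annotation) to TSV
#'
#' Values are rendered with `%.17g`, which round-trips IEEE doubles exactly
#' through decimal text.
#'
#' @param x an [ExpressionProfile-class].
#' @param matrixPath output path for the matrix TSV.
#' @param annotationPath optional output path for the annotation TSV.
#' @return `matrixPath`, invisibly.
#' @export
writeExpressionMatrix <- function(x, matrixPath, annotationPath = NULL) {
  v <- exprValues(x)
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], fmtNum(v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), matrixPath)
  if (!is.null(annotationPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- intersect(c("sample_id", "condition", "mutation"), names(cd))
    write.table(cd[, keep, drop = FALSE], annotationPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(matrixPath)
}

#' Remove weakly expressed features
#'
#' Drops features whose mean expression falls strictly below the
#' `dropFraction` empirical quantile (linear-interpolation, type 7) of the
#' per-feature means. Survivor order is preserved.
#'
#' @param x an [ExpressionProfile-class].
#' @param dropFraction proportion of the mean-expression distribution below
#'   which features are removed; default 0.25 (lowest quarter).
#' @return the filtered ExpressionProfile.
#' @export
meanExpressionFilter <- function(x, dropFraction = 0.25) {
  stopIfNot(dropFraction >= 0 && dropFraction < 1,
            "dropFraction must be in [0, 1)")
  m <- rowMeans(exprValues(x))
  if (length(m) == 0L) stop("empty expression matrix", call. = FALSE)
  cut <- quantile(m, probs = dropFraction, type = 7, names = FALSE)
  x[m >= cut, ]
}

#' Shannon entropy of an expression profile, in bits
#'
#' The profile's own range is split into `nBins` equal-width bins
#' (right-open, last bin closed); entropy is `-sum p_b log2 p_b` over the bin
#' occupancy fractions. A constant profile has entropy 0 by convention (all
#' mass in one bin). Bounded by `log2(nBins)` and invariant to affine
#' rescaling of the profile.
#'
#' @param profile numeric vector, length >= 2.
#' @param nBins number of equal-width bins (default 10).
#' @return entropy in bits.
#' @examples
#' shannonEntropyBits(rep(1, 10))         # 0
#' shannonEntropyBits(rep(1:8, each = 10)) # 3 bits: uniform over 8 of 10 bins
#' @export
shannonEntropyBits <- function(profile, nBins = 10L) {
  stopIfNot(length(profile) >= 2L, "profile needs at least 2 values")
  stopIfNot(nBins >= 1L, "nBins must be positive")
  rng <- range(profile)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(findInterval(profile, breaks), nBins)
  p <- tabulate(bin, nbins = nBins) / length(profile)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Remove poorly variable features by Shannon entropy
#'
#' Features with per-feature entropy strictly below `threshold` bits are
#' removed.
#'
#' @inheritParams shannonEntropyBits
#' @param x an [ExpressionProfile-class].
#' @param threshold entropy cutoff in bits (default 1.4).
#' @return the filtered ExpressionProfile.
#' @export
entropyFilter <- function(x, threshold = 1.4, nBins = 10L) {
  v <- exprValues(x)
  H <- apply(v, 1L, shannonEntropyBits, nBins = nBins)
  x[H >= threshold, ]
}

#' Combined low-expression / low-entropy filter
#'
#' Removes the union of the features flagged by [meanExpressionFilter()] and
#' [entropyFilter()] ("weakly expressed and/or poorly variable"). Both
#' removal sets are computed on the original matrix, so the composition is
#' order-insensitive: the mean-expression quantile is not recomputed after
#' entropy removal.
#'
#' @inheritParams meanExpressionFilter
#' @inheritParams entropyFilter
#' @return the filtered ExpressionProfile.
#' @export
filterExpression <- function(x, dropFraction = 0.25, threshold = 1.4,
                             nBins = 10L) {
  v <- exprValues(x)
  m <- rowMeans(v)
  cut <- quantile(m, probs = dropFraction, type = 7, names = FALSE)
  H <- apply(v, 1L, shannonEntropyBits, nBins = nBins)
  keep <- m >= cut & H >= threshold
  if (!any(keep)) stop("all features removed by filtering", call. = FALSE)
  x[keep, ]
}

#' Per-feature log2 fold change between two sample groups
#'
#' `FC = mean(group A) - mean(group B)` on the log2 scale. When `stratifyBy`
#' is given, group A is restricted to samples carrying that mutation label
#' (group B, the reference, is unchanged), which is how mutation-stratified
#' fold changes are recomputed.
#'
#' @param x an [ExpressionProfile-class].
#' @param groupA,groupB condition labels.
#' @param stratifyBy optional mutation label restricting group A.
#' @return named numeric vector of fold changes, one per feature.
#' @export
log2FoldChange <- function(x, groupA, groupB, stratifyBy = NULL) {
  cond <- sampleConditions(x)
  for (g in c(groupA, groupB)) {
    if (!g %in% cond) stop("unknown condition: ", g, call. = FALSE)
  }
  aSel <- cond == groupA
  if (!is.null(stratifyBy)) {
    mut <- sampleMutations(x)
    if (is.null(mut)) stop("no mutation column to stratify by", call. = FALSE)
    aSel <- aSel & mut == stratifyBy
    if (!any(aSel)) stop("empty stratum: ", stratifyBy, call. = FALSE)
  }
  bSel <- cond == groupB
  v <- exprValues(x)
  rowMeans(v[, aSel, drop = FALSE]) - rowMeans(v[, bSel, drop = FALSE])
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distance with complete
#' linkage, computed on a feature subset (for instance the members of a final
#' network). Samples are ordered lexicographically before clustering so that
#' merge heights do not depend on input column order.
#'
#' @param x an [ExpressionProfile-class].
#' @param featureSubset feature ids to cluster on; default all features.
#' @return an [stats::hclust] object.
#' @export
hclusterSamples <- function(x, featureSubset = NULL) {
  v <- exprValues(x)
  if (ncol(v) < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
  if (!is.null(featureSubset)) {
    missing <- setdiff(featureSubset, rownames(v))
    if (length(missing)) {
      stop("features not in matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    v <- v[featureSubset, , drop = FALSE]
  }
  v <- v[, order(colnames(v)), drop = FALSE]
  hclust(dist(t(v), method = "euclidean"), method = "complete")
}

#' Stack gene and miRNA profiles into one mixed ExpressionProfile
#'
#' Requires identical sample sets and order and disjoint feature ids; used by
#' the topological analysis, which tests pathways containing both genes and
#' miRNAs.
#'
#' @param geneExpr,mirnaExpr [ExpressionProfile-class] objects sharing samples.
#' @return an ExpressionProfile with `featureKind = "mixed"`.
#' @export
combineExpression <- function(geneExpr, mirnaExpr) {
  stopIfNot(identical(sampleIds(geneExpr), sampleIds(mirnaExpr)),
            "gene and miRNA matrices must share identical sample order")
  stopIfNot(length(intersect(featureIds(geneExpr), featureIds(mirnaExpr))) == 0L,
            "gene and miRNA feature ids overlap")
  vals <- rbind(exprValues(geneExpr), exprValues(mirnaExpr))
  ann <- as.data.frame(SummarizedExperiment::colData(geneExpr))
  ExpressionProfile(vals, ann, featureKind = "mixed")
}
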