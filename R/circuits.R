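# TF-miRNA-gene feed-forward circuit discovery and coherence classification.

#' Read a TF regulation catalog
#'
#' Two TSV tables: TF->miRNA rows (`tf_id`, `mirna_id`, `source`) and
#' TF->gene rows (`tf_id`, `target_gene_id`, `source`). TF ids live in gene
#' identifier space. Duplicate pairs are dropped.
#'
#' @param tfMirnaPath,tfGenePath file paths.
#' @return list with elements `tf_mirna` and `tf_gene` (data.frames).
#' @export
readTfCatalog <- function(tfMirnaPath, tfGenePath) {
  tm <- read.delim(tfMirnaPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  tg <- read.delim(tfGenePath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopIfNot(all(c("tf_id", "mirna_id") %in% names(tm)),
            "TF-miRNA table needs columns tf_id, mirna_id")
  stopIfNot(all(c("tf_id", "target_gene_id") %in% names(tg)),
            "TF-gene table needs columns tf_id, target_gene_id")
  tm <- tm[!duplicated(paste(tm$tf_id, tm$mirna_id)), , drop = FALSE]
  tg <- tg[!duplicated(paste(tg$tf_id, tg$target_gene_id)), , drop = FALSE]
  list(tf_mirna = tm, tf_gene = tg)
}

#' Enumerate candidate TF-miRNA-gene circuits
#'
#' Two feed-forward topologies are enumerated from the regulation catalog and
#' a (score-filtered) prediction table:
#' * `tf_master`: the TF regulates both the miRNA and the gene promoter and
#'   the miRNA targets the gene -- `(tf, m) in tf_mirna`, `(tf, g) in
#'   tf_gene`, `(m, g) in predictions`.
#' * `mirna_master`: the miRNA post-transcriptionally regulates both the TF
#'   transcript and the gene, and the TF regulates the gene -- `(m, tf) in
#'   predictions`, `(m, g) in predictions`, `(tf, g) in tf_gene`.
#'
#' All three members must be present in the expression data and `g != tf`.
#' Output is de-duplicated and sorted, so it is invariant to catalog row
#' order.
#'
#' @param catalog list as from [readTfCatalog()].
#' @param predictions prediction table, already filtered to the configured
#'   score mode (see [filterPredictions()]).
#' @param mirnaIds,geneIds feature ids available in the expression matrices.
#' @return data.frame: topology, tf_id, mirna_id, gene_id.
#' @export
enumerateCandidates <- function(catalog, predictions, mirnaIds, geneIds) {
  empty <- data.frame(topology = character(), tf_id = character(),
                      mirna_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  tm <- catalog$tf_mirna
  tg <- catalog$tf_gene
  predKey <- paste(predictions$mirna_id, predictions$gene_id)

  out <- empty
  if (!is.null(tm) && nrow(tm) && !is.null(tg) && nrow(tg) &&
      nrow(predictions)) {
    j <- merge(tm[, c("tf_id", "mirna_id")],
               tg[, c("tf_id", "target_gene_id")], by = "tf_id")
    j <- j[paste(j$mirna_id, j$target_gene_id) %in% predKey, , drop = FALSE]
    if (nrow(j)) {
      out <- rbind(out, data.frame(
        topology = "tf_master", tf_id = j$tf_id, mirna_id = j$mirna_id,
        gene_id = j$target_gene_id, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(tg) && nrow(tg) && nrow(predictions)) {
    tfs <- unique(tg$tf_id)
    mt <- predictions[predictions$gene_id %in% tfs,
                      c("mirna_id", "gene_id"), drop = FALSE]
    names(mt) <- c("mirna_id", "tf_id")
    j <- merge(mt, tg[, c("tf_id", "target_gene_id")], by = "tf_id")
    j <- j[paste(j$mirna_id, j$target_gene_id) %in% predKey, , drop = FALSE]
    if (nrow(j)) {
      out <- rbind(out, data.frame(
        topology = "mirna_master", tf_id = j$tf_id, mirna_id = j$mirna_id,
        gene_id = j$target_gene_id, stringsAsFactors = FALSE))
    }
  }
  out <- out[out$gene_id != out$tf_id &
               out$mirna_id %in% mirnaIds &
               out$tf_id %in% geneIds &
               out$gene_id %in% geneIds, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$topology, out$tf_id, out$mirna_id, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidate circuits and keep strongly correlated ones
#'
#' Computes the three pairwise Pearson correlations (TF-miRNA, TF-gene,
#' miRNA-gene) on the selected sample set and retains circuits in which all
#' three satisfy `|r| >= minAbsR` (non-strict: "at least 0.5" keeps an exact
#' 0.5). Candidates involving a constant profile are dropped with a warning.
#'
#' @param candidates data.frame from [enumerateCandidates()].
#' @param mirnaExpr,geneExpr sample-aligned [ExpressionProfile-class] objects.
#' @param minAbsR absolute-correlation threshold (default 0.5).
#' @param samples optional sample-id subset (one comparison's cases plus its
#'   controls).
#' @return the retained candidates with r_tf_mirna, r_tf_gene, r_mirna_gene
#'   columns added.
#' @export
scoreAndFilter <- function(candidates, mirnaExpr, geneExpr, minAbsR = 0.5,
                           samples = NULL) {
  stopIfNot(identical(sampleIds(mirnaExpr), sampleIds(geneExpr)),
            "miRNA and gene matrices must share identical sample order")
  out <- candidates
  out$r_tf_mirna <- numeric(nrow(out))
  out$r_tf_gene <- numeric(nrow(out))
  out$r_mirna_gene <- numeric(nrow(out))
  if (nrow(out) == 0L) return(out)
  M <- exprValues(mirnaExpr)
  G <- exprValues(geneExpr)
  if (!is.null(samples)) {
    M <- M[, samples, drop = FALSE]
    G <- G[, samples, drop = FALSE]
  }
  safeCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  for (i in seq_len(nrow(out))) {
    tf <- G[out$tf_id[i], ]
    m <- M[out$mirna_id[i], ]
    g <- G[out$gene_id[i], ]
    out$r_tf_mirna[i] <- safeCor(tf, m)
    out$r_tf_gene[i] <- safeCor(tf, g)
    out$r_mirna_gene[i] <- safeCor(m, g)
  }
  const <- !stats::complete.cases(
    out[, c("r_tf_mirna", "r_tf_gene", "r_mirna_gene")])
  if (any(const)) {
    warning(sum(const), " circuit(s) dropped: constant expression profile",
            call. = FALSE)
    out <- out[!const, , drop = FALSE]
  }
  keep <- abs(out$r_tf_mirna) >= minAbsR &
    abs(out$r_tf_gene) >= minAbsR &
    abs(out$r_mirna_gene) >= minAbsR
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify circuits as coherent or incoherent feed-forward loops
#'
#' Edge signs are taken as `sign(r)` for TF edges and as repression (minus)
#' for miRNA->target edges regardless of the observed correlation sign, which
#' is reported alongside. A circuit is coherent when the sign of its direct
#' route to the target equals the product of signs along the two-step
#' indirect route:
#' * `tf_master`: direct TF->gene = `sign(r_tf_gene)`; indirect
#'   TF->miRNA->gene = `sign(r_tf_mirna) * (-1)`.
#' * `mirna_master`: direct miRNA->gene = `-1`; indirect miRNA->TF->gene =
#'   `(-1) * sign(r_tf_gene)`.
#'
#' A zero correlation has no sign; classification is then undefined and an
#' error.
#'
#' @param circuits data.frame from [scoreAndFilter()].
#' @return the input with a `coherence` column (`"coherent"`/`"incoherent"`).
#' @export
classifyFfl <- function(circuits) {
  if (nrow(circuits) == 0L) {
    circuits$coherence <- character(0)
    return(circuits)
  }
  rs <- circuits[, c("r_tf_mirna", "r_tf_gene", "r_mirna_gene")]
  if (any(rs == 0)) {
    stop("zero correlation: feed-forward coherence undefined", call. = FALSE)
  }
  direct <- ifelse(circuits$topology == "tf_master",
                   sign(circuits$r_tf_gene), -1)
  indirect <- ifelse(circuits$topology == "tf_master",
                     sign(circuits$r_tf_mirna) * -1,
                     -1 * sign(circuits$r_tf_gene))
  circuits$coherence <- ifelse(direct == indirect, "coherent", "incoherent")
  circuits
}

#' Keep circuits connected to a network
#'
#' Retains circuits sharing at least one member node (TF, miRNA or gene) with
#' the given network, the rule used to nest reverse-engineered circuits onto
#' the pathway-derived network.
#'
#' @param circuits data.frame of circuits.
#' @param net a [RegulatoryNetwork-class].
#' @return the connected subset of `circuits`.
#' @export
linkToNetwork <- function(circuits, net) {
  ids <- networkNodes(net)$id
  keep <- circuits$tf_id %in% ids | circuits$mirna_id %in% ids |
    circuits$gene_id %in% ids
  out <- circuits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
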