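#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist hclust p.adjust pt quantile rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Edge vocabularies ----------------------------------------------------------

PATHWAY_EDGE_TYPES <- c("activation", "inhibition", "binding",
                        "mirna_validated", "mirna_predicted")
NETWORK_EDGE_TYPES <- c(PATHWAY_EDGE_TYPES, "tf_mirna", "tf_gene")
NODE_KINDS <- c("gene", "mirna")
NETWORK_NODE_KINDS <- c("gene", "tf", "mirna")

# ExpressionProfile -----------------------------------------------------------

#' ExpressionProfile: a log2 expression matrix with sample annotation
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay named `"log2"` (features x samples), per-sample `condition` (and
#' optional `mutation`) labels in `colData`, and a `featureKind` tag saying
#' whether rows are genes, miRNAs, or a mix of both.
#'
#' Validity requires finite values, unique non-empty feature and sample
#' identifiers, and a condition label for every sample.
#'
#' @slot featureKind one of `"gene"`, `"mirna"`, `"mixed"`.
#' @export
setClass("ExpressionProfile",
         contains = "SummarizedExperiment",
         representation(featureKind = "character"))

setValidity("ExpressionProfile", function(object) {
  msgs <- character()
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% c("gene", "mirna", "mixed")) {
    msgs <- c(msgs, "featureKind must be one of 'gene', 'mirna', 'mixed'")
  }
  if (!"log2" %in% SummarizedExperiment::assayNames(object)) {
    return(c(msgs, "assay 'log2' is required"))
  }
  v <- SummarizedExperiment::assay(object, "log2")
  if (nrow(v) == 0L || ncol(v) == 0L) {
    msgs <- c(msgs, "expression matrix must be non-empty")
  }
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)) ||
      any(!nzchar(rownames(v)))) {
    msgs <- c(msgs, "feature ids must be unique and non-empty")
  }
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)) ||
      any(!nzchar(colnames(v)))) {
    msgs <- c(msgs, "sample ids must be unique and non-empty")
  }
  if (!all(is.finite(v))) {
    msgs <- c(msgs, "expression values must all be finite (no NA/NaN/Inf)")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must carry a 'condition' column")
  } else if (anyNA(cd$condition) || any(!nzchar(as.character(cd$condition)))) {
    msgs <- c(msgs, "every sample needs a non-missing condition label")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionProfile
#'
#' @param values numeric matrix of log2 intensities, features in rows (row
#'   names are feature ids), samples in columns (column names are sample ids).
#' @param annotation data.frame with columns `sample_id`, `condition` and
#'   optionally `mutation`; must cover every column of `values`.
#' @param featureKind `"gene"`, `"mirna"` or `"mixed"`.
#' @return an [ExpressionProfile-class] object. Sample order follows `values`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ann <- data.frame(sample_id = c("s1", "s2"), condition = c("case", "ctrl"))
#' ExpressionProfile(m, ann)
#' @export
ExpressionProfile <- function(values, annotation, featureKind = "gene") {
  stopIfNot(is.matrix(values) && is.numeric(values),
            "values must be a numeric matrix")
  stopIfNot(is.data.frame(annotation) &&
              all(c("sample_id", "condition") %in% names(annotation)),
            "annotation needs columns sample_id and condition")
  ann <- annotation
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample ids in annotation", call. = FALSE)
  }
  missing <- setdiff(colnames(values), ann$sample_id)
  if (length(missing)) {
    stop("samples without annotation: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[match(colnames(values), ann$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(ann, row.names = ann$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values), colData = cd)
  new("ExpressionProfile", se, featureKind = featureKind)
}

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile (%s): %d features x %d samples\n",
              object@featureKind, nrow(object), ncol(object)))
  cond <- table(SummarizedExperiment::colData(object)$condition)
  cat("conditions:",
      paste(sprintf("%s=%d", names(cond), as.integer(cond)), collapse = ", "),
      "\n")
})

#' @rdname ExpressionProfile
#' @param x an ExpressionProfile.
#' @export
featureKind <- function(x) x@featureKind

#' @rdname ExpressionProfile
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' @rdname ExpressionProfile
#' @export
featureIds <- function(x) rownames(x)

#' @rdname ExpressionProfile
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname ExpressionProfile
#' @export
sampleConditions <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$condition),
           colnames(x))
}

#' @rdname ExpressionProfile
#' @export
sampleMutations <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"mutation" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$mutation), colnames(x))
}

# PathwayGraph ----------------------------------------------------------------

#' PathwayGraph: a typed, signed, partially directed pathway topology
#'
#' Nodes are genes or miRNAs; edges carry a type (`activation`, `inhibition`,
#' `binding`, `mirna_validated`, `mirna_predicted`), a directedness flag and a
#' provenance string. miRNA-target edges always run miRNA -> gene, are directed
#' and are repressive in sign semantics.
#'
#' @slot pathwayId single identifier string.
#' @slot name human-readable name.
#' @slot nodes data.frame with columns `id`, `kind` (extra columns allowed).
#' @slot edges data.frame with columns `src`, `dst`, `directed`, `etype`,
#'   `provenance`.
#' @export
setClass("PathwayGraph",
         representation(pathwayId = "character", name = "character",
                        nodes = "data.frame", edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  msgs <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "kind") %in% names(nd))) {
    return("nodes need columns id, kind")
  }
  if (!all(c("src", "dst", "directed", "etype", "provenance") %in% names(ed))) {
    return("edges need columns src, dst, directed, etype, provenance")
  }
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  if (!all(nd$kind %in% NODE_KINDS)) {
    msgs <- c(msgs, "node kind must be 'gene' or 'mirna'")
  }
  if (nrow(ed)) {
    if (any(ed$src == ed$dst)) msgs <- c(msgs, "self-loops are not allowed")
    if (!all(c(ed$src, ed$dst) %in% nd$id)) {
      msgs <- c(msgs, "every edge endpoint must exist among the nodes")
    }
    if (!all(ed$etype %in% PATHWAY_EDGE_TYPES)) {
      msgs <- c(msgs, paste("edge types must be one of:",
                            paste(PATHWAY_EDGE_TYPES, collapse = ", ")))
    }
    mir <- ed$etype %in% c("mirna_validated", "mirna_predicted")
    if (any(mir)) {
      kindOf <- setNames(nd$kind, nd$id)
      ok <- kindOf[ed$src[mir]] == "mirna" & kindOf[ed$dst[mir]] == "gene" &
        ed$directed[mir]
      if (!all(ok)) {
        msgs <- c(msgs, "miRNA-target edges must run directed miRNA -> gene")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PathwayGraph
#'
#' @param pathwayId,name identifiers of the pathway.
#' @param nodes data.frame with columns `id`, `kind`.
#' @param edges data.frame with columns `src`, `dst`, `directed`, `etype` and
#'   optionally `provenance` (defaults to the pathway id).
#' @return a validated [PathwayGraph-class].
#' @export
PathwayGraph <- function(pathwayId, name = pathwayId,
                         nodes, edges = emptyPathwayEdges()) {
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (nrow(edges)) {
    edges$src <- as.character(edges$src)
    edges$dst <- as.character(edges$dst)
    edges$directed <- as.logical(edges$directed)
    edges$etype <- as.character(edges$etype)
    if (is.null(edges$provenance)) edges$provenance <- pathwayId
  } else {
    edges <- emptyPathwayEdges()
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("PathwayGraph", pathwayId = pathwayId, name = name,
      nodes = nodes, edges = edges)
}

emptyPathwayEdges <- function() {
  data.frame(src = character(), dst = character(), directed = logical(),
             etype = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph '%s' (%s): %d nodes (%d miRNA), %d edges\n",
              object@pathwayId, object@name, nrow(object@nodes),
              sum(object@nodes$kind == "mirna"), nrow(object@edges)))
})

#' @rdname PathwayGraph
#' @param pw a PathwayGraph.
#' @export
pathwayId <- function(pw) pw@pathwayId

#' @rdname PathwayGraph
#' @export
pathwayName <- function(pw) pw@name

#' @rdname PathwayGraph
#' @export
pathwayNodes <- function(pw) pw@nodes

#' @rdname PathwayGraph
#' @export
pathwayEdges <- function(pw) pw@edges

# CliqueTree ------------------------------------------------------------------

#' CliqueTree: junction tree of a chordal graph
#'
#' Maximal cliques of a chordal graph arranged in a tree (or forest, one tree
#' per connected component) satisfying the running intersection property.
#'
#' @slot cliques list of character vectors (sorted node ids per clique).
#' @slot separators list of character vectors, one per tree edge.
#' @slot treeEdges integer matrix with two columns of clique indices.
#' @export
setClass("CliqueTree",
         representation(cliques = "list", separators = "list",
                        treeEdges = "matrix"))

setValidity("CliqueTree", function(object) {
  if (length(object@separators) != nrow(object@treeEdges)) {
    return("one separator per tree edge required")
  }
  if (nrow(object@treeEdges) &&
      max(object@treeEdges) > length(object@cliques)) {
    return("tree edge refers to a missing clique")
  }
  TRUE
})

setMethod("show", "CliqueTree", function(object) {
  sizes <- lengths(object@cliques)
  cat(sprintf("CliqueTree: %d cliques (sizes %d..%d), %d tree edges\n",
              length(object@cliques), min(sizes), max(sizes),
              nrow(object@treeEdges)))
})

#' @rdname CliqueTree-class
#' @param ct a CliqueTree.
#' @export
treeCliques <- function(ct) ct@cliques

#' @rdname CliqueTree-class
#' @export
treeSeparators <- function(ct) ct@separators

#' @rdname CliqueTree-class
#' @export
treeEdges <- function(ct) ct@treeEdges

# GGMEstimate -----------------------------------------------------------------

#' GGMEstimate: covariance fitted under a graphical constraint
#'
#' Result of iterative proportional scaling: the maximum-likelihood covariance
#' whose inverse is zero on non-adjacent node pairs of the constraint graph
#' and whose clique marginals match the sample covariance.
#'
#' @slot nodes node order of the fit.
#' @slot sigma fitted covariance matrix.
#' @slot iterations IPS sweeps used.
#' @slot maxDiscrepancy largest clique-marginal deviation at convergence.
#' @export
setClass("GGMEstimate",
         representation(nodes = "character", sigma = "matrix",
                        iterations = "integer", maxDiscrepancy = "numeric"))

setMethod("show", "GGMEstimate", function(object) {
  cat(sprintf(
    "GGMEstimate: %d nodes, %d IPS iterations, max clique discrepancy %.3g\n",
    length(object@nodes), object@iterations, object@maxDiscrepancy))
})

#' @rdname GGMEstimate-class
#' @param fit a GGMEstimate.
#' @export
fittedCovariance <- function(fit) fit@sigma

# RegulatoryNetwork -----------------------------------------------------------

#' RegulatoryNetwork: merged, provenance-tagged regulatory network
#'
#' Nodes carry a kind (`gene`, `tf`, `mirna`), a provenance set and optional
#' per-comparison fold-change annotations (columns named `fc_<label>`,
#' `NA` meaning absent). Edges are identified by `(src, dst, etype)` and carry
#' provenance sets. Provenance sets are serialized as ";"-joined sorted
#' strings.
#'
#' @slot nodes data.frame: `id`, `kind`, `provenance`, optional `fc_*`.
#' @slot edges data.frame: `src`, `dst`, `etype`, `provenance`.
#' @export
setClass("RegulatoryNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (!all(c("id", "kind", "provenance") %in% names(nd))) {
    return("nodes need columns id, kind, provenance")
  }
  if (!all(c("src", "dst", "etype", "provenance") %in% names(ed))) {
    return("edges need columns src, dst, etype, provenance")
  }
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  if (!all(nd$kind %in% NETWORK_NODE_KINDS)) {
    msgs <- c(msgs, "node kinds must be gene/tf/mirna")
  }
  if (nrow(nd) && any(!nzchar(nd$provenance))) {
    msgs <- c(msgs, "node provenance sets must be non-empty")
  }
  if (nrow(ed)) {
    key <- paste(ed$src, ed$dst, ed$etype)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "edge identity (src, dst, etype) must be unique")
    }
    if (!all(c(ed$src, ed$dst) %in% nd$id)) {
      msgs <- c(msgs, "edge endpoints must exist among the nodes")
    }
    if (!all(ed$etype %in% NETWORK_EDGE_TYPES)) {
      msgs <- c(msgs, "unknown network edge type")
    }
    if (any(!nzchar(ed$provenance))) {
      msgs <- c(msgs, "edge provenance sets must be non-empty")
    }
    mir <- ed$etype %in% c("mirna_validated", "mirna_predicted")
    if (any(mir)) {
      kindOf <- setNames(nd$kind, nd$id)
      ok <- kindOf[ed$src[mir]] == "mirna" &
        kindOf[ed$dst[mir]] %in% c("gene", "tf")
      if (!all(ok)) {
        msgs <- c(msgs, "miRNA edges must run miRNA -> gene/tf")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegulatoryNetwork
#'
#' Node and edge order is canonicalized (nodes by id; edges by src, dst,
#' etype) so that equal networks compare equal regardless of assembly order.
#'
#' @param nodes data.frame with `id`, `kind`, optional `provenance` and
#'   `fc_<label>` columns.
#' @param edges data.frame with `src`, `dst`, `etype`, optional `provenance`.
#' @return a validated [RegulatoryNetwork-class].
#' @export
RegulatoryNetwork <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), kind = character(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(src = character(), dst = character(),
                        etype = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(nodes$provenance)) nodes$provenance <- rep("unspecified", nrow(nodes))
  if (is.null(edges$provenance)) edges$provenance <- rep("unspecified", nrow(edges))
  for (col in c("id", "kind", "provenance")) nodes[[col]] <- as.character(nodes[[col]])
  for (col in c("src", "dst", "etype", "provenance")) edges[[col]] <- as.character(edges[[col]])
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$src, edges$dst, edges$etype), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("RegulatoryNetwork", nodes = nodes, edges = edges)
}

setMethod("show", "RegulatoryNetwork", function(object) {
  s <- networkSummary(object)
  cat(sprintf("RegulatoryNetwork: %d nodes (%d miRNA), %d edges\n",
              s$n_nodes, s$n_mirnas, s$n_edges))
  if (s$n_edges > 0) {
    et <- s$edges_by_type[s$edges_by_type > 0]
    cat("edge types:",
        paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
  }
})

#' @rdname RegulatoryNetwork
#' @param net a RegulatoryNetwork.
#' @export
networkNodes <- function(net) net@nodes

#' @rdname RegulatoryNetwork
#' @export
networkEdges <- function(net) net@edges
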