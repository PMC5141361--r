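# Pathway graph IO, miRNA augmentation and moralization.

#' Read pathway graphs from a typed edge-list file
#'
#' Dialect: tab-separated; each graph opens with a header line
#' `#pathway<TAB><pathway_id><TAB><name>`; edge rows are
#' `src_id<TAB>src_kind<TAB>etype<TAB>dst_id<TAB>dst_kind<TAB>directed(0/1)`;
#' other lines starting with `#` are comments and blank lines are skipped.
#'
#' @param path file path.
#' @return a named list of [PathwayGraph-class] objects (names are pathway
#'   ids).
#' @export
readPathwayEdgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  graphs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    nd <- unique(cur$nodes)
    if (anyDuplicated(nd$id)) {
      dup <- unique(nd$id[duplicated(nd$id)])
      stop("node(s) declared with conflicting kinds in pathway '",
           cur$id, "': ", paste(dup, collapse = ", "), call. = FALSE)
    }
    PathwayGraph(cur$id, cur$name, nodes = nd,
                 edges = do.call(rbind, cur$edges) %||% emptyPathwayEdges())
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (startsWith(ln, "#pathway\t")) {
      if (length(f) < 3L) stop("malformed #pathway header at line ", i,
                               call. = FALSE)
      g <- flush(cur)
      if (!is.null(g)) {
        if (pathwayId(g) %in% names(graphs)) {
          stop("duplicate pathway id: ", pathwayId(g), call. = FALSE)
        }
        graphs[[pathwayId(g)]] <- g
      }
      cur <- list(id = f[2], name = f[3],
                  nodes = data.frame(id = character(), kind = character(),
                                     stringsAsFactors = FALSE),
                  edges = list())
      next
    }
    if (startsWith(ln, "#")) next
    if (is.null(cur)) stop("edge row before any #pathway header at line ", i,
                           call. = FALSE)
    if (length(f) != 6L) stop("expected 6 tab-separated fields at line ", i,
                              call. = FALSE)
    if (!f[3] %in% PATHWAY_EDGE_TYPES) {
      stop("unknown edge type '", f[3], "' at line ", i, ": ", ln,
           call. = FALSE)
    }
    if (!all(c(f[2], f[5]) %in% NODE_KINDS)) {
      stop("unknown node kind at line ", i, call. = FALSE)
    }
    cur$nodes <- rbind(cur$nodes,
                       data.frame(id = c(f[1], f[4]), kind = c(f[2], f[5]),
                                  stringsAsFactors = FALSE))
    cur$edges[[length(cur$edges) + 1L]] <-
      data.frame(src = f[1], dst = f[4], directed = f[6] == "1",
                 etype = f[3], provenance = cur$id, stringsAsFactors = FALSE)
  }
  g <- flush(cur)
  if (!is.null(g)) {
    if (pathwayId(g) %in% names(graphs)) {
      stop("duplicate pathway id: ", pathwayId(g), call. = FALSE)
    }
    graphs[[pathwayId(g)]] <- g
  }
  graphs
}

#' Write pathway graphs in the edge-list dialect of [readPathwayEdgelist()]
#'
#' Isolated nodes are not representable in the edge-list dialect and are
#' dropped with a warning on write.
#'
#' @param pathways a list of [PathwayGraph-class] objects (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePathwayEdgelist <- function(pathways, path) {
  if (is(pathways, "PathwayGraph")) pathways <- list(pathways)
  out <- character()
  for (pw in pathways) {
    nd <- pathwayNodes(pw)
    ed <- pathwayEdges(pw)
    iso <- setdiff(nd$id, c(ed$src, ed$dst))
    if (length(iso)) {
      warning("dropping isolated node(s) on write: ",
              paste(iso, collapse = ", "), call. = FALSE)
    }
    kindOf <- setNames(nd$kind, nd$id)
    out <- c(out, paste("#pathway", pathwayId(pw), pathwayName(pw), sep = "\t"))
    if (nrow(ed)) {
      out <- c(out, paste(ed$src, kindOf[ed$src], ed$etype, ed$dst,
                          kindOf[ed$dst], as.integer(ed$directed), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' SIF rendering of a pathway graph
#'
#' One `src<TAB>etype<TAB>dst` line per edge, loadable by Cytoscape.
#'
#' @param pw a [PathwayGraph-class].
#' @param path optional file to write to.
#' @return the SIF lines, invisibly when `path` is given.
#' @export
pathwaySif <- function(pw, path = NULL) {
  ed <- pathwayEdges(pw)
  lines <- if (nrow(ed)) paste(ed$src, ed$etype, ed$dst, sep = "\t") else character()
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Augment a pathway with miRNA-target edges
#'
#' For every miRNA with at least one target gene already annotated in the
#' pathway, the miRNA node is added together with one directed repressive edge
#' per such target. An edge is typed `mirna_validated` when the pair appears
#' in the validated table (validated evidence takes precedence over
#' prediction), else `mirna_predicted`. Genes are never added: only miRNAs
#' targeting genes already in the pathway enter. The operation is idempotent
#' and insensitive to interaction row order.
#'
#' @param pw a [PathwayGraph-class].
#' @param validated data.frame with mirna_id, gene_id (validated pairs); may
#'   be `NULL`.
#' @param supported data.frame as from [selectSupported()]; only rows with
#'   `passed == TRUE` are used (rows are assumed to have passed selection; a
#'   `passed` column, when present, is honored). May be `NULL`.
#' @return the augmented PathwayGraph.
#' @export
augmentPathway <- function(pw, validated = NULL, supported = NULL) {
  nd <- pathwayNodes(pw)
  ed <- pathwayEdges(pw)
  pwGenes <- nd$id[nd$kind == "gene"]

  pairDf <- function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      return(data.frame(mirna_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(mirna_id = as.character(d$mirna_id),
               gene_id = as.character(d$gene_id), stringsAsFactors = FALSE)
  }
  val <- pairDf(validated)
  sup <- supported
  if (!is.null(sup) && "passed" %in% names(sup)) {
    sup <- sup[sup$passed, , drop = FALSE]
  }
  sup <- pairDf(sup)

  cand <- unique(rbind(val, sup))
  cand <- cand[cand$gene_id %in% pwGenes, , drop = FALSE]

  # pool with pre-existing miRNA edges so repeated augmentation is idempotent
  isMir <- ed$etype %in% c("mirna_validated", "mirna_predicted")
  existing <- data.frame(mirna_id = ed$src[isMir], gene_id = ed$dst[isMir],
                         etype = ed$etype[isMir], stringsAsFactors = FALSE)
  valKey <- paste(val$mirna_id, val$gene_id)
  allPairs <- unique(rbind(cand,
                           existing[, c("mirna_id", "gene_id"), drop = FALSE]))
  if (nrow(allPairs) == 0L) return(pw)
  key <- paste(allPairs$mirna_id, allPairs$gene_id)
  wasValidated <- key %in% valKey |
    key %in% paste(existing$mirna_id, existing$gene_id)[
      existing$etype == "mirna_validated"]
  mirEdges <- data.frame(
    src = allPairs$mirna_id, dst = allPairs$gene_id, directed = TRUE,
    etype = ifelse(wasValidated, "mirna_validated", "mirna_predicted"),
    provenance = "augmentation", stringsAsFactors = FALSE)
  mirEdges <- mirEdges[order(mirEdges$src, mirEdges$dst), , drop = FALSE]

  newMirnas <- setdiff(allPairs$mirna_id, nd$id)
  if (length(newMirnas)) {
    add <- data.frame(id = sort(newMirnas), kind = "mirna",
                      stringsAsFactors = FALSE)
    for (col in setdiff(names(nd), names(add))) add[[col]] <- NA
    nd <- rbind(nd, add[, names(nd), drop = FALSE])
  }
  PathwayGraph(pathwayId(pw), pathwayName(pw), nodes = nd,
               edges = rbind(ed[!isMir, , drop = FALSE], mirEdges))
}

#' Moral graph of a pathway
#'
#' Drops edge directions and connects ("marries") every pair of directed
#' parents of each node. Undirected `binding` edges are kept as plain
#' adjacencies. miRNA edges enter as ordinary adjacencies: the Gaussian model
#' downstream is sign-agnostic.
#'
#' @param pw a [PathwayGraph-class].
#' @return an undirected simple [igraph::graph] whose vertex names are node
#'   ids.
#' @export
moralGraph <- function(pw) {
  nd <- pathwayNodes(pw)
  ed <- pathwayEdges(pw)
  base <- ed[, c("src", "dst"), drop = FALSE]
  marry <- NULL
  if (nrow(ed)) {
    dir <- ed[ed$directed, , drop = FALSE]
    marry <- do.call(rbind, lapply(unique(dir$dst), function(child) {
      parents <- sort(unique(dir$src[dir$dst == child]))
      if (length(parents) < 2L) return(NULL)
      pairs <- t(utils::combn(parents, 2L))
      data.frame(src = pairs[, 1], dst = pairs[, 2], stringsAsFactors = FALSE)
    }))
  }
  g <- igraph::graph_from_data_frame(rbind(base, marry), directed = FALSE,
                                     vertices = nd$id)
  igraph::simplify(g)
}

# induced subgraph of a pathway on a node subset (drops dangling edges)
inducePathway <- function(pw, ids) {
  nd <- pathwayNodes(pw)
  ed <- pathwayEdges(pw)
  nd <- nd[nd$id %in% ids, , drop = FALSE]
  ed <- ed[ed$src %in% nd$id & ed$dst %in% nd$id, , drop = FALSE]
  PathwayGraph(pathwayId(pw), pathwayName(pw), nodes = nd, edges = ed)
}
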