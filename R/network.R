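# Regulatory-network assembly, merging, annotation, summary and IO.

#' Build a network from the selected paths of a meta-pathway
#'
#' Nodes are the union of the selected paths' node sets; edges are the
#' meta-pathway edges induced on that union. Node kind is upgraded from
#' `gene` to `tf` for ids found in the TF catalog. Provenance records the
#' comparison label plus the source pathways.
#'
#' @param meta the meta [PathwayGraph-class].
#' @param finalPaths scored-path data.frame from [finalPathSelection()].
#' @param label comparison label (e.g. `"case_vs_ctrlA"`).
#' @param tfIds gene-space ids to mark as transcription factors.
#' @return a [RegulatoryNetwork-class].
#' @export
pathsToNetwork <- function(meta, finalPaths, label, tfIds = character()) {
  nodeIds <- sort(unique(unlist(finalPaths$nodes)))
  nd <- pathwayNodes(meta)
  nd <- nd[nd$id %in% nodeIds, , drop = FALSE]
  kind <- ifelse(nd$kind == "gene" & nd$id %in% tfIds, "tf", nd$kind)
  src <- if ("source" %in% names(nd)) nd$source else pathwayId(meta)
  nodes <- data.frame(id = nd$id, kind = kind,
                      provenance = vapply(src, function(s) {
                        provJoin(c(label, strsplit(s, ";")[[1]]))
                      }, character(1)),
                      stringsAsFactors = FALSE)
  ed <- pathwayEdges(meta)
  ed <- ed[ed$src %in% nodeIds & ed$dst %in% nodeIds, , drop = FALSE]
  edges <- data.frame(src = ed$src, dst = ed$dst, etype = ed$etype,
                      provenance = vapply(ed$provenance, function(s) {
                        provJoin(c(label, strsplit(s, ";")[[1]]))
                      }, character(1)),
                      stringsAsFactors = FALSE)
  RegulatoryNetwork(nodes, edges)
}

#' Render circuits as a network fragment
#'
#' Each circuit contributes its three members and three edges: `tf_mirna` and
#' `tf_gene` for transcriptional regulation, `mirna_predicted` for the
#' miRNA-target arm(s); in `mirna_master` circuits the miRNA->TF edge is also
#' a predicted targeting edge. Edge provenance carries the circuits' labels.
#'
#' @param circuits data.frame of (classified) circuits; an optional
#'   `comparison` column feeds provenance.
#' @param tfIds ids to type as `tf` nodes.
#' @param label fallback provenance label.
#' @return a [RegulatoryNetwork-class].
#' @export
circuitsToNetwork <- function(circuits, tfIds = character(),
                              label = "circuits") {
  if (nrow(circuits) == 0L) return(RegulatoryNetwork())
  prov <- if ("comparison" %in% names(circuits)) {
    paste(label, circuits$comparison, sep = ":")
  } else {
    rep(label, nrow(circuits))
  }
  nodes <- rbind(
    data.frame(id = circuits$tf_id, kind = "tf", provenance = prov,
               stringsAsFactors = FALSE),
    data.frame(id = circuits$mirna_id, kind = "mirna", provenance = prov,
               stringsAsFactors = FALSE),
    data.frame(id = circuits$gene_id,
               kind = ifelse(circuits$gene_id %in% tfIds, "tf", "gene"),
               provenance = prov, stringsAsFactors = FALSE))
  mkEdges <- function(src, dst, etype, pv) {
    data.frame(src = src, dst = dst, etype = rep(etype, length(src)),
               provenance = pv, stringsAsFactors = FALSE)
  }
  isTfm <- circuits$topology == "tf_master"
  edges <- rbind(
    mkEdges(circuits$tf_id, circuits$gene_id, "tf_gene", prov),
    mkEdges(circuits$tf_id[isTfm], circuits$mirna_id[isTfm], "tf_mirna",
            prov[isTfm]),
    mkEdges(circuits$mirna_id, circuits$gene_id, "mirna_predicted", prov),
    mkEdges(circuits$mirna_id[!isTfm], circuits$tf_id[!isTfm],
            "mirna_predicted", prov[!isTfm]))
  collapseNetworkParts(nodes, edges)
}

# de-duplicate node and edge rows, unioning provenance; kind conflicts error
collapseNetworkParts <- function(nodes, edges) {
  nodes <- do.call(rbind, lapply(split(nodes, nodes$id), function(d) {
    kinds <- unique(d$kind)
    if (length(kinds) > 1L) {
      stop("conflicting node kinds for '", d$id[1], "': ",
           paste(kinds, collapse = " vs "), call. = FALSE)
    }
    fc <- d[1, grep("^fc_", names(d), value = TRUE), drop = FALSE]
    base <- data.frame(id = d$id[1], kind = kinds,
                       provenance = provJoin(unlist(strsplit(d$provenance, ";"))),
                       stringsAsFactors = FALSE)
    if (ncol(fc)) {
      for (col in names(fc)) {
        vals <- d[[col]][!is.na(d[[col]])]
        base[[col]] <- if (length(vals)) vals[1] else NA_real_
      }
    }
    base
  }))
  if (!is.null(edges) && nrow(edges)) {
    key <- paste(edges$src, edges$dst, edges$etype)
    edges <- do.call(rbind, lapply(split(edges, key), function(d) {
      d$provenance[1] <- provJoin(unlist(strsplit(d$provenance, ";")))
      d[1, , drop = FALSE]
    }))
  }
  RegulatoryNetwork(nodes, edges)
}

#' Merge regulatory networks
#'
#' Union on node id and on edge identity `(src, dst, etype)`; provenance sets
#' are unioned; a node appearing with two different kinds is an error. The
#' result's ordering is canonical, so merging is associative and commutative
#' up to ordering and `merge(N, N) == N`.
#'
#' @param nets list of [RegulatoryNetwork-class] objects.
#' @return the merged [RegulatoryNetwork-class].
#' @export
mergeNetworks <- function(nets) {
  stopIfNot(length(nets) >= 1L, "need at least one network")
  ndList <- lapply(nets, networkNodes)
  allCols <- unique(unlist(lapply(ndList, names)))
  ndList <- lapply(ndList, function(d) {
    for (col in setdiff(allCols, names(d))) d[[col]] <- NA_real_
    d[, allCols, drop = FALSE]
  })
  nodes <- do.call(rbind, ndList)
  edges <- do.call(rbind, lapply(nets, networkEdges))
  collapseNetworkParts(nodes, edges)
}

#' Attach per-comparison fold-change annotations to network nodes
#'
#' Each comparison contributes one `fc_<label>` column; nodes absent from a
#' fold-change table get `NA` (recorded as absent, not zero).
#'
#' @param net a [RegulatoryNetwork-class].
#' @param fcTables named list of named numeric vectors (feature id ->
#'   log2 fold change), one per comparison label.
#' @return the annotated network.
#' @export
annotateFoldChanges <- function(net, fcTables) {
  nodes <- networkNodes(net)
  for (label in names(fcTables)) {
    fc <- fcTables[[label]]
    nodes[[paste0("fc_", label)]] <- unname(fc[nodes$id])
  }
  RegulatoryNetwork(nodes, networkEdges(net))
}

#' Summarize a regulatory network
#'
#' @param net a [RegulatoryNetwork-class].
#' @return list with `n_nodes`, `n_edges`, `n_mirnas` and `edges_by_type`
#'   (named integer vector over all known edge types).
#' @export
networkSummary <- function(net) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  byType <- setNames(integer(length(NETWORK_EDGE_TYPES)), NETWORK_EDGE_TYPES)
  if (nrow(ed)) {
    tab <- table(ed$etype)
    byType[names(tab)] <- as.integer(tab)
  }
  list(n_nodes = nrow(nd), n_edges = nrow(ed),
       n_mirnas = sum(nd$kind == "mirna"), edges_by_type = byType)
}

#' Export / import a regulatory network
#'
#' Formats: `"json"` (lossless native dump), `"graphml"` (all node and edge
#' attributes, Cytoscape-loadable; fold changes travel as full-precision
#' decimal strings with `""` for absent) and `"sif"` (topology only, edge
#' type as the relation). `importNetwork(exportNetwork(net))` reproduces the
#' network exactly for json and graphml.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file.
#' @param format `"json"`, `"graphml"` or `"sif"`; `importNetwork` infers it
#'   from the file extension when not given.
#' @return `path` invisibly (`exportNetwork`); a [RegulatoryNetwork-class]
#'   (`importNetwork`).
#' @export
exportNetwork <- function(net, path, format = c("json", "graphml", "sif")) {
  format <- match.arg(format)
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  fcCols <- grep("^fc_", names(nd), value = TRUE)
  if (format == "json") {
    payload <- list(nodes = nd, edges = ed)
    jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  } else if (format == "graphml") {
    vdf <- data.frame(name = nd$id, kind = nd$kind,
                      provenance = nd$provenance, stringsAsFactors = FALSE)
    for (col in fcCols) vdf[[col]] <- ifelse(is.na(nd[[col]]), "",
                                             fmtNum(nd[[col]]))
    if (nrow(ed)) {
      edf <- data.frame(from = ed$src, to = ed$dst, etype = ed$etype,
                        provenance = ed$provenance, stringsAsFactors = FALSE)
      g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
    } else {
      g <- igraph::graph_from_data_frame(
        data.frame(from = character(), to = character()),
        directed = TRUE, vertices = vdf)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- if (nrow(ed)) paste(ed$src, ed$etype, ed$dst, sep = "\t") else character()
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname exportNetwork
#' @export
importNetwork <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(sub(".*\\.", "", path))
  }
  if (format == "json") {
    payload <- jsonlite::fromJSON(path)
    nodes <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(payload$edges, stringsAsFactors = FALSE)
    if (!nrow(nodes)) nodes <- NULL
    if (!length(edges) || !nrow(edges)) edges <- NULL
    return(RegulatoryNetwork(nodes, edges))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- data.frame(id = va$name, kind = va$kind,
                        provenance = va$provenance, stringsAsFactors = FALSE)
    for (col in grep("^fc_", names(va), value = TRUE)) {
      nodes[[col]] <- as.numeric(ifelse(va[[col]] == "", NA, va[[col]]))
    }
    if (igraph::ecount(g)) {
      el <- igraph::as_edgelist(g)
      ea <- igraph::edge_attr(g)
      edges <- data.frame(src = el[, 1], dst = el[, 2], etype = ea$etype,
                          provenance = ea$provenance, stringsAsFactors = FALSE)
    } else {
      edges <- NULL
    }
    return(RegulatoryNetwork(nodes, edges))
  }
  stop("cannot import format: ", format, call. = FALSE)
}
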