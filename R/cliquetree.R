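# Chordal decomposition: min-fill triangulation and clique-tree construction.

#' Triangulate an undirected graph (min-fill heuristic)
#'
#' Adds fill-in edges by eliminating, at each step, the vertex whose
#' remaining neighbors require the fewest new edges to become a clique;
#' ties are broken by lexicographic node id, making the output deterministic.
#' The result is chordal and a supergraph of the input. Disconnected inputs
#' are handled transparently (elimination never fills across components).
#'
#' @param g an undirected [igraph::graph] with vertex names.
#' @return a chordal undirected igraph on the same vertices.
#' @export
triangulate <- function(g) {
  stopIfNot(!igraph::is_directed(g), "triangulate expects an undirected graph")
  vs <- sort(igraph::V(g)$name)
  adj <- lapply(vs, function(v) {
    sort(setdiff(names(igraph::neighbors(g, v)), v))
  })
  names(adj) <- vs

  fill <- list()
  work <- adj
  remaining <- vs
  while (length(remaining) > 1L) {
    # number of missing edges among each vertex's remaining neighborhood
    nFill <- vapply(remaining, function(v) {
      nb <- work[[v]]
      k <- length(nb)
      if (k < 2L) return(0L)
      present <- 0L
      for (i in seq_len(k - 1L)) {
        present <- present + sum(nb[(i + 1L):k] %in% work[[nb[i]]])
      }
      as.integer(k * (k - 1L) / 2L - present)
    }, integer(1))
    v <- remaining[which.min(nFill)]  # remaining is sorted: lexicographic ties
    nb <- work[[v]]
    k <- length(nb)
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          a <- nb[i]; b <- nb[j]
          if (!b %in% work[[a]]) {
            fill[[length(fill) + 1L]] <- c(a, b)
            work[[a]] <- sort(c(work[[a]], b))
            work[[b]] <- sort(c(work[[b]], a))
          }
        }
      }
    }
    for (u in nb) work[[u]] <- setdiff(work[[u]], v)
    work[[v]] <- character()
    remaining <- setdiff(remaining, v)
  }

  if (length(fill)) {
    fillMat <- do.call(rbind, fill)
    g <- igraph::add_edges(g, as.vector(t(fillMat)))
  }
  igraph::simplify(g)
}

#' Maximal cliques of a graph
#'
#' Canonicalized: each clique is a sorted character vector and cliques are
#' ordered by their comma-joined label.
#'
#' @param g an undirected [igraph::graph] with vertex names.
#' @return list of character vectors.
#' @export
maximalCliques <- function(g) {
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(c) sort(names(c)))
  cl[order(vapply(cl, paste, character(1), collapse = ","))]
}

#' Build a clique tree (junction tree) of a chordal graph
#'
#' Maximum-weight spanning tree over clique-intersection sizes, built by a
#' deterministic Kruskal pass (edges sorted by decreasing weight, ties by the
#' sorted clique labels). Only clique pairs with non-empty intersection are
#' joined, so a disconnected chordal graph yields a forest with one tree per
#' component; the running intersection property holds within each tree.
#'
#' @param g a chordal undirected [igraph::graph] with vertex names.
#' @return a [CliqueTree-class].
#' @export
buildCliqueTree <- function(g) {
  if (!igraph::is_chordal(g)$chordal) {
    stop("input graph is not chordal; triangulate first", call. = FALSE)
  }
  cl <- maximalCliques(g)
  m <- length(cl)
  if (m == 1L) {
    return(new("CliqueTree", cliques = cl, separators = list(),
               treeEdges = matrix(integer(), ncol = 2)))
  }
  labels <- vapply(cl, paste, character(1), collapse = ",")
  cand <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      w <- length(intersect(cl[[i]], cl[[j]]))
      if (w > 0L) cand[[length(cand) + 1L]] <- list(i = i, j = j, w = w)
    }
  }
  ord <- order(-vapply(cand, `[[`, numeric(1), "w"),
               labels[vapply(cand, `[[`, numeric(1), "i")],
               labels[vapply(cand, `[[`, numeric(1), "j")])
  parent <- seq_len(m)
  findRoot <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  edges <- matrix(integer(), ncol = 2)
  seps <- list()
  for (e in cand[ord]) {
    ri <- findRoot(e$i); rj <- findRoot(e$j)
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, c(e$i, e$j))
      seps[[length(seps) + 1L]] <- intersect(cl[[e$i]], cl[[e$j]])
    }
  }
  new("CliqueTree", cliques = cl, separators = seps, treeEdges = edges)
}
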