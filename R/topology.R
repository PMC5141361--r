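# Topological pathway analysis: permutation mean/variance tests on GGMs,
# clique-level tests, path enumeration/scoring, meta-pathway, final selection.

# --- decomposition of a pathway against available expression features -------

# Restrict a pathway to features present in `availableIds`, moralize,
# triangulate and build the clique tree. Returns NULL-free list or errors.
pathwayDecomposition <- function(pw, availableIds) {
  ids <- pathwayNodes(pw)$id
  present <- intersect(ids, availableIds)
  dropped <- setdiff(ids, present)
  if (length(dropped)) {
    warning("pathway '", pathwayId(pw), "': dropping ", length(dropped),
            " node(s) absent from the expression data", call. = FALSE)
  }
  if (length(present) < 2L) {
    stop("pathway '", pathwayId(pw),
         "' has fewer than 2 nodes with expression data", call. = FALSE)
  }
  sub <- inducePathway(pw, present)
  tg <- triangulate(moralGraph(sub))
  list(pathway = sub, graph = tg, cliqueTree = buildCliqueTree(tg),
       nodes = sort(present))
}

# --- test statistics ---------------------------------------------------------

# Pathway-level mean and variance statistics for one labelling.
# X: samples x nodes; aIdx/bIdx: row indices of the two classes; ct: clique
# tree of the constraint graph. Variance statistic is the GGM log-likelihood
# ratio of class-specific fits against the pooled fit; mean statistic is the
# squared Mahalanobis-type form of the class mean difference in the pooled
# concentration metric.
ggmPairStats <- function(X, aIdx, bIdx, ct) {
  na <- length(aIdx); nb <- length(bIdx)
  Sa <- covML(X[aIdx, , drop = FALSE])
  Sb <- covML(X[bIdx, , drop = FALSE])
  Sp <- (na * Sa + nb * Sb) / (na + nb)
  fa <- fitDecomposableGgm(Sa, ct)
  fb <- fitDecomposableGgm(Sb, ct)
  fp <- fitDecomposableGgm(Sp, ct)
  tVar <- na * (fp$logDetSigma - fa$logDetSigma) +
    nb * (fp$logDetSigma - fb$logDetSigma)
  d <- colMeans(X[aIdx, , drop = FALSE]) - colMeans(X[bIdx, , drop = FALSE])
  d <- d[fp$nodes]
  tMean <- (na * nb / (na + nb)) * drop(t(d) %*% fp$K %*% d)
  c(mean = tMean, var = tVar)
}

# Saturated per-clique statistics for one labelling; returns a 2 x nCliques
# matrix (rows: mean, var).
cliquePairStats <- function(X, aIdx, bIdx, cliqueIdx) {
  na <- length(aIdx); nb <- length(bIdx)
  Sa <- covML(X[aIdx, , drop = FALSE])
  Sb <- covML(X[bIdx, , drop = FALSE])
  Sp <- (na * Sa + nb * Sb) / (na + nb)
  d <- colMeans(X[aIdx, , drop = FALSE]) - colMeans(X[bIdx, , drop = FALSE])
  vapply(cliqueIdx, function(idx) {
    ldA <- logDetPd(Sa[idx, idx, drop = FALSE], "clique class-a")
    ldB <- logDetPd(Sb[idx, idx, drop = FALSE], "clique class-b")
    ldP <- logDetPd(Sp[idx, idx, drop = FALSE], "clique pooled")
    tVar <- na * (ldP - ldA) + nb * (ldP - ldB)
    dC <- d[idx]
    tMean <- (na * nb / (na + nb)) *
      drop(t(dC) %*% invPd(Sp[idx, idx, drop = FALSE], "clique pooled") %*% dC)
    c(mean = tMean, var = tVar)
  }, numeric(2))
}

# assemble X (samples x nodes) and the two class index sets
classDesign <- function(mat, nodes, classA, classB) {
  cond <- sampleConditions(mat)
  for (g in c(classA, classB)) {
    if (!g %in% cond) stop("unknown condition: ", g, call. = FALSE)
  }
  sel <- cond %in% c(classA, classB)
  X <- t(exprValues(mat)[nodes, sel, drop = FALSE])
  lab <- cond[sel]
  aIdx <- which(lab == classA)
  bIdx <- which(lab == classB)
  stopIfNot(length(aIdx) >= 3L && length(bIdx) >= 3L,
            "need at least 3 samples per class")
  list(X = X, aIdx = aIdx, bIdx = bIdx)
}

addOneP <- function(nullStats, observed) {
  (1 + sum(nullStats >= observed)) / (1 + length(nullStats))
}

#' Whole-pathway permutation tests for mean and variance deregulation
#'
#' The pathway (after miRNA augmentation) is moralized, min-fill triangulated
#' and decomposed into a clique tree; the Gaussian graphical model it defines
#' is fitted to each class and to the pooled data. The variance statistic is
#' the log-likelihood ratio of the class-specific fits against the pooled
#' fit; the mean statistic is the quadratic form of the class mean difference
#' weighted by the pooled concentration matrix. Null distributions come from
#' permuting class labels; both tests share one permutation stream, and
#' p-values use the add-one estimator, so they are bounded below by
#' `1/(1 + nPerm)`. Pathway nodes absent from the expression data are dropped
#' with a warning.
#'
#' @param mat an [ExpressionProfile-class] (typically mixed gene+miRNA, see
#'   [combineExpression()]).
#' @param pw a [PathwayGraph-class].
#' @param classA,classB condition labels (>= 3 samples each).
#' @param nPerm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return one-row data.frame: pathway_id, n_nodes, stat_mean, stat_var,
#'   p_mean, p_var, n_perm, seed.
#' @export
pathwayTests <- function(mat, pw, classA, classB, nPerm = 1000L, seed = 1L) {
  dec <- pathwayDecomposition(pw, featureIds(mat))
  des <- classDesign(mat, dec$nodes, classA, classB)
  obs <- ggmPairStats(des$X, des$aIdx, des$bIdx, dec$cliqueTree)
  n <- nrow(des$X)
  na <- length(des$aIdx)
  perms <- makePerms(n, nPerm, seed)
  nullStats <- vapply(seq_len(nPerm), function(k) {
    prm <- perms[k, ]
    ggmPairStats(des$X, prm[seq_len(na)], prm[(na + 1L):n], dec$cliqueTree)
  }, numeric(2))
  data.frame(pathway_id = pathwayId(pw), n_nodes = length(dec$nodes),
             stat_mean = obs["mean"], stat_var = obs["var"],
             p_mean = addOneP(nullStats["mean", ], obs["mean"]),
             p_var = addOneP(nullStats["var", ], obs["var"]),
             n_perm = nPerm, seed = seed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Adjust pathway p-values and flag significant pathways
#'
#' Benjamini-Hochberg adjustment is applied separately to the mean-test and
#' variance-test p-value families across pathways. Under the default
#' `rule = "either"` a pathway is significant when `min(q_mean, q_var)` is at
#' most `qMax` (non-strict); `rule = "both"` requires both q-values to pass.
#'
#' @param tests data.frame of stacked [pathwayTests()] rows.
#' @param qMax q-value cutoff (default 0.1, inclusive).
#' @param rule `"either"` (default) or `"both"`.
#' @return the input with q_mean, q_var and significant columns added.
#' @export
adjustPathwayQvalues <- function(tests, qMax = 0.1,
                                 rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopIfNot(nrow(tests) > 0L, "no pathway tests to adjust")
  tests$q_mean <- bhFdr(tests$p_mean)
  tests$q_var <- bhFdr(tests$p_var)
  tests$significant <- switch(rule,
    either = pmin(tests$q_mean, tests$q_var) <= qMax,
    both = pmax(tests$q_mean, tests$q_var) <= qMax)
  tests
}

#' Per-clique permutation tests
#'
#' The same mean and variance statistics as [pathwayTests()], computed on each
#' clique's node subset under the saturated (unconstrained) Gaussian model,
#' with the identical permutation scheme: given the same seed and sample set,
#' a single-clique tree reproduces the whole-pathway test exactly.
#'
#' @param mat an [ExpressionProfile-class].
#' @param ct a [CliqueTree-class]; all clique members must be in `mat`.
#' @param classA,classB condition labels.
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per clique: clique label, size, p_mean,
#'   p_var.
#' @export
cliqueTests <- function(mat, ct, classA, classB, nPerm = 1000L, seed = 1L) {
  nodes <- sort(unique(unlist(treeCliques(ct))))
  stopIfNot(all(nodes %in% featureIds(mat)),
            "clique members missing from expression data")
  des <- classDesign(mat, nodes, classA, classB)
  cliqueIdx <- lapply(treeCliques(ct), function(cl) match(cl, nodes))
  obs <- cliquePairStats(des$X, des$aIdx, des$bIdx, cliqueIdx)
  n <- nrow(des$X)
  na <- length(des$aIdx)
  perms <- makePerms(n, nPerm, seed)
  nullMean <- matrix(0, nPerm, length(cliqueIdx))
  nullVar <- matrix(0, nPerm, length(cliqueIdx))
  for (k in seq_len(nPerm)) {
    prm <- perms[k, ]
    st <- cliquePairStats(des$X, prm[seq_len(na)], prm[(na + 1L):n],
                          cliqueIdx)
    nullMean[k, ] <- st["mean", ]
    nullVar[k, ] <- st["var", ]
  }
  data.frame(
    clique = vapply(treeCliques(ct), paste, character(1), collapse = ","),
    size = lengths(treeCliques(ct)),
    p_mean = vapply(seq_along(cliqueIdx), function(i) {
      addOneP(nullMean[, i], obs["mean", i])
    }, numeric(1)),
    p_var = vapply(seq_along(cliqueIdx), function(i) {
      addOneP(nullVar[, i], obs["var", i])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

# --- paths -------------------------------------------------------------------

#' Enumerate clique paths of a clique tree
#'
#' All simple paths between every pair of leaf cliques; in a tree the
#' leaf-pair path is unique, and a single-clique tree yields the one trivial
#' path. Forest components are handled separately (no path crosses
#' components).
#'
#' @param ct a [CliqueTree-class].
#' @return list of integer vectors (clique index sequences).
#' @export
enumerateCliquePaths <- function(ct) {
  m <- length(treeCliques(ct))
  te <- treeEdges(ct)
  if (m == 1L) return(list(1L))
  adjacency <- vector("list", m)
  for (k in seq_len(nrow(te))) {
    i <- te[k, 1]; j <- te[k, 2]
    adjacency[[i]] <- c(adjacency[[i]], j)
    adjacency[[j]] <- c(adjacency[[j]], i)
  }
  comp <- integer(m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adjacency[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cid
          queue <- c(queue, u)
        }
      }
    }
  }
  treePath <- function(from, to) {
    # BFS parents
    parent <- rep(NA_integer_, m)
    parent[from] <- from
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      for (u in adjacency[[v]]) {
        if (is.na(parent[u])) {
          parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    path <- to
    while (path[1] != from) path <- c(parent[path[1]], path)
    path
  }
  paths <- list()
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    if (length(members) == 1L) {
      paths[[length(paths) + 1L]] <- members
      next
    }
    deg <- lengths(adjacency[members])
    leaves <- members[deg <= 1L]
    if (length(leaves) < 2L) leaves <- members  # degenerate, defensive
    for (i in seq_len(length(leaves) - 1L)) {
      for (j in (i + 1L):length(leaves)) {
        paths[[length(paths) + 1L]] <- treePath(leaves[i], leaves[j])
      }
    }
  }
  paths
}

#' Score clique paths by aggregated clique significance
#'
#' The score of a path is the mean over its cliques of
#' `-log10(min(p_mean, p_var))`: larger means more deregulated. All-null
#' cliques (p = 1) give score 0.
#'
#' @param paths list of clique index vectors (see [enumerateCliquePaths()]).
#' @param cliqueResults data.frame from [cliqueTests()] in clique-tree order.
#' @param ct the [CliqueTree-class] the paths refer to.
#' @param pathwayId provenance label attached to each path row.
#' @return data.frame: pathway_id, path (label), score, n_cliques, nodes
#'   (list column of node-id vectors).
#' @export
scorePaths <- function(paths, cliqueResults, ct, pathwayId = "pathway") {
  minP <- pmin(cliqueResults$p_mean, cliqueResults$p_var)
  cl <- treeCliques(ct)
  out <- data.frame(
    pathway_id = pathwayId,
    path = vapply(paths, paste, character(1), collapse = "-"),
    score = vapply(paths, function(idx) mean(-log10(minP[idx])), numeric(1)),
    n_cliques = lengths(paths),
    stringsAsFactors = FALSE)
  out$nodes <- lapply(paths, function(idx) sort(unique(unlist(cl[idx]))))
  out
}

#' Decompose, test and score all paths of one pathway
#'
#' Convenience wrapper: decomposition + [cliqueTests()] +
#' [enumerateCliquePaths()] + [scorePaths()].
#'
#' @inheritParams pathwayTests
#' @return the scored-path data.frame of [scorePaths()].
#' @export
pathwayPaths <- function(mat, pw, classA, classB, nPerm = 1000L, seed = 1L) {
  dec <- pathwayDecomposition(pw, featureIds(mat))
  cres <- cliqueTests(mat, dec$cliqueTree, classA, classB, nPerm, seed)
  paths <- enumerateCliquePaths(dec$cliqueTree)
  scorePaths(paths, cres, dec$cliqueTree, pathwayId(pw))
}

#' Merge the top-scoring paths into a meta-pathway
#'
#' Takes the top `k` paths by score across all significant pathways (ties
#' broken by pathway id then path label), forms the union of their node sets,
#' and induces on that union all edges of the augmented source graphs. Node
#' provenance records the source pathway(s).
#'
#' @param scoredPaths stacked [scorePaths()] rows across significant pathways.
#' @param k number of top paths to merge (default 10; fewer paths means all
#'   are merged).
#' @param augmentedGraphs named list of augmented [PathwayGraph-class]
#'   objects keyed by pathway id.
#' @return a [PathwayGraph-class] with id `"meta-pathway"`; its nodes carry a
#'   `source` column naming contributing pathways.
#' @export
selectMetaPathway <- function(scoredPaths, k = 10L, augmentedGraphs) {
  stopIfNot(nrow(scoredPaths) > 0L, "no scored paths to merge")
  ord <- order(-scoredPaths$score, scoredPaths$pathway_id, scoredPaths$path)
  top <- scoredPaths[ord[seq_len(min(k, nrow(scoredPaths)))], , drop = FALSE]
  nodeUnion <- sort(unique(unlist(top$nodes)))

  nodes <- NULL
  edges <- NULL
  for (pwid in sort(unique(top$pathway_id))) {
    pw <- augmentedGraphs[[pwid]]
    stopIfNot(!is.null(pw), paste("no augmented graph for pathway", pwid))
    nd <- pathwayNodes(pw)
    nd <- nd[nd$id %in% nodeUnion, c("id", "kind"), drop = FALSE]
    if (nrow(nd)) nd$source <- pwid
    ed <- pathwayEdges(pw)
    ed <- ed[ed$src %in% nodeUnion & ed$dst %in% nodeUnion, , drop = FALSE]
    nodes <- rbind(nodes, nd)
    edges <- rbind(edges, ed)
  }
  # collapse duplicate nodes, recording all source pathways
  nodeList <- split(nodes, nodes$id)
  nodes <- do.call(rbind, lapply(nodeList, function(d) {
    if (length(unique(d$kind)) > 1L) {
      stop("conflicting node kinds for ", d$id[1], call. = FALSE)
    }
    data.frame(id = d$id[1], kind = d$kind[1],
               source = provJoin(d$source), stringsAsFactors = FALSE)
  }))
  # collapse duplicate edges, provenance unioned
  if (!is.null(edges) && nrow(edges)) {
    key <- paste(edges$src, edges$dst, edges$etype)
    edges <- do.call(rbind, lapply(split(edges, key), function(d) {
      d$provenance[1] <- provJoin(d$provenance)
      d[1, , drop = FALSE]
    }))
    edges <- edges[order(edges$src, edges$dst, edges$etype), , drop = FALSE]
  } else {
    edges <- emptyPathwayEdges()
  }
  PathwayGraph("meta-pathway", "meta-pathway", nodes = nodes, edges = edges)
}

#' Re-analyze the meta-pathway and keep the upper-quartile paths
#'
#' Full re-analysis of the meta-pathway (moralize, triangulate, clique tree,
#' clique tests, path scoring); paths whose score is at or above the 75th
#' percentile of the score distribution (linear-interpolation quantile) are
#' returned; ties at the threshold are kept. With all scores equal, all paths
#' are selected.
#'
#' @param meta the meta [PathwayGraph-class] from [selectMetaPathway()].
#' @param mat an [ExpressionProfile-class].
#' @param classA,classB condition labels.
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return the selected rows of the scored-path data.frame.
#' @export
finalPathSelection <- function(meta, mat, classA, classB, nPerm = 1000L,
                               seed = 1L) {
  stopIfNot(nrow(pathwayNodes(meta)) > 0L, "empty meta-pathway")
  scored <- pathwayPaths(mat, meta, classA, classB, nPerm, seed)
  sel <- scored[upperQuartileKeep(scored$score), , drop = FALSE]
  sel[order(-sel$score, sel$path), , drop = FALSE]
}

# selection rule of finalPathSelection: scores at or above the interpolated
# 75th percentile; ties at the threshold are kept
upperQuartileKeep <- function(scores) {
  scores >= quantile(scores, probs = 0.75, type = 7, names = FALSE)
}
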