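# Shared fixtures and independent brute-force oracles used across test files.

# --- tiny ExpressionProfile builders ----------------------------------------

makeProfile <- function(values, conditions, featureKind = "gene",
                        mutation = NULL) {
  ann <- data.frame(sample_id = colnames(values), condition = conditions,
                    stringsAsFactors = FALSE)
  if (!is.null(mutation)) ann$mutation <- mutation
  ExpressionProfile(values, ann, featureKind)
}

randomProfile <- function(nFeatures, nSamples, conditions = NULL,
                          prefix = "f", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(nFeatures * nSamples, mean = 8),
              nrow = nFeatures,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(nFeatures)),
                              sprintf("s%03d", seq_len(nSamples))))
  if (is.null(conditions)) {
    conditions <- rep(c("case", "ctrl"), length.out = nSamples)
  }
  makeProfile(v, conditions)
}

# --- independent statistical oracles -----------------------------------------

# naive O(m^2) Benjamini-Hochberg step-up
naiveBH <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  qSorted <- numeric(m)
  for (k in seq_len(m)) {
    qSorted[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[ord] <- qSorted
  out
}

# linear-interpolation empirical quantile (type 7), written out longhand
quantileOracle <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# two-sided correlation p-value by numeric integration of the t density
correlationPOracle <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  df <- n - 2
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-12,
                       abs.tol = 0)$value
}

# histogram-entropy oracle: explicit loop over equal-width bins
entropyOracle <- function(x, nBins = 10L) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  w <- (hi - lo) / nBins
  counts <- integer(nBins)
  for (v in x) {
    b <- min(nBins, floor((v - lo) / w) + 1L)
    counts[b] <- counts[b] + 1L
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

# --- graph oracles -----------------------------------------------------------

# adjacency matrix of an igraph (named, symmetric)
adjMatrixOf <- function(g) {
  am <- as.matrix(igraph::as_adjacency_matrix(g))
  am[am > 1] <- 1
  am
}

# chordality by brute force: no induced cycle of length >= 4. Enumerates all
# vertex subsets of size >= 4 and checks whether the induced subgraph is a
# cycle (connected, all degrees exactly 2).
chordalOracle <- function(g) {
  am <- adjMatrixOf(g)
  n <- nrow(am)
  if (n < 4L) return(TRUE)
  for (size in 4:n) {
    combos <- utils::combn(seq_len(n), size)
    for (k in seq_len(ncol(combos))) {
      idx <- combos[, k]
      sub <- am[idx, idx]
      if (!all(rowSums(sub) == 2)) next
      # connected 2-regular induced subgraph = chordless cycle
      seen <- rep(FALSE, size)
      seen[1] <- TRUE
      queue <- 1L
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(sub[v, ] == 1 & !seen)
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      if (all(seen)) return(FALSE)
    }
  }
  TRUE
}

# running intersection property, checked exhaustively: for every pair of
# cliques, their intersection must be contained in every clique on the unique
# tree path between them.
ripHolds <- function(ct) {
  cl <- treeCliques(ct)
  te <- treeEdges(ct)
  m <- length(cl)
  if (m <= 1L) return(TRUE)
  adjacency <- vector("list", m)
  for (k in seq_len(nrow(te))) {
    adjacency[[te[k, 1]]] <- c(adjacency[[te[k, 1]]], te[k, 2])
    adjacency[[te[k, 2]]] <- c(adjacency[[te[k, 2]]], te[k, 1])
  }
  pathBetween <- function(a, b) {
    parent <- rep(NA_integer_, m)
    parent[a] <- a
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adjacency[[v]]) {
        if (is.na(parent[u])) { parent[u] <- v; queue <- c(queue, u) }
      }
    }
    if (is.na(parent[b])) return(NULL)  # different components
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    path
  }
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      inter <- intersect(cl[[i]], cl[[j]])
      if (!length(inter)) next
      path <- pathBetween(i, j)
      if (is.null(path)) return(FALSE)  # shared nodes across components
      for (v in path) {
        if (!all(inter %in% cl[[v]])) return(FALSE)
      }
    }
  }
  TRUE
}

# Erdos-Renyi-ish random named undirected graph
randomGraph <- function(n, pEdge = 0.4) {
  ids <- letters[seq_len(n)]
  am <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < pEdge) am[i, j] <- am[j, i] <- 1L
    }
  }
  igraph::graph_from_adjacency_matrix(am, mode = "undirected")
}

# small pathway fixture: chain a -> b -> c (activation, inhibition)
chainPathway <- function(id = "pwX") {
  PathwayGraph(id, "chain",
               nodes = data.frame(id = c("a", "b", "c"),
                                  kind = "gene", stringsAsFactors = FALSE),
               edges = data.frame(src = c("a", "b"), dst = c("b", "c"),
                                  directed = TRUE,
                                  etype = c("activation", "inhibition"),
                                  stringsAsFactors = FALSE))
}
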