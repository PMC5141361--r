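# Gaussian graphical model fitting: IPS and the decomposable closed form.

#' Fit a graph-constrained covariance by iterative proportional scaling
#'
#' Computes the maximum-likelihood covariance under the Gaussian graphical
#' model defined by `graph`: clique marginals of the fit match the sample
#' covariance, and concentration-matrix entries of non-adjacent node pairs
#' are zero. Cycles over the maximal cliques, updating the concentration
#' matrix block-wise, until every clique marginal matches `sampleCov` within
#' `tol`.
#'
#' @param sampleCov sample covariance with dimnames; must be positive
#'   definite on every clique.
#' @param graph an undirected [igraph::graph]; vertex names must index
#'   `sampleCov`.
#' @param tol convergence tolerance on the largest clique-marginal deviation
#'   (default 1e-8).
#' @param maxIter maximum sweeps over the cliques (default 500); exceeding it
#'   is an error reporting the last discrepancy.
#' @return a [GGMEstimate-class].
#' @examples
#' S <- cov(matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4])))
#' g <- igraph::make_graph(c("a","b", "b","c", "c","d"), directed = FALSE)
#' ipsCovariance(S, g)
#' @export
ipsCovariance <- function(sampleCov, graph, tol = 1e-8, maxIter = 500L) {
  nodes <- igraph::V(graph)$name
  stopIfNot(!is.null(rownames(sampleCov)) &&
              all(nodes %in% rownames(sampleCov)),
            "sampleCov must carry dimnames covering the graph's vertices")
  S <- sampleCov[nodes, nodes, drop = FALSE]
  p <- length(nodes)
  cliques <- maximalCliques(graph)
  cliqueIdx <- lapply(cliques, function(cl) match(cl, nodes))
  for (idx in cliqueIdx) invPd(S[idx, idx, drop = FALSE], "clique sample")

  K <- diag(1 / diag(S), p)
  dimnames(K) <- list(nodes, nodes)
  Sigma <- diag(diag(S), p)
  dimnames(Sigma) <- dimnames(K)
  disc <- Inf
  for (iter in seq_len(maxIter)) {
    for (idx in cliqueIdx) {
      K[idx, idx] <- K[idx, idx] +
        invPd(S[idx, idx, drop = FALSE], "clique sample") -
        invPd(Sigma[idx, idx, drop = FALSE], "clique fit")
      Sigma <- invPd(K, "concentration")
      dimnames(Sigma) <- dimnames(K)
    }
    disc <- max(vapply(cliqueIdx, function(idx) {
      max(abs(Sigma[idx, idx] - S[idx, idx]))
    }, numeric(1)))
    if (disc < tol) {
      return(new("GGMEstimate", nodes = nodes, sigma = Sigma,
                 iterations = iter, maxDiscrepancy = disc))
    }
  }
  stop(sprintf(
    "IPS did not converge in %d iterations (last discrepancy %.3g)",
    maxIter, disc), call. = FALSE)
}

#' Closed-form GGM fit for a decomposable model
#'
#' For a chordal graph with clique tree `ct`, the maximum-likelihood
#' concentration matrix is the sum of padded clique-block inverses of the
#' sample covariance minus the padded separator-block inverses, and the
#' log-determinant of the fitted covariance is the corresponding sum of
#' clique log-determinants minus separator log-determinants. Exact, no
#' iteration; the topological permutation tests use this fit.
#'
#' @param sampleCov sample covariance with dimnames covering all clique
#'   members.
#' @param ct a [CliqueTree-class] of the (chordal) constraint graph.
#' @return list with `K` (concentration matrix), `logDetSigma`, and `nodes`.
#' @export
fitDecomposableGgm <- function(sampleCov, ct) {
  nodes <- sort(unique(unlist(treeCliques(ct))))
  stopIfNot(all(nodes %in% rownames(sampleCov)),
            "sampleCov must cover every clique member")
  S <- sampleCov[nodes, nodes, drop = FALSE]
  p <- length(nodes)
  K <- matrix(0, p, p, dimnames = list(nodes, nodes))
  ld <- 0
  for (cl in treeCliques(ct)) {
    idx <- match(cl, nodes)
    blk <- S[idx, idx, drop = FALSE]
    K[idx, idx] <- K[idx, idx] + invPd(blk, "clique sample")
    ld <- ld + logDetPd(blk, "clique sample")
  }
  for (sep in treeSeparators(ct)) {
    if (length(sep) == 0L) next
    idx <- match(sep, nodes)
    blk <- S[idx, idx, drop = FALSE]
    K[idx, idx] <- K[idx, idx] - invPd(blk, "separator sample")
    ld <- ld - logDetPd(blk, "separator sample")
  }
  list(K = K, logDetSigma = ld, nodes = nodes)
}
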