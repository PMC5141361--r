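# Build a small two-class profile over the nodes of a pathway, optionally
# shifting `shiftNodes` by `delta` in the case class.
twoClassProfile <- function(nodes, nPerClass = 15, delta = 0,
                            shiftNodes = character(0), seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  v <- matrix(rnorm(length(nodes) * n, 8), length(nodes), n,
              dimnames = list(nodes, sprintf("s%03d", 1:n)))
  cond <- rep(c("case", "ctrl"), each = nPerClass)
  v[shiftNodes, cond == "case"] <- v[shiftNodes, cond == "case"] + delta
  makeProfile(v, cond, "mixed")
}

starPathway <- function() {
  # hub h with three arms of length 2: clique tree is a star of leaf cliques
  PathwayGraph("star", nodes = data.frame(
    id = c("h", "a1", "a2", "b1", "b2", "c1", "c2"), kind = "gene"),
    edges = data.frame(src = c("h", "a1", "h", "b1", "h", "c1"),
                       dst = c("a1", "a2", "b1", "b2", "c1", "c2"),
                       directed = TRUE, etype = "activation"))
}

test_that("pathway p-values are valid, seeded and bounded by the add-one rule", {
  pw <- chainPathway()
  mat <- twoClassProfile(c("a", "b", "c"), nPerClass = 10, seed = 3)
  t1 <- pathwayTests(mat, pw, "case", "ctrl", nPerm = 99, seed = 5)
  t2 <- pathwayTests(mat, pw, "case", "ctrl", nPerm = 99, seed = 5)
  expect_equal(t1, t2)  # deterministic given seed
  expect_gte(t1$p_mean, 1 / 100)
  expect_gte(t1$p_var, 1 / 100)
  expect_lte(t1$p_mean, 1)

  # nodes absent from the matrix are dropped with a warning
  pwX <- PathwayGraph("px", nodes = data.frame(id = c("a", "b", "c", "zz"),
                                               kind = "gene"),
                      edges = pathwayEdges(chainPathway()))
  expect_warning(pathwayTests(mat, pwX, "case", "ctrl", nPerm = 49, seed = 1),
                 "absent from the expression data")
})

test_that("null pathway p-values are approximately uniform", {
  pw <- chainPathway()
  set.seed(101)
  seeds <- sample.int(1e6, 400)
  pm <- vapply(seq_along(seeds), function(i) {
    mat <- twoClassProfile(c("a", "b", "c"), nPerClass = 8, seed = seeds[i])
    res <- pathwayTests(mat, pw, "case", "ctrl", nPerm = 199,
                        seed = seeds[i] + 1)
    c(res$p_mean, res$p_var)
  }, numeric(2))
  ksDist <- function(p) {
    ps <- sort(p)
    n <- length(ps)
    max(abs(seq_len(n) / n - ps), abs((seq_len(n) - 1) / n - ps))
  }
  expect_lt(ksDist(pm[1, ]), 0.1)
  expect_lt(ksDist(pm[2, ]), 0.1)
})

test_that("a planted mean shift is detected with high power", {
  pw <- chainPathway()
  hits <- 0L
  for (i in 1:20) {
    mat <- twoClassProfile(c("a", "b", "c"), nPerClass = 30, delta = 2,
                           shiftNodes = c("a", "b", "c"), seed = 400 + i)
    res <- pathwayTests(mat, pw, "case", "ctrl", nPerm = 199, seed = i)
    hits <- hits + (res$p_mean <= 0.01)
  }
  expect_gte(hits, 19L)
})

test_that("q-value adjustment per family with inclusive significance rule", {
  tests <- data.frame(pathway_id = "p1", p_mean = 0.03, p_var = 0.8)
  adj <- adjustPathwayQvalues(tests)
  expect_equal(adj$q_mean, 0.03)  # single pathway: q = p
  expect_equal(adj$q_var, 0.8)
  expect_true(adj$significant)

  # q exactly at the cutoff is significant (inclusive)
  adjB <- adjustPathwayQvalues(data.frame(pathway_id = "p", p_mean = 0.1,
                                          p_var = 0.9))
  expect_true(adjB$significant)

  # matches the BH oracle per family; "both" rule is stricter
  set.seed(6)
  tests3 <- data.frame(pathway_id = paste0("p", 1:8),
                       p_mean = runif(8), p_var = runif(8))
  adj3 <- adjustPathwayQvalues(tests3, rule = "both")
  expect_equal(adj3$q_mean, naiveBH(tests3$p_mean))
  expect_equal(adj3$q_var, naiveBH(tests3$p_var))
  expect_true(all(adj3$significant ==
                    (pmax(adj3$q_mean, adj3$q_var) <= 0.1)))
})

test_that("clique tests agree with the pathway test on a single complete clique", {
  ids <- c("a", "b", "c")
  full <- PathwayGraph("k3", nodes = data.frame(id = ids, kind = "gene"),
                       edges = data.frame(src = c("a", "a", "b"),
                                          dst = c("b", "c", "c"),
                                          directed = FALSE, etype = "binding"))
  mat <- twoClassProfile(ids, nPerClass = 12, delta = 1, shiftNodes = "a",
                         seed = 9)
  pt <- pathwayTests(mat, full, "case", "ctrl", nPerm = 199, seed = 4)
  ct <- buildCliqueTree(triangulate(moralGraph(full)))
  clt <- cliqueTests(mat, ct, "case", "ctrl", nPerm = 199, seed = 4)
  expect_equal(nrow(clt), 1L)
  expect_equal(clt$p_mean, pt$p_mean)
  expect_equal(clt$p_var, pt$p_var)
})

test_that("clique tests localize a planted signal", {
  pw <- starPathway()
  nodes <- pathwayNodes(pw)$id
  pShift <- pNull <- numeric(0)
  for (i in 1:10) {
    mat <- twoClassProfile(nodes, nPerClass = 25, delta = 1.8,
                           shiftNodes = c("a1", "a2"), seed = 700 + i)
    ct <- buildCliqueTree(triangulate(moralGraph(pw)))
    res <- cliqueTests(mat, ct, "case", "ctrl", nPerm = 199, seed = i)
    hit <- vapply(strsplit(res$clique, ","), function(cl) {
      all(c("a1", "a2") %in% cl)
    }, logical(1))
    null <- vapply(strsplit(res$clique, ","), function(cl) {
      !any(c("a1", "a2", "h") %in% cl)
    }, logical(1))
    pShift <- c(pShift, res$p_mean[hit])
    pNull <- c(pNull, res$p_mean[null])
  }
  expect_lt(mean(pShift), 0.05)
  expect_gt(mean(pNull), 0.2)
})

test_that("path enumeration covers all leaf pairs, matching brute force", {
  # path-shaped tree with 3 cliques: one leaf pair
  pathCT <- new("CliqueTree",
                cliques = list(c("a", "b"), c("b", "c"), c("c", "d")),
                separators = list("b", "c"),
                treeEdges = rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(enumerateCliquePaths(pathCT), list(c(1L, 2L, 3L)))

  # star with 3 leaves: 3 paths
  starCT <- new("CliqueTree",
                cliques = list(c("h", "x"), c("h", "y"), c("h", "z"),
                               c("h", "w")),
                separators = list("h", "h", "h"),
                treeEdges = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  starPaths <- enumerateCliquePaths(starCT)
  expect_length(starPaths, 3L)
  expect_true(all(vapply(starPaths, function(p) p[2] == 1L, logical(1))))

  # single clique: the trivial path
  oneCT <- new("CliqueTree", cliques = list(c("a", "b")),
               separators = list(), treeEdges = matrix(integer(), ncol = 2))
  expect_equal(enumerateCliquePaths(oneCT), list(1L))

  # random trees <= 8 cliques: count equals all-pairs leaf enumeration
  set.seed(14)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    edges <- cbind(2:m, vapply(2:m, function(j) sample.int(j - 1, 1), 1L))
    deg <- tabulate(as.vector(edges), nbins = m)
    nLeaves <- sum(deg <= 1)
    ctR <- new("CliqueTree",
               cliques = lapply(1:m, function(i) sprintf("n%d", i)),
               separators = rep(list(character(0)), m - 1),
               treeEdges = matrix(as.integer(edges), ncol = 2))
    expect_length(enumerateCliquePaths(ctR), choose(nLeaves, 2))
  }
})

test_that("path scores aggregate clique significance as mean -log10 min p", {
  ct <- new("CliqueTree",
            cliques = list(c("a", "b"), c("b", "c"), c("c", "d")),
            separators = list("b", "c"),
            treeEdges = rbind(c(1L, 2L), c(2L, 3L)))
  paths <- list(c(1L, 2L, 3L), 2L)
  res1 <- data.frame(clique = c("a,b", "b,c", "c,d"),
                     p_mean = 1, p_var = 1)
  expect_equal(scorePaths(paths, res1, ct)$score, c(0, 0))
  res2 <- data.frame(clique = res1$clique, p_mean = 0.01, p_var = 0.5)
  expect_equal(scorePaths(paths, res2, ct)$score, c(2, 2))
  res3 <- data.frame(clique = res1$clique,
                     p_mean = c(0.1, 0.01, 1), p_var = c(0.5, 0.1, 0.001))
  expect_equal(scorePaths(paths, res3, ct)$score[1],
               mean(-log10(c(0.1, 0.01, 0.001))))
  # nodes are the union over path cliques
  expect_equal(scorePaths(paths, res3, ct)$nodes[[1]], c("a", "b", "c", "d"))
})

test_that("meta-pathway merges top paths with provenance and induced edges", {
  pwA <- chainPathway("pwA")
  pwB <- PathwayGraph("pwB", nodes = data.frame(id = c("c", "d"), kind = "gene"),
                      edges = data.frame(src = "c", dst = "d", directed = TRUE,
                                         etype = "activation"))
  scored <- data.frame(pathway_id = c("pwA", "pwA", "pwB"),
                       path = c("1-2", "2", "1"),
                       score = c(3, 1, 2), n_cliques = c(2, 1, 1),
                       stringsAsFactors = FALSE)
  scored$nodes <- list(c("a", "b", "c"), c("b", "c"), c("c", "d"))
  graphs <- list(pwA = pwA, pwB = pwB)

  # fewer than k paths: all merged
  meta <- selectMetaPathway(scored, k = 10, graphs)
  expect_setequal(pathwayNodes(meta)$id, c("a", "b", "c", "d"))
  expect_equal(nrow(pathwayEdges(meta)), 3L)  # a-b, b-c from pwA; c-d from pwB
  expect_equal(pathwayNodes(meta)$source[pathwayNodes(meta)$id == "c"],
               "pwA;pwB")

  # top-2 selection honors the score ranking
  meta2 <- selectMetaPathway(scored, k = 2, graphs)
  expect_setequal(pathwayNodes(meta2)$id, c("a", "b", "c", "d"))

  # duplicate paths leave the union unchanged
  meta3 <- selectMetaPathway(rbind(scored, scored), k = 100, graphs)
  expect_equal(pathwayNodes(meta3), pathwayNodes(meta))
  expect_equal(pathwayEdges(meta3), pathwayEdges(meta))
})

test_that("upper-quartile path selection keeps ties and singletons", {
  # 4 distinct scores: only the maximum reaches the interpolated Q3
  expect_equal(sum(mirtopnet:::upperQuartileKeep(c(1, 2, 3, 4))), 1L)
  expect_equal(quantileOracle(c(1, 2, 3, 4), 0.75), 3.25)
  # all equal: everything selected
  expect_true(all(mirtopnet:::upperQuartileKeep(rep(2, 5))))
  # single path: selected
  expect_true(mirtopnet:::upperQuartileKeep(0.7))
  # ties at the threshold are kept
  expect_equal(sum(mirtopnet:::upperQuartileKeep(c(1, 4, 4, 4, 4))), 4L)
})

test_that("final path selection recovers a planted path end to end", {
  pw <- starPathway()
  nodes <- pathwayNodes(pw)$id
  mat <- twoClassProfile(nodes, nPerClass = 25, delta = 2,
                         shiftNodes = c("b1", "b2"), seed = 88)
  scored <- pathwayPaths(mat, pw, "case", "ctrl", nPerm = 199, seed = 2)
  meta <- selectMetaPathway(scored, k = 3, list(star = pw))
  final <- finalPathSelection(meta, mat, "case", "ctrl", nPerm = 199, seed = 3)
  expect_gte(nrow(final), 1L)
  expect_true(all(c("b1", "b2") %in% unlist(final$nodes)))
})
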