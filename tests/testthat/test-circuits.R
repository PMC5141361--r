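# exact-correlation building blocks: cor(xPat, yPat) is exactly 0.5 and
# cor(xPat, yNeg) exactly -0.5 in floating point (small-integer sums)
xPat <- rep(c(-1, 0, 1), 4) + 8
yPat <- rep(c(0, -2, 2), 4) + 8
yNeg <- rep(c(2, -2, 0), 4) + 8

test_that("candidate enumeration matches brute-force triple enumeration", {
  catalog <- list(
    tf_mirna = data.frame(tf_id = "tf1", mirna_id = "m1", source = "s"),
    tf_gene = data.frame(tf_id = "tf1", target_gene_id = "g1", source = "s"))
  preds <- data.frame(mirna_id = "m1", gene_id = "g1", score = 0.9)

  # 1 TF, 1 miRNA, 1 gene with all three relations: exactly one tf_master
  cands <- enumerateCandidates(catalog, preds, "m1", c("tf1", "g1"))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$topology, "tf_master")

  # empty catalogs give an empty frame
  cands0 <- enumerateCandidates(list(tf_mirna = NULL, tf_gene = NULL),
                                preds, "m1", c("tf1", "g1"))
  expect_equal(nrow(cands0), 0L)

  # mirna_master requires the miRNA to target the TF transcript and the gene
  preds2 <- data.frame(mirna_id = c("m1", "m1"), gene_id = c("tf1", "g1"),
                       score = 0.9)
  cands2 <- enumerateCandidates(list(tf_mirna = NULL,
                                     tf_gene = catalog$tf_gene),
                                preds2, "m1", c("tf1", "g1"))
  expect_equal(cands2$topology, "mirna_master")

  # random small catalogs equal brute-force triple enumeration
  set.seed(13)
  tfs <- paste0("tf", 1:3); ms <- paste0("m", 1:3); gs <- paste0("g", 1:4)
  for (rep in 1:10) {
    tm <- unique(data.frame(tf_id = sample(tfs, 5, TRUE),
                            mirna_id = sample(ms, 5, TRUE), source = "s"))
    tg <- unique(data.frame(tf_id = sample(tfs, 6, TRUE),
                            target_gene_id = sample(c(gs, tfs), 6, TRUE),
                            source = "s"))
    pr <- unique(data.frame(mirna_id = sample(ms, 6, TRUE),
                            gene_id = sample(c(gs, tfs), 6, TRUE),
                            score = 0.9))
    got <- enumerateCandidates(list(tf_mirna = tm, tf_gene = tg), pr,
                               ms, c(gs, tfs))
    want <- NULL
    pk <- paste(pr$mirna_id, pr$gene_id)
    for (tf in tfs) for (m in ms) for (g in c(gs, tfs)) {
      if (g == tf) next
      if (paste(tf, m) %in% paste(tm$tf_id, tm$mirna_id) &&
          paste(tf, g) %in% paste(tg$tf_id, tg$target_gene_id) &&
          paste(m, g) %in% pk) {
        want <- rbind(want, data.frame(topology = "tf_master", tf_id = tf,
                                       mirna_id = m, gene_id = g))
      }
      if (paste(m, tf) %in% pk && paste(m, g) %in% pk &&
          paste(tf, g) %in% paste(tg$tf_id, tg$target_gene_id)) {
        want <- rbind(want, data.frame(topology = "mirna_master", tf_id = tf,
                                       mirna_id = m, gene_id = g))
      }
    }
    want <- unique(want)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_setequal(paste(got$topology, got$tf_id, got$mirna_id, got$gene_id),
                      paste(want$topology, want$tf_id, want$mirna_id,
                            want$gene_id))
    }
    # invariance to catalog row order
    got2 <- enumerateCandidates(
      list(tf_mirna = tm[rev(seq_len(nrow(tm))), ],
           tf_gene = tg[rev(seq_len(nrow(tg))), ]), pr, ms, c(gs, tfs))
    expect_equal(got, got2)
  }
})

test_that("circuit filtering keeps |r| >= 0.5 inclusively and is monotone", {
  n <- length(xPat)
  cond <- rep(c("case", "ctrl"), each = n / 2)
  G <- rbind(tf1 = xPat, g1 = yPat)
  M <- rbind(m1 = yNeg)
  colnames(G) <- colnames(M) <- sprintf("s%02d", 1:n)
  gene <- makeProfile(G, cond); mirna <- makeProfile(M, cond, "mirna")
  cands <- data.frame(topology = "tf_master", tf_id = "tf1",
                      mirna_id = "m1", gene_id = "g1")

  kept <- scoreAndFilter(cands, mirna, gene, minAbsR = 0.5)
  expect_equal(nrow(kept), 1L)  # boundary |r| = 0.5 retained
  expect_equal(abs(kept$r_tf_mirna), 0.5)
  expect_equal(abs(kept$r_tf_gene), 0.5)

  # one edge just below the threshold drops the circuit
  expect_equal(nrow(scoreAndFilter(cands, mirna, gene, minAbsR = 0.51)), 0L)

  # monotone: raising the threshold never adds circuits
  set.seed(44)
  G2 <- matrix(rnorm(5 * 40, 8), 5, 40,
               dimnames = list(c("tf1", "tf2", "g1", "g2", "g3"),
                               sprintf("s%02d", 1:40)))
  M2 <- matrix(rnorm(2 * 40, 8), 2, 40,
               dimnames = list(c("m1", "m2"), colnames(G2)))
  gene2 <- makeProfile(G2, rep(c("case", "ctrl"), 20))
  mirna2 <- makeProfile(M2, rep(c("case", "ctrl"), 20), "mirna")
  cands2 <- expand.grid(tf_id = c("tf1", "tf2"), mirna_id = c("m1", "m2"),
                        gene_id = c("g1", "g2", "g3"),
                        stringsAsFactors = FALSE)
  cands2$topology <- "tf_master"
  prev <- Inf
  for (thr in c(0, 0.1, 0.2, 0.4)) {
    nKept <- nrow(scoreAndFilter(cands2, mirna2, gene2, minAbsR = thr))
    expect_lte(nKept, prev)
    prev <- nKept
  }

  # constant profile drops the circuit with a warning
  G3 <- rbind(tf1 = rep(8, n), g1 = yPat)
  colnames(G3) <- colnames(G)
  expect_warning(
    out <- scoreAndFilter(cands, mirna, makeProfile(G3, cond)),
    "constant")
  expect_equal(nrow(out), 0L)
})

test_that("feed-forward coherence follows the sign truth table exactly", {
  # tf_master: direct = sign(r_tf_gene); indirect = sign(r_tf_mirna) * (-1).
  # mirna_master: direct = -1; indirect = -sign(r_tf_gene).
  signs <- expand.grid(s_tm = c(1, -1), s_tg = c(1, -1), s_mg = c(1, -1))
  for (topo in c("tf_master", "mirna_master")) {
    for (k in seq_len(nrow(signs))) {
      circ <- data.frame(topology = topo, tf_id = "tf", mirna_id = "m",
                         gene_id = "g",
                         r_tf_mirna = 0.8 * signs$s_tm[k],
                         r_tf_gene = 0.7 * signs$s_tg[k],
                         r_mirna_gene = 0.6 * signs$s_mg[k])
      got <- classifyFfl(circ)$coherence
      want <- if (topo == "tf_master") {
        if (signs$s_tg[k] == -signs$s_tm[k]) "coherent" else "incoherent"
      } else {
        if (signs$s_tg[k] > 0) "coherent" else "incoherent"
      }
      expect_equal(got, want,
                   label = sprintf("%s (%d,%d,%d)", topo, signs$s_tm[k],
                                   signs$s_tg[k], signs$s_mg[k]))
    }
  }
  # spec'd reference case: r_tf_gene > 0, r_tf_mirna < 0 is coherent
  ref <- data.frame(topology = "tf_master", tf_id = "t", mirna_id = "m",
                    gene_id = "g", r_tf_mirna = -0.6, r_tf_gene = 0.9,
                    r_mirna_gene = -0.7)
  expect_equal(classifyFfl(ref)$coherence, "coherent")
  ref$r_tf_mirna <- 0.6
  expect_equal(classifyFfl(ref)$coherence, "incoherent")

  # zero correlation has no sign
  ref$r_tf_gene <- 0
  expect_error(classifyFfl(ref), "undefined")
})

test_that("linking keeps circuits sharing at least one node with the network", {
  net <- RegulatoryNetwork(
    nodes = data.frame(id = c("g1", "m1"), kind = c("gene", "mirna"),
                       provenance = "x"),
    edges = NULL)
  circuits <- data.frame(
    topology = "tf_master",
    tf_id = c("tfA", "tfB", "tfC"),
    mirna_id = c("mX", "m1", "mY"),
    gene_id = c("gX", "gY", "gZ"), stringsAsFactors = FALSE)
  linked <- linkToNetwork(circuits, net)
  expect_equal(linked$tf_id, "tfB")  # shares only its miRNA: kept
  # disjoint circuits all dropped; empty in, empty out
  expect_equal(nrow(linkToNetwork(circuits[c(1, 3), ], net)), 0L)
  expect_equal(nrow(linkToNetwork(circuits[0, ], net)), 0L)
})
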