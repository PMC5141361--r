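smallNet <- function() {
  RegulatoryNetwork(
    nodes = data.frame(id = c("g1", "g2", "m1", "tf1"),
                       kind = c("gene", "gene", "mirna", "tf"),
                       provenance = c("bm", "bm", "pb", "pb"),
                       stringsAsFactors = FALSE),
    edges = data.frame(src = c("g1", "m1", "tf1"),
                       dst = c("g2", "g1", "g2"),
                       etype = c("activation", "mirna_predicted", "tf_gene"),
                       provenance = c("bm", "pb", "pb"),
                       stringsAsFactors = FALSE))
}

test_that("network merging is a provenance-unioning idempotent set union", {
  net <- smallNet()
  # merge(N, N) = N
  expect_equal(networkNodes(mergeNetworks(list(net, net))),
               networkNodes(net))
  expect_equal(networkEdges(mergeNetworks(list(net, net))),
               networkEdges(net))

  # disjoint networks: counts add
  other <- RegulatoryNetwork(
    nodes = data.frame(id = c("g9", "m9"), kind = c("gene", "mirna"),
                       provenance = "z"),
    edges = data.frame(src = "m9", dst = "g9", etype = "mirna_validated",
                       provenance = "z"))
  merged <- mergeNetworks(list(net, other))
  s <- networkSummary(merged)
  expect_equal(s$n_nodes, 6L)
  expect_equal(s$n_edges, 4L)
  expect_equal(s$n_mirnas, 2L)

  # dangling edge endpoints are rejected at construction
  expect_error(RegulatoryNetwork(
    nodes = data.frame(id = c("g1", "g9"), kind = "gene", provenance = "pb"),
    edges = data.frame(src = "g1", dst = "g2", etype = "activation",
                       provenance = "pb")), "endpoint")

  # overlapping networks equal a brute-force set union; provenance unions
  overlap2 <- RegulatoryNetwork(
    nodes = data.frame(id = c("g1", "g2"), kind = "gene", provenance = "pb"),
    edges = data.frame(src = "g1", dst = "g2", etype = "activation",
                       provenance = "pb"))
  m2 <- mergeNetworks(list(net, overlap2))
  expect_equal(nrow(networkNodes(m2)), 4L)
  nd <- networkNodes(m2)
  expect_equal(nd$provenance[nd$id == "g1"], "bm;pb")
  ed <- networkEdges(m2)
  expect_equal(ed$provenance[ed$etype == "activation"], "bm;pb")

  # merging is commutative and associative up to canonical ordering
  expect_equal(mergeNetworks(list(net, other)),
               mergeNetworks(list(other, net)))

  # conflicting node kinds are an error
  bad <- RegulatoryNetwork(
    nodes = data.frame(id = "g1", kind = "mirna", provenance = "z"),
    edges = NULL)
  expect_error(mergeNetworks(list(net, bad)), "conflicting node kinds")
})

test_that("fold-change annotation records absence as NA, never zero", {
  net <- smallNet()
  fc <- list(bm = c(g1 = 0.5, g2 = -1.25, zz = 3),
             pb = c(g1 = 0))
  ann <- annotateFoldChanges(net, fc)
  nd <- networkNodes(ann)
  expect_equal(nd$fc_bm[nd$id == "g2"], -1.25)
  expect_equal(nd$fc_pb[nd$id == "g1"], 0)
  expect_true(is.na(nd$fc_pb[nd$id == "g2"]))
  expect_true(is.na(nd$fc_bm[nd$id == "m1"]))
})

test_that("network summary counts stored elements exactly", {
  empty <- RegulatoryNetwork()
  s0 <- networkSummary(empty)
  expect_equal(s0$n_nodes, 0L)
  expect_equal(s0$n_edges, 0L)
  expect_true(all(s0$edges_by_type == 0L))

  s <- networkSummary(smallNet())
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$n_mirnas, 1L)
  expect_equal(unname(s$edges_by_type[c("activation", "mirna_predicted",
                                        "tf_gene")]), c(1L, 1L, 1L))
  # independent recount from the stored tables
  expect_equal(s$n_edges, nrow(networkEdges(smallNet())))
})

test_that("export/import round-trips json and graphml exactly; SIF is one line per edge", {
  dir <- withr::local_tempdir()
  net <- annotateFoldChanges(smallNet(),
                             list(bm = c(g1 = pi, g2 = -0.125),
                                  pb = c(m1 = 1 / 3)))

  jsonPath <- file.path(dir, "net.json")
  exportNetwork(net, jsonPath, "json")
  backJ <- importNetwork(jsonPath)
  expect_equal(networkNodes(backJ), networkNodes(net))
  expect_equal(networkEdges(backJ), networkEdges(net))

  gmlPath <- file.path(dir, "net.graphml")
  exportNetwork(net, gmlPath, "graphml")
  backG <- importNetwork(gmlPath)
  expect_equal(networkNodes(backG), networkNodes(net))
  expect_equal(networkEdges(backG), networkEdges(net))

  sifPath <- file.path(dir, "net.sif")
  exportNetwork(net, sifPath, "sif")
  expect_length(readLines(sifPath), nrow(networkEdges(net)))

  # empty network exports and re-imports
  emptyPath <- file.path(dir, "empty.json")
  exportNetwork(RegulatoryNetwork(), emptyPath, "json")
  backE <- importNetwork(emptyPath)
  expect_equal(nrow(networkNodes(backE)), 0L)

  # random networks round-trip through both lossless formats
  set.seed(3)
  for (rep in 1:5) {
    ids <- paste0("n", 1:6)
    kinds <- sample(c("gene", "tf", "mirna"), 6, TRUE)
    pairs <- t(utils::combn(ids, 2))
    take <- sample(nrow(pairs), 8)
    srcKind <- kinds[match(pairs[take, 1], ids)]
    dstKind <- kinds[match(pairs[take, 2], ids)]
    etype <- sample(c("activation", "inhibition", "tf_gene"), 8, TRUE)
    etype[srcKind == "mirna" & dstKind != "mirna"] <- "mirna_predicted"
    rnet <- RegulatoryNetwork(
      nodes = data.frame(id = ids, kind = kinds,
                         provenance = sample(c("bm", "pb", "bm;pb"), 6, TRUE),
                         fc_bm = round(rnorm(6), 3)),
      edges = data.frame(src = pairs[take, 1], dst = pairs[take, 2],
                         etype = etype, provenance = "sim"))
    for (fmt in c("json", "graphml")) {
      p <- file.path(dir, paste0("r.", fmt))
      exportNetwork(rnet, p, fmt)
      back <- importNetwork(p)
      expect_equal(networkNodes(back), networkNodes(rnet))
      expect_equal(networkEdges(back), networkEdges(rnet))
    }
  }
})

test_that("circuit fragments become typed network edges", {
  circ <- data.frame(
    topology = c("tf_master", "mirna_master"),
    tf_id = c("tfA", "tfB"), mirna_id = c("m1", "m2"),
    gene_id = c("g1", "g2"), comparison = c("bm", "pb"),
    stringsAsFactors = FALSE)
  net <- circuitsToNetwork(circ, tfIds = c("tfA", "tfB"))
  s <- networkSummary(net)
  expect_equal(s$n_nodes, 6L)
  # tf_master: tf_gene + tf_mirna + mirna_predicted; mirna_master: tf_gene +
  # 2x mirna_predicted
  expect_equal(unname(s$edges_by_type["tf_gene"]), 2L)
  expect_equal(unname(s$edges_by_type["tf_mirna"]), 1L)
  expect_equal(unname(s$edges_by_type["mirna_predicted"]), 3L)
  nd <- networkNodes(net)
  expect_equal(nd$kind[nd$id == "tfA"], "tf")
})
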