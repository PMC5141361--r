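# Seeded synthetic input bundles with known ground truth, plus recovery
# scoring. The generator emulates the statistical structure the pipeline
# assumes: two-class log2-normal expression with a mean shift planted along a
# designated pathway path, bivariate-normal anticorrelated miRNA-target
# pairs, and latent-driver feed-forward circuits with chosen sign patterns.

#' Synthetic-bundle generator configuration
#'
#' Defaults describe the study conditions the test suite runs under: one case
#' class and two control classes of 30 samples each (mirroring a design with
#' disease samples compared in parallel against two control tissues), 300
#' genes, 40 miRNAs, 3 pathways of 25 genes, one planted 5-node path shifted
#' by `delta` standard deviations in cases, `nPairs` miRNA-target pairs with
#' population correlation `rho`, and `nCircuits` planted circuits per
#' feed-forward topology driven by a latent factor.
#'
#' @param nPerClass named integer vector of class sizes (case first).
#' @param nGenes,nMirnas feature counts.
#' @param nPathways,pathwaySize pathway scaffold dimensions.
#' @param pathLength planted path length (nodes).
#' @param delta planted mean shift in units of `sigma` (0 disables).
#' @param rho planted miRNA-target correlation, `|rho| < 1` (0 disables).
#' @param nPairs planted anticorrelated pairs (when `rho != 0`).
#' @param nCircuits planted circuits per topology (0 disables).
#' @param sigma baseline log2 noise standard deviation.
#' @param nDecoyPredictions random prediction-table decoys, so the FDR step is
#'   exercised rather than vacuous.
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(nPerClass = c(case = 30L, ctrlA = 30L, ctrlB = 30L),
                            nGenes = 300L, nMirnas = 40L,
                            nPathways = 3L, pathwaySize = 25L,
                            pathLength = 5L, delta = 1.5, rho = -0.8,
                            nPairs = 10L, nCircuits = 2L, sigma = 1,
                            nDecoyPredictions = 200L, seed = 1L) {
  cfg <- list(nPerClass = nPerClass, nGenes = as.integer(nGenes),
              nMirnas = as.integer(nMirnas), nPathways = as.integer(nPathways),
              pathwaySize = as.integer(pathwaySize),
              pathLength = as.integer(pathLength), delta = delta, rho = rho,
              nPairs = as.integer(nPairs), nCircuits = as.integer(nCircuits),
              sigma = sigma, nDecoyPredictions = as.integer(nDecoyPredictions),
              seed = as.integer(seed))
  stopIfNot(length(cfg$nPerClass) >= 2L && all(cfg$nPerClass > 0),
            "need at least two classes with positive sizes")
  stopIfNot(abs(cfg$rho) < 1, "|rho| must be < 1")
  stopIfNot(cfg$delta >= 0, "delta must be non-negative")
  stopIfNot(cfg$pathLength < cfg$pathwaySize,
            "planted path must fit inside a pathway")
  nCircuitFeatures <- 4L * cfg$nCircuits  # one TF and one gene per circuit
  if (cfg$nPathways * cfg$pathwaySize + cfg$nPairs + nCircuitFeatures >
      cfg$nGenes) {
    stop("config plants more gene features than it generates", call. = FALSE)
  }
  if (cfg$nPairs + 2L * cfg$nCircuits + 2L > cfg$nMirnas) {
    stop("config plants more miRNA features than it generates", call. = FALSE)
  }
  cfg
}

#' Generate a complete synthetic input bundle
#'
#' @param config a [syntheticConfig()] list.
#' @return list with elements `geneExpr`, `mirnaExpr`
#'   ([ExpressionProfile-class]), `annotation` (data.frame), `pathways`
#'   (named list of [PathwayGraph-class]), `predictions`, `validated`,
#'   `catalog` (TF tables) and `truth` (planted path nodes per pathway,
#'   planted pairs, planted circuits, config echo).
#' @export
simulateBundle <- function(config = syntheticConfig()) {
  withSeed(config$seed, simulateBundleImpl(config))
}

simulateBundleImpl <- function(cfg) {
  classes <- names(cfg$nPerClass)
  sampleIds <- unlist(lapply(classes, function(cl) {
    sprintf("%s_%02d", cl, seq_len(cfg$nPerClass[[cl]]))
  }))
  condition <- rep(classes, cfg$nPerClass)
  n <- length(sampleIds)
  caseSel <- condition == classes[1]
  mutation <- rep("none", n)
  mutation[caseSel] <- sample(c("JAK2V617F", "CALR", "MPLW515", "3N"),
                              sum(caseSel), replace = TRUE,
                              prob = c(28, 7, 4, 5) / 44)
  annotation <- data.frame(sample_id = sampleIds, condition = condition,
                           mutation = mutation, stringsAsFactors = FALSE)

  geneIds <- sprintf("g%04d", seq_len(cfg$nGenes))
  mirnaIds <- sprintf("mir%03d", seq_len(cfg$nMirnas))

  # ---- baseline expression ----
  geneMu <- runif(cfg$nGenes, 4, 12)
  G <- matrix(rnorm(cfg$nGenes * n, mean = geneMu, sd = cfg$sigma),
              nrow = cfg$nGenes, ncol = n,
              dimnames = list(geneIds, sampleIds))
  # planted regulators sit in the upper expression range so the abundance
  # filter models weakly-expressed dropouts without touching planted signal
  nRegulators <- cfg$nPairs + 2L * cfg$nCircuits
  mirnaMu <- c(runif(nRegulators, 8, 12),
               runif(cfg$nMirnas - nRegulators, 4, 12))
  M <- matrix(rnorm(cfg$nMirnas * n, mean = mirnaMu, sd = cfg$sigma),
              nrow = cfg$nMirnas, ncol = n,
              dimnames = list(mirnaIds, sampleIds))

  # ---- pathway scaffolds ----
  pwIds <- sprintf("pw%d", seq_len(cfg$nPathways))
  pathways <- list()
  plantedPathNodes <- setNames(vector("list", cfg$nPathways), pwIds)
  for (i in seq_len(cfg$nPathways)) {
    members <- geneIds[((i - 1L) * cfg$pathwaySize + 1L):(i * cfg$pathwaySize)]
    hasPath <- (i == 1L) && cfg$delta > 0
    pathways[[pwIds[i]]] <- buildScaffoldPathway(pwIds[i], members,
                                                 cfg$pathLength, hasPath)
    plantedPathNodes[[pwIds[i]]] <-
      if (hasPath) members[seq_len(cfg$pathLength)] else character(0)
  }
  # plant the case-class mean shift along the designated path
  shifted <- unlist(plantedPathNodes)
  if (length(shifted)) {
    G[shifted, caseSel] <- G[shifted, caseSel] + cfg$delta * cfg$sigma
  }

  # ---- planted anticorrelated miRNA-target pairs ----
  plantedPairs <- data.frame(mirna_id = character(), gene_id = character(),
                             rho = numeric(), stringsAsFactors = FALSE)
  if (cfg$rho != 0 && cfg$nPairs > 0L) {
    pairMirnas <- mirnaIds[seq_len(cfg$nPairs)]
    # some targets inside pathway scaffolds (never on the planted path), the
    # rest outside any pathway, so augmentation is exercised both ways
    nIn <- min(4L, cfg$nPairs)
    inTargets <- vapply(seq_len(nIn), function(j) {
      pw <- ((j - 1L) %% cfg$nPathways) + 1L
      offset <- cfg$pathLength + 2L + (j - 1L) %/% cfg$nPathways
      geneIds[(pw - 1L) * cfg$pathwaySize + offset]
    }, character(1))
    outTargets <- geneIds[cfg$nPathways * cfg$pathwaySize +
                            seq_len(cfg$nPairs - nIn)]
    pairGenes <- c(inTargets, outTargets)
    for (j in seq_len(cfg$nPairs)) {
      z1 <- rnorm(n)
      z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * rnorm(n)
      M[pairMirnas[j], ] <- mirnaMu[match(pairMirnas[j], mirnaIds)] +
        cfg$sigma * z1
      G[pairGenes[j], ] <- geneMu[match(pairGenes[j], geneIds)] +
        cfg$sigma * z2
    }
    plantedPairs <- data.frame(mirna_id = pairMirnas, gene_id = pairGenes,
                               rho = cfg$rho, stringsAsFactors = FALSE)
  }

  # ---- planted feed-forward circuits (latent driver) ----
  plantedCircuits <- data.frame(topology = character(), tf_id = character(),
                                mirna_id = character(), gene_id = character(),
                                coherence = character(),
                                stringsAsFactors = FALSE)
  catalogTfMirna <- data.frame(tf_id = character(), mirna_id = character(),
                               source = character(), stringsAsFactors = FALSE)
  catalogTfGene <- data.frame(tf_id = character(),
                              target_gene_id = character(),
                              source = character(), stringsAsFactors = FALSE)
  circuitPredRows <- NULL
  if (cfg$nCircuits > 0L) {
    nCirc <- 2L * cfg$nCircuits
    tfPool <- geneIds[(cfg$nGenes - nCirc + 1L):cfg$nGenes]
    genePool <- geneIds[(cfg$nGenes - 2L * nCirc + 1L):(cfg$nGenes - nCirc)]
    mirPool <- mirnaIds[cfg$nPairs + seq_len(nCirc)]
    topologies <- rep(c("tf_master", "mirna_master"), each = cfg$nCircuits)
    # sign loadings (tf, mirna, gene) on the latent driver; alternate
    # coherent / incoherent patterns within each topology
    signTab <- list(c(1, -1, 1), c(1, 1, 1))  # tf_master: coh, incoh
    signTabMm <- list(c(1, -1, 1), c(1, 1, -1))  # mirna_master: coh, incoh
    for (k in seq_len(nCirc)) {
      topo <- topologies[k]
      s <- if (topo == "tf_master") {
        signTab[[(k - 1L) %% cfg$nCircuits %% 2L + 1L]]
      } else {
        signTabMm[[(k - 1L) %% cfg$nCircuits %% 2L + 1L]]
      }
      tf <- tfPool[k]; mir <- mirPool[k]; gene <- genePool[k]
      t <- rnorm(n)
      load <- function(sgn) (sgn * t + 0.5 * rnorm(n)) / sqrt(1.25)
      G[tf, ] <- geneMu[match(tf, geneIds)] + cfg$sigma * load(s[1])
      M[mir, ] <- mirnaMu[match(mir, mirnaIds)] + cfg$sigma * load(s[2])
      G[gene, ] <- geneMu[match(gene, geneIds)] + cfg$sigma * load(s[3])
      rTfGene <- s[1] * s[3]
      coherence <- if (topo == "tf_master") {
        if (sign(rTfGene) == -sign(s[1] * s[2])) "coherent" else "incoherent"
      } else {
        if (rTfGene > 0) "coherent" else "incoherent"
      }
      plantedCircuits <- rbind(plantedCircuits, data.frame(
        topology = topo, tf_id = tf, mirna_id = mir, gene_id = gene,
        coherence = coherence, stringsAsFactors = FALSE))
      catalogTfGene <- rbind(catalogTfGene, data.frame(
        tf_id = tf, target_gene_id = gene, source = "synthetic",
        stringsAsFactors = FALSE))
      if (topo == "tf_master") {
        catalogTfMirna <- rbind(catalogTfMirna, data.frame(
          tf_id = tf, mirna_id = mir, source = "synthetic",
          stringsAsFactors = FALSE))
        circuitPredRows <- rbind(circuitPredRows, data.frame(
          mirna_id = mir, gene_id = gene, stringsAsFactors = FALSE))
      } else {
        circuitPredRows <- rbind(circuitPredRows, data.frame(
          mirna_id = mir, gene_id = c(tf, gene), stringsAsFactors = FALSE))
      }
    }
    # decoy catalog rows keep enumeration honest
    decoyTf <- sample(geneIds[seq_len(cfg$nGenes - 2L * nCirc)], 5L)
    catalogTfGene <- rbind(catalogTfGene, data.frame(
      tf_id = rep(decoyTf, each = 2L),
      target_gene_id = sample(geneIds, 10L), source = "decoy",
      stringsAsFactors = FALSE))
    catalogTfMirna <- rbind(catalogTfMirna, data.frame(
      tf_id = decoyTf, mirna_id = sample(mirnaIds, 5L), source = "decoy",
      stringsAsFactors = FALSE))
    catalogTfGene <- catalogTfGene[
      catalogTfGene$tf_id != catalogTfGene$target_gene_id, , drop = FALSE]
    catalogTfGene <- catalogTfGene[
      !duplicated(paste(catalogTfGene$tf_id, catalogTfGene$target_gene_id)), ,
      drop = FALSE]
    catalogTfMirna <- catalogTfMirna[
      !duplicated(paste(catalogTfMirna$tf_id, catalogTfMirna$mirna_id)), ,
      drop = FALSE]
  }

  # ---- prediction table: planted pairs + circuit arms + decoys ----
  planted <- rbind(
    if (nrow(plantedPairs)) plantedPairs[, c("mirna_id", "gene_id")] else NULL,
    circuitPredRows)
  predictions <- NULL
  if (!is.null(planted) && nrow(planted)) {
    predictions <- data.frame(mirna_id = planted$mirna_id,
                              gene_id = planted$gene_id,
                              score = runif(nrow(planted), 0.8, 1),
                              stringsAsFactors = FALSE)
  }
  decoys <- data.frame(
    mirna_id = sample(mirnaIds, cfg$nDecoyPredictions, replace = TRUE),
    gene_id = sample(geneIds, cfg$nDecoyPredictions, replace = TRUE),
    score = runif(cfg$nDecoyPredictions), stringsAsFactors = FALSE)
  predictions <- rbind(predictions, decoys)
  predictions <- predictions[
    !duplicated(paste(predictions$mirna_id, predictions$gene_id)), ,
    drop = FALSE]
  rownames(predictions) <- NULL

  # ---- validated table: reporter-assay style pairs targeting pathway genes;
  # one overlaps a planted supported pair to exercise validated precedence ----
  validated <- data.frame(
    mirna_id = c(mirnaIds[cfg$nMirnas], mirnaIds[cfg$nMirnas - 1L]),
    gene_id = c(geneIds[cfg$pathLength + 4L],
                geneIds[cfg$pathwaySize + cfg$pathLength + 4L]),
    source = c("miRTarBase", "miRecords"),
    assay = "reporter", stringsAsFactors = FALSE)
  if (nrow(plantedPairs) >= 1L) {
    validated <- rbind(validated, data.frame(
      mirna_id = plantedPairs$mirna_id[1], gene_id = plantedPairs$gene_id[1],
      source = "miRTarBase", assay = "reporter", stringsAsFactors = FALSE))
  }

  geneExpr <- ExpressionProfile(G, annotation, "gene")
  mirnaExpr <- ExpressionProfile(M, annotation, "mirna")
  truth <- list(plantedPathNodes = plantedPathNodes,
                plantedPairs = plantedPairs,
                plantedCircuits = plantedCircuits,
                config = cfg)
  list(geneExpr = geneExpr, mirnaExpr = mirnaExpr, annotation = annotation,
       pathways = pathways, predictions = predictions, validated = validated,
       catalog = list(tf_mirna = catalogTfMirna, tf_gene = catalogTfGene),
       truth = truth)
}

# Random connected scaffold with, optionally, the planted chain attached as a
# pendant path so the deregulated path ends in a leaf clique.
buildScaffoldPathway <- function(pwId, members, pathLength, hasPath) {
  edges <- NULL
  if (hasPath) {
    chain <- members[seq_len(pathLength)]
    rest <- members[-seq_len(pathLength)]
    edges <- data.frame(src = chain[-length(chain)], dst = chain[-1],
                        directed = TRUE, etype = "activation",
                        provenance = pwId, stringsAsFactors = FALSE)
    # attach chain end to the scaffold root
    edges <- rbind(edges, data.frame(
      src = chain[length(chain)], dst = rest[1], directed = TRUE,
      etype = "activation", provenance = pwId, stringsAsFactors = FALSE))
  } else {
    rest <- members
  }
  # random tree over the scaffold members
  if (length(rest) > 1L) {
    for (j in 2:length(rest)) {
      parent <- rest[sample.int(j - 1L, 1L)]
      edges <- rbind(edges, data.frame(
        src = parent, dst = rest[j], directed = TRUE,
        etype = sample(c("activation", "inhibition"), 1L),
        provenance = pwId, stringsAsFactors = FALSE))
    }
  }
  # a few undirected binding edges among scaffold members
  nExtra <- max(2L, length(rest) %/% 5L)
  tries <- 0L
  added <- 0L
  existing <- paste(edges$src, edges$dst)
  while (added < nExtra && tries < 50L) {
    tries <- tries + 1L
    pair <- sample(rest, 2L)
    if (paste(pair[1], pair[2]) %in% existing ||
        paste(pair[2], pair[1]) %in% existing) next
    edges <- rbind(edges, data.frame(
      src = pair[1], dst = pair[2], directed = FALSE, etype = "binding",
      provenance = pwId, stringsAsFactors = FALSE))
    existing <- c(existing, paste(pair[1], pair[2]))
    added <- added + 1L
  }
  PathwayGraph(pwId, paste("synthetic pathway", pwId),
               nodes = data.frame(id = members, kind = "gene",
                                  stringsAsFactors = FALSE),
               edges = edges)
}

#' Write / read a synthetic bundle as a directory of plain-text files
#'
#' Files use the same TSV dialects the pipeline readers consume
#' (`gene_expr.tsv`, `mirna_expr.tsv`, `samples.tsv`, `pathways.tsv`,
#' `predicted_targets.tsv`, `validated_targets.tsv`, `tf_mirna.tsv`,
#' `tf_gene.tsv`) plus `truth.json`.
#'
#' @param bundle a [simulateBundle()] result.
#' @param dir target directory (created if needed).
#' @return `dir` invisibly (`writeBundle`); a bundle list (`readBundle`).
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeExpressionMatrix(bundle$geneExpr, fp("gene_expr.tsv"), fp("samples.tsv"))
  writeExpressionMatrix(bundle$mirnaExpr, fp("mirna_expr.tsv"))
  writePathwayEdgelist(bundle$pathways, fp("pathways.tsv"))
  write.table(bundle$predictions, fp("predicted_targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$validated, fp("validated_targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$catalog$tf_mirna, fp("tf_mirna.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$catalog$tf_gene, fp("tf_gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  geneExpr <- readExpressionMatrix(fp("gene_expr.tsv"), fp("samples.tsv"),
                                   "gene")
  mirnaExpr <- readExpressionMatrix(fp("mirna_expr.tsv"), fp("samples.tsv"),
                                    "mirna")
  truth <- jsonlite::fromJSON(fp("truth.json"), simplifyVector = TRUE)
  truth$plantedPathNodes <- lapply(truth$plantedPathNodes, as.character)
  list(geneExpr = geneExpr, mirnaExpr = mirnaExpr,
       annotation = readSampleAnnotation(fp("samples.tsv")),
       pathways = readPathwayEdgelist(fp("pathways.tsv")),
       predictions = readPredictedTargets(fp("predicted_targets.tsv")),
       validated = readValidatedTargets(fp("validated_targets.tsv")),
       catalog = readTfCatalog(fp("tf_mirna.tsv"), fp("tf_gene.tsv")),
       truth = truth)
}

#' Precision/recall of pipeline outputs against planted truth
#'
#' Standard set precision and recall per component: supported interactions
#' (miRNA-gene pairs that passed selection, unioned across comparisons),
#' meta-pathway nodes and final-path nodes (against the planted path nodes),
#' and circuits (topology + member triple). Undefined ratios (empty
#' denominator) are reported as `NA` (absent).
#'
#' @param results a [runPipeline()] result.
#' @param truth the `truth` element of the generating bundle.
#' @return data.frame with columns component, precision, recall, n_predicted,
#'   n_truth.
#' @export
evaluateRecovery <- function(results, truth) {
  pr <- function(predicted, truthSet) {
    predicted <- unique(predicted)
    truthSet <- unique(truthSet)
    hits <- length(intersect(predicted, truthSet))
    c(precision = if (length(predicted)) hits / length(predicted) else NA_real_,
      recall = if (length(truthSet)) hits / length(truthSet) else NA_real_,
      n_predicted = length(predicted), n_truth = length(truthSet))
  }
  pairKey <- function(d) if (is.null(d) || nrow(d) == 0L) character(0) else
    paste(d$mirna_id, d$gene_id)
  circKey <- function(d) if (is.null(d) || nrow(d) == 0L) character(0) else
    paste(d$topology, d$tf_id, d$mirna_id, d$gene_id)

  suppPred <- unlist(lapply(results$comparisons, function(cmp) {
    s <- cmp$supported
    pairKey(s[s$passed, , drop = FALSE])
  }))
  metaNodes <- unlist(lapply(results$comparisons, function(cmp) {
    if (is.null(cmp$meta)) character(0) else pathwayNodes(cmp$meta)$id
  }))
  finalNodes <- unlist(lapply(results$comparisons, function(cmp) {
    unlist(cmp$finalPaths$nodes)
  }))
  plantedNodes <- unlist(truth$plantedPathNodes)

  rows <- rbind(
    supported_interactions = pr(suppPred, pairKey(truth$plantedPairs)),
    meta_pathway_nodes = pr(metaNodes, plantedNodes),
    final_path_nodes = pr(finalNodes, plantedNodes),
    circuits = pr(circKey(results$circuits), circKey(truth$plantedCircuits)))
  data.frame(component = rownames(rows), rows, row.names = NULL,
             stringsAsFactors = FALSE)
}
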