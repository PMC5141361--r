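# End-to-end orchestration: filter -> integrate -> per-comparison topological
# analysis -> circuits -> link -> merge -> annotate -> export.

#' Read a pipeline configuration from YAML
#'
#' The file maps directly onto the `config` list of [runPipeline()]: an
#' `input_dir` (a bundle directory as written by [writeBundle()]), a
#' `comparisons` map of label -> {case, control}, optional `thresholds`
#' overrides, a `seed` and an optional `out_dir`.
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(path)
}

defaultThresholds <- function() {
  list(dropFraction = 0.25, entropyThreshold = 1.4, entropyBins = 10L,
       scoreMin = 0.8, rMax = -0.5, qMax = 0.1,
       pathwayQMax = 0.1, significanceRule = "either",
       topK = 10L, minAbsR = 0.5, nPerm = 1000L)
}

#' Run the full network-reconstruction pipeline
#'
#' Stages: (1) miRNA abundance/entropy filtering; (2) per comparison:
#' anticorrelation-supported target selection on that comparison's samples,
#' restriction to pathway-annotated genes, miRNA augmentation of every
#' pathway, whole-pathway permutation tests with BH adjustment, clique-level
#' tests and path scoring within significant pathways, meta-pathway
#' construction from the top paths, re-analysis with upper-quartile path
#' selection, and a per-comparison network; (3) circuit enumeration, scoring
#' and coherence classification per comparison; (4) merge of the comparison
#' networks, linking of circuits sharing at least one node, fold-change
#' annotation and export. Fully deterministic given `config$seed`; every
#' randomized stage derives its seed from it.
#'
#' @param config list with elements:
#'   * `bundle` (an in-memory [simulateBundle()]-shaped list) or `input_dir`
#'     (a bundle directory);
#'   * `comparisons`: named list, each `list(case = <condition>, control =
#'     <condition>)`;
#'   * `thresholds`: optional overrides of the defaults (dropFraction 0.25,
#'     entropyThreshold 1.4, scoreMin 0.8, rMax -0.5, qMax 0.1, pathwayQMax
#'     0.1, topK 10, minAbsR 0.5, nPerm 1000);
#'   * `seed`: integer;
#'   * `out_dir`: optional output directory.
#' @param verbose emit stage messages.
#' @return list: `comparisons` (per-label list of supported, pathwayTests,
#'   scoredPaths, meta, finalPaths, network, circuits), `network` (the merged
#'   annotated [RegulatoryNetwork-class]), `circuits`, `circuitsLinked`,
#'   `summary`, `params`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  need <- function(key) {
    if (is.null(config[[key]])) {
      stop("pipeline config is missing required key: ", key, call. = FALSE)
    }
    config[[key]]
  }
  bundle <- config$bundle
  if (is.null(bundle)) {
    bundle <- readBundle(need("input_dir"))
  }
  comparisons <- need("comparisons")
  stopIfNot(length(comparisons) >= 1L && !is.null(names(comparisons)),
            "comparisons must be a named list")
  for (label in names(comparisons)) {
    cmp <- comparisons[[label]]
    if (is.null(cmp$case) || is.null(cmp$control)) {
      stop("comparison '", label, "' is missing required key: ",
           if (is.null(cmp$case)) "case" else "control", call. = FALSE)
    }
  }
  seed <- as.integer(need("seed"))
  thr <- defaultThresholds()
  thr[names(config$thresholds %||% list())] <- config$thresholds

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage filter: miRNA abundance/entropy filtering")
  mirnaF <- stage("filter", filterExpression(
    bundle$mirnaExpr, dropFraction = thr$dropFraction,
    threshold = thr$entropyThreshold, nBins = thr$entropyBins))
  combined <- stage("filter", combineExpression(bundle$geneExpr, mirnaF))
  cond <- sampleConditions(combined)
  for (label in names(comparisons)) {
    cmp <- comparisons[[label]]
    for (cls in c(cmp$case, cmp$control)) {
      if (!cls %in% cond) {
        stop("comparison '", label, "' names unknown condition: ", cls,
             call. = FALSE)
      }
    }
  }

  tfIds <- sort(unique(c(bundle$catalog$tf_gene$tf_id,
                         bundle$catalog$tf_mirna$tf_id)))
  geneUniverse <- sort(unique(unlist(lapply(bundle$pathways, function(pw) {
    nd <- pathwayNodes(pw)
    nd$id[nd$kind == "gene"]
  }))))
  validatedUse <- bundle$validated[
    bundle$validated$mirna_id %in% featureIds(mirnaF), , drop = FALSE]
  predFiltered <- filterPredictions(bundle$predictions, thr$scoreMin)
  candidates <- stage("circuits", enumerateCandidates(
    bundle$catalog, predFiltered,
    mirnaIds = featureIds(mirnaF), geneIds = featureIds(bundle$geneExpr)))

  cmpResults <- list()
  cmpNets <- list()
  allCircuits <- NULL
  fcTables <- list()
  for (ci in seq_along(comparisons)) {
    label <- names(comparisons)[ci]
    cmp <- comparisons[[ci]]
    cmpSeed <- seed + 1009L * ci
    say("comparison '", label, "': ", cmp$case, " vs ", cmp$control)
    samples <- names(cond)[cond %in% c(cmp$case, cmp$control)]

    say("  stage integrate: anticorrelation-supported targets")
    supported <- stage("integrate", selectSupported(
      bundle$predictions, mirnaF, bundle$geneExpr,
      scoreMin = thr$scoreMin, rMax = thr$rMax, qMax = thr$qMax,
      samples = samples))
    supPass <- supported[supported$passed, , drop = FALSE]
    restricted <- restrictToPathwayGenes(supPass, geneUniverse)

    say("  stage pathways: augmentation and whole-pathway tests")
    augmented <- stage("pathways", lapply(
      bundle$pathways, augmentPathway,
      validated = validatedUse, supported = restricted))
    tests <- stage("pathways", do.call(rbind, lapply(
      seq_along(augmented), function(pi) {
        pathwayTests(combined, augmented[[pi]], cmp$case, cmp$control,
                     nPerm = thr$nPerm, seed = cmpSeed + pi)
      })))
    tests <- adjustPathwayQvalues(tests, qMax = thr$pathwayQMax,
                                  rule = thr$significanceRule)
    sig <- tests$pathway_id[tests$significant]

    meta <- NULL
    finalPaths <- NULL
    scoredPaths <- NULL
    if (length(sig) == 0L) {
      warning("comparison '", label, "': no significant pathways",
              call. = FALSE)
      netCmp <- RegulatoryNetwork()
    } else {
      say("  stage paths: clique tests and path scoring in ",
          length(sig), " significant pathway(s)")
      scoredPaths <- stage("paths", do.call(rbind, lapply(
        seq_along(sig), function(si) {
          pathwayPaths(combined, augmented[[sig[si]]], cmp$case, cmp$control,
                       nPerm = thr$nPerm, seed = cmpSeed + 103L * si)
        })))
      meta <- stage("paths", selectMetaPathway(scoredPaths, k = thr$topK,
                                               augmentedGraphs = augmented))
      finalPaths <- stage("paths", finalPathSelection(
        meta, combined, cmp$case, cmp$control,
        nPerm = thr$nPerm, seed = cmpSeed + 7L))
      netCmp <- pathsToNetwork(meta, finalPaths, label, tfIds)
    }

    say("  stage circuits: scoring ", nrow(candidates), " candidate(s)")
    circuitsCmp <- stage("circuits", scoreAndFilter(
      candidates, mirnaF, bundle$geneExpr, minAbsR = thr$minAbsR,
      samples = samples))
    if (nrow(circuitsCmp)) {
      circuitsCmp <- classifyFfl(circuitsCmp)
      circuitsCmp$comparison <- label
    } else {
      circuitsCmp$coherence <- character(0)
      circuitsCmp$comparison <- character(0)
    }

    fcTables[[label]] <- log2FoldChange(combined, cmp$case, cmp$control)
    cmpNets[[label]] <- netCmp
    allCircuits <- rbind(allCircuits, circuitsCmp)
    cmpResults[[label]] <- list(
      supported = supported, pathwayTests = tests, scoredPaths = scoredPaths,
      meta = meta, finalPaths = finalPaths, network = netCmp,
      circuits = circuitsCmp)
  }

  say("stage merge: merging ", length(cmpNets), " comparison network(s)")
  merged <- stage("merge", mergeNetworks(cmpNets))
  if (is.null(allCircuits)) {
    allCircuits <- data.frame(topology = character(), tf_id = character(),
                              mirna_id = character(), gene_id = character(),
                              stringsAsFactors = FALSE)
  }
  linked <- stage("merge", linkToNetwork(allCircuits, merged))
  full <- merged
  if (nrow(linked)) {
    full <- stage("merge", mergeNetworks(list(
      merged, circuitsToNetwork(linked, tfIds))))
  }
  full <- stage("annotate", annotateFoldChanges(full, fcTables))
  summary <- networkSummary(full)

  params <- list(seed = seed, thresholds = thr,
                 comparisons = comparisons)
  result <- list(comparisons = cmpResults, network = full,
                 circuits = allCircuits, circuitsLinked = linked,
                 summary = summary, params = params)
  if (!is.null(config$out_dir)) {
    say("stage export: writing artifacts to ", config$out_dir)
    stage("export", writePipelineOutputs(result, config$out_dir))
  }
  result
}

# Serialize the result bundle; all JSON is written deterministically (no
# timestamps), so reruns with the same seed are byte-identical.
writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  exportNetwork(result$network, fp("network.json"), "json")
  exportNetwork(result$network, fp("network.graphml"), "graphml")
  exportNetwork(result$network, fp("network.sif"), "sif")
  jsonlite::write_json(result$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(result$params, fp("params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  circuitCols <- c("topology", "tf_id", "mirna_id", "gene_id", "r_tf_mirna",
                   "r_tf_gene", "r_mirna_gene", "coherence", "comparison")
  circ <- result$circuits
  write.table(circ[, intersect(circuitCols, names(circ)), drop = FALSE],
              fp("circuits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (label in names(result$comparisons)) {
    cmp <- result$comparisons[[label]]
    write.table(cmp$supported, fp(sprintf("supported_%s.tsv", label)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cmp$pathwayTests, fp(sprintf("pathway_tests_%s.tsv", label)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- cmp$finalPaths
    if (!is.null(paths)) {
      jsonlite::write_json(
        list(paths = data.frame(pathway_id = paths$pathway_id,
                                path = paths$path, score = paths$score,
                                n_cliques = paths$n_cliques),
             nodes = paths$nodes),
        fp(sprintf("final_paths_%s.json", label)),
        dataframe = "columns", digits = NA, pretty = TRUE)
    }
  }
  invisible(dir)
}
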