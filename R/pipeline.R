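#' Read a plain-text run configuration
#'
#' One \code{key = value} pair per line; '#' starts a comment. Values are
#' kept as strings; numeric keys are coerced by [runPipeline()]. Referenced
#' files are checked for existence at validation time, before any stage
#' runs.
#'
#' @param path configuration file path.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  cfg <- lapply(kv, function(x) trimws(x[3L]))
  names(cfg) <- vapply(kv, function(x) trimws(x[2L]), "")
  attr(cfg, "dir") <- dirname(normalizePath(path))
  cfg
}

.cfgNum <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}
.cfgStr <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the multi-omics network-enrichment analysis in memory
#'
#' Executes the full stage chain on already-loaded objects: differential
#' abundance per layer (Welch surrogate on log2(x + pseudocount)),
#' preranked GSEA on the transcript ranking, metabolite ORA with Jaccard
#' clustering of enriched pathways, prize assignment with hub penalty and
#' confidence-derived edge costs, PCSF solving, and community
#' decomposition with prize-density ranking.
#'
#' Protein fold changes are computed on spectral counts: the per-protein
#' length factor of NSAF cancels inside a within-protein fold change, so
#' NSAF is produced as the normalized quantification output while DE runs
#' on counts where the unit pseudocount is meaningful.
#'
#' @param network global [InteractionNetwork-class].
#' @param omics named list with transcript / protein / metabolite
#'   [OmicsMatrix-class] entries (protein and metabolite may be NULL).
#' @param pathways a [GeneSetCollection-class].
#' @param tx2gene optional transcript-to-gene map applied to the
#'   transcript layer before DE.
#' @param pseudocount,alpha,minAbsLfc differential-abundance settings.
#' @param gseaNPerm,gseaMinSize,gseaMaxSize,weightExponent GSEA settings;
#'   set \code{gseaNPerm = 0} to skip the GSEA stage.
#' @param jaccardThreshold pathway-cluster similarity threshold.
#' @param pcsf a [pcsfConfig()].
#' @param fdrCutoff strict FDR filter for subnetwork ranking.
#' @param communityMethod "greedy" or "louvain".
#' @param seed master seed for the stochastic stages.
#' @return list with stats (per-layer and combined), nsaf, gsea,
#'   metaboliteOra, pathwayClusters, network (prized), solution,
#'   subnetworks.
#' @export
runStudyAnalysis <- function(network, omics, pathways, tx2gene = NULL,
                             pseudocount = 1, alpha = 0.05, minAbsLfc = 1,
                             gseaNPerm = 1000L, gseaMinSize = 5L,
                             gseaMaxSize = 500L, weightExponent = 1,
                             jaccardThreshold = 0.5,
                             pcsf = pcsfConfig(), fdrCutoff = 0.05,
                             communityMethod = "greedy", seed = 1L) {
  tr <- omics$transcript
  if (!is.null(tx2gene)) tr <- geneTpmFromTranscripts(tr, tx2gene)
  stats <- list(transcript = diffAbundance(tr, pseudocount, alpha,
                                           minAbsLfc))
  nsaf <- NULL
  if (!is.null(omics$protein)) {
    stats$protein <- diffAbundance(omics$protein, pseudocount, alpha,
                                   minAbsLfc)
    if (!is.null(proteinLengths(omics$protein)))
      nsaf <- nsafNormalize(omics$protein)
  }
  if (!is.null(omics$metabolite))
    stats$metabolite <- diffAbundance(omics$metabolite, pseudocount,
                                      alpha, minAbsLfc)
  combined <- do.call(rbind, stats)
  rownames(combined) <- NULL

  gsea <- NULL
  if (gseaNPerm >= 100L) {
    ranked <- rankFeatures(stats$transcript)
    gsea <- tryCatch(
      gseaPreranked(ranked, pathways, nPerm = gseaNPerm,
                    seed = seed, minSize = gseaMinSize,
                    maxSize = gseaMaxSize,
                    weightExponent = weightExponent),
      error = function(e) NULL)      # no set within size bounds
  }

  metaboliteOra <- NULL
  pathwayClusters <- NULL
  if (!is.null(stats$metabolite)) {
    ms <- stats$metabolite
    universe <- ms$feature_id
    sig <- ms$feature_id[ms$significant]
    sets <- geneSets(pathways)
    rows <- lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], universe)
      if (!length(members)) return(NULL)
      r <- oraHypergeometric(sig, universe, members)
      data.frame(set_name = nm, overlap = r$overlap,
                 p_value = r$p_value,
                 sig_members = paste(sort(intersect(sig, members)),
                                     collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    metaboliteOra <- do.call(rbind, rows)
    if (!is.null(metaboliteOra) && nrow(metaboliteOra)) {
      metaboliteOra$fdr <- bhAdjust(metaboliteOra$p_value)
      enriched <- metaboliteOra[metaboliteOra$fdr < 0.05 &
                                  metaboliteOra$overlap > 0, ]
      sigMembers <- lapply(strsplit(enriched$sig_members, ";",
                                    fixed = TRUE),
                           function(x) x[nzchar(x)])
      names(sigMembers) <- enriched$set_name
      pathwayClusters <- clusterEnrichedPathways(sigMembers,
                                                 jaccardThreshold)
    }
  }

  prized <- assignPrizes(network, combined)
  prized <- applyHubPenalty(prized, pcsf@mu)
  prized <- edgeCostsFromConfidence(prized)
  solution <- solvePCSF(prized, pcsf)
  subnetworks <- if (length(selectedNodes(solution))) {
    analyzeSubnetworks(prized, solution, pathways,
                       fdrCutoff = fdrCutoff,
                       method = communityMethod, seed = seed)
  } else NULL

  list(stats = stats, combined = combined, nsaf = nsaf, gsea = gsea,
       metaboliteOra = metaboliteOra, pathwayClusters = pathwayClusters,
       network = prized, solution = solution, subnetworks = subnetworks)
}

#' Fraction of planted module nodes recovered by the top-ranked subnetworks
#'
#' @param truth a [SyntheticTruth-class].
#' @param subnetworks result component of [runStudyAnalysis()] (or
#'   [analyzeSubnetworks()] output).
#' @param topK number of top-ranked subnetworks to pool.
#' @return recall in [0, 1].
#' @export
plantedRecall <- function(truth, subnetworks, topK = 3L) {
  planted <- unlist(plantedModules(truth), use.names = FALSE)
  if (is.null(subnetworks)) return(0)
  s <- subnetworks$summary
  top <- s$subnetwork_id[!is.na(s$rank) & s$rank <= topK]
  got <- unlist(subnetworks$members[as.character(top)], use.names = FALSE)
  length(intersect(planted, got)) / length(planted)
}

#' Run the pipeline from a configuration file and write all outputs
#'
#' Reads the omics matrices, maps, network and pathway files named in the
#' config, validates them before any stage runs, executes the stage chain
#' of [runStudyAnalysis()], and writes per-stage TSVs, GraphML exports and
#' a JSON run manifest into the output directory. Identical config and
#' seed produce byte-identical outputs.
#'
#' Recognized keys (paths): transcript_matrix, protein_matrix,
#' metabolite_matrix, condition_map, tx2gene, protein_lengths, edge_list,
#' node_types, gmt. Settings: pseudocount, alpha, min_abs_lfc,
#' gsea_n_perm, gsea_min_size, gsea_max_size, weight_exponent,
#' jaccard_threshold, beta, omega, mu, fdr_cutoff, community_method,
#' seed, out_dir.
#'
#' @param config path to a config file (see [readRunConfig()]) or an
#'   equivalent named list.
#' @param outDir output directory (overrides the config's out_dir).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- if (!is.null(outDir)) outDir
            else .cfgStr(config, "out_dir", "pipeline_out")
  pathKeys <- c("transcript_matrix", "protein_matrix",
                "metabolite_matrix", "condition_map", "tx2gene",
                "protein_lengths", "edge_list", "node_types", "gmt")
  cfgDir <- attr(config, "dir")
  for (key in pathKeys) {
    p <- .cfgStr(config, key)
    if (is.null(p)) next
    # relative paths resolve against the config file's directory
    if (!file.exists(p) && !is.null(cfgDir) &&
          file.exists(file.path(cfgDir, p)))
      config[[key]] <- p <- file.path(cfgDir, p)
    if (!file.exists(p))
      stop("config error: file for '", key, "' not found: ", p)
  }
  for (key in c("transcript_matrix", "condition_map", "edge_list",
                "node_types", "gmt"))
    if (is.null(config[[key]]))
      stop("config error: required key '", key, "' missing")

  condMap <- read.delim(config$condition_map, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  omics <- list(
    transcript = readOmicsMatrix(config$transcript_matrix, "transcript",
                                 condMap))
  if (!is.null(config$protein_matrix)) {
    lens <- NULL
    if (!is.null(config$protein_lengths)) {
      lt <- read.delim(config$protein_lengths, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
      lens <- setNames(as.numeric(lt[[2L]]), lt[[1L]])
    }
    omics$protein <- readOmicsMatrix(config$protein_matrix, "protein",
                                     condMap, proteinLengths = lens)
  }
  if (!is.null(config$metabolite_matrix))
    omics$metabolite <- readOmicsMatrix(config$metabolite_matrix,
                                        "metabolite", condMap)
  tx2gene <- NULL
  if (!is.null(config$tx2gene)) {
    tg <- read.delim(config$tx2gene, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    tx2gene <- setNames(as.character(tg[[2L]]), as.character(tg[[1L]]))
  }
  network <- readEdgeList(config$edge_list, config$node_types)
  pathways <- readGMT(config$gmt)
  seed <- as.integer(.cfgNum(config, "seed", 1))
  pcsf <- pcsfConfig(beta = .cfgNum(config, "beta", 1),
                     omega = .cfgNum(config, "omega", 2),
                     mu = .cfgNum(config, "mu", 0.01),
                     seed = seed)

  res <- runStudyAnalysis(
    network, omics, pathways, tx2gene = tx2gene,
    pseudocount = .cfgNum(config, "pseudocount", 1),
    alpha = .cfgNum(config, "alpha", 0.05),
    minAbsLfc = .cfgNum(config, "min_abs_lfc", 1),
    gseaNPerm = as.integer(.cfgNum(config, "gsea_n_perm", 1000)),
    gseaMinSize = as.integer(.cfgNum(config, "gsea_min_size", 5)),
    gseaMaxSize = as.integer(.cfgNum(config, "gsea_max_size", 500)),
    weightExponent = .cfgNum(config, "weight_exponent", 1),
    jaccardThreshold = .cfgNum(config, "jaccard_threshold", 0.5),
    pcsf = pcsf,
    fdrCutoff = .cfgNum(config, "fdr_cutoff", 0.05),
    communityMethod = .cfgStr(config, "community_method", "greedy"),
    seed = seed)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) writeFeatureStats(x, file.path(outDir, f))
  stageRows <- list()
  for (layer in names(res$stats)) {
    tsv(res$stats[[layer]], paste0("de_", layer, ".tsv"))
    stageRows[[paste0("de_", layer)]] <- nrow(res$stats[[layer]])
  }
  if (!is.null(res$nsaf))
    writeOmicsMatrix(res$nsaf, file.path(outDir, "nsaf.tsv"))
  if (!is.null(res$gsea)) {
    tsv(res$gsea, "gsea.tsv")
    stageRows$gsea <- nrow(res$gsea)
  }
  if (!is.null(res$metaboliteOra)) {
    tsv(res$metaboliteOra, "metabolite_ora.tsv")
    stageRows$metabolite_ora <- nrow(res$metaboliteOra)
  }
  if (!is.null(res$pathwayClusters)) {
    cl <- res$pathwayClusters
    assign <- rbind(
      if (length(cl$clusters))
        do.call(rbind, lapply(seq_along(cl$clusters), function(i)
          data.frame(set_name = cl$clusters[[i]], cluster_id = i,
                     stringsAsFactors = FALSE)))
      else NULL,
      if (length(cl$unassigned))
        data.frame(set_name = cl$unassigned, cluster_id = NA_integer_,
                   stringsAsFactors = FALSE)
      else NULL)
    if (!is.null(assign)) tsv(assign, "pathway_clusters.tsv")
  }
  writeNetworkGraphML(res$network, file.path(outDir, "network.graphml"))
  writeNetworkGraphML(res$network, file.path(outDir, "solution.graphml"),
                      solution = res$solution)
  tsv(selectedEdges(res$solution), "solution_edges.tsv")
  if (!is.null(res$subnetworks)) {
    tsv(res$subnetworks$summary, "subnetworks.tsv")
    stageRows$subnetworks <- nrow(res$subnetworks$summary)
    g <- networkGraph(res$network)
    for (i in seq_along(res$subnetworks$members)) {
      sub <- new("InteractionNetwork",
                 graph = igraph::induced_subgraph(
                   g, res$subnetworks$members[[i]]))
      writeNetworkGraphML(sub, file.path(
        outDir, sprintf("subnetwork_%03d.graphml", i)))
    }
  }
  manifest <- list(
    package = "OmicsForest",
    version = as.character(utils::packageVersion("OmicsForest")),
    config = config[order(names(config))],
    seed = seed,
    stages = c("omics_io", "diff_abundance", "enrichment",
               "global_network", "pcsf_solver", "subnetwork_analysis"),
    rows = stageRows,
    solution = list(n_nodes = length(selectedNodes(res$solution)),
                    n_edges = nrow(selectedEdges(res$solution)),
                    kappa = treeCount(res$solution),
                    objective = solutionObjective(res$solution),
                    n_steiner = length(steinerNodes(res$solution))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
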