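#' Simulate a scale-free gene network with attached metabolites
#'
#' Genes form a preferential-attachment (Barabasi-Albert) graph: each new
#' gene attaches to \code{attachM} existing genes chosen with probability
#' proportional to degree (the first few genes attach to all precursors),
#' so the gene graph is connected with exactly
#' (nGenes - attachM) * attachM + choose(attachM, 2) edges; with
#' attachM = 2 that is (nGenes - 2) * 2 + 1. Each metabolite then
#' attaches to 1-3 uniformly chosen genes. Edge confidences are
#' U(0.5, 1). Deterministic given \code{seed}.
#'
#' @param nGenes number of gene nodes (> attachM).
#' @param nMetabolites number of metabolite nodes (>= 0).
#' @param attachM edges added per new gene.
#' @param seed integer seed.
#' @return an [InteractionNetwork-class] (prizes 0, measured FALSE).
#' @export
simulateGlobalNetwork <- function(nGenes = 500L, nMetabolites = 50L,
                                  attachM = 2L, seed = 1L) {
  stopifnot(nGenes >= attachM + 1L, nMetabolites >= 0L, attachM >= 1L)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  deg <- integer(nGenes)
  eu <- character(0); ev <- character(0)
  for (i in 2:nGenes) {
    m <- min(attachM, i - 1L)         # early nodes attach to all precursors
    targets <- if (m == i - 1L) seq_len(m)
               else sample.int(i - 1L, m, replace = FALSE,
                               prob = deg[seq_len(i - 1L)])
    eu <- c(eu, rep(genes[i], m)); ev <- c(ev, genes[targets])
    deg[i] <- m; deg[targets] <- deg[targets] + 1L
  }
  nodes <- data.frame(node_id = genes, node_type = "gene",
                      stringsAsFactors = FALSE)
  if (nMetabolites > 0L) {
    mets <- sprintf("M%03d", seq_len(nMetabolites))
    for (m in mets) {
      k <- sample.int(3L, 1L)
      tg <- sample(genes, k)
      eu <- c(eu, rep(m, k)); ev <- c(ev, tg)
    }
    nodes <- rbind(nodes, data.frame(node_id = mets,
                                     node_type = "metabolite",
                                     stringsAsFactors = FALSE))
  }
  interactionNetwork(nodes,
                     data.frame(u = eu, v = ev,
                                confidence = runif(length(eu), 0.5, 1),
                                stringsAsFactors = FALSE))
}

#' Plant perturbed connected modules and draw true fold changes
#'
#' Grows \code{k} disjoint connected node sets by seeded breadth-first
#' expansion from random start nodes. Module nodes receive true log2 fold
#' changes ~ N(signalMean, signalSd) with a random sign per module;
#' all remaining (background) nodes receive N(0, noiseSd).
#'
#' @param net an [InteractionNetwork-class].
#' @param k number of modules.
#' @param moduleSize nodes per module (k * moduleSize <= network size).
#' @param signalMean mean |log2FC| planted in modules.
#' @param signalSd sd of the planted signal.
#' @param noiseSd sd of background log2FC noise.
#' @param seed integer seed.
#' @return a [SyntheticTruth-class].
#' @export
plantModules <- function(net, k = 3L, moduleSize = 15L, signalMean = 2,
                         signalSd = 0.25, noiseSd = 0.3, seed = 1L) {
  g <- net@graph
  nm <- igraph::V(g)$name
  stopifnot(k * moduleSize <= length(nm))
  set.seed(seed)
  used <- character(0)
  modules <- vector("list", k)
  for (mi in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      start <- sample(setdiff(nm, used), 1L)
      members <- start
      frontier <- start
      while (length(members) < moduleSize) {
        nbrs <- setdiff(
          unique(unlist(igraph::adjacent_vertices(g, frontier))), NULL)
        nbrs <- setdiff(nm[nbrs], c(members, used))
        if (!length(nbrs)) break
        take <- sample(nbrs, min(length(nbrs),
                                 moduleSize - length(members)))
        members <- c(members, take)
        frontier <- take
      }
      if (length(members) == moduleSize) {
        modules[[mi]] <- sort(members)
        used <- c(used, members)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", k, " disjoint connected modules of size ",
           moduleSize)
  }
  lfc <- rnorm(length(nm), 0, noiseSd)
  names(lfc) <- nm
  for (mi in seq_len(k)) {
    sgn <- sample(c(-1, 1), 1L)
    lfc[modules[[mi]]] <- sgn * rnorm(moduleSize, signalMean, signalSd)
  }
  new("SyntheticTruth", plantedModules = modules, trueLog2fc = lfc,
      moduleSignalMean = as.numeric(signalMean),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Simulate the three omics layers from a planted truth
#'
#' Transcript counts are negative binomial with mean
#' base * 2^(lfc * [KO]) and dispersion \code{phi}, then scaled per
#' sample to transcripts-per-million. Protein spectral counts are Poisson
#' with a layer-specific base mean, measured for a random fraction of
#' genes (mirroring the much smaller coverage of shotgun proteomes).
#' Metabolite intensities are log-normal with the planted fold change on
#' the log2 scale. Three replicates per condition by default; bit-wise
#' deterministic given \code{seed}.
#'
#' @param truth a [SyntheticTruth-class].
#' @param net the [InteractionNetwork-class] the truth was planted in.
#' @param nReps replicates per condition (>= 2).
#' @param phi negative-binomial dispersion of transcript counts.
#' @param baseLogMean,baseLogSd log-normal parameters of base expression
#'   in count space.
#' @param proteinFraction fraction of genes measured at the protein level.
#' @param proteinBaseMean mean spectral count of an unperturbed protein.
#' @param metaboliteSigma log-scale noise sd of metabolite intensities.
#' @param seed integer seed.
#' @return list with elements \code{transcript}, \code{protein},
#'   \code{metabolite} ([OmicsMatrix-class] each).
#' @export
simulateOmics <- function(truth, net, nReps = 3L, phi = 0.1,
                          baseLogMean = 5, baseLogSd = 1.5,
                          proteinFraction = 0.4, proteinBaseMean = 20,
                          metaboliteSigma = 0.25, seed = 1L) {
  stopifnot(nReps >= 2L)
  set.seed(seed)
  nt <- nodeTable(net)
  genes <- nt$node_id[nt$node_type == "gene"]
  mets <- nt$node_id[nt$node_type == "metabolite"]
  lfc <- trueLog2fc(truth)
  samples <- c(sprintf("WT_%d", seq_len(nReps)),
               sprintf("KO_%d", seq_len(nReps)))
  cond <- setNames(rep(c("WT", "KO"), each = nReps), samples)
  isKO <- cond == "KO"

  base <- rlnorm(length(genes), baseLogMean, baseLogSd)
  mu <- outer(base, rep(1, 2 * nReps)) *
    2^(outer(lfc[genes], as.numeric(isKO)))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  tpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  transcript <- OmicsMatrix(tpm, "transcript", cond)

  nProt <- max(2L, round(proteinFraction * length(genes)))
  protGenes <- sort(sample(genes, nProt))
  muP <- proteinBaseMean * 2^(outer(lfc[protGenes], as.numeric(isKO)))
  spc <- matrix(rpois(length(muP), muP), nrow = nProt,
                dimnames = list(protGenes, samples))
  lens <- setNames(sample(100:1000, nProt, replace = TRUE), protGenes)
  protein <- OmicsMatrix(spc, "protein", cond, proteinLengths = lens)

  metabolite <- NULL
  if (length(mets)) {
    baseM <- rlnorm(length(mets), 8, 1)
    muM <- log(baseM) + outer(lfc[mets], as.numeric(isKO)) * log(2)
    inten <- matrix(rlnorm(length(muM), muM, metaboliteSigma),
                    nrow = length(mets),
                    dimnames = list(mets, samples))
    metabolite <- OmicsMatrix(inten, "metabolite", cond)
  }
  list(transcript = transcript, protein = protein,
       metabolite = metabolite)
}

#' Synthetic pathway collection for a planted truth
#'
#' Each planted module contributes a "true" pathway (its members; gene
#' and metabolite ids are both kept so the collection serves both geneset
#' ORA and metabolite ORA, each of which intersects members with its own
#' universe); decoy sets of matched size are drawn from all nodes.
#'
#' @param truth a [SyntheticTruth-class].
#' @param net the network the truth was planted in.
#' @param nDecoys number of decoy sets.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
syntheticPathways <- function(truth, net, nDecoys = 20L, seed = 1L) {
  set.seed(seed)
  nt <- nodeTable(net)
  mods <- plantedModules(truth)
  sets <- lapply(mods, sort)
  names(sets) <- sprintf("module_%02d", seq_along(sets))
  size <- max(lengths(sets))
  for (d in seq_len(nDecoys)) {
    sets[[sprintf("decoy_%02d", d)]] <- sort(sample(nt$node_id, size))
  }
  GeneSetCollection(sets)
}

#' Generate a complete synthetic multi-omics study
#'
#' One call producing the global network, the planted truth, the three
#' omics layers and a matching pathway collection — everything the
#' pipeline consumes, plus ground truth to validate against.
#'
#' @param nGenes,nMetabolites,attachM network size parameters
#'   (see [simulateGlobalNetwork()]).
#' @param k,moduleSize,signalMean,signalSd,noiseSd planted-module
#'   parameters (see [plantModules()]).
#' @param nReps replicates per condition.
#' @param nDecoys decoy pathway count.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param ... further arguments passed to [simulateOmics()].
#' @return list with network, truth, omics (list of OmicsMatrix),
#'   pathways, seed.
#' @export
simulateStudy <- function(nGenes = 500L, nMetabolites = 50L, attachM = 2L,
                          k = 3L, moduleSize = 15L, signalMean = 2,
                          signalSd = 0.25, noiseSd = 0.3, nReps = 3L,
                          nDecoys = 20L, seed = 1L, ...) {
  seed <- as.integer(seed)
  net <- simulateGlobalNetwork(nGenes, nMetabolites, attachM,
                               seed = seed)
  truth <- plantModules(net, k, moduleSize, signalMean, signalSd, noiseSd,
                        seed = seed + 1000L)
  omics <- simulateOmics(truth, net, nReps = nReps, seed = seed + 2000L,
                         ...)
  pathways <- syntheticPathways(truth, net, nDecoys = nDecoys,
                                seed = seed + 3000L)
  list(network = net, truth = truth, omics = omics, pathways = pathways,
       seed = seed)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits the TSV matrices, condition map, edge list, node types, GMT
#' pathway collection and a truth.json (modules, true log2FC, seed) into
#' \code{dir}, plus a ready-to-run pipeline config file.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return path to the generated config file, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeOmicsMatrix(study$omics$transcript, p("transcript.tsv"))
  writeOmicsMatrix(study$omics$protein, p("protein.tsv"))
  if (!is.null(study$omics$metabolite))
    writeOmicsMatrix(study$omics$metabolite, p("metabolite.tsv"))
  cond <- conditionLabels(study$omics$transcript)
  write.table(data.frame(sample_id = names(cond), condition = cond),
              p("condition_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lens <- proteinLengths(study$omics$protein)
  write.table(data.frame(protein_id = names(lens), length = lens),
              p("protein_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ed <- edgeTable(study$network)
  write.table(data.frame(node_u = ed$u, node_v = ed$v,
                         confidence = ed$confidence),
              p("edge_list.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nt <- nodeTable(study$network)
  write.table(nt[, c("node_id", "node_type")], p("node_types.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(study$pathways, p("pathways.gmt"))
  jsonlite::write_json(
    list(seed = study$seed,
         planted_modules = plantedModules(study$truth),
         true_log2fc = as.list(trueLog2fc(study$truth)),
         module_signal_mean = study$truth@moduleSignalMean,
         noise_sd = study$truth@noiseSd),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  # paths are relative to the config file, so the directory is portable
  cfgLines <- c(
    "transcript_matrix = transcript.tsv",
    "protein_matrix = protein.tsv",
    if (!is.null(study$omics$metabolite))
      "metabolite_matrix = metabolite.tsv",
    "condition_map = condition_map.tsv",
    "protein_lengths = protein_lengths.tsv",
    "edge_list = edge_list.tsv",
    "node_types = node_types.tsv",
    "gmt = pathways.gmt",
    paste0("seed = ", study$seed))
  writeLines(cfgLines, p("config.txt"))
  invisible(p("config.txt"))
}
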