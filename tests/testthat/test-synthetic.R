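test_that("the simulated network has the prescribed shape", {
  net <- simulateGlobalNetwork(nGenes = 100, nMetabolites = 0,
                               attachM = 2, seed = 9)
  expect_identical(nrow(edgeTable(net)), (100L - 2L) * 2L + 1L)
  nt <- nodeTable(net)
  expect_true(all(nt$node_type == "gene"))
  expect_equal(as.integer(igraph::components(networkGraph(net))$no), 1L)

  withMet <- simulateGlobalNetwork(nGenes = 100, nMetabolites = 10,
                                   attachM = 2, seed = 9)
  nt2 <- nodeTable(withMet)
  mdeg <- nt2$degree[nt2$node_type == "metabolite"]
  expect_identical(sum(nt2$node_type == "metabolite"), 10L)
  expect_true(all(mdeg >= 1 & mdeg <= 3))
  conf <- edgeTable(withMet)$confidence
  expect_true(all(conf >= 0.5 & conf <= 1))

  # determinism
  a <- simulateGlobalNetwork(50, 5, seed = 31)
  b <- simulateGlobalNetwork(50, 5, seed = 31)
  expect_identical(edgeTable(a), edgeTable(b))
  expect_error(simulateGlobalNetwork(nGenes = 2, attachM = 2), "nGenes")
})

test_that("planted modules are disjoint, connected, and carry the signal", {
  net <- simulateGlobalNetwork(nGenes = 1500, nMetabolites = 100,
                               seed = 14)
  truth <- plantModules(net, k = 3, moduleSize = 50, signalMean = 2,
                        signalSd = 0.25, noiseSd = 0.3, seed = 14)
  mods <- plantedModules(truth)
  expect_identical(lengths(mods), rep(50L, 3))
  expect_identical(anyDuplicated(unlist(mods)), 0L)
  g <- networkGraph(net)
  for (m in mods)
    expect_equal(as.integer(
      igraph::components(igraph::induced_subgraph(g, m))$no), 1L)

  lfc <- trueLog2fc(truth)
  inMod <- names(lfc) %in% unlist(mods)
  expect_equal(mean(abs(lfc[inMod])), 2, tolerance = 0.1)
  # background |lfc| has half-normal mean sd * sqrt(2 / pi)
  expect_equal(mean(abs(lfc[!inMod])), 0.3 * sqrt(2 / pi),
               tolerance = 0.03)

  single <- plantModules(net, k = 1, moduleSize = 1, seed = 2)
  expect_identical(lengths(plantedModules(single)), 1L)
})

test_that("omics simulation is seeded and centers on the planted truth", {
  net <- simulateGlobalNetwork(nGenes = 120, nMetabolites = 12, seed = 5)
  truth <- plantModules(net, k = 2, moduleSize = 10, seed = 5)
  a <- simulateOmics(truth, net, seed = 8)
  b <- simulateOmics(truth, net, seed = 8)
  expect_identical(SummarizedExperiment::assay(a$transcript),
                   SummarizedExperiment::assay(b$transcript))
  expect_identical(SummarizedExperiment::assay(a$protein),
                   SummarizedExperiment::assay(b$protein))
  expect_identical(SummarizedExperiment::assay(a$metabolite),
                   SummarizedExperiment::assay(b$metabolite))

  # null truth: estimated fold changes center on zero
  nullTruth <- plantModules(net, k = 1, moduleSize = 1, signalMean = 0,
                            signalSd = 0, noiseSd = 0, seed = 5)
  om <- simulateOmics(nullTruth, net, nReps = 10, seed = 3)
  est <- computeLog2FC(om$transcript)
  expect_lt(abs(mean(est)), 0.05)

  # consistency: well-expressed features with true lfc 2 are recovered
  # within 0.2 at high replication (after removing the global shift that
  # TPM renormalization spreads across all genes)
  big <- simulateGlobalNetwork(nGenes = 600, nMetabolites = 0, seed = 5)
  truth2 <- plantModules(big, k = 1, moduleSize = 10, signalMean = 2,
                         signalSd = 1e-6, noiseSd = 0, seed = 6)
  om2 <- simulateOmics(truth2, big, nReps = 50, phi = 0.01,
                       baseLogMean = 7, baseLogSd = 0.5, seed = 7)
  est2 <- computeLog2FC(om2$transcript)
  mod <- plantedModules(truth2)[[1]]
  shift <- mean(est2[setdiff(names(est2), mod)])
  expect_true(all(abs(abs(est2[mod] - shift) - 2) < 0.2))
})

test_that("fold-change estimates become unbiased as replication grows", {
  net <- simulateGlobalNetwork(nGenes = 600, nMetabolites = 0, seed = 44)
  truth <- plantModules(net, k = 3, moduleSize = 8, signalMean = 2,
                        seed = 44)
  mod <- unlist(plantedModules(truth))
  bias <- vapply(c(3, 10, 50), function(nr) {
    om <- simulateOmics(truth, net, nReps = nr, seed = 90 + nr)
    est <- computeLog2FC(om$transcript)
    mean(abs(est[mod] - trueLog2fc(truth)[mod]))
  }, 0)
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.15)
})

test_that("the synthetic pathway collection pairs modules with decoys", {
  study <- simulateStudy(nGenes = 100, nMetabolites = 10, k = 2,
                         moduleSize = 8, nDecoys = 6, seed = 2)
  sets <- geneSets(study$pathways)
  expect_identical(sum(startsWith(names(sets), "module_")), 2L)
  expect_identical(sum(startsWith(names(sets), "decoy_")), 6L)
  expect_setequal(sets$module_01, plantedModules(study$truth)[[1]])
  expect_true(all(lengths(sets[startsWith(names(sets), "decoy_")]) == 8L))
})

test_that("a study written to disk reloads into the same analysis inputs", {
  study <- simulateStudy(nGenes = 60, nMetabolites = 6, k = 1,
                         moduleSize = 5, nDecoys = 4, seed = 10)
  dir <- withr::local_tempdir()
  cfgPath <- writeStudy(study, dir)
  expect_true(file.exists(cfgPath))
  cfg <- readRunConfig(cfgPath)
  inDir <- function(f) file.path(dir, f)
  m <- readOmicsMatrix(inDir(cfg$transcript_matrix), "transcript",
                       read.delim(inDir(cfg$condition_map)))
  expect_equal(SummarizedExperiment::assay(m),
               SummarizedExperiment::assay(study$omics$transcript),
               tolerance = 1e-12)
  net <- readEdgeList(inDir(cfg$edge_list), inDir(cfg$node_types))
  expect_identical(nrow(nodeTable(net)), nrow(nodeTable(study$network)))
  expect_identical(nrow(edgeTable(net)), nrow(edgeTable(study$network)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$seed, 10L)
})
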