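#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats p.adjust phyper pt rnorm rnbinom rpois rlnorm runif setNames
#' @importFrom utils read.delim write.table combn head
NULL

.LAYERS <- c("transcript", "protein", "metabolite")
.CONDITIONS <- c("WT", "KO")

#' OmicsMatrix: one omics layer as a SummarizedExperiment
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' feature-by-sample abundance matrix for one omics layer (transcript-level
#' or gene-level TPM, protein spectral counts, or metabolite intensities),
#' the WT/KO condition of every sample in \code{colData(x)$condition}, and,
#' for the protein layer, amino-acid lengths in
#' \code{rowData(x)$protein_length}.
#'
#' @slot layer single string, one of \code{"transcript"}, \code{"protein"},
#'   \code{"metabolite"}.
#'
#' @seealso [OmicsMatrix()] for the constructor, [nsafNormalize()],
#'   [geneTpmFromTranscripts()].
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(layer = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of %s",
                          paste(.LAYERS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!all(is.finite(v)) || any(v < 0))
    msg <- c(msg, "abundance values must be finite and non-negative")
  cond <- SummarizedExperiment::colData(object)$condition
  if (is.null(cond) || !all(cond %in% .CONDITIONS))
    msg <- c(msg, "colData(x)$condition must assign WT or KO to every sample")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids); all entries finite and non-negative.
#' @param layer one of \code{"transcript"}, \code{"protein"},
#'   \code{"metabolite"}.
#' @param condition named character vector (or unnamed, in column order)
#'   assigning \code{"WT"} or \code{"KO"} to every sample.
#' @param proteinLengths optional named numeric vector of protein lengths in
#'   amino acids; required downstream by [nsafNormalize()].
#' @return a validated [OmicsMatrix-class] object.
#' @examples
#' m <- OmicsMatrix(matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("s1", "s2"))),
#'                  "transcript", c(s1 = "WT", s2 = "KO"))
#' layerType(m)
#' @export
OmicsMatrix <- function(values, layer, condition, proteinLengths = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing))
      stop("no condition given for sample(s): ", paste(missing, collapse = ", "))
    condition <- unname(condition[colnames(values)])
  }
  cd <- S4Vectors::DataFrame(condition = condition, row.names = colnames(values))
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(proteinLengths)) {
    if (!all(rownames(values) %in% names(proteinLengths)))
      stop("protein length missing for feature(s): ",
           paste(setdiff(rownames(values), names(proteinLengths)), collapse = ", "))
    rd$protein_length <- unname(proteinLengths[rownames(values)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd, rowData = rd)
  new("OmicsMatrix", se, layer = layer)
}

#' @describeIn OmicsMatrix layer of an OmicsMatrix ("transcript", "protein"
#'   or "metabolite").
#' @param x an OmicsMatrix.
#' @export
layerType <- function(x) x@layer

#' Per-sample condition labels of an OmicsMatrix
#' @param x an OmicsMatrix.
#' @return named character vector of "WT"/"KO", one per sample.
#' @export
conditionLabels <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$condition),
           colnames(x))
}

#' Protein lengths stored in an OmicsMatrix
#' @param x an OmicsMatrix (protein layer).
#' @return named numeric vector, or NULL if absent.
#' @export
proteinLengths <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"protein_length" %in% colnames(rd)) return(NULL)
  setNames(as.numeric(rd$protein_length), rownames(x))
}

setMethod("show", "OmicsMatrix", function(object) {
  cond <- conditionLabels(object)
  cat(sprintf("OmicsMatrix [%s layer]: %d features x %d samples (%d WT, %d KO)\n",
              object@layer, nrow(object), ncol(object),
              sum(cond == "WT"), sum(cond == "KO")))
})

#' GeneSetCollection: named genesets (GMT content)
#'
#' @slot sets named list of character vectors (unique set names, non-empty
#'   deduplicated members).
#' @slot descriptions named character vector, one per set.
#' @seealso [readGMT()], [gseaPreranked()], [oraHypergeometric()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "sets must have at least one member")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "one description per set required")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection from a named list
#' @param sets named list of character membership vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection membership list accessor.
#' @param x a GeneSetCollection.
#' @export
geneSets <- function(x) x@sets

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, member counts %s\n",
              length(object@sets),
              paste(range(lengths(object@sets)), collapse = "-")))
})

#' InteractionNetwork: typed, prized gene-metabolite graph
#'
#' An undirected simple graph over gene and metabolite nodes, backed by an
#' igraph object. Vertex attributes: \code{type} ("gene"/"metabolite"),
#' \code{prize} (>= 0, the effective prize used by the PCSF objective),
#' \code{prizeOriginal} (pre-hub-penalty prize, for reporting) and
#' \code{measured}. Edge attributes: \code{confidence} in (0, 1] and
#' \code{cost} >= 0.
#'
#' @slot graph the backing igraph object.
#' @seealso [interactionNetwork()], [readEdgeList()], [assignPrizes()],
#'   [applyHubPenalty()], [edgeCostsFromConfidence()], [solvePCSF()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork", slots = c(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "network must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msg <- c(msg, "network must be simple (no loops or multi-edges)")
  va <- igraph::vertex_attr_names(g)
  if (!all(c("name", "type", "prize", "measured") %in% va))
    msg <- c(msg, "vertices need attributes name, type, prize, measured")
  else {
    if (anyDuplicated(igraph::V(g)$name))
      msg <- c(msg, "node ids must be unique")
    if (!all(igraph::V(g)$type %in% c("gene", "metabolite")))
      msg <- c(msg, "node type must be gene or metabolite")
    if (any(igraph::V(g)$prize < 0))
      msg <- c(msg, "prizes must be non-negative")
  }
  if (igraph::ecount(g) > 0 &&
      "confidence" %in% igraph::edge_attr_names(g)) {
    conf <- igraph::E(g)$confidence
    if (any(conf <= 0 | conf > 1))
      msg <- c(msg, "edge confidence must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork from node and edge tables
#'
#' @param nodes data.frame with columns \code{node_id}, \code{node_type}
#'   ("gene"/"metabolite"); optional \code{prize}, \code{measured}.
#' @param edges data.frame with columns \code{u}, \code{v},
#'   \code{confidence}; optional \code{cost}. Undirected; duplicate pairs or
#'   self-loops are an error.
#' @return an [InteractionNetwork-class].
#' @export
interactionNetwork <- function(nodes, edges = NULL) {
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node id: ",
         nodes$node_id[duplicated(nodes$node_id)][1L])
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = character(), v = character(),
                        confidence = numeric())
  }
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  unknown <- setdiff(c(edges$u, edges$v), nodes$node_id)
  if (length(unknown))
    stop("edge endpoint(s) not in node table: ",
         paste(head(unknown, 5L), collapse = ", "))
  if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
  if (anyDuplicated(key))
    stop("duplicate edge: ", key[duplicated(key)][1L])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node_id)
  igraph::V(g)$type <- nodes$node_type
  igraph::V(g)$prize <- if (!is.null(nodes$prize)) nodes$prize else 0
  igraph::V(g)$prizeOriginal <- igraph::V(g)$prize
  igraph::V(g)$measured <-
    if (!is.null(nodes$measured)) nodes$measured else FALSE
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$cost))
    igraph::E(g)$cost <- NA_real_
  new("InteractionNetwork", graph = g)
}

#' @describeIn interactionNetwork the backing igraph object.
#' @param net an InteractionNetwork.
#' @export
networkGraph <- function(net) net@graph

#' Node table of an InteractionNetwork
#' @param net an InteractionNetwork.
#' @return data.frame with node_id, node_type, prize, prize_original,
#'   measured, degree.
#' @export
nodeTable <- function(net) {
  g <- net@graph
  data.frame(node_id = igraph::V(g)$name,
             node_type = igraph::V(g)$type,
             prize = igraph::V(g)$prize,
             prize_original = igraph::V(g)$prizeOriginal,
             measured = igraph::V(g)$measured,
             degree = igraph::degree(g),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge table of an InteractionNetwork
#' @param net an InteractionNetwork.
#' @return data.frame with u, v, confidence, cost.
#' @export
edgeTable <- function(net) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  data.frame(u = el[, 1L], v = el[, 2L],
             confidence = if (igraph::ecount(g)) igraph::E(g)$confidence
                          else numeric(),
             cost = if (igraph::ecount(g)) igraph::E(g)$cost else numeric(),
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  tp <- igraph::V(g)$type
  cat(sprintf(paste0("InteractionNetwork: %d nodes (%d genes, %d metabolites),",
                     " %d edges; total prize %.3f\n"),
              igraph::vcount(g), sum(tp == "gene"), sum(tp == "metabolite"),
              igraph::ecount(g), sum(igraph::V(g)$prize)))
})

#' PCSF solver configuration
#'
#' @param beta prize scaling (> 0): weight of excluded prizes in the
#'   minimization objective.
#' @param omega per-tree penalty (> 0): cost of opening a tree (the virtual
#'   root edge cost).
#' @param mu hub penalty (>= 0) applied upstream by [applyHubPenalty()];
#'   recorded here for provenance.
#' @param seed integer seed (only consumed if randomized tie-breaking is
#'   enabled; the default solver is fully deterministic).
#' @return a \code{PCSFConfig} object.
#' @export
pcsfConfig <- function(beta = 1, omega = 2, mu = 0.01, seed = 1L) {
  stopifnot(beta > 0, omega > 0, mu >= 0)
  new("PCSFConfig", beta = as.numeric(beta), omega = as.numeric(omega),
      mu = as.numeric(mu), seed = as.integer(seed))
}

#' @rdname pcsfConfig
#' @exportClass PCSFConfig
setClass("PCSFConfig",
  slots = c(beta = "numeric", omega = "numeric", mu = "numeric",
            seed = "integer"))

#' PCSFSolution: a selected prize-collecting forest
#'
#' @slot selectedNodes character vector of node ids in the forest.
#' @slot selectedEdges data.frame (u, v, cost) of forest edges.
#' @slot kappa number of trees.
#' @slot objective minimization objective value
#'   (beta * excluded prizes + edge costs + omega * kappa).
#' @slot steinerNodes selected nodes with zero prize (connectors only).
#' @exportClass PCSFSolution
setClass("PCSFSolution",
  slots = c(selectedNodes = "character", selectedEdges = "data.frame",
            kappa = "integer", objective = "numeric",
            steinerNodes = "character"))

setMethod("show", "PCSFSolution", function(object) {
  cat(sprintf(paste0("PCSFSolution: %d nodes, %d edges, %d tree(s); ",
                     "objective %.4f; %d Steiner node(s)\n"),
              length(object@selectedNodes), nrow(object@selectedEdges),
              object@kappa, object@objective, length(object@steinerNodes)))
})

#' @describeIn pcsfConfig accessor for the solution objective.
#' @param sol a PCSFSolution.
#' @export
solutionObjective <- function(sol) sol@objective

#' Nodes of a PCSF solution
#' @param sol a PCSFSolution.
#' @export
selectedNodes <- function(sol) sol@selectedNodes

#' Edges of a PCSF solution
#' @param sol a PCSFSolution.
#' @export
selectedEdges <- function(sol) sol@selectedEdges

#' Steiner (zero-prize connector) nodes of a PCSF solution
#' @param sol a PCSFSolution.
#' @export
steinerNodes <- function(sol) sol@steinerNodes

#' Number of trees in a PCSF solution
#' @param sol a PCSFSolution.
#' @export
treeCount <- function(sol) sol@kappa

#' SyntheticTruth: ground truth of a simulated study
#'
#' @slot plantedModules list of character vectors, each a connected node set
#'   carrying the planted perturbation.
#' @slot trueLog2fc named numeric vector of true log2 fold changes (KO vs
#'   WT) over all network nodes.
#' @slot moduleSignalMean mean |log2FC| planted in module nodes.
#' @slot noiseSd standard deviation of background log2FC noise.
#' @slot seed integer seed the truth was generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(plantedModules = "list", trueLog2fc = "numeric",
            moduleSignalMean = "numeric", noiseSd = "numeric",
            seed = "integer"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d planted module(s) covering %d ",
                     "nodes; signal mean %.2f, noise sd %.2f, seed %d\n"),
              length(object@plantedModules),
              length(unlist(object@plantedModules)),
              object@moduleSignalMean, object@noiseSd, object@seed))
})

#' @describeIn plantModules planted module node sets of a SyntheticTruth.
#' @param truth a SyntheticTruth.
#' @export
plantedModules <- function(truth) truth@plantedModules

#' True log2 fold changes of a SyntheticTruth
#' @param truth a SyntheticTruth.
#' @export
trueLog2fc <- function(truth) truth@trueLog2fc
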