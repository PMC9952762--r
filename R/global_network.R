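#' Read a global interaction network from edge-list and node-type TSVs
#'
#' The edge list is three tab-separated columns (node_u, node_v,
#' confidence in (0, 1]); node types are two columns (node_id,
#' gene|metabolite). Nodes present in the type table but absent from the
#' edge list become isolated nodes. Duplicate undirected pairs are
#' collapsed keeping the maximum confidence; self-loops are dropped.
#'
#' @param edgePath path to the edge-list TSV (with header).
#' @param nodeTypePath path to the node-type TSV (with header).
#' @return an [InteractionNetwork-class] with prizes 0, measured FALSE.
#' @export
readEdgeList <- function(edgePath, nodeTypePath) {
  ed <- read.delim(edgePath, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  nt <- read.delim(nodeTypePath, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  names(ed)[1:3] <- c("u", "v", "confidence")
  names(nt)[1:2] <- c("node_id", "node_type")
  if (any(!is.finite(ed$confidence) | ed$confidence <= 0 |
            ed$confidence > 1))
    stop("edge confidence must lie in (0, 1]")
  ed <- ed[ed$u != ed$v, , drop = FALSE]
  key <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(ed$confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    ed <- data.frame(u = vapply(parts, `[[`, "", 1L),
                     v = vapply(parts, `[[`, "", 2L),
                     confidence = as.numeric(conf),
                     stringsAsFactors = FALSE)
  }
  unknown <- setdiff(c(ed$u, ed$v), nt$node_id)
  if (length(unknown))
    stop("edge node(s) missing from the type table: ",
         paste(head(unknown, 5L), collapse = ", "))
  interactionNetwork(
    data.frame(node_id = nt$node_id, node_type = nt$node_type,
               stringsAsFactors = FALSE),
    ed)
}

#' Merge two interaction networks (gene net + metabolic net)
#'
#' Node union and edge union; shared node ids must agree on type; a pair
#' present in both networks keeps the maximum confidence. The result is
#' simple and undirected. Merging is commutative and idempotent.
#'
#' @param a,b [InteractionNetwork-class] objects sharing an id namespace.
#' @return the merged [InteractionNetwork-class].
#' @export
mergeNetworks <- function(a, b) {
  na <- nodeTable(a); nb <- nodeTable(b)
  shared <- intersect(na$node_id, nb$node_id)
  if (length(shared)) {
    ta <- setNames(na$node_type, na$node_id)[shared]
    tb <- setNames(nb$node_type, nb$node_id)[shared]
    bad <- shared[ta != tb]
    if (length(bad))
      stop("conflicting node type for id(s): ",
           paste(head(bad, 5L), collapse = ", "))
  }
  nodes <- rbind(na[, c("node_id", "node_type")],
                 nb[!nb$node_id %in% na$node_id, c("node_id", "node_type")])
  ed <- rbind(edgeTable(a)[, c("u", "v", "confidence")],
              edgeTable(b)[, c("u", "v", "confidence")])
  if (nrow(ed)) {
    key <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
    conf <- tapply(ed$confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    ed <- data.frame(u = vapply(parts, `[[`, "", 1L),
                     v = vapply(parts, `[[`, "", 2L),
                     confidence = as.numeric(conf),
                     stringsAsFactors = FALSE)
  }
  interactionNetwork(nodes, ed)
}

#' Assign node prizes from multi-omics fold changes
#'
#' A node quantified in at least one layer receives prize =
#' max over layers of |log2FC| (regardless of significance unless
#' \code{onlySignificant}); nodes never measured keep prize 0 and act as
#' potential Steiner connectors. Features absent from the network are
#' counted and reported via a warning, not added.
#'
#' @param net an [InteractionNetwork-class].
#' @param stats data.frame of feature statistics (feature_id, log2fc,
#'   significant), typically several layers row-bound together.
#' @param onlySignificant if TRUE, only significant features contribute
#'   prizes.
#' @return the network with prize, prizeOriginal and measured updated.
#' @export
assignPrizes <- function(net, stats, onlySignificant = FALSE) {
  if (onlySignificant) stats <- stats[stats$significant, , drop = FALSE]
  g <- net@graph
  inNet <- stats$feature_id %in% igraph::V(g)$name
  if (any(!inNet))
    warning(sum(!inNet), " measured feature(s) absent from the network; ",
            "ignored")
  stats <- stats[inNet, , drop = FALSE]
  prize <- rep(0, igraph::vcount(g))
  names(prize) <- igraph::V(g)$name
  if (nrow(stats)) {
    best <- tapply(abs(stats$log2fc), stats$feature_id, max)
    prize[names(best)] <- as.numeric(best)
  }
  igraph::V(g)$prize <- unname(prize)
  igraph::V(g)$prizeOriginal <- unname(prize)
  igraph::V(g)$measured <- igraph::V(g)$name %in% stats$feature_id
  new("InteractionNetwork", graph = g)
}

#' Degree-proportional hub penalty on prizes
#'
#' Replaces each prize with max(0, prize - mu * degree), discouraging the
#' selection of highly connected nodes; clamping at zero keeps the PCSF
#' exclusion term well defined. Original prizes stay available in
#' \code{prizeOriginal} for reporting.
#'
#' @param net an [InteractionNetwork-class] with prizes assigned.
#' @param mu penalty per unit degree (>= 0); 0 is the identity.
#' @return the network with adjusted prizes.
#' @export
applyHubPenalty <- function(net, mu = 0.01) {
  if (mu < 0) stop("mu must be non-negative")
  g <- net@graph
  igraph::V(g)$prize <-
    pmax(0, igraph::V(g)$prizeOriginal - mu * igraph::degree(g))
  new("InteractionNetwork", graph = g)
}

#' Derive edge costs from confidences
#'
#' cost(e) = 1 - confidence(e), mapping confidence in (0, 1] onto cost in
#' [0, 1) monotonically (higher confidence, lower cost).
#'
#' @param net an [InteractionNetwork-class].
#' @return the network with the \code{cost} edge attribute set.
#' @export
edgeCostsFromConfidence <- function(net) {
  g <- net@graph
  if (igraph::ecount(g) > 0) {
    conf <- igraph::E(g)$confidence
    if (any(!is.finite(conf) | conf <= 0 | conf > 1))
      stop("edge confidence must lie in (0, 1]")
    igraph::E(g)$cost <- 1 - conf
  }
  new("InteractionNetwork", graph = g)
}

#' Export a network (or solution subgraph) as GraphML
#'
#' Writes node attributes type, prize, measured (and is_steiner for
#' solution graphs) and edge attributes confidence and cost, in a format
#' Cytoscape opens directly.
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path.
#' @param solution optional [PCSFSolution-class]; when given, only the
#'   solution subgraph is written and is_steiner is annotated.
#' @return \code{path}, invisibly.
#' @export
writeNetworkGraphML <- function(net, path, solution = NULL) {
  g <- net@graph
  if (!is.null(solution)) {
    g <- igraph::induced_subgraph(g, solution@selectedNodes)
    sel <- paste(pmin(solution@selectedEdges$u, solution@selectedEdges$v),
                 pmax(solution@selectedEdges$u, solution@selectedEdges$v))
    el <- igraph::as_edgelist(g)
    keep <- paste(pmin(el[, 1L], el[, 2L]),
                  pmax(el[, 1L], el[, 2L])) %in% sel
    g <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
    igraph::V(g)$is_steiner <- igraph::V(g)$name %in% solution@steinerNodes
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
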