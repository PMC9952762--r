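#' Decompose a solution graph into communities
#'
#' Greedy modularity-maximizing agglomeration (Clauset-Newman-Moore, via
#' \code{igraph::cluster_fast_greedy}) on the solution subgraph; node ids
#' are processed in sorted order so the partition is deterministic.
#' Louvain is available behind \code{method = "louvain"} with a mandatory
#' seed. The partition always covers every node; disconnected components
#' never share a community.
#'
#' @param net an [InteractionNetwork-class] (typically the PCSF solution
#'   subgraph, see [solutionSubgraph()]).
#' @param method "greedy" (default) or "louvain".
#' @param seed integer seed, required for "louvain".
#' @return list of character vectors (node sets), ordered by smallest
#'   member id.
#' @export
detectCommunities <- function(net, method = c("greedy", "louvain"),
                              seed = 1L) {
  method <- match.arg(method)
  g <- net@graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  g <- igraph::permute(g, match(igraph::V(g)$name,
                                sort(igraph::V(g)$name)))
  memb <- if (method == "greedy") {
    m <- igraph::membership(igraph::cluster_fast_greedy(g, weights = NULL))
    .mergeWhileImproving(g, m)
  } else {
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g, weights = NULL))
  }
  groups <- split(igraph::V(g)$name, memb)
  groups <- lapply(groups, sort)
  names(groups) <- NULL
  groups[order(vapply(groups, `[[`, "", 1L))]
}

## Finish the agglomeration: while merging some pair of communities still
## raises modularity, apply the best merge (ties: smallest lexicographic
## pair of community representatives, i.e. lowest community labels after
## relabeling by first member). Usually a no-op; guards degenerate graphs
## where the dendrogram cut stops early.
.mergeWhileImproving <- function(g, memb) {
  memb <- as.integer(factor(memb, levels = unique(memb)))
  repeat {
    q0 <- igraph::modularity(g, memb)
    ids <- sort(unique(memb))
    if (length(ids) < 2L) break
    best <- NULL; bestQ <- q0 + 1e-12
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      m2 <- memb
      m2[m2 == ids[j]] <- ids[i]
      q <- igraph::modularity(g, m2)
      if (q > bestQ) { bestQ <- q; best <- m2 }
    }
    if (is.null(best)) break
    memb <- best
  }
  memb
}

#' Induced subgraph of a PCSF solution in the global network
#'
#' Restricts the global network to the solution's nodes, keeping every
#' global-network edge between two selected nodes (not only the forest
#' edges): the forest certifies which nodes belong to the solution, while
#' community structure is read from the full connectivity among them —
#' this is why a solution of n nodes typically has far more relations
#' than n - 1.
#'
#' @param net the global [InteractionNetwork-class].
#' @param solution a [PCSFSolution-class].
#' @return an [InteractionNetwork-class] over the solution nodes.
#' @export
solutionSubgraph <- function(net, solution) {
  g <- igraph::induced_subgraph(net@graph, solution@selectedNodes)
  new("InteractionNetwork", graph = g)
}

#' Prize density of a node set
#'
#' The ranking statistic for subnetworks: sum of prizes divided by the
#' fraction of the global network the subnetwork occupies,
#' D = sum(prize) / (|S| / N_global). With uniform prizes p this equals
#' p * N_global for every subnetwork.
#'
#' @param nodes non-empty character vector of node ids.
#' @param net the [InteractionNetwork-class] carrying prizes.
#' @param globalN total node count of the global network (>= length(nodes)).
#' @return the prize density (numeric scalar).
#' @export
prizeDensity <- function(nodes, net, globalN) {
  if (!length(nodes)) stop("empty node set")
  stopifnot(globalN >= length(nodes))
  g <- net@graph
  prize <- setNames(igraph::V(g)$prize, igraph::V(g)$name)
  if (anyNA(prize[nodes])) stop("unknown node id in subnetwork")
  sum(prize[nodes]) / (length(nodes) / globalN)
}

#' Per-subnetwork pathway over-representation
#'
#' Runs [oraHypergeometric()] for every geneset using the subnetwork's
#' gene-type nodes as the significant list and the gene-type nodes of the
#' global network as the universe; FDR is BH across sets within the
#' subnetwork. Metabolite nodes are excluded from the ORA (they still
#' count toward prize density). A subnetwork with no gene nodes gets an
#' empty table and min_fdr = 1.
#'
#' @param nodes character vector of subnetwork node ids.
#' @param net the global [InteractionNetwork-class].
#' @param collection a [GeneSetCollection-class].
#' @return list with \code{enrichment} (data.frame set_name, overlap,
#'   p_value, fdr) and \code{min_fdr}.
#' @export
subnetworkEnrichment <- function(nodes, net, collection) {
  nt <- nodeTable(net)
  universe <- nt$node_id[nt$node_type == "gene"]
  genes <- intersect(nodes, universe)
  sets <- geneSets(collection)
  if (!length(genes) || !length(sets))
    return(list(enrichment = data.frame(set_name = character(),
                                        overlap = integer(),
                                        p_value = numeric(),
                                        fdr = numeric()),
                min_fdr = 1))
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (!length(members)) return(NULL)
    r <- oraHypergeometric(genes, universe, members)
    data.frame(set_name = nm, overlap = r$overlap, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  enr <- do.call(rbind, rows)
  if (is.null(enr) || !nrow(enr))
    return(list(enrichment = data.frame(set_name = character(),
                                        overlap = integer(),
                                        p_value = numeric(),
                                        fdr = numeric()),
                min_fdr = 1))
  enr$fdr <- bhAdjust(enr$p_value)
  list(enrichment = enr, min_fdr = min(enr$fdr))
}

#' Decompose, score, enrich and rank the subnetworks of a PCSF solution
#'
#' Communities of the solution subgraph become subnetworks; each gets a
#' prize sum, a prize density relative to the global network, and a
#' within-subnetwork pathway ORA. Subnetworks whose best pathway FDR is
#' strictly below \code{fdrCutoff} are ranked by prize density
#' (descending; ties by prize sum descending, then id ascending).
#'
#' @param net the global [InteractionNetwork-class] (prizes assigned).
#' @param solution a [PCSFSolution-class].
#' @param collection a [GeneSetCollection-class] for per-subnetwork ORA.
#' @param fdrCutoff strict FDR threshold for entering the ranking.
#' @param method community detection method (see [detectCommunities()]).
#' @param seed seed for "louvain".
#' @return list with \code{summary} (data.frame: subnetwork_id, n_nodes,
#'   n_genes, n_metabolites, prize_sum, prize_density, top_pathway,
#'   min_fdr, rank — NA rank for unranked), \code{members} (named list of
#'   node sets) and \code{enrichment} (named list of ORA tables).
#' @export
analyzeSubnetworks <- function(net, solution, collection, fdrCutoff = 0.05,
                               method = "greedy", seed = 1L) {
  if (!length(solution@selectedNodes))
    stop("empty PCSF solution has no subnetworks")
  sub <- solutionSubgraph(net, solution)
  comms <- detectCommunities(sub, method = method, seed = seed)
  nt <- nodeTable(net)
  type <- setNames(nt$node_type, nt$node_id)
  globalN <- nrow(nt)
  rows <- vector("list", length(comms))
  enrich <- vector("list", length(comms))
  for (i in seq_along(comms)) {
    nodes <- comms[[i]]
    e <- subnetworkEnrichment(nodes, net, collection)
    enrich[[i]] <- e$enrichment
    prize <- setNames(nt$prize, nt$node_id)[nodes]
    top <- if (nrow(e$enrichment))
      e$enrichment$set_name[which.min(e$enrichment$fdr)] else NA_character_
    rows[[i]] <- data.frame(
      subnetwork_id = i,
      n_nodes = length(nodes),
      n_genes = sum(type[nodes] == "gene"),
      n_metabolites = sum(type[nodes] == "metabolite"),
      prize_sum = sum(prize),
      prize_density = prizeDensity(nodes, net, globalN),
      top_pathway = top,
      min_fdr = e$min_fdr,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  summary <- rankSubnetworks(summary, fdrCutoff)
  names(comms) <- as.character(seq_along(comms))
  names(enrich) <- names(comms)
  list(summary = summary, members = comms, enrichment = enrich)
}

#' Rank subnetworks by prize density under an enrichment FDR filter
#'
#' Keeps rows with \code{min_fdr < fdrCutoff} (strict) in the ranking;
#' rank 1..k is assigned by prize density descending, ties by prize sum
#' descending, then subnetwork id ascending. Unranked rows keep rank NA.
#' The operation is idempotent and returns all rows (ranked first).
#'
#' @param summary data.frame with columns subnetwork_id, prize_sum,
#'   prize_density, min_fdr.
#' @param fdrCutoff strict FDR threshold.
#' @return the data.frame with a \code{rank} column, ranked rows first.
#' @export
rankSubnetworks <- function(summary, fdrCutoff = 0.05) {
  eligible <- summary$min_fdr < fdrCutoff
  summary$rank <- NA_integer_
  if (any(eligible)) {
    idx <- which(eligible)
    ord <- idx[order(-summary$prize_density[idx], -summary$prize_sum[idx],
                     summary$subnetwork_id[idx])]
    summary$rank[ord] <- seq_along(ord)
  }
  summary[order(is.na(summary$rank), summary$rank,
                summary$subnetwork_id), , drop = FALSE]
}
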