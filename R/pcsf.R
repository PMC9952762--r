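## Internal representation used by the solver and oracle: nodes in sorted
## id order, integer edge endpoints, costs populated.
.netArrays <- function(net, cfg) {
  g <- net@graph
  nm <- sort(igraph::V(g)$name)
  prize <- setNames(igraph::V(g)$prize, igraph::V(g)$name)[nm]
  ed <- edgeTable(net)
  if (nrow(ed) && anyNA(ed$cost))
    stop("edge costs missing; run edgeCostsFromConfidence() first")
  iu <- match(ed$u, nm); iv <- match(ed$v, nm)
  swap <- iu > iv
  tmp <- iu[swap]; iu[swap] <- iv[swap]; iv[swap] <- tmp
  ord <- order(iu, iv)
  eu <- iu[ord]; ev <- iv[ord]; cost <- ed$cost[ord]
  n <- length(nm)
  adj <- vector("list", n)
  for (k in seq_along(eu)) {
    adj[[eu[k]]] <- c(adj[[eu[k]]], ev[k])
    adj[[ev[k]]] <- c(adj[[ev[k]]], eu[k])
  }
  list(names = nm, n = n, prize = unname(prize),
       pi = cfg@beta * unname(prize),
       eu = eu, ev = ev, cost = cost,
       costOrder = order(cost, eu, ev), adj = adj)
}

#' PCSF objective of a candidate forest
#'
#' The minimization form of the prize-collecting Steiner forest objective:
#' beta * (sum of prizes of excluded nodes) + (sum of selected edge costs)
#' + omega * kappa, where kappa is the number of trees. Lower is better;
#' the empty forest scores beta * (total prize).
#'
#' @param net an [InteractionNetwork-class] with prizes and edge costs.
#' @param nodes character vector of selected node ids.
#' @param edges data.frame (u, v) of selected edges; must be edges of
#'   \code{net}, span only selected nodes, and be acyclic.
#' @param cfg a [pcsfConfig()].
#' @return the objective value (numeric scalar).
#' @export
pcsfObjective <- function(net, nodes, edges, cfg) {
  g <- net@graph
  allnm <- igraph::V(g)$name
  if (length(setdiff(nodes, allnm)))
    stop("selected node(s) not in the network")
  ed <- edgeTable(net)
  if (nrow(ed) && anyNA(ed$cost))
    stop("edge costs missing; run edgeCostsFromConfidence() first")
  netKey <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "\r")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = character(), v = character())
  }
  selKey <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  hit <- match(selKey, netKey)
  if (anyNA(hit)) stop("selected edge not present in the network")
  if (length(setdiff(c(edges$u, edges$v), nodes)))
    stop("selected edge with an unselected endpoint")
  fg <- igraph::graph_from_data_frame(edges[, c("u", "v")],
                                      directed = FALSE, vertices = nodes)
  comp <- igraph::components(fg)
  if (igraph::ecount(fg) != igraph::vcount(fg) - comp$no)
    stop("selected edges contain a cycle")
  kappa <- if (length(nodes)) comp$no else 0L
  prize <- setNames(igraph::V(g)$prize, allnm)
  excluded <- sum(prize[setdiff(allnm, nodes)])
  cfg@beta * excluded + sum(ed$cost[hit]) + cfg@omega * kappa
}

## Goemans-Williamson moat growth on the root-augmented graph.
## Vertices 1..n plus virtual root n+1 joined to every positive-prize node
## by an edge of cost omega. Returns the merge-tree edges of the final
## root cluster (indices into the augmented edge arrays).
.gwGrow <- function(n, pi, eu, ev, cost, omega) {
  root <- n + 1L
  pos <- which(pi > 0)
  aeu <- c(eu, rep(root, length(pos)))
  aev <- c(ev, pos)
  aec <- c(cost, rep(omega, length(pos)))
  cl <- seq_len(root)                 # cluster id of each vertex
  W <- rep(0, root)                   # dual accumulated per cluster
  P <- c(pi, 0)                       # prize capacity per cluster
  act <- c(pi > 0, FALSE)             # zero-prize clusters start tight
  d <- rep(0, root)                   # moat depth per vertex
  merges <- integer(0)
  tol <- 1e-12
  for (iter in seq_len(4L * root + 8L)) {
    if (!any(act)) break
    cu <- cl[aeu]; cv <- cl[aev]
    rate <- (act[cu] + 0) + (act[cv] + 0)
    te <- (aec - d[aeu] - d[aev]) / rate
    te[cu == cv | rate == 0] <- Inf
    te[te < 0] <- 0
    ie <- which.min(te); tEdge <- te[ie]
    actIds <- which(act)
    tDe <- P[actIds] - W[actIds]
    tDe[tDe < 0] <- 0
    idx <- which.min(tDe); tDeact <- tDe[idx]
    delta <- min(tEdge, tDeact)
    grow <- act[cl]
    d[grow] <- d[grow] + delta
    W[actIds] <- W[actIds] + delta
    if (tEdge <= tDeact + tol) {      # merge event (edges before deactivation)
      c1 <- cl[aeu[ie]]; c2 <- cl[aev[ie]]
      cl[cl == c2] <- c1
      W[c1] <- W[c1] + W[c2]; P[c1] <- P[c1] + P[c2]
      act[c2] <- FALSE
      act[c1] <- (cl[root] != c1) && (W[c1] < P[c1] - tol)
      merges <- c(merges, ie)
    } else {
      act[actIds[idx]] <- FALSE
    }
  }
  rootCl <- cl[root]
  keep <- merges[cl[aeu[merges]] == rootCl]
  list(eu = aeu[keep], ev = aev[keep], cost = aec[keep], root = root)
}

## Strong pruning of a tree rooted at `root` (virtual root, pi 0):
## net worth of a subtree is its pi plus every child subtree whose net
## worth strictly exceeds the connecting edge cost. Returns kept vertices
## (excluding root) and kept non-root edges.
.strongPrune <- function(treeEu, treeEv, treeCost, root, pi) {
  vs <- sort(unique(c(treeEu, treeEv, root)))
  nv <- length(vs)
  vi <- match(c(treeEu, treeEv), vs)
  m <- length(treeEu)
  a <- vi[seq_len(m)]; b <- vi[m + seq_len(m)]
  adj <- vector("list", nv)
  for (k in seq_len(m)) {
    adj[[a[k]]] <- rbind(adj[[a[k]]], c(b[k], k))
    adj[[b[k]]] <- rbind(adj[[b[k]]], c(a[k], k))
  }
  r <- match(root, vs)
  parent <- rep(NA_integer_, nv); pedge <- rep(NA_integer_, nv)
  order <- integer(0); stack <- r; seen <- rep(FALSE, nv); seen[r] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    if (!is.null(adj[[v]])) {
      for (k in seq_len(nrow(adj[[v]]))) {
        u <- adj[[v]][k, 1L]
        if (!seen[u]) {
          seen[u] <- TRUE; parent[u] <- v; pedge[u] <- adj[[v]][k, 2L]
          stack <- c(stack, u)
        }
      }
    }
  }
  piv <- c(pi, 0)[vs]                 # root (index n+1) has pi 0
  nw <- piv
  keepEdge <- rep(FALSE, m)
  tol <- 1e-12
  for (v in rev(order)) {
    if (!is.na(parent[v])) {
      gain <- nw[v] - treeCost[pedge[v]]
      if (gain > tol) {
        keepEdge[pedge[v]] <- TRUE
        nw[parent[v]] <- nw[parent[v]] + gain
      }
    }
  }
  # forward pass: only subtrees connected to the root through kept edges
  alive <- rep(FALSE, nv); alive[r] <- TRUE
  for (v in order) {
    if (!is.na(parent[v]) && alive[parent[v]] && keepEdge[pedge[v]])
      alive[v] <- TRUE
  }
  keepEdge <- keepEdge & alive[a] & alive[b]
  list(vertices = vs[alive & vs != root],
       eu = treeEu[keepEdge], ev = treeEv[keepEdge],
       cost = treeCost[keepEdge], root = root)
}

## Optimal edge completion for a fixed node set: Kruskal over the induced
## edges in ascending cost order, accepting an edge only while it is
## acyclic and cheaper than omega (connecting two trees saves one tree
## penalty, so an edge with cost >= omega never helps). Exact for the
## fixed set because forests form a matroid.
.completion <- function(arr, omega, inS) {
  ord <- arr$costOrder
  cand <- ord[inS[arr$eu[ord]] & inS[arr$ev[ord]]]
  n <- arr$n
  uf <- seq_len(n)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  chosen <- integer(0); costSum <- 0
  for (k in cand) {
    if (arr$cost[k] >= omega) break   # sorted: nothing cheaper follows
    ra <- find(arr$eu[k]); rb <- find(arr$ev[k])
    if (ra != rb) { uf[ra] <- rb; chosen <- c(chosen, k)
                    costSum <- costSum + arr$cost[k] }
  }
  nS <- sum(inS)
  kappa <- nS - length(chosen)
  obj <- sum(arr$pi[!inS]) + costSum + omega * kappa
  list(edges = chosen, obj = obj, kappa = as.integer(kappa))
}

## First-improvement hill climbing over node sets, evaluating each flip by
## its optimal completion. Deterministic: nodes are visited in sorted-id
## order; passes repeat until a fixed point (bounded).
.flipSearch <- function(arr, omega, start) {
  tol <- 1e-12
  n <- arr$n
  inS <- rep(FALSE, n); inS[start] <- TRUE
  cur <- .completion(arr, omega, inS)
  nbrCount <- function(v) sum(inS[arr$adj[[v]]])
  for (pass in seq_len(40L)) {
    improved <- FALSE
    for (v in seq_len(n)) {
      if (!inS[v] && arr$pi[v] <= tol && nbrCount(v) < 2L)
        next                          # a Steiner node needs >= 2 anchors
      inS[v] <- !inS[v]
      cand <- .completion(arr, omega, inS)
      if (cand$obj < cur$obj - tol) {
        cur <- cand; improved <- TRUE
      } else {
        inS[v] <- !inS[v]
      }
    }
    if (!improved) break
  }
  list(vertices = which(inS), eu = arr$eu[cur$edges],
       ev = arr$ev[cur$edges], cost = arr$cost[cur$edges],
       kappa = cur$kappa)
}

.forestToSolution <- function(net, cfg, arr, fr) {
  nodes <- arr$names[sort(fr$vertices)]
  edges <- if (length(fr$eu)) {
    u <- arr$names[pmin(fr$eu, fr$ev)]
    v <- arr$names[pmax(fr$eu, fr$ev)]
    ord <- order(u, v)
    data.frame(u = u[ord], v = v[ord], cost = fr$cost[ord],
               stringsAsFactors = FALSE)
  } else data.frame(u = character(), v = character(), cost = numeric())
  obj <- pcsfObjective(net, nodes, edges, cfg)
  prize <- setNames(igraph::V(net@graph)$prize, igraph::V(net@graph)$name)
  new("PCSFSolution", selectedNodes = nodes, selectedEdges = edges,
      kappa = if (length(nodes)) fr$kappa else 0L,
      objective = obj,
      steinerNodes = nodes[prize[nodes] == 0])
}

#' Solve the prize-collecting Steiner forest problem (heuristic)
#'
#' Transforms the instance to a rooted prize-collecting Steiner tree by
#' joining a virtual root to every positive-prize node at cost omega, runs
#' Goemans-Williamson moat growth followed by strong pruning, and removes
#' the root; the surviving components are the forest. A strong-pruned
#' minimum spanning tree of the same root-augmented graph is evaluated as
#' a second candidate; each candidate then receives a greedy add/drop
#' local-improvement pass and the best objective is returned (tie: fewer
#' nodes). Fully deterministic: all iteration orders follow sorted node
#' ids.
#'
#' @param net an [InteractionNetwork-class] with prizes assigned (hub
#'   penalty already applied upstream) and edge costs populated.
#' @param cfg a [pcsfConfig()].
#' @return a [PCSFSolution-class].
#' @export
solvePCSF <- function(net, cfg = pcsfConfig()) {
  arr <- .netArrays(net, cfg)
  empty <- list(vertices = integer(), eu = integer(), ev = integer(),
                cost = numeric(), kappa = 0L)
  if (arr$n == 0L || sum(arr$pi) == 0)
    return(.forestToSolution(net, cfg, arr, empty))
  starts <- list(integer(0))
  gw <- .gwGrow(arr$n, arr$pi, arr$eu, arr$ev, arr$cost, cfg@omega)
  if (length(gw$eu)) {
    pr <- .strongPrune(gw$eu, gw$ev, gw$cost, gw$root, arr$pi)
    starts <- c(starts, list(pr$vertices))
  }
  mst <- .rootedMstTree(arr, cfg@omega)
  if (length(mst$eu)) {
    pr <- .strongPrune(mst$eu, mst$ev, mst$cost, mst$root, arr$pi)
    starts <- c(starts, list(pr$vertices))
  }
  candidates <- lapply(starts, function(s) .flipSearch(arr, cfg@omega, s))
  sols <- lapply(candidates, function(fr) .forestToSolution(net, cfg, arr, fr))
  objs <- vapply(sols, function(s) s@objective, 0)
  sizes <- vapply(sols, function(s) length(s@selectedNodes), 0L)
  best <- order(objs, sizes)[1L]
  sols[[best]]
}

## Minimum spanning tree of the root-augmented graph, restricted to the
## component containing the virtual root.
.rootedMstTree <- function(arr, omega) {
  root <- arr$n + 1L
  pos <- which(arr$pi > 0)
  aeu <- c(arr$eu, rep(root, length(pos)))
  aev <- c(arr$ev, pos)
  aec <- c(arr$cost, rep(omega, length(pos)))
  g <- igraph::make_empty_graph(n = root, directed = FALSE)
  g <- igraph::add_edges(g, rbind(aeu, aev))
  igraph::E(g)$weight <- aec
  comp <- igraph::components(g)
  keepV <- comp$membership == comp$membership[root]
  sub <- igraph::induced_subgraph(g, which(keepV))
  idx <- which(keepV)                 # original index of each sub vertex
  mt <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  el <- igraph::as_edgelist(mt, names = FALSE)
  if (nrow(el) == 0L)
    return(list(eu = integer(), ev = integer(), cost = numeric(),
                root = root))
  list(eu = idx[el[, 1L]], ev = idx[el[, 2L]],
       cost = igraph::E(mt)$weight, root = root)
}

#' Exact PCSF by exhaustive enumeration (test oracle)
#'
#' Enumerates every node subset (hence limited to 15 nodes); for a fixed
#' subset the optimal edge completion is a Kruskal forest that accepts an
#' edge only when its cost is below omega (connecting two trees saves one
#' tree penalty). Ties are broken toward fewer nodes, then lexicographic
#' node ids.
#'
#' @param net an [InteractionNetwork-class] with prizes and edge costs.
#' @param cfg a [pcsfConfig()].
#' @return the optimal [PCSFSolution-class].
#' @export
bruteForcePCSF <- function(net, cfg = pcsfConfig()) {
  arr <- .netArrays(net, cfg)
  n <- arr$n
  if (n > 15L) stop("brute force is limited to 15 nodes")
  ord <- order(arr$cost)
  eu <- arr$eu[ord]; ev <- arr$ev[ord]; ec <- arr$cost[ord]
  usable <- ec < cfg@omega            # an edge with cost >= omega never helps
  eu <- eu[usable]; ev <- ev[usable]; ec <- ec[usable]
  totalPi <- sum(arr$pi)
  bits <- bitwShiftL(1L, 0:(max(n, 1L) - 1L))
  bestObj <- Inf; bestSize <- -1L; bestKey <- ""
  bestS <- integer(); bestE <- integer(0)
  for (mask in 0:(bitwShiftL(1L, n) - 1L)) {
    inS <- bitwAnd(mask, bits) != 0L
    S <- which(inS)
    uf <- seq_len(n)
    find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
    chosen <- integer(0); costSum <- 0
    for (k in seq_along(eu)) {
      if (inS[eu[k]] && inS[ev[k]]) {
        ra <- find(eu[k]); rb <- find(ev[k])
        if (ra != rb) { uf[ra] <- rb; chosen <- c(chosen, k); costSum <- costSum + ec[k] }
      }
    }
    kappa <- length(S) - length(chosen)
    obj <- totalPi - sum(arr$pi[S]) + costSum + cfg@omega * kappa
    key <- paste(S, collapse = ",")
    better <- obj < bestObj - 1e-12 ||
      (abs(obj - bestObj) <= 1e-12 &&
         (length(S) < bestSize ||
            (length(S) == bestSize && key < bestKey)))
    if (better) {
      bestObj <- obj; bestSize <- length(S); bestKey <- key
      bestS <- S; bestE <- chosen
    }
  }
  fr <- list(vertices = bestS, eu = eu[bestE], ev = ev[bestE],
             cost = ec[bestE],
             kappa = as.integer(length(bestS) - length(bestE)))
  .forestToSolution(net, cfg, arr, fr)
}
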