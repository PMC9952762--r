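# Independent oracles, coded straight from the definitions and kept free
# of any package internals.

# Benjamini-Hochberg step-up, literal: sort ascending, q_i = p_i * m / i,
# enforce monotonicity from the largest rank down, cap at 1.
bhStepUp <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Running-sum enrichment score by plain single-pass accumulation; the
# positive excursion wins a magnitude tie (same convention, independent
# code path).
esBruteForce <- function(scores, members, w = 1) {
  n <- length(scores)
  hit <- names(scores) %in% members
  nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^w)
  run <- 0
  hi <- -Inf; lo <- Inf
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (wsum == 0) 1 / nh else abs(scores[i])^w / wsum
    } else {
      -1 / (n - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  unname(if (hi >= -lo - 1e-9) hi else lo)
}

# Upper-tail hypergeometric by explicit combinatorial summation.
hyperTailSum <- function(ov, N, K, n) {
  js <- max(0, n + K - N):min(K, n)
  js <- js[js >= ov]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random PCSF instance on n nodes, Erdos-Renyi edges, prizes U[0, 3],
# costs U[0, 1) via confidence.
randomPcsfInstance <- function(n, pEdge = 0.4) {
  ids <- sprintf("N%02d", seq_len(n))
  ed <- NULL
  if (n >= 2) {
    pairs <- t(combn(n, 2))
    sel <- runif(nrow(pairs)) < pEdge
    if (any(sel))
      ed <- data.frame(u = ids[pairs[sel, 1]], v = ids[pairs[sel, 2]],
                       confidence = 1 - runif(sum(sel)) * 0.999)
  }
  net <- interactionNetwork(
    data.frame(node_id = ids, node_type = "gene", prize = runif(n, 0, 3)),
    ed)
  edgeCostsFromConfidence(net)
}

# Forest validity checks on a PCSFSolution against its network.
expectValidForest <- function(sol, net) {
  nodes <- selectedNodes(sol)
  ed <- selectedEdges(sol)
  expect_true(all(c(ed$u, ed$v) %in% nodes))
  g <- igraph::graph_from_data_frame(ed[, c("u", "v")], directed = FALSE,
                                     vertices = if (length(nodes)) nodes
                                                else NULL)
  comp <- if (length(nodes)) igraph::components(g)$no else 0L
  expect_identical(nrow(ed), length(nodes) - treeCount(sol))
  expect_equal(as.integer(comp), as.integer(treeCount(sol)))
}
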