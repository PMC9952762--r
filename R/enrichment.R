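#' Read a GMT geneset file
#'
#' Standard GMT dialect: one set per line, fields separated by tabs —
#' name, description, then members. Duplicate members within a line are
#' collapsed.
#'
#' @param path GMT path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name: ", nms[duplicated(nms)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  GeneSetCollection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write a GeneSetCollection as GMT
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, collection@descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Rank features by log2 fold change for preranked GSEA
#'
#' Descending score order (score = log2FC); ties broken by ascending
#' feature id so the ranking is deterministic.
#'
#' @param stats data.frame with columns feature_id and log2fc.
#' @return named numeric vector of scores, names in rank order.
#' @export
rankFeatures <- function(stats) {
  if (nrow(stats) == 0L) stop("empty feature table")
  if (anyDuplicated(stats$feature_id))
    stop("duplicate feature id: ",
         stats$feature_id[duplicated(stats$feature_id)][1L])
  ord <- order(-stats$log2fc, stats$feature_id)
  setNames(stats$log2fc[ord], stats$feature_id[ord])
}

## Running-sum ES for hit positions `pos` (sorted or not) in a list of
## length n with precomputed |score|^w weights. Increment at hits is the
## hit's weight / total hit weight; decrement elsewhere is 1/(n - #hits).
## Returns the signed extremum of largest magnitude and its position; an
## exact magnitude tie between the positive and negative excursions
## resolves to the positive one (tolerance guards float noise).
.esCore <- function(absw, pos, n) {
  k <- length(pos)
  delta <- rep.int(-1 / (n - k), n)
  wsum <- sum(absw[pos])
  if (wsum == 0) delta[pos] <- 1 / k else delta[pos] <- absw[pos] / wsum
  r <- cumsum(delta)
  maxP <- max(r); minP <- min(r)
  if (maxP >= -minP - 1e-9) c(maxP, which.max(r))
  else c(minP, which.min(r))
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list adding |score|^weightExponent (normalized over
#' member hits) at member positions and subtracting 1/(N - N_hits)
#' elsewhere; the ES is the signed extremum of largest magnitude. The
#' leading edge holds the members at or before (positive ES) / at or after
#' (negative ES) the extremum.
#'
#' @param ranked named numeric vector of scores in rank order (from
#'   [rankFeatures()]).
#' @param members character vector of member feature ids.
#' @param weightExponent exponent on |score| for hit increments (0 =
#'   unweighted Kolmogorov-Smirnov walk; default 1).
#' @return list with \code{es} (in [-1, 1]) and \code{leadingEdge}.
#' @export
enrichmentScore <- function(ranked, members, weightExponent = 1) {
  n <- length(ranked)
  pos <- which(names(ranked) %in% members)
  if (length(pos) == 0L) stop("no members present in the ranked list")
  if (length(pos) == n) stop("members cover the entire ranked list")
  absw <- abs(ranked)^weightExponent
  es <- .esCore(absw, pos, n)
  le <- if (es[1L] >= 0) pos[pos <= es[2L]] else pos[pos >= es[2L]]
  list(es = es[1L], leadingEdge = names(ranked)[le])
}

#' Preranked geneset enrichment with a permutation null
#'
#' For every set within the size bounds, computes the observed running-sum
#' ES, then a null of \code{nPerm} random member-position placements
#' (scores held fixed). The permutation p-value is one-tailed on the
#' observed sign: p = (1 + #\{same-sign null with |ES| >= |obs|\}) /
#' (1 + #\{same-sign null\}); NES = ES / mean(|same-sign null ES|); FDR is
#' BH across sets. Fully reproducible given \code{seed}.
#'
#' @param ranked named score vector in rank order (see [rankFeatures()]).
#' @param collection a [GeneSetCollection-class].
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param minSize,maxSize set size bounds (on members present in the
#'   ranked list), inclusive.
#' @param weightExponent exponent on |score| (see [enrichmentScore()]).
#' @param exhaustive if TRUE the null enumerates every distinct member
#'   placement (feasible only for small instances, choose(N, k) <= 1e4)
#'   instead of sampling \code{nPerm} of them; \code{nPerm} and
#'   \code{seed} are then ignored.
#' @return data.frame with set_name, size, es, nes, p_value, fdr,
#'   core_members (semicolon-joined leading edge).
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000L, seed = 1L,
                          minSize = 5L, maxSize = 500L, weightExponent = 1,
                          exhaustive = FALSE) {
  stopifnot(exhaustive || nPerm >= 100L)
  n <- length(ranked)
  absw <- abs(ranked)^weightExponent
  sets <- geneSets(collection)
  keep <- vapply(sets, function(s) {
    k <- sum(names(ranked) %in% s)
    k >= minSize && k <= maxSize && k < n
  }, TRUE)
  if (!any(keep)) stop("no sets within size bounds")
  sets <- sets[keep]
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    obs <- enrichmentScore(ranked, sets[[nm]], weightExponent)
    k <- sum(names(ranked) %in% sets[[nm]])
    null <- if (exhaustive) {
      if (choose(n, k) > 1e4)
        stop("exhaustive null infeasible: choose(", n, ", ", k, ") > 1e4")
      apply(combn(n, k), 2L, function(pos) .esCore(absw, pos, n)[1L])
    } else {
      vapply(seq_len(nPerm), function(i) {
        .esCore(absw, sample.int(n, k), n)[1L]
      }, 0)
    }
    same <- if (obs$es >= 0) null >= 0 else null < 0
    p <- (1 + sum(same & abs(null) >= abs(obs$es))) / (1 + sum(same))
    nes <- if (any(same)) obs$es / mean(abs(null[same])) else NA_real_
    data.frame(set_name = nm, size = k, es = obs$es, nes = nes,
               p_value = p,
               core_members = paste(obs$leadingEdge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p_value)
  out[, c("set_name", "size", "es", "nes", "p_value", "fdr", "core_members")]
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability P(X >= overlap) for the overlap between a
#' significant-feature list and a pathway, under sampling without
#' replacement from the universe.
#'
#' @param significant character vector of significant feature ids
#'   (subset of \code{universe}).
#' @param universe character vector of all testable feature ids.
#' @param members pathway members (subset of \code{universe}).
#' @return list with \code{overlap} (integer) and \code{p_value}.
#' @export
oraHypergeometric <- function(significant, universe, members) {
  significant <- unique(significant); universe <- unique(universe)
  members <- unique(members)
  if (length(setdiff(members, universe)))
    stop("members must be a subset of the universe")
  if (length(setdiff(significant, universe)))
    stop("significant features must be a subset of the universe")
  ov <- length(intersect(significant, members))
  p <- phyper(ov - 1L, length(members),
              length(universe) - length(members),
              length(significant), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}

#' Cluster enriched pathways by Jaccard similarity of their hits
#'
#' Builds a graph over enriched pathways with an edge whenever the Jaccard
#' index of their significant members reaches \code{threshold}; connected
#' components of size >= 2 become clusters, singletons stay unassigned.
#' Mirrors the grouping style of metabolite-pathway databases that report
#' pathway clusters alongside unassigned pathways.
#'
#' @param sigMembers named list: pathway name -> character vector of its
#'   significant members (e.g. the ORA overlap or GSEA leading edge).
#' @param threshold Jaccard threshold in (0, 1].
#' @return list with \code{clusters} (list of character vectors of pathway
#'   names), \code{unassigned} (character vector) and \code{threshold}.
#' @export
clusterEnrichedPathways <- function(sigMembers, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  nms <- names(sigMembers)
  if (length(sigMembers) == 0L)
    return(list(clusters = list(), unassigned = character(),
                threshold = threshold))
  nms <- sort(nms)
  sigMembers <- sigMembers[nms]
  edges <- NULL
  if (length(nms) >= 2L) {
    pairs <- combn(seq_along(nms), 2L)
    jac <- apply(pairs, 2L, function(ij) {
      a <- sigMembers[[ij[1L]]]; b <- sigMembers[[ij[2L]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    hit <- jac >= threshold
    if (any(hit))
      edges <- cbind(nms[pairs[1L, hit]], nms[pairs[2L, hit]])
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else as.data.frame(edges),
    directed = FALSE, vertices = nms)
  comp <- igraph::components(g)
  groups <- split(nms, comp$membership[nms])
  clusters <- Filter(function(x) length(x) >= 2L, groups)
  names(clusters) <- NULL
  clusters <- clusters[order(vapply(clusters, `[[`, "", 1L))]
  list(clusters = lapply(clusters, sort),
       unassigned = sort(as.character(
         unlist(Filter(function(x) length(x) == 1L, groups),
                use.names = FALSE))),
       threshold = threshold)
}
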