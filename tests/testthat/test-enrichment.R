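test_that("GMT parsing collapses duplicates and flags malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tG1\tG2", "P2\tdesc\tG1\tG1"), path)
  gs <- readGMT(path)
  expect_identical(length(gs), 2L)
  expect_identical(geneSets(gs)$P1, c("G1", "G2"))
  expect_identical(geneSets(gs)$P2, "G1")

  writeLines(c("P1\tdesc\tG1", "short\tonly"), path)
  expect_error(readGMT(path), "line 2")
  writeLines(c("P1\tdesc\tG1", "P1\tdesc\tG2"), path)
  expect_error(readGMT(path), "duplicate set name")

  # write/read round trip
  writeGMT(gs, path)
  expect_equal(geneSets(readGMT(path)), geneSets(gs))
})

test_that("feature ranking is descending with deterministic ties", {
  tab <- data.frame(feature_id = c("A", "B", "C"), log2fc = c(2, -1, 3))
  expect_identical(names(rankFeatures(tab)), c("C", "A", "B"))
  tie <- data.frame(feature_id = c("B", "A"), log2fc = c(1, 1))
  expect_identical(names(rankFeatures(tie)), c("A", "B"))
  expect_error(rankFeatures(tab[0, ]), "empty")
  expect_error(rankFeatures(data.frame(feature_id = c("A", "A"),
                                       log2fc = 1:2)), "duplicate")
})

test_that("enrichment score matches worked extremes and the brute oracle", {
  ranked <- c(f1 = 4, f2 = 3, f3 = 2, f4 = 1)
  top <- enrichmentScore(ranked, "f1")
  expect_equal(top$es, 1)
  expect_identical(top$leadingEdge, "f1")
  bottom <- enrichmentScore(ranked, "f4")
  expect_equal(bottom$es, -1)
  expect_identical(bottom$leadingEdge, "f4")
  expect_error(enrichmentScore(ranked, names(ranked)), "entire")
  expect_error(enrichmentScore(ranked, "nope"), "no members")

  set.seed(17)
  for (i in 1:150) {
    n <- sample(5:60, 1)
    scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", sample.int(999, n))
    k <- sample(1:(n - 1), 1)
    members <- sample(names(scores), k)
    w <- sample(c(0, 1, 2), 1)
    expect_equal(enrichmentScore(scores, members, w)$es,
                 esBruteForce(scores, members, w), tolerance = 1e-12)
  }
})

test_that("preranked GSEA is reproducible and exhaustive null enumerates", {
  set.seed(4)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:50)
  gs <- GeneSetCollection(list(S1 = names(scores)[c(1:4, 9)],
                               S2 = sample(names(scores), 10)))
  a <- gseaPreranked(scores, gs, nPerm = 200, seed = 7)
  b <- gseaPreranked(scores, gs, nPerm = 200, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(a$es) <= 1))
  expect_true(all(a$p_value >= 0 & a$p_value <= 1))

  # exhaustive null over all 4 singleton placements: same-sign nulls are
  # ES = 1 (obs) and 2/3, so p = (1 + 1)/(1 + 2)
  ranked <- c(f1 = 4, f2 = 3, f3 = 2, f4 = 1)
  one <- GeneSetCollection(list(S = "f1"))
  ex <- gseaPreranked(ranked, one, minSize = 1, exhaustive = TRUE)
  expect_equal(ex$es, 1)
  expect_equal(ex$p_value, 2 / 3, tolerance = 1e-12)

  expect_error(gseaPreranked(scores, GeneSetCollection(list(S = "g01")),
                             nPerm = 200), "size bounds")
})

test_that("hypergeometric ORA equals the combinatorial tail", {
  u <- sprintf("g%02d", 1:10)
  r <- oraHypergeometric(u[1:4], u, u[1:5])
  expect_identical(r$overlap, 4L)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)

  expect_equal(oraHypergeometric(character(), u, u[1:5])$p_value, 1)
  expect_equal(oraHypergeometric(u, u, u[1:5])$p_value, 1)
  expect_error(oraHypergeometric(c("zz"), u, u[1:3]), "subset")
  expect_error(oraHypergeometric(u[1:2], u, c(u[1:3], "zz")), "subset")

  # exhaustive small configurations against the explicit sum
  for (N in c(4, 7, 9)) {
    uu <- sprintf("x%02d", seq_len(N))
    for (K in 0:N) for (n in 0:N) {
      sig <- uu[seq_len(n)]
      r <- oraHypergeometric(sig, uu, uu[seq_len(K)])
      expect_equal(r$p_value, hyperTailSum(r$overlap, N, K, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("pathway clustering follows Jaccard components", {
  twin <- list(P1 = c("m1", "m2"), P2 = c("m1", "m2"))
  cl <- clusterEnrichedPathways(twin, 0.5)
  expect_identical(cl$clusters, list(c("P1", "P2")))
  expect_identical(cl$unassigned, character())

  disjoint <- list(P1 = "a", P2 = "b", P3 = "c")
  cl2 <- clusterEnrichedPathways(disjoint, 0.2)
  expect_identical(cl2$clusters, list())
  expect_identical(cl2$unassigned, c("P1", "P2", "P3"))

  # A~B and B~C at 0.6, A~C at 0.1: one transitive cluster at 0.5
  chain <- list(A = c("1", "2", "3", "4", "6"),
                B = c("1", "2", "3", "4", "5"),
                C = c("2", "3", "4", "5", "7"))
  j <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(j(chain$A, chain$B), 0.5)
  expect_gte(j(chain$B, chain$C), 0.5)
  expect_lt(j(chain$A, chain$C), 0.5)
  cl3 <- clusterEnrichedPathways(chain, 0.5)
  expect_identical(cl3$clusters, list(c("A", "B", "C")))

  # order invariance
  cl4 <- clusterEnrichedPathways(rev(chain), 0.5)
  expect_identical(cl3$clusters, cl4$clusters)
  expect_identical(clusterEnrichedPathways(list(), 0.5)$clusters, list())
})

test_that("enrichment score agrees with fgsea on tie-free instances", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    scores <- sort(rnorm(n, sd = 1.5), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", 1:n)
    k <- sample(2:(n - 2), 1)
    members <- sample(names(scores), k)
    ours <- enrichmentScore(scores, members, weightExponent = 1)$es
    ref <- fgsea::calcGseaStat(scores,
                               selectedStats = which(names(scores) %in%
                                                       members),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})
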