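# Small in-code fixtures shared across test files.

tinyOmics <- function(values = matrix(c(1, 3, 2, 4), 2,
                                      dimnames = list(c("G1", "G2"),
                                                      c("s1", "s2"))),
                      layer = "transcript",
                      condition = c(s1 = "WT", s2 = "KO"), ...) {
  OmicsMatrix(values, layer, condition, ...)
}

# Two-condition matrix with nReps replicates per condition.
repOmics <- function(wt, ko, layer = "transcript", ...) {
  v <- cbind(wt, ko)
  colnames(v) <- c(paste0("WT_", seq_len(ncol(wt))),
                   paste0("KO_", seq_len(ncol(ko))))
  cond <- setNames(rep(c("WT", "KO"), c(ncol(wt), ncol(ko))),
                   colnames(v))
  OmicsMatrix(v, layer, cond, ...)
}

# The worked path instance A(5) - B(0) - C(5) with both edge costs 0.4.
pathABC <- function() {
  net <- interactionNetwork(
    data.frame(node_id = c("A", "B", "C"), node_type = "gene",
               prize = c(5, 0, 5)),
    data.frame(u = c("A", "B"), v = c("B", "C"),
               confidence = c(0.6, 0.6)))
  edgeCostsFromConfidence(net)
}
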