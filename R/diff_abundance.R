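#' Per-feature log2 fold change (KO relative to WT)
#'
#' For every feature, the mean of log2(x + pseudocount) over KO samples
#' minus the same mean over WT samples. The pseudocount keeps features
#' detected in only one condition usable (presence/absence signal) instead
#' of dropping them.
#'
#' @param x an [OmicsMatrix-class].
#' @param pseudocount positive value added before the log transform.
#' @return named numeric vector of log2 fold changes.
#' @export
computeLog2FC <- function(x, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  cond <- conditionLabels(x)
  if (!all(.CONDITIONS %in% cond))
    stop("both WT and KO samples are required")
  lv <- log2(SummarizedExperiment::assay(x) + pseudocount)
  rowMeans(lv[, cond == "KO", drop = FALSE]) -
    rowMeans(lv[, cond == "WT", drop = FALSE])
}

## Vectorized Welch statistics over the rows of a (transformed) matrix.
## Returns t, df and two-sided p per row. Degenerate rows (zero variance in
## both groups) follow the documented convention: equal means -> p = 1,
## unequal means -> p = 0.
.welchRows <- function(lv, cond) {
  ko <- lv[, cond == "KO", drop = FALSE]
  wt <- lv[, cond == "WT", drop = FALSE]
  n1 <- ncol(ko); n2 <- ncol(wt)
  if (n1 < 2L || n2 < 2L)
    stop("Welch test needs >= 2 samples per condition")
  m1 <- rowMeans(ko); m2 <- rowMeans(wt)
  v1 <- rowSums((ko - m1)^2) / (n1 - 1L)
  v2 <- rowSums((wt - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
    df[degen] <- NA_real_
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  }
  list(t = t, df = df, p = p)
}

#' Welch's unequal-variance t-test for one feature
#'
#' Two-sided Welch t-test on log2(x + pseudocount)-transformed values,
#' KO vs WT, with Welch-Satterthwaite degrees of freedom. With zero
#' variance in both groups the convention is p = 1 for equal means and
#' p = 0 otherwise.
#'
#' @param x an [OmicsMatrix-class].
#' @param featureId feature to test.
#' @param pseudocount positive value added before the log transform.
#' @return list with elements \code{t}, \code{df}, \code{p_value}.
#' @export
welchTest <- function(x, featureId, pseudocount = 1) {
  if (!featureId %in% rownames(x)) stop("unknown feature: ", featureId)
  lv <- log2(SummarizedExperiment::assay(x)[featureId, , drop = FALSE] +
               pseudocount)
  r <- .welchRows(lv, conditionLabels(x))
  list(t = unname(r$t), df = unname(r$df), p_value = unname(r$p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving wrapper around \code{stats::p.adjust(method = "BH")}
#' with input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance calls from FDR and fold-change thresholds
#'
#' Sets \code{significant := (fdr < alpha) & (|log2fc| >= minAbsLfc)}; the
#' FDR inequality is strict.
#'
#' @param stats data.frame with columns \code{log2fc} and \code{fdr}.
#' @param alpha FDR threshold (strict).
#' @param minAbsLfc minimum absolute log2 fold change (inclusive).
#' @return \code{stats} with a logical \code{significant} column.
#' @export
callSignificant <- function(stats, alpha = 0.05, minAbsLfc = 1) {
  stats$significant <- (stats$fdr < alpha) & (abs(stats$log2fc) >= minAbsLfc)
  stats
}

#' Differential abundance for one omics layer
#'
#' Computes per-feature log2 fold change (KO vs WT) on
#' log2(x + pseudocount), a Welch t-test p-value, BH-adjusted FDR and a
#' significance call. This surrogate test is recorded in the \code{test}
#' column so externally computed DE tables (e.g. a negative-binomial fit)
#' can be imported interchangeably via [readFeatureStats()].
#'
#' @param x an [OmicsMatrix-class] with >= 2 samples per condition.
#' @param pseudocount positive value added before the log transform.
#' @param alpha FDR threshold for the significance call (strict).
#' @param minAbsLfc minimum |log2FC| for the significance call.
#' @return data.frame with columns feature_id, layer, log2fc, p_value,
#'   fdr, significant, test.
#' @export
diffAbundance <- function(x, pseudocount = 1, alpha = 0.05, minAbsLfc = 1) {
  cond <- conditionLabels(x)
  lv <- log2(SummarizedExperiment::assay(x) + pseudocount)
  w <- .welchRows(lv, cond)
  out <- data.frame(
    feature_id = rownames(x),
    layer = layerType(x),
    log2fc = unname(computeLog2FC(x, pseudocount)),
    p_value = unname(w$p),
    fdr = unname(bhAdjust(w$p)),
    stringsAsFactors = FALSE)
  out <- callSignificant(out, alpha, minAbsLfc)
  out$test <- "welch_log2"
  out
}

#' Write a differential-abundance table as TSV
#' @param stats data.frame as returned by [diffAbundance()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureStats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-abundance table (own or external)
#'
#' Accepts any TSV with at least the columns feature_id, layer, log2fc,
#' p_value, fdr, significant — including tables produced by other DE tools,
#' so a negative-binomial fit can replace the built-in Welch surrogate.
#'
#' @param path TSV path.
#' @return data.frame of feature statistics.
#' @export
readFeatureStats <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("feature_id", "layer", "log2fc", "p_value", "fdr", "significant")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  tab$significant <- as.logical(tab$significant)
  tab
}
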