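#' Read a feature x sample abundance table
#'
#' Reads a tab-separated matrix (first column = feature id, header row =
#' sample ids; decimal point, no thousands separators) into an
#' [OmicsMatrix-class]. Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @param layer one of "transcript", "protein", "metabolite".
#' @param conditionMap named character vector (or two-column data.frame
#'   sample_id, condition) assigning WT/KO to every sample in the header.
#' @param proteinLengths optional named numeric vector of amino-acid
#'   lengths (protein layer).
#' @return an [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(path, layer, conditionMap, proteinLengths = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("matrix file needs a feature column and >= 1 sample")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  rownames(num) <- ids
  if (is.data.frame(conditionMap))
    conditionMap <- setNames(as.character(conditionMap[[2L]]),
                             as.character(conditionMap[[1L]]))
  missing <- setdiff(colnames(num), names(conditionMap))
  if (length(missing))
    stop("sample(s) missing from condition map: ",
         paste(missing, collapse = ", "))
  OmicsMatrix(num, layer, conditionMap[colnames(num)],
              proteinLengths = proteinLengths)
}

#' Write an OmicsMatrix as a tab-separated table
#'
#' Inverse of [readOmicsMatrix()]: feature ids in the first column
#' (\code{feature_id}), one column per sample. Values are written with 15
#' significant digits so a read/write round trip is lossless.
#'
#' @param x an [OmicsMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- SummarizedExperiment::assay(x)
  out <- data.frame(feature_id = rownames(v),
                    format(v, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate transcript-level TPM to gene level
#'
#' Gene expression is the sum of its transcripts' TPM in each sample, so
#' per-sample totals are conserved exactly.
#'
#' @param x transcript-layer [OmicsMatrix-class] of TPM values.
#' @param tx2gene named character vector (or two-column data.frame
#'   transcript_id, gene_id) mapping every transcript to a gene.
#' @return a transcript-layer OmicsMatrix with one row per gene.
#' @export
geneTpmFromTranscripts <- function(x, tx2gene) {
  if (is.data.frame(tx2gene))
    tx2gene <- setNames(as.character(tx2gene[[2L]]),
                        as.character(tx2gene[[1L]]))
  v <- SummarizedExperiment::assay(x)
  missing <- setdiff(rownames(v), names(tx2gene))
  if (length(missing))
    stop("transcript(s) missing from tx2gene: ",
         paste(head(missing, 5L), collapse = ", "))
  genes <- tx2gene[rownames(v)]
  agg <- rowsum(v, group = genes, reorder = FALSE)
  OmicsMatrix(agg, "transcript", conditionLabels(x))
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Length-normalizes spectral counts and rescales each sample to sum to 1:
#' NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j), computed per sample.
#'
#' @param x protein-layer [OmicsMatrix-class] of spectral counts with
#'   protein lengths available via [proteinLengths()].
#' @return a protein-layer OmicsMatrix of NSAF values (columns sum to 1).
#' @export
nsafNormalize <- function(x) {
  lens <- proteinLengths(x)
  if (is.null(lens)) stop("protein lengths are required for NSAF")
  if (any(!is.finite(lens) | lens <= 0))
    stop("protein lengths must be positive: ",
         paste(names(lens)[!is.finite(lens) | lens <= 0], collapse = ", "))
  v <- SummarizedExperiment::assay(x)
  saf <- v / lens
  tot <- colSums(saf)
  if (any(tot == 0))
    stop("all-zero spectral counts in sample(s): ",
         paste(colnames(v)[tot == 0], collapse = ", "))
  OmicsMatrix(sweep(saf, 2L, tot, "/"), "protein", conditionLabels(x),
              proteinLengths = lens)
}
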