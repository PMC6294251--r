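#' TrendAnnotation: a poly(A)-site isoform annotation
#'
#' Container for a set of 3' end (poly(A)-site-defined) transcript isoforms.
#' Each isoform is a width-1 genomic position (the cleavage site, i.e. the
#' last transcribed nucleotide) with metadata columns: \code{isoform_id},
#' \code{gene_id}, \code{class} (one of \code{tandem}, \code{internal},
#' \code{novel}, \code{non_coding}), \code{rank_3p} (1 = most proximal within
#' the gene, ordered 5' to 3'), \code{support} (PASS read support) and
#' \code{ip_flag} (internal-priming flag).
#'
#' @slot sites A [GenomicRanges::GRanges] of width-1 cleavage-site positions
#'   with the metadata columns listed above.
#' @seealso [buildTrendAnnotation()], [assignSitesToGenes()]
#' @export
setClass("TrendAnnotation", representation(sites = "GRanges"))

setValidity("TrendAnnotation", function(object) {
  gr <- object@sites
  need <- c("isoform_id", "gene_id", "class", "rank_3p", "support", "ip_flag")
  miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
  if (length(miss))
    return(paste("missing site metadata column(s):", paste(miss, collapse = ", ")))
  if (length(gr)) {
    if (any(GenomicRanges::width(gr) != 1L))
      return("sites must be width-1 cleavage positions")
    if (anyDuplicated(gr$isoform_id))
      return("isoform_id values must be unique")
    bad <- !gr$class %in% c("tandem", "internal", "novel", "non_coding")
    if (any(bad))
      return("invalid isoform class(es)")
    rk <- split(gr$rank_3p, gr$gene_id)
    ok <- vapply(rk, function(r) setequal(r, seq_along(r)), logical(1))
    if (!all(ok))
      return("rank_3p within each gene must be a permutation of 1..k")
  }
  TRUE
})

#' Construct a TrendAnnotation
#'
#' @param sites A GRanges of width-1 cleavage sites carrying the metadata
#'   columns documented in [TrendAnnotation-class].
#' @return A [TrendAnnotation-class] object.
#' @export
TrendAnnotation <- function(sites) {
  if (is.null(sites$support)) sites$support <- NA_integer_
  if (is.null(sites$ip_flag)) sites$ip_flag <- NA
  new("TrendAnnotation", sites = sites)
}

#' @describeIn TrendAnnotation-class number of isoforms
#' @param x,object A TrendAnnotation.
#' @export
setMethod("length", "TrendAnnotation", function(x) length(x@sites))

#' Accessors for TrendAnnotation
#'
#' \code{trendSites()} returns the underlying GRanges; \code{isoformId()},
#' \code{geneId()}, \code{isoformClass()}, \code{siteRank()}, \code{ipFlag()}
#' return the corresponding per-isoform metadata.
#'
#' @param x A [TrendAnnotation-class].
#' @return \code{trendSites}: a GRanges; the others: vectors parallel to the
#'   isoforms.
#' @name trend-accessors
#' @export
trendSites <- function(x) x@sites

#' @rdname trend-accessors
#' @export
isoformId <- function(x) x@sites$isoform_id

#' @rdname trend-accessors
#' @export
geneId <- function(x) x@sites$gene_id

#' @rdname trend-accessors
#' @export
isoformClass <- function(x) x@sites$class

#' @rdname trend-accessors
#' @export
siteRank <- function(x) x@sites$rank_3p

#' @rdname trend-accessors
#' @export
ipFlag <- function(x) x@sites$ip_flag

setMethod("show", "TrendAnnotation", function(object) {
  gr <- object@sites
  cat("TrendAnnotation with", length(gr), "isoforms in",
      length(unique(gr$gene_id)), "genes\n")
  if (length(gr)) {
    cat("  classes:", paste(sprintf("%s=%d", names(table(gr$class)),
                                    as.integer(table(gr$class))), collapse = " "), "\n")
    cat("  internal-priming flagged:", sum(gr$ip_flag %in% TRUE), "\n")
  }
  invisible(NULL)
})

setAs("TrendAnnotation", "GRanges", function(from) from@sites)

#' TrendCounts: isoform x sample read counts
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]; rows are
#' annotated 3' end isoforms (rowRanges carry the cleavage sites and isoform
#' metadata of the originating [TrendAnnotation-class]), columns are samples,
#' and the \code{"counts"} assay holds non-negative integer read counts.
#' Per-sample QC tallies (assigned / ambiguous / no_feature / ip_removed) live
#' in \code{metadata(x)$qc}.
#'
#' @export
setClass("TrendCounts", contains = "RangedSummarizedExperiment")

setValidity("TrendCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  need <- c("isoform_id", "gene_id", "rank_3p", "class")
  miss <- setdiff(need, colnames(S4Vectors::mcols(SummarizedExperiment::rowRanges(object))))
  if (length(miss))
    return(paste("missing rowRanges column(s):", paste(miss, collapse = ", ")))
  TRUE
})

#' Construct a TrendCounts object
#'
#' @param counts Integer matrix of read counts, isoforms in rows, samples in
#'   columns; rownames are isoform ids.
#' @param rowRanges GRanges of cleavage sites parallel to the rows (from a
#'   [TrendAnnotation-class]).
#' @param colData Optional DataFrame of sample annotation.
#' @param qc Optional per-sample QC data.frame stored in the metadata.
#' @return A [TrendCounts-class] object.
#' @export
TrendCounts <- function(counts, rowRanges, colData = NULL, qc = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- rowRanges$isoform_id
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(sample_id = colnames(counts),
                                    row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = rowRanges, colData = colData)
  obj <- new("TrendCounts", se)
  if (!is.null(qc))
    S4Vectors::metadata(obj)$qc <- qc
  obj
}

#' @describeIn TrendCounts-class the counts assay
#' @param object A TrendCounts.
#' @export
setGeneric("trendCounts", function(object) standardGeneric("trendCounts"))

#' @rdname TrendCounts-class
#' @export
setMethod("trendCounts", "TrendCounts",
          function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "TrendCounts", function(object) {
  callNextMethod()
  qc <- S4Vectors::metadata(object)$qc
  if (!is.null(qc))
    cat("QC tallies available via metadata(x)$qc\n")
  invisible(NULL)
})

#' TrendTestResult: differential 3' end usage test results
#'
#' Result container for [testTrend()].  \code{isoformResults(x)} is a
#' data.frame with one row per tested isoform (Fisher p, BH-adjusted p,
#' per-condition isoform percentages, fold-regulation, position relative to
#' the Zero-isoform); \code{geneResults(x)} has one row per gene
#' (Zero-isoform, log2 shortening index \code{si}, direction).
#'
#' @slot isoformResults data.frame of per-isoform results.
#' @slot geneResults data.frame of per-gene summaries.
#' @slot alpha Significance threshold used (BH-adjusted p).
#' @slot contrast Character vector \code{c(kd, ctrl)} naming the compared
#'   conditions.
#' @export
setClass("TrendTestResult",
         representation(isoformResults = "data.frame",
                        geneResults = "data.frame",
                        alpha = "numeric",
                        contrast = "character"))

#' @rdname TrendTestResult-class
#' @param x A TrendTestResult.
#' @export
isoformResults <- function(x) x@isoformResults

#' @rdname TrendTestResult-class
#' @export
geneResults <- function(x) x@geneResults

setMethod("show", "TrendTestResult", function(object) {
  ir <- object@isoformResults
  gr <- object@geneResults
  cat(sprintf("TrendTestResult: %s vs %s\n", object@contrast[1], object@contrast[2]))
  cat(sprintf("  %d isoforms tested in %d genes; %d isoforms with p_adj <= %g\n",
              nrow(ir), length(unique(ir$gene_id)),
              sum(ir$p_adj <= object@alpha, na.rm = TRUE), object@alpha))
  cat(sprintf("  genes shortened: %d, lengthened: %d\n",
              sum(gr$direction == "shortened", na.rm = TRUE),
              sum(gr$direction == "lengthened", na.rm = TRUE)))
  invisible(NULL)
})

#' RocResult: a receiver-operating characteristic curve
#'
#' @slot auc Area under the curve (normalized Mann-Whitney statistic, ties
#'   counted one half).
#' @slot scores,labels The underlying per-sample scores and binary labels
#'   (kept for paired AUC comparison).
#' @slot curve data.frame of (threshold, fpr, tpr) points.
#' @slot nPos,nNeg Class sizes.
#' @export
setClass("RocResult",
         representation(auc = "numeric", scores = "numeric", labels = "logical",
                        curve = "data.frame", nPos = "integer", nNeg = "integer"))

#' @rdname RocResult-class
#' @param x A RocResult.
#' @export
aucOf <- function(x) x@auc

#' @rdname RocResult-class
#' @export
rocCurve <- function(x) x@curve

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (%d positives, %d negatives)\n",
              object@auc, object@nPos, object@nNeg))
  invisible(NULL)
})
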