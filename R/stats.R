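# Statistical core: per-isoform Fisher exact tests against the gene's
# remaining isoforms, BH adjustment, percentage fold-regulation,
# Zero-isoform anchoring, shortening index, set enrichment.

#' Two-sided Fisher exact test for one isoform's usage
#'
#' Tests a 2x2 contingency table of (tested isoform, all other isoforms of
#' the same gene) x (knockdown, control) read counts.  The two-sided p-value
#' sums hypergeometric probabilities, at fixed margins, of all tables at most
#' as probable as the observed one (point-probability rule, the same rule as
#' \code{stats::fisher.test}).
#'
#' @param a,b Reads of the tested isoform / of all other isoforms in the
#'   knockdown sample.
#' @param c,d The same two counts in the control sample.
#' @return The two-sided p-value.
#' @examples
#' fisherIsoformTest(50, 50, 50, 50)  # identical proportions -> 1
#' @export
fisherIsoformTest <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0))
    stop("contingency cells must be non-negative")
  if ((a + b) <= 0 || (c + d) <= 0)
    stop("both condition margins must be positive")
  K <- a + c            # tested-isoform column total
  O <- b + d            # other-isoform column total
  nKD <- a + b          # knockdown row total
  if (K == 0 || O == 0)
    return(1)
  support <- max(0, nKD - O):min(K, nKD)
  probs <- dhyper(support, K, O, nKD)
  pObs <- dhyper(a, K, O, nKD)
  # relative tolerance absorbs floating-point ties between equal-probability tables
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percentage-normalized fold-regulation per isoform
#'
#' Within one gene, total reads per condition are normalized to 100% and the
#' fold-regulation of each isoform is its percentage in the knockdown divided
#' by its percentage in the control.  A pseudocount (default 0.5) is added to
#' every isoform count in both conditions before forming percentages, so that
#' unexpressed isoforms yield finite fold-regulations; the Fisher test never
#' sees the pseudocount.  The result is invariant to any per-condition
#' library scaling.
#'
#' @param countsKd,countsCtrl Integer vectors of per-isoform counts for one
#'   gene (parallel, length >= 2).
#' @param pseudocount Added to every isoform count in both conditions
#'   (default 0.5).
#' @return data.frame with columns \code{pct_kd}, \code{pct_ctrl}, \code{fc}
#'   and an attribute \code{untestable} (TRUE when a condition has zero total
#'   raw counts).
#' @export
foldRegulation <- function(countsKd, countsCtrl, pseudocount = 0.5) {
  if (length(countsKd) != length(countsCtrl))
    stop("count vectors must be parallel")
  if (length(countsKd) < 2L)
    stop("fold-regulation needs >= 2 isoforms")
  untestable <- sum(countsKd) == 0 || sum(countsCtrl) == 0
  kd <- countsKd + pseudocount
  ct <- countsCtrl + pseudocount
  pctKd <- 100 * kd / sum(kd)
  pctCt <- 100 * ct / sum(ct)
  out <- data.frame(pct_kd = pctKd, pct_ctrl = pctCt, fc = pctKd / pctCt)
  attr(out, "untestable") <- untestable
  out
}

#' The Zero-isoform of a gene
#'
#' The longest (strand-aware most 3'-distal) significantly affected
#' (\code{p_adj <= alpha}) and annotated isoform of a gene; \code{novel}
#' isoforms, which exceed the annotated gene 3' end, are excluded.  The
#' Zero-isoform anchors relative-position reporting.
#'
#' @param geneDf data.frame of one gene's isoform results with columns
#'   \code{isoform_id}, \code{class}, \code{pos}, \code{strand},
#'   \code{p_adj}.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return The Zero-isoform id, or \code{NA_character_} when no annotated
#'   isoform is significant.
#' @export
zeroIsoform <- function(geneDf, alpha = 0.05) {
  sig <- geneDf[!is.na(geneDf$p_adj) & geneDf$p_adj <= alpha &
                  geneDf$class != "novel", , drop = FALSE]
  if (!nrow(sig))
    return(NA_character_)
  distal <- if (sig$strand[1] == "-") which.min(sig$pos) else which.max(sig$pos)
  sig$isoform_id[distal]
}

#' Positions and fold-changes relative to the Zero-isoform
#'
#' Signed transcript-orientation distance (nt) of each significant isoform's
#' 3' end from the Zero-isoform (negative = upstream, i.e. a shorter
#' transcript), paired with its fold-regulation.
#'
#' @inheritParams zeroIsoform
#' @param zeroId Zero-isoform id (from [zeroIsoform()]).
#' @return data.frame with columns \code{isoform_id}, \code{rel_pos},
#'   \code{fc} for significant isoforms.
#' @export
relativeProfile <- function(geneDf, zeroId, alpha = 0.05) {
  if (is.na(zeroId))
    stop("Zero-isoform is undefined for this gene")
  zpos <- geneDf$pos[match(zeroId, geneDf$isoform_id)]
  sig <- geneDf[!is.na(geneDf$p_adj) & geneDf$p_adj <= alpha, , drop = FALSE]
  rel <- if (sig$strand[1] == "-") zpos - sig$pos else sig$pos - zpos
  data.frame(isoform_id = sig$isoform_id, rel_pos = rel, fc = sig$fc)
}

#' Log2 shortening index of a gene
#'
#' Summarizes a gene's overall shift towards shorter or longer 3' ends upon
#' perturbation through its two most significantly affected isoforms (ties
#' broken by smaller raw p, then more distal 3' end): the fold-regulation of
#' the shorter isoform of the pair normalized to that of the longer one, on
#' log2 scale.  Positive = relatively more of the shorter isoform in the
#' knockdown (3' UTR shortening); negative = lengthening.
#'
#' @inheritParams zeroIsoform
#' @return list with \code{si} (log2 shortening index) and \code{direction}
#'   (\code{"shortened"}, \code{"lengthened"} or \code{"none"}), or NULL when
#'   fewer than two isoforms are significant.
#' @export
shorteningIndex <- function(geneDf, alpha = 0.05) {
  sig <- geneDf[!is.na(geneDf$p_adj) & geneDf$p_adj <= alpha, , drop = FALSE]
  if (nrow(sig) < 2L)
    return(NULL)
  neg <- sig$strand[1] == "-"
  distalKey <- if (neg) -sig$pos else sig$pos  # larger = more distal
  ord <- order(sig$p_adj, sig$p, -distalKey)
  pair <- sig[ord[1:2], ]
  # order the pair 5'->3': shorter isoform first
  pairKey <- if (neg) -pair$pos else pair$pos
  pair <- pair[order(pairKey), ]
  si <- log2(pair$fc[1] / pair$fc[2])
  direction <- if (si > 0) "shortened" else if (si < 0) "lengthened" else "none"
  list(si = si, direction = direction)
}

#' Hypergeometric set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a hit set and a category, within a finite universe.
#'
#' @param hits,category Character vectors of gene ids, both subsets of
#'   \code{universe}.
#' @param universe Character vector of all eligible gene ids.
#' @return The enrichment p-value.
#' @export
setEnrichment <- function(hits, universe, category) {
  hits <- unique(hits); category <- unique(category); universe <- unique(universe)
  if (length(setdiff(hits, universe)))
    stop("hits must be a subset of the universe")
  if (length(setdiff(category, universe)))
    stop("category must be a subset of the universe")
  q <- length(intersect(hits, category))
  phyper(q - 1, length(category), length(universe) - length(category),
         length(hits), lower.tail = FALSE)
}

#' Differential 3' end isoform usage between two conditions
#'
#' The screen's per-comparison analysis: for every gene with at least two
#' isoforms and at least \code{minGeneReads} reads in each condition, each
#' isoform is Fisher-tested against the pooled remaining isoforms of its
#' gene ([fisherIsoformTest()]); p-values are BH-adjusted across all isoform
#' tests of the comparison; percentage fold-regulations are computed with
#' [foldRegulation()]; and per gene the Zero-isoform, relative positions and
#' the log2 shortening index are derived.
#'
#' @param tc A [TrendCounts-class].
#' @param kd,ctrl Column names (or indices) of the knockdown and control
#'   samples; multiple columns are pooled by summation.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param minGeneReads Minimum per-condition gene total for testability
#'   (default 10).
#' @param pseudocount Pseudocount for fold-regulation only (default 0.5).
#' @return A [TrendTestResult-class].
#' @export
testTrend <- function(tc, kd, ctrl, alpha = 0.05, minGeneReads = 10L,
                      pseudocount = 0.5) {
  stopifnot(is(tc, "TrendCounts"))
  cts <- trendCounts(tc)
  kdv <- if (length(kd) > 1L) rowSums(cts[, kd, drop = FALSE]) else cts[, kd]
  ctv <- if (length(ctrl) > 1L) rowSums(cts[, ctrl, drop = FALSE]) else cts[, ctrl]
  rr <- SummarizedExperiment::rowRanges(tc)
  info <- data.frame(isoform_id = rr$isoform_id, gene_id = rr$gene_id,
                     rank_3p = rr$rank_3p, class = rr$class,
                     pos = GenomicRanges::start(rr),
                     strand = as.character(GenomicRanges::strand(rr)),
                     kd = as.numeric(kdv), ctrl = as.numeric(ctv))

  res <- list()
  for (g in unique(info$gene_id)) {
    gi <- info[info$gene_id == g, , drop = FALSE]
    gi <- gi[order(gi$rank_3p), , drop = FALSE]
    if (nrow(gi) < 2L)
      next
    if (sum(gi$kd) < minGeneReads || sum(gi$ctrl) < minGeneReads)
      next
    fr <- foldRegulation(gi$kd, gi$ctrl, pseudocount)
    gi$p <- vapply(seq_len(nrow(gi)), function(i) {
      fisherIsoformTest(gi$kd[i], sum(gi$kd) - gi$kd[i],
                        gi$ctrl[i], sum(gi$ctrl) - gi$ctrl[i])
    }, numeric(1))
    gi$pct_kd <- fr$pct_kd
    gi$pct_ctrl <- fr$pct_ctrl
    gi$fc <- fr$fc
    res[[g]] <- gi
  }
  if (!length(res)) {
    empty <- data.frame()
    return(new("TrendTestResult", isoformResults = empty, geneResults = empty,
               alpha = alpha,
               contrast = c(paste(kd, collapse = "+"), paste(ctrl, collapse = "+"))))
  }
  iso <- do.call(rbind, res)
  rownames(iso) <- NULL
  iso$p_adj <- bhAdjust(iso$p)

  genes <- unique(iso$gene_id)
  iso$rel_pos <- NA_real_
  geneRows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    gi <- iso[iso$gene_id == g, , drop = FALSE]
    zid <- zeroIsoform(gi, alpha)
    si <- shorteningIndex(gi, alpha)
    if (!is.na(zid)) {
      rp <- relativeProfile(gi, zid, alpha)
      iso$rel_pos[match(rp$isoform_id, iso$isoform_id)] <- rp$rel_pos
    }
    geneRows[[k]] <- data.frame(
      gene_id = g, n_isoforms = nrow(gi),
      n_significant = sum(gi$p_adj <= alpha),
      zero_isoform = zid,
      si = if (is.null(si)) NA_real_ else si$si,
      direction = if (is.null(si)) "none" else si$direction)
  }
  geneDf <- do.call(rbind, geneRows)
  ord <- order(iso$gene_id, iso$rank_3p)
  iso <- iso[ord, c("isoform_id", "gene_id", "rank_3p", "class", "pos",
                    "strand", "kd", "ctrl", "p", "p_adj", "pct_kd",
                    "pct_ctrl", "fc", "rel_pos")]
  rownames(iso) <- NULL
  geneDf <- geneDf[order(geneDf$gene_id), ]
  rownames(geneDf) <- NULL
  new("TrendTestResult", isoformResults = iso, geneResults = geneDf,
      alpha = alpha,
      contrast = c(paste(kd, collapse = "+"), paste(ctrl, collapse = "+")))
}
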