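# Annotation assembly: PASS filtering, site clustering, gene assignment,
# isoform classification and internal-priming flagging.

#' Filter poly(A)-site-supporting (PASS) reads
#'
#' A 3' end read supports a genuine cleavage/polyadenylation event only when
#' its soft-clipped terminal adenosines cannot be explained by the genome:
#' the number of untemplated A's (soft-clipped A count minus the run of
#' genome-templated A's immediately downstream of the alignment 3' end) must
#' reach \code{minUntemplatedA}.
#'
#' @param reads GRanges of aligned 3' end reads with metadata columns
#'   \code{read_id} and \code{soft_tail_A} (the adapter/trimming-derived count
#'   of terminal A's not aligned to the genome).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param minUntemplatedA Minimum number of untemplated terminal A's
#'   (default 2).
#' @return The retained reads, input order preserved.
#' @export
filterPassReads <- function(reads, genome, minUntemplatedA = 2L) {
  .checkContigs(reads, genome)
  tail <- reads$soft_tail_A
  if (is.null(tail))
    stop("reads must carry a 'soft_tail_A' metadata column")
  keep <- tail >= minUntemplatedA
  idx <- which(keep)
  if (length(idx)) {
    down <- .downstreamSeq(genome,
                           GenomicRanges::seqnames(reads)[idx],
                           GenomicRanges::strand(reads)[idx],
                           .end3p(reads)[idx],
                           tail[idx])
    templated <- pmin(.leadingA(down), tail[idx])
    keep[idx] <- (tail[idx] - templated) >= minUntemplatedA
  }
  reads[keep]
}

#' Cluster read 3' ends into poly(A) sites
#'
#' Single-linkage clustering of PASS-read 3'-terminal coordinates per
#' contig and strand: neighbouring coordinates at gap <= \code{window} join
#' one cluster.  Each cluster is summarized by its modal coordinate (ties
#' resolved to the strand-aware downstream-most mode) and its read support;
#' clusters below \code{minSupport} are dropped.
#'
#' @param passReads GRanges of PASS-filtered reads.
#' @param window Maximum gap (nt) joining neighbouring read ends (default 25).
#' @param minSupport Minimum PASS reads per retained site (default 2).
#' @return GRanges of width-1 sites with columns \code{support} and
#'   \code{ip_flag} (NA until [flagInternalPriming()] is applied).
#' @export
clusterSites <- function(passReads, window = 25L, minSupport = 2L) {
  if (window < 0)
    stop("'window' must be non-negative")
  ends <- .end3p(passReads)
  key <- paste(as.character(GenomicRanges::seqnames(passReads)),
               as.character(GenomicRanges::strand(passReads)), sep = "\r")
  out <- list()
  for (k in unique(key)) {
    pos <- sort(ends[key == k])
    if (!length(pos)) next
    grp <- cumsum(c(0L, as.integer(diff(pos) > window)))
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < minSupport) next
      tab <- table(p)
      modes <- as.integer(names(tab)[tab == max(tab)])
      site <- if (parts[2] == "-") min(modes) else max(modes)
      out[[length(out) + 1L]] <- data.frame(
        contig = parts[1], strand = parts[2], pos = site, support = length(p))
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(support = integer(), ip_flag = logical()))
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$pos, df$pos),
                               strand = df$strand)
  gr$support <- df$support
  gr$ip_flag <- NA
  sort(gr, ignore.strand = TRUE)
}

#' Classify a 3' end isoform relative to its gene model
#'
#' Classes follow the usual 3' end taxonomy: sites in non-coding genes are
#' \code{non_coding}; sites strand-aware beyond the annotated gene 3' end are
#' \code{novel}; sites between the stop codon boundary and the annotated 3'
#' end are \code{tandem} (alternative 3' UTR length); sites upstream of the
#' stop codon are \code{internal} (altered protein C-terminus).
#'
#' @param pos Integer vector of cleavage-site positions (1-based, last
#'   transcribed base).
#' @param gene A length-1 GRanges gene span with metadata columns
#'   \code{gene_id}, \code{biotype} (\code{coding}/\code{non_coding}) and
#'   \code{cds_end} (strand-aware 1-based coordinate of the last coding base;
#'   NA for non-coding genes).
#' @return Character vector of classes.
#' @export
classifyIsoform <- function(pos, gene) {
  stopifnot(length(gene) == 1L)
  if (identical(gene$biotype, "non_coding"))
    return(rep("non_coding", length(pos)))
  cds <- gene$cds_end
  if (is.null(cds) || is.na(cds))
    stop("coding gene '", gene$gene_id, "' lacks cds_end")
  tp <- .tpEnd(gene)
  if (as.character(GenomicRanges::strand(gene)) == "-") {
    ifelse(pos < tp, "novel", ifelse(pos < cds, "tandem", "internal"))
  } else {
    ifelse(pos > tp, "novel", ifelse(pos > cds, "tandem", "internal"))
  }
}

#' Assign poly(A) sites to genes and build the isoform annotation
#'
#' A site is assigned to the same-contig, same-strand gene whose span
#' contains it; otherwise to the gene whose annotated 3' end lies strand-aware
#' upstream of the site within \code{maxDownstream} nt (such sites become
#' \code{novel} isoforms).  When several gene spans contain a site, the one
#' with the nearest annotated 3' end wins, ties broken towards the
#' lexicographically smaller \code{gene_id}.  Unassignable sites are dropped
#' (tally in \code{metadata()$n_unassigned} of the result).  Isoforms are
#' ranked 5' to 3' within each gene (\code{rank_3p} 1 = most proximal) and
#' classified with [classifyIsoform()].
#'
#' @param sites GRanges of width-1 sites (from [clusterSites()]).
#' @param genes GRanges of gene spans with columns \code{gene_id},
#'   \code{biotype}, \code{cds_end}.
#' @param maxDownstream Maximum distance (nt) past the annotated 3' end for
#'   novel isoforms (default 5000).
#' @return A [TrendAnnotation-class].
#' @export
assignSitesToGenes <- function(sites, genes, maxDownstream = 5000L) {
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique")
  pos <- GenomicRanges::start(sites)
  assigned <- rep(NA_integer_, length(sites))

  ov <- GenomicRanges::findOverlaps(sites, genes)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    d <- abs(pos[qh] - .tpEnd(genes)[sh])
    ord <- order(qh, d, genes$gene_id[sh])
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- sh[ord][first]
  }

  # downstream extension for still-unassigned sites
  todo <- which(is.na(assigned))
  if (length(todo)) {
    plus <- as.character(GenomicRanges::strand(genes)) != "-"
    tp <- .tpEnd(genes)
    fl <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes),
      IRanges::IRanges(ifelse(plus, tp + 1L, pmax(1L, tp - maxDownstream)),
                       ifelse(plus, tp + maxDownstream, pmax(1L, tp - 1L))),
      strand = GenomicRanges::strand(genes))
    ov2 <- GenomicRanges::findOverlaps(sites[todo], fl)
    if (length(ov2)) {
      qh <- S4Vectors::queryHits(ov2); sh <- S4Vectors::subjectHits(ov2)
      d <- abs(pos[todo][qh] - tp[sh])
      ord <- order(qh, d, genes$gene_id[sh])
      first <- !duplicated(qh[ord])
      assigned[todo[qh[ord][first]]] <- sh[ord][first]
    }
  }

  keep <- which(!is.na(assigned))
  nUnassigned <- length(sites) - length(keep)
  gr <- sites[keep]
  gi <- assigned[keep]
  gr$gene_id <- genes$gene_id[gi]
  cls <- character(length(gr))
  for (g in unique(gi))
    cls[gi == g] <- classifyIsoform(GenomicRanges::start(gr)[gi == g], genes[g])
  gr$class <- cls

  # 5'->3' rank within gene and isoform ids
  p <- GenomicRanges::start(gr)
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  ordkey <- ifelse(neg, -p, p)
  rk <- integer(length(gr))
  for (g in unique(gr$gene_id)) {
    i <- which(gr$gene_id == g)
    rk[i] <- rank(ordkey[i], ties.method = "first")
  }
  gr$rank_3p <- rk
  gr$isoform_id <- sprintf("%s.%d", gr$gene_id, rk)
  if (is.null(gr$support)) gr$support <- NA_integer_
  if (is.null(gr$ip_flag)) gr$ip_flag <- NA
  ann <- TrendAnnotation(gr)
  S4Vectors::metadata(ann@sites)$n_unassigned <- nUnassigned
  ann
}

#' Flag internal-priming-prone positions
#'
#' Reads can arise from oligo(dT) priming on genomically encoded A-rich
#' stretches rather than genuine poly(A) tails.  A position is flagged when
#' its strand-aware downstream window of \code{win} nt contains more than
#' \code{maxA} adenosines or a run of more than \code{maxRun} consecutive
#' adenosines.  Near a contig end the truncated window is used with
#' \code{maxA} scaled proportionally.
#'
#' @param sites GRanges of width-1 positions (or a [TrendAnnotation-class]).
#' @param genome Named DNAStringSet.
#' @param win Downstream window length (default 20).
#' @param maxA Maximum tolerated A count in the window (default 12).
#' @param maxRun Maximum tolerated consecutive-A run (default 6).
#' @return For a GRanges input, a logical vector; for a TrendAnnotation, the
#'   annotation with its \code{ip_flag} column set.
#' @export
flagInternalPriming <- function(sites, genome, win = 20L, maxA = 12L, maxRun = 6L) {
  isAnn <- is(sites, "TrendAnnotation")
  gr <- if (isAnn) trendSites(sites) else sites
  if (!length(gr)) {
    if (isAnn) return(sites) else return(logical(0))
  }
  down <- .downstreamSeq(genome, GenomicRanges::seqnames(gr),
                         GenomicRanges::strand(gr),
                         GenomicRanges::start(gr), win)
  wlen <- nchar(down)
  maxAeff <- maxA * wlen / win
  flag <- (.countA(down) > maxAeff) | (.maxARun(down) > maxRun)
  if (isAnn) {
    sites@sites$ip_flag <- flag
    sites
  } else flag
}

#' Build a TREND annotation from aligned 3' end reads
#'
#' Convenience pipeline: [filterPassReads()] then [clusterSites()] then
#' [assignSitesToGenes()] then [flagInternalPriming()].
#'
#' @inheritParams filterPassReads
#' @inheritParams clusterSites
#' @inheritParams assignSitesToGenes
#' @inheritParams flagInternalPriming
#' @param genes GRanges of gene spans (see [assignSitesToGenes()]).
#' @return A [TrendAnnotation-class] with internal-priming flags set.
#' @export
buildTrendAnnotation <- function(reads, genome, genes,
                                 minUntemplatedA = 2L, window = 25L,
                                 minSupport = 2L, maxDownstream = 5000L,
                                 win = 20L, maxA = 12L, maxRun = 6L) {
  pass <- filterPassReads(reads, genome, minUntemplatedA)
  sites <- clusterSites(pass, window, minSupport)
  ann <- assignSitesToGenes(sites, genes, maxDownstream)
  flagInternalPriming(ann, genome, win, maxA, maxRun)
}
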