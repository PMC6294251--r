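# Demultiplexing, A/T-stretch trimming, exact-match alignment of synthetic
# reads, and intersection-strict isoform counting.

#' Demultiplex paired barcode/insert reads
#'
#' Read 1 carries an in-lane sample barcode; read 2 is the RNA insert.  A
#' pair is assigned to the sample whose barcode exactly matches the first
#' \code{barcode_length} bases of read 1.  Pairs whose read-2 mean per-base
#' quality is not above \code{minMeanQ}, or whose barcode matches no sample,
#' are dropped and tallied (quality gate applied first).
#'
#' @param r1,r2 Paired [Biostrings::QualityScaledDNAStringSet] streams of
#'   equal length (barcode read and insert read).
#' @param sampleSheet Named character vector mapping barcode to sample id
#'   (names are the barcodes), all barcodes of equal length over A/C/G/T.
#' @param minMeanQ Minimum mean read-2 Phred quality, exclusive (default 20).
#' @return A list with \code{samples} (named list of per-sample read-2
#'   QualityScaledDNAStringSet) and \code{tally} (named integer vector with
#'   per-sample assigned counts plus \code{low_quality} and
#'   \code{unmatched}).
#' @export
demultiplexReads <- function(r1, r2, sampleSheet, minMeanQ = 20) {
  if (length(r1) != length(r2))
    stop("read-1 and read-2 streams differ in length")
  bcs <- names(sampleSheet)
  if (is.null(bcs) || anyDuplicated(bcs))
    stop("sampleSheet must be a named vector with unique barcodes")
  blen <- unique(nchar(bcs))
  if (length(blen) != 1L || any(grepl("[^ACGT]", bcs)))
    stop("barcodes must be equal-length strings over A/C/G/T")

  samples <- unname(sampleSheet)
  tally <- setNames(integer(length(samples) + 2L),
                    c(samples, "low_quality", "unmatched"))
  out <- setNames(vector("list", length(samples)), samples)
  if (!length(r1))
    return(list(samples = out, tally = tally))

  meanQ <- mean(methods::as(Biostrings::quality(r2), "IntegerList"))
  obsBc <- as.character(Biostrings::subseq(r1, 1L, blen))
  sample <- sampleSheet[obsBc]
  lowq <- meanQ <= minMeanQ
  unmatched <- !lowq & is.na(sample)
  tally["low_quality"] <- sum(lowq)
  tally["unmatched"] <- sum(unmatched)
  ok <- !lowq & !unmatched
  for (s in samples) {
    i <- which(ok & sample == s)
    out[[s]] <- r2[i]
    tally[s] <- length(i)
  }
  list(samples = out, tally = tally)
}

#' Trim terminal A-stretches and leading T-stretches
#'
#' Removes a 5'-leading T-run of length >= \code{minStretch}, then truncates
#' the read at the first A-run of length >= \code{minStretch}, discarding the
#' run and everything 3' of it.  The length of that contiguous A-run is
#' recorded per read as \code{soft_tail_A} (the evidence consumed by
#' [filterPassReads()] downstream).  Reads shorter than \code{minLen} after
#' trimming are dropped and tallied in \code{metadata()$n_dropped}.
#'
#' @param reads A QualityScaledDNAStringSet (or DNAStringSet) of insert reads
#'   in mRNA sense.
#' @param minStretch Minimum run length that triggers trimming (default 5).
#' @param minLen Minimum retained read length (default 15).
#' @return Trimmed reads with an mcols column \code{soft_tail_A}.
#' @export
trimStretches <- function(reads, minStretch = 5L, minLen = 15L) {
  seqs <- as.character(reads)
  lead <- regexpr(sprintf("^T{%d,}", minStretch), seqs)
  from <- ifelse(lead > 0L, attr(lead, "match.length") + 1L, 1L)
  rest <- substr(seqs, from, nchar(seqs))
  arun <- regexpr(sprintf("A{%d,}", minStretch), rest)
  tailA <- ifelse(arun > 0L, attr(arun, "match.length"), 0L)
  to <- ifelse(arun > 0L, from + arun - 2L, nchar(seqs))
  keep <- (to - from + 1L) >= minLen
  trimmed <- Biostrings::subseq(reads[keep], from[keep], to[keep])
  S4Vectors::mcols(trimmed)$soft_tail_A <- as.integer(tailA[keep])
  S4Vectors::metadata(trimmed)$n_dropped <- sum(!keep)
  trimmed
}

#' Exact-match placement of simulated 3' end reads
#'
#' Not a general-purpose aligner: places trimmed reads on a genome by exact
#' matching of their 3'-terminal \code{anchorWidth}-mer on both strands,
#' suitable for the package's error-free synthetic reads (the synthetic
#' reference generator guarantees anchor uniqueness).  Reads whose anchor
#' matches no position, or more than one, are dropped and tallied.
#'
#' @param reads Trimmed reads with an mcols column \code{soft_tail_A}
#'   (from [trimStretches()]).
#' @param genome Named DNAStringSet.
#' @param anchorWidth Width of the 3'-terminal exact-match anchor
#'   (default 20).
#' @return GRanges of alignments with columns \code{read_id} and
#'   \code{soft_tail_A}; \code{metadata()$n_unplaced} tallies dropped reads.
#' @export
alignReadsExact <- function(reads, genome, anchorWidth = 20L) {
  wid <- Biostrings::width(reads)
  ok <- wid >= anchorWidth
  reads <- reads[ok]
  wid <- wid[ok]
  tailA <- S4Vectors::mcols(reads)$soft_tail_A
  if (is.null(tailA)) tailA <- rep(0L, length(reads))
  anchors <- as.character(Biostrings::subseq(reads, wid - anchorWidth + 1L, wid))
  uq <- unique(anchors)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq))
  hit <- data.frame(contig = character(), strand = character(),
                    s = integer(), e = integer(), a = integer())
  for (ctg in names(genome)) {
    fwd <- Biostrings::matchPDict(pd, genome[[ctg]])
    rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(genome[[ctg]]))
    clen <- length(genome[[ctg]])
    for (i in seq_along(uq)) {
      f <- fwd[[i]]
      if (length(f))
        hit <- rbind(hit, data.frame(contig = ctg, strand = "+",
                                     s = IRanges::start(f), e = IRanges::end(f), a = i))
      r <- rev[[i]]
      if (length(r))  # revcomp coords back to forward genome
        hit <- rbind(hit, data.frame(contig = ctg, strand = "-",
                                     s = clen - IRanges::end(r) + 1L,
                                     e = clen - IRanges::start(r) + 1L, a = i))
    }
  }
  nhits <- tabulate(hit$a, nbins = length(uq))
  placed <- which(nhits == 1L)
  hit1 <- hit[hit$a %in% placed, ]
  rowOf <- match(match(anchors, uq), hit1$a)
  keep <- which(!is.na(rowOf))
  h <- hit1[rowOf[keep], ]
  plus <- h$strand == "+"
  # extend the anchor match to the full read interval
  s <- ifelse(plus, h$e - wid[keep] + 1L, h$s)
  e <- ifelse(plus, h$e, h$s + wid[keep] - 1L)
  gr <- GenomicRanges::GRanges(h$contig, IRanges::IRanges(s, e), strand = h$strand)
  ids <- names(reads)
  gr$read_id <- if (is.null(ids)) sprintf("read_%d", keep) else ids[keep]
  gr$soft_tail_A <- tailA[keep]
  S4Vectors::metadata(gr)$n_unplaced <- length(anchors) - length(keep) + sum(!ok)
  gr
}

.countingIntervals <- function(annot, flank) {
  gr <- trendSites(annot)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(GenomicRanges::start(gr) - flank,
                                          GenomicRanges::start(gr) + flank - 1L),
                         strand = GenomicRanges::strand(gr))
}

.end3pGR <- function(aln) {
  e <- .end3p(aln)
  GenomicRanges::GRanges(GenomicRanges::seqnames(aln), IRanges::IRanges(e, e),
                         strand = GenomicRanges::strand(aln))
}

#' Count reads per 3' end isoform (intersection-strict)
#'
#' Each isoform owns a counting interval of \code{flank} nt either side of
#' its cleavage site, on its strand.  A read contributes one count to an
#' isoform iff its alignment 3'-terminal coordinate lies in exactly one
#' isoform's interval; reads hitting none are tallied \code{no_feature},
#' reads hitting two or more are tallied \code{ambiguous} and discarded
#' (the intersection-strict analogue for single-position features).
#'
#' @param alignmentsBySample Named list of alignment GRanges (one per
#'   sample), each with \code{read_id} metadata.
#' @param annot A [TrendAnnotation-class].
#' @param flank Interval half-width in nt (default 50).
#' @return A [TrendCounts-class]; per-sample tallies in
#'   \code{metadata(x)$qc}.
#' @export
countIsoforms <- function(alignmentsBySample, annot, flank = 50L) {
  if (anyDuplicated(isoformId(annot)))
    stop("isoform ids are not unique")
  if (is(alignmentsBySample, "GRanges"))
    alignmentsBySample <- list(sample = alignmentsBySample)
  iv <- .countingIntervals(annot, flank)
  n <- length(iv)
  samples <- names(alignmentsBySample)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(isoformId(annot), samples))
  qc <- data.frame(sample = samples, total = 0L, assigned = 0L,
                   ambiguous = 0L, no_feature = 0L)
  for (j in seq_along(samples)) {
    aln <- alignmentsBySample[[j]]
    ep <- .end3pGR(aln)
    nh <- GenomicRanges::countOverlaps(ep, iv)
    ov <- GenomicRanges::findOverlaps(ep[nh == 1L], iv)
    tb <- tabulate(S4Vectors::subjectHits(ov), nbins = n)
    counts[, j] <- tb
    qc$total[j] <- length(aln)
    qc$assigned[j] <- sum(nh == 1L)
    qc$ambiguous[j] <- sum(nh > 1L)
    qc$no_feature[j] <- sum(nh == 0L)
  }
  TrendCounts(counts, rowRanges = trendSites(annot), qc = qc)
}

#' Remove internal-priming reads before counting
#'
#' Drops reads whose 3' end falls in the counting interval of an
#' internal-priming-flagged site, and reads whose own downstream genomic
#' window is A-rich (same rule as [flagInternalPriming()]) while not
#' matching any unflagged annotated site.
#'
#' @param alignments GRanges of aligned reads.
#' @param annot A [TrendAnnotation-class] with \code{ip_flag} set.
#' @param genome Named DNAStringSet.
#' @param flank Counting-interval half-width (default 50).
#' @inheritParams flagInternalPriming
#' @return The retained alignments; \code{metadata()$ip_removed} holds the
#'   number removed.
#' @export
dropInternalPrimingReads <- function(alignments, annot, genome, flank = 50L,
                                     win = 20L, maxA = 12L, maxRun = 6L) {
  flag <- ipFlag(annot) %in% TRUE
  ep <- .end3pGR(alignments)
  iv <- .countingIntervals(annot, flank)
  inFlagged <- GenomicRanges::countOverlaps(ep, iv[flag]) > 0L
  inUnflagged <- GenomicRanges::countOverlaps(ep, iv[!flag]) > 0L
  aRich <- flagInternalPriming(ep, genome, win, maxA, maxRun)
  remove <- inFlagged | (aRich & !inUnflagged)
  kept <- alignments[!remove]
  S4Vectors::metadata(kept)$ip_removed <- sum(remove)
  kept
}

#' Quantify samples: internal-priming removal plus isoform counting
#'
#' @inheritParams countIsoforms
#' @inheritParams dropInternalPrimingReads
#' @return A [TrendCounts-class] whose QC table additionally carries
#'   \code{ip_removed} per sample, so that
#'   assigned + ambiguous + no_feature + ip_removed = total aligned reads.
#' @export
quantifySamples <- function(alignmentsBySample, annot, genome, flank = 50L,
                            win = 20L, maxA = 12L, maxRun = 6L) {
  if (is(alignmentsBySample, "GRanges"))
    alignmentsBySample <- list(sample = alignmentsBySample)
  ipr <- integer(length(alignmentsBySample))
  tot <- integer(length(alignmentsBySample))
  cleaned <- alignmentsBySample
  for (j in seq_along(cleaned)) {
    tot[j] <- length(cleaned[[j]])
    cleaned[[j]] <- dropInternalPrimingReads(cleaned[[j]], annot, genome,
                                             flank, win, maxA, maxRun)
    ipr[j] <- S4Vectors::metadata(cleaned[[j]])$ip_removed
  }
  tc <- countIsoforms(cleaned, annot, flank)
  qc <- S4Vectors::metadata(tc)$qc
  qc$ip_removed <- ipr
  qc$total <- tot
  S4Vectors::metadata(tc)$qc <- qc
  tc
}
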