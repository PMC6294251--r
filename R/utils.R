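# Internal helpers shared across modules.

.STREAMS <- c("reference", "counts", "fastq", "array", "survival",
              "layout", "boot", "split", "noise")

#' Derive a named RNG sub-stream seed from a master seed
#'
#' One master seed fans out to fixed named sub-streams so that individual
#' simulation stages can be regenerated independently and reproducibly.
#' Results stay within 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param stream Stream name, one of a fixed set; unknown names are hashed by
#'   their characters.
#' @param counter Optional non-negative offset (e.g. a bootstrap replicate
#'   index) so replicate-level streams are prefix-stable in the number of
#'   replicates.
#' @return An integer seed.
#' @export
subSeed <- function(seed, stream = "reference", counter = 0L) {
  idx <- match(stream, .STREAMS)
  if (is.na(idx))
    idx <- sum(utf8ToInt(stream)) %% 1000L
  m <- 2147483629
  val <- (as.numeric(seed) %% m) * 48271 + idx * 7919 + as.numeric(counter) * 104729
  as.integer(val %% m)
}

# strand-aware 3'-terminal coordinate of alignments (1-based, last aligned base)
.end3p <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "-",
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# strand-aware annotated 3' end of gene spans
.tpEnd <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

# sample n integers uniformly from lo..hi (safe when lo == hi)
.sampleRange <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

.checkContigs <- function(gr, genome) {
  miss <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), names(genome))
  if (length(miss))
    stop("alignments reference contig(s) absent from the genome: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

# Extract, per position, the `len`-nt window immediately downstream (in
# transcript direction) of 1-based position `pos`, truncated at contig bounds.
# Returns sequences in transcript orientation (reverse complement on "-").
.downstreamSeq <- function(genome, contig, strand, pos, len) {
  contig <- as.character(contig)
  strand <- as.character(strand)
  clen <- width(genome)[match(contig, names(genome))]
  plus <- strand != "-"
  from <- ifelse(plus, pos + 1L, pmax(1L, pos - len))
  to <- ifelse(plus, pmin(clen, pos + len), pos - 1L)
  out <- character(length(pos))
  ok <- to >= from
  if (any(ok)) {
    grs <- GenomicRanges::GRanges(contig[ok], IRanges::IRanges(from[ok], to[ok]),
                                  strand = ifelse(plus[ok], "+", "-"))
    seqs <- .extractSeq(genome, grs)
    out[ok] <- as.character(seqs)
  }
  out[!ok] <- ""
  out
}

# transcript-orientation sequence extraction from a DNAStringSet genome
.extractSeq <- function(genome, gr) {
  res <- Biostrings::DNAStringSet(rep("", length(gr)))
  for (ctg in unique(as.character(GenomicRanges::seqnames(gr)))) {
    i <- which(as.character(GenomicRanges::seqnames(gr)) == ctg)
    ir <- IRanges::IRanges(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    res[i] <- Biostrings::extractAt(genome[[ctg]], ir)
  }
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(neg))
    res[neg] <- Biostrings::reverseComplement(res[neg])
  res
}

# leading-A count of each string
.leadingA <- function(x) {
  m <- regexpr("^A*", x)
  attr(m, "match.length")
}

# longest A-run per string (0 when absent)
.maxARun <- function(x) {
  vapply(gregexpr("A+", x), function(m) {
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

.countA <- function(x) {
  nchar(x) - nchar(gsub("A", "", x, fixed = TRUE))
}
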