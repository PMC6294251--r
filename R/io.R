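# Readers and writers for the pipeline's plain-text interchange formats.
# Internal coordinates are 1-based closed (GRanges); BED output is converted
# to its native 0-based half-open convention.

#' Write / read a TREND annotation
#'
#' \code{writeTrendAnnotation} emits a BED6 file (name =
#' \code{gene|isoform|class}, score = PASS support) plus a TSV side table
#' with all isoform metadata including the internal-priming flag;
#' \code{readTrendAnnotation} restores the annotation from the TSV.
#'
#' @param annot A [TrendAnnotation-class].
#' @param bedPath,tsvPath Output paths.
#' @return \code{readTrendAnnotation}: a [TrendAnnotation-class].
#' @export
writeTrendAnnotation <- function(annot, bedPath, tsvPath) {
  gr <- trendSites(annot)
  pos <- GenomicRanges::start(gr)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = pos - 1L, end = pos,
                    name = sprintf("%s|%s|%s", gr$gene_id, gr$isoform_id,
                                   gr$class),
                    score = ifelse(is.na(gr$support), 0L, gr$support),
                    strand = as.character(GenomicRanges::strand(gr)))
  write.table(bed, bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tsv <- data.frame(isoform_id = gr$isoform_id, gene_id = gr$gene_id,
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    position = pos,
                    strand = as.character(GenomicRanges::strand(gr)),
                    class = gr$class, rank_3p = gr$rank_3p,
                    support = gr$support, ip_flag = gr$ip_flag)
  write.table(tsv, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeTrendAnnotation
#' @export
readTrendAnnotation <- function(tsvPath) {
  df <- read.table(tsvPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$position, df$position),
                               strand = df$strand)
  gr$isoform_id <- df$isoform_id
  gr$gene_id <- df$gene_id
  gr$class <- df$class
  gr$rank_3p <- df$rank_3p
  gr$support <- df$support
  gr$ip_flag <- df$ip_flag
  TrendAnnotation(gr)
}

#' Write / read an isoform count matrix
#'
#' TSV with isoform metadata columns followed by one column per sample.
#'
#' @param tc A [TrendCounts-class].
#' @param path File path.
#' @return \code{readTrendCounts}: a [TrendCounts-class].
#' @export
writeTrendCounts <- function(tc, path) {
  rr <- SummarizedExperiment::rowRanges(tc)
  df <- data.frame(isoform_id = rr$isoform_id, gene_id = rr$gene_id,
                   contig = as.character(GenomicRanges::seqnames(rr)),
                   position = GenomicRanges::start(rr),
                   strand = as.character(GenomicRanges::strand(rr)),
                   class = rr$class, rank_3p = rr$rank_3p)
  df <- cbind(df, as.data.frame(trendCounts(tc)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeTrendCounts
#' @export
readTrendCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("isoform_id", "gene_id", "contig", "position", "strand",
            "class", "rank_3p")
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$position, df$position),
                               strand = df$strand)
  gr$isoform_id <- df$isoform_id
  gr$gene_id <- df$gene_id
  gr$class <- df$class
  gr$rank_3p <- df$rank_3p
  gr$support <- NA_integer_
  gr$ip_flag <- NA
  counts <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  rownames(counts) <- df$isoform_id
  TrendCounts(counts, rowRanges = gr)
}

#' Read 3' end alignments from the 6-column TSV interchange format
#'
#' Columns: \code{read_id}, \code{contig}, \code{strand}, \code{start},
#' \code{end} (1-based closed) and \code{soft_tail_A} (count of
#' adapter/trimming-derived terminal A's not aligned to the genome).
#'
#' @param path File path (with header).
#' @return GRanges of alignments.
#' @export
readAlignmentsTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("read_id", "contig", "strand", "start", "end", "soft_tail_A")
  if (!all(need %in% colnames(df)))
    stop("alignment TSV needs columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$read_id <- df$read_id
  gr$soft_tail_A <- as.integer(df$soft_tail_A)
  gr
}

#' @rdname readAlignmentsTSV
#' @param gr Alignment GRanges with \code{read_id} and \code{soft_tail_A}.
#' @export
writeAlignmentsTSV <- function(gr, path) {
  df <- data.frame(read_id = gr$read_id,
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   soft_tail_A = gr$soft_tail_A)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read 3' end alignments from SAM/BAM
#'
#' Extracts, per aligned read, the reference interval and the count of
#' soft-clipped terminal adenosines on the 3' side of the alignment (A's on
#' the plus strand's right clip, T's on the minus strand's left clip, read
#' as stored in SAM plus-strand orientation).  Requires the Rsamtools
#' package; SAM input is converted on the fly.
#'
#' @param path Path to a SAM or BAM file.
#' @return GRanges of alignments with \code{read_id} and \code{soft_tail_A}.
#' @export
readAlignmentsSAM <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("readAlignmentsSAM requires the Rsamtools package")
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "strand", "pos",
                                        "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ok <- !is.na(x$pos)
  cig <- x$cigar[ok]
  refw <- vapply(cig, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MDN=X]$", ops)])))
  }, integer(1), USE.NAMES = FALSE)
  seqs <- as.character(x$seq[ok])
  minus <- as.character(x$strand[ok]) == "-"
  tailA <- integer(sum(ok))
  rightClip <- leftClip <- rep(0L, length(cig))
  hasR <- grepl("\\d+S$", cig)
  rightClip[hasR] <- as.integer(sub(".*?(\\d+)S$", "\\1", cig[hasR]))
  hasL <- grepl("^\\d+S", cig)
  leftClip[hasL] <- as.integer(sub("^(\\d+)S.*", "\\1", cig[hasL]))
  for (i in seq_along(cig)) {
    if (minus[i]) {
      if (leftClip[i] > 0L) {
        clip <- substr(seqs[i], 1L, leftClip[i])
        # 3' tail in read orientation = reversed leading T run on the ref strand
        m <- regexpr("T+$", clip)
        tailA[i] <- if (m > 0L) attr(m, "match.length") else 0L
      }
    } else if (rightClip[i] > 0L) {
      clip <- substr(seqs[i], nchar(seqs[i]) - rightClip[i] + 1L,
                     nchar(seqs[i]))
      tailA[i] <- .leadingA(clip)
    }
  }
  gr <- GenomicRanges::GRanges(as.character(x$rname[ok]),
                               IRanges::IRanges(x$pos[ok],
                                                x$pos[ok] + refw - 1L),
                               strand = x$strand[ok])
  gr$read_id <- x$qname[ok]
  gr$soft_tail_A <- tailA
  gr
}

#' Read gene models from GTF
#'
#' Builds the gene-span GRanges consumed by [assignSitesToGenes()] from a
#' GTF file: per gene, the exon span, the strand-aware last CDS base
#' (\code{cds_end}; genes without CDS features are \code{non_coding}).
#' Requires rtracklayer.
#'
#' @param path GTF file path.
#' @return GRanges with \code{gene_id}, \code{biotype}, \code{cds_end}.
#' @export
readGeneModelsGTF <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("readGeneModelsGTF requires the rtracklayer package")
  gtf <- rtracklayer::import(path)
  ex <- gtf[gtf$type == "exon"]
  cds <- gtf[gtf$type == "CDS"]
  genes <- sort(unique(ex$gene_id))
  spans <- unlist(range(GenomicRanges::split(ex, factor(ex$gene_id,
                                                        levels = genes))))
  cdsEnd <- rep(NA_integer_, length(genes))
  if (length(cds)) {
    for (i in seq_along(genes)) {
      cg <- cds[cds$gene_id == genes[i]]
      if (!length(cg)) next
      cdsEnd[i] <- if (as.character(GenomicRanges::strand(cg))[1] == "-")
        min(GenomicRanges::start(cg)) else max(GenomicRanges::end(cg))
    }
  }
  spans$gene_id <- genes
  spans$biotype <- ifelse(is.na(cdsEnd), "non_coding", "coding")
  spans$cds_end <- cdsEnd
  unname(spans)
}

#' Write gene models as GTF
#'
#' One exon line per gene span plus a CDS line for coding genes; used to
#' export synthetic references.
#'
#' @param genes Gene-span GRanges with \code{gene_id}, \code{biotype},
#'   \code{cds_end}.
#' @param path Output path.
#' @export
writeGeneModelsGTF <- function(genes, path) {
  lines <- character(0)
  for (i in seq_along(genes)) {
    ctg <- as.character(GenomicRanges::seqnames(genes))[i]
    st <- GenomicRanges::start(genes)[i]
    en <- GenomicRanges::end(genes)[i]
    std <- as.character(GenomicRanges::strand(genes))[i]
    attrs <- sprintf('gene_id "%s";', genes$gene_id[i])
    lines <- c(lines, paste(ctg, "trendseq", "exon", st, en, ".", std, ".",
                            attrs, sep = "\t"))
    if (!is.na(genes$cds_end[i])) {
      ce <- genes$cds_end[i]
      cs <- if (std == "-") ce else st
      cEnd <- if (std == "-") en else ce
      lines <- c(lines, paste(ctg, "trendseq", "CDS", cs, cEnd, ".", std,
                              "0", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Write / read FASTQ with qualities
#'
#' Thin wrappers over Biostrings' quality-scaled FASTQ support.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path FASTQ path.
#' @return \code{readFastq}: a QualityScaledDNAStringSet.
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(NULL)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # the parser's provisional mcols are dropped by design
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write network edges and layout coordinates
#'
#' Edges as TSV plus a Graphviz DOT export (edge weight = score, style
#' separates synergy from antagonism); coordinates as TSV.
#'
#' @param edges Edge data.frame from [buildRegulatorNetwork()].
#' @param tsvPath,dotPath Output paths (either may be NULL to skip).
#' @export
writeNetwork <- function(edges, tsvPath = NULL, dotPath = NULL) {
  if (!is.null(tsvPath))
    write.table(edges, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dotPath)) {
    lines <- c("graph trend_regulators {")
    for (i in seq_len(nrow(edges))) {
      style <- if (edges$score[i] >= 0) "solid" else "dashed"
      lines <- c(lines, sprintf('  "%s" -- "%s" [weight=%.3f, style=%s];',
                                edges$reg_a[i], edges$reg_b[i],
                                abs(edges$score[i]), style))
    }
    lines <- c(lines, "}")
    writeLines(lines, dotPath)
  }
  invisible(NULL)
}
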