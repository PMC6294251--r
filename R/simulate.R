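# Synthetic-data generators with ground truth for every pipeline stage:
# reference genomes with planted poly(A) sites and A-rich decoys, barcoded
# 3' end reads, isoform count matrices with planted usage shifts,
# probe-level array expression and survival data tied to isoform ratios.

# Break A/T homopolymer runs (>= 3) inside a window of a per-base genome
# vector so that read trimming and internal-priming rules never fire on
# genomic sequence around planted features.
.sanitizeWindow <- function(g, from, to) {
  from <- max(1L, from); to <- min(length(g), to)
  run <- 0L; prev <- ""
  for (i in from:to) {
    if (g[i] %in% c("A", "T") && g[i] == prev) {
      run <- run + 1L
      if (run >= 2L) {
        g[i] <- "C"
        run <- 0L; prev <- "C"
        next
      }
    } else {
      run <- 0L
    }
    prev <- g[i]
  }
  g
}

# Cap the transcript-sense A content of the downstream window of a site.
.capDownstreamA <- function(g, pos, strand, win = 20L, maxCount = 6L) {
  if (strand == "+") {
    idx <- (pos + 1L):min(length(g), pos + win)
    hits <- idx[g[idx] == "A"]
  } else {
    idx <- max(1L, pos - win):(pos - 1L)
    hits <- idx[g[idx] == "T"]
  }
  if (length(hits) > maxCount)
    g[utils::tail(hits, length(hits) - maxCount)] <- "C"
  g
}

#' Simulate a reference genome with planted poly(A) sites and decoys
#'
#' Builds a single-contig genome of non-overlapping genes on both strands.
#' Each coding gene carries \code{k} tandem poly(A) sites in its 3' UTR with
#' spacing >= 100 nt; base composition is uniform outside planted features.
#' Sequence around every planted site is sanitized (no A/T runs, A-poor
#' downstream windows, unique 20-mer upstream anchors) so that error-free
#' reads from planted sites survive trimming, PASS filtering,
#' internal-priming removal and exact-anchor placement without loss.
#' A-rich decoy runs (20 nt of A) are planted in intergenic gaps at
#' \code{decoyRate} per kb of intergenic sequence, emulating internal-priming
#' traps.
#'
#' @param nGenes Number of genes (default 300).
#' @param isoformsPerGene Integer range \code{c(min, max)} of tandem sites
#'   per gene (default 2-4).
#' @param cdsLen Length of the coding region 5' of the first site
#'   (default 600 nt).
#' @param spacing Range of inter-site spacings (default 150-300 nt,
#'   >= 100 required).
#' @param intergenic Intergenic gap length (default 500 nt).
#' @param decoyRate Decoy A-runs per kb of intergenic sequence (default 0.5).
#' @param seed Master seed.
#' @return list with \code{genome} (DNAStringSet, contig \code{"chrS"}),
#'   \code{genes} (GRanges with \code{gene_id}, \code{biotype},
#'   \code{cds_end}), \code{sites} (truth GRanges with \code{isoform_id},
#'   \code{gene_id}, \code{class}, \code{rank_3p}) and \code{decoys}
#'   (GRanges of decoy priming positions).
#' @export
simulateReference <- function(nGenes = 300L, isoformsPerGene = c(2L, 4L),
                              cdsLen = 600L, spacing = c(150L, 300L),
                              intergenic = 500L, decoyRate = 0.5,
                              seed = 1L) {
  if (min(spacing) < 100L)
    stop("site spacing below 100 nt is not supported")
  if (intergenic < 150L || cdsLen < 100L)
    stop("genome too small for the requested gene structure")
  set.seed(subSeed(seed, "reference"))
  if (nGenes == 0L) {
    g <- sample(c("A", "C", "G", "T"), intergenic, replace = TRUE)
    genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), "chrS"))
    empty <- GenomicRanges::GRanges()
    return(list(genome = genome, genes = empty, sites = empty,
                decoys = empty))
  }

  tailMargin <- 60L
  geneRows <- list(); siteRows <- list()
  cursor <- intergenic + 1L
  for (i in seq_len(nGenes)) {
    k <- .sampleRange(isoformsPerGene[1], isoformsPerGene[2], 1L)
    sp <- .sampleRange(spacing[1], spacing[2], k)
    glen <- cdsLen + sum(sp) + tailMargin
    strand <- if (i %% 2L == 0L) "-" else "+"
    g0 <- cursor; g1 <- cursor + glen - 1L
    if (strand == "+") {
      cds <- g0 + cdsLen - 1L
      pos <- cds + cumsum(sp)
    } else {
      cds <- g1 - cdsLen + 1L
      pos <- cds - cumsum(sp)
    }
    gid <- sprintf("g%04d", i)
    geneRows[[i]] <- data.frame(gene_id = gid, start = g0, end = g1,
                                strand = strand, cds_end = cds)
    siteRows[[i]] <- data.frame(gene_id = gid, pos = pos, strand = strand,
                                rank_3p = seq_len(k))
    cursor <- g1 + intergenic + 1L
  }
  genomeLen <- cursor - 1L
  g <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
  genesDf <- do.call(rbind, geneRows)
  sitesDf <- do.call(rbind, siteRows)

  # plant decoys in intergenic gaps
  gapStarts <- c(1L, genesDf$end + 1L)
  gapEnds <- c(genesDf$start - 1L, genomeLen)
  decoyPos <- integer(0)
  runLen <- 20L
  for (j in seq_along(gapStarts)) {
    room <- gapEnds[j] - gapStarts[j] + 1L - 2L * tailMargin - runLen
    if (room <= 0) next
    lambda <- decoyRate * (gapEnds[j] - gapStarts[j] + 1L) / 1000
    nd <- rpois(1L, lambda)
    if (!nd) next
    off <- sort(sample.int(room, min(nd, 1L)))  # at most one per gap: no overlap
    runStart <- gapStarts[j] + tailMargin + off
    g[runStart:(runStart + runLen - 1L)] <- "A"
    decoyPos <- c(decoyPos, runStart - 1L)      # priming position: last non-run base
  }

  # sanitize sites and decoy priming positions (transcript sense)
  fixOne <- function(g, pos, strand) {
    if (strand == "+") {
      g <- .sanitizeWindow(g, pos - tailMargin + 1L, pos)
      if (g[pos] == "A") g[pos] <- "C"
      if (g[pos + 1L] == "A") g[pos + 1L] <- "G"
    } else {
      g <- .sanitizeWindow(g, pos, pos + tailMargin - 1L)
      if (g[pos] == "T") g[pos] <- "G"
      if (g[pos - 1L] == "T") g[pos - 1L] <- "C"
    }
    .capDownstreamA(g, pos, strand)
  }
  for (r in seq_len(nrow(sitesDf)))
    g <- fixOne(g, sitesDf$pos[r], sitesDf$strand[r])
  for (p in decoyPos) {
    g <- .sanitizeWindow(g, p - tailMargin + 1L, p)
    if (g[p] == "A") g[p] <- "C"
  }

  # enforce unique 20-mer anchors (read placement must be unambiguous)
  anchorAt <- function(g, pos, strand) {
    if (strand == "+") paste(g[(pos - 19L):pos], collapse = "")
    else paste(rev(chartr("ACGT", "TGCA", g[pos:(pos + 19L)])), collapse = "")
  }
  allPos <- c(sitesDf$pos, decoyPos)
  allStr <- c(sitesDf$strand, rep("+", length(decoyPos)))
  for (iter in 1:10) {
    genomeSeq <- Biostrings::DNAString(paste(g, collapse = ""))
    anchors <- vapply(seq_along(allPos),
                      function(i) anchorAt(g, allPos[i], allStr[i]), "")
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors))
    nhit <- Biostrings::countPDict(pd, genomeSeq) +
      Biostrings::countPDict(pd, Biostrings::reverseComplement(genomeSeq))
    dup <- which(nhit != 1L | duplicated(anchors) |
                   duplicated(anchors, fromLast = TRUE))
    if (!length(dup)) break
    for (i in dup) {  # mutate one mid-anchor base, keeping A/T out
      off <- 9L + (iter %% 5L)
      at <- if (allStr[i] == "+") allPos[i] - off else allPos[i] + off
      g[at] <- if (g[at] == "C") "G" else "C"
    }
  }

  genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), "chrS"))
  genes <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(genesDf$start, genesDf$end),
                                  strand = genesDf$strand)
  genes$gene_id <- genesDf$gene_id
  genes$biotype <- "coding"
  genes$cds_end <- genesDf$cds_end
  sites <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(sitesDf$pos, sitesDf$pos),
                                  strand = sitesDf$strand)
  sites$gene_id <- sitesDf$gene_id
  sites$rank_3p <- sitesDf$rank_3p
  sites$isoform_id <- sprintf("%s.%d", sitesDf$gene_id, sitesDf$rank_3p)
  sites$class <- "tandem"
  sites$support <- NA_integer_
  sites$ip_flag <- FALSE
  decoys <- GenomicRanges::GRanges(rep("chrS", length(decoyPos)),
                                   IRanges::IRanges(decoyPos, decoyPos),
                                   strand = rep("+", length(decoyPos)))
  list(genome = genome, genes = genes, sites = sites, decoys = decoys)
}

.abstractSites <- function(nGenes, isoformsPerGene) {
  k <- .sampleRange(isoformsPerGene[1], isoformsPerGene[2], nGenes)
  gid <- rep(sprintf("g%04d", seq_len(nGenes)), k)
  rk <- unlist(lapply(k, seq_len))
  pos <- 10000L * rep(seq_len(nGenes), k) + 200L * rk
  gr <- GenomicRanges::GRanges("synth", IRanges::IRanges(pos, pos),
                               strand = "+")
  gr$gene_id <- gid
  gr$rank_3p <- rk
  gr$isoform_id <- sprintf("%s.%d", gid, rk)
  gr$class <- "tandem"
  gr$support <- NA_integer_
  gr$ip_flag <- FALSE
  gr
}

#' Simulate an isoform count matrix with planted usage shifts
#'
#' Per gene, isoform usage is drawn from a symmetric Dirichlet
#' (concentration \code{usageAlpha}); in perturbed genes the knockdown
#' condition moves \code{effect} of usage mass from the most proximal to the
#' most distal isoform (a proximal-to-distal shift, i.e. 3' UTR
#' lengthening).  Reads are multinomial at \code{depth} per gene per
#' condition (optionally Poisson-jittered).
#'
#' @param sites Optional truth GRanges (e.g. from [simulateReference()]);
#'   when NULL an abstract single-contig annotation is generated.
#' @param nGenes,isoformsPerGene Used only when \code{sites} is NULL.
#' @param usageAlpha Dirichlet concentration (default 2).
#' @param effect Usage mass moved proximal to distal in perturbed genes
#'   (default 0.3).
#' @param fracPerturbed Fraction of genes perturbed (default 1/3).
#' @param depth Reads per gene per condition (default 200).
#' @param poissonJitter Draw each gene/condition depth from
#'   Poisson(\code{depth}) (default FALSE).
#' @param seed Master seed.
#' @return A [TrendCounts-class] with samples \code{KD} and \code{Ctrl};
#'   \code{metadata()$truth} holds per-gene ground truth (perturbed flag,
#'   usage vectors, true direction).
#' @export
simulateCounts <- function(sites = NULL, nGenes = 300L,
                           isoformsPerGene = c(2L, 4L), usageAlpha = 2,
                           effect = 0.3, fracPerturbed = 1 / 3, depth = 200L,
                           poissonJitter = FALSE, seed = 1L) {
  set.seed(subSeed(seed, "counts"))
  if (is.null(sites))
    sites <- .abstractSites(nGenes, isoformsPerGene)
  genes <- unique(sites$gene_id)
  perturbed <- rep(FALSE, length(genes))
  perturbed[sample.int(length(genes), round(fracPerturbed * length(genes)))] <- TRUE
  names(perturbed) <- genes

  counts <- matrix(0L, length(sites), 2L,
                   dimnames = list(sites$isoform_id, c("KD", "Ctrl")))
  usageCtrl <- usageKd <- vector("list", length(genes))
  names(usageCtrl) <- names(usageKd) <- genes
  delta <- setNames(numeric(length(genes)), genes)
  for (gname in genes) {
    idx <- which(sites$gene_id == gname)
    idx <- idx[order(sites$rank_3p[idx])]
    k <- length(idx)
    u <- rgamma(k, usageAlpha)
    u <- u / sum(u)
    uk <- u
    if (perturbed[gname] && k >= 2L) {
      # guarantee the full planted shift is donatable by the proximal isoform
      if (u[1] < effect + 0.04) {
        u[-1] <- u[-1] * (1 - effect - 0.04) / sum(u[-1])
        u[1] <- effect + 0.04
        uk <- u
      }
      uk[1] <- uk[1] - effect
      uk[k] <- uk[k] + effect
      delta[gname] <- effect
    }
    dc <- if (poissonJitter) rpois(1L, depth) else depth
    dk <- if (poissonJitter) rpois(1L, depth) else depth
    counts[idx, "Ctrl"] <- as.integer(rmultinom(1L, dc, u))
    counts[idx, "KD"] <- as.integer(rmultinom(1L, dk, uk))
    usageCtrl[[gname]] <- u
    usageKd[[gname]] <- uk
  }
  truth <- data.frame(gene_id = genes, perturbed = unname(perturbed),
                      delta = unname(delta),
                      direction = ifelse(perturbed & delta > 0, "lengthened",
                                         "none"))
  tc <- TrendCounts(counts, rowRanges = sites)
  S4Vectors::metadata(tc)$truth <- truth
  S4Vectors::metadata(tc)$usage <- list(ctrl = usageCtrl, kd = usageKd)
  tc
}

.phredString <- function(widths, phred) {
  chr <- rawToChar(as.raw(phred + 33L))
  vapply(widths, function(w) strrep(chr, w), "")
}

#' Simulate multiplexed paired barcode/insert FASTQ reads
#'
#' Emits one multiplexed pair of read streams: read 1 carries the sample
#' barcode, read 2 the RNA insert.  Each insert read ends at its isoform's
#' cleavage site with an appended untemplated A-tail (uniform 5-15 nt,
#' read total \code{readLen}); a configurable fraction of reads instead
#' originates at planted genomic A-run decoys (internal-priming truth).
#'
#' @param reference Output of [simulateReference()].
#' @param counts A [TrendCounts-class] over \code{reference$sites} (e.g.
#'   from [simulateCounts()]); its columns define the samples.
#' @param barcodes Named character vector sample -> barcode (default two
#'   9-nt barcodes for \code{KD}/\code{Ctrl}).
#' @param readLen Insert read length (default 50).
#' @param tailRange A-tail length range (default 5-15).
#' @param qualityPhred Constant per-base Phred quality (default 30).
#' @param decoyFrac Fraction of additional internal-priming decoy reads per
#'   sample (default 0).
#' @param seed Master seed.
#' @return list with \code{r1}, \code{r2}
#'   ([Biostrings::QualityScaledDNAStringSet], shuffled read order) and
#'   \code{truth} (data.frame: read_id, sample, isoform_id (NA for decoys),
#'   decoy, end3p, tail).
#' @export
simulateFastq <- function(reference, counts,
                          barcodes = c(KD = "ACGTACGTA", Ctrl = "TGCATGCAT"),
                          readLen = 50L, tailRange = c(5L, 15L),
                          qualityPhred = 30L, decoyFrac = 0, seed = 1L) {
  set.seed(subSeed(seed, "fastq"))
  sites <- SummarizedExperiment::rowRanges(counts)
  cts <- trendCounts(counts)
  samples <- colnames(cts)
  if (!all(samples %in% names(barcodes)))
    stop("every sample needs a barcode")
  genome <- reference$genome
  maxPart <- readLen - tailRange[1]
  # transcript-sense upstream context ending at each cleavage site
  plus <- as.character(GenomicRanges::strand(sites)) != "-"
  pos <- GenomicRanges::start(sites)
  ctxGr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites),
    IRanges::IRanges(ifelse(plus, pos - maxPart + 1L, pos),
                     ifelse(plus, pos, pos + maxPart - 1L)),
    strand = GenomicRanges::strand(sites))
  ctx <- as.character(.extractSeq(genome, ctxGr))
  decoyCtx <- character(0)
  if (length(reference$decoys)) {
    dpos <- GenomicRanges::start(reference$decoys)
    dGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reference$decoys),
                                  IRanges::IRanges(dpos - maxPart + 1L, dpos),
                                  strand = "+")
    decoyCtx <- as.character(.extractSeq(genome, dGr))
  }

  seqs <- list(); quals1 <- list(); quals2 <- list(); bc <- list()
  truth <- list()
  for (s in samples) {
    n <- cts[, s]
    isoIdx <- rep(seq_along(sites), n)
    nDecoy <- if (length(decoyCtx)) round(decoyFrac * length(isoIdx)) else 0L
    decIdx <- if (nDecoy) sample(seq_along(decoyCtx), nDecoy, replace = TRUE) else integer(0)
    total <- length(isoIdx) + nDecoy
    if (!total) next
    tails <- .sampleRange(tailRange[1], tailRange[2], total)
    part <- readLen - tails
    upstream <- c(ctx[isoIdx], decoyCtx[decIdx])
    body <- substr(upstream, maxPart - part + 1L, maxPart)
    rseq <- paste0(body, strrep("A", tails))
    ids <- sprintf("%s_r%06d", s, seq_len(total))
    truth[[s]] <- data.frame(
      read_id = ids, sample = s,
      isoform_id = c(sites$isoform_id[isoIdx], rep(NA_character_, nDecoy)),
      decoy = c(rep(FALSE, length(isoIdx)), rep(TRUE, nDecoy)),
      end3p = c(pos[isoIdx],
                if (nDecoy) GenomicRanges::start(reference$decoys)[decIdx] else integer(0)),
      tail = tails)
    seqs[[s]] <- setNames(rseq, ids)
    bc[[s]] <- setNames(rep(barcodes[[s]], total), ids)
  }
  allSeq <- unlist(unname(seqs)); allBc <- unlist(unname(bc))
  truthDf <- do.call(rbind, unname(truth))
  ord <- sample.int(length(allSeq))
  allSeq <- allSeq[ord]; allBc <- allBc[ord]
  truthDf <- truthDf[match(names(allSeq), truthDf$read_id), ]
  rownames(truthDf) <- NULL
  r2 <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(allSeq),
    Biostrings::PhredQuality(.phredString(nchar(allSeq), qualityPhred)))
  r1 <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(allBc),
    Biostrings::PhredQuality(.phredString(nchar(allBc), qualityPhred)))
  list(r1 = r1, r2 = r2, truth = truthDf)
}

#' Simulate probe-level array expression resolving two isoforms per gene
#'
#' For each gene with at least two tandem sites, two probes are placed: a
#' common-region probe upstream of the proximal site (shortest-isoform
#' proxy) and a long-isoform probe between the proximal and distal sites.
#' Per-sample log2 intensities are gene abundance times isoform fraction
#' plus Gaussian noise.  Samples split into two groups; in informative
#' genes the second group's distal usage is raised by \code{effect}
#' (transcript lengthening).
#'
#' @param sites Truth GRanges of tandem sites (from [simulateReference()] or
#'   [simulateCounts()] rowRanges).
#' @param nSamples Number of arrays (default 100, split half/half).
#' @param fracInformative Fraction of genes whose usage differs between
#'   groups (default 1/3).
#' @param effect Distal-usage increase in the second group (default 0.3).
#' @param noiseSd Gaussian noise s.d. on log2 intensities (default 0.25).
#' @param proximalUsage Baseline proximal usage (default 0.65).
#' @param baseLog2Mean,baseLog2Sd Gene abundance distribution on log2 scale.
#' @param bgLog2 Per-array additive background level on log2 scale
#'   (default 5); a matching set of pure-background probes (fraction
#'   \code{fracBgProbes} of the gene probes) anchors the background
#'   percentile used by [preprocessExpression()].
#' @param fracBgProbes Fraction of extra background-only probes
#'   (default 0.25).
#' @param seed Master seed.
#' @return list with \code{probes} (GRanges with \code{probe_id}),
#'   \code{expr} (linear-scale probe x sample matrix), \code{labels}
#'   (logical, TRUE = lengthened group) and \code{truth} (data.frame of
#'   per-gene group usage).
#' @export
simulateArray <- function(sites, nSamples = 100L, fracInformative = 1 / 3,
                          effect = 0.3, noiseSd = 0.25, proximalUsage = 0.65,
                          baseLog2Mean = 8, baseLog2Sd = 1, bgLog2 = 5,
                          fracBgProbes = 0.25, seed = 1L) {
  set.seed(subSeed(seed, "array"))
  bgLevel <- 2^rnorm(nSamples, bgLog2, 0.1)
  genes <- unique(sites$gene_id)
  keep <- genes[vapply(genes, function(g) sum(sites$gene_id == g) >= 2L,
                       logical(1))]
  labels <- rep(c(FALSE, TRUE), length.out = nSamples)
  informative <- setNames(rep(FALSE, length(keep)), keep)
  informative[sample.int(length(keep),
                         round(fracInformative * length(keep)))] <- TRUE

  probeRows <- list(); exprRows <- list(); truthRows <- list()
  for (g in keep) {
    sg <- sites[sites$gene_id == g]
    sg <- sg[order(sg$rank_3p)]
    p1 <- GenomicRanges::start(sg)[1]; p2 <- GenomicRanges::start(sg)[2]
    neg <- as.character(GenomicRanges::strand(sg))[1] == "-"
    mid <- (p1 + p2) %/% 2L
    if (neg) {
      shortIv <- IRanges::IRanges(p1 + 31L, p1 + 70L)
    } else {
      shortIv <- IRanges::IRanges(p1 - 70L, p1 - 31L)
    }
    longIv <- IRanges::IRanges(mid - 19L, mid + 20L)
    ids <- paste0(g, c("_S", "_L"))
    probeRows[[g]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(sg)[1],
      c(shortIv, longIv),
      strand = GenomicRanges::strand(sg)[1],
      probe_id = ids)
    pProx <- rep(proximalUsage, nSamples)
    if (informative[g])
      pProx[labels] <- proximalUsage - effect
    abundance <- 2^rnorm(nSamples, baseLog2Mean, baseLog2Sd)
    shortSig <- 2^(log2(abundance) + rnorm(nSamples, 0, noiseSd)) + bgLevel
    longSig <- 2^(log2(abundance * (1 - pProx)) +
                    rnorm(nSamples, 0, noiseSd)) + bgLevel
    m <- rbind(shortSig, longSig)
    rownames(m) <- ids
    exprRows[[g]] <- m
    truthRows[[g]] <- data.frame(gene_id = g, informative = informative[g],
                                 proximal_ctrl = proximalUsage,
                                 proximal_case = if (informative[g])
                                   proximalUsage - effect else proximalUsage)
  }
  expr <- do.call(rbind, exprRows)
  nBg <- round(fracBgProbes * nrow(expr))
  if (nBg > 0) {
    bgExpr <- outer(rep(1, nBg), bgLevel) *
      2^matrix(rnorm(nBg * nSamples, 0, noiseSd), nBg)
    rownames(bgExpr) <- sprintf("bg_%04d", seq_len(nBg))
    expr <- rbind(expr, bgExpr)
  }
  colnames(expr) <- sprintf("s%03d", seq_len(nSamples))
  probes <- unlist(GenomicRanges::GRangesList(probeRows), use.names = FALSE)
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  list(probes = probes, expr = expr, labels = labels, truth = truth)
}

#' Simulate survival records whose hazard follows an isoform ratio
#'
#' Event times are exponential with hazard
#' \code{baselineHazard * exp(beta * ratio)} where \code{ratio} is the log
#' proximal-to-distal isoform ratio (supplied, or standard normal);
#' censoring is independent exponential at \code{censorRate} (0 = no
#' censoring).  Decoy noise covariates are appended.
#'
#' @param nSamples Number of records (default 100; ignored when
#'   \code{ratio} is supplied).
#' @param beta Log-hazard coefficient of the ratio (default 1).
#' @param baselineHazard Baseline exponential hazard (default 0.1).
#' @param censorRate Exponential censoring rate (default 0.05).
#' @param nNoise Number of uninformative covariates (default 2).
#' @param ratio Optional numeric vector of log proximal-to-distal ratios.
#' @param seed Master seed.
#' @return data.frame: \code{sample_id}, \code{time}, \code{event},
#'   \code{ratio}, \code{noise1..}, plus attribute-free truth columns
#'   \code{true_hazard}.
#' @export
simulateSurvival <- function(nSamples = 100L, beta = 1, baselineHazard = 0.1,
                             censorRate = 0.05, nNoise = 2L, ratio = NULL,
                             seed = 1L) {
  set.seed(subSeed(seed, "survival"))
  if (is.null(ratio))
    ratio <- rnorm(nSamples)
  n <- length(ratio)
  hazard <- baselineHazard * exp(beta * ratio)
  tEvent <- rexp(n, hazard)
  if (censorRate > 0) {
    tCens <- rexp(n, censorRate)
  } else {
    tCens <- rep(Inf, n)
  }
  out <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                    time = pmin(tEvent, tCens),
                    event = as.integer(tEvent <= tCens),
                    ratio = ratio,
                    true_hazard = hazard)
  for (j in seq_len(nNoise))
    out[[paste0("noise", j)]] <- rnorm(n)
  out
}
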