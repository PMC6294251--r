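# Shared fixtures and independent oracles.  Oracles are deliberately written
# as plain brute-force code paths, distinct from the package implementation.

library(GenomicRanges)
library(Biostrings)
library(S4Vectors)

makeGenome <- function(...) {
  DNAStringSet(c(...))
}

makeReads <- function(contig, strand, start, end, soft_tail_A,
                      read_id = sprintf("r%03d", seq_along(start))) {
  gr <- GRanges(contig, IRanges(start, end), strand = strand)
  gr$read_id <- read_id
  gr$soft_tail_A <- as.integer(soft_tail_A)
  gr
}

makeGene <- function(contig, start, end, strand, gene_id,
                     cds_end = NA_integer_, biotype = "coding") {
  gr <- GRanges(contig, IRanges(start, end), strand = strand)
  gr$gene_id <- gene_id
  gr$biotype <- biotype
  gr$cds_end <- as.integer(cds_end)
  gr
}

makeSites <- function(contig, pos, strand, gene_id, rank_3p,
                      class = "tandem", support = 10L, ip_flag = FALSE) {
  gr <- GRanges(contig, IRanges(pos, pos), strand = strand)
  gr$gene_id <- gene_id
  gr$rank_3p <- as.integer(rank_3p)
  gr$isoform_id <- sprintf("%s.%d", gene_id, rank_3p)
  gr$class <- class
  gr$support <- support
  gr$ip_flag <- ip_flag
  gr
}

makeQReads <- function(seqs, phred = 30L, ids = NULL) {
  if (is.null(ids))
    ids <- sprintf("q%04d", seq_along(seqs))
  phred <- rep_len(phred, length(seqs))
  quals <- vapply(seq_along(seqs),
                  function(i) strrep(rawToChar(as.raw(phred[i] + 33L)),
                                     nchar(seqs[i])), "")
  QualityScaledDNAStringSet(DNAStringSet(setNames(seqs, ids)),
                            PhredQuality(quals))
}

# --- independent oracles ----------------------------------------------------

# two-sided Fisher p by exhaustive enumeration with choose() arithmetic
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  pObs <- choose(r1, a) * choose(r2, c) / choose(n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# AUC by exhaustive pairwise comparison, half credit for ties
aucOracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (x in pos)
    for (y in neg)
      s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# DeLong placement values and variance of the AUC difference, explicit loops
delongOracle <- function(scoresA, scoresB, labels) {
  place <- function(sc) {
    x <- sc[labels]; y <- sc[!labels]
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- place(scoresA); pb <- place(scoresB)
  m <- sum(labels); n <- sum(!labels)
  vd <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  list(varDiff = vd, diff = pa$auc - pb$auc,
       p = if (vd <= 0) as.numeric(abs(pa$auc - pb$auc) < 1e-12) else
         2 * pnorm(-abs((pa$auc - pb$auc) / sqrt(vd))))
}

# Harrell C by brute force over usable pairs
harrellOracle <- function(time, event, risk) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # the pair is usable if the earlier time is an event
      ti <- time[i]; tj <- time[j]
      if (ti == tj && event[i] && event[j]) next  # tied event times: unusable (Harrell)
      if (ti < tj && event[i] || tj < ti && event[j]) {
        early <- if (ti < tj) i else j
        late <- if (ti < tj) j else i
        comp <- comp + 1
        if (risk[early] > risk[late]) conc <- conc + 1
        else if (risk[early] == risk[late]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# two-group log-rank statistic from the risk-table definition
logrankOracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in times) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}
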