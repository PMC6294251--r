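# Clinical signature stage: probe-to-isoform mapping, expression
# preprocessing, lengthening indices, group comparison.

#' Map expression-array probes to 3' end isoform regions
#'
#' Restricted to \code{tandem} sites, each gene's transcript is partitioned
#' into isoform-specific regions in transcript orientation: the region
#' upstream of the most proximal site (bounded by \code{maxUpstream}) is the
#' common region, present in every isoform, and proxies the shortest
#' isoform's signal; the region between consecutive sites is specific to the
#' longer isoform(s) cleaved downstream of it.  A probe is assigned to the
#' single region it overlaps; probes overlapping no region or more than one
#' are dropped.  Genes whose probes resolve fewer than two isoforms are
#' dropped.
#'
#' @param probes GRanges of probe genomic intervals with a \code{probe_id}
#'   metadata column (strand-aware).
#' @param annot A [TrendAnnotation-class]; only \code{tandem} isoforms are
#'   used.
#' @param maxUpstream Extent (nt) of the common region upstream of the most
#'   proximal site (default 5000).
#' @return data.frame with one row per retained probe: \code{probe_id},
#'   \code{gene_id}, \code{isoform_id}, \code{role} (\code{"shortest"} for
#'   the most proximal detectable isoform of the gene, else \code{"long"}).
#' @export
mapProbesToIsoforms <- function(probes, annot, maxUpstream = 5000L) {
  gr <- trendSites(annot)
  gr <- gr[gr$class == "tandem"]
  if (!length(gr))
    return(data.frame(probe_id = character(), gene_id = character(),
                      isoform_id = character(), role = character()))
  regs <- list()
  for (g in unique(gr$gene_id)) {
    sites <- gr[gr$gene_id == g]
    neg <- as.character(GenomicRanges::strand(sites))[1] == "-"
    pos <- GenomicRanges::start(sites)
    ord <- order(if (neg) -pos else pos)   # 5' -> 3'
    sites <- sites[ord]; pos <- pos[ord]
    k <- length(sites)
    if (neg) {
      starts <- c(pos[1], if (k > 1) pos[2:k])
      ends <- c(pos[1] + maxUpstream, if (k > 1) pos[1:(k - 1)] - 1L)
    } else {
      starts <- c(pmax(1L, pos[1] - maxUpstream), if (k > 1) pos[1:(k - 1)] + 1L)
      ends <- c(pos[1], if (k > 1) pos[2:k])
    }
    regs[[g]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(sites), IRanges::IRanges(starts, ends),
      strand = GenomicRanges::strand(sites),
      gene_id = g, isoform_id = sites$isoform_id,
      region_rank = seq_len(k))
  }
  regions <- unlist(GenomicRanges::GRangesList(regs), use.names = FALSE)
  # common regions stop where another gene's isoform-specific territory
  # begins, so closely spaced genes do not shadow each other's probes
  commons <- which(regions$region_rank == 1L)
  others <- regions[regions$region_rank > 1L]
  ov <- GenomicRanges::findOverlaps(regions[commons], others)
  if (length(ov)) {
    for (i in unique(S4Vectors::queryHits(ov))) {
      ri <- commons[i]
      hits <- others[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
      hits <- hits[hits$gene_id != regions$gene_id[ri]]
      if (!length(hits)) next
      if (as.character(GenomicRanges::strand(regions))[ri] == "-") {
        GenomicRanges::end(regions)[ri] <-
          max(GenomicRanges::start(regions)[ri],
              min(GenomicRanges::start(hits)) - 1L)
      } else {
        GenomicRanges::start(regions)[ri] <-
          min(GenomicRanges::end(regions)[ri],
              max(GenomicRanges::end(hits)) + 1L)
      }
    }
  }
  nh <- GenomicRanges::countOverlaps(probes, regions)
  ov <- GenomicRanges::findOverlaps(probes[nh == 1L], regions)
  if (!length(ov))
    return(data.frame(probe_id = character(), gene_id = character(),
                      isoform_id = character(), role = character()))
  pid <- probes$probe_id[nh == 1L][S4Vectors::queryHits(ov)]
  hit <- regions[S4Vectors::subjectHits(ov)]
  map <- data.frame(probe_id = pid, gene_id = hit$gene_id,
                    isoform_id = hit$isoform_id,
                    region_rank = hit$region_rank)
  # keep genes resolving >= 2 distinct isoform regions; the most proximal
  # detectable region is the shortest-isoform proxy
  out <- list()
  for (g in unique(map$gene_id)) {
    mg <- map[map$gene_id == g, , drop = FALSE]
    if (length(unique(mg$region_rank)) < 2L)
      next
    mg$role <- ifelse(mg$region_rank == min(mg$region_rank), "shortest", "long")
    out[[g]] <- mg
  }
  if (!length(out))
    return(data.frame(probe_id = character(), gene_id = character(),
                      isoform_id = character(), role = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("probe_id", "gene_id", "isoform_id", "region_rank", "role")]
}

#' Background-correct and quantile-normalize array intensities
#'
#' Per-array background subtraction (the array's \code{bgQuantile} intensity
#' percentile, default the 5th, floored at a small positive constant),
#' followed by quantile normalization across arrays.
#'
#' @param raw Positive numeric matrix, probes in rows, arrays in columns.
#' @param bgQuantile Background percentile subtracted per array
#'   (default 0.05).
#' @param floor Positive floor applied after subtraction (default 0.01).
#' @return Normalized matrix of the same shape.
#' @export
preprocessExpression <- function(raw, bgQuantile = 0.05, floor = 0.01) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw)))
    stop("intensities must be finite")
  if (floor <= 0)
    stop("'floor' must be positive")
  bg <- apply(raw, 2L, stats::quantile, probs = bgQuantile, names = FALSE)
  x <- pmax(sweep(raw, 2L, bg), floor)
  if (any(x <= 0))
    stop("non-positive intensities after background correction")
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(raw)
  out
}

#' Per-gene, per-sample lengthening index
#'
#' For each gene with probe-resolved isoforms, the expression of each
#' detectable long isoform is divided by the expression of the shortest
#' (common-region) signal, per sample, on linear scale.  Multiple probes in
#' one region are averaged.  A zero denominator flags the sample missing
#' (NA) for that gene.
#'
#' @param expr Preprocessed linear-scale expression matrix (probes x
#'   samples; rownames are probe ids).
#' @param map Probe map from [mapProbesToIsoforms()].
#' @return list with \code{li} (matrix, one row per gene x long-isoform
#'   series, samples in columns) and \code{info} (data.frame: series_id,
#'   gene_id, long_isoform_id).
#' @export
lengtheningIndex <- function(expr, map) {
  expr <- as.matrix(expr)
  rows <- list(); info <- list()
  for (g in unique(map$gene_id)) {
    mg <- map[map$gene_id == g, , drop = FALSE]
    shortProbes <- mg$probe_id[mg$role == "shortest"]
    if (!length(shortProbes))
      next
    short <- colMeans(expr[shortProbes, , drop = FALSE])
    for (iso in unique(mg$isoform_id[mg$role == "long"])) {
      longProbes <- mg$probe_id[mg$isoform_id == iso & mg$role == "long"]
      long <- colMeans(expr[longProbes, , drop = FALSE])
      li <- long / short
      li[short == 0] <- NA_real_
      sid <- paste(g, iso, sep = "|")
      rows[[sid]] <- li
      info[[sid]] <- data.frame(series_id = sid, gene_id = g,
                                long_isoform_id = iso)
    }
  }
  if (!length(rows))
    return(list(li = matrix(numeric(), 0, ncol(expr)),
                info = data.frame(series_id = character(),
                                  gene_id = character(),
                                  long_isoform_id = character())))
  li <- do.call(rbind, rows)
  colnames(li) <- colnames(expr)
  inf <- do.call(rbind, info)
  rownames(inf) <- NULL
  list(li = li, info = inf)
}

#' Two-group comparison of a lengthening index
#'
#' Two-sided two-sample t-test on the log2 lengthening index (ratio data are
#' compared on log scale; raw values are preserved in outputs).
#'
#' @param li Numeric vector of lengthening indices (one per sample).
#' @param groups Two-level factor (or coercible) parallel to \code{li}.
#' @param logScale Compare on log2 scale (default TRUE).
#' @return list with \code{t}, \code{p}, \code{df}, \code{means} (group
#'   means on the analysis scale); \code{p} is NA when a group variance is
#'   degenerate.
#' @export
groupCompareLI <- function(li, groups, logScale = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required")
  ok <- is.finite(li)
  li <- li[ok]; groups <- droplevels(groups[ok])
  if (min(table(groups)) < 2L)
    stop("each group needs >= 2 samples")
  y <- if (logScale) log2(li) else li
  means <- tapply(y, groups, mean)
  if (any(tapply(y, groups, function(v) isTRUE(all.equal(stats::var(v), 0))))) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, means = means))
  }
  tt <- t.test(y ~ groups)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), means = means)
}
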