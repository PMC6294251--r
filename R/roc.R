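# ROC / AUC machinery: rank-statistic AUC, DeLong and bootstrap AUC
# comparison, signature-gene selection, multifactor (combined) ROC.

#' ROC curve and AUC
#'
#' The AUC is computed as the normalized Mann-Whitney rank statistic with
#' half credit for ties; the curve enumerates all score thresholds.
#'
#' @param scores Numeric per-sample scores (larger = more positive-like).
#' @param labels Binary labels (logical, or coercible 0/1); both classes
#'   must be present.
#' @return A [RocResult-class].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels)))
    stop("scores/labels must not contain NA")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present")
  r <- rank(scores)  # midranks: ties get half credit
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  new("RocResult", auc = auc, scores = as.numeric(scores), labels = labels,
      curve = curve, nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

# DeLong placement values via midranks (Sun & Xu style fast computation):
# V10[i] = placement of positive i among negatives, V01[j] likewise.
.delongPlacements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  rAll <- rank(c(x, y))
  rX <- rank(x); rY <- rank(y)
  v10 <- (rAll[seq_len(m)] - rX) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - rY) / m
  list(v10 = v10, v01 = v01, auc = sum(rAll[seq_len(m)] - rX) / (m * n))
}

#' Compare two paired AUCs (DeLong or bootstrap)
#'
#' Both ROC curves must be computed on the same samples (identical label
#' vectors), as in comparing two candidate markers on one cohort.  DeLong's
#' method estimates the variance of the AUC difference from placement
#' values and applies a two-sided z-test; the bootstrap method resamples
#' samples (stratified by class) and returns a two-sided percentile p.
#'
#' @param rocA,rocB [RocResult-class] objects over the same samples.
#' @param method \code{"delong"} (default) or \code{"bootstrap"}.
#' @param nBoot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return list with \code{p}, \code{aucA}, \code{aucB}, \code{method}, and
#'   \code{z} (DeLong) or \code{nBoot}.
#' @export
compareAuc <- function(rocA, rocB, method = c("delong", "bootstrap"),
                       nBoot = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (length(rocA@labels) != length(rocB@labels) ||
      !all(rocA@labels == rocB@labels))
    stop("AUC comparison requires paired ROCs over identical samples")
  labels <- rocA@labels
  if (method == "delong") {
    pa <- .delongPlacements(rocA@scores, labels)
    pb <- .delongPlacements(rocB@scores, labels)
    m <- sum(labels); n <- sum(!labels)
    vdiff <- 0
    if (m > 1L) vdiff <- vdiff + stats::var(pa$v10 - pb$v10) / m
    if (n > 1L) vdiff <- vdiff + stats::var(pa$v01 - pb$v01) / n
    diff <- rocA@auc - rocB@auc
    if (vdiff <= 0) {
      z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else sign(diff) * Inf
    } else {
      z <- diff / sqrt(vdiff)
    }
    list(p = 2 * pnorm(-abs(z)), aucA = rocA@auc, aucB = rocB@auc,
         method = "delong", z = z, varDiff = vdiff)
  } else {
    set.seed(subSeed(seed, "boot"))
    posIdx <- which(labels); negIdx <- which(!labels)
    d <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- c(sample(posIdx, length(posIdx), replace = TRUE),
               sample(negIdx, length(negIdx), replace = TRUE))
      lab <- labels[idx]
      d[b] <- rocAuc(rocA@scores[idx], lab)@auc -
        rocAuc(rocB@scores[idx], lab)@auc
    }
    p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
    list(p = p, aucA = rocA@auc, aucB = rocB@auc, method = "bootstrap",
         nBoot = nBoot)
  }
}

#' Select signature genes by AUC threshold
#'
#' @param aucs Named numeric vector of per-gene AUCs.
#' @param threshold Strict lower bound (default 0.7): genes with
#'   \code{auc > threshold} are retained.
#' @return Gene names ordered by descending AUC.
#' @export
selectSignatureGenes <- function(aucs, threshold = 0.7) {
  keep <- aucs[aucs > threshold]
  names(sort(keep, decreasing = TRUE))
}

#' Multifactor (combined) ROC over a gene signature
#'
#' Combines per-gene log2 short-to-long isoform ratios into one score with a
#' ridge-penalized logistic model fitted on a stratified training split
#' (default 70%), and evaluates the ROC on the held-out split.  The ridge
#' penalty keeps the fit defined under separation and collinearity
#' (e.g. duplicated informative genes).
#'
#' @param li Matrix of lengthening indices (long/short), signature genes in
#'   rows, samples in columns; the model input is \code{-log2(li)}, the log2
#'   short-to-long ratio.
#' @param labels Binary per-sample labels.
#' @param trainFrac Training fraction (default 0.7).
#' @param seed Seed for the split.
#' @param lambda Ridge penalty (default 0.01).
#' @return list with \code{roc} (held-out [RocResult-class]),
#'   \code{coefficients}, \code{trainIdx}.
#' @export
multifactorRoc <- function(li, labels, trainFrac = 0.7, seed = 1L,
                           lambda = 0.01) {
  labels <- as.logical(labels)
  if (nrow(li) < 2L)
    stop("the combined ROC needs >= 2 signature genes")
  x <- t(-log2(li))
  set.seed(subSeed(seed, "split"))
  posIdx <- which(labels); negIdx <- which(!labels)
  tr <- c(sample(posIdx, floor(trainFrac * length(posIdx))),
          sample(negIdx, floor(trainFrac * length(negIdx))))
  te <- setdiff(seq_along(labels), tr)
  fit <- glmnet::glmnet(x[tr, , drop = FALSE], factor(labels[tr]),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  score <- as.numeric(predict(fit, x[te, , drop = FALSE]))
  list(roc = rocAuc(score, labels[te]),
       coefficients = as.numeric(stats::coef(fit))[-1],
       trainIdx = sort(tr))
}
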