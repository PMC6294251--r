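# Survival stage: Kaplan-Meier/log-rank, Harrell concordance, and the
# bootstrapped train/validate Cox concordance pipeline.

#' Kaplan-Meier curves and the log-rank test
#'
#' Product-limit survival estimates per group and the two-group (or k-group)
#' log-rank statistic.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (0 censored / 1 event).
#' @param group Grouping vector (two or more non-empty levels).
#' @return list with \code{chisq}, \code{df}, \code{p} and \code{fit} (the
#'   \code{survfit} object with the KM curves).  \code{chisq}/\code{p} are NA
#'   when no events occurred.
#' @export
kmLogrank <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("all groups must be non-empty (>= 2 groups)")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0L)
    return(list(chisq = NA_real_, df = nlevels(group) - 1L, p = NA_real_,
                fit = fit))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE), fit = fit)
}

#' Log-rank scan over candidate groupings with BH adjustment
#'
#' When several candidate dichotomizations of a marker are scanned (e.g.
#' expression cutpoints), the per-grouping log-rank p-values are
#' BH-adjusted across the scan.
#'
#' @inheritParams kmLogrank
#' @param groupings Named list of grouping vectors.
#' @return data.frame with \code{grouping}, \code{chisq}, \code{p},
#'   \code{p_adj}.
#' @export
kmScan <- function(time, event, groupings) {
  res <- lapply(groupings, function(g) kmLogrank(time, event, g))
  df <- data.frame(grouping = names(groupings),
                   chisq = vapply(res, `[[`, numeric(1), "chisq"),
                   p = vapply(res, `[[`, numeric(1), "p"))
  df$p_adj <- bhAdjust(df$p)
  rownames(df) <- NULL
  df
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable (usable) pair, the sample with the
#' higher risk score fails first; 0.5 = chance, 1 = perfect concordance.
#'
#' @param time,event Survival outcome.
#' @param risk Numeric risk scores (higher = earlier expected failure).
#' @return The C-index.
#' @export
harrellC <- function(time, event, risk) {
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  unname(cf$concordance)
}

#' Bootstrapped Cox train/validate concordance comparison
#'
#' For each bootstrap replicate the cohort is split into a training fraction
#' (stratified on event status) and a validation remainder; each candidate
#' covariate set is fitted by a Cox proportional-hazards model (Efron tie
#' handling) on the training split and scored by Harrell's C-index on the
#' held-out split.  Models are compared by a two-sided paired t-test on the
#' replicate C-index samples.  Replicates where any model fails to converge
#' are dropped; more than 20% dropped is an error.
#'
#' @param data data.frame with columns \code{time}, \code{event} and the
#'   covariates.
#' @param covariateSets Named list of character vectors (covariate columns
#'   per model).
#' @param trainFrac Training fraction (default 0.7).
#' @param nBoot Number of bootstrap replicates (default 100).
#' @param seed Master seed; replicate streams are derived by counter so the
#'   first replicates are identical whatever \code{nBoot}.
#' @return list with \code{cindex} (replicates x models matrix),
#'   \code{means}, \code{comparisons} (data.frame of pairwise paired t-test
#'   p-values), \code{nDropped}.
#' @export
coxBootstrap <- function(data, covariateSets, trainFrac = 0.7, nBoot = 100L,
                         seed = 1L) {
  stopifnot(all(c("time", "event") %in% colnames(data)))
  models <- names(covariateSets)
  if (is.null(models))
    stop("covariateSets must be a named list")
  ev1 <- which(data$event == 1); ev0 <- which(data$event == 0)
  C <- matrix(NA_real_, nBoot, length(models), dimnames = list(NULL, models))
  for (b in seq_len(nBoot)) {
    set.seed(subSeed(seed, "boot", counter = b))
    tr <- c(sample(ev1, floor(trainFrac * length(ev1))),
            sample(ev0, floor(trainFrac * length(ev0))))
    te <- setdiff(seq_len(nrow(data)), tr)
    for (m in seq_along(models)) {
      covs <- covariateSets[[m]]
      fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                     paste(covs, collapse = " + ")))
      fit <- tryCatch(
        withCallingHandlers(
          survival::coxph(fml, data = data[tr, , drop = FALSE],
                          ties = "efron"),
          warning = function(w) {
            if (grepl("converge|infinite|singular", conditionMessage(w)))
              stop("non-convergence")
            invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
      if (is.null(fit))
        next
      cc <- tryCatch(
        survival::concordance(fit, newdata = data[te, , drop = FALSE]),
        error = function(e) NULL)
      if (!is.null(cc))
        C[b, m] <- unname(cc$concordance)
    }
  }
  ok <- stats::complete.cases(C)
  nDropped <- sum(!ok)
  if (nDropped > 0.2 * nBoot)
    stop(sprintf("%d of %d bootstrap replicates failed to converge", nDropped,
                 nBoot))
  C <- C[ok, , drop = FALSE]
  comparisons <- NULL
  if (length(models) >= 2L) {
    rows <- list()
    for (i in seq_len(length(models) - 1L)) {
      for (j in seq(i + 1L, length(models))) {
        tt <- t.test(C[, i], C[, j], paired = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          model_a = models[i], model_b = models[j],
          mean_diff = mean(C[, i] - C[, j]), p = tt$p.value)
      }
    }
    comparisons <- do.call(rbind, rows)
  }
  list(cindex = C, means = colMeans(C), comparisons = comparisons,
       nDropped = nDropped)
}
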