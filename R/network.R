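# APA-regulator interaction network: pairwise synergy/antagonism from shared
# affected genes, and a force-directed layout.

#' Per-regulator profiles of affected genes
#'
#' Converts per-gene test summaries (one per knockdown) into regulator
#' profiles: the set of genes with a defined shortening index, each with the
#' direction sign (+1 shortened, -1 lengthened).
#'
#' @param geneResultsList Named list (one entry per regulator/knockdown) of
#'   per-gene data.frames as returned by \code{geneResults(testTrend(...))},
#'   or of [TrendTestResult-class] objects.
#' @return Named list of signed integer vectors (names = gene ids).
#' @export
regulatorProfiles <- function(geneResultsList) {
  lapply(geneResultsList, function(df) {
    if (is(df, "TrendTestResult"))
      df <- geneResults(df)
    df <- df[!is.na(df$si) & df$direction %in% c("shortened", "lengthened"), ,
             drop = FALSE]
    setNames(ifelse(df$direction == "shortened", 1L, -1L), df$gene_id)
  })
}

#' Pairwise synergy/antagonism between two regulators
#'
#' Two knockdowns interact synergistically when they affect shared genes in
#' the same direction and antagonistically when directions oppose.  The edge
#' score is \code{(2*concordance - 1) * overlap_weight} with
#' \code{overlap_weight = n_shared / min(|a|, |b|)}, so a clone pair scores
#' +1, a mirror pair -1 and unrelated regulators ~0; overlap significance is
#' the hypergeometric enrichment of the shared set ([setEnrichment()]).
#'
#' @param a,b Signed profiles from [regulatorProfiles()].
#' @param universe Character vector of all genes eligible in both screens.
#' @return One-row data.frame: \code{n_shared}, \code{concordance},
#'   \code{score}, \code{p}.
#' @export
pairwiseInteraction <- function(a, b, universe) {
  if (!length(universe))
    stop("empty gene universe")
  shared <- intersect(names(a), names(b))
  nShared <- length(shared)
  if (!length(a) || !length(b) || !nShared) {
    return(data.frame(n_shared = nShared, concordance = NA_real_,
                      score = 0, p = 1))
  }
  concordance <- mean(a[shared] == b[shared])
  weight <- nShared / min(length(a), length(b))
  p <- setEnrichment(names(a), universe, names(b))
  data.frame(n_shared = nShared, concordance = concordance,
             score = (2 * concordance - 1) * weight, p = p)
}

#' Build the regulator interaction network
#'
#' All pairwise interactions between regulator profiles; edges with
#' \code{p > pruneP} or fewer than \code{minShared} shared genes are pruned.
#'
#' @param profiles Named list from [regulatorProfiles()].
#' @param universe Gene universe (default: union of all affected sets).
#' @param pruneP Edge significance cutoff (default 0.05).
#' @param minShared Minimum shared genes per retained edge (default 5).
#' @return data.frame of edges: \code{reg_a}, \code{reg_b}, \code{n_shared},
#'   \code{concordance}, \code{score}, \code{p}.
#' @export
buildRegulatorNetwork <- function(profiles, universe = NULL, pruneP = 0.05,
                                  minShared = 5L) {
  regs <- names(profiles)
  if (is.null(universe))
    universe <- unique(unlist(lapply(profiles, names)))
  rows <- list()
  if (length(regs) >= 2L) {
    for (i in seq_len(length(regs) - 1L)) {
      for (j in seq(i + 1L, length(regs))) {
        e <- pairwiseInteraction(profiles[[i]], profiles[[j]], universe)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(reg_a = regs[i], reg_b = regs[j]), e)
      }
    }
  }
  if (!length(rows))
    return(data.frame(reg_a = character(), reg_b = character(),
                      n_shared = integer(), concordance = numeric(),
                      score = numeric(), p = numeric()))
  edges <- do.call(rbind, rows)
  edges[edges$p <= pruneP & edges$n_shared >= minShared, , drop = FALSE]
}

#' Force-directed (Fruchterman-Reingold) network layout
#'
#' Standard Fruchterman-Reingold placement with the interaction semantics of
#' the regulator map: synergistic edges attract with strength proportional to
#' \code{max(score, 0) * min(-log10(p), 10)}, antagonistic pairs receive
#' extra pairwise repulsion proportional to \code{max(-score, 0)}.
#' Deterministic for a fixed seed.
#'
#' @param edges Edge data.frame from [buildRegulatorNetwork()].
#' @param nodes Optional character vector of node names (default: all nodes
#'   appearing in \code{edges}).
#' @param iterations Number of cooling iterations (default 500).
#' @param seed Integer seed for the initial placement.
#' @param area Layout area (default 1).
#' @param attractScale,repelScale Coefficients of the interaction-specific
#'   attraction/repulsion terms.
#' @return data.frame with \code{node}, \code{x}, \code{y}.
#' @export
layoutForceDirected <- function(edges, nodes = NULL, iterations = 500L,
                                seed = 1L, area = 1, attractScale = 1,
                                repelScale = 1) {
  if (is.null(nodes))
    nodes <- unique(c(as.character(edges$reg_a), as.character(edges$reg_b)))
  n <- length(nodes)
  if (!n)
    return(data.frame(node = character(), x = numeric(), y = numeric()))
  set.seed(subSeed(seed, "layout"))
  pos <- matrix(runif(2L * n, -sqrt(area) / 2, sqrt(area) / 2), ncol = 2L)
  if (n == 1L)
    return(data.frame(node = nodes, x = pos[1, 1], y = pos[1, 2]))
  k <- sqrt(area / n)

  ia <- match(as.character(edges$reg_a), nodes)
  ib <- match(as.character(edges$reg_b), nodes)
  attract <- pmax(edges$score, 0) * pmin(-log10(pmax(edges$p, 1e-300)), 10) *
    attractScale
  repel <- pmax(-edges$score, 0) * repelScale
  t0 <- 0.1 * sqrt(area)
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2L)
    # global pairwise repulsion
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2); d[d < 1e-9] <- 1e-9
    f <- k * k / d; diag(f) <- 0
    disp[, 1] <- rowSums(dx / d * f)
    disp[, 2] <- rowSums(dy / d * f)
    # edge-specific terms
    if (length(ia)) {
      ex <- pos[ia, 1] - pos[ib, 1]
      ey <- pos[ia, 2] - pos[ib, 2]
      ed <- sqrt(ex * ex + ey * ey); ed[ed < 1e-9] <- 1e-9
      fa <- ed * ed / k * attract       # attraction towards the partner
      fr <- k * k / ed * repel          # extra antagonistic repulsion
      for (e in seq_along(ia)) {
        ux <- ex[e] / ed[e]; uy <- ey[e] / ed[e]
        disp[ia[e], ] <- disp[ia[e], ] + c(-ux, -uy) * fa[e] + c(ux, uy) * fr[e]
        disp[ib[e], ] <- disp[ib[e], ] + c(ux, uy) * fa[e] + c(-ux, -uy) * fr[e]
      }
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    len <- sqrt(rowSums(disp^2)); len[len < 1e-9] <- 1e-9
    step <- pmin(len, temp)
    pos <- pos + disp / len * step
  }
  data.frame(node = nodes, x = pos[, 1], y = pos[, 2])
}
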