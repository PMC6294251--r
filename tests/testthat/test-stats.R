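# Statistical core: Fisher, BH, fold-regulation, Zero-isoform, shortening
# index, set enrichment, and the testTrend wrapper.

test_that("Fisher exact test follows the point-probability rule", {
  expect_equal(fisherIsoformTest(50, 50, 50, 50), 1)
  expect_equal(fisherIsoformTest(0, 100, 0, 100), 1)
  expect_equal(fisherIsoformTest(10, 90, 90, 10),
               fisherOracle(10, 90, 90, 10), tolerance = 1e-9)
  expect_error(fisherIsoformTest(-1, 5, 5, 5), "non-negative")
  expect_error(fisherIsoformTest(0, 0, 5, 5), "positive")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:60) {
    tb <- as.integer(sample.int(80, 4, replace = TRUE) - 1L)
    if ((tb[1] + tb[2]) == 0 || (tb[3] + tb[4]) == 0) next
    ours <- fisherIsoformTest(tb[1], tb[2], tb[3], tb[4])
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # closed form: p_adj(i) = min over i' >= i of m * p_(i') / i'
  set.seed(11)
  p <- runif(40)
  m <- length(p)
  o <- order(p)
  closed <- numeric(m)
  for (i in seq_len(m))
    closed[o[i]] <- min(1, m * sort(p)[i:m] / seq(i, m))
  expect_equal(bhAdjust(p), closed)
  expect_true(all(bhAdjust(p) >= p))
  # permutation invariance
  perm <- sample(m)
  expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold-regulation is percentage-based and scale-invariant", {
  fr <- foldRegulation(c(30, 70), c(50, 50), pseudocount = 0)
  expect_equal(fr$fc, c(0.6, 1.4))
  expect_equal(sum(fr$pct_kd), 100)
  expect_equal(sum(fr$pct_ctrl), 100)

  fr2 <- foldRegulation(c(10, 20, 30), c(10, 20, 30), pseudocount = 0)
  expect_equal(fr2$fc, rep(1, 3))

  fr3 <- foldRegulation(c(0, 100), c(50, 50), pseudocount = 0.5)
  expect_equal(fr3$fc[1], (0.5 / 101) / (50.5 / 101))

  # per-condition library scaling cancels
  fr4 <- foldRegulation(c(30, 70) * 7, c(50, 50) * 3, pseudocount = 0)
  expect_equal(fr4$fc, fr$fc)

  frZ <- foldRegulation(c(0, 0), c(5, 5))
  expect_true(attr(frZ, "untestable"))
  expect_error(foldRegulation(5, 5), ">= 2")
})

test_that("the Zero-isoform is the most distal significant annotated isoform", {
  df <- data.frame(isoform_id = c("g.1", "g.2", "g.3"),
                   class = c("tandem", "tandem", "tandem"),
                   pos = c(100, 400, 900), strand = "+",
                   p_adj = c(0.01, 0.5, 0.02))
  expect_equal(zeroIsoform(df), "g.3")
  df$class <- c("tandem", "tandem", "novel")
  expect_equal(zeroIsoform(df), "g.1")
  df$p_adj <- c(0.9, 0.9, 0.01)  # only the novel isoform is significant
  expect_true(is.na(zeroIsoform(df)))
  df$p_adj <- rep(0.9, 3)
  expect_true(is.na(zeroIsoform(df)))
  # minus strand: distal = smallest coordinate
  dfn <- data.frame(isoform_id = c("g.1", "g.2"), class = "tandem",
                    pos = c(900, 300), strand = "-", p_adj = c(0.01, 0.01))
  expect_equal(zeroIsoform(dfn), "g.2")
})

test_that("relative positions are signed transcript-orientation distances", {
  df <- data.frame(isoform_id = c("g.1", "g.2"), class = "tandem",
                   pos = c(600, 1000), strand = "+",
                   p_adj = c(0.01, 0.01), fc = c(2, 0.5))
  rp <- relativeProfile(df, "g.2")
  expect_equal(rp$rel_pos[rp$isoform_id == "g.2"], 0)
  expect_equal(rp$rel_pos[rp$isoform_id == "g.1"], -400)

  dfn <- data.frame(isoform_id = c("g.1", "g.2"), class = "tandem",
                    pos = c(1250, 1000), strand = "-",
                    p_adj = c(0.01, 0.01), fc = c(2, 0.5))
  rp2 <- relativeProfile(dfn, "g.2")
  expect_equal(rp2$rel_pos[rp2$isoform_id == "g.1"], -250)
  expect_error(relativeProfile(df, NA_character_), "undefined")
})

test_that("shortening index sign encodes the short/long fold-regulation ratio", {
  mk <- function(fcShort, fcLong, strand = "+") {
    data.frame(isoform_id = c("g.1", "g.2"), class = "tandem",
               pos = if (strand == "+") c(100, 500) else c(500, 100),
               strand = strand, p = c(1e-6, 1e-6), p_adj = c(1e-5, 1e-5),
               fc = c(fcShort, fcLong))
  }
  expect_equal(shorteningIndex(mk(2, 0.5)),
               list(si = 2, direction = "shortened"))
  expect_equal(shorteningIndex(mk(0.5, 2)),
               list(si = -2, direction = "lengthened"))
  expect_equal(shorteningIndex(mk(1.3, 1.3))$si, 0)
  # strand-aware: same transcript-level pattern on the minus strand
  expect_equal(shorteningIndex(mk(2, 0.5, strand = "-"))$si, 2)
  # fewer than two significant isoforms -> undefined
  one <- mk(2, 0.5); one$p_adj <- c(1e-5, 0.9)
  expect_null(shorteningIndex(one))
})

test_that("the two most significant isoforms are selected deterministically", {
  df <- data.frame(isoform_id = paste0("g.", 1:4), class = "tandem",
                   pos = c(100, 300, 500, 700), strand = "+",
                   p = c(1e-8, 1e-3, 1e-8, 0.04),
                   p_adj = c(1e-6, 1e-2, 1e-6, 0.049),
                   fc = c(4, 1, 0.25, 1))
  # pair = isoforms 1 and 3 (smallest p_adj); si = log2(4/0.25) = 4
  expect_equal(shorteningIndex(df)$si, 4)
})

test_that("set enrichment equals the closed-form hypergeometric tail", {
  universe <- sprintf("u%03d", 1:100)
  category <- universe[1:10]
  expect_equal(setEnrichment(universe, universe, universe), 1)
  expect_equal(setEnrichment(category, universe, category),
               choose(10, 10) * choose(90, 0) / choose(100, 10))
  # zero overlap: P(overlap >= 0) = 1 exactly
  expect_equal(setEnrichment(universe[51:60], universe, category), 1)
  expect_error(setEnrichment(c("zz"), universe, category), "subset")
})

test_that("testTrend integrates Fisher, BH and gene summaries", {
  sites <- c(makeSites("c1", 1000, "+", "gA", 1),
             makeSites("c1", 1500, "+", "gA", 2),
             makeSites("c1", 9000, "+", "gB", 1),
             makeSites("c1", 9500, "+", "gB", 2))
  counts <- matrix(c(20L, 180L, 100L, 100L,   # KD
                     180L, 20L, 100L, 100L),  # Ctrl
                   ncol = 2, dimnames = list(sites$isoform_id, c("KD", "Ctrl")))
  tc <- TrendCounts(counts, rowRanges = sites)
  res <- testTrend(tc, "KD", "Ctrl")
  ir <- isoformResults(res)
  gr <- geneResults(res)
  # gA: proximal collapses, distal rises -> lengthened, si < 0
  expect_equal(gr$direction[gr$gene_id == "gA"], "lengthened")
  expect_lt(gr$si[gr$gene_id == "gA"], 0)
  expect_equal(gr$zero_isoform[gr$gene_id == "gA"], "gA.2")
  # gB is null
  expect_equal(gr$direction[gr$gene_id == "gB"], "none")
  expect_true(all(ir$p_adj[ir$gene_id == "gB"] > 0.05))
  # percentages sum to 100 within each gene and condition
  for (g in c("gA", "gB")) {
    expect_equal(sum(ir$pct_kd[ir$gene_id == g]), 100)
    expect_equal(sum(ir$pct_ctrl[ir$gene_id == g]), 100)
  }
  # relative positions anchored at the Zero-isoform
  expect_equal(ir$rel_pos[ir$isoform_id == "gA.2"], 0)
  expect_equal(ir$rel_pos[ir$isoform_id == "gA.1"], -500)
})

test_that("swapping conditions negates the shortening index exactly", {
  set.seed(5)
  cts <- simulateCounts(nGenes = 40, effect = 0.3, fracPerturbed = 0.5,
                        depth = 150, seed = 6)
  fwd <- geneResults(testTrend(cts, "KD", "Ctrl"))
  rev <- geneResults(testTrend(cts, "Ctrl", "KD"))
  m <- merge(fwd, rev, by = "gene_id")
  both <- !is.na(m$si.x) & !is.na(m$si.y)
  expect_gt(sum(both), 5)
  expect_equal(m$si.x[both], -m$si.y[both])
})

test_that("single-isoform and shallow genes are untestable, not p = 1", {
  sites <- c(makeSites("c1", 1000, "+", "gSolo", 1),
             makeSites("c1", 5000, "+", "gThin", 1),
             makeSites("c1", 5400, "+", "gThin", 2))
  counts <- matrix(c(50L, 2L, 3L, 50L, 2L, 2L), ncol = 2,
                   dimnames = list(sites$isoform_id, c("KD", "Ctrl")))
  tc <- TrendCounts(counts, rowRanges = sites)
  res <- testTrend(tc, "KD", "Ctrl", minGeneReads = 10)
  expect_equal(nrow(isoformResults(res)), 0L)
})
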