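# Synthetic-data generators: determinism, distributional ground truth, and
# the features the pipeline's filters exercise.

test_that("reference simulation is deterministic and validates its config", {
  r1 <- simulateReference(nGenes = 8, seed = 5)
  r2 <- simulateReference(nGenes = 8, seed = 5)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(start(r1$sites), start(r2$sites))
  r3 <- simulateReference(nGenes = 8, seed = 6)
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))

  r0 <- simulateReference(nGenes = 0, seed = 5)
  expect_equal(length(r0$genes), 0L)
  expect_gt(width(r0$genome)[1], 0)

  expect_error(simulateReference(spacing = c(50, 80)), "spacing")
  expect_error(simulateReference(intergenic = 50), "too small")
})

test_that("planted sites respect the gene structure", {
  ref <- simulateReference(nGenes = 10, seed = 8)
  # >= 100 nt spacing within genes, tandem class, ranks are 1..k
  for (g in unique(ref$sites$gene_id)) {
    s <- ref$sites[ref$sites$gene_id == g]
    expect_gte(min(diff(sort(start(s)))), 100)
    expect_setequal(s$rank_3p, seq_along(s))
  }
  expect_true(validObject(TrendAnnotation(ref$sites)))
})

test_that("counts follow the planted multinomial usage", {
  cts <- simulateCounts(nGenes = 30, effect = 0, fracPerturbed = 0,
                        depth = 200, seed = 9)
  m <- trendCounts(cts)
  gid <- SummarizedExperiment::rowRanges(cts)$gene_id
  sums <- rowsum(m, gid)
  expect_true(all(sums == 200L))  # fixed depth without jitter

  # law of large numbers: counts match depth * usage in expectation, with
  # per-replicate usage read back from the recorded ground truth
  reps <- 300
  dev <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    ci <- simulateCounts(nGenes = 1, isoformsPerGene = c(3, 3),
                         usageAlpha = 2, effect = 0, fracPerturbed = 0,
                         depth = 100, seed = 1000 + i)
    u <- S4Vectors::metadata(ci)$usage$ctrl[[1]]
    dev[i, ] <- trendCounts(ci)[, "Ctrl"] - 100 * u
  }
  # multinomial variance is at most depth/4 per isoform
  seMax <- sqrt(25 / reps)
  expect_true(all(abs(colMeans(dev)) <= 3 * seMax))
})

test_that("a large effect drives knockdown usage to the distal isoform", {
  cts <- simulateCounts(nGenes = 40, isoformsPerGene = c(2, 2), effect = 0.9,
                        fracPerturbed = 1, depth = 300, seed = 10)
  m <- trendCounts(cts)
  rr <- SummarizedExperiment::rowRanges(cts)
  distal <- rr$rank_3p == 2
  distalFrac <- sum(m[distal, "KD"]) / sum(m[, "KD"])
  expect_gt(distalFrac, 0.85)
  # truth labels the perturbation direction
  truth <- S4Vectors::metadata(cts)$truth
  expect_true(all(truth$direction == "lengthened"))
})

test_that("zero effect leaves both conditions exchangeable", {
  cts <- simulateCounts(nGenes = 50, effect = 0, fracPerturbed = 0.5,
                        depth = 200, seed = 11)
  truth <- S4Vectors::metadata(cts)$truth
  expect_true(all(truth$delta == 0))
  expect_true(all(truth$direction == "none"))
})

test_that("simulated reads carry barcode, tail and quality structure", {
  ref <- simulateReference(nGenes = 6, seed = 12)
  cts <- simulateCounts(sites = ref$sites, depth = 20, seed = 12)
  fq <- simulateFastq(ref, cts, seed = 12)
  expect_equal(length(fq$r1), length(fq$r2))
  expect_equal(length(fq$r2), sum(trendCounts(cts)))
  expect_true(all(width(fq$r2) == 50))
  expect_true(all(as.character(fq$r1) %in% c("ACGTACGTA", "TGCATGCAT")))
  # every read ends in its recorded A-tail
  tails <- fq$truth$tail
  expect_true(all(substr(as.character(fq$r2), 51 - tails, 50) ==
                    strrep("A", tails)))
  # low quality sinks every pair at demultiplexing
  fqLow <- simulateFastq(ref, cts, qualityPhred = 10, seed = 12)
  dm <- demultiplexReads(fqLow$r1, fqLow$r2,
                         c(ACGTACGTA = "KD", TGCATGCAT = "Ctrl"))
  expect_equal(unname(dm$tally["low_quality"]), length(fqLow$r2))
})

test_that("array simulation encodes the planted lengthening contrast", {
  ref <- simulateReference(nGenes = 40, seed = 13)
  arr <- simulateArray(ref$sites, nSamples = 80, fracInformative = 0.4,
                       effect = 0.3, noiseSd = 0.15, seed = 13)
  map <- mapProbesToIsoforms(arr$probes, TrendAnnotation(ref$sites))
  expect_gt(length(unique(map$gene_id)), 10)
  li <- lengtheningIndex(preprocessExpression(arr$expr), map)
  aucs <- apply(li$li, 1, function(v) rocAuc(v, arr$labels)@auc)
  inf <- li$info$gene_id %in% arr$truth$gene_id[arr$truth$informative]
  expect_gt(mean(aucs[inf]), 0.8)
  # uninformative genes sit near chance; quantile normalization couples
  # arrays slightly when many genes shift one way, hence the wider band
  expect_lt(abs(mean(aucs[!inf]) - 0.5), 0.08)

  # with no effect anywhere, every gene is at chance after preprocessing
  arr0 <- simulateArray(ref$sites, nSamples = 80, fracInformative = 0,
                        effect = 0, noiseSd = 0.15, seed = 14)
  li0 <- lengtheningIndex(preprocessExpression(arr0$expr), map)
  aucs0 <- apply(li0$li, 1, function(v) rocAuc(v, arr0$labels)@auc)
  expect_lt(abs(mean(aucs0) - 0.5), 0.04)

  # ratio invariance: rescaling one whole array cancels in the index
  expr2 <- arr$expr
  expr2[, 3] <- expr2[, 3] * 2
  li2 <- lengtheningIndex(expr2, map)
  liRaw <- lengtheningIndex(arr$expr, map)
  expect_equal(li2$li[, 3], liRaw$li[, 3], tolerance = 1e-12)
})

test_that("survival simulation honours its hazard and censoring settings", {
  s0 <- simulateSurvival(nSamples = 300, beta = 0, censorRate = 0.05,
                         seed = 14)
  expect_lt(abs(harrellC(s0$time, s0$event, s0$ratio) - 0.5), 0.1)

  sNC <- simulateSurvival(nSamples = 100, censorRate = 0, seed = 15)
  expect_true(all(sNC$event == 1))

  # doubling the baseline hazard halves the median event time
  sA <- simulateSurvival(nSamples = 2000, beta = 0, baselineHazard = 0.1,
                         censorRate = 0, seed = 16)
  sB <- simulateSurvival(nSamples = 2000, beta = 0, baselineHazard = 0.2,
                         censorRate = 0, seed = 17)
  expect_lt(abs(median(sA$time) / median(sB$time) - 2), 0.35)
})
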