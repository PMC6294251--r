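# Annotation assembly: PASS filtering, clustering, gene assignment,
# classification, internal-priming flagging.

test_that("PASS filtering subtracts genome-templated adenosines", {
  # positions 21-25 hold AAAAG: 4 templated A's downstream of a read ending at 20
  genome <- makeGenome(chr1 = paste0(strrep("C", 20), "AAAAG", strrep("C", 25)))
  reads <- makeReads("chr1", "+", c(11, 11, 11), c(20, 20, 20),
                     soft_tail_A = c(10, 0, 5))
  kept <- filterPassReads(reads, genome)
  # tail 10: 10-4=6 untemplated -> kept; tail 0: dropped; tail 5: 5-4=1 < 2
  expect_identical(kept$read_id, "r001")
  kept1 <- filterPassReads(reads, genome, minUntemplatedA = 1L)
  expect_identical(kept1$read_id, c("r001", "r003"))
})

test_that("PASS filtering is strand-aware and preserves order", {
  # minus-strand read ending (3') at 10; its transcript-sense downstream is
  # positions 9..6 complemented: genome TTTT there -> 4 templated A's
  genome <- makeGenome(chr1 = paste0("CCCCC", "TTTT", strrep("G", 41)))
  reads <- makeReads("chr1", "-", c(10, 10), c(30, 30), soft_tail_A = c(5, 8))
  kept <- filterPassReads(reads, genome)
  expect_identical(kept$read_id, "r002")  # 8-4=4 >= 2; 5-4=1 dropped

  expect_error(
    filterPassReads(makeReads("chrX", "+", 1, 10, 3), genome),
    "chrX")
})

test_that("site clustering is single-linkage with a modal summit", {
  mk <- function(pos, strand = "+")
    makeReads("c1", strand, pmax(1, pos - 30), pos, soft_tail_A = 5)
  # all ends within the gap: one site; tie among modes -> downstream-most on +
  s1 <- clusterSites(mk(rep(c(100, 101, 103), each = 5)), window = 25)
  expect_equal(length(s1), 1L)
  expect_equal(start(s1), 103)
  expect_equal(s1$support, 15L)

  # gap 100 > 25: two sites
  s2 <- clusterSites(mk(rep(c(100, 200), each = 3)), window = 25)
  expect_equal(start(s2), c(100, 200))

  # mode tie 100/102 -> 102 on +; singleton at 160 dropped at minSupport 2
  s3 <- clusterSites(mk(c(rep(100, 4), rep(102, 4), 160)), window = 25,
                     minSupport = 2)
  expect_equal(length(s3), 1L)
  expect_equal(start(s3), 102)
  expect_equal(s3$support, 8L)

  # on the minus strand the downstream-most mode is the smaller coordinate
  neg <- makeReads("c1", "-", c(100, 100, 102, 102), c(130, 130, 132, 132),
                   soft_tail_A = 5)
  s4 <- clusterSites(neg, window = 25)
  expect_equal(start(s4), 100)

  expect_error(clusterSites(mk(100), window = -1), "non-negative")
})

test_that("clustering its own output is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample.int(5000, 120, replace = TRUE))
    reads <- makeReads("c1", "+", pmax(1, pos - 20), pos, soft_tail_A = 5)
    sites <- clusterSites(reads, window = 25, minSupport = 1)
    again <- clusterSites(
      makeReads("c1", "+", start(sites), start(sites), soft_tail_A = 5),
      window = 25, minSupport = 1)
    expect_equal(start(again), start(sites))
  }
})

test_that("sites assign by containment, then nearest annotated 3' end downstream", {
  genes <- c(makeGene("c1", 1000, 2000, "+", "geneA", cds_end = 1500),
             makeGene("c1", 9000, 9500, "+", "geneB", cds_end = 9200))
  mkSites <- function(pos) {
    gr <- GRanges("c1", IRanges(pos, pos), strand = "+")
    gr$support <- 5L; gr$ip_flag <- FALSE
    gr
  }
  # 300 nt downstream of geneA -> novel isoform of geneA
  ann <- assignSitesToGenes(mkSites(2300), genes)
  expect_equal(geneId(ann), "geneA")
  expect_equal(isoformClass(ann), "novel")
  # 6000 nt downstream -> dropped
  ann2 <- assignSitesToGenes(mkSites(8000), genes)
  expect_equal(length(ann2), 0L)
  # containment in the 3' UTR -> tandem
  ann3 <- assignSitesToGenes(mkSites(1800), genes)
  expect_equal(geneId(ann3), "geneA")
  expect_equal(isoformClass(ann3), "tandem")
})

test_that("overlapping gene claims resolve to the nearer 3' end, then gene id", {
  genes <- c(makeGene("c1", 1000, 3000, "+", "gX", cds_end = 1200),
             makeGene("c1", 1000, 2600, "+", "gY", cds_end = 1200))
  site <- GRanges("c1", IRanges(2500, 2500), strand = "+")
  site$support <- 5L; site$ip_flag <- FALSE
  ann <- assignSitesToGenes(site, genes)
  expect_equal(geneId(ann), "gY")  # |2500-2600| = 100 < |2500-3000| = 500

  # equidistant claims -> lexicographically smaller gene id
  genes2 <- c(makeGene("c1", 1000, 2600, "+", "gB", cds_end = 1200),
              makeGene("c1", 1000, 2400, "+", "gA", cds_end = 1200))
  site2 <- GRanges("c1", IRanges(2500, 2500), strand = "+")
  site2$support <- 5L; site2$ip_flag <- FALSE
  # distances: gB contains (|2500-2600|=100); gA 3' end 2400 is 100 upstream
  # -> only gB contains the site; force a true tie with two containing genes
  genes3 <- c(makeGene("c1", 1000, 2600, "+", "gB", cds_end = 1200),
              makeGene("c1", 1400, 2400, "+", "gA", cds_end = 1500))
  ann3 <- assignSitesToGenes(site2, genes3)  # both contain 2500? gA ends 2400: no
  expect_equal(geneId(ann3), "gB")
})

test_that("rank_3p orders isoforms 5' to 3' on both strands", {
  genes <- c(makeGene("c1", 1000, 3000, "+", "gP", cds_end = 1200),
             makeGene("c1", 5000, 7000, "-", "gM", cds_end = 6800))
  pos <- c(2000, 1600, 2500, 5600, 6400)
  gr <- GRanges("c1", IRanges(pos, pos),
                strand = c("+", "+", "+", "-", "-"))
  gr$support <- 5L; gr$ip_flag <- FALSE
  ann <- assignSitesToGenes(gr, genes)
  tr <- trendSites(ann)
  gP <- tr[tr$gene_id == "gP"]
  expect_equal(start(gP)[order(gP$rank_3p)], c(1600, 2000, 2500))
  gM <- tr[tr$gene_id == "gM"]
  # minus strand: most proximal = largest coordinate
  expect_equal(start(gM)[order(gM$rank_3p)], c(6400, 5600))
  expect_true(validObject(ann))
})

test_that("isoform classes partition the coding span exhaustively", {
  gene <- makeGene("c1", 1000, 2000, "+", "gA", cds_end = 1500)
  expect_equal(classifyIsoform(1200, gene), "internal")
  expect_equal(classifyIsoform(1500, gene), "internal")  # last coding base
  expect_equal(classifyIsoform(1501, gene), "tandem")
  expect_equal(classifyIsoform(2000, gene), "tandem")    # annotated 3' end
  expect_equal(classifyIsoform(2001, gene), "novel")
  # every position gets exactly one class
  cls <- classifyIsoform(1000:2500, gene)
  expect_true(all(cls %in% c("internal", "tandem", "novel")))

  neg <- makeGene("c1", 1000, 2000, "-", "gB", cds_end = 1500)
  expect_equal(classifyIsoform(1800, neg), "internal")
  expect_equal(classifyIsoform(1499, neg), "tandem")
  expect_equal(classifyIsoform(1000, neg), "tandem")
  expect_equal(classifyIsoform(999, neg), "novel")

  nc <- makeGene("c1", 1000, 2000, "+", "gN", biotype = "non_coding")
  expect_equal(classifyIsoform(c(1200, 2400), nc),
               c("non_coding", "non_coding"))

  broken <- makeGene("c1", 1000, 2000, "+", "gC")
  expect_error(classifyIsoform(1500, broken), "cds_end")
})

test_that("internal-priming flag fires on A content or A runs downstream", {
  win20 <- function(s) {
    genome <- makeGenome(c1 = paste0(strrep("G", 50), s, strrep("G", 30)))
    site <- GRanges("c1", IRanges(50, 50), strand = "+")
    flagInternalPriming(site, genome)
  }
  expect_true(win20(strrep("A", 20)))                      # maximal A content
  expect_false(win20(strrep("ACGT", 5)))                   # 5 A, run 1
  expect_true(win20(paste0(strrep("AAC", 6), "AG")))       # 13 A dispersed, run 2
  expect_false(win20(paste0(strrep("AAC", 6), "GG")))      # exactly 12 A
  expect_true(win20(paste0(strrep("A", 7), strrep("C", 13))))   # run 7 > 6
  expect_false(win20(paste0(strrep("A", 6), strrep("C", 14))))  # run 6 allowed
})

test_that("truncated windows near the contig end scale the A budget", {
  # only 10 nt of genome downstream: budget 12 * 10/20 = 6
  genome <- makeGenome(c1 = paste0(strrep("G", 50), "AACAACAACA"))
  site <- GRanges("c1", IRanges(50, 50), strand = "+")
  expect_true(flagInternalPriming(site, genome))   # 7 A > 6
  genome2 <- makeGenome(c1 = paste0(strrep("G", 50), "AACAACGGGG"))
  expect_false(flagInternalPriming(site, genome2)) # 4 A <= 6
})

test_that("planted decoys are flagged and sanitized true sites are not", {
  ref <- simulateReference(nGenes = 15, decoyRate = 2, seed = 3)
  expect_gt(length(ref$decoys), 0)
  expect_true(all(flagInternalPriming(ref$decoys, ref$genome)))
  expect_false(any(flagInternalPriming(ref$sites, ref$genome)))
})

test_that("every emitted isoform lies in its gene span or the downstream margin", {
  set.seed(99)
  ref <- simulateReference(nGenes = 20, seed = 5)
  glen <- width(ref$genome)[1]
  pos <- sample.int(glen - 10L, 400)
  rnd <- GRanges("chrS", IRanges(pos, pos),
                 strand = sample(c("+", "-"), 400, replace = TRUE))
  rnd$support <- 3L; rnd$ip_flag <- FALSE
  ann <- assignSitesToGenes(rnd, ref$genes, maxDownstream = 5000L)
  tr <- trendSites(ann)
  g <- ref$genes[match(tr$gene_id, ref$genes$gene_id)]
  inSpan <- start(tr) >= start(g) & start(tr) <= end(g)
  neg <- as.character(strand(g)) == "-"
  dist <- ifelse(neg, start(g) - start(tr), start(tr) - end(g))
  expect_true(all(inSpan | (dist >= 1 & dist <= 5000)))
  # class partition is exhaustive and exclusive for every assigned site
  expect_true(all(tr$class %in% c("tandem", "internal", "novel", "non_coding")))
})
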