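---
title: "Quantifying 3' end diversification with trendseq: models and methods"
author: "trendseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3' end diversification with trendseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendseq)
```

## The problem

Most eukaryotic genes carry several cleavage/polyadenylation sites, so one
gene expresses transcript isoforms that differ only in their 3' ends
(alternative polyadenylation, APA).  Shifts between proximal (short) and
distal (long) isoforms rewire microRNA and RBP regulation without changing
the protein, and systematic shortening or lengthening of 3' UTRs is a
recurrent feature of proliferative and neoplastic states.  trendseq
implements the computational workflow of a multiplexed 3' end sequencing
screen for APA regulators: from raw barcoded reads to an annotated atlas of
3' end isoforms, per-isoform differential-usage statistics per knockdown, a
regulator interaction map, and a downstream clinical stage that scores
isoform-ratio signatures in expression-array cohorts with ROC and survival
models.

## Annotation assembly

3' end reads carry a stretch of untemplated adenosines from the poly(A)
tail.  A read is **poly(A)-site-supporting (PASS)** when its soft-clipped
terminal A count exceeds the run of genome-templated A's immediately
downstream of its alignment by at least `minUntemplatedA` (default 2):
templated A's can be primed from the genome and are no evidence of a tail.

PASS-read 3' ends are clustered per contig and strand by single linkage
with a 25-nt gap.  The cluster summit (the modal coordinate; ties resolve
to the strand-aware downstream-most mode) becomes the cleavage-site
position; clusters with fewer than `minSupport = 2` reads are discarded as
noise-prone singletons.  The 25-nt gap matches typical poly(A)-site cluster
widths — cleavage is heterogeneous over a couple of dozen nucleotides — and
is configurable, as no canonical value exists.

Sites are assigned to the same-strand gene whose span contains them;
remaining sites are assigned to a gene whose annotated 3' end lies upstream
within `maxDownstream = 5000` nt, becoming *novel* isoforms.  When two gene
spans contain a site, the nearer annotated 3' end wins, with ties broken by
gene id so output is deterministic.  Within a gene, isoforms are ranked 5'
to 3' (`rank_3p`, 1 = most proximal) and classified:

* **tandem** — between the stop codon boundary and the annotated 3' end
  (alternative 3' UTR length);
* **internal** — upstream of the stop codon (altered protein C-terminus);
* **novel** — beyond the annotated 3' end;
* **non_coding** — any site in a non-coding gene.

**Internal priming.** Oligo(dT) also primes on genomically encoded A-rich
stretches, producing artefactual "sites".  A position is flagged when its
downstream 20-nt window holds more than 12 adenosines or a run of more than
6; both thresholds follow the prevailing convention for A-rich filters and
are configurable since no single standard exists.  Near a contig end the
truncated window is used with the A budget scaled proportionally.

**Coordinates.** Internally everything is 1-based, closed-interval
GRanges — the native Bioconductor convention — with conversion to 0-based
half-open coordinates only at BED I/O.  A single internal convention
prevents off-by-one drift.

## Read processing and counting

Read 1 carries a 9-nt in-lane barcode, read 2 the insert.  Demultiplexing
matches barcodes exactly — screen barcodes are designed at Hamming distance
where single errors cannot cross samples, and exact matching is
deterministic — and drops pairs whose read-2 mean Phred quality is not
above 20.  Trimming removes a leading T-run and truncates at the first
A-run of length at least 5, recording the run length as the read's
`soft_tail_A`; reads shorter than 15 nt after trimming are dropped.

Counting is intersection-strict in spirit: each isoform owns a counting
interval of ±50 nt around its site (covering cluster spread after 25-nt
clustering), and a read contributes one count only when its 3'-terminal
coordinate falls in exactly one interval.  Reads in no interval
(`no_feature`) or several (`ambiguous`) are tallied, as are reads removed
by the internal-priming rule, so per sample

```
assigned + ambiguous + no_feature + ip_removed = total aligned reads.
```

## The statistical core

For one knockdown-vs-control comparison, every isoform of every testable
gene (at least two isoforms; at least `minGeneReads = 10` reads per
condition) is tested with a two-sided Fisher exact test on the 2×2 table

|            | knockdown | control |
|------------|-----------|---------|
| isoform *i*      | $a$ | $c$ |
| other isoforms   | $b$ | $d$ |

using the point-probability rule (sum of hypergeometric probabilities of
tables at most as probable as observed, at fixed margins).  The test is
replicate-free by design: the screen pools reads per condition.  P-values
are Benjamini-Hochberg adjusted **within one comparison** — the screen's
natural family — not across knockdowns, so each regulator's result does not
depend on which other regulators were screened.

**Fold-regulation** normalizes each gene to 100% per condition:
$fc_i = \mathrm{pct}^{KD}_i / \mathrm{pct}^{Ctrl}_i$, which is invariant to
any per-condition library scaling.  A pseudocount of 0.5 is added to every
isoform count (both conditions) before forming percentages so unexpressed
isoforms give finite fold-regulations; the Fisher test never sees the
pseudocount.

**Zero-isoform.** Per gene, the longest significantly affected
(BH-adjusted $p \le 0.05$) *annotated* isoform (novel isoforms excluded)
anchors reporting: significant isoforms get signed transcript-orientation
distances from it (negative = shorter).

**Shortening index.** The gene-level direction summary takes the two most
significantly affected isoforms (ties: smaller raw p, then more distal
site — fully deterministic) and computes
$si = \log_2(fc_\text{shorter} / fc_\text{longer})$: positive means the
shorter isoform gained relative to the longer one upon perturbation
(3' UTR shortening), negative means lengthening.  Swapping conditions
negates $si$ exactly because fold-regulations invert.  Genes with a single
detected isoform are untestable, not $p = 1$.

**Set enrichment** (e.g. overrepresentation of cancer-associated genes
among affected genes) is the upper-tail hypergeometric probability of the
observed overlap.

## The regulator network

Per knockdown, the affected-gene profile is the set of genes with a defined
shortening index and its sign.  For two regulators the edge score is

$$\mathrm{score} = (2 \cdot \mathrm{concordance} - 1) \cdot
\frac{|shared|}{\min(|A|, |B|)}$$

so a cloned regulator pair scores +1, a mirrored (antagonistic) pair −1,
and unrelated regulators ≈ 0; overlap significance is hypergeometric.  The
score and weight formulas are this package's own construction within the
qualitative contract that synergy attracts and antagonism repels, scaled by
overlap and significance; coefficients are exposed as arguments.  Layout is
standard Fruchterman-Reingold with attraction
$\max(\mathrm{score}, 0)\cdot\min(-\log_{10} p, 10)$ on edges and extra
pairwise repulsion $\max(-\mathrm{score}, 0)$, deterministic under a fixed
seed.  Edges with $p > 0.05$ or fewer than 5 shared genes are pruned by
default for readability.

## The clinical signature stage

Expression arrays can resolve APA when probes fall in isoform-specific
regions.  Restricted to tandem sites, each gene partitions into a common
region upstream of the most proximal site — present in all isoforms, a
proxy for the shortest isoform's signal — and inter-site regions specific
to longer isoforms.  This partition is the standard interpretation of
probe-level isoform resolution; probes overlapping no region or more than
one are dropped, and genes resolving fewer than two isoforms are dropped.
Common regions are truncated where another gene's isoform-specific
territory begins so closely spaced genes do not shadow each other.

Intensities are background-corrected (per-array 5th-percentile offset,
floored at a small positive constant) and quantile-normalized
(`limma::normalizeQuantiles`).  The **lengthening index** of a gene is
long-isoform expression divided by shortest-isoform expression per sample,
on linear scale; group comparisons use a two-sided t-test on $\log_2 li$
since ratios live on a multiplicative scale (raw values are preserved in
outputs).

Per-gene discrimination is the AUC of the ROC over an outcome label,
computed as the normalized Mann-Whitney rank statistic with half credit for
ties.  Signature genes are those with AUC strictly above 0.7.  The
**multifactor ROC** combines per-gene $\log_2$ short-to-long ratios with a
ridge-penalized logistic score ($\alpha = 0$, fixed small $\lambda = 0.01$)
fitted on a stratified 70% training split and evaluated on the held-out
30%; the ridge keeps the fit defined under separation and duplicated
(collinear) genes, and the 70/30 split mirrors the Cox stage for
consistency.  AUCs are compared pairwise with DeLong's placement-value
z-test or a stratified bootstrap percentile test.

**Survival.** Kaplan-Meier curves with the log-rank test handle group
contrasts (median split by default for expression markers; a scan over
candidate groupings BH-adjusts across the scan).  Prognostic value of
isoform ratios is assessed with a bootstrapped Cox pipeline: per replicate,
a stratified 70/30 train/validation split, a Cox proportional-hazards fit
with Efron tie handling (the common default) on training, Harrell's
C-index on validation; models are compared by a two-sided paired t-test
over 100 replicate C-indices.  Replicates with non-convergent fits are
dropped; more than 20% dropped is an error.

## The synthetic-data generator

Every stage is exercised end-to-end on generated data with recorded ground
truth.  A single master seed fans out to named sub-streams (reference,
counts, fastq, array, survival, plus bootstrap counters), so stages can be
regenerated independently and bootstrap streams are prefix-stable in the
replicate count.

* **Reference**: a single contig of non-overlapping genes on both strands,
  each with 2–4 tandem sites spaced ≥ 150 nt beyond a 600-nt coding region;
  uniform base composition outside planted features; A-run decoys of 20 nt
  in intergenic gaps.  Sequence near planted sites is sanitized — no A/T
  homopolymers, A-poor downstream windows, a non-A base at and just past
  the cleavage position, and genome-wide unique 20-mer upstream anchors —
  so that error-free reads from true sites survive trimming, PASS
  filtering, internal-priming removal and exact-anchor placement without
  loss.  This is what makes the zero-noise round trip exactly
  count-preserving, by construction rather than by luck.
* **Counts**: per gene, usage from a symmetric Dirichlet (concentration 2);
  perturbed genes move a fixed usage mass (`effect`, default 0.3) from the
  most proximal to the most distal isoform — transcript lengthening, the
  dominant phenotype upon depleting 3' end machinery.  So that the planted
  shift is always the full stated effect, the proximal usage of perturbed
  genes is floored at `effect + 0.04` (remainder renormalized); without
  this, genes drawing low proximal usage could not donate the shift and
  the "planted effect" would silently vary by gene.  Reads are multinomial
  at depth 200 per gene per condition.
* **FASTQ**: read 1 is the sample barcode, read 2 ends at the isoform's
  cleavage site with an appended 5–15-nt A-tail at constant Phred quality;
  a configurable fraction of reads originates at decoy A-runs (internal
  priming ground truth).
* **Array**: two probes per gene (common/short and long-region), log2
  intensities = gene abundance × isoform fraction plus Gaussian noise, a
  per-array additive background, and a set of pure-background probes so
  that percentile background correction estimates a real quantity.  In the
  "case" group, informative genes raise distal usage by the effect size.
  Note that quantile normalization couples arrays slightly when a large
  fraction of genes shifts in one direction — with whole-array
  distributions forced equal, unaffected probes compensate — so
  uninformative genes sit near, not exactly at, AUC 0.5 in such designs.
* **Survival**: event times exponential with hazard
  $h_0 \exp(\beta \cdot x)$ where $x$ is the log proximal-to-distal ratio,
  independent exponential censoring, plus noise covariates.

What the generator does **not** emulate: sequencing errors, alignment
ambiguity beyond exact repeats, GC or positional biases, batch effects,
probe cross-hybridization, or non-proportional hazards.  Passing tests
therefore validate the algorithms and their contracts, not robustness to
every artefact of real libraries.

## Numerical choices and problem sizes

Fisher p-values compare hypergeometric point probabilities with a relative
tolerance of $10^{-7}$ so floating-point-equal tables tie correctly.  The
ROC uses midranks (ties get half credit); the DeLong variance uses
placement values via midranks.  Degenerate cases are explicit: identical
scores compare with $p = 1$; a zero-variance group makes a t-test
untestable (NA) rather than infinite; all-censored data yield NA log-rank
statistics.  Validation and the worked examples run at deliberate desk
scale — hundreds of genes, depth 200, cohorts of 100–150, 100 bootstrap
replicates — chosen so the full suite exercises every stage in a few
minutes while keeping Monte-Carlo standard errors well inside the asserted
bounds.

## Known limitations

* The Fisher test ignores biological replicate variance by design
  (pooled-count screens); replicate-aware count models are out of scope.
* Exact barcode matching assumes well-separated barcodes.
* `alignReadsExact()` is a placement tool for the package's error-free
  synthetic reads, not an aligner; real data should arrive as SAM/BAM or
  the documented alignment TSV from a genuine aligner.
* The network edge formula is one reasonable instantiation of a
  qualitative contract; its coefficients are arguments, not estimates.
* Probe-to-isoform mapping assumes probes were already placed on the
  genome; probe sequence alignment is consumed, not performed.
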