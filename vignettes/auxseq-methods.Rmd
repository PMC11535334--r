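---
title: "Methods: fitness statistics, hit calling and simulation in auxseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness statistics, hit calling and simulation in auxseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`auxseq` analyses pooled complementation screens: a DNA-barcoded shotgun
expression library of ~3 kb genomic fragments is transformed into an
auxotrophic host, selected on minimal medium, and read out by barcode
sequencing (BarSeq) of the pre-selection (t0) and post-selection samples.
This vignette documents the statistical model, the tunable parameters, the
synthetic-data generator, and the design decisions behind them.

## Coordinates and containers

All genomic coordinates are 1-based and inclusive (the GFF3 convention), so
an interval's length is always `end - start + 1`; no other convention
appears anywhere in the package. The shared containers are plain data
frames — a mapping table (barcode, genome, interval, vector orientation),
an annotation table, fitness records — plus a `count_table` bundling a
dense barcode × sample count matrix with its experiment sheet. A missing
barcode × sample cell means zero reads ("not detected"), never missing
data, because the BarSeq counting step observes every barcode in every
sample.

## From reads to counts

BarSeq reads have a fixed layout inherited from the barcoding primer:
`...CGTACG <20-nt barcode> AGAGACCTCGTGGACATC...`. `extract_barcodes()`
anchors on exact flank matches (the 6-mer `CGTACG` upstream, the full
18-mer downstream); approximate flank matching is deliberately out of
scope since the layout is fixed by the primer. Every read either yields a
barcode or a tallied rejection reason (`no_flank`, `bad_length`,
`ambiguous_base`, `low_quality`), so accepted + rejected = total reads by
construction.

Two quality regimes mirror screen practice: `min_quality = 0` for fitness
counting (count noise is handled downstream by the z statistic) and
`min_quality = 30` for library diversity estimation. Requiring Q ≥ 30 at
each of the 20 barcode positions bounds the probability of any barcode
error by 20 × 0.001 = 2% (union bound); the test suite verifies both the
closed form and the simulated rate.

`collapse_offby1()` removes every barcode at Hamming distance 1 from a
strictly more common barcode. The removed reads are *discarded*, not
reassigned to the neighbour — reassignment would systematically inflate
abundant barcodes. Ties are kept, reading "more common" strictly. The
operation is idempotent and order-independent, and is checked against an
all-pairs Hamming oracle.

## Fitness and the z statistic

For barcode $i$ in a selected/t0 sample pair with totals $N_{sel}, N_{t0}$
and $B$ barcodes:

$$f_i = \log_2\frac{n_{sel,i} + p}{N_{sel} + pB} -
        \log_2\frac{n_{t0,i} + p}{N_{t0} + pB}, \qquad p = 0.5$$

Normalization is by total reads (relative abundance) only. Median-centred
normalization, common in growth-based fitness tools, would be degenerate
here: after plate selection the vast majority of barcodes die, so the
median log-ratio is dominated by extinguished barcodes. The pseudocount
keeps $f$ finite at zero counts while preserving exact scaling invariance
in the $p \to 0$ limit; it is configurable via `fitness_params()`.

The supporting statistic is a delta-method z score under Poisson count
noise on the log2 scale:

$$z_i = f_i \Big/ \left[\frac{1}{\ln 2}\sqrt{\frac{1}{n_{sel,i}+p} +
  \frac{1}{n_{t0,i}+p}}\right]$$

This form was chosen for transparency: it is simple, has $\mathrm{sign}(z)
= \mathrm{sign}(f)$, requires a larger fold change from low-count barcodes,
and is calibrated by simulation — under a no-enrichment screen at depth
$10^5$ with $10^5$ barcodes, the probability that a barcode passes both
thresholds ($f > 5$ and $z > 4$) is below $10^{-3}$ (the acceptance suite
measures it at 0). No claim of equivalence with any other screen-analysis
code base is made; agreement is at the level of enriched/unenriched calls.

Thresholds are strict inequalities, $f > 5$ and $z > 4$, and configurable.

## Hit confirmation, regions, gene association

Selection on plates admits false positives: very small colonies that grow
marginally on nutrient carryover or agar impurities contribute a little
DNA to the scraped pool. A significant fitness value alone is therefore
not enough. A fragment × background is *high-confidence* only when
confirmed either by an overlapping significant fragment in the same
experiment (two independent clones covering the same locus) or by
significance in another experiment of the same background, regardless of
induction level.

Design choices here:

* Overlap means ≥ 1 shared bp on the same source genome; hits in different
  mutant backgrounds never confirm or merge with each other. Overlap across
  homologous loci of *different* source genomes is not considered.
* "Another experiment" is any distinct selected sample of the same
  background — a different inducer level or a different transformation both
  qualify.
* Fragments spanning the origin of a circular genome are not supported
  (`start ≤ end` is enforced at input); sheared-library inserts are linear
  and wrap-around mappings are rare enough to reject at validation.

Regions are connected components of the interval-overlap graph within each
(background, genome), computed by a sorted sweep and verified against a
transitive-closure oracle. Each region is associated with the genes fully
contained in its best insert — the member with the highest mean fitness
across that background's experiments, ties broken by longer insert then
lexicographic barcode (determinism; the choice is otherwise arbitrary).
Regions are classified `one_orf` / `multi_orf` / `no_full_orf` by the
number of fully contained genes. Genes that are *nearly* full length on
the best insert — at least 90% of the gene covered including its start
codon — are reported in a separate column and deliberately excluded from
the ORF class: a truncated enzyme may still complement, but the call is
weaker and is surfaced as such. The 90% figure is this package's choice;
it is a parameter (`nearly_threshold`) everywhere it is used.

Gene *containment* (used for library QC and recovery) is strand-agnostic —
it asks what a fragment physically carries. Gene *orientation* matters
separately: a gene is sense iff its strand equals the insert's vector
orientation, i.e. the synthetic promoter transcribes it. Library coverage
("fraction of genes covered") means full containment in at least one
mapped fragment, which makes coverage identically `1 − P(fragments per
gene = 0)` and ties the QC table's columns together; partial-overlap
definitions would break that identity.

## Expected-hit recovery

Given a user-supplied table of proteins expected a priori to complement
each background, `classify_expected()` computes (never takes as input)
whether each gene is carried full length in the library, whether any
carrier was detected at t0 (> 0 reads), whether any carrier is sense, and
the recovery status against high-confidence hits. Success rates are
reported per *insert* rather than per gene, since one gene may ride many
inserts; a per-gene view can be had by aggregating the covariate table.
Confidence intervals are central Clopper–Pearson at 90% — the exact,
conservative choice when only "binomial" is specified.

Sequence covariates: GC fraction of the insert; CAI of the gene's CDS
(geometric mean of relative adaptiveness over codons, excluding stop
codons and the single-codon families ATG and TGG, with near-zero reference
values lifted to 0.01 — the Sharp & Li / EMBOSS convention; the default
reference is the highly expressed *E. coli* gene set distributed with
seqinr, and any usage table can be supplied); and the fraction of the
eight codons rare in *E. coli* (ATA, CGG, CGA, CTA, AGA, AGG, GGA, CCC)
among non-stop codons. RBS strength is accepted as an external covariate
column only — computing it is out of scope. Covariates are compared between
successful and unsuccessful cases by two-sided Wilcoxon rank-sum tests;
per-library RBS means by t tests with Bonferroni correction over the
number of libraries.

## The synthetic-data generator

The simulator reproduces the statistical structure the analysis relies on,
at desk scale:

* **Genome**: random ACGT of configurable GC, with non-overlapping genes
  whose bodies are stop-free codon runs (ATG … TAA) so CDS covariates are
  well defined. Real operon structure, intergenic signal and codon bias
  are *not* emulated.
* **Library**: fragment lengths are normal (mean 3000 nt, sd 800 nt)
  truncated to the 1.5–5 kb gel-excision window — the simplest shape
  consistent with a sonication smear plus a gel cut; starts uniform;
  vector orientation uniform ±; barcodes unique random 20-mers.
* **t0 sample**: log-normal relative abundances (sigma 1), with an
  independent 13% dropout modelling transformation loss, then multinomial
  sampling at the configured depth. Dropout is drawn independently of
  abundance because the loss mechanism is unspecified; real dropout is
  likely abundance-correlated.
* **Selection**: plate selection is all-or-nothing per clone, so it is
  modelled winner-take-mass: each barcode carrying a full-length
  complementing gene (and present at t0) founds a colony with probability
  `p_sense` = 0.66 or `p_antisense` = 0.35 by orientation — the antisense
  probability is a phenomenological constant standing in for internal
  promoters and is given no mechanistic model. Winner mass is the t0
  abundance × 2^`enrichment_log2` (default 2^10), and all non-winners
  collectively retain `background_mass` = 1e-4 of the post-selection mass
  (the "faint colony" background), in proportion to their t0 abundance.
  With no winners the composition is unchanged — selection found nothing.
* **Reads**: one read per counted unit with the primer-derived flanks,
  per-base substitution errors at 0.001, Q40 qualities with an optional
  injected low-quality fraction.

Two consequences of winner-take-mass are worth knowing. First, once
winners dominate, every winner's fitness is ≈ log2(total t0 mass / winner
t0 mass) — set by how rare the winners were at t0 rather than by the
nominal `enrichment_log2` — which is also how plate selections behave;
configurations in the tests keep winners near 1/1000 of t0 mass so
fitness lands in the 7–10 range the thresholds were designed for. Second,
colony founding is drawn independently per experiment, so concordance of
significance across inducer levels is bounded by the orientation
probabilities; a real screen, where the same transformation is plated
twice, shows higher concordance than this model produces. Passing tests
therefore demonstrate correctness of the statistics and calls under a
known generative model, not that real screens meet these rates.

Every generator draws from `set.seed(seed + fixed offset)` (a distinct
offset per operation, plus a caller-supplied `rng_offset` for repeated
experiments), so partial re-runs are reproducible.

## Problem sizes and runtime choices

Simulation-based tests use a 0.6–1.2 Mb genome with 50–60 genes,
3,000–100,000 fragments and depths of 1e5–1e6 reads per sample — large
enough that winners must clear the significance thresholds through the
same count statistics as a real screen (t0 counts of ~25–100 per barcode),
small enough that the whole suite runs in a couple of minutes. Orientation
parameter recovery uses ten seeds of a 40,000-fragment screen with ~550
expected-gene carriers detected at t0, checking that 90% Clopper–Pearson
intervals cover the generating 0.66/0.35 in at least 8 of 10 seeds per
orientation. Gene density in simulated genomes is deliberately sparse
(~1 gene / 10 kb versus ~1 gene / kb in bacteria): it keeps complementing
genes on disjoint fragment neighbourhoods so ground truth stays
unambiguous, at the cost of genes-per-fragment distributions that are not
comparable to a real library's.

## Known limitations

* No replicate-variance shrinkage or gene-level (as opposed to
  fragment-level) fitness model.
* No liquid-selection dynamics (jackpot consolidation to a few barcodes is
  documented behaviour of liquid passaging and is simply not modelled).
* No cross-feeding: a fragment can only benefit its own carrier.
* Circular-genome wrap-around inserts are rejected rather than handled.
* The expected-hit table is an input contract; homology search and
  pathway-based candidate construction are out of scope.
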