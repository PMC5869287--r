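---
title: "Diagnosing haplotype separation in diploid assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing haplotype separation in diploid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiag)
```

## The problem

Long-read assemblers applied to highly heterozygous diploid genomes — the
motivating case is the *Aedes albopictus* C6/36 cell-line assembly, with an
estimated 5.7% heterozygosity — do something that looks like a defect but is
actually information: wherever the two haplotypes diverge beyond roughly 2%,
the assembler emits *both* haplotypes as separate contigs ("haplotigs"),
while lowly diverged regions collapse into a single consensus contig. The
result is an assembly whose span is nearly twice the haploid genome size,
whose single-copy orthologs appear twice, and whose contigs fall into two
read-depth classes: a haplotig attracts about half the read depth of a
collapsed contig.

`haplodiag` implements the diagnostics that make this structure measurable:

* **mode coverage** — a robust per-contig depth statistic, and its two-class
  window classification (the ×18 ± 6 / ×36 ± 6 pattern at ~36× diploid
  depth);
* a **genome-size model** converting the separated span fraction *h* into a
  haploid genome size, `S * (h/2 + (1 - h))`;
* **paired contigs (PCs)** — counterpart haplotigs detected from read pairs
  that map exactly twice, once on each contig, with an anchor-based
  intra-pair identity estimate and "walks" across staggered contig pairs;
* a **single-copy-ortholog crosstab** (instances × coverage class) with a
  Fisher exact test of the duplication/separation association and a triage
  of genes present on only one side of a PC;
* a **chromosomal quotient (CQ)** scan for male-specific sequence
  (female/male alignment-count ratio over 1-kb repeat-masked tiles,
  CQ < 0.01);
* **RPKM expression thresholding** (expressed = RPKM ≥ 1; highly expressed =
  ≥ 2× the mean of expressed transcripts) and gene-family presence reports;
* **cascade host subtraction** (transcripts, then genome) with exact
  stagewise accounting.

Everything is exercised end-to-end on synthetic diploid genomes whose truth
tables make every stage testable without external data.

## The synthetic generator and what it emulates

`genome_sim_spec()` builds a haploid genome as a grid of loci (default
10 kb), assigns each locus a divergence, and derives haplotype B from
haplotype A by per-site substitution. The defaults are the study conditions
the diagnostics target: 5.7% genome-wide heterozygosity, 80% of the span
above the 2% separation threshold, collapsed loci at ~0.5% divergence.
Separated loci draw divergences uniformly around the value that balances the
genome-wide target, which gives the within-assembly identity spread that
makes some counterpart pairs barely cross-mappable and others not — the
property that produces a realistic "fraction of pairs mapping exactly twice".

Deliberate simplifications:

* **Substitutions only.** Indels are off so haplotype coordinates stay
  aligned and truth checks are positional. Collapsed contigs are haplotype A
  verbatim rather than an IUPAC consensus: downstream coverage logic is
  unaffected and mapping stays exact-matchable.
* **The male-limited locus (M-locus)** is a terminal extension of haplotype
  A of chromosome 1 rather than an internal insertion — again to keep every
  other coordinate aligned. Female read sets simply exclude the extension.
* **Allele loss is modelled in annotation space**: a lost or partially lost
  gene copy is recorded in the truth table and reflected in the simulated
  ortholog hit table, not excised from the sequence. The triage logic
  consumes hits, depth and contig geometry, so nothing downstream needs the
  sequence edit, and heterozygosity accounting stays exact.
* **Reads** are 2 × 150 bp pairs at 350 bp fragments (the default avoids
  mate overlap; 270 bp reproduces a tight-insert library), uniform across
  both haplotypes, with truth encoded in the read name
  (`p<idx>:<chrom>:<hap>:<start>:<fraglen>:<strand>`). `depth_total` is
  fold-coverage of the *haploid* span, so a haplotig receives about half of
  it and a collapsed contig all of it (the ×18/×36 pattern at the default
  36).

What the generator does **not** emulate: assembler graph behaviour beyond
the two-class emission rule, long-read error models, base-quality realism,
GC bias, or cell-line passage mutation accumulation. Passing tests therefore
demonstrate that the *diagnostics* recover planted structure under their own
assumptions; they do not certify performance on real libraries with indels,
repeats and coverage bias.

## The mapper

The mapping module exists because the diagnostics depend on *controlled*
reporting semantics. Placements come from exact seed k-mers (default
k = 31, one seed every k bases plus one flush with the read end) verified
end-to-end with at most `max_mismatches` substitutions per mate (default 8);
only concordant FR pairs on a single contig within the fragment bounds
count. Three contracts are exposed:

* `best_one` — one minimum-mismatch placement, ties broken by a seeded
  shuffle (feeds depth histograms and read counting);
* `best_k` — up to 4 best placements after a deterministic sort plus seeded
  shuffle of equals ("best 4"; feeds doubly-mapped pair counting, where
  "mapped exactly twice" means exactly two reported concordant placements);
* `all_exact` — every zero-mismatch alignment (the `-a -v 0` contract;
  feeds CQ counting, where hard-masked bases can neither seed nor match).

For exact search the offset-0 seed guarantees completeness; for approximate
search a mate is missed only when every seed carries an error, which is
what `expected_shared_pairs()` reproduces (by Monte Carlo over the seed
geometry) when deciding which truth contig pairs a given read set can
plausibly reveal. Real-data users with gapped or quality-aware alignments
supply SAM/BAM/PAF through `ingest_alignments()` instead.

## Numerical choices

* **Mode coverage** slides its 3-wide window by 1 (centres 4, 5, 6, …)
  rather than tiling disjointly; the printed example (a 3×–5× histogram
  reports 4×) fits both readings and sliding is the less lossy. Depths
  below 3× are never counted; contigs with no bases at ≥3× have an
  undefined mode and class OTHER, and are excluded from *h*. Tied windows
  prefer the centre holding the most bases at the centre depth itself, then
  the smallest centre — the stated smallest-centre rule alone would report a
  uniformly 18× contig as 17×.
* **Class windows are closed intervals**, tested SEPARATED before COLLAPSED;
  with the reference values (centre 18, halfwidth 6) the windows [12, 24]
  and [30, 42] cannot overlap. `estimation = "auto"` generalises to other
  depths (span-weighted modal mode as the centre, halfwidth `centre / 3`);
  `fixed` reproduces the reference analysis.
* **PC detection** keeps the absolute 10,000-shared-pair threshold as the
  fidelity default; the density alternative (default 4.5 pairs per kb of
  the smaller contig, i.e. the reference threshold at ~2.2 Mb scale) exists
  solely so megabase-scale synthetic genomes can exercise detection.
* **Intra-PC identity** is anchor-based (unique shared 21-mers, longest
  colinear chain, gap-free extension between anchors advancing both contigs
  equally, gaps over 500 bp or unequal advances left unaligned) rather than
  full dynamic programming; on substitution-only synthetic pairs it recovers
  1 − divergence to within a percentage point.
* **Walks** are a disclosed heuristic: an edge is TILING when each contig
  extends at least `min_extension` (default 1 kb) beyond the partner
  alignment on opposite ends; walks are maximal simple paths over TILING
  edges grown greedily from the highest shared-count edge, each contig
  joining at most one walk.
* **Fisher exact test** is two-sided (the sidedness is immaterial at the
  reference effect size), with the odds ratio taken from the cells directly
  (0.5 continuity correction when a cell is zero); a zero margin reports
  p = 1 with a warning rather than erroring.
* **Missing-gene triage** thresholds are conventions: depth elevation 1.5×
  the contig mode, contig-end margin 10 kb, partial-hit cutoff 50% of gene
  length, tested in that order with CLEAN_LOSS as the fallback.
* **CQ** assigns an alignment to the tile containing its start (counts stay
  additive across tiles) and requires at least `min_male = 10` male
  alignments before reporting a quotient — a guard against 0/0 and
  low-count artifacts; set 1 to reproduce a floor-less scan. Terminal tiles
  shorter than half a tile are dropped.
* **RPKM** uses reads mapped to the transcript set as the per-million
  denominator (the printed description is ambiguous between mapped and
  sequenced totals). The NOMINAL family band
  `[threshold, 2 × threshold)` encodes "RPKM = 1" verdicts; ABSENT means no
  expressed member. The expression simulator calibrates *library size*
  against the target mean expressed RPKM; since RPKM over a fully expressed
  set must sum to `1e9 / sum(length)`, targets below that floor are
  unattainable for a given transcript set and trigger a warning rather than
  silent failure.
* **Subtraction** removes a read on any end-to-end placement with at most 2
  substitutions (stringency undocumented in the reference; disclosed
  default), counts unique reads (not alignment events), and reports the
  remaining fraction as the downstream workload estimate.

## Problem sizes

The test suite and acceptance checks run the full pipeline at a 1 Mb haploid
genome (two 500 kb chromosomes) at 36× total depth with 0.5% read error —
about 120,000 read pairs mapped under both the best-one and best-4
contracts — plus a 200 kb genome for the M-locus and subtraction scenarios
(20,000-read 85/15 host/foreign mixes, sexed read sets at 20× per sex).
These sizes were chosen so every recovery property (class accuracy, *h*,
genome size, PC detection, CQ calls, subtraction fractions) is measured on
hundreds to thousands of units while a complete run stays in the minutes
range on one CPU.

## Known limitations

* Genome-scale reference numbers (contig counts, N50s, the 0.7%/14% CQ
  contrast, the 13.2/76.1/10.7% subtraction splits) depend on the original
  read sets and are reproduced here only as arithmetic on printed values or
  as directional properties on synthetic data.
* The internal mapper is substitution-only and ungapped; spliced or indel
  alignments must come in via SAM/BAM/PAF.
* Walk extraction is greedy and unscored; it recovers planted staggered
  tilings but is not a scaffolder.
* Equivalence with any particular aligner's "best 4" tie-break behaviour is
  not claimed; the contract is deterministic given a seed.

## A worked miniature

```{r example, eval = FALSE}
genome <- simulate_diploid_genome(genome_sim_spec(
  n_chromosomes = 1, chrom_length = 2e5, gene_count = 10, seed = 7))
assembly <- simulate_assembly(genome)
reads <- simulate_reads(genome, read_sim_spec(seed = 3))
index <- build_index(assembly$contigs)

best1 <- map_pairs(reads, index, mapper_config("best_one", seed = 11))
classes <- classify_contigs(depth_histogram(best1))
glance(classes)
estimate_genome_size(classes)

best4 <- map_pairs(reads, index, mapper_config("best_k", seed = 12))
pcs <- detect_pcs(doubly_mapped(best4), pc_config(density_threshold = 4.5))
glance(pcs)
autoplot(classes)
```

The same flow, orchestrated with consolidated reporting, is
`run_pipeline()`; section-by-section summaries come from the `glance()`
methods and per-unit tables from `tidy()`.
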