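---
title: "Integrated read-level taxonomic annotation and profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated read-level taxonomic annotation and profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readtax)
```

## The problem and the approach

Direct taxonomic annotation of short metagenomic reads is noisy: a 150 bp
read carries little signal, and its best database hit is often a close
relative rather than the organism it came from. Assembled contigs, and
even more so bins of contigs (metagenome-assembled genomes, MAGs), pool
the signal of many reads and can be annotated far more reliably. `readtax`
exploits this by annotating every read with the most reliable signal
available for it:

1. reads are mapped back to the assembly, keeping only primary mappings
   with MAPQ at or above a threshold (default Phred 2), with seeded random
   resolution of exact MAPQ ties;
2. contigs and bins are annotated from the homology hits of their
   predicted ORFs — each ORF gets the lowest common ancestor (LCA) of the
   hits within a bit-score window below its top hit, and the contig or bin
   is assigned by bit-score-weighted voting over its ORF annotations;
3. unmapped reads (and contigs without an ORF-based annotation) are
   annotated directly by the same windowed-LCA rule on their own hits;
4. each read receives the first available annotation along the priority
   MAG > voted contig > direct contig > direct read, else it is
   unclassified;
5. per-rank relative abundances are the read counts per taxon divided by
   the total number of sequenced reads.

Three modes restrict the admissible evidence: `mcr` (all of it), `mc`
(assembly-derived signal only; the direct annotations of step 3 are
skipped), and `cr` (contigs and reads, ignoring MAG annotations).

## The classification rules

**Windowed LCA (the r-parameter).** For one query with hits scored in
bits, keep every hit with `bit_score >= (1 - r) * top` and assign the LCA
of the retained subject taxa. The boundary is inclusive — ties with the
top hit are never dropped — and the default `r = 0.10` keeps hits within
10% of the top score. A wider window can only move the LCA towards the
root, never deeper (this monotonicity is property-tested).

**Bit-score voting (the f-parameter).** For a contig or bin, every
annotated ORF deposits its top bit-score on each node of its annotation's
lineage. Scores are divided by the summed top bit-scores of annotated
ORFs, so the root always scores 1, scores never increase towards the
leaves, and the competing taxa at any single rank sum to at most 1. The
sequence is assigned the deepest node scoring *strictly above* `f`. The
default `f = 0.5` is majority voting; the strict inequality means an
exact 50/50 split between two sibling species escalates to their genus,
so a single winner always exists (values of `f` below 0.5, which would
permit multiple winners, are rejected). Hitless ORFs are excluded from
the denominator: the score is support among the assignments made, and
including hitless ORFs would break the root-sums-to-1 convention. Each
ORF contributes its top-hit bit-score only, not the sum over its retained
hits — the simplest weighting consistent with scores summing to at most 1.

**Integration.** The cascade falls through on *missing* annotations: a
read on a binned contig whose bin could not be annotated still gets the
contig's own annotation, and so on down the chain, so no read loses
information because a stronger stage was silent. Paired reads are treated
as independent records; all denominators count reads.

## Profiling rules

At each official rank (superkingdom/domain down to species) a read
contributes to the projection of its annotation onto that rank. A read
annotated at genus level is simply absent from the species rank — it is
neither a species-level count nor unclassified there — so the classified
mass can only shrink with depth. The minimum-abundance cut-off (default
0.001%, i.e. `1e-5`) is applied independently at every rank: a species
falling below the cut-off vanishes at species rank while its reads still
support its genus. The cut-off is a noise filter for spuriously detected
taxa carried by a handful of mis-annotated reads.

Read-fraction abundances are *sequence* abundances (fractions of
sequenced DNA). `to_taxonomic_abundance()` converts them to genome-copy
estimates by dividing by per-taxon mean genome sizes and renormalising
within each rank's retained mass; taxa without a size entry fall back to
the nearest ancestor that has one, which matches size tables aggregated
at every rank.

## Evaluation metrics

Per-read scoring projects prediction and truth onto each of the six
evaluated ranks (phylum to species): correct, incorrect, or unannotated.
TPR is correct / (correct + incorrect) — the correct fraction *of
annotated reads* — and is 0 by convention when nothing is annotated at a
rank; correct / total is reported separately as accuracy.

Profile comparisons use four measures:

* **L1 distance** at one rank: the sum over the union of taxa of absolute
  abundance differences, from 0 (identical) to 2 (disjoint full-mass
  profiles).
* **Precision** TP/(TP+FP) and **sensitivity** TP/(TP+FN) of binary
  detection at a rank, where a taxon is detected when its abundance is at
  least the cut-off; both are undefined (returned as `NA`) when their
  denominator is empty.
* **Weighted UniFrac**: the earth-mover's distance between the two
  classified-mass distributions placed on the taxonomy, with edge length
  1 per official-rank step. Mass annotated at an internal rank sits on
  that node itself rather than being spread to leaves. Both profiles are
  renormalised over their classified mass before transport (profiles with
  different unclassified fractions must still carry equal total mass for
  the distance to exist), and the distance is computed by the standard
  bottom-up traversal: process nodes deepest-first, push each node's
  signed surplus to its parent, and accumulate |moved mass| x edge
  length. Only official ranks carry unit edges by default; an
  `edge_unit = "node"` option counts every intervening taxonomy node
  instead, for taxonomies with informal levels between official ranks.

**Rarefaction** subsamples the annotated reads without replacement
(1–100% in the conventional steps, ten repeats), rebuilds the profile on
the subsample's own denominator, and counts detected taxa. Without a
cut-off a curve that keeps climbing at full depth indicates spurious
detections accumulating with sequencing depth; with the cut-off the
curves should level off.

## The synthetic-data generator

`simulate_dataset()` emulates a benchmark setting with known ground
truth: a random fully-ranked taxonomy; species abundances drawn from a
log-normal distribution (`mu = 1`, `sigma = 1.5` by default — a
realistically uneven community with a few dominant and many rare
species; `sigma = 0` gives a uniform community); reads assigned true
species by multinomial sampling; a configurable share of reads mapped to
pure per-species contigs (`assembled_fraction`, default 0.8); contigs
binned into per-species MAGs with probability `binned_fraction` (default
0.6), so the expected MAG-annotated read share is their product —
spanning regimes from well-assembled benchmark communities to
environmental samples where only a fifth of reads reach a MAG. "Novel"
species (no reference representative) receive ORF and contig hits
scattered over at least two sister taxa inside the bit-score window, so
their sequences are only annotatable at genus rank or above; direct read
hits are corrupted with probability `hit_noise` by a species from a
different genus. Bit-scores are synthetic (around 100 for true hits)
because only their relative magnitudes enter any rule. Bins are pure by
default; a `contamination` knob misplaces binned contigs to stress the
voting escalation.

The generator's ground-truth profile is the *realised* per-read
composition, so noiseless settings must be recovered exactly (L1 = 0,
precision = sensitivity = 1 at every rank) — a planted-signal test of the
whole pipeline, not a statistical approximation.

What the generator does not emulate: read sequences and error models
(no stage of the core consumes bases), chimeric or misassembled contigs,
uneven coverage along genomes, inter-sample variation, and databases
whose taxonomy disagrees with the truth taxonomy. Passing tests
therefore validate the algorithmic core, not robustness to assembler or
aligner artefacts.

## Numerical and design choices

* r-window boundary inclusive; voting threshold strict (`> f`). Both
  choices keep degenerate ties well-defined (top-score ties stay in; a
  50/50 vote escalates).
* Equal-MAPQ tie-breaks use an explicit caller seed, and the draw is
  invariant to input row order (mappings are canonically sorted first).
* Retired taxon ids are remapped transparently through the merged map;
  ids absent from the taxonomy altogether raise lookup errors rather
  than being dropped silently — hit tables built against an older
  database release should fail loudly, not shrink.
* NCBI "superkingdom" and GTDB "domain" share one rank slot, so profiles
  from either taxonomy live on the same rank axis; GTDB's two domains
  hang from a synthetic root so cross-domain LCAs exist.
* The per-rank cut-off is interpreted strictly as a relative-abundance
  rule (a fraction of the sample's reads), not as an absolute read
  count.
* UniFrac mass placement keeps internal-rank mass on the internal node;
  spreading it to leaves would fabricate resolution the annotation does
  not have.
* Test and vignette simulations use 10–50 species and 10^3–10^4 reads:
  large enough that per-rank profiles are dense and the integration
  orderings are stable across seeds, small enough to keep the whole
  suite fast on one CPU.

## Worked example

```{r example}
cfg <- simulation_config(seed = 7, n_species = 30, n_reads = 5000,
                         assembled_fraction = 0.8, binned_fraction = 0.6,
                         hit_noise = 0.3)
sim <- simulate_dataset(cfg)
res <- run_workflow(sim, mode = "mcr")
table(res$annotations$source)
score_read_annotations(res$annotations, sim$truth_reads, sim$tree)
l1_distance(res$raw_profile, sim$truth_profile, "species")
weighted_unifrac(res$raw_profile, sim$truth_profile, sim$tree)
```

```{r rarefy, fig.width = 5, fig.height = 4}
tab <- rarefaction(res$annotations, sim$tree, repeats = 5, seed = 1,
                   cutoff = 1e-5)
plot_rarefaction(tab)
```

## Known limitations

* Abundances are read counts, not base counts; coverage-weighted
  abundance and copy-number corrections are out of scope.
* The voting weight (per-ORF top score) is one defensible reading of
  bit-score voting; implementations that sum an ORF's retained hit
  scores would differ on contigs whose ORFs have many near-tied hits.
* The UniFrac convention (classified-mass renormalisation, official-rank
  unit edges) is one of several in circulation; distances are comparable
  only between profiles computed under the same convention.
* `lca()` and `lineage()` are exact but walk parent links per query;
  the implementation targets taxonomies up to the tens of thousands of
  nodes typical of profiling studies rather than the full nr taxonomy.
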