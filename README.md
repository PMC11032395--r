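# readtax

Integrated read-level taxonomic annotation and profiling for shotgun
metagenomes.

## What it does and for whom

Taxonomic profilers estimate the community composition of a metagenome
from its sequencing reads. Direct read annotation is sensitive but noisy:
short reads produce spurious hits, inflating the number of falsely
detected taxa. Assembled contigs — and bins of contigs (metagenome-
assembled genomes, MAGs) — carry a much stronger signal. `readtax` is for
microbiome researchers who have reads, a de novo assembly, optionally
bins, and homology hit tables (e.g. DIAMOND tabular output against a
protein database), and who want per-read annotations and a taxonomic
profile that uses the most reliable evidence available for each read.

The core algorithm:

* **Windowed LCA.** A query (ORF, contig, or read) with hits scored in
  bits is assigned the lowest common ancestor of the subjects scoring at
  least `(1 − r)·top` (default `r = 0.10`).
* **Bit-score voting.** A contig or bin is assigned the deepest taxon
  whose lineage support exceeds `f` (default `f = 0.5`, majority), where
  each annotated ORF deposits its top bit-score on its annotation's
  lineage and scores are normalised so the root scores 1.
* **Priority integration.** Each read takes the first available
  annotation along MAG > voted contig > direct contig > direct read,
  else it is unclassified. Modes: `mcr` (all evidence), `mc` (assembly
  evidence only), `cr` (ignore MAGs).
* **Profiling.** Per-rank abundance `p_i` = reads assigned to taxon *i*
  (by rank projection) / total sequenced reads, with a per-rank minimum-
  abundance cut-off (default 0.001%) and optional genome-size
  normalisation of sequence abundance into taxonomic abundance.
* **Evaluation.** Per-read scoring (TPR by rank), L1 distance
  `Σ_i |p1_i − p2_i|` over the union of taxa (0 = identical, 2 =
  disjoint), detection precision `TP/(TP+FP)` and sensitivity
  `TP/(TP+FN)`, weighted UniFrac as an earth-mover's distance on the
  taxonomy with unit edges between official ranks, and rarefaction
  curves.
* **Simulation.** A seeded generator produces taxonomies, log-normal
  communities, mappings, bins and noisy hit tables with full ground
  truth, so the entire pipeline is testable without aligners or
  reference databases.

## Worked example

Simulate a moderately hard dataset — 30 species, 5,000 reads, 80%
assembled, 60% of contigs binned, 30% of direct read hits corrupted —
then run the integrated workflow and compare against the known truth:

```r
library(readtax)
cfg <- simulation_config(seed = 7, n_species = 30, n_reads = 5000,
                         assembled_fraction = 0.8, binned_fraction = 0.6,
                         hit_noise = 0.3)
sim <- simulate_dataset(cfg)
res <- run_workflow(sim, mode = "mcr")

table(res$annotations$source)
#>           mag    contig_cat contig_direct   read_direct  unclassified
#>          2245          1729             0          1026             0

score_read_annotations(res$annotations, sim$truth_reads, sim$tree)
#>      rank correct incorrect unannotated    tpr accuracy
#> 1  phylum    5000         0           0 1.0000   1.0000
#> 2   class    5000         0           0 1.0000   1.0000
#> 3   order    4846       154           0 0.9692   0.9692
#> 4  family    4783       217           0 0.9566   0.9566
#> 5   genus    4696       304           0 0.9392   0.9392
#> 6 species    4696       304           0 0.9392   0.9392

l1_distance(res$raw_profile, sim$truth_profile, "species")
#> [1] 0.0816
weighted_unifrac(res$raw_profile, sim$truth_profile, sim$tree)
#> [1] 0.16
```

About 45% of reads were annotated through their MAG and another 35%
through their contig; only the ~20% unassembled tail relied on noisy
direct hits, which is why the species-rank TPR stays at 0.94 despite 30%
hit noise — annotating the same reads directly yields a species TPR
around 0.70 (see the integration tests). The profile is within L1 0.08
of the truth at species rank.

A command-line wrapper with `simulate`, `annotate`, `evaluate` and
`rarefy` subcommands is installed at `inst/cli/readtax`; every run
writes a manifest (parameters, seed, input checksums) for
reproducibility.

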