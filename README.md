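# gmekit

Reference genomes are least complete exactly where DNA is most repetitive:
satellite and microsatellite (MST) arrays resist assembly, and standard
exome capture deliberately avoids them. `gmekit` implements the
computational core of a **global microsatellite enrichment (GME)** workflow
for people who want to find repeat loci that are *missing from the
reference*:

* **Bait design.** Every 1–6-base repeat motif family — the equivalence
  class of a motif under cyclic rotation and reverse complementation, 501
  primitive families in all — is represented on a 120 nt capture oligo
  built from four 30 nt tandem-motif segments, balanced toward 40% G+C and
  screened for hairpin stems.
* **Unmapped-read analysis.** Sliding-window quality trimming (window 10,
  Q20, ≥70 bases) and N filtering (≥50 bases); tandem-repeat detection at
  periods 1–6 with the classic scoring (match +2, mismatch −7, minimum
  score 14, so the shortest reportable perfect repeat is period + 7 bases);
  known/novel classification by perfect match over more than half the
  contig; *concordant groups* of novel contigs seen in ≥2 samples at ≤1
  mismatch over >70% length, with consensus sequences; k-mer family depth
  tables, motif-class fractions and fold enrichment; matching of contigs
  and exon-derived cDNAs against RNA-seq-like reads.
* **A synthetic world.** A seeded genome/read simulator with planted,
  provably extra-referential pentamer loci (AATGG- and GTGGA-dominated),
  plus a naive mapper and a greedy assembler that emits Velvet-style IDs
  (`NODE_35_length_226_cov_17.079645`, convertible to read depth via
  `C = Ck·L/(L−k+1)`), so the whole pipeline runs and is tested end to end
  with no external data.

## Worked example

```r
library(gmekit)

# a motif and its family: GTTA belongs to the AACT family
canonical_family("GTTA")
#> <motif family AACT, period 4, 8 members>
#>   AACT ACTA AGTT CTAA GTTA TAAC TAGT TTAG

# find the pentamer array planted in a small contig
s <- paste0("ACGTCTGACTGA", strrep("AATGG", 4), "CTGAGTCA")
find_tandem_repeats(s, sequence_id = "contig1")
#>   sequence_id start end period motif family copies score percent_match
#> 1     contig1    12  32      5 AATGG  AATGG      4    30           100

# Velvet coverage -> read depth (150-base reads, k-mer 71)
read_depth(17.079645, L = 150, k = 71)
#> [1] 32.02433
```

The hit table says: a period-5 repeat occupies bases 12–32 (0-based
half-open), its consensus motif is `AATGG` (canonical family `AATGG`), it
has 4.0 copies, alignment score 30 = (20 − 5)·2 with 100% matching
positions. The depth conversion says a contig with k-mer coverage 17.08 was
sequenced at ~32× read depth.

End to end on synthetic data:

```r
truth <- simulate_genome(sim_config(seed = 609))   # 6 samples, 20 planted loci
res   <- run_unmapped_pipeline(truth)              # trim→map→filter→assemble→detect→classify→group
evaluate_recovery(res)[c("recovery_rate", "false_groups")]
#> $recovery_rate
#> [1] 1
#> $false_groups
#> [1] 0
```

All 20 planted extra-referential loci are recovered inside concordant
groups with the correct family, and no group is built from reference
material.

## Bait design

```r
baits <- design_bait_set()          # ~1 minute, fully deterministic
nrow(baits)                         # 353 baits covering all 501 families
round(100 * mean(baits$gc))         # 40
write_bait_fasta(baits, "baits.fa")
```

## Command line

A thin CLI ships under `inst/cli/gme`:

```sh
gme design-baits --gc-target 0.40 --gc-tol 0.05 --min-loop 3 --seed 1 -o baits.fa
gme trim --window 10 --q 20 --min-len 70 in.fastq -o trimmed.fastq
gme nfilter --min-len 50 trimmed.fastq -o filtered.fastq
gme find-repeats --min-score 14 --max-period 6 contigs.fa -o hits.tsv
gme simulate --seed 1 -o simout/
```

## Scope

The package reproduces algorithms and worked values, not the original
study's sample counts: statistics that depend on deposited raw sequencing
data (790 concordant contigs, 9.2-fold pentamer enrichment, 53% AATGG read
prevalence, the Hg19 MST census) are out of scope, though the functions
that compute them (`fold_enrichment()`, `motif_prevalence()`,
`class_fractions()`) are here to run on data you supply. See
`vignettes/gme-methods.Rmd` for the model, parameter and design rationale.
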