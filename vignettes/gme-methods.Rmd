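---
title: "Global microsatellite enrichment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global microsatellite enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmekit)
```

# The problem

Reference genomes are incomplete precisely where the DNA is most repetitive:
centromeric and other satellite arrays resist both assembly and the
locus-specific capture designs used in exome sequencing. `gmekit` implements
the computational side of a *global microsatellite enrichment* (GME)
strategy: instead of targeting the unique flanks of known loci, capture baits
are built from the repeat motifs themselves, so that every 1–6-mer
microsatellite (MST) family in the genome — including families that exist
only outside the reference — is pulled down. Downstream, reads that fail to
map to the reference are assembled into contigs, screened for tandem
repeats, classified as known or novel, and cross-validated across samples:
a *concordant* contig is a novel contig observed (to at most one mismatch
over more than 70% of its length) in two or more independent samples, and is
therefore unlikely to be an assembly or sequencing artifact.

# Motif families

Two repeat units describe the same locus if one is a cyclic rotation of the
other, or a rotation of its reverse complement (the same repeat read from
the opposite strand). `gmekit` works with the exact equivalence classes:
`family_members("AACT")` has the full `2 * 4 = 8` members, while
`family_members("AT")` has only 2, because `AT` is its own reverse
complement. The `N * 2` member count is an upper bound, not an identity, and
the package implements the classes exactly rather than the bound.

The canonical family name is the lexicographically smallest member. This is
a free choice — any deterministic representative would unify names across
samples — and the minimum is the convention that makes tables easiest to
scan. One consequence worth knowing: the centromere-like motif `GTGGA`
canonicalises to family `ACTCC`, and the telomeric repeat `GGGTTA` to
`AACCCT`.

Non-primitive motifs (`ATAT` = `AT` twice) are enumerated but flagged;
bait design and statistics use `primitive_only = TRUE` so a dimer locus is
never targeted twice under a tetramer alias. There are 2, 4, 10, 33, 102 and
350 primitive families of periods 1–6 — 501 in total — verified in the test
suite against an independent brute-force partition of all `4^k` strings.

# Bait design

Each 120 nt bait is four 30 nt segments, each a tandem fill (phase 0,
partial final copy allowed) of a member of a distinct motif family. Two
constraints shape the combinatorics:

* **G+C target.** Baits should sit near 40% G+C over their full length.
  Because base composition is preserved within a family (rotation and
  reverse complementation both conserve G+C count), a family contributes an
  essentially fixed G+C to any bait carrying it — and the 501 primitive
  families average ~50% G+C. Covering every family exactly once therefore
  *cannot* average 40%: the design must re-tile A/T-rich families as
  fillers. `design_bait_set()` seats the most extreme remaining family
  first, then fills the other three slots with whichever family (unused
  preferred, reused otherwise) brings the bait mean closest to target;
  reuse is recorded per bait. The default design yields 353 baits, mean G+C
  0.402, none outside the ±0.05 tolerance.
* **Hairpin potential.** The hairpin metric is the longest perfect
  inverted-repeat stem with a loop of at least `min_loop = 3` bases —
  a geometric screen, not a thermodynamic model, which is all the design
  objective ("lower probability of internal hairpin formation") requires.
  Member choice and segment order are optimised per bait by one pass of
  coordinate descent plus a scan of the 24 segment orderings, stopping once
  the longest stem is 3 bases or fewer (with a ≥3-base loop such a stem is
  not stable). Some families are intrinsically self-complementary (an `AT`
  tract is its own reverse complement), so a zero-hairpin design is not
  achievable and the residual stem is reported per bait.

All tie-breaks are by canonical name, so the design is byte-identical across
runs; the `seed` argument is echoed in the configuration for provenance but
nothing random remains to consume it.

# Read preparation

Quality trimming follows the sliding-window convention of the standard
trimmers: windows of 10 bases are scanned from the 5' end; at the first
window whose mean quality drops below 20 the read is cut at the first base
below the threshold from that window's start (not at the window boundary —
the boundary rule would discard up to 9 good bases, and the worked trimming
examples in the tests pin this behaviour). Reads shorter than 70 bases
after trimming are dropped, both mates of a pair together.

N filtering deletes all `N` characters (qualities in lockstep) and drops
reads shorter than 50 bases. Deleting rather than splitting at N runs is a
deliberate interpretation: the downstream rule is a single length test per
read. Note the pipeline applies the N filter to *unmapped* reads only (see
below), so the deletions never create false unmapped reads.

A Phred score `q` means error probability `10^(-q/10)`; `Q20 = 1/100`.

# Repeat detection

Detection uses the classic tandem-repeat scoring parameters: match +2,
mismatch −7, indel −5, minimum score 14, maximum period 6. The score of a
region at period `p` is its ungapped self-alignment at lag `p`: position `i`
compared with `i + p` across the region, so a perfect repeat of length `l`
scores exactly `(l − p) · 2` and the shortest reportable perfect repeat is
`p + 7` bases (score 14 at `l = p + 7`). Indels are not modelled in the
alignment: the indel penalty and the match/indel probability parameters are
carried in `repeat_params()` for fidelity of the record but unused. This is
a simplification relative to wraparound dynamic programming; it preserves
the reporting threshold semantics exactly, and the synthetic world contains
substitution errors only.

Per period, maximal-scoring intervals are extracted greedily (best interval,
mask, repeat; ties broken toward the smaller end coordinate, then the
smaller start). Overlapping calls across periods are collapsed keeping the
highest score, ties toward the smaller period — so a perfect `AT` tract is
reported once at period 2, never again at period 4. The consensus motif is
the per-phase majority base (ties toward the alphabetically smallest base);
copy number is `(end − start)/period` to one decimal.

`brute_force_repeats()` is the test oracle: exhaustive enumeration of every
`(start, end, period)` interval with direct scoring, same selection rules.
The acceptance suite checks exact agreement on 500 random strings with
planted repeats.

Coordinates are 0-based half-open everywhere in memory; the TSV writer
emits 1-based inclusive coordinates and the BED writer keeps 0-based
half-open, per each format's convention.

# Novelty, concordance, and expression support

* **Known/novel.** A contig is known when a reference sequence contains a
  perfect, ungapped match (either strand) to a contig substring strictly
  longer than half the contig. For 100%-identity ungapped matching, BLAST
  against an indexed database and exact substring search are mathematically
  equivalent; the package uses the latter, which is deterministic and makes
  the e-value threshold moot.
* **Concordance.** Contigs are linked when an ungapped alignment with at
  most 0 or 1 substitutions covers more than 70% of the shorter contig
  (the "query" in either direction), and groups are connected components
  (single linkage; the clustering rule is otherwise unspecified, and single
  linkage is both order-invariant and the weakest assumption). Long pairs
  are anchored on shared 31-mers — any qualifying block of ≥63 bases with
  ≤1 mismatch must contain an exact 31-mer — with an exhaustive offset scan
  as fallback for short contigs, so the anchoring is an optimisation, not an
  approximation. Zero-mismatch groups are by construction a refinement of
  one-mismatch groups.
* **Consensus.** Groups are consensus-called by a star alignment anchored on
  the longest member (tie: lexicographically smallest), per-column majority,
  ties toward the anchor base. Members that do not place against the anchor
  at ≥90% identity are flagged irreconcilable and excluded from the vote.
* **Expression support.** Putative cDNAs are exon concatenations
  (annotations with fewer than two exons are rejected — single-exon calls
  are not treated as gene-like structures). A read supports a query when a
  perfect ungapped match covers more than 70% of `min(query, read)`: a
  75-base read cannot cover 70% of a 300-base contig, so the threshold must
  be resolved on the shorter of the two for the comparison to be satisfiable
  at all — this matches the evident intent of counting read hits to long
  contigs.
* **Read depth.** Velvet-style IDs (`NODE_35_length_226_cov_17.079645`)
  carry k-mer coverage `Ck`, converted to read depth by
  `C = Ck · L/(L − k + 1)`; at `L = 150`, `k = 71` the example converts to
  32.02.

# The synthetic world

`sim_config()` states the world once; tests never tune it:

| parameter | default | why |
|---|---|---|
| reference_length | 10 kb | large enough for ~12 reference MST loci with disjoint flanks, small enough for minutes-scale runs |
| n_extra_referential_loci | 20 | the stated end-to-end scenario |
| motif_pool | AATGG 5, GTGGA 3, AATGC 1, AACCT 1 | extra-referential loci are pentamer-dominated, led by the two centromere-like motifs |
| reference pool | A, AC, AAG, AAT, AGAT, AAAT, AATG | deliberately excludes AATGG/GTGGA: their absence from the reference is what makes the extra loci unmappable |
| n_samples | 6 | the stated scenario |
| read_length / rna_read_length | 150 / 75 | the instrument read lengths being emulated |
| depth | 30× | the stated scenario |
| substitution_error_rate | 1e-3 | a Q30 instrument |
| n_rate | 5e-4 | "occasional" N bases at a realistic per-base rate (~7% of reads carry ≥1 N) |
| repeat_copies | 16–22 | pentamer arrays of 80–110 bases: detectable, but shorter than a read, so every read spans unique flank and assembly is unambiguous |

Backgrounds are rejection-sampled until no interval reaches the reporting
threshold, so any detected repeat is a planted one. Every extra-referential
segment is checked to share no 50-base substring with the reference (either
strand): the mapper's "unmapped" verdict for its reads is then provable
ground truth, not a heuristic. The generator does *not* emulate indel
errors, PCR duplicates, quality-by-cycle decay, or the GC bias of capture —
a green end-to-end test establishes that the algorithms compose correctly
on clean repeat structure, not that the laboratory protocol works.

The pipeline stage order is trim → map → extract unmapped → N-filter →
assemble; the N filter acts on unmapped reads (the mapper counts N as a
mismatch), because N-deleting a mappable read before mapping would shift its
coordinates and manufacture false unmapped reads.

`naive_map()` is exact under its stated budget: a read with at most
`max_mismatches` bad positions must contain an error-free seed among
`max_mismatches + 1` disjoint probes, and every probe hit is verified by
full comparison. `greedy_assemble()` merges maximal exact suffix–prefix
overlaps (≥31 bases), largest first, on both strands, then removes
reverse-complement and contained duplicates; `Ck` is total read k-mers
assigned to the contig over `L − k + 1`, with `k = 71` (odd, so a k-mer is
never its own reverse complement).

With the stated world (seed 609 in the acceptance test) the pipeline
recovers 20/20 planted loci inside concordant groups with the correct
canonical family and produces zero concordant groups from reference-only
material; the acceptance criterion requires ≥90% and exactly zero.

# Numerical and degenerate-input choices

* Empty hit sets: `class_fractions()` rejects (a fraction of nothing is
  undefined); `motif_prevalence()` returns `NA`; `family_depth_table()`
  returns a 0×0 matrix.
* `classify_novel()` with no references warns and reports everything novel.
* `read_depth()` requires `L ≥ k ≥ 1` and reduces to `Ck` at `k = 1`.
* Contigs shorter than the assembly k-mer get `Ck = 0` rather than a
  division by a non-positive length.
* All randomness flows from explicit integer seeds; per-sample streams are
  derived as `seed + 7919 · sample_index` (kept below 2^31).

# Known limitations

* Repeat alignment is substitution-only; a locus whose array contains an
  indel is reported as two adjacent hits rather than one.
* The hairpin screen is geometric; no free-energy model, no G·U/G·T wobble.
* The concordance 1-mismatch allowance names substitutions only — gapped
  variants between samples will not group.
* The assembler is a stand-in: it has no error correction, so reads with
  sequencing errors typically surface as singleton contigs (they are
  subsequently classified against the reference like any other contig).
* The paper-scale headline counts (790 concordant contigs, 9.2-fold
  pentamer enrichment, 53% AATGG prevalence) depend on the deposited raw
  data of the original study and are out of scope; the package computes the
  same statistics (`fold_enrichment()`, `motif_prevalence()`) on data you
  supply.
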