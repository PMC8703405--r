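---
title: "mosaicpaint: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mosaicpaint: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mosaicpaint` takes a de novo scaffold assembly of an introgressed line, a
reference genome, and a three-sample VCF (offspring plus its two parents),
and produces reference-ordered pseudomolecules, assembly statistics, gene
localisations, a window-based "painting" of the offspring genome by
parental origin, and a zoomed report for a QTL region. This vignette
explains the models and the choices behind each stage, and what the
package's synthetic benchmarks do and do not demonstrate.

## Scaffold placement

Placement is exact-match seeding plus colinear chaining, the standard
recipe behind whole-genome aligners.

* **Seeding.** The reference is indexed by all its `k`-mers (default
  `k = 15`). Every scaffold `k`-mer (both strands) that matches the index
  yields an anchor `(ref_start, scf_start)`. `k`-mers containing ambiguous
  bases are never indexed, and `k`-mers occurring more than `max_occ = 50`
  times are masked: anchors inside high-copy repeats carry no ordering
  information and would swamp the chainer. With these defaults a random
  (non-repetitive) sub-megabase genome is resolved uniquely: a random
  15-mer has a ~10^-9 chance of a spurious match per position.
* **Run collapsing.** Anchors on the same diagonal
  (`ref_start − scf_start`) at consecutive positions are merged into
  maximal exact runs first; an error-free scaffold reduces to a single run,
  and a scaffold with substitution rate *e* to roughly `e·L` runs, keeping
  the chaining quadratic-time DP trivial in practice.
* **Chaining.** Within one (chromosome, strand), the best chain maximises
  the sum of overlap-trimmed anchor bases minus, at each junction, the
  absolute difference between the reference gap and the scaffold gap (the
  implied indel length). Junctions with a gap above `max_gap = 10 kb` on
  either coordinate are forbidden, so a scaffold cannot chain across large
  rearrangements. The DP considers every predecessor, so it attains the
  exhaustive optimum over all colinear anchor subsets; the test suite
  verifies this against full enumeration on instances of up to 12 anchors.
  Chains are extracted best-first without anchor reuse and discarded below
  `min_chain_bases = 100`.
* **Placement and identity.** The whole scaffold is projected onto the
  reference through the chain (clipped at chromosome ends). Identity over
  the projected span is estimated gap-free: anchored columns are exact by
  construction; equal-length inter-anchor intervals are compared column by
  column; unequal intervals contribute their length difference as
  mismatches. This is an O(L) estimate, not an alignment — sufficient
  because downstream stages use identity only to rank chains and resolve
  overlaps, never as a reported alignment statistic.
* **Determinism.** One best chain is kept per scaffold (score =
  anchored bases × identity); ties break by (chromosome name, reference
  start). A scaffold with no chain above threshold is *unplaced* — a
  value, not an error.

## Pseudomolecule construction

Per chromosome, placements are sorted by reference start and connected in
order. Two choices deserve explanation:

* **Overlap resolution.** When projected intervals overlap, the
  lower-scoring scaffold is trimmed by the overlap on its conflicting end
  and dropped entirely if fully contained. Trimming (rather than dropping
  on any conflict) preserves each component's unique sequence; the
  higher-scoring component keeps its bases because its placement evidence
  is stronger.
* **Gap model.** Consecutive components are separated by an N gap equal to
  the reference gap between their projected intervals, and a leading N gap
  is inserted when the first scaffold starts after position 1. The
  alternative — a fixed 100-N spacer — would make pseudomolecule
  coordinates drift away from reference coordinates; mirroring the
  reference gaps keeps window coordinates, gene positions and QTL bounds
  directly comparable between pseudomolecule and reference.

The construction is emitted as AGP v2.1; rebuilding the sequence from the
AGP plus the scaffold FASTA is byte-identical to the emitted pseudomolecule
FASTA (tested). The assembled genome size counts scaffold (W-row) bases
only — gap Ns are placeholders, not assembled sequence — and coverage of a
reference is `100 · genome_size / reference_size`, rounded half-up to one
decimal. Unplaced scaffolds are listed but excluded from genome size.

## Assembly statistics

N50 uses the descending cumulative-sum convention: the smallest scaffold
length L such that scaffolds ≥ L contain at least half of the total bases.
Under this definition ties need no special handling, and the statistic is
invariant under permutation of the scaffolds (both property-tested, the
former against a brute-force evaluation of the definition on 1000 random
length sets).

## Gene localisation

Gene queries reuse the placement machinery; hits are ranked by
`identity × query_coverage`. The two criteria ("similarity" and
"coverage") are combined by their product because a top match must be good
on *both* axes — a verbatim fragment covering 40% of the query and a
full-length 80%-identity decoy both score below a full-length 98% copy.
Hits below 50% query coverage or 80% identity are rejected; ties break by
identity, then (chromosome, start). The distance between two gene hits is
the outer span `max(end) − min(start)`: this is the convention consistent
with published distances recomputed from top-match coordinates, and it is
reported in bp and in kb rounded half-up to one decimal. Hits on different
chromosomes produce an error naming both chromosomes, since an inter-gene
distance is then undefined.

## SNP classification and painting

Sites from the trio VCF are kept when QUAL ≥ 30 (inclusive — a site at
exactly the threshold passes) and the record is a biallelic SNP.
Classification compares homozygous alleles:

| offspring vs parents                  | class          |
|---------------------------------------|----------------|
| = parent A, parents differ            | parent-A-like  |
| = parent B, parents differ            | parent-B-like  |
| matches neither parent                | other          |
| all three equal                       | uninformative  |
| any heterozygous / missing genotype   | uninformative  |

Heterozygous calls are treated as uninformative rather than assigned,
because the intended material is inbred lines: a het call there is more
likely a mapping or calling artefact than a true genotype, and guessing a
parental origin from it would inject noise into exactly the windows with
the least reliable data.

Windows are anchored at position 1 of each chromosome, with window *i*
covering `[(i−1)·w + 1, i·w]` and a SNP at position *p* assigned to window
`⌈p/w⌉`; the last window of a chromosome is kept whole. Each window is
labelled by its dominant class. A tie is labelled "other": promoting
either parent on a tie would bias the composition estimate, while "other"
states only that the window is not clearly attributable. An empty window
is "missing" and is excluded from composition percentages, which are
computed over classified units and rounded half-up to integers (the
half-up convention matters: banker's rounding changes several published
percentage reproductions).

Composition can be computed over windows (each window one unit, its
dominant class its vote) or over raw classified SNPs. Window-based
composition downweights SNP-dense clusters and is the basis of the
"percent of genome from each parent" estimate; both are reported.

## QTL zoom

Windows are selected on the genome-anchored grid, indices
`⌊start/w⌋ + 1 … ⌈end/w⌉`, i.e. edge windows are included whole and a
window whose last base merely touches the region start is excluded. Keeping
the genome grid (rather than re-binning from the region start) means the
50 kb and 100 kb zooms line up with the whole-genome painting. Segments are
the run-length encoding of the window labels; runs of missing windows are
preserved as segments so the report shows where evidence is absent rather
than silently bridging it.

## The synthetic study system

The generator simulates the data structure of a backcross-derived line and
its parents:

* **Founders.** Three genomes (recurrent parent A, donor parent B, and a
  third "unknown" founder U) share one coordinate system and differ at
  biallelic sites drawn independently per bp at `snp_rate` (default
  1/200). Each site is private to one founder. By default the private-site
  proportions are (A, B, U) = (0.25, 0.25, 0.5): the two named parents
  share recent breeding ancestry, while the unknown founder is more
  diverged from either of them. This asymmetry is not cosmetic — if all
  three founders were equally diverged, a window truly inherited from U
  would contain equal numbers of A-like, B-like and other classifications
  and the "other" class would be statistically unidentifiable at the
  window level. Real unknown-source segments are detectable for exactly
  this reason: they carry an excess of alleles absent from both parents.
* **Offspring.** A copy-paste mosaic: segment lengths are
  `min_segment_len` (default 100 kb) plus an exponential with overall mean
  `mean_segment_len` (default 200 kb); origins are i.i.d. with
  probabilities `target_fracs` (default 0.61/0.23/0.16, the midpoints of a
  published backcross-line composition estimate). Adjacent same-origin
  segments are merged, and a chromosome-end remainder shorter than the
  minimum is absorbed into the final segment, so the configured minimum
  truly holds — sub-window fragments would otherwise make breakpoint
  recovery ill-posed by construction, not by any property of the method.
  There is no crossover-interference model; segments are independent.
* **Scaffolds.** Chromosomes are cut into pieces with lognormal lengths
  (arithmetic mean 25 kb, sd 15 kb — scaled to typical short-read scaffold
  N50s), each reverse-complemented with probability 1/2, with substitution
  errors at `scaffold_error_rate` (default 10^-3).
* **Trio VCF.** One VCFv4.2 record per catalogued site where the three
  emitted samples are not all identical; REF is the ancestral allele;
  genotypes are homozygous diploid (inbred lines — heterozygous truth is
  never generated; het handling is purely a classifier decision). QUAL is
  constant 60, with an injectable fraction of QUAL-10 sites to exercise
  the filter.
* **Truth files.** Mosaic segments (BED, 0-based half-open as the format
  requires; all in-memory coordinates are 1-based inclusive), scaffold
  placements and gene positions (TSV).

Everything is deterministic given the config seed: two runs produce
byte-identical FASTA/VCF/BED/TSV outputs (tested).

**What the simulator does not emulate:** read-level errors and coverage
variation (it emits scaffolds, not reads), genotype-likelihood artefacts,
indels and structural variants, repeat families and transposons,
centromeric recombination suppression, segregation distortion, and residual
heterozygosity in the parents. Passing the synthetic benchmarks therefore
demonstrates the correctness of the algorithms under clean assumptions —
not robustness to repeat-rich plant genomes, which would require a
repeat-aware placement stage upstream.

## Benchmark scales and tolerances

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core while each property is still
measured on hundreds of units: round-trip assembly on 1 Mb
(2 × 500 kb, ~40–50 scaffolds), painting on 5 Mb (10 × 500 kb, ~25,000
segregating sites, 100 windows of 50 kb), chaining oracles on ≤ 12 anchors
(exhaustive enumeration), N50 on 1000 random length sets. At the 5 Mb
painting scale, window quantisation alone contributes up to ~1–2 percentage
points of composition error (each of ~25 breakpoints is located only to
±half a window), so the observed 1–2 pp agreement is near the resolution
limit of the window method itself, not a deficiency of the classifier.

## Known limitations

* Placement assumes the reference and the assembled line are colinear up
  to `max_gap`; inversions smaller than a scaffold are split or mis-joined
  rather than detected.
* Identity is a gap-free estimate; indel-rich divergence deflates it.
* The dominant-type window rule has no uncertainty model — an HMM would
  smooth single-window noise, but the plain rule keeps each window an
  independent, auditable vote.
* `coverage_percent` compares assembled bases to a scalar reference size;
  it does not check *which* bases are covered.
* The window composition treats each non-missing window equally; partial
  terminal windows get full weight.
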