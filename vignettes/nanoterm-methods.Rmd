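---
title: "Models and methods behind nanoterm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoterm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nanoterm works on macronuclear genomes of stichotrichous ciliates, which are
fragmented into tens of thousands of gene-sized "nanochromosomes". Each
mature nanochromosome is capped on both ends by a short C4A4-type telomeric
repeat (`CCCCAAAA` on the 5' strand, `GGGGTTTT` on the complement), is
amplified to a chromosome-specific copy number, and may exist as several
isoforms produced by alternative fragmentation — alternative positions at
which telomeres are added de novo during macronuclear development. These
properties drive every design choice below: telomeres mark *completeness*
(a contig with both caps is a finished chromosome), read depth measures
*copy number*, and telomere-bearing reads that map internally reveal
*alternative fragmentation*.

This vignette explains the models, the tunable parameters, and the choices
made where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The synthetic genome model

`simulate_genome()` plants a ground truth against which every downstream
stage is validated:

* **Chromosome lengths** are lognormal with a 2,500 bp median
  (`length_meanlog = log(2500)`, `length_sdlog = 0.55`), truncated to
  [500, 20,000] bp by resampling — gene-sized molecules with a long tail,
  the architecture these genomes show.
* **Copy numbers** are lognormal with `copy_sdlog = 0.6`, rescaled to mean
  1. That sigma places most chromosomes within roughly one order of
  magnitude of each other, the spread reported for these genomes.
* **Telomeres** are exactly 20 bp (2.5 repeat units) per end, starting in
  repeat phase 0 at the molecule terminus.
* **Alternative fragmentation**: 10% of chromosomes carry one internal
  telomere-addition site at least 100 bp from either cap. Each such
  chromosome yields a complementary isoform pair — the left isoform keeps
  the left telomere and gains a fresh cap at the breakpoint, and vice
  versa. Isoform abundance is a free parameter
  (`alt_frag_isoform_weight = 0.3` relative to the parent): no published
  abundance model exists, only the observation that isoform coverage steps
  are unequal.
* **Telomere-addition jitter**: the junction coordinate of every sequenced
  molecule is shifted by round(Normal(0, 3)) bp. Because each sequenced
  fragment comes from a distinct molecule copy, drawing the jitter per
  fragment *is* the per-molecule model. Jitter is the single most
  consequential nuisance process in the system; see the extension section.
* **Haplotypes**: two, differing by i.i.d. substitutions at 0.002/bp in the
  genomic interior. The pipeline does not phase; heterozygosity acts purely
  as consensus stress, and the majority vote collapses to one allele.
* **Reads**: 90 bp inward-facing pairs, outer distance Normal(163, 20) —
  the short-fragment library geometry that makes telomeric ends reachable —
  with i.i.d. substitution errors at 0.001/base and constant Phred quality.
  Fragment ends are not uniform: random fragmentation of a molecule always
  produces two molecule-terminal fragments, so a size-selected fragment is
  terminal with probability about `frag_mean / molecule_length` per end.
  This matters: molecule-terminal fragments are precisely the ones whose
  reads begin with the telomeric selector, and a uniform-start model would
  underrepresent them by two orders of magnitude.

What the simulator does **not** emulate: indel sequencing errors, quality
score profiles, GC-coverage bias, micronuclear precursor sequence, and
chimeric library artifacts. Passing tests therefore demonstrate algorithmic
correctness under substitution-dominated Illumina-like noise, not
robustness to every artifact of real libraries.

## The mapper

The mapper is deterministic, gapless and self-contained, with an explicit
mismatch budget — chosen so that an exhaustive Hamming-distance oracle can
check it exactly. Placements are proposed from exact shared 21-mers (every
position indexed, both strands) and scored gaplessly; `N` counts as a
mismatch. The best placement maximizes matching bases, breaking ties by
fewest mismatches, then lowest contig id, lowest coordinate, then forward
strand. With full-length alignment (strict mode) this is identical to
"fewest mismatches"; under partial end-overlaps (lenient mode) fewest
mismatches alone would degenerate toward tiny clean overlaps, hence the
most-matches objective.

Two modes reflect two jobs:

* **strict** — full-length, at most 1 substitution: extension anchoring and
  telomere-addition-site mapping, where precision matters.
* **lenient** — at least 90% identity over at least 70% of the read, end
  overhangs allowed: coverage and depth metrics, where recall matters.

Seeding guarantees: a 90-bp read with at most `floor(90/21) - 1 = 3`
substitutions always retains one clean 21-mer, so the seeded search
provably returns the exhaustive optimum for such reads. Beyond 3
substitutions sensitivity decays gracefully but is no longer guaranteed;
the oracle-equivalence tests generate reads in the guaranteed regime plus
unrelated random reads.

Indels are not aligned at all — substitutions dominate Illumina error, the
finishing rules are substitution-phrased, and gapless alignment keeps the
oracle exact. Reads spanning a jittered telomere junction are the visible
cost: a junction shift acts as an indel, such reads fail the lenient
identity floor, and total read coverage of a jittered simulation sits
around 97% rather than 100% (the same few-percent shortfall seen in real
nanochromosomal assemblies). With jitter disabled, coverage is complete,
which is exactly what the tests assert.

## The finishing loop

`run_terminator()` iterates classify → extend → merge → remove-chaff until
the objective — the fraction of contigs that are complete nanochromosomes
(2-telomere contigs / total contigs) — gains less than `min_gain = 0.001`,
a round would decrease it (the round is rejected and the loop stops), or
`max_rounds = 20`.

**Extension** is pair-constrained: a candidate mate votes on an uncapped
end only if its partner maps full-length to that contig with at most one
substitution, oriented so the candidate points off the end. The candidate
is placed on the terminal region at its best offset with at most
`max_overhang_mismatch = 1` substitution over the overlap (at least 10 bp
of overlap), and its overhanging bases vote per column. Columns are
appended while at least `min_support = 3` reads vote and a strict-majority
base exists — three reads guard against a single errored or chimeric read
at 60x, and strict majority resolves haplotype collapse to the major
allele. Interior bases are never modified; extension only appends.

**Telomere capping.** Column voting cannot finish a telomere under
junction jitter: reads from molecules whose junctions differ by a few bases
carry the repeat in shifted phases, so votes a few bases into the repeat
split between G and T and deadlock. The repeat itself is invariant, which
makes the fix safe: once the extended end enters the cap — the first
G-block in the terminal zone whose suffix is at least 80% G/T marks the
junction — everything beyond the junction is replaced by the canonical
2.5-unit cap (`install_telomere_cap`). A capped end is permanently closed.
The residual risk is a genomic end that happens to terminate in `GGGG`
with a G/T-rich tail being falsely capped; at the default GC content this
affects well under 1% of ends and is visible in recovery statistics rather
than hidden.

**Merging** discovers candidate junctions from shared 16-mers within 300 bp
of contig ends (both orientations; 300 bp covers a split-contig overlap
plus one round of extension on each side). K-mers with fewer than 3 C/A or
fewer than 3 G/T bases are masked: such k-mers blanket the telomeric
repeat, which every capped contig shares and which can never be a junction.
Verified overlaps (gapless, at least 40 bp and 97% identity) merge greedily
in descending overlap x identity order with id-based tie-breaks;
containments at 97% are absorbed; a telomere-capped end is never a
junction. With two sequences, per-column majority voting with ties to the
longer contig reduces to taking the longer contig's overlap bases, which is
what the implementation does. **Chaff** removal drops contigs under 500 bp
that align to a longer contig covering more than 80% of their length at
more than 90% identity.

Stalled ends are reported, never forced: the loop re-maps each round with
the same mapper contract rather than alternating mappers with different
sensitivities, trading a little recall for determinism and testability.
Chimera detection is deliberately absent — with pair-constrained extension
and a greedy merge at 97% identity it has not been needed at these problem
sizes.

## Fragmentation-site calling

Read pairs are selected when a mate begins *exactly* with the 20-bp C-rich
selector `CCCCAAAACCCCAAAACCCC`. In an inward-oriented library every
telomere-junction read presents the C-rich repeat at its stored 5' start —
G-rich ends are sequenced as their reverse complement — so this single
selector covers both chromosome ends; the junction's side is recovered from
the mapped strand of the stripped residual (forward hit: left/C-rich
junction at the alignment start; reverse hit: right/G-rich junction at the
alignment end). The maximal leading repeat run, whole and partial units, is
stripped before strict-mode mapping; residues shorter than the seed length
are discarded and logged.

Raw sites of one contig and sense are clustered single-linkage with a
100-bp gap; a cluster's position is the support-weighted mode of its raw
coordinates (ties to the smaller coordinate), so every reported position is
witnessed by a read — the mode, not the mean, because telomere addition is
position-discrete with jitter. Sites within `terminal_margin = 50` bp of a
contig end are ordinary chromosome ends; the margin exceeds the jitter
scale while staying below gene scale. A contig with at least one internal
cluster passing `min_support` is alternatively fragmented.
`compare_site_sets()` reduces two assemblies' flags over a contig pairing
to both/either/neither counts and the both/either conservation fraction.

## Copy number, metrics, synteny

Copy number is mapped reads per base of contig, each lenient-mode read
counted once at its tie-broken best placement (multi-mapping reads are not
deduplicated, matching depth-based counting practice). Cross-library
normalization multiplies the smaller library's reads/bp by the ratio of
total mapped reads, and `correlate_orthologs()` reports plain Pearson's *r*
over reciprocal-best, optionally single-gene, ortholog pairs — raw by
default, with a log10 option, since published practice is ambiguous on the
transform. Assembly metrics collect size, contig/telomere tallies, the
2/1/0-telomere decomposition, lenient read-coverage percentages (total and
telomeric), and the proper-pair fraction (same contig, opposite strands,
inward, outer distance within mean ± 4 SD of the library). Two-gene
synteny flags a two-gene contig when both genes match genes on a single
partner contig below an e-value threshold (default 1e-10), with gene-order
agreement reported separately.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere, including BED output;
  1-based appears only in human-readable prints.
* Contig-end telomere classification tolerates 1 mismatch per complete
  20 bp of run (assembled consensus carries allelic bases; recall), while
  read selection is exact (precision). A run must end on at least 4
  consecutive repeat bases so chance matches in flanking sequence cannot
  extend it, and a capping run must begin within 30 bp of the terminus —
  tolerant of small adapter overhangs without misclassifying internal
  repeats as caps.
* `N` is legal in contigs, never emitted by the simulator, and always a
  mismatch in alignment.
* Empty inputs (no reads, no candidates, zero-length extension, all ends
  capped) are fixpoints, not errors; zero-mapped contigs stay in
  copy-number output with 0.0 reads/bp.
* Truth-recovery identity is Needleman–Wunsch over the full sequences
  (both strands), matches divided by the longer length, so junction shifts
  cost their indel length rather than a cascade of repeat mismatches.
* All randomness flows from one integer seed; reruns are byte-identical.

## Problem sizes

The test suite and acceptance script run the full system on 200 simulated
chromosomes (~0.57 Mb of genome, ~190,000 read pairs at 60x) — large
enough for cluster statistics, depth regression and recovery rates to be
meaningful, small enough for a complete run on one CPU in minutes — with
smaller constructions for threshold-exactness and oracle-equivalence
checks. Known limitations at larger scales: the every-position k-mer index
is memory-proportional to genome size and intended for desk-scale (tens of
Mb) genomes, and gapless alignment is unsuitable for indel-rich data.
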