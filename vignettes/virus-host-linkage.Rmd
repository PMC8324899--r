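---
title: "CRISPR spacer-based virus-host linkage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR spacer-based virus-host linkage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerlink)
```

## The analysis in one paragraph

A CRISPR array is a genomic ledger of past infections: short spacers,
copied from invaders, separated by a conserved direct repeat (DR). When a
spacer from a host's array aligns to a locus (a protospacer) on an
assembled scaffold, that scaffold's replicon is linked to the host as a
current or past invader. `spacerlink` mines spacers from raw reads
anchored on the DR, clusters them, matches cluster representatives to
candidate scaffolds, classifies the spacer-targeted scaffolds into
viruses and putative viruses, and follows coverages, host–virus ratios
and spacer diversification across samples and timepoints. Everything is
exercised against a synthetic community with known ground truth.

## Spacer extraction

Reads are scanned for *exact, complete* occurrences of the DR consensus
and of its reverse complement (`N` never matches). On each read the
strand with more DR hits wins (ties go forward): a biological array is
single-stranded per locus, so mixed-strand hits on one read are
artifacts. The sequence between each pair of consecutive same-strand
occurrences is one spacer; segments bounded by only one DR are discarded
by default (`allow_partial = FALSE`), because a single flank cannot fix
the spacer boundary and would emit truncated sequences. Spacers outside
20–60 nt are dropped. Reverse-strand spacers are reverse complemented
into DR-forward orientation so clustering merges observations from either
strand. When the host population carries several DR variants, extraction
runs once per variant and results are kept separate by `dr_label`.

## Clustering at 99% identity

`pairwise_identity(a, b)` is the number of matched bases in the best
gap-free-scored global alignment (equivalently the longest common
subsequence) divided by the *shorter* sequence length — the cd-hit
convention, so a contained fragment scores 1.0. Clustering is greedy and
representative-based: unique sequences sorted by length descending (ties
lexicographic) join the first cluster whose representative reaches the
threshold, else found a new cluster. The sort makes the outcome
independent of input order, and the founder (longest, lexicographically
smallest member) is the representative. At 99% and spacer lengths under
100 nt, a single substitution already separates sequences — sequencing
errors therefore surface as singleton clusters, which is exactly how the
real data behave and why singleton counts are reported separately.

## Protospacer matching

The aligner is blastn-short in spirit: match +1, mismatch −3, affine gaps
costing 5 + 2k, exact word seeds (default word 7) merged by diagonal and
extended by banded local dynamic programming (band half-width `pad = 10`).
Two numerical choices matter:

* **Guaranteed sensitivity.** A word-7 seed cannot promise to find a
  40-mer protospacer carrying 8 substitutions (the mismatches can break
  every 7-run). `match_clusters_to_scaffolds()` therefore uses a scan
  mode: per-diagonal match counts are computed exhaustively and every
  diagonal holding at least `ceiling(similarity × length) − gap_slack`
  matches is extended. Any substitution-only hit at the threshold is
  found by construction; `gap_slack = 3` keeps lightly gapped hits
  reachable while leaving random diagonals (mean L/4 matches) hopeless.
* **Maximal identities among co-optimal alignments.** Local alignments
  can be co-optimal while differing in matched-base counts (a terminal
  `mismatch + 3 matches` segment scores zero). Traceback keeps such
  zero-score diagonal tails, so the reported identities are the maximum
  over co-optimal alignments and the similarity of a planted
  8-substitution 40-mer is exactly 32/40.

Similarity is identities divided by the full spacer length by default
(`sim_denominator = "query"`), the conservative reading that penalizes
partial-length local hits; identities over the aligned span is available
as an option. The threshold is inclusive at 0.80. Alignments sharing more
than half of their subject span are collapsed to the best-scoring one;
distinct loci on the same scaffold are all reported. Matching uses
cluster representatives only. In the pipeline the host genome is excluded
from the candidate scaffolds — it trivially contains its own spacers.

## Scaffold classification

Rules apply in a fixed order and every feature vector gets exactly one
verdict: (1) length ≤ 3000 bp → `not_considered`; (2) detected CRISPR
arrays totalling ≥ 5 spacers → `rejected` (a misbinned host CRISPR
fragment — genuine viral mini-arrays carry 1–2 spacers and do not
trigger this); (3) ≥ 3 bacterial annotation hits with zero hallmark genes
→ `rejected`; (4) ≥ 1 hallmark gene and circular → `virus`; (5)
spacer-targeted → `putative_virus`; (6) otherwise `not_considered`. The
decision nodes reconstruct the published scheme's stated outcomes from
its text; the exact flowchart is not public, so the rule set should be
read as a documented reconstruction with configurable thresholds.

Circularity is called from an exact terminal direct repeat of ≥ 20 bp
(search capped at min(length/2, 500)) — the standard assembler signature
of a complete circular genome; the generator emits circular replicons in
the same convention (default 55 bp), giving the detector a well-defined
target. Mini-CRISPR detection looks for maximal runs of ≥ 2 exact copies
of a candidate repeat (23–50 bp) separated by 20–60 nt spacers; for each
start the chain with the most units wins, ties to the longer repeat.

Intergenomic similarity is
`100 · 2 · (identical bases over the best non-overlapping local alignments) / (lenA + lenB)`,
computed in both directions and averaged, which makes it exactly
symmetric; alignments below score 25 are ignored, so unrelated genomes
score 0 (the chance local-alignment score between unrelated 10-kb genomes
is ~13–15 under +1/−3). This is a single-formula approximation in the
VIRIDIC spirit, not a re-implementation. Species (95%) and genus (15.8%)
demarcation is single-linkage clustering (`hclust` + `cutree`), joining
at similarity ≥ threshold; species clusters nest within genus clusters by
monotonicity.

## Abundance and dynamics

Read assignment is a purpose-built best-hit assigner, not a re-creation
of a general mapper: exact 15-mer seeds propose ungapped placements on
both strands, the fewest-mismatch placement wins, ties go to the first
reference in input order (`multi = "first"`; `discard` and `fractional`
are options), and placements with more than 2% mismatches are discarded.
Only the mismatch-filter semantics matter downstream; mapping fidelity is
not the scientific contribution. Coverage is mapped bases per reference
base; normalization multiplies every coverage in sample *s* by
`min(total bp) / total bp(s)`, expressing all samples at the depth of the
shallowest one and leaving within-sample ratios unchanged — hence the
host–virus ratio is scale-invariant. A virus with zero coverage yields an
`NA` ratio, never infinity. Spacer-abundance totals are additionally
divided by the host's normalized coverage relative to its minimum across
samples, so repertoire growth is not confounded with host abundance;
distinct-cluster counts stay un-normalized. The alternative reading of
that normalization (host relative abundance rather than host coverage)
differs only by a constant per sample and is not separately implemented.

## The synthetic community

The generator emulates: one dominant host whose genome carries a single
CRISPR locus (`DR (spacer DR)×n`, default 25 spacers of 30–45 nt — inside
the 20–60 filter by construction); viruses of 5–25 kb each carrying 5
protospacers copied from host spacers with independent per-base
substitutions (default 2%), on random strands at non-overlapping
positions; one third circular; two random background genomes (20–40 kb);
and 10^5 single-end 150 bp reads per sample with uniform substitution
errors (default 0.5%, a post-quality-control Illumina figure) drawn from
replicons proportionally to weight × length, so expected coverage is
proportional to weight alone. Default weights are host 60, viruses
15/10/5, backgrounds 5 — planted host–virus ratios of 4, 6 and 12, within
the range observed in real subsurface data. Everything is a function of
the seed; identical configs reproduce byte-identical files.

Between timepoints the array acquires new spacers at the leader end — the
canonical polarized acquisition mode — and loses random existing spacers.
Acquired spacers are copied from a random locus of a random co-occurring
virus (`acquisition_source = "virus"`): that is how adaptation works
biologically, and it is what makes the number of *matching* spacer
clusters grow over time for the right reason. A `"random"` source is
available for null experiments. The turnover model is a stand-in: no
published generative model of spacer turnover exists for this system, and
its parameters are not calibrated to field data.

What the generator does *not* emulate: quality-dependent or indel errors,
GC bias, strain mixtures within the host, assembly artifacts beyond the
terminal-repeat convention, or gene content (annotations are a synthetic
table mirroring the external evidence the classifier consumes). Passing
tests therefore demonstrate the correctness of the algorithms under a
substitution-only error model and known ground truth — not performance on
real assemblies, where chimeric scaffolds, strain variation and
annotation noise add failure modes this package does not model.

## Problem sizes and verification experiments

The test-suite experiments are sized for interactive runs: the end-to-end
recovery check uses the full default community (10^5 reads, one sample)
and asserts that all three planted viruses — and no background genome —
are spacer-targeted and that recovered host–virus ratios fall within 10%
of the planted weights. The temporal check runs three timepoints with
viral weights halving each step and three spacers acquired per step, and
asserts strictly increasing host–virus ratios and non-decreasing
distinct matching clusters. That scenario uses error-free reads by
design: at 99% clustering identity each sequencing error mints a
sample-specific singleton cluster, and with default error rates those
noise clusters (tens per virus per sample) would dominate the ±3-spacer
acquisition signal, turning a repertoire-turnover check into a test of
Poisson noise. The error model is exercised separately (ratio recovery,
mismatch filtering, recovery-at-coverage), where it belongs.

Oracle experiments pin the primitives: extraction against a brute-force
regex splitter on a thousand planted reads; the aligner against full
Smith–Waterman (Biostrings `pairwiseAlignment`) on planted fixtures built
to have unique optima (internal, separated substitutions), plus the
inclusive-threshold boundary at 8 vs 9 substitutions in a 40-mer;
clustering against an independent all-pairs greedy implementation on 300
spacers. Randomized fixtures use fixed seeds.

## Known limitations

* Identity and similarity definitions are conventions; other tools'
  numbers (cd-hit word filtering, BLAST E-values, VIRIDIC's exact
  procedure) will differ in edge cases even where the biology agrees.
* The read assigner is ungapped; indel-rich references would undercount
  coverage.
* Mini-CRISPR detection requires exact repeat copies; degenerate repeats
  are missed.
* Strand choice on reads with equally many DR hits on both strands is a
  convention (forward wins) and such chimeric reads are not strand-
  symmetric.
* Accession-based validation against deposited viral genomes requires
  network access and is deliberately out of the test suite; the pipeline
  accepts real FASTA/FASTQ inputs for that purpose.
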