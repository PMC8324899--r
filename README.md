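# spacerlink

CRISPR spacer–based virus–host linkage for metagenomes.

## The problem

Most viruses of uncultivated archaea and bacteria carry no recognizable
hallmark genes, so homology search alone cannot connect them to their
hosts. The host's own CRISPR array can: each spacer is a sequence copied
from a past invader, so a spacer that aligns to a scaffold (a
*protospacer* match) is direct evidence that the scaffold's replicon
infects that host. In ecosystems dominated by a single organism — such as
subsurface biofilms of the carbon-fixing archaeon *Ca.* Altiarchaeum —
this record is deep enough to identify the resident viruses, follow their
abundance over years, and watch the host's immune repertoire diversify in
response.

`spacerlink` implements that analysis as a tested, reusable pipeline for
anyone studying virus–host dynamics with metagenomic reads:

1. **Spacer extraction** — spacers are mined directly from raw reads
   anchored on exact matches of the direct-repeat (DR) consensus, in both
   orientations; only segments bounded by two complete DR copies and
   20–60 nt long are kept.
2. **Clustering** — occurrences are collapsed at 99% identity by greedy,
   representative-based clustering (cd-hit semantics: identity =
   matches / shorter sequence length), yielding per-sample cluster
   abundances.
3. **Protospacer matching** — cluster representatives are searched
   against candidate scaffolds with a blastn-short-style local aligner
   (+1/−3, gap 5/2) and kept when
   *similarity* = identities / spacer length ≥ 0.80 (inclusive).
4. **Scaffold classification** — spacer-targeted scaffolds pass a > 3 kb
   length gate, then: extensive CRISPR arrays (≥ 5 spacers) or bacterial
   annotation without hallmark genes ⇒ rejected; hallmark genes plus
   terminal-repeat circularity ⇒ *virus*; otherwise ⇒ *putative virus*.
   Whole-genome intergenomic similarity
   (100 · 2·identities / (lenA + lenB)) demarcates species at 95% and
   genera at 15.8% by single linkage.
5. **Abundance & dynamics** — reads are assigned to references by best
   ungapped identity with a 2% mismatch cap, coverages are normalized to
   the sample with the lowest sequencing depth, and the report tracks
   host–virus ratios (host / virus normalized coverage), total and
   distinct spacer clusters, singletons, and per-virus matching-spacer
   statistics across timepoints.

A first-class synthetic community generator (`community_config()`,
`simulate_timeseries()`) produces a dominant host with an evolving CRISPR
array, protospacer-bearing viruses (some circular, emitted with a
duplicated terminal repeat), background genomes, and shotgun reads with
known ground truth, so every stage is testable without downloads.

## Worked example

The `analysis/` scripts run the whole study on a two-timepoint synthetic
community (three viruses halve in abundance between t1 and t2 while the
host acquires three spacers and loses one):

```sh
Rscript analysis/01_simulate_community.R   # scratch/sim/: genomes + reads
Rscript analysis/02_extract_spacers.R
Rscript analysis/03_cluster_spacers.R
Rscript analysis/04_match_and_classify.R
Rscript analysis/05_abundance_dynamics.R   # tables under results/
```

Output of the run shipped in `results/` (seed 42):

```
spacer occurrences per sample: t1=1755, t2=2065
627 clusters from 3820 occurrences; 552 singletons (88%)
spacer-targeted scaffolds: virus_1, virus_2, virus_3
  scaffold_id        verdict                 reasons
1     virus_1 putative_virus       spacer_match_only
2     virus_2          virus hallmark_genes,circular
3     virus_3 putative_virus       spacer_match_only
4        bg_1       rejected   bacterial_no_hallmark
5        bg_2       rejected   bacterial_no_hallmark
virus_1: host-virus ratio 4 -> 8 (rose); distinct matching clusters 65 -> 69
virus_2: host-virus ratio 6 -> 12.2 (rose); distinct matching clusters 64 -> 93
virus_3: host-virus ratio 12.1 -> 24.9 (rose); distinct matching clusters 44 -> 60
```

Reading: all three planted viruses — and no background genome — are
recovered as spacer-targeted; the circular, hallmark-carrying genome is
classified *virus* and the rest *putative virus*; the host–virus ratios
double as the planted viral weights halve; and the spacer repertoire
diversifies (301 → 365 distinct clusters, singleton-dominated), the
qualitative signature of an ongoing arms race.

The same steps are available in one call:

```r
library(spacerlink)
cfg <- community_config(seed = 42)
sim <- simulate_timeseries(cfg)
scaffolds <- sapply(c(list(sim$community$host), sim$community$viruses,
                      sim$community$backgrounds), assembly_sequence)
names(scaffolds) <- c("host", "virus_1", "virus_2", "virus_3", "bg_1", "bg_2")
report <- run_pipeline(lapply(sim$samples, `[[`, "reads"), scaffolds,
                       cfg$dr_sequence, host_id = "host",
                       annotations = sim$community$annotations)
report$dynamics$per_virus
```

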