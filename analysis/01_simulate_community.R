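#!/usr/bin/env Rscript
# Step 1: emit the synthetic subsurface community used throughout the
# analysis — a dominant CRISPR-carrying host, three protospacer-bearing
# viruses (one circular), two background genomes, and two timepoints in
# which the viruses halve in abundance while the host acquires three
# spacers and loses one (the biofilm 2012 -> 2018 situation in miniature).
#
# Writes scratch/sim/: genomes.fasta, annotations.tsv, per-sample
# <t>.reads.fastq + <t>.truth.json, config.yaml.

library(spacerlink)

out <- file.path("scratch", "sim")
cfg <- community_config(
  seed = 42,
  timepoints = list(
    timepoint("t1"),
    timepoint("t2", virus_weight_factor = 0.5, n_acquired = 3L, n_lost = 1L)))
sim <- simulate_community(cfg, out)

for (sid in names(sim$samples)) {
  tr <- sim$samples[[sid]]$truth
  message(sprintf("%s: %d reads, %d spacers in the host array, host weight %g",
                  sid, sum(tr$read_counts), nrow(tr$spacers),
                  tr$weights[["host"]]))
}
message("planted protospacers: ", nrow(sim$community$protospacers),
        " across ", length(sim$community$viruses), " viruses")
message("wrote ", out)
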