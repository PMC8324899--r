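#!/usr/bin/env Rscript
# Step 2: mine CRISPR spacers from the raw reads of every sample, anchored
# on exact matches of the direct-repeat consensus (both orientations),
# with the 20-60 nt length filter. One row per spacer occurrence.
#
# Reads scratch/sim/; writes results/spacers.tsv.

library(spacerlink)

cfg <- yaml::read_yaml(file.path("scratch", "sim", "config.yaml"))
fq <- list.files(file.path("scratch", "sim"), pattern = "\\.reads\\.fastq$",
                 full.names = TRUE)
spacers <- do.call(rbind, lapply(fq, function(f) {
  sid <- sub("\\.reads\\.fastq$", "", basename(f))
  extract_spacers(f, cfg$dr_sequence, sample_id = sid)
}))
write_tsv(spacers, file.path("results", "spacers.tsv"))

tab <- table(spacers$sample_id)
message("spacer occurrences per sample: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))
message("length range observed: ", min(spacers$length), "-",
        max(spacers$length), " nt")
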