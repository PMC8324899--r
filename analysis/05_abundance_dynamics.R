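#!/usr/bin/env Rscript
# Step 5: read assignment (2% mismatch cap), depth normalization to the
# shallowest sample, host-virus ratios, and the temporal spacer-dynamics
# report: total spacer abundance (host-normalized), distinct and singleton
# clusters, and per-virus matching-spacer statistics.
#
# Reads scratch/sim/, results/spacers.tsv, results/matches.tsv; writes
# profiles.tsv, dynamics_per_sample.tsv, dynamics_per_virus.tsv,
# dynamics.json.

library(spacerlink)

scaffolds <- read_fasta(file.path("scratch", "sim", "genomes.fasta"))
fq <- list.files(file.path("scratch", "sim"), pattern = "\\.reads\\.fastq$",
                 full.names = TRUE)
samples <- setNames(as.list(fq), sub("\\.reads\\.fastq$", "", basename(fq)))
spacers <- read_tsv(file.path("results", "spacers.tsv"))
matches <- read_tsv(file.path("results", "matches.tsv"))
cl <- cluster_spacers(spacers, threshold = 0.99)

profiles <- normalize_coverage(sample_profiles(samples, scaffolds))
dyn <- spacer_dynamics(cl, matches, profiles, "host")

write_tsv(profiles, file.path("results", "profiles.tsv"))
write_tsv(dyn$per_sample, file.path("results", "dynamics_per_sample.tsv"))
write_tsv(dyn$per_virus, file.path("results", "dynamics_per_virus.tsv"))
jsonlite::write_json(list(per_sample = dyn$per_sample,
                          per_virus = dyn$per_virus),
                     file.path("results", "dynamics.json"),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)

print(dyn$per_sample)
for (v in unique(dyn$per_virus$virus_id)) {
  x <- dyn$per_virus[dyn$per_virus$virus_id == v, ]
  x <- x[order(x$sample_id), ]
  dir <- if (all(diff(x$host_virus_ratio) > 0)) "rose" else "did not rise"
  message(v, ": host-virus ratio ",
          paste(round(x$host_virus_ratio, 1), collapse = " -> "),
          " (", dir, "); distinct matching clusters ",
          paste(x$matching_distinct_clusters, collapse = " -> "))
}
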