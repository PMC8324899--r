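#!/usr/bin/env Rscript
# Step 3: collapse spacer occurrences from all samples jointly into 99%
# identity clusters (greedy, representative-based) and report the
# per-sample cluster abundance table plus the singleton share — the
# signature of a diversifying host population.
#
# Reads results/spacers.tsv; writes results/clusters.tsv and
# results/representatives.fasta.

library(spacerlink)

spacers <- read_tsv(file.path("results", "spacers.tsv"))
cl <- cluster_spacers(spacers, threshold = 0.99)
write_clusters(cl, file.path("results", "clusters.tsv"),
               file.path("results", "representatives.fasta"))

n <- nrow(cl$clusters)
message(n, " clusters from ", nrow(spacers), " occurrences; ",
        sum(cl$clusters$is_singleton), " singletons (",
        round(100 * mean(cl$clusters$is_singleton)), "%)")
for (s in cl$samples)
  message(s, ": ", sum(cl$clusters[[s]] > 0), " distinct clusters")
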