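#!/usr/bin/env Rscript
# Step 4: match spacer-cluster representatives as protospacers against
# every candidate scaffold (everything except the host genome) at the 80%
# similarity threshold, then classify spacer-targeted scaffolds: length
# gate (> 3 kb), terminal-repeat circularity, hallmark-gene evidence,
# mini-CRISPR screening and false-positive removal. Finally compute
# whole-genome intergenomic similarities of the predicted (putative)
# viruses and demarcate species (95%) and genera (15.8%).
#
# Reads scratch/sim/ and results/spacers.tsv; writes matches.tsv,
# linkage.tsv, features.tsv, classification.tsv, similarity.tsv.

library(spacerlink)

scaffolds <- read_fasta(file.path("scratch", "sim", "genomes.fasta"))
annotations <- read_tsv(file.path("scratch", "sim", "annotations.tsv"))
spacers <- read_tsv(file.path("results", "spacers.tsv"))
cl <- cluster_spacers(spacers, threshold = 0.99)

candidates <- scaffolds[setdiff(names(scaffolds), "host")]
matches <- match_clusters_to_scaffolds(cl, candidates, min_similarity = 0.80)
linkage <- summarize_linkage(matches, candidates, cl)
features <- scaffold_features(candidates, linkage, annotations)
classification <- classify_scaffolds(features)

write_tsv(matches, file.path("results", "matches.tsv"))
write_tsv(linkage, file.path("results", "linkage.tsv"))
write_tsv(features, file.path("results", "features.tsv"))
write_tsv(classification, file.path("results", "classification.tsv"))

message("spacer-targeted scaffolds: ",
        paste(sort(unique(matches$scaffold_id)), collapse = ", "))
print(classification)

viral <- classification$scaffold_id[
  classification$verdict %in% c("virus", "putative_virus")]
if (length(viral) >= 2) {
  m <- matrix(100, length(viral), length(viral),
              dimnames = list(viral, viral))
  for (i in seq_along(viral)[-length(viral)])
    for (j in seq(i + 1, length(viral))) {
      m[i, j] <- m[j, i] <-
        intergenomic_similarity(scaffolds[[viral[i]]], scaffolds[[viral[j]]])
    }
  dem <- demarcate(m)
  write_tsv(data.frame(scaffold_id = viral, m, check.names = FALSE,
                       species = dem$species, genus = dem$genus),
            file.path("results", "similarity.tsv"))
  message(length(unique(dem$species)), " species, ",
          length(unique(dem$genus)), " genera among ", length(viral),
          " predicted (putative) viruses")
}
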