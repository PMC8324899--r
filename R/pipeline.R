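#' Pipeline thresholds and options
#'
#' All thresholds of the linkage analysis with their standard values:
#' spacer length bounds 20-60 nt, cluster identity 0.99, protospacer
#' similarity 0.80, scaffold length gate 3000 bp, read mismatch fraction
#' 0.02, species demarcation 95%, genus demarcation 15.8%.
#'
#' @param spacer_len_min,spacer_len_max Spacer length filter (nt).
#' @param cluster_identity Spacer clustering identity threshold.
#' @param match_similarity Protospacer similarity threshold (inclusive).
#' @param min_scaffold_len Scaffold length gate (bp).
#' @param max_mismatch_frac Read-mapping mismatch cap.
#' @param species_threshold,genus_threshold Demarcation thresholds (%).
#' @param extensive_crispr Spacer count marking an extensive CRISPR array.
#' @param bacterial_evidence Bacterial hit count for rejection.
#' @param sim_denominator Similarity denominator (`"query"` or
#'   `"alignment"`).
#' @param multi Multi-mapping read policy.
#' @param seed RNG seed recorded in the run manifest.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(spacer_len_min = 20L, spacer_len_max = 60L,
                            cluster_identity = 0.99,
                            match_similarity = 0.80,
                            min_scaffold_len = 3000L,
                            max_mismatch_frac = 0.02,
                            species_threshold = 95.0,
                            genus_threshold = 15.8,
                            extensive_crispr = 5L,
                            bacterial_evidence = 3L,
                            sim_denominator = c("query", "alignment"),
                            multi = c("first", "discard", "fractional"),
                            seed = 1L) {
  sim_denominator <- match.arg(sim_denominator)
  multi <- match.arg(multi)
  if (!(cluster_identity > 0 && cluster_identity <= 1))
    stop("cluster_identity must be in (0, 1]")
  if (!(match_similarity > 0 && match_similarity <= 1))
    stop("match_similarity must be in (0, 1]")
  check_fraction(max_mismatch_frac, "max_mismatch_frac")
  stopifnot(spacer_len_min >= 1, spacer_len_max >= spacer_len_min,
            min_scaffold_len >= 0,
            species_threshold >= 0, species_threshold <= 100,
            genus_threshold >= 0, genus_threshold <= 100)
  structure(list(spacer_len_min = as.integer(spacer_len_min),
                 spacer_len_max = as.integer(spacer_len_max),
                 cluster_identity = cluster_identity,
                 match_similarity = match_similarity,
                 min_scaffold_len = as.integer(min_scaffold_len),
                 max_mismatch_frac = max_mismatch_frac,
                 species_threshold = species_threshold,
                 genus_threshold = genus_threshold,
                 extensive_crispr = as.integer(extensive_crispr),
                 bacterial_evidence = as.integer(bacterial_evidence),
                 sim_denominator = sim_denominator,
                 multi = multi,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full virus-host linkage pipeline
#'
#' Executes extract -> cluster -> match -> classify -> abundance ->
#' dynamics over one or more samples: spacers are mined per sample from
#' the reads, clustered jointly, cluster representatives are matched as
#' protospacers against every candidate scaffold (all scaffolds except
#' the host genome — which necessarily contains its own spacers), matched
#' scaffolds are classified, reads are assigned for coverage and
#' host-virus ratios, and the spacer dynamics are summarized. Whole-genome
#' similarity and species/genus demarcation are computed over scaffolds
#' classified `virus`/`putative_virus`. Outputs are deterministic given
#' the inputs.
#'
#' @param samples Named list: sample_id -> reads (path, data.frame, named
#'   character vector, or `DNAStringSet`).
#' @param scaffolds Named character vector (or FASTA path) of assembled
#'   replicons, including the host genome named by `host_id`.
#' @param dr Direct-repeat consensus (uppercase ACGT), or a named
#'   character vector of DR variants (extraction runs once per variant).
#' @param host_id Name of the host genome within `scaffolds`.
#' @param annotations Optional gene annotation table (`scaffold_id`,
#'   `is_hallmark`, `is_vog_hit`, `is_bacterial`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the TSV/JSON bundle.
#' @return A `linkage_report` list: `spacers`, `clusters`, `matches`,
#'   `linkage`, `features`, `classification`, `profiles`, `dynamics`,
#'   `similarity`, `demarcation`, `summary`.
#' @export
run_pipeline <- function(samples, scaffolds, dr, host_id,
                         annotations = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  scaffolds <- as_sequence_set(scaffolds, "scaffolds")
  if (!host_id %in% names(scaffolds))
    stop("host_id '", host_id, "' not among the scaffolds")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named list")
  if (is.null(names(dr))) names(dr) <- sprintf("DR%d", seq_along(dr))

  spacers <- do.call(rbind, lapply(names(samples), function(sid) {
    do.call(rbind, lapply(names(dr), function(lab)
      extract_spacers(samples[[sid]], dr[[lab]],
                      min_len = config$spacer_len_min,
                      max_len = config$spacer_len_max,
                      sample_id = sid, dr_label = lab)))
  }))

  clusters <- cluster_spacers(spacers, threshold = config$cluster_identity)
  candidates <- scaffolds[setdiff(names(scaffolds), host_id)]
  matches <- match_clusters_to_scaffolds(
    clusters, candidates, min_similarity = config$match_similarity,
    sim_denominator = config$sim_denominator)
  linkage <- summarize_linkage(matches, candidates, clusters)
  features <- scaffold_features(candidates, linkage, annotations)
  classification <- classify_scaffolds(
    features, min_len = config$min_scaffold_len,
    extensive_crispr = config$extensive_crispr,
    bacterial_evidence = config$bacterial_evidence)

  profiles <- normalize_coverage(sample_profiles(
    samples, scaffolds, max_mismatch_frac = config$max_mismatch_frac,
    multi = config$multi))
  dynamics <- spacer_dynamics(clusters, matches, profiles, host_id)

  viral_ids <- classification$scaffold_id[
    classification$verdict %in% c("virus", "putative_virus")]
  similarity <- demarcation <- NULL
  if (length(viral_ids) >= 1) {
    m <- matrix(100, length(viral_ids), length(viral_ids),
                dimnames = list(viral_ids, viral_ids))
    if (length(viral_ids) >= 2) {
      for (i in seq_along(viral_ids)[-length(viral_ids)]) {
        for (j in seq((i + 1), length(viral_ids))) {
          s <- intergenomic_similarity(scaffolds[[viral_ids[i]]],
                                       scaffolds[[viral_ids[j]]])
          m[i, j] <- m[j, i] <- s
        }
      }
    }
    similarity <- m
    demarcation <- demarcate(m, config$species_threshold,
                             config$genus_threshold)
  }

  summary <- list(
    n_samples = length(samples),
    n_spacer_occurrences = nrow(spacers),
    n_spacer_clusters = nrow(clusters$clusters),
    n_singleton_clusters = sum(clusters$clusters$is_singleton),
    n_matches = nrow(matches),
    spacer_targeted = sort(unique(matches$scaffold_id)),
    verdicts = table(classification$verdict),
    config = unclass(config),
    package_version = as.character(utils::packageVersion("spacerlink")))

  report <- structure(list(spacers = spacers, clusters = clusters,
                           matches = matches, linkage = linkage,
                           features = features,
                           classification = classification,
                           profiles = profiles, dynamics = dynamics,
                           similarity = similarity,
                           demarcation = demarcation, summary = summary),
                      class = "linkage_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.linkage_report <- function(x, ...) {
  s <- x$summary
  cat("linkage_report:", s$n_spacer_occurrences, "spacer occurrences in",
      s$n_spacer_clusters, "clusters;", s$n_matches,
      "protospacer matches on", length(s$spacer_targeted), "scaffold(s)\n")
  print(x$classification)
  invisible(x)
}

#' Write a linkage report bundle to disk
#'
#' @param report A `linkage_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$spacers, file.path(out_dir, "spacers.tsv"))
  write_clusters(report$clusters, file.path(out_dir, "clusters.tsv"),
                 file.path(out_dir, "representatives.fasta"))
  write_tsv(report$matches, file.path(out_dir, "matches.tsv"))
  write_tsv(report$linkage, file.path(out_dir, "linkage.tsv"))
  write_tsv(report$features, file.path(out_dir, "features.tsv"))
  write_tsv(report$classification, file.path(out_dir, "classification.tsv"))
  write_tsv(report$profiles, file.path(out_dir, "profiles.tsv"))
  write_tsv(report$dynamics$per_sample,
            file.path(out_dir, "dynamics_per_sample.tsv"))
  write_tsv(report$dynamics$per_virus,
            file.path(out_dir, "dynamics_per_virus.tsv"))
  if (!is.null(report$similarity)) {
    sim <- data.frame(scaffold_id = rownames(report$similarity),
                      report$similarity, check.names = FALSE)
    write_tsv(sim, file.path(out_dir, "similarity.tsv"))
  }
  s <- report$summary
  s$verdicts <- as.list(s$verdicts)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
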