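#' Assign reads to references by best ungapped identity
#'
#' A purpose-built best-hit assigner: exact word seeds (default 15-mers)
#' locate candidate ungapped placements on both strands; the placement
#' with the fewest mismatches wins, ties going to the first reference in
#' input order. Assignments with more than `max_mismatch_frac x read
#' length` mismatches are discarded — the post-mapping mismatch filter
#' (2% by default). `mapped_bp` accumulates the aligned read length.
#'
#' @param reads Reads (path, data.frame, named character, DNAStringSet).
#' @param references Named character vector of reference sequences or a
#'   FASTA path.
#' @param max_mismatch_frac Mismatch fraction cap; default 0.02.
#' @param word_size Seed word size; default 15.
#' @param multi Handling of reads tying across references: `"first"`
#'   (first reference in input order), `"discard"`, or `"fractional"`
#'   (mapped bp split equally).
#' @return List: `mapped_bp` (named), `n_assigned`, `n_unassigned`,
#'   `assignments` (per read: reference, 0-based position, strand,
#'   mismatches; NA when unassigned).
#' @export
assign_reads <- function(reads, references, max_mismatch_frac = 0.02,
                         word_size = 15L, multi = c("first", "discard",
                                                    "fractional")) {
  multi <- match.arg(multi)
  refs <- as_sequence_set(references, "references")
  tbl <- as_read_table(reads)
  if (nrow(tbl) == 0) {
    return(list(mapped_bp = setNames(numeric(length(refs)), names(refs)),
                n_assigned = 0L, n_unassigned = 0L,
                assignments = data.frame(read_id = character(),
                                         reference = character(),
                                         pos0 = integer(), strand = character(),
                                         mismatches = integer())))
  }
  mode <- match(multi, c("first", "discard", "fractional")) - 1L
  res <- assign_reads_cpp(tbl$sequence, unname(refs), as.integer(word_size),
                          max_mismatch_frac, mode)
  mapped <- setNames(res$mapped_bp, names(refs))
  list(mapped_bp = mapped,
       n_assigned = res$n_assigned,
       n_unassigned = nrow(tbl) - res$n_assigned,
       assignments = data.frame(read_id = tbl$id,
                                reference = names(refs)[res$ref_index],
                                pos0 = res$pos, strand = res$strand,
                                mismatches = res$mismatches,
                                stringsAsFactors = FALSE))
}

#' Per-sample coverage profiles
#'
#' Maps every sample's reads against the references and reports
#' `mapped_bp` and raw coverage (`mapped_bp / reference length`) along
#' with the sample's total sequenced bases.
#'
#' @param samples Named list: sample_id -> reads.
#' @param references Named character vector or FASTA path.
#' @param ... Passed to [assign_reads()].
#' @return data.frame: `sample_id`, `reference`, `mapped_bp`,
#'   `raw_coverage`, `total_bp`.
#' @export
sample_profiles <- function(samples, references, ...) {
  refs <- as_sequence_set(references, "references")
  rows <- lapply(names(samples), function(sid) {
    tbl <- as_read_table(samples[[sid]])
    asn <- assign_reads(tbl, refs, ...)
    data.frame(sample_id = sid, reference = names(refs),
               mapped_bp = unname(asn$mapped_bp),
               raw_coverage = unname(asn$mapped_bp) / nchar(unname(refs)),
               total_bp = sum(nchar(tbl$sequence)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize coverages to the sample with the lowest sequencing depth
#'
#' Every coverage in sample *s* is scaled by
#' `min over samples of total_bp / total_bp(s)`, so all samples are
#' expressed at the depth of the shallowest one. Within-sample coverage
#' ratios are unchanged.
#'
#' @param profiles Output of [sample_profiles()].
#' @return `profiles` with `norm_factor` and `normalized_coverage` added.
#' @export
normalize_coverage <- function(profiles) {
  stopifnot(nrow(profiles) >= 1)
  totals <- tapply(profiles$total_bp, profiles$sample_id, `[`, 1)
  if (any(totals <= 0)) stop("total_bp must be positive for every sample")
  fac <- min(totals) / totals
  profiles$norm_factor <- as.numeric(fac[profiles$sample_id])
  profiles$normalized_coverage <- profiles$raw_coverage * profiles$norm_factor
  profiles
}

#' Host-virus ratio
#'
#' Host normalized coverage divided by virus normalized coverage, per
#' sample. A virus coverage of zero yields `NA` (an explicit undefined
#' sentinel — never infinite arithmetic downstream).
#'
#' @param profiles Normalized profiles from [normalize_coverage()].
#' @param host_id,virus_id Reference identifiers.
#' @param sample_id Optional subset of samples.
#' @return Named numeric vector of ratios, one per sample.
#' @export
host_virus_ratio <- function(profiles, host_id, virus_id, sample_id = NULL) {
  if (!host_id %in% profiles$reference) stop("unknown host_id: ", host_id)
  if (!virus_id %in% profiles$reference) stop("unknown virus_id: ", virus_id)
  sids <- sample_id %||% unique(profiles$sample_id)
  vapply(sids, function(s) {
    h <- profiles$normalized_coverage[profiles$sample_id == s &
                                        profiles$reference == host_id]
    v <- profiles$normalized_coverage[profiles$sample_id == s &
                                        profiles$reference == virus_id]
    if (length(h) != 1 || length(v) != 1) stop("missing profile rows for ", s)
    if (v == 0) NA_real_ else h / v
  }, numeric(1))
}

#' Spacer dynamics across samples
#'
#' The temporal statistics of the CRISPR arms race: per sample, the total
#' spacer abundance (normalized by the host's coverage relative to its
#' minimum across samples), the number of distinct spacer clusters, the
#' singleton cluster count, and — per spacer-targeted virus — the
#' abundance and number of distinct clusters matching it plus the
#' host-virus ratio.
#'
#' @param clusters A `spacer_clusters` built over all samples jointly.
#' @param matches Protospacer matches from
#'   [match_clusters_to_scaffolds()].
#' @param profiles Normalized profiles covering the same samples.
#' @param host_id Host reference identifier.
#' @return A `dynamics_report`: `$per_sample` and `$per_virus`
#'   data.frames.
#' @export
spacer_dynamics <- function(clusters, matches, profiles, host_id) {
  samples <- clusters$samples
  psamples <- unique(profiles$sample_id)
  if (!setequal(samples, psamples))
    stop("sample ids of clusters and profiles disagree: ",
         paste(symdiff_chr(samples, psamples), collapse = ", "))
  samples <- sort(samples)
  if (!host_id %in% profiles$reference) stop("unknown host_id: ", host_id)
  if (!"normalized_coverage" %in% names(profiles))
    profiles <- normalize_coverage(profiles)

  host_norm <- vapply(samples, function(s)
    profiles$normalized_coverage[profiles$sample_id == s &
                                   profiles$reference == host_id],
    numeric(1))
  if (any(host_norm <= 0)) stop("host coverage must be positive in every sample")
  fac <- host_norm / min(host_norm)

  cnt <- as.matrix(clusters$clusters[, samples, drop = FALSE])
  total <- rowSums(cnt)
  per_sample <- data.frame(
    sample_id = samples,
    total_spacer_abundance = as.numeric(colSums(cnt)[samples] / fac),
    distinct_clusters = as.integer(colSums(cnt[, samples, drop = FALSE] > 0)),
    singleton_clusters = as.integer(
      colSums(cnt[, samples, drop = FALSE] > 0 & total == 1)),
    host_normalized_coverage = as.numeric(host_norm),
    stringsAsFactors = FALSE)

  viruses <- sort(unique(matches$scaffold_id))
  pv <- list()
  for (v in viruses) {
    cl <- unique(matches$cluster_id[matches$scaffold_id == v])
    idx <- clusters$clusters$cluster_id %in% cl
    vnorm <- vapply(samples, function(s) {
      x <- profiles$normalized_coverage[profiles$sample_id == s &
                                          profiles$reference == v]
      if (length(x) == 1) x else NA_real_
    }, numeric(1))
    pv[[v]] <- data.frame(
      sample_id = samples, virus_id = v,
      matching_abundance = as.numeric(
        colSums(cnt[idx, samples, drop = FALSE])[samples] / fac),
      matching_distinct_clusters = as.integer(
        colSums(cnt[idx, samples, drop = FALSE] > 0)),
      host_virus_ratio = ifelse(!is.na(vnorm) & vnorm > 0,
                                host_norm / vnorm, NA_real_),
      stringsAsFactors = FALSE)
  }
  per_virus <- if (length(pv)) do.call(rbind, pv) else
    data.frame(sample_id = character(), virus_id = character(),
               matching_abundance = numeric(),
               matching_distinct_clusters = integer(),
               host_virus_ratio = numeric(), stringsAsFactors = FALSE)
  rownames(per_virus) <- NULL
  structure(list(per_sample = per_sample, per_virus = per_virus),
            class = "dynamics_report")
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @export
print.dynamics_report <- function(x, ...) {
  cat("dynamics_report over", nrow(x$per_sample), "sample(s) and",
      length(unique(x$per_virus$virus_id)), "virus(es)\n")
  print(x$per_sample)
  invisible(x)
}
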