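#' Seeded local alignment of a short query against a subject
#'
#' blastn-short-style search: exact `word_size` seeds on both strands,
#' merged by diagonal, then banded ungapped-plus-gapped extension under
#' match +1 / mismatch -3 scoring with affine gaps (a gap of length k costs
#' `gap_open + k * gap_extend`). Maximal-scoring local alignments are
#' returned sorted by score; alignments sharing more than half of their
#' subject span are collapsed to the best-scoring one. Among co-optimal
#' alignments the one with the most identities is reported (zero-score
#' diagonal tails are retained).
#'
#' `method = "scan"` replaces word seeding with exhaustive per-diagonal
#' match counting and extends every diagonal holding at least
#' `min_matches` matched bases. This guarantees that any substitution-only
#' alignment with `>= min_matches` identities is found regardless of word
#' size, which short-word seeding cannot promise for heavily mutated
#' protospacers.
#'
#' @param query Query sequence (the spacer); length `>= word_size`.
#' @param subject Subject sequence (the scaffold).
#' @param word_size Seed word size; default 7 (blastn-short).
#' @param match,mismatch,gap_open,gap_extend Scoring; blastn-short
#'   defaults +1/-3, gap 5/2.
#' @param pad Diagonal band half-width for the gapped extension.
#' @param min_score Minimum reported score; defaults to `word_size`.
#' @param method `"word"` (seeded) or `"scan"` (guaranteed-sensitivity
#'   diagonal scan).
#' @param min_matches Diagonal match-count threshold for `method="scan"`.
#' @return data.frame: `subject_start`, `subject_end` (0-based half-open),
#'   `strand`, `query_start`, `query_end`, `score`, `identities`,
#'   `aligned_length` (subject span).
#' @export
seed_and_extend <- function(query, subject, word_size = 7L, match = 1L,
                            mismatch = -3L, gap_open = 5L, gap_extend = 2L,
                            pad = 10L, min_score = NULL,
                            method = c("word", "scan"), min_matches = NULL) {
  method <- match.arg(method)
  check_dna(query, "query", allow_n = TRUE)
  check_dna(subject, "subject", allow_n = TRUE)
  if (method == "word" && nchar(query) < word_size)
    stop("query (", nchar(query), " nt) shorter than word_size ", word_size)
  min_score <- min_score %||% word_size
  if (method == "scan" && is.null(min_matches))
    min_matches <- max(4L, ceiling(0.5 * nchar(query)))

  one <- function(q, strand) {
    df <- if (method == "word")
      seed_extend_cpp(q, subject, as.integer(word_size), as.integer(match),
                      as.integer(mismatch), as.integer(gap_open),
                      as.integer(gap_extend), as.integer(pad),
                      as.integer(min_score), 1L)
    else
      scan_extend_cpp(q, subject, as.integer(min_matches), as.integer(match),
                      as.integer(mismatch), as.integer(gap_open),
                      as.integer(gap_extend), as.integer(pad),
                      as.integer(min_score))
    if (nrow(df) == 0) return(NULL)
    n <- nchar(q)
    qs <- df$query_start; qe <- df$query_end
    if (strand == "-") { tmp <- qs; qs <- n - qe; qe <- n - tmp }
    data.frame(subject_start = df$subject_start, subject_end = df$subject_end,
               strand = strand, query_start = qs, query_end = qe,
               score = df$score, identities = df$identities,
               aligned_length = df$subject_end - df$subject_start,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(query, "+"), one(revcomp(query), "-"))
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(subject_start = integer(), subject_end = integer(),
                      strand = character(), query_start = integer(),
                      query_end = integer(), score = integer(),
                      identities = integer(), aligned_length = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- dedup_alignments(out)
  out[order(-out$score, out$subject_start), , drop = FALSE]
}

# Both-strand scan search with a precomputed reverse complement; the hot
# path of match_clusters_to_scaffolds.
scan_pair <- function(q, q_rc, subject, min_matches, pad = 10L, match = 1L,
                      mismatch = -3L, gap_open = 5L, gap_extend = 2L) {
  n <- nchar(q)
  fw <- scan_extend_cpp(q, subject, as.integer(min_matches),
                        as.integer(match), as.integer(mismatch),
                        as.integer(gap_open), as.integer(gap_extend),
                        as.integer(pad), 1L)
  rv <- scan_extend_cpp(q_rc, subject, as.integer(min_matches),
                        as.integer(match), as.integer(mismatch),
                        as.integer(gap_open), as.integer(gap_extend),
                        as.integer(pad), 1L)
  out <- NULL
  if (nrow(fw))
    out <- data.frame(subject_start = fw$subject_start,
                      subject_end = fw$subject_end, strand = "+",
                      query_start = fw$query_start, query_end = fw$query_end,
                      score = fw$score, identities = fw$identities,
                      aligned_length = fw$subject_end - fw$subject_start,
                      stringsAsFactors = FALSE)
  if (nrow(rv))
    out <- rbind(out, data.frame(
      subject_start = rv$subject_start, subject_end = rv$subject_end,
      strand = "-", query_start = n - rv$query_end,
      query_end = n - rv$query_start, score = rv$score,
      identities = rv$identities,
      aligned_length = rv$subject_end - rv$subject_start,
      stringsAsFactors = FALSE))
  if (is.null(out))
    return(data.frame(subject_start = integer(), subject_end = integer(),
                      strand = character(), query_start = integer(),
                      query_end = integer(), score = integer(),
                      identities = integer(), aligned_length = integer(),
                      stringsAsFactors = FALSE))
  dedup_alignments(out)
}

# Collapse alignments sharing > `frac` of the shorter subject span; the
# best score (ties: leftmost, then '+' strand) wins.
dedup_alignments <- function(df, frac = 0.5) {
  if (nrow(df) < 2) return(df)
  o <- order(-df$score, df$subject_start, df$strand)
  df <- df[o, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in which(keep)) {
      ov <- min(df$subject_end[i], df$subject_end[j]) -
        max(df$subject_start[i], df$subject_start[j])
      span <- min(df$subject_end[i] - df$subject_start[i],
                  df$subject_end[j] - df$subject_start[j])
      if (ov > frac * span) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Match spacer-cluster representatives to candidate scaffolds
#'
#' Every cluster representative is searched against every scaffold with
#' the guaranteed-sensitivity scan aligner; alignments whose similarity
#' (`identities / representative length` by default) reaches
#' `min_similarity` are reported, one row per (cluster, scaffold, locus).
#' The threshold is inclusive at exactly `min_similarity` (a 40-nt spacer
#' with 8 substitutions, 32 identities, is retained at 0.80).
#'
#' @param clusters A `spacer_clusters` object, or a named character vector
#'   of representative sequences.
#' @param scaffolds Named character vector of scaffold sequences, or a
#'   FASTA path.
#' @param min_similarity Similarity threshold; default 0.80, inclusive.
#' @param sim_denominator `"query"` (identities over the full spacer
#'   length, the conservative reading) or `"alignment"` (over the aligned
#'   subject span).
#' @param gap_slack Relaxation of the diagonal match-count prefilter, to
#'   keep gapped alignments reachable.
#' @param ... Passed to [seed_and_extend()] (scoring, pad).
#' @return data.frame of protospacer matches: `cluster_id`, `scaffold_id`,
#'   `scaffold_start`, `scaffold_end`, `strand`, `aligned_length`,
#'   `identities`, `similarity`, plus the per-sample abundance columns of
#'   the cluster when available.
#' @export
match_clusters_to_scaffolds <- function(clusters, scaffolds,
                                        min_similarity = 0.80,
                                        sim_denominator = c("query", "alignment"),
                                        gap_slack = 3L, ...) {
  sim_denominator <- match.arg(sim_denominator)
  stopifnot(min_similarity > 0, min_similarity <= 1)
  scaffolds <- as_sequence_set(scaffolds, "scaffolds")
  reps <- cluster_reps(clusters)
  counts <- NULL
  if (inherits(clusters, "spacer_clusters") && length(clusters$samples)) {
    counts <- clusters$clusters[, clusters$samples, drop = FALSE]
    rownames(counts) <- clusters$clusters$cluster_id
  }
  reps_rc <- revcomp(unname(reps))
  rows <- list()
  for (ci in seq_along(reps)) {
    q <- unname(reps[ci])
    L <- nchar(q)
    req <- ceiling(min_similarity * L - 1e-9)
    mm <- max(1L, req - as.integer(gap_slack))
    for (si in seq_along(scaffolds)) {
      alns <- scan_pair(q, reps_rc[ci], unname(scaffolds[si]),
                        min_matches = mm, ...)
      if (nrow(alns) == 0) next
      denom <- if (sim_denominator == "query") L else alns$aligned_length
      sim <- alns$identities / denom
      keep <- alns$identities + 1e-9 >= min_similarity * denom
      if (!any(keep)) next
      alns <- alns[keep, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = names(reps)[ci], scaffold_id = names(scaffolds)[si],
        scaffold_start = alns$subject_start, scaffold_end = alns$subject_end,
        strand = alns$strand, aligned_length = alns$aligned_length,
        identities = alns$identities, similarity = sim[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), scaffold_id = character(),
               scaffold_start = integer(), scaffold_end = integer(),
               strand = character(), aligned_length = integer(),
               identities = integer(), similarity = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(counts) && nrow(out)) {
    out <- cbind(out, counts[out$cluster_id, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Per-scaffold linkage summary
#'
#' Summarizes protospacer matches per scaffold: distinct matching
#' clusters, distinct protospacer loci (overlapping loci are merged), and
#' the total matching spacer abundance per sample (each contributing
#' cluster counted once per scaffold). Scaffolds with at least one match
#' are "spacer-targeted"; scaffolds without matches do not appear.
#'
#' @param matches Output of [match_clusters_to_scaffolds()].
#' @param scaffolds Named character vector of scaffolds (for lengths).
#' @param clusters Optional `spacer_clusters` supplying per-sample counts
#'   when `matches` does not carry them.
#' @return data.frame: `scaffold_id`, `length`, `n_clusters`, `n_loci`,
#'   `spacer_targeted`, plus per-sample abundance columns when available.
#' @export
summarize_linkage <- function(matches, scaffolds, clusters = NULL) {
  scaffolds <- as_sequence_set(scaffolds, "scaffolds")
  samples <- character()
  counts <- NULL
  if (!is.null(clusters) && inherits(clusters, "spacer_clusters")) {
    samples <- clusters$samples
    counts <- clusters$clusters[, samples, drop = FALSE]
    rownames(counts) <- clusters$clusters$cluster_id
  } else {
    samples <- setdiff(names(matches),
                       c("cluster_id", "scaffold_id", "scaffold_start",
                         "scaffold_end", "strand", "aligned_length",
                         "identities", "similarity"))
  }
  if (nrow(matches) == 0) {
    return(data.frame(scaffold_id = character(), length = integer(),
                      n_clusters = integer(), n_loci = integer(),
                      spacer_targeted = logical(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(matches, matches$scaffold_id), function(m) {
    sid <- m$scaffold_id[1]
    loci <- merged_locus_count(m$scaffold_start, m$scaffold_end)
    row <- data.frame(scaffold_id = sid,
                      length = nchar(scaffolds[[sid]]),
                      n_clusters = length(unique(m$cluster_id)),
                      n_loci = loci, spacer_targeted = TRUE,
                      stringsAsFactors = FALSE)
    if (length(samples)) {
      cl <- unique(m$cluster_id)
      ab <- if (!is.null(counts)) colSums(counts[cl, , drop = FALSE])
      else colSums(m[!duplicated(m$cluster_id), samples, drop = FALSE])
      row <- cbind(row, as.data.frame(as.list(ab), optional = TRUE))
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Number of connected components of overlapping intervals.
merged_locus_count <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  n <- 1L
  hi <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] >= hi) n <- n + 1L
    hi <- max(hi, end[i])
  }
  n
}
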