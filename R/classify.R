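#' Detect circularity through an exact terminal direct repeat
#'
#' A scaffold is called circular when its longest exact prefix that also
#' occurs as a suffix has length at least `min_repeat` — the standard
#' assembler signature of a complete circular genome. The search is capped
#' at `min(length/2, max_repeat)`.
#'
#' @param sequence Scaffold sequence.
#' @param min_repeat,max_repeat Terminal-repeat length bounds (bp).
#' @return List: `is_circular`, `terminal_repeat_len`, `trimmed_length`.
#' @export
detect_circularity <- function(sequence, min_repeat = 20L, max_repeat = 500L) {
  L <- nchar(sequence)
  cap <- min(L %/% 2L, max_repeat)
  if (cap >= min_repeat) {
    for (k in seq(cap, min_repeat)) {
      if (substr(sequence, 1L, k) == substr(sequence, L - k + 1L, L))
        return(list(is_circular = TRUE, terminal_repeat_len = k,
                    trimmed_length = L - k))
    }
  }
  list(is_circular = FALSE, terminal_repeat_len = 0L, trimmed_length = L)
}

#' Detect mini-CRISPR arrays on a scaffold
#'
#' Finds maximal runs of at least `min_units` exact copies of a candidate
#' repeat separated by spacers within `spacer_len_range`. Viral genomes may
#' legitimately carry 1-2-spacer mini-arrays; extensive arrays flag a
#' misbinned host fragment.
#'
#' @param sequence Scaffold sequence.
#' @param repeat_len_range Candidate repeat length range (bp).
#' @param spacer_len_range Spacer length range between repeat copies (bp).
#' @param min_units Minimum number of repeat copies.
#' @return data.frame: `start`, `end` (0-based half-open), `repeat`,
#'   `spacer_count`.
#' @export
detect_mini_crispr <- function(sequence, repeat_len_range = c(23L, 50L),
                               spacer_len_range = c(20L, 60L),
                               min_units = 2L) {
  mini_crispr_cpp(sequence, as.integer(repeat_len_range[1]),
                  as.integer(repeat_len_range[2]),
                  as.integer(spacer_len_range[1]),
                  as.integer(spacer_len_range[2]), as.integer(min_units))
}

#' Build the per-scaffold feature table
#'
#' Gathers the evidence the classifier consumes: length, terminal-repeat
#' circularity, annotation counts (hallmark / VOG / bacterial genes, from
#' an external annotation table), detected CRISPR-array spacer counts, and
#' whether the scaffold is spacer-targeted.
#'
#' @param scaffolds Named character vector or FASTA path.
#' @param linkage Linkage table from [summarize_linkage()] (or `NULL`).
#' @param annotations Gene table with columns `scaffold_id`,
#'   `is_hallmark`, `is_vog_hit`, `is_bacterial` (or `NULL`).
#' @param lytic_category Optional named character passthrough metadata.
#' @param ... Passed to [detect_circularity()] / [detect_mini_crispr()].
#' @return data.frame of `ScaffoldFeatures`.
#' @export
scaffold_features <- function(scaffolds, linkage = NULL, annotations = NULL,
                              lytic_category = NULL, ...) {
  scaffolds <- as_sequence_set(scaffolds, "scaffolds")
  targeted <- if (!is.null(linkage) && nrow(linkage))
    linkage$scaffold_id[linkage$spacer_targeted] else character()
  rows <- lapply(names(scaffolds), function(id) {
    s <- scaffolds[[id]]
    circ <- detect_circularity(s)
    arrays <- detect_mini_crispr(s)
    ann <- if (!is.null(annotations) && nrow(annotations))
      annotations[annotations$scaffold_id == id, , drop = FALSE] else NULL
    data.frame(scaffold_id = id, length = nchar(s),
               is_circular = circ$is_circular,
               terminal_repeat_len = circ$terminal_repeat_len,
               hallmark_gene_count = if (is.null(ann)) 0L else sum(ann$is_hallmark),
               vog_hit_count = if (is.null(ann)) 0L else sum(ann$is_vog_hit),
               bacterial_hit_count = if (is.null(ann)) 0L else sum(ann$is_bacterial),
               crispr_array_spacer_count =
                 if (nrow(arrays)) sum(arrays$spacer_count) else 0L,
               spacer_targeted = id %in% targeted,
               lytic_category = if (!is.null(lytic_category) &&
                                    id %in% names(lytic_category))
                 lytic_category[[id]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one scaffold
#'
#' Fixed rule order: (1) `length <= min_len` -> `not_considered` (length
#' gate); (2) CRISPR-array spacer count `>= extensive_crispr` -> `rejected`
#' (a misbinned host CRISPR fragment); (3) `>= bacterial_evidence`
#' bacterial hits with zero hallmark genes -> `rejected`; (4) at least one
#' hallmark gene and circular -> `virus`; (5) spacer-targeted ->
#' `putative_virus`; (6) otherwise `not_considered`. Every feature vector
#' yields exactly one verdict.
#'
#' @param features One row of [scaffold_features()] (or an equivalent
#'   list).
#' @param min_len Length gate (bp); default 3000.
#' @param extensive_crispr Spacer count at which an array counts as
#'   extensive; default 5 (1-2-spacer mini-arrays are legitimate on
#'   viruses).
#' @param bacterial_evidence Bacterial hit count that, absent hallmark
#'   genes, rejects the scaffold; default 3.
#' @return List: `scaffold_id`, `verdict`, `reasons`.
#' @export
classify <- function(features, min_len = 3000L, extensive_crispr = 5L,
                     bacterial_evidence = 3L) {
  f <- as.list(features)
  verdict <- NULL; reasons <- character()
  if (f$length <= min_len) {
    verdict <- "not_considered"; reasons <- "length_gate"
  } else if (f$crispr_array_spacer_count >= extensive_crispr) {
    verdict <- "rejected"; reasons <- "extensive_crispr_array"
  } else if (f$bacterial_hit_count >= bacterial_evidence &&
             f$hallmark_gene_count == 0) {
    verdict <- "rejected"; reasons <- "bacterial_no_hallmark"
  } else if (f$hallmark_gene_count >= 1 && isTRUE(f$is_circular)) {
    verdict <- "virus"; reasons <- c("hallmark_genes", "circular")
  } else if (isTRUE(f$spacer_targeted)) {
    verdict <- "putative_virus"; reasons <- "spacer_match_only"
  } else {
    verdict <- "not_considered"; reasons <- "no_evidence"
  }
  list(scaffold_id = f$scaffold_id %||% NA_character_,
       verdict = verdict, reasons = reasons)
}

#' Classify every scaffold in a feature table
#'
#' @param features Output of [scaffold_features()].
#' @param ... Passed to [classify()].
#' @return data.frame: `scaffold_id`, `verdict`, `reasons`
#'   (comma-separated rule tags).
#' @export
classify_scaffolds <- function(features, ...) {
  rows <- lapply(seq_len(nrow(features)), function(i) {
    cl <- classify(features[i, , drop = FALSE], ...)
    data.frame(scaffold_id = cl$scaffold_id, verdict = cl$verdict,
               reasons = paste(cl$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intergenomic nucleotide similarity between two genomes
#'
#' Whole-genome similarity in the VIRIDIC spirit:
#' `100 * 2 * (identical bases summed over the best non-overlapping local
#' alignments) / (len_a + len_b)`, computed in both directions and
#' averaged (hence exactly symmetric). Alignments below `min_score` are
#' ignored, so unrelated genomes score 0.
#'
#' @param genome_a,genome_b Non-empty genome sequences.
#' @param word_size Seed word size; default 11.
#' @param min_score Minimum local alignment score retained; default 25
#'   (chance alignments between unrelated 10-kb genomes stay well below).
#' @param min_seeds Minimum word seeds supporting a diagonal cluster.
#' @param pad Diagonal band half-width.
#' @return Percent similarity in `[0, 100]`.
#' @export
intergenomic_similarity <- function(genome_a, genome_b, word_size = 11L,
                                    min_score = 25L, min_seeds = 2L,
                                    pad = 16L) {
  check_dna(genome_a, "genome_a", allow_n = TRUE)
  check_dna(genome_b, "genome_b", allow_n = TRUE)
  la <- nchar(genome_a); lb <- nchar(genome_b)
  one_dir <- function(q, s) {
    alns <- rbind(
      strand_alns(q, s, "+", word_size, min_score, min_seeds, pad),
      strand_alns(revcomp(q), s, "-", word_size, min_score, min_seeds, pad))
    if (is.null(alns) || nrow(alns) == 0) return(0)
    o <- order(-alns$score, alns$subject_start)
    alns <- alns[o, , drop = FALSE]
    ident <- 0
    subj <- matrix(numeric(0), ncol = 2)
    qry <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(alns))) {
      a <- alns[i, ]
      s_ok <- nrow(subj) == 0 ||
        all(a$subject_end <= subj[, 1] | a$subject_start >= subj[, 2])
      q_ok <- nrow(qry) == 0 ||
        all(a$query_end <= qry[, 1] | a$query_start >= qry[, 2])
      if (s_ok && q_ok) {
        ident <- ident + a$identities
        subj <- rbind(subj, c(a$subject_start, a$subject_end))
        qry <- rbind(qry, c(a$query_start, a$query_end))
      }
    }
    ident
  }
  id_ab <- one_dir(genome_a, genome_b)
  id_ba <- one_dir(genome_b, genome_a)
  sim <- 100 * (2 * id_ab / (la + lb) + 2 * id_ba / (la + lb)) / 2
  min(100, sim)
}

strand_alns <- function(q, s, strand, word_size, min_score, min_seeds, pad) {
  df <- seed_extend_filtered(q, s, word_size, min_score, min_seeds, pad)
  if (nrow(df) == 0) return(NULL)
  n <- nchar(q)
  qs <- df$query_start; qe <- df$query_end
  if (strand == "-") { tmp <- qs; qs <- n - qe; qe <- n - tmp }
  data.frame(subject_start = df$subject_start, subject_end = df$subject_end,
             query_start = qs, query_end = qe, score = df$score,
             identities = df$identities, stringsAsFactors = FALSE)
}

# Word-seeded search with a minimum seed-support filter: diagonal clusters
# backed by fewer than min_seeds exact words are not extended, which prunes
# chance diagonals between unrelated genomes.
seed_extend_filtered <- function(q, s, word_size, min_score, min_seeds, pad) {
  seed_extend_cpp(q, s, as.integer(word_size), 1L, -3L, 5L, 2L,
                  as.integer(pad), as.integer(min_score), as.integer(min_seeds))
}

#' Species and genus demarcation by single-linkage clustering
#'
#' Genomes are joined at a threshold when their intergenomic similarity
#' reaches it (single linkage). Species clusters (default 95%) always nest
#' within genus clusters (default 15.8%).
#'
#' @param similarity_matrix Square symmetric percent-similarity matrix
#'   with 100 on the diagonal.
#' @param species_threshold,genus_threshold Demarcation thresholds
#'   (percent similarity).
#' @return List: `species`, `genus` — named integer cluster memberships.
#' @export
demarcate <- function(similarity_matrix, species_threshold = 95.0,
                      genus_threshold = 15.8) {
  m <- as.matrix(similarity_matrix)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (max(abs(m - t(m))) > 1e-6) stop("similarity matrix must be symmetric")
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (nrow(m) == 1L)
    return(list(species = setNames(1L, ids), genus = setNames(1L, ids)))
  d <- as.dist(100 - m)
  h <- hclust(d, method = "single")
  species <- cutree(h, h = 100 - species_threshold)
  genus <- cutree(h, h = 100 - genus_threshold)
  names(species) <- names(genus) <- ids
  list(species = species, genus = genus)
}
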