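#' Pairwise identity between two spacer sequences
#'
#' Identity is the number of matched bases in the best global alignment
#' (gaps and end-gaps free for the purpose of counting, i.e. the longest
#' common subsequence) divided by the length of the shorter sequence —
#' cd-hit's convention. A sequence contained in another therefore scores
#' 1.0; two 40-mers differing at one position score 0.975.
#'
#' @param a,b Non-empty DNA sequences.
#' @return Fraction in `[0, 1]`; symmetric.
#' @export
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty strings")
  lcs_length_cpp(a, b) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of spacer occurrences
#'
#' Unique sequences are sorted by length descending (ties lexicographic)
#' and clustered greedily: each sequence joins the first existing cluster
#' whose representative reaches the identity threshold, else founds a new
#' cluster. The founder is the representative (the longest member, ties
#' lexicographically smallest). Per-sample member counts accumulate the
#' occurrence multiplicities of all member sequences. Clustering is
#' order-independent because of the sort.
#'
#' @param records Spacer occurrence table from [extract_spacers()]
#'   (columns `spacer_seq`, `sample_id`).
#' @param threshold Identity threshold in `(0, 1]`; default 0.99.
#' @return A `spacer_clusters` object: `$clusters` (cluster_id,
#'   representative, length, one count column per sample, total_count,
#'   distinct_members, is_singleton), `$members` (sequence -> cluster_id),
#'   `$samples`, `$threshold`.
#' @export
cluster_spacers <- function(records, threshold = 0.99) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  if (nrow(records) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = character(),
                            representative = character(), length = integer(),
                            total_count = integer(), distinct_members = integer(),
                            is_singleton = logical(), stringsAsFactors = FALSE),
      members = data.frame(sequence = character(), cluster_id = character(),
                           stringsAsFactors = FALSE),
      samples = character(), threshold = threshold),
      class = "spacer_clusters"))
  }
  occ <- table(records$spacer_seq, records$sample_id)
  uniq <- rownames(occ)
  ord <- order(-nchar(uniq), uniq, method = "radix")
  srt <- uniq[ord]
  cl <- greedy_cluster_cpp(srt, threshold)
  ncl <- max(cl)
  rep_seq <- srt[match(seq_len(ncl), cl)]
  counts <- rowsum(matrix(occ[srt, , drop = FALSE], nrow = length(srt),
                          dimnames = list(srt, colnames(occ))), cl)
  samples <- colnames(occ)
  colnames(counts) <- samples
  total <- rowSums(counts)
  distinct <- as.vector(table(factor(cl, levels = seq_len(ncl))))
  clusters <- data.frame(cluster_id = sprintf("SC%04d", seq_len(ncl)),
                         representative = rep_seq, length = nchar(rep_seq),
                         stringsAsFactors = FALSE)
  clusters <- cbind(clusters, as.data.frame(counts, optional = TRUE))
  clusters$total_count <- as.integer(total)
  clusters$distinct_members <- distinct
  clusters$is_singleton <- total == 1L
  rownames(clusters) <- NULL
  members <- data.frame(sequence = srt,
                        cluster_id = clusters$cluster_id[cl],
                        stringsAsFactors = FALSE)
  structure(list(clusters = clusters, members = members,
                 samples = samples, threshold = threshold),
            class = "spacer_clusters")
}

#' @export
print.spacer_clusters <- function(x, ...) {
  cat(sprintf("spacer_clusters: %d clusters (%d singletons) over %d sample(s) at %.2f identity\n",
              nrow(x$clusters), sum(x$clusters$is_singleton),
              length(x$samples), x$threshold))
  invisible(x)
}

#' Overlap between two cluster repertoires
#'
#' Greedy best-first matching of representatives by pairwise identity; a
#' cluster pair is shared when the representatives reach the threshold,
#' and each cluster is used at most once.
#'
#' @param clusters_a,clusters_b `spacer_clusters` objects or character
#'   vectors of representatives.
#' @param threshold Identity threshold; default 0.99.
#' @return List: `shared`, `only_a`, `only_b`, and the matched `pairs`.
#' @export
cluster_overlap <- function(clusters_a, clusters_b, threshold = 0.99) {
  ra <- cluster_reps(clusters_a)
  rb <- cluster_reps(clusters_b)
  if (length(ra) == 0 || length(rb) == 0) {
    return(list(shared = 0L, only_a = length(ra), only_b = length(rb),
                pairs = data.frame(a = character(), b = character(),
                                   identity = numeric())))
  }
  M <- identity_matrix_cpp(unname(ra), unname(rb))
  hits <- which(M + 1e-12 >= threshold, arr.ind = TRUE)
  if (nrow(hits)) {
    o <- order(-M[hits], hits[, 1], hits[, 2])
    hits <- hits[o, , drop = FALSE]
  }
  used_a <- logical(length(ra)); used_b <- logical(length(rb))
  pa <- integer(); pb <- integer()
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]; j <- hits[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pa <- c(pa, i); pb <- c(pb, j)
    }
  }
  list(shared = length(pa), only_a = sum(!used_a), only_b = sum(!used_b),
       pairs = data.frame(a = names(ra)[pa] %||% as.character(pa),
                          b = names(rb)[pb] %||% as.character(pb),
                          identity = M[cbind(pa, pb)]))
}

cluster_reps <- function(x) {
  if (inherits(x, "spacer_clusters"))
    return(setNames(x$clusters$representative, x$clusters$cluster_id))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("C%04d", seq_along(x))
    return(x)
  }
  stop("expected a spacer_clusters object or a character vector")
}

#' Write cluster table and representative FASTA
#'
#' @param clusters A `spacer_clusters` object.
#' @param tsv,fasta Output paths (either may be `NULL`).
#' @export
write_clusters <- function(clusters, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) write_tsv(clusters$clusters, tsv)
  if (!is.null(fasta))
    write_fasta(setNames(clusters$clusters$representative,
                         clusters$clusters$cluster_id), fasta)
  invisible(clusters)
}
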