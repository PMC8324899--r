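#' Find exact direct-repeat occurrences in a read
#'
#' Reports every exact, complete occurrence of the DR and of its reverse
#' complement in the read, as 0-based half-open intervals sorted by start.
#' `N` bases in the read never match (strict exactness); overlapping
#' occurrences are all reported.
#'
#' @param read_sequence Read sequence, uppercase ACGT with N allowed.
#' @param dr Direct-repeat sequence, uppercase ACGT.
#' @return data.frame with columns `start`, `end`, `strand`.
#' @export
find_dr_occurrences <- function(read_sequence, dr) {
  check_dna(read_sequence, "read", allow_n = TRUE)
  check_dna(dr, "dr")
  s <- Biostrings::DNAString(read_sequence)
  f <- Biostrings::matchPattern(dr, s, fixed = TRUE)
  r <- Biostrings::matchPattern(revcomp(dr), s, fixed = TRUE)
  out <- data.frame(
    start = c(IRanges::start(f), IRanges::start(r)) - 1L,
    end = c(IRanges::end(f), IRanges::end(r)),
    strand = rep(c("+", "-"), c(length(f), length(r))),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract CRISPR spacers from reads anchored on exact DR matches
#'
#' For each read, occurrences of the DR (and of its reverse complement)
#' are located exactly; the strand with more occurrences wins (ties go to
#' the forward strand). The sequence between each pair of consecutive
#' same-strand occurrences is emitted as one spacer; segments bounded by
#' only one DR (read-terminal fragments) are discarded unless
#' `allow_partial`. Spacers outside `[min_len, max_len]` nt are dropped.
#' Reverse-strand spacers are reverse complemented into DR-forward
#' (canonical) orientation so that clustering merges spacers observed on
#' either strand.
#'
#' @param reads Reads: FASTQ/FASTA path, data.frame (`id`, `sequence`),
#'   named character vector or `DNAStringSet`.
#' @param dr Direct-repeat consensus (uppercase ACGT). Run once per DR
#'   variant; results are kept separate per `dr_label`.
#' @param min_len,max_len Spacer length filter (nt); defaults 20 and 60.
#' @param sample_id Sample identifier recorded on every row.
#' @param dr_label Label of the DR variant.
#' @param allow_partial Also emit read-terminal fragments bounded by a
#'   single DR (off by default: both flanks must be complete DR copies).
#' @return data.frame: `sample_id`, `read_id`, `dr_label`,
#'   `dr_orientation`, `spacer_seq`, `length`.
#' @export
extract_spacers <- function(reads, dr, min_len = 20L, max_len = 60L,
                            sample_id = "sample", dr_label = "DR1",
                            allow_partial = FALSE) {
  check_dna(dr, "dr")
  tbl <- as_read_table(reads)
  empty <- data.frame(sample_id = character(), read_id = character(),
                      dr_label = character(), dr_orientation = character(),
                      spacer_seq = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tbl) == 0) return(empty)

  subj <- Biostrings::DNAStringSet(tbl$sequence)
  fh <- Biostrings::vmatchPattern(dr, subj, fixed = TRUE)
  rh <- Biostrings::vmatchPattern(revcomp(dr), subj, fixed = TRUE)
  nf <- S4Vectors::elementNROWS(fh)
  nr <- S4Vectors::elementNROWS(rh)
  use_rev <- nr > nf
  nwin <- ifelse(use_rev, nr, nf)
  need <- if (allow_partial) 1L else 2L
  cand <- which(nwin >= need)
  if (!length(cand)) return(empty)

  rows <- vector("list", length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    m <- if (use_rev[i]) rh[[i]] else fh[[i]]
    st <- IRanges::start(m)
    en <- IRanges::end(m)
    o <- order(st)
    st <- st[o]; en <- en[o]
    seg_start <- en[-length(en)] + 1L
    seg_end <- st[-1] - 1L
    if (allow_partial) {
      seg_start <- c(1L, seg_start)
      seg_end <- c(st[1] - 1L, seg_end)
      seg_start <- c(seg_start, en[length(en)] + 1L)
      seg_end <- c(seg_end, nchar(tbl$sequence[i]))
    }
    len <- seg_end - seg_start + 1L
    keep <- len >= min_len & len <= max_len
    if (!any(keep)) next
    sp <- substring(tbl$sequence[i], seg_start[keep], seg_end[keep])
    if (use_rev[i]) sp <- revcomp(sp)
    rows[[ci]] <- data.frame(
      sample_id = sample_id, read_id = tbl$id[i], dr_label = dr_label,
      dr_orientation = if (use_rev[i]) "reverse-complement" else "forward",
      spacer_seq = sp, length = len[keep], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
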