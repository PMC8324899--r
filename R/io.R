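#' Read a FASTA file into a named character vector
#'
#' Identifiers are taken verbatim up to the first whitespace. Gzipped input
#' is read transparently.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ file into a read table
#'
#' @param path Path to a FASTQ file (gzip transparent).
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  data.frame(id = sub("\\s.*$", "", names(x)), sequence = unname(as.character(x)),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a read table to FASTQ (Phred+33, constant qualities)
#'
#' @param reads A read table as produced by [simulate_reads()] (columns `id`,
#'   `sequence`, optionally `source`, `start0`, `strand`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  hdr <- paste0("@", reads$id)
  if (all(c("source", "start0", "strand") %in% names(reads)))
    hdr <- paste0(hdr, " source=", reads$source, " pos=", reads$start0,
                  " strand=", reads$strand)
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(as.vector(rbind(hdr, reads$sequence, "+", qual)), path)
  invisible(path)
}

#' Write/read a tab-separated table
#'
#' Plain TSV with a header row, no quoting, no row names.
#'
#' @param df A data.frame.
#' @param path File path.
#' @return The path (write) or a data.frame (read).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Accept reads as a file path, data.frame(id, sequence), named character
# vector, or DNAStringSet; return a data.frame(id, sequence).
as_read_table <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", reads)) {
      x <- read_fasta(reads)
      return(data.frame(id = names(x), sequence = unname(x),
                        stringsAsFactors = FALSE))
    }
    return(read_fastq(reads))
  }
  if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    return(data.frame(id = sub("\\s.*$", "", ids),
                      sequence = unname(as.character(reads)),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "sequence") %in% names(reads)))
    return(reads[, c("id", "sequence")])
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    return(data.frame(id = ids, sequence = unname(reads),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret 'reads'; give a path, data.frame, ",
       "named character vector or DNAStringSet", call. = FALSE)
}

# Accept references/scaffolds as a FASTA path or named character vector.
as_sequence_set <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fasta(x)
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named character vector or a FASTA path",
         call. = FALSE)
  x
}
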