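`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' @param lengths Integer vector of sequence lengths.
#' @return Character vector of uppercase ACGT sequences, one per length.
#' @keywords internal
random_dna <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) return(character())
  chars <- sample(DNA_BASES, sum(lengths), replace = TRUE)
  if (length(lengths) == 1L) return(paste(chars, collapse = ""))
  f <- factor(rep.int(seq_along(lengths), lengths), levels = seq_along(lengths))
  unname(vapply(split(chars, f), paste, character(1), collapse = ""))
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Derive a stream-specific RNG seed from the master seed; stays within the
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483629)
}

check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (length(x) != 1L || is.na(x) || !nzchar(x) || !grepl(pat, x))
    stop(what, " must be a non-empty uppercase ",
         if (allow_n) "ACGTN" else "ACGT", " string", call. = FALSE)
  invisible(x)
}

# Uniform integer draw from [lo, hi]; safe when lo == hi (base sample()
# would interpret a scalar as 1:x).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]", call. = FALSE)
  invisible(x)
}
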