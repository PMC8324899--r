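# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: brute-force scans, regex splitting, Biostrings
# dynamic programming.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# Position-by-position exact scan for DR occurrences on both strands.
brute_dr_scan <- function(read, dr) {
  L <- nchar(read); w <- nchar(dr)
  drr <- revcomp_chr(dr)
  out <- data.frame(start = integer(), end = integer(), strand = character())
  if (L < w) return(out)
  for (p in seq_len(L - w + 1)) {
    seg <- substr(read, p, p + w - 1)
    if (seg == dr)
      out <- rbind(out, data.frame(start = p - 1L, end = p + w - 1L,
                                   strand = "+"))
    if (seg == drr)
      out <- rbind(out, data.frame(start = p - 1L, end = p + w - 1L,
                                   strand = "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Regex-based spacer splitter: same strand rule (majority, ties forward),
# internal segments between consecutive same-strand DR copies, length
# filter, canonical DR-forward orientation.
brute_extract <- function(read, dr, min_len = 20, max_len = 60) {
  f <- gregexpr(dr, read, fixed = TRUE)[[1]]
  r <- gregexpr(revcomp_chr(dr), read, fixed = TRUE)[[1]]
  nf <- if (f[1] == -1) 0L else length(f)
  nr <- if (r[1] == -1) 0L else length(r)
  use_rev <- nr > nf
  occ <- if (use_rev) r else f
  n <- if (use_rev) nr else nf
  if (n < 2) return(character())
  occ <- sort(as.integer(occ))
  w <- nchar(dr)
  sp <- character()
  for (k in seq_len(n - 1)) {
    s0 <- occ[k] + w
    e0 <- occ[k + 1] - 1
    len <- e0 - s0 + 1
    if (len >= min_len && len <= max_len) {
      seg <- substr(read, s0, e0)
      if (use_rev) seg <- revcomp_chr(seg)
      sp <- c(sp, seg)
    }
  }
  sp
}

nsm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                baseOnly = TRUE)

# Full Smith-Waterman oracle (Biostrings), both strands; blastn-short
# scoring. Returns the strand-best score and the alignment detail of the
# best strand.
sw_oracle <- function(q, s) {
  a1 <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                      substitutionMatrix = nsm,
                                      gapOpening = 5, gapExtension = 2)
  a2 <- Biostrings::pairwiseAlignment(revcomp_chr(q), s, type = "local",
                                      substitutionMatrix = nsm,
                                      gapOpening = 5, gapExtension = 2)
  best <- if (Biostrings::score(a1) >= Biostrings::score(a2)) a1 else a2
  list(score = max(Biostrings::score(a1), Biostrings::score(a2)),
       identities = Biostrings::nmatch(best),
       subject_start = BiocGenerics::start(Biostrings::subject(best)) - 1L,
       subject_end = BiocGenerics::end(Biostrings::subject(best)),
       strand = if (Biostrings::score(a1) >= Biostrings::score(a2)) "+" else "-")
}

# Max-matches (LCS) identity oracle: global alignment with match 1,
# mismatch 0, free gaps maximizes the number of matched bases.
lcs_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                    baseOnly = TRUE)
identity_oracle <- function(a, b) {
  sc <- Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = lcs_mat,
    gapOpening = 0, gapExtension = 0))
  sc / min(nchar(a), nchar(b))
}

# Independent greedy clustering: same semantics, Biostrings-scored
# identities, vectorized against current representatives.
greedy_cluster_oracle <- function(seqs, threshold = 0.99) {
  ord <- order(-nchar(seqs), seqs, method = "radix")
  srt <- seqs[ord]
  reps <- character()
  assign <- integer(length(srt))
  for (i in seq_along(srt)) {
    hit <- 0L
    if (length(reps)) {
      sc <- Biostrings::score(Biostrings::pairwiseAlignment(
        rep(srt[i], length(reps)), reps, type = "global",
        substitutionMatrix = lcs_mat, gapOpening = 0, gapExtension = 0))
      ident <- sc / pmin(nchar(srt[i]), nchar(reps))
      ok <- which(ident + 1e-12 >= threshold)
      if (length(ok)) hit <- ok[1]
    }
    if (hit == 0L) { reps <- c(reps, srt[i]); hit <- length(reps) }
    assign[i] <- hit
  }
  split(srt, assign)
}

# Plant a mutated copy of `q` into a random subject of length `slen` at
# `mm_pos` (1-based positions within q); returns the subject and locus.
plant_query <- function(q, slen, mm_pos = integer(), strand = "+") {
  subj <- rand_dna(slen)
  qq <- strsplit(q, "", fixed = TRUE)[[1]]
  for (p in mm_pos) qq[p] <- sample(setdiff(c("A", "C", "G", "T"), qq[p]), 1)
  ins <- paste(qq, collapse = "")
  if (strand == "-") ins <- revcomp_chr(ins)
  pos <- sample.int(slen - nchar(q) + 1, 1)
  substr(subj, pos, pos + nchar(q) - 1) <- ins
  list(subject = subj, start0 = pos - 1L, end0 = pos + nchar(q) - 1L)
}

# Shared default simulation for the heavier end-to-end checks (generated
# once per test run).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- community_config(seed = 101, timepoints = list(timepoint("t1")))
      cache <<- simulate_timeseries(cfg)
    }
    cache
  }
})

sim_scaffolds <- function(sim) {
  com <- sim$community
  reps <- c(list(com$host), com$viruses, com$backgrounds)
  setNames(vapply(reps, assembly_sequence, character(1)),
           vapply(reps, `[[`, character(1), "id"))
}
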