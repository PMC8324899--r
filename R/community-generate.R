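#' Generate the host genome with its CRISPR locus
#'
#' The genome is random DNA flanking a single CRISPR array of the form
#' `DR (spacer DR) x n_host_spacers`; spacers are i.i.d. random DNA with
#' lengths drawn from `spacer_len_range`. Fully determined by the config
#' seed.
#'
#' @param config A [community_config()].
#' @return A list with `id`, `sequence`, `circular`, `locus` (0-based
#'   half-open array coordinates), `dr` and a `spacers` data.frame
#'   (`id`, `sequence`, `source`).
#' @export
generate_host <- function(config) {
  check_dna(config$dr_sequence, "dr_sequence")
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_host_spacers
  lens <- if (n > 0)
    sample_range(config$spacer_len_range[1], config$spacer_len_range[2], n)
  else integer()
  sp <- random_dna(lens)
  spacers <- data.frame(id = sprintf("sp%03d", seq_len(n)),
                        sequence = sp, source = rep("initial", n),
                        stringsAsFactors = FALSE)
  arr <- crispr_array(config$dr_sequence, sp)
  f1 <- config$host_genome_length %/% 2L
  f2 <- config$host_genome_length - f1
  flank1 <- random_dna(f1)
  flank2 <- random_dna(f2)
  list(id = "host",
       sequence = paste0(flank1, arr, flank2),
       circular = FALSE,
       locus = c(start = f1, end = f1 + nchar(arr)),
       dr = config$dr_sequence,
       flanks = c(flank1, flank2),
       spacers = spacers)
}

crispr_array <- function(dr, spacers) {
  paste0(dr, paste(vapply(spacers, function(s) paste0(s, dr), character(1)),
                   collapse = ""))
}

# Rebuild the host genome around an updated spacer repertoire; flanks stay
# fixed so only the array region changes between timepoints.
rebuild_host <- function(host, spacers) {
  arr <- crispr_array(host$dr, spacers$sequence)
  host$sequence <- paste0(host$flanks[1], arr, host$flanks[2])
  host$locus <- c(start = nchar(host$flanks[1]),
                  end = nchar(host$flanks[1]) + nchar(arr))
  host$spacers <- spacers
  host
}

#' Generate viral genomes carrying planted protospacers
#'
#' Each virus embeds `protospacers_per_virus` copies of randomly chosen
#' host spacers, independently mutated at `protospacer_mutation_rate`, on a
#' random strand at non-overlapping positions. A `circular_fraction` subset
#' is flagged circular; circular genomes are emitted in assembly
#' convention, i.e. with their first `terminal_repeat` bases duplicated at
#' the end (see [assembly_sequence()]).
#'
#' @param config A [community_config()].
#' @param host Output of [generate_host()].
#' @return A list with `viruses` (list of replicons) and `protospacers`
#'   (data.frame: virus_id, spacer_id, start0, end0 on the core sequence,
#'   strand, n_mutations).
#' @export
generate_viruses <- function(config, host) {
  set.seed(derive_seed(config$seed, 2L))
  nv <- config$n_viruses
  pp <- config$protospacers_per_virus
  if (pp > 0 && nrow(host$spacers) == 0)
    stop("host has no spacers but protospacers_per_virus > 0")
  circ <- rep(FALSE, nv)
  n_circ <- round(config$circular_fraction * nv)
  if (n_circ > 0) circ[sample(nv, n_circ)] <- TRUE

  viruses <- vector("list", nv)
  proto <- list()
  for (v in seq_len(nv)) {
    L <- sample_range(config$virus_len_range[1], config$virus_len_range[2])
    core <- random_dna(L)
    k <- if (circ[v]) config$terminal_repeat else 0L
    taken <- matrix(numeric(0), ncol = 2)
    if (pp > 0) {
      picks <- sample(nrow(host$spacers), pp, replace = pp > nrow(host$spacers))
      for (j in seq_len(pp)) {
        src <- host$spacers[picks[j], ]
        mut <- mutate_seq(src$sequence, config$protospacer_mutation_rate)
        ins <- mut$sequence
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") ins <- revcomp(ins)
        w <- nchar(ins)
        lo <- k + 1L
        hi <- L - w + 1L
        if (hi < lo) stop("virus_", v, " (", L, " bp) too short to host ",
                          pp, " protospacers")
        ok <- FALSE
        for (try in 1:1000) {
          s0 <- sample_range(lo, hi)
          if (nrow(taken) == 0 ||
              all(s0 + w - 1 < taken[, 1] | s0 > taken[, 2])) { ok <- TRUE; break }
        }
        if (!ok) stop("virus_", v, " too short/crowded to place protospacers")
        substr(core, s0, s0 + w - 1L) <- ins
        taken <- rbind(taken, c(s0, s0 + w - 1L))
        proto[[length(proto) + 1L]] <-
          data.frame(virus_id = sprintf("virus_%d", v),
                     spacer_id = src$id, start0 = s0 - 1L, end0 = s0 + w - 1L,
                     strand = strand, n_mutations = mut$n_mutations,
                     stringsAsFactors = FALSE)
      }
    }
    viruses[[v]] <- list(id = sprintf("virus_%d", v), sequence = core,
                         circular = circ[v], terminal_repeat = k)
  }
  list(viruses = viruses,
       protospacers = if (length(proto)) do.call(rbind, proto) else
         data.frame(virus_id = character(), spacer_id = character(),
                    start0 = integer(), end0 = integer(), strand = character(),
                    n_mutations = integer(), stringsAsFactors = FALSE))
}

# Independent per-base substitutions; returns the mutated sequence and the
# realized substitution count.
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    seq <- paste(ch, collapse = "")
  }
  list(sequence = seq, n_mutations = length(hit))
}

#' Generate background genomes
#'
#' Random genomes with no CRISPR array and no planted protospacers; the
#' negative controls of the linkage analysis.
#'
#' @param config A [community_config()].
#' @return List of replicons.
#' @export
generate_background <- function(config) {
  set.seed(derive_seed(config$seed, 3L))
  lapply(seq_len(config$n_background_genomes), function(b) {
    L <- sample_range(config$background_len_range[1],
                      config$background_len_range[2])
    list(id = sprintf("bg_%d", b), sequence = random_dna(L),
         circular = FALSE, terminal_repeat = 0L)
  })
}

#' Emit a replicon in assembly convention
#'
#' Circular replicons are emitted as their linear core with the first
#' `terminal_repeat` bases duplicated at the end — the standard assembler
#' signature of a circular (complete) genome. Linear replicons are emitted
#' unchanged.
#'
#' @param replicon A replicon list (`sequence`, `circular`,
#'   `terminal_repeat`).
#' @return Character scalar.
#' @export
assembly_sequence <- function(replicon) {
  if (isTRUE(replicon$circular) && replicon$terminal_repeat > 0)
    paste0(replicon$sequence, substr(replicon$sequence, 1L,
                                     replicon$terminal_repeat))
  else replicon$sequence
}

# Deterministic synthetic gene-annotation table mirroring the external
# evidence the classifier consumes: circular viruses carry hallmark genes
# and VOG hits; background genomes carry bacterial hits.
synthetic_annotations <- function(viruses, backgrounds) {
  rows <- list()
  add <- function(scaffold, n, hallmark, vog, bact, tag) {
    if (n == 0) return()
    rows[[length(rows) + 1L]] <<-
      data.frame(gene_id = sprintf("%s_%s%02d", scaffold, tag, seq_len(n)),
                 scaffold_id = scaffold, is_hallmark = hallmark,
                 is_vog_hit = vog, is_bacterial = bact,
                 stringsAsFactors = FALSE)
  }
  for (v in viruses) {
    if (isTRUE(v$circular)) {
      add(v$id, 2L, TRUE, TRUE, FALSE, "hallmark")
      add(v$id, 3L, FALSE, TRUE, FALSE, "vog")
    }
  }
  for (b in backgrounds) add(b$id, 4L, FALSE, FALSE, TRUE, "bact")
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), scaffold_id = character(),
               is_hallmark = logical(), is_vog_hit = logical(),
               is_bacterial = logical(), stringsAsFactors = FALSE)
}

#' Generate the full synthetic community
#'
#' @param config A [community_config()].
#' @return A `synthetic_community` list: `config`, `host`, `viruses`,
#'   `backgrounds`, `annotations`, `protospacers`.
#' @export
generate_community <- function(config) {
  host <- generate_host(config)
  vir <- generate_viruses(config, host)
  bg <- generate_background(config)
  structure(list(config = config, host = host, viruses = vir$viruses,
                 backgrounds = bg,
                 annotations = synthetic_annotations(vir$viruses, bg),
                 protospacers = vir$protospacers),
            class = "synthetic_community")
}
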