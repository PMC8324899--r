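#' Simulate shotgun reads from a set of replicons
#'
#' Reads are drawn from replicons proportionally to `weight x length`, with
#' uniform random start positions (circular replicons wrap across the
#' origin), uniformly random strand, and independent per-base substitution
#' errors. Quality strings are constant. The seed fully determines the
#' output; exactly `n_reads` reads are emitted.
#'
#' @param replicons List of replicon lists (`id`, `sequence`, `circular`)
#'   or a named character vector (all linear).
#' @param weights Named non-negative weights, one per replicon; not all
#'   zero.
#' @param n_reads Number of reads.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @return A data.frame: `id`, `sequence`, `source`, `start0`, `strand`,
#'   with per-replicon read counts in `attr(, "read_counts")`.
#' @export
simulate_reads <- function(replicons, weights, n_reads, read_length,
                           error_rate, seed) {
  reps <- as_replicon_list(replicons)
  ids <- vapply(reps, `[[`, character(1), "id")
  if (is.null(names(weights)) || !all(ids %in% names(weights)))
    stop("weights must be named and cover every replicon")
  w <- as.numeric(weights[ids])
  if (any(w < 0) || all(w == 0)) stop("weights must be non-negative, not all zero")
  check_fraction(error_rate, "error_rate")

  lens <- vapply(reps, function(r) nchar(r$sequence), integer(1))
  circ <- vapply(reps, function(r) isTRUE(r$circular), logical(1))
  usable <- circ | lens >= read_length
  if (any(!usable & w > 0))
    warning("replicon(s) shorter than the read length contribute no reads: ",
            paste(ids[!usable & w > 0], collapse = ", "))
  eff <- w * lens
  eff[!usable] <- 0
  if (all(eff == 0)) stop("no replicon can produce reads")

  set.seed(seed)
  counts <- as.vector(rmultinom(1, n_reads, eff))
  names(counts) <- ids

  pieces <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    cnt <- counts[i]
    if (cnt == 0) next
    s <- reps[[i]]$sequence
    L <- lens[i]
    if (circ[i]) {
      src <- paste0(s, substr(s, 1L, read_length - 1L))
      starts <- sample.int(L, cnt, replace = TRUE)
    } else {
      starts <- sample.int(L - read_length + 1L, cnt, replace = TRUE)
      src <- s
    }
    strands <- sample(c("+", "-"), cnt, replace = TRUE)
    seqs <- substring(src, starts, starts + read_length - 1L)
    neg <- strands == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    n_err <- rbinom(cnt, read_length, error_rate)
    for (j in which(n_err > 0)) {
      pos <- sample.int(read_length, n_err[j])
      ch <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      seqs[j] <- paste(ch, collapse = "")
    }
    pieces[[i]] <- data.frame(sequence = seqs, source = ids[i],
                              start0 = starts - 1L, strand = strands,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  out <- cbind(id = sprintf("read%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  attr(out, "read_counts") <- counts
  out
}

as_replicon_list <- function(replicons) {
  if (is.character(replicons)) {
    if (is.null(names(replicons))) stop("replicons must be named")
    return(lapply(names(replicons), function(id)
      list(id = id, sequence = unname(replicons[[id]]), circular = FALSE)))
  }
  if (is.list(replicons) && !is.null(replicons$id))  # a single replicon
    return(list(replicons))
  replicons
}

#' Simulate a multi-timepoint community with spacer turnover
#'
#' Generates the community once, then for each timepoint evolves the host
#' CRISPR array (random deletions among existing spacers, then acquisition
#' of new spacers at the leader end — copied from co-occurring viral
#' genomes by default), applies the abundance-weight overrides, and
#' simulates a read set. The ground truth records the per-timepoint spacer
#' repertoire, weights, realized read counts and expected coverages
#' (`reads x read_length / replicon length`).
#'
#' @param config A [community_config()].
#' @return A `community_simulation`: `config`, `community`, and `samples`
#'   (named per sample: `reads`, `truth`, `host`).
#' @export
simulate_timeseries <- function(config) {
  if (length(config$timepoints) < 1L) stop("at least one timepoint required")
  com <- generate_community(config)
  w0 <- base_weights(config)
  virus_ids <- vapply(com$viruses, `[[`, character(1), "id")
  spacers <- com$host$spacers
  host_t <- com$host
  samples <- list()

  for (t in seq_along(config$timepoints)) {
    tp <- config$timepoints[[t]]
    set.seed(derive_seed(config$seed, 10L + t))
    if (tp$n_lost > 0) {
      if (tp$n_lost > nrow(spacers))
        stop("timepoint ", tp$sample_id, ": cannot delete ", tp$n_lost,
             " spacers from a repertoire of ", nrow(spacers))
      spacers <- spacers[-sample.int(nrow(spacers), tp$n_lost), , drop = FALSE]
    }
    if (tp$n_acquired > 0) {
      newsp <- acquire_spacers(config, com, tp$n_acquired, t)
      spacers <- rbind(newsp, spacers)
    }
    host_t <- rebuild_host(host_t, spacers)

    w <- w0
    if (length(virus_ids)) w[virus_ids] <- w[virus_ids] * tp$virus_weight_factor
    if (!is.null(tp$weights)) w[names(tp$weights)] <- tp$weights

    reps <- c(list(host_t), com$viruses, com$backgrounds)
    reads <- simulate_reads(reps, w, config$n_reads, config$read_length,
                            config$read_error_rate,
                            seed = derive_seed(config$seed, 100L + t))
    counts <- attr(reads, "read_counts")
    lens <- vapply(reps, function(r) nchar(r$sequence), integer(1))
    expected_cov <- counts * config$read_length / lens

    samples[[tp$sample_id]] <- list(
      reads = reads,
      host = host_t,
      truth = list(sample_id = tp$sample_id,
                   spacers = spacers,
                   weights = w,
                   read_counts = counts,
                   expected_coverage = expected_cov))
  }
  structure(list(config = config, community = com, samples = samples),
            class = "community_simulation")
}

# New spacers are protospacer-derived by default: copied exactly from a
# random locus of a random co-occurring virus (random strand), so the host
# gains immunity against it; lengths are drawn from spacer_len_range.
acquire_spacers <- function(config, com, n, t) {
  lens <- sample_range(config$spacer_len_range[1], config$spacer_len_range[2], n)
  seqs <- character(n)
  src <- character(n)
  from_virus <- config$acquisition_source == "virus" && length(com$viruses) > 0
  for (i in seq_len(n)) {
    if (from_virus) {
      v <- com$viruses[[sample.int(length(com$viruses), 1L)]]
      p <- sample.int(nchar(v$sequence) - lens[i] + 1L, 1L)
      s <- substr(v$sequence, p, p + lens[i] - 1L)
      if (sample(c(TRUE, FALSE), 1L)) s <- revcomp(s)
      seqs[i] <- s
      src[i] <- v$id
    } else {
      seqs[i] <- random_dna(lens[i])
      src[i] <- "random"
    }
  }
  data.frame(id = sprintf("acq_t%d_%02d", t, seq_len(n)),
             sequence = seqs, source = src, stringsAsFactors = FALSE)
}

#' Simulate a community and optionally write it to disk
#'
#' Writes `genomes.fasta` (assembly convention: circular genomes carry a
#' duplicated terminal repeat), one `<sample_id>.reads.fastq` and
#' `<sample_id>.truth.json` per timepoint, and a `config.yaml` echo.
#'
#' @param config A [community_config()].
#' @param out_dir Output directory (`NULL` keeps everything in memory).
#' @return The `community_simulation`, invisibly when writing.
#' @export
simulate_community <- function(config, out_dir = NULL) {
  sim <- simulate_timeseries(config)
  if (is.null(out_dir)) return(sim)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  com <- sim$community
  reps <- c(list(com$host), com$viruses, com$backgrounds)
  seqs <- vapply(reps, assembly_sequence, character(1))
  names(seqs) <- vapply(reps, `[[`, character(1), "id")
  write_fasta(seqs, file.path(out_dir, "genomes.fasta"))
  if (nrow(com$annotations))
    write_tsv(com$annotations, file.path(out_dir, "annotations.tsv"))
  for (sid in names(sim$samples)) {
    s <- sim$samples[[sid]]
    write_fastq(s$reads, file.path(out_dir, paste0(sid, ".reads.fastq")))
    jsonlite::write_json(
      c(s$truth["sample_id"],
        list(spacers = s$truth$spacers,
             weights = as.list(s$truth$weights),
             read_counts = as.list(s$truth$read_counts),
             expected_coverage = as.list(s$truth$expected_coverage),
             protospacers = com$protospacers)),
      file.path(out_dir, paste0(sid, ".truth.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  cfg <- sim$config
  cfg$timepoints <- lapply(cfg$timepoints, unclass)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(sim)
}
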