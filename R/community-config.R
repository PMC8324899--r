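# Default direct repeat: 30 nt, conserved, with the AAA(N) motif typical of
# archaeal CRISPR repeats.
DEFAULT_DR <- "GTTTCAGACGAACCCTTGTGGGATTGAAAC"

#' Describe one timepoint of a simulated timeseries
#'
#' A timepoint carries the per-sample overrides of the community state:
#' replicon abundance weights, a multiplicative factor applied to all viral
#' weights, and the number of spacers the host acquires (at the leader end
#' of the array) or loses before the sample is sequenced.
#'
#' @param sample_id Sample identifier; defaults to `t<k>` by position.
#' @param weights Named numeric vector of absolute abundance-weight
#'   overrides (partial; unnamed replicons keep their base weight).
#' @param virus_weight_factor Scalar multiplier applied to every viral
#'   weight, relative to the base weights.
#' @param n_acquired Number of new spacers acquired at the array start.
#' @param n_lost Number of existing spacers deleted at random.
#' @return A `timepoint` list.
#' @export
timepoint <- function(sample_id = NULL, weights = NULL,
                      virus_weight_factor = 1, n_acquired = 0L, n_lost = 0L) {
  stopifnot(is.null(weights) || (is.numeric(weights) && !is.null(names(weights))),
            virus_weight_factor >= 0, n_acquired >= 0, n_lost >= 0)
  structure(list(sample_id = sample_id, weights = weights,
                 virus_weight_factor = virus_weight_factor,
                 n_acquired = as.integer(n_acquired),
                 n_lost = as.integer(n_lost)),
            class = "timepoint")
}

#' Configuration of the synthetic subsurface community
#'
#' Defines the study conditions of the simulated ecosystem: one dominant
#' host genome carrying a CRISPR array with a conserved direct repeat (DR)
#' and variable spacers, co-occurring viral genomes bearing protospacers
#' derived from host spacers with point mutations (a subset circular,
#' emitted in assembly convention with a duplicated terminal repeat),
#' minority background genomes, shotgun reads with uniform substitution
#' errors, and timepoints with shifting virus abundance and spacer
#' turnover. The seed fully determines every emitted byte.
#'
#' @param seed Master RNG seed (integer).
#' @param dr_sequence Direct-repeat consensus, uppercase ACGT.
#' @param n_host_spacers Number of spacers in the initial host array.
#' @param spacer_len_range Spacer length range (nt); default 30-45 so that
#'   planted spacers survive the 20-60 nt extraction filter.
#' @param host_genome_length Host flanking-genome length (bp) excluding the
#'   CRISPR array itself.
#' @param n_viruses Number of viral genomes.
#' @param virus_len_range Virus genome length range (bp).
#' @param circular_fraction Fraction of viruses that are circular.
#' @param terminal_repeat Length (bp) of the duplicated terminal repeat
#'   used to emit circular genomes in assembly convention.
#' @param protospacers_per_virus Protospacers planted per virus, each
#'   copied from a random host spacer.
#' @param protospacer_mutation_rate Per-base substitution probability
#'   applied independently to each planted protospacer.
#' @param n_background_genomes Number of background (non-targeted) genomes.
#' @param background_len_range Background genome length range (bp).
#' @param read_length Read length (bp), single-end.
#' @param read_error_rate Per-base substitution error rate of reads.
#' @param n_reads Reads per sample.
#' @param per_sample_abundance Named numeric base abundance weights per
#'   replicon (`host`, `virus_1`..., `bg_1`...). `NULL` uses the default
#'   dominant-host profile (host 60; viruses 15, 10, 5 recycled;
#'   backgrounds 5).
#' @param acquisition_source Where newly acquired spacers come from:
#'   `"virus"` (copied from a co-occurring viral genome, the canonical
#'   adaptation route) or `"random"`.
#' @param timepoints List of [timepoint()] objects; `NULL` gives two
#'   timepoints (baseline, then viral weights halved with 3 spacers
#'   acquired and 1 lost).
#' @return A validated `community_config` list.
#' @export
community_config <- function(seed = 1L,
                             dr_sequence = DEFAULT_DR,
                             n_host_spacers = 25L,
                             spacer_len_range = c(30L, 45L),
                             host_genome_length = 40000L,
                             n_viruses = 3L,
                             virus_len_range = c(5000L, 25000L),
                             circular_fraction = 1 / 3,
                             terminal_repeat = 55L,
                             protospacers_per_virus = 5L,
                             protospacer_mutation_rate = 0.02,
                             n_background_genomes = 2L,
                             background_len_range = c(20000L, 40000L),
                             read_length = 150L,
                             read_error_rate = 0.005,
                             n_reads = 100000L,
                             per_sample_abundance = NULL,
                             acquisition_source = c("virus", "random"),
                             timepoints = NULL) {
  check_dna(dr_sequence, "dr_sequence")
  check_fraction(circular_fraction, "circular_fraction")
  check_fraction(protospacer_mutation_rate, "protospacer_mutation_rate")
  check_fraction(read_error_rate, "read_error_rate")
  stopifnot(length(spacer_len_range) == 2L,
            spacer_len_range[1] <= spacer_len_range[2],
            spacer_len_range[1] >= 1L,
            length(virus_len_range) == 2L,
            virus_len_range[1] <= virus_len_range[2],
            n_host_spacers >= 0L, n_viruses >= 0L,
            n_background_genomes >= 0L,
            read_length >= 20L, n_reads >= 1L,
            terminal_repeat >= 1L, host_genome_length >= 1000L)
  acquisition_source <- match.arg(acquisition_source)

  cfg <- list(seed = as.integer(seed),
              dr_sequence = dr_sequence,
              n_host_spacers = as.integer(n_host_spacers),
              spacer_len_range = as.integer(spacer_len_range),
              host_genome_length = as.integer(host_genome_length),
              n_viruses = as.integer(n_viruses),
              virus_len_range = as.integer(virus_len_range),
              circular_fraction = circular_fraction,
              terminal_repeat = as.integer(terminal_repeat),
              protospacers_per_virus = as.integer(protospacers_per_virus),
              protospacer_mutation_rate = protospacer_mutation_rate,
              n_background_genomes = as.integer(n_background_genomes),
              background_len_range = as.integer(background_len_range),
              read_length = as.integer(read_length),
              read_error_rate = read_error_rate,
              n_reads = as.integer(n_reads),
              per_sample_abundance = per_sample_abundance,
              acquisition_source = acquisition_source,
              timepoints = timepoints)
  if (is.null(cfg$timepoints)) {
    cfg$timepoints <- list(
      timepoint("t1"),
      timepoint("t2", virus_weight_factor = 0.5, n_acquired = 3L, n_lost = 1L))
  }
  if (length(cfg$timepoints) < 1L) stop("at least one timepoint is required")
  for (i in seq_along(cfg$timepoints)) {
    if (is.null(cfg$timepoints[[i]]$sample_id))
      cfg$timepoints[[i]]$sample_id <- sprintf("t%d", i)
  }
  structure(cfg, class = "community_config")
}

replicon_ids <- function(config) {
  c("host",
    if (config$n_viruses > 0) sprintf("virus_%d", seq_len(config$n_viruses)),
    if (config$n_background_genomes > 0)
      sprintf("bg_%d", seq_len(config$n_background_genomes)))
}

# Base abundance weights; a dominant host over minority viruses/backgrounds.
base_weights <- function(config) {
  ids <- replicon_ids(config)
  w <- setNames(numeric(length(ids)), ids)
  w["host"] <- 60
  if (config$n_viruses > 0)
    w[sprintf("virus_%d", seq_len(config$n_viruses))] <-
      rep(c(15, 10, 5), length.out = config$n_viruses)
  if (config$n_background_genomes > 0)
    w[sprintf("bg_%d", seq_len(config$n_background_genomes))] <- 5
  if (!is.null(config$per_sample_abundance)) {
    o <- config$per_sample_abundance
    bad <- setdiff(names(o), ids)
    if (length(bad)) stop("unknown replicon ids in per_sample_abundance: ",
                          paste(bad, collapse = ", "))
    w[names(o)] <- o
  }
  w
}
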