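test_that("host generation plants exactly the recorded CRISPR array", {
  cfg <- community_config(seed = 5, n_host_spacers = 5L,
                          host_genome_length = 3000L)
  host <- generate_host(cfg)
  occ <- gregexpr(cfg$dr_sequence, host$sequence, fixed = TRUE)[[1]]
  expect_length(occ, 6L)  # n + 1 DR copies
  segs <- substring(host$sequence,
                    occ[-length(occ)] + nchar(cfg$dr_sequence), occ[-1] - 1)
  expect_identical(unname(segs), host$spacers$sequence)
  # locus coordinates frame the array
  arr <- paste0(cfg$dr_sequence,
                paste0(host$spacers$sequence, cfg$dr_sequence, collapse = ""))
  expect_identical(substr(host$sequence, host$locus[["start"]] + 1,
                          host$locus[["end"]]), arr)
})

test_that("zero spacers gives a bare single-DR array", {
  cfg <- community_config(seed = 5, n_host_spacers = 0L,
                          protospacers_per_virus = 0L,
                          host_genome_length = 2000L)
  host <- generate_host(cfg)
  occ <- gregexpr(cfg$dr_sequence, host$sequence, fixed = TRUE)[[1]]
  expect_length(occ, 1L)
  expect_equal(nrow(host$spacers), 0L)
})

test_that("generation is byte-identical under the same seed", {
  cfg <- community_config(seed = 77, n_reads = 500L,
                          host_genome_length = 5000L, n_host_spacers = 5L,
                          virus_len_range = c(4000L, 6000L))
  a <- simulate_timeseries(cfg)
  b <- simulate_timeseries(cfg)
  expect_identical(a$community$host$sequence, b$community$host$sequence)
  expect_identical(lapply(a$community$viruses, `[[`, "sequence"),
                   lapply(b$community$viruses, `[[`, "sequence"))
  expect_identical(a$samples$t1$reads, b$samples$t1$reads)
  expect_identical(a$samples$t2$reads, b$samples$t2$reads)
  # and written FASTQ bytes reproduce
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_community(cfg, d1); simulate_community(cfg, d2)
  expect_identical(readLines(file.path(d1, "t1.reads.fastq")),
                   readLines(file.path(d2, "t1.reads.fastq")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid DR and impossible placements are input errors", {
  expect_error(community_config(dr_sequence = "ACGTX"), "ACGT")
  cfg <- community_config(seed = 1, virus_len_range = c(120L, 150L),
                          protospacers_per_virus = 10L,
                          host_genome_length = 2000L)
  host <- generate_host(cfg)
  expect_error(generate_viruses(cfg, host), "too short")
  cfg2 <- community_config(seed = 1, n_host_spacers = 0L,
                           host_genome_length = 2000L)
  h2 <- generate_host(cfg2)
  expect_error(generate_viruses(cfg2, h2), "no spacers")
})

test_that("mutation-free protospacers are exact copies; circular viruses carry the terminal repeat", {
  cfg <- community_config(seed = 3, protospacer_mutation_rate = 0,
                          circular_fraction = 1, n_viruses = 3L,
                          virus_len_range = c(4000L, 8000L),
                          host_genome_length = 5000L)
  host <- generate_host(cfg)
  vir <- generate_viruses(cfg, host)
  vids <- vapply(vir$viruses, `[[`, character(1), "id")
  for (k in seq_len(nrow(vir$protospacers))) {
    p <- vir$protospacers[k, ]
    vseq <- vir$viruses[[match(p$virus_id, vids)]]$sequence
    ps <- substr(vseq, p$start0 + 1, p$end0)
    if (p$strand == "-") ps <- revcomp_chr(ps)
    expect_identical(ps, host$spacers$sequence[host$spacers$id == p$spacer_id])
  }
  for (v in vir$viruses) {
    emitted <- assembly_sequence(v)
    k <- cfg$terminal_repeat
    expect_identical(substr(emitted, 1, k),
                     substr(emitted, nchar(emitted) - k + 1, nchar(emitted)))
  }
})

test_that("realized protospacer mutation counts follow the binomial model", {
  cfg <- community_config(seed = 13, n_viruses = 10L,
                          protospacers_per_virus = 12L,
                          protospacer_mutation_rate = 0.1,
                          spacer_len_range = c(40L, 40L),
                          n_host_spacers = 40L,
                          virus_len_range = c(8000L, 12000L),
                          host_genome_length = 8000L)
  host <- generate_host(cfg)
  vir <- generate_viruses(cfg, host)
  p <- vir$protospacers
  expect_gte(nrow(p), 100L)
  # recorded counts equal realized Hamming distances
  vids <- vapply(vir$viruses, `[[`, character(1), "id")
  hd <- vapply(seq_len(nrow(p)), function(k) {
    vseq <- vir$viruses[[match(p$virus_id[k], vids)]]$sequence
    ps <- substr(vseq, p$start0[k] + 1, p$end0[k])
    if (p$strand[k] == "-") ps <- revcomp_chr(ps)
    src <- host$spacers$sequence[host$spacers$id == p$spacer_id[k]]
    sum(strsplit(ps, "")[[1]] != strsplit(src, "")[[1]])
  }, numeric(1))
  expect_identical(as.integer(hd), as.integer(p$n_mutations))
  # total mutations within binomial 95% bounds (n plantings x 40 nt at 0.1)
  nb <- nrow(p) * 40L
  expect_gte(sum(p$n_mutations), qbinom(0.025, nb, 0.1))
  expect_lte(sum(p$n_mutations), qbinom(0.975, nb, 0.1))
})

test_that("read simulation conserves read counts and respects weights and errors", {
  r1 <- rand_dna(4000); r2 <- rand_dna(4000)
  reps <- list(list(id = "a", sequence = r1, circular = FALSE),
               list(id = "b", sequence = r2, circular = FALSE))
  reads <- simulate_reads(reps, c(a = 3, b = 1), 10000L, 100L, 0, seed = 21)
  expect_equal(nrow(reads), 10000L)
  na <- sum(reads$source == "a")
  expect_gte(na, qbinom(0.005, 10000, 0.75))
  expect_lte(na, qbinom(0.995, 10000, 0.75))
  # error-free reads are exact substrings of a replicon or its revcomp
  idx <- sample.int(10000, 30)
  for (i in idx) {
    src <- if (reads$source[i] == "a") r1 else r2
    hit <- grepl(reads$sequence[i], src, fixed = TRUE) ||
      grepl(revcomp_chr(reads$sequence[i]), src, fixed = TRUE)
    expect_true(hit)
  }
  # same seed, same bytes
  reads2 <- simulate_reads(reps, c(a = 3, b = 1), 10000L, 100L, 0, seed = 21)
  expect_identical(reads, reads2)
})

test_that("circular replicons wrap and short linear replicons warn", {
  core <- rand_dna(500)
  circ <- list(id = "c", sequence = core, circular = TRUE)
  reads <- simulate_reads(list(circ), c(c = 1), 2000L, 120L, 0, seed = 2)
  dbl <- paste0(core, core)
  ok <- vapply(reads$sequence, function(r)
    grepl(r, dbl, fixed = TRUE) || grepl(revcomp_chr(r), dbl, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
  expect_true(any(reads$start0 + 120 > 500))  # some reads span the origin
  short <- list(id = "s", sequence = rand_dna(50), circular = FALSE)
  expect_warning(
    simulate_reads(list(circ, short), c(c = 1, s = 1), 100L, 120L, 0, seed = 3),
    "contribute no reads")
})

test_that("timeseries spacer turnover follows the configured arithmetic", {
  mk <- function(tps) community_config(seed = 4, n_host_spacers = 5L,
                                       n_reads = 200L,
                                       host_genome_length = 3000L,
                                       virus_len_range = c(4000L, 5000L),
                                       timepoints = tps)
  # zero turnover: identical repertoires
  sim0 <- simulate_timeseries(mk(list(timepoint("t1"), timepoint("t2"))))
  expect_identical(sim0$samples$t1$truth$spacers,
                   sim0$samples$t2$truth$spacers)
  # acquire 3, lose 1 from 5 -> 7
  sim1 <- simulate_timeseries(mk(list(
    timepoint("t1"),
    timepoint("t2", n_acquired = 3L, n_lost = 1L))))
  expect_equal(nrow(sim1$samples$t2$truth$spacers), 7L)
  # acquisitions sit at the leader (array start) end
  expect_match(sim1$samples$t2$truth$spacers$id[1], "^acq_t2")
  # excess deletions error
  expect_error(simulate_timeseries(mk(list(
    timepoint("t1", n_lost = 6L)))), "cannot delete")
})

test_that("expected coverage from ground truth matches mapped coverage", {
  sim <- default_sim()
  truth <- sim$samples$t1$truth
  scaf <- sim_scaffolds(sim)
  prof <- sample_profiles(list(t1 = sim$samples$t1$reads), scaf)
  for (id in names(truth$expected_coverage)) {
    expc <- truth$expected_coverage[[id]]
    n <- truth$read_counts[[id]]
    if (n < 100) next
    se <- expc / sqrt(n)
    got <- prof$raw_coverage[prof$reference == id]
    expect_lt(abs(got - expc), 3 * se + 0.05 * expc)
  }
})
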