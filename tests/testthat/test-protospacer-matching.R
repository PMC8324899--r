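test_that("seeded search finds contained queries on either strand", {
  set.seed(61)
  q <- rand_dna(40)
  pl <- plant_query(q, 200)
  out <- seed_and_extend(q, pl$subject)
  expect_gte(nrow(out), 1L)
  expect_equal(out$identities[1], 40L)
  expect_equal(out$subject_start[1], pl$start0)
  expect_equal(out$subject_end[1], pl$end0)
  expect_equal(out$strand[1], "+")
  # reverse-complement planting: '-' strand alignment of equal score
  pl2 <- plant_query(q, 200, strand = "-")
  out2 <- seed_and_extend(q, pl2$subject)
  expect_equal(out2$strand[1], "-")
  expect_equal(out2$score[1], out$score[1])
  expect_error(seed_and_extend(rand_dna(5), pl$subject), "word_size")
})

test_that("word and scan search equal the full Smith-Waterman oracle on planted instances", {
  set.seed(62)
  for (i in 1:40) {
    L <- sample(35:45, 1)
    q <- rand_dna(L)
    nmm <- sample(0:3, 1)
    # internal positions, pairwise separation >= 4, so the full-length
    # alignment is the unique optimum
    pos <- integer()
    if (nmm > 0) {
      cand <- seq(5, L - 4)
      while (length(pos) < nmm && length(cand)) {
        p <- sample(cand, 1)
        pos <- c(pos, p)
        cand <- setdiff(cand, (p - 3):(p + 3))
      }
    }
    strand <- sample(c("+", "-"), 1)
    pl <- plant_query(q, 200, mm_pos = pos, strand = strand)
    or <- sw_oracle(q, pl$subject)
    for (method in c("word", "scan")) {
      out <- seed_and_extend(q, pl$subject, method = method,
                             min_matches = L - 10L)
      expect_gte(nrow(out), 1L)
      expect_equal(out$score[1], or$score)
      expect_equal(out$identities[1], or$identities)
      expect_equal(out$subject_start[1], or$subject_start)
      expect_equal(out$subject_end[1], or$subject_end)
    }
  }
})

test_that("similarity threshold is inclusive at 0.80 with query-length denominator", {
  set.seed(63)
  q <- rand_dna(40)
  # 8 evenly spread substitutions: full-length optimum, 32 identities
  pl8 <- plant_query(q, 200, mm_pos = c(5, 9, 13, 17, 21, 25, 29, 33))
  m8 <- match_clusters_to_scaffolds(c(C1 = q), c(sc = pl8$subject))
  expect_equal(nrow(m8), 1L)
  expect_equal(m8$identities, 32L)
  expect_equal(m8$similarity, 0.80)
  # 9 substitutions -> 0.775, rejected
  pl9 <- plant_query(q, 200, mm_pos = c(5, 8, 11, 14, 17, 20, 23, 26, 29))
  m9 <- match_clusters_to_scaffolds(c(C1 = q), c(sc = pl9$subject))
  expect_equal(nrow(m9), 0L)
  # absent spacer -> no rows
  m0 <- match_clusters_to_scaffolds(c(C1 = q), c(sc = rand_dna(5000)))
  expect_equal(nrow(m0), 0L)
  # alignment-length denominator is available
  m8b <- match_clusters_to_scaffolds(c(C1 = q), c(sc = pl8$subject),
                                     sim_denominator = "alignment")
  expect_equal(nrow(m8b), 1L)
})

test_that("matching is strand symmetric under scaffold reverse complement", {
  set.seed(64)
  q <- rand_dna(36)
  pl <- plant_query(q, 400, mm_pos = c(10, 20))
  fwd <- match_clusters_to_scaffolds(c(C1 = q), c(sc = pl$subject))
  rev <- match_clusters_to_scaffolds(c(C1 = q),
                                     c(sc = revcomp_chr(pl$subject)))
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$identities, fwd$identities)
  expect_equal(rev$scaffold_start, 400 - fwd$scaffold_end)
  expect_equal(rev$scaffold_end, 400 - fwd$scaffold_start)
  expect_true(fwd$strand != rev$strand)
})

test_that("sensitivity: planted protospacers at 5% mutation are recovered", {
  set.seed(65)
  n <- 0L; rec <- 0L
  for (i in 1:200) {
    L <- sample(30:45, 1)
    q <- rand_dna(L)
    nmm <- rbinom(1, L, 0.05)
    pos <- sample(L, nmm)
    pl <- plant_query(q, 300, mm_pos = pos,
                      strand = sample(c("+", "-"), 1))
    m <- match_clusters_to_scaffolds(c(C = q),
                                     c(sc = pl$subject))
    n <- n + 1L
    if (nrow(m) >= 1) rec <- rec + 1L
  }
  expect_gte(rec / n, 0.95)
})

test_that("specificity: random spacers never match 1 Mbp of random DNA", {
  set.seed(66)
  subj <- rand_dna(1e6)
  for (i in 1:20) {
    q <- rand_dna(35)
    expect_equal(nrow(match_clusters_to_scaffolds(c(C = q), c(big = subj))), 0L)
  }
})

test_that("linkage summary counts loci and conserves abundance", {
  cfg <- community_config(seed = 71, protospacer_mutation_rate = 0,
                          host_genome_length = 5000L,
                          virus_len_range = c(8000L, 12000L))
  host <- generate_host(cfg)
  vir <- generate_viruses(cfg, host)
  # one occurrence per host spacer, clustered
  recs <- data.frame(spacer_seq = host$spacers$sequence, sample_id = "s1")
  cl <- cluster_spacers(recs)
  scaf <- setNames(vapply(vir$viruses, assembly_sequence, character(1)),
                   vapply(vir$viruses, `[[`, character(1), "id"))
  mt <- match_clusters_to_scaffolds(cl, scaf)
  lk <- summarize_linkage(mt, scaf, cl)
  expect_setequal(lk$scaffold_id, names(scaf))
  for (v in names(scaf)) {
    planted <- sum(vir$protospacers$virus_id == v)
    expect_equal(lk$n_loci[lk$scaffold_id == v], planted)
    # abundance equals the member counts of contributing clusters
    cls <- unique(mt$cluster_id[mt$scaffold_id == v])
    expect_equal(lk$s1[lk$scaffold_id == v],
                 sum(cl$clusters$s1[cl$clusters$cluster_id %in% cls]))
  }
  # zero matches -> empty table
  empty <- summarize_linkage(mt[0, , drop = FALSE], scaf, cl)
  expect_equal(nrow(empty), 0L)
})
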