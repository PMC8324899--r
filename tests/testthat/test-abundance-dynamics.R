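test_that("read assignment recovers coverage and applies the mismatch cap", {
  set.seed(91)
  ref <- rand_dna(20000)
  reads <- simulate_reads(list(list(id = "r", sequence = ref,
                                    circular = FALSE)),
                          c(r = 1), 5000L, 100L, 0, seed = 92)
  asn <- assign_reads(reads, c(r = ref))
  expect_equal(asn$n_assigned, 5000L)
  cov <- asn$mapped_bp[["r"]] / nchar(ref)
  expc <- 5000 * 100 / 20000
  expect_lt(abs(cov - expc), 3 * expc / sqrt(5000))
  # conservation: mapped bp never exceeds sequenced bp
  expect_lte(sum(asn$mapped_bp), sum(nchar(reads$sequence)))
  # a read with 3% substitutions fails the 2% cap
  r3 <- substr(ref, 501, 600)
  ch <- strsplit(r3, "")[[1]]
  for (p in sample(100, 3)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                    ch[p]), 1)
  r3 <- paste(ch, collapse = "")
  asn3 <- assign_reads(c(x = r3), c(r = ref))
  expect_equal(asn3$n_assigned, 0L)
  # 2% exactly (2 of 100) passes
  r2 <- substr(ref, 501, 600)
  ch <- strsplit(r2, "")[[1]]
  for (p in c(10, 60)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1)
  asn2 <- assign_reads(c(x = paste(ch, collapse = "")), c(r = ref))
  expect_equal(asn2$n_assigned, 1L)
  expect_equal(asn2$assignments$mismatches, 2L)
  # empty read set -> zeros
  asn0 <- assign_reads(data.frame(id = character(), sequence = character()),
                       c(r = ref))
  expect_equal(asn0$n_assigned, 0L)
  expect_equal(unname(asn0$mapped_bp), 0)
})

test_that("multi-mapping ties follow the configured policy", {
  set.seed(93)
  g <- rand_dna(3000)
  refs <- c(a = g, b = g)  # identical references
  reads <- simulate_reads(list(list(id = "a", sequence = g,
                                    circular = FALSE)),
                          c(a = 1), 200L, 100L, 0, seed = 94)
  first <- assign_reads(reads, refs, multi = "first")
  expect_equal(unname(first$mapped_bp), c(200 * 100, 0))
  disc <- assign_reads(reads, refs, multi = "discard")
  expect_equal(disc$n_assigned, 0L)
  frac <- assign_reads(reads, refs, multi = "fractional")
  expect_equal(unname(frac$mapped_bp), c(100 * 100, 100 * 100))
})

test_that("normalization scales to the shallowest sample and preserves ratios", {
  prof <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 2),
    reference = rep(c("host", "v"), 2),
    mapped_bp = c(1e7, 1e6, 4e7, 2e6),
    raw_coverage = c(100, 10, 200, 20),
    total_bp = c(1e9, 1e9, 2e9, 2e9))
  norm <- normalize_coverage(prof)
  expect_equal(norm$norm_factor, c(1, 1, 0.5, 0.5))
  # 10x raw in the 2 Gbp sample -> 5x normalized
  expect_equal(norm$normalized_coverage[norm$sample_id == "s2"], c(100, 10))
  # single sample: factor 1
  one <- normalize_coverage(prof[prof$sample_id == "s1", ])
  expect_true(all(one$norm_factor == 1))
  expect_error(normalize_coverage(transform(prof, total_bp = 0)), "positive")
  # host/virus ratio is scale invariant
  raw_ratio <- prof$raw_coverage[1] / prof$raw_coverage[2]
  norm_ratio <- host_virus_ratio(norm, "host", "v", "s1")[["s1"]]
  expect_equal(norm_ratio, raw_ratio, tolerance = 1e-9)
})

test_that("host-virus ratio handles the degenerate zero-coverage virus", {
  prof <- data.frame(sample_id = "s", reference = c("host", "v1", "v2"),
                     mapped_bp = c(300, 100, 0), raw_coverage = c(30, 10, 0),
                     total_bp = 1e6)
  prof <- normalize_coverage(prof)
  expect_equal(unname(host_virus_ratio(prof, "host", "v1")), 3.0)
  expect_equal(unname(host_virus_ratio(prof, "host", "host")), 1.0)
  expect_true(is.na(host_virus_ratio(prof, "host", "v2")[["s"]]))
  expect_error(host_virus_ratio(prof, "host", "nope"), "unknown")
})

test_that("spacer dynamics normalizes by host coverage and restricts per-virus statistics", {
  set.seed(95)
  # two samples with identical spacer counts but host coverage ratio 2:1
  sp <- replicate(6, rand_dna(36))
  recs <- rbind(data.frame(spacer_seq = rep(sp, 2), sample_id = "s1"),
                data.frame(spacer_seq = rep(sp, 2), sample_id = "s2"))
  cl <- cluster_spacers(recs)
  matches <- data.frame(cluster_id = cl$clusters$cluster_id[1:3],
                        scaffold_id = "v1", scaffold_start = 0L,
                        scaffold_end = 36L, strand = "+",
                        aligned_length = 36L, identities = 36L,
                        similarity = 1.0)
  prof <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     reference = rep(c("host", "v1"), 2),
                     mapped_bp = c(2e6, 1e5, 1e6, 1e5),
                     raw_coverage = c(200, 10, 100, 10),
                     total_bp = 1e8)
  prof <- normalize_coverage(prof)
  dyn <- spacer_dynamics(cl, matches, prof, "host")
  ps <- dyn$per_sample
  # s1 host coverage is 2x the minimum -> abundance halved; s2 factor 1
  expect_equal(ps$total_spacer_abundance[ps$sample_id == "s1"], 12 / 2)
  expect_equal(ps$total_spacer_abundance[ps$sample_id == "s2"], 12)
  expect_equal(ps$distinct_clusters, c(6L, 6L))
  expect_true(all(ps$singleton_clusters <= ps$distinct_clusters))
  pv <- dyn$per_virus
  expect_equal(pv$matching_distinct_clusters, c(3L, 3L))
  expect_true(all(pv$matching_abundance <=
                    ps$total_spacer_abundance[match(pv$sample_id,
                                                    ps$sample_id)]))
  expect_equal(pv$host_virus_ratio, c(20, 10))
  # mismatched sample ids error
  bad <- prof[prof$sample_id == "s1", ]
  expect_error(spacer_dynamics(cl, matches, bad, "host"), "disagree")
})
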