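test_that("terminal-repeat circularity is detected exactly", {
  set.seed(81)
  core <- rand_dna(10000)
  emitted <- paste0(core, substr(core, 1, 55))
  d <- detect_circularity(emitted)
  expect_true(d$is_circular)
  expect_equal(d$terminal_repeat_len, 55L)
  expect_equal(d$trimmed_length, 10000L)
  # random sequence: no chance >= 20 bp terminal repeat
  d2 <- detect_circularity(rand_dna(10000))
  expect_false(d2$is_circular)
  expect_equal(d2$trimmed_length, 10000L)
  # degenerate short input
  d3 <- detect_circularity(rand_dna(30))
  expect_false(d3$is_circular)
  # rotation invariance: regenerate the convention from a rotated circle
  rot <- paste0(substr(core, 4001, 10000), substr(core, 1, 4000))
  d4 <- detect_circularity(paste0(rot, substr(rot, 1, 55)))
  expect_true(d4$is_circular)
  expect_equal(d4$terminal_repeat_len, 55L)
})

test_that("mini-CRISPR arrays are found with correct spacer counts", {
  set.seed(82)
  rep_seq <- rand_dna(30)
  one <- paste0(rand_dna(300), rep_seq, rand_dna(35), rep_seq, rand_dna(300))
  a1 <- detect_mini_crispr(one)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$spacer_count, 1L)
  expect_equal(a1$`repeat`, rep_seq)
  # extensive array: 30 spacers
  body <- paste0(vapply(1:30, function(i) paste0(rand_dna(40), rep_seq),
                        character(1)), collapse = "")
  ext <- paste0(rand_dna(200), rep_seq, body, rand_dna(200))
  a2 <- detect_mini_crispr(ext)
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$spacer_count, 30L)
  # random sequence: nothing
  expect_equal(nrow(detect_mini_crispr(rand_dna(20000))), 0L)
})

test_that("classification rules reproduce the scheme's worked outcomes", {
  base <- data.frame(scaffold_id = "s", length = 10000L, is_circular = FALSE,
                     terminal_repeat_len = 0L, hallmark_gene_count = 0L,
                     vog_hit_count = 0L, bacterial_hit_count = 0L,
                     crispr_array_spacer_count = 0L, spacer_targeted = TRUE,
                     stringsAsFactors = FALSE)
  # short spacer-targeted scaffold: length gate
  f <- base; f$length <- 2900L
  expect_equal(classify(f)$verdict, "not_considered")
  # circular with hallmark genes and VOG hits: virus
  f <- base; f$is_circular <- TRUE; f$hallmark_gene_count <- 2L
  f$vog_hit_count <- 3L
  v <- classify(f)
  expect_equal(v$verdict, "virus")
  expect_setequal(v$reasons, c("hallmark_genes", "circular"))
  # linear, no hallmark, spacer-targeted: putative virus
  expect_equal(classify(base)$verdict, "putative_virus")
  # extensive CRISPR array: rejected
  f <- base; f$crispr_array_spacer_count <- 30L
  expect_equal(classify(f)$verdict, "rejected")
  # bacterial hits without hallmark genes: rejected
  f <- base; f$bacterial_hit_count <- 5L
  expect_equal(classify(f)$verdict, "rejected")
  # a 1-spacer mini-array does not reject a genuine virus
  f <- base; f$crispr_array_spacer_count <- 1L
  expect_equal(classify(f)$verdict, "putative_virus")
})

test_that("classification is total with exactly one verdict over a feature grid", {
  grid <- expand.grid(length = c(2000L, 8000L),
                      is_circular = c(TRUE, FALSE),
                      hallmark_gene_count = c(0L, 2L),
                      bacterial_hit_count = c(0L, 4L),
                      crispr_array_spacer_count = c(0L, 6L),
                      spacer_targeted = c(TRUE, FALSE))
  grid$scaffold_id <- sprintf("g%02d", seq_len(nrow(grid)))
  grid$vog_hit_count <- 0L
  grid$terminal_repeat_len <- 0L
  out <- classify_scaffolds(grid)
  expect_equal(nrow(out), nrow(grid))
  expect_true(all(out$verdict %in% c("virus", "putative_virus", "rejected",
                                     "not_considered")))
  expect_true(all(nzchar(out$reasons)))
})

test_that("intergenomic similarity is symmetric, 100 iff identical, 0 for unrelated", {
  set.seed(83)
  g <- rand_dna(4000)
  expect_equal(intergenomic_similarity(g, g), 100)
  h <- rand_dna(4000)
  expect_equal(intergenomic_similarity(g, h), 0)
  flip <- setdiff(c("A", "C", "G", "T"), substr(g, 2000, 2000))[1]
  g_sub <- g; substr(g_sub, 2000, 2000) <- flip
  expect_lt(intergenomic_similarity(g, g_sub), 100)
  # ~5% substitutions -> ~95% similarity
  sims <- vapply(1:3, function(i) {
    gg <- strsplit(g, "")[[1]]
    pos <- which(runif(4000) < 0.05)
    for (p in pos) gg[p] <- sample(setdiff(c("A", "C", "G", "T"), gg[p]), 1)
    mut <- paste(gg, collapse = "")
    s <- intergenomic_similarity(g, mut)
    expect_equal(s, intergenomic_similarity(mut, g))  # symmetric
    s
  }, numeric(1))
  expect_true(all(abs(sims - 95) <= 1.5))
})

test_that("demarcation performs single linkage with nested species within genera", {
  m <- matrix(c(100, 96, 50, 96, 100, 50, 50, 50, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- demarcate(m)
  expect_equal(unname(d$species["A"]), unname(d$species["B"]))
  expect_false(d$species[["C"]] == d$species[["A"]])
  expect_equal(length(unique(d$genus)), 1L)  # all >= 15.8
  # all pairwise below the genus threshold: every genome its own genus
  m2 <- matrix(10, 3, 3); diag(m2) <- 100
  dimnames(m2) <- dimnames(m)
  d2 <- demarcate(m2)
  expect_equal(length(unique(d2$genus)), 3L)
  # single genome
  d1 <- demarcate(matrix(100, 1, 1, dimnames = list("X", "X")))
  expect_equal(unname(d1$species), 1L)
  # nesting property on random symmetric matrices
  set.seed(84)
  for (i in 1:10) {
    n <- 6
    r <- matrix(runif(n * n, 0, 100), n, n)
    r <- (r + t(r)) / 2; diag(r) <- 100
    dd <- demarcate(r)
    # two genomes in one species share a genus
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (dd$species[a] == dd$species[b])
        expect_equal(dd$genus[[a]], dd$genus[[b]])
  }
  # asymmetric input errors
  bad <- m; bad[1, 2] <- 80
  expect_error(demarcate(bad), "symmetric")
})
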