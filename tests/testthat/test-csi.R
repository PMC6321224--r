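test_that("fragment extraction slides with stride 1 and flags M/W middles", {
  set.seed(5)
  g5 <- first_codon_gene("g5", "MKWKM")
  fr <- extract_fragments(g5, 5L)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$fragment, "MKWKM")
  expect_identical(fr$middle_aa, "W")
  expect_false(fr$degenerate)

  g101 <- first_codon_gene("g101", random_protein(101L))
  expect_identical(nrow(extract_fragments(g101, 7L)), 95L)

  # shorter than the window -> empty
  expect_identical(nrow(extract_fragments(g5, 7L)), 0L)
})

test_that("fragment multiset equals a naive substring enumeration", {
  set.seed(6)
  genes <- lapply(1:5, function(i) first_codon_gene(paste0("g", i),
                                                   random_protein(40L)))
  for (w in c(5L, 7L)) {
    got <- unlist(lapply(genes, function(g) extract_fragments(g, w)$fragment))
    oracle <- unlist(lapply(genes, function(g) {
      p <- g$protein
      vapply(seq_len(nchar(p) - w + 1L),
             function(s) substr(p, s, s + w - 1L), character(1))
    }))
    expect_identical(sort(got), sort(oracle))
  }
})

test_that("CSI accumulates middle-codon counts per distinct fragment", {
  one <- list(gene_from_codons("g", "ATG AAA AAA AAA TGG"))
  csi <- build_csi(one, 5L)
  expect_identical(csi_n_entries(csi), 1L)
  e <- csi_entry(csi, "MKKKW")
  expect_identical(e$occurrences, 1L)
  expect_identical(unname(e$middle_codon_counts["AAA"]), 1L)
  expect_length(e$position_mean_usage, 5L)

  # same fragment 10 times, middle codons 7x AAA / 3x AAG
  mids <- c(rep("AAA", 7), rep("AAG", 3))
  ten <- lapply(seq_along(mids), function(i)
    gene_from_codons(paste0("g", i),
                     paste("ATG AAA", mids[i], "AAA TGG")))
  csi10 <- build_csi(ten, 5L)
  e10 <- csi_entry(csi10, "MKKKW")
  expect_identical(e10$occurrences, 10L)
  expect_identical(unname(e10$middle_codon_counts["AAA"]), 7L)
  expect_identical(unname(e10$middle_codon_counts["AAG"]), 3L)
})

test_that("a planted context rule shows up as the conditional codon fraction", {
  sc <- small_rule_corpus(strength = 1, n_families = 15L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  b <- csi$buckets$K
  # oracle: direct conditional frequency count over K-middle fragments
  trigger <- substring(b$fragments, 4L, 4L) == "P"   # rule offset +1
  if (any(trigger)) {
    frac_aag <- sum(b$counts[trigger, "AAG"]) / sum(b$counts[trigger, ])
    expect_equal(frac_aag, 1.0)
  }
  non <- !trigger
  frac_aag_bg <- sum(b$counts[non, "AAG"]) / sum(b$counts[non, ])
  expect_lt(frac_aag_bg, 0.5)
})

test_that("occurrences are conserved and counts normalize to distributions", {
  sc <- small_rule_corpus(strength = 0.9)
  csi <- build_csi(sc$corpus, 7L)
  n_positions <- sum(vapply(sc$corpus, function(g) {
    fr <- extract_fragments(g, 7L)
    sum(fr$degenerate)
  }, integer(1)))
  expect_identical(sum(vapply(csi$buckets, function(b) sum(b$occurrences),
                              integer(1))), n_positions)
  expect_identical(csi$n_positions, n_positions)
  for (b in csi$buckets) {
    expect_equal(unname(rowSums(b$counts)), as.numeric(b$occurrences))
    expect_true(all(b$pos_mean >= 0 & b$pos_mean <= 1))
  }
})

test_that("CSI building is additive over corpus halves", {
  sc <- small_rule_corpus(strength = 0.8, n_families = 6L, members = 3L)
  corpus <- sc$corpus
  bg <- usage_table_from_corpus(corpus)
  half <- length(corpus) %/% 2L
  a <- build_csi(corpus[1:half], 5L, background = bg)
  b <- build_csi(corpus[(half + 1L):length(corpus)], 5L, background = bg)
  merged <- merge_csi(a, b)
  full <- build_csi(corpus, 5L, background = bg)
  expect_identical(csi_n_entries(merged), csi_n_entries(full))
  for (aa in names(full$buckets)) {
    expect_identical(merged$buckets[[aa]]$fragments, full$buckets[[aa]]$fragments)
    expect_identical(merged$buckets[[aa]]$counts, full$buckets[[aa]]$counts)
    expect_equal(merged$buckets[[aa]]$pos_mean, full$buckets[[aa]]$pos_mean,
                 tolerance = 1e-12)
  }
})

test_that("CSI files round-trip losslessly and reject bad headers", {
  sc <- small_rule_corpus(strength = 0.9, n_families = 12L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  tmp <- withr::local_tempfile(fileext = ".csi")
  save_csi(csi, tmp)
  back <- load_csi(tmp)
  expect_identical(back$window, csi$window)
  expect_identical(back$n_genes, csi$n_genes)
  expect_identical(csi_n_entries(back), csi_n_entries(csi))
  for (aa in names(csi$buckets)) {
    expect_identical(back$buckets[[aa]]$fragments, csi$buckets[[aa]]$fragments)
    expect_identical(back$buckets[[aa]]$occurrences, csi$buckets[[aa]]$occurrences)
    expect_identical(back$buckets[[aa]]$counts, csi$buckets[[aa]]$counts)
    expect_equal(back$buckets[[aa]]$pos_mean, csi$buckets[[aa]]$pos_mean,
                 tolerance = 1e-5)
  }
  expect_equal(back$background$usage, csi$background$usage, tolerance = 1e-12)

  # wrong magic / version
  bad1 <- withr::local_tempfile(fileext = ".csi")
  writeLines(c("#something v1 window=5", "#background {}", "x"), bad1)
  expect_error(load_csi(bad1), "magic")
  lines <- readLines(tmp)
  lines[1L] <- sub(" v1 ", " v99 ", lines[1L], fixed = TRUE)
  bad2 <- withr::local_tempfile(fileext = ".csi")
  writeLines(lines, bad2)
  expect_error(load_csi(bad2), "version")
})

test_that("saved CSI bytes are deterministic", {
  sc <- small_rule_corpus(strength = 0.9, n_families = 8L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  save_csi(csi, t1); save_csi(csi, t2)
  expect_identical(readLines(t1), readLines(t2))
})
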