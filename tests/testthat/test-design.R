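test_that("positional tables take the modal codon at each terminal slot", {
  genes <- lapply(1:5, function(i)
    gene_from_codons(paste0("g", i), "ATG GAT AAA CCA CTG GAA TTA GGT"))
  pt <- build_positional_tables(genes)
  expect_identical(unname(pt$head[["1"]]["M"]), "ATG")
  expect_identical(unname(pt$head[["2"]]["D"]), "GAT")
  expect_identical(unname(pt$tail[["n2"]]["L"]), "TTA")
  expect_identical(unname(pt$tail[["n1"]]["G"]), "GGT")
  # amino acid never observed at a slot -> absent
  expect_true(is.na(pt$head[["2"]]["K"]))
})

test_that("a planted 70/30 split at position 2 picks the 70% codon", {
  set.seed(61)
  n <- 200L
  cod2 <- sample(c("GAA", "GAG"), n, replace = TRUE, prob = c(0.7, 0.3))
  genes <- lapply(seq_len(n), function(i)
    coding_sequence(paste0("g", i), c("ATG", cod2[i], "AAA", "CCA", "GGT")))
  pt <- build_positional_tables(genes)
  expect_identical(unname(pt$head[["2"]]["E"]), "GAA")   # counting oracle: 70% arm
  cnt <- pt$counts[pt$counts$slot == "2" & pt$counts$amino_acid == "E", ]
  expect_identical(sum(cnt$count), n)
})

test_that("positional tables round-trip through TSV", {
  sc <- small_rule_corpus(n_families = 5L, members = 3L)
  pt <- build_positional_tables(sc$corpus)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_positional_tsv(pt, tmp)
  back <- read_positional_tsv(tmp, usage_table_from_corpus(sc$corpus))
  for (slot in c("1", "2")) {
    expect_identical(back$head[[slot]][sort(names(pt$head[[slot]]))],
                     pt$head[[slot]][sort(names(pt$head[[slot]]))])
  }
  for (slot in c("n1", "n2")) {
    expect_identical(back$tail[[slot]][sort(names(pt$tail[[slot]]))],
                     pt$tail[[slot]][sort(names(pt$tail[[slot]]))])
  }
})

test_that("design config validates its cascade", {
  expect_error(design_config(cutoff_cascade = c(0.7, 0.9)), "descending")
  expect_error(design_config(window = 6L))
  expect_silent(design_config(window = 5L, cutoff_cascade = 0.9))
})

# one small bundle shared by the design tests
sc <- small_rule_corpus(strength = 1, n_families = 8L, members = 3L,
                        seed = 77L)
bundle <- train_grid(sc$corpus, windows = 5L, cutoffs = c(0.7, 0.9, 1),
                     n_trees = 30L, seed = 7L, host_name = "toy")
dcfg <- design_config(window = 5L, cutoff_cascade = c(0.9, 0.7))

test_that("Met/Trp-only proteins are designed from the code alone", {
  res <- design_gene("MW", bundle, dcfg)
  expect_identical(res$dna, "ATGTGG")
  expect_identical(nrow(res$per_position), 2L)
  expect_setequal(unique(res$per_position$source), "non-degenerate")
})

test_that("designed genes always translate back to the input protein", {
  set.seed(62)
  for (i in 1:60) {
    protein <- random_protein(sample(5:120, 1L))
    res <- design_gene(protein, bundle, dcfg)
    expect_identical(translate_codons(split_codons(res$dna)), protein)
    expect_identical(nchar(res$dna), 3L * nchar(protein))
  }
  # very short proteins take the table/fallback path throughout
  for (protein in c("MK", "MKL", "MKLV")) {
    res <- design_gene(protein, bundle, dcfg)
    expect_identical(translate_codons(split_codons(res$dna)), protein)
    expect_true(all(res$per_position$source %in%
                      c("non-degenerate", "head-table", "tail-table",
                        "fallback")))
  }
  expect_error(design_gene("MKXLV", bundle, dcfg), "non-standard")
})

test_that("design is deterministic and an optional stop codon is appended", {
  set.seed(63)
  protein <- random_protein(80L)
  r1 <- design_gene(protein, bundle, dcfg)
  r2 <- design_gene(protein, bundle, dcfg)
  expect_identical(r1$dna, r2$dna)
  cfg_stop <- design_config(window = 5L, cutoff_cascade = c(0.9, 0.7),
                            append_stop = "TAA")
  r3 <- design_gene(protein, bundle, cfg_stop)
  expect_identical(r3$dna, paste0(r1$dna, "TAA"))
})

test_that("with no usable context the design is modal back-translation", {
  # interior residues drawn from amino acids the corpus never shows in
  # context: every position falls back to the highest-usage codon
  skinny <- list(gene_from_codons("g1", paste(rep("AAA", 120L), collapse = " ")),
                 gene_from_codons("g2", paste(rep("AAG", 120L), collapse = " ")),
                 gene_from_codons("g3", paste(rep("AAA", 120L), collapse = " ")))
  b2 <- train_grid(skinny, windows = 5L, cutoffs = 1, n_trees = 10L, seed = 8L)
  protein <- "LVSTRLVSTR"
  res <- design_gene(protein, b2, design_config(window = 5L,
                                                cutoff_cascade = 0.9))
  expect_setequal(unique(res$per_position$source), "fallback")
  closed_form <- vapply(strsplit(protein, "")[[1L]], modal_codon, character(1),
                        usage = b2$background)
  expect_identical(split_codons(res$dna), unname(closed_form))
})

test_that("design reports partition positions by source", {
  set.seed(64)
  protein <- random_protein(60L)
  res <- design_gene(protein, bundle, dcfg)
  rep <- design_report(res, bundle$background)
  expect_equal(sum(rep$summary$fraction), 1.0, tolerance = 1e-12)
  expect_identical(sum(rep$summary$n), nchar(protein))
  # rare positions are flagged against the 0.5/k usage bar
  if (nrow(rep$rare_positions)) {
    k <- vapply(rep$rare_positions$amino_acid,
                function(a) length(codons_for(a)), integer(1))
    expect_true(all(bundle$background$usage[rep$rare_positions$codon] <
                      0.5 / k))
  }
})

test_that("a planted deterministic rule drives designed interior codons", {
  # proteins from the same families, fresh codon draws: rule positions with
  # model coverage must follow the rule
  ev <- generate_eval_set(sc, members_per_family = 2L, seed = 78L,
                          mutation_rate = 0)
  rec <- evaluate_recovery(bundle, ev, dcfg)
  expect_gt(rec$n_positions, 0L)
  model_rows <- grepl("^model@", rec$by_source$source)
  if (any(model_rows))
    expect_gt(sum(rec$by_source$recovery[model_rows] *
                    rec$by_source$n[model_rows]) /
                sum(rec$by_source$n[model_rows]), 0.95)
})
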