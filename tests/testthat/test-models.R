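# helper: a hand-built training set for an amino acid with k codons
make_training_set <- function(features, labels, aa, window) {
  structure(list(features = features, labels = labels,
                 gene_ids = rep("g", length(labels)),
                 fragments = rep(strrep(aa, window), length(labels)),
                 amino_acid = aa, window = window, cutoff = 1),
            class = "training_set")
}

feat_names <- function(aa, window) c(codons_for(aa), paste0("pos", seq_len(window)))

# features: first k columns a (noisy) one-hot of `intended`, pos columns noise
simulate_features <- function(intended, aa, window, noise = 0.05) {
  syn <- codons_for(aa)
  n <- length(intended)
  F <- matrix(stats::runif(n * (length(syn) + window), 0, noise),
              nrow = n, dimnames = list(NULL, feat_names(aa, window)))
  for (j in seq_along(syn)) F[intended == syn[j], j] <- 1
  F[, seq_along(syn)] <- F[, seq_along(syn)] / rowSums(F[, seq_along(syn)])
  F
}

test_that("training at cut-off 1 labels each position with its own codon", {
  set.seed(41)
  gene <- first_codon_gene("g", random_protein(60L))
  corpus <- list(gene)
  csi <- build_csi(corpus, 5L)
  ts <- assemble_training_data(corpus, csi, match_config(cutoff = 1), "L")
  # every eligible position matches itself, labels are the gene's own codons
  chars <- strsplit(gene$protein, "", fixed = TRUE)[[1L]]
  eligible <- which(chars == "L")
  eligible <- eligible[eligible >= 3L & eligible <= length(chars) - 2L]
  expect_identical(sort(ts$labels), sort(gene$codons[eligible]))
  expect_identical(ncol(ts$features), length(codons_for("L")) + 5L)
})

test_that("non-degenerate amino acids are rejected for training", {
  sc <- small_rule_corpus(n_families = 4L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  expect_error(assemble_training_data(sc$corpus, csi, match_config(), "M"),
               "not degenerate")
  expect_error(classifier_spec("W"), "not degenerate")
})

test_that("at cut-off 1 the label marginal equals the windowed codon counts", {
  sc <- small_rule_corpus(strength = 0.8, n_families = 8L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  ts <- assemble_training_data(sc$corpus, csi, match_config(cutoff = 1), "E")
  # counting oracle: codons at all E positions with a full window
  oracle <- unlist(lapply(sc$corpus, function(g) {
    fr <- extract_fragments(g, 5L)
    fr$middle_codon[fr$middle_aa == "E"]
  }))
  expect_identical(sort(ts$labels), sort(oracle))
})

test_that("a separable toy problem is learned perfectly", {
  set.seed(43)
  labels <- sample(c("AAA", "AAG"), 200L, replace = TRUE)
  F <- simulate_features(labels, "K", 5L)
  ts <- make_training_set(F, labels, "K", 5L)
  mdl <- train_classifier(ts, classifier_spec("K", 5L, 1, n_trees = 50L, seed = 1L))
  expect_false(mdl$degenerate)
  expect_identical(predict_codon(mdl, F), labels)
})

test_that("single-label training sets yield a flagged constant predictor", {
  set.seed(44)
  labels <- rep("GAA", 30L)
  F <- simulate_features(labels, "E", 5L)
  ts <- make_training_set(F, labels, "E", 5L)
  mdl <- train_classifier(ts, classifier_spec("E", 5L, 1, n_trees = 50L))
  expect_true(mdl$degenerate)
  expect_identical(predict_codon(mdl, F[1:5, ]), rep("GAA", 5L))
  # constant-label data cross-validates at accuracy 1
  cv <- cross_validate(ts, classifier_spec("E", 5L, 1, n_trees = 50L))
  expect_equal(cv$accuracy, 1.0)
})

test_that("feature dimension mismatches are rejected", {
  set.seed(48)
  labels <- sample(c("AAA", "AAG"), 40L, replace = TRUE)
  F <- simulate_features(labels, "K", 5L)[, 1:5]
  ts <- make_training_set(F, labels, "K", 5L)
  expect_error(train_classifier(ts, classifier_spec("K", 5L, 1)), "dimension")
})

test_that("uninformative features cross-validate at chance level", {
  set.seed(45)
  n <- 2000L
  labels <- sample(c("AAA", "AAG"), n, replace = TRUE)   # two equiprobable codons
  F <- matrix(stats::runif(n * 7), nrow = n,
              dimnames = list(NULL, feat_names("K", 5L)))
  ts <- make_training_set(F, labels, "K", 5L)
  cv <- cross_validate(ts, classifier_spec("K", 5L, 1, n_trees = 50L, seed = 2L))
  expect_equal(cv$accuracy, 0.5, tolerance = 0.05 / 0.5)
})

test_that("cross-validation attains the Bayes rate of a planted rule", {
  set.seed(46)
  n <- 2000L
  intended <- sample(c("AAA", "AAG"), n, replace = TRUE)
  observed <- ifelse(stats::runif(n) < 0.8, intended,
                     ifelse(intended == "AAA", "AAG", "AAA"))
  F <- simulate_features(intended, "K", 5L)
  ts <- make_training_set(F, observed, "K", 5L)
  cv <- cross_validate(ts, classifier_spec("K", 5L, 1, n_trees = 50L, seed = 3L))
  expect_equal(cv$accuracy, 0.8, tolerance = 0.05 / 0.8)
})

test_that("cross-validation needs at least as many samples as folds", {
  set.seed(47)
  labels <- c("AAA", "AAG", "AAA")
  F <- simulate_features(labels, "K", 5L)
  ts <- make_training_set(F, labels, "K", 5L)
  expect_error(cross_validate(ts, classifier_spec("K", 5L, 1)), "folds")
})

test_that("cross-validation reports are reproducible from the seed", {
  sc <- small_rule_corpus(strength = 0.9, n_families = 6L, members = 3L)
  csi <- build_csi(sc$corpus, 5L)
  ts <- assemble_training_data(sc$corpus, csi, match_config(cutoff = 0.8), "K")
  spec <- classifier_spec("K", 5L, 0.8, n_trees = 50L, seed = 19L)
  cv1 <- cross_validate(ts, spec)
  cv2 <- cross_validate(ts, spec)
  expect_identical(cv1, cv2)
})

test_that("a small grid trains at most one model per degenerate amino acid", {
  sc <- small_rule_corpus(n_families = 5L, members = 3L, strength = 0.9)
  bundle <- train_grid(sc$corpus, windows = 5L, cutoffs = 1,
                       n_trees = 20L, seed = 4L)
  expect_lte(length(bundle$models), 18L)
  expect_identical(nrow(bundle$grid), 18L)
  expect_true(all(bundle$grid$status %in% c("trained", "degenerate", "skipped")))
})

test_that("classifiers only ever emit synonymous codons", {
  sc <- small_rule_corpus(n_families = 5L, members = 3L, strength = 0.9)
  bundle <- train_grid(sc$corpus, windows = 5L, cutoffs = c(0.7, 1),
                       n_trees = 20L, seed = 5L)
  set.seed(50)
  for (key in sample(names(bundle$models), 10L)) {
    mdl <- bundle$models[[key]]
    k <- length(codons_for(mdl$amino_acid))
    F <- matrix(stats::runif(20L * (k + 5L)), nrow = 20L,
                dimnames = list(NULL, feat_names(mdl$amino_acid, 5L)))
    expect_true(all(predict_codon(mdl, F) %in% codons_for(mdl$amino_acid)))
  }
})

test_that("bundles round-trip through disk with identical predictions", {
  sc <- small_rule_corpus(n_families = 6L, members = 3L, strength = 0.9)
  bundle <- train_grid(sc$corpus, windows = 5L, cutoffs = c(0.8, 1),
                       n_trees = 20L, seed = 6L)
  dir <- withr::local_tempdir()
  save_bundle(bundle, dir)
  back <- load_bundle(dir)
  expect_identical(names(back$models), names(bundle$models))
  set.seed(51)
  for (key in c("K_w5_c0.8", "L_w5_c1")) {
    mdl <- bundle$models[[key]]
    k <- length(codons_for(mdl$amino_acid))
    F <- matrix(stats::runif(100L * (k + 5L)), nrow = 100L,
                dimnames = list(NULL, feat_names(mdl$amino_acid, 5L)))
    expect_identical(predict_codon(back$models[[key]], F),
                     predict_codon(mdl, F))
  }
  # version mismatch is an explicit error
  mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::fromJSON(mf)
  manifest$version <- "99"
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(dir), "version")
  # an empty bundle refuses to save
  empty <- bundle
  empty$models <- list()
  expect_error(save_bundle(empty, withr::local_tempdir()), "empty")
})
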