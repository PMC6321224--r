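# Per-amino-acid codon classifiers: training-set assembly, random-forest
# training, ten-fold cross-validation, the (cutoff x window) model grid,
# and bundle persistence.

#' Classifier specification
#'
#' @param amino_acid Degenerate one-letter amino-acid code.
#' @param window Odd window size the training CSI was built with.
#' @param cutoff Matched-percent cut-off in (0, 1].
#' @param n_trees Number of random-forest trees. The published configuration
#'   uses 10,000; the package default is 200, where accuracy has long
#'   plateaued at these dimensionalities (k + w features).
#' @param seed Integer seed for reproducible training.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(amino_acid, window = 7L, cutoff = 0.7,
                            n_trees = 200L, seed = 1L) {
  code <- genetic_code()
  if (!amino_acid %in% code$degenerate_aas)
    stop("amino acid '", amino_acid,
         "' is not degenerate; no codon choice to learn")
  stopifnot(cutoff > 0, cutoff <= 1, n_trees >= 1L)
  structure(list(amino_acid = amino_acid, window = as.integer(window),
                 cutoff = cutoff, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Assemble a training set for one amino acid
#'
#' Every corpus window position whose middle residue is `amino_acid` and
#' whose CSI search returns at least one entry above the cut-off contributes
#' one labelled example: the k + w feature vector (see
#' [build_feature_vector()]) and, as the label, the codon actually used at
#' that position. Positions with no match are skipped; their count is kept in
#' the `skipped` attribute.
#'
#' @param corpus List of `coding_sequence` objects.
#' @param csi A `csi` built with the same window size.
#' @param config A `match_config` (carries the cut-off and matrix).
#' @param amino_acid Degenerate amino acid to assemble for.
#' @return Object of class `training_set`: list with `features` (matrix,
#'   n x (k + w)), `labels` (character codons), `gene_ids`, `fragments`,
#'   `amino_acid`, `window`, `cutoff`.
#' @export
assemble_training_data <- function(corpus, csi, config = match_config(),
                                   amino_acid) {
  code <- genetic_code()
  if (!amino_acid %in% code$degenerate_aas)
    stop("amino acid '", amino_acid,
         "' is not degenerate; no codon choice to learn")
  frs <- lapply(corpus, function(g) {
    fr <- extract_fragments(g, csi$window)
    fr <- fr[fr$middle_aa == amino_acid, , drop = FALSE]
    if (nrow(fr)) fr$gene_id <- g$id
    fr
  })
  frs <- do.call(rbind, frs[vapply(frs, nrow, integer(1)) > 0L])
  if (is.null(frs) || nrow(frs) == 0L)
    stop("no window positions with middle residue ", amino_acid,
         " (window ", csi$window, ", cutoff ", config$cutoff, ")")
  uq <- sort(unique(frs$fragment))
  ff <- .features_for_queries(uq, csi, config$cutoff, amino_acid,
                              matrix = config$matrix)
  row <- match(frs$fragment, uq)
  feats <- ff$features[row, , drop = FALSE]
  ok <- ff$n_matches[row] > 0L
  if (!any(ok))
    stop("empty training set: no CSI matches for ", amino_acid,
         " at window ", csi$window, ", cutoff ", config$cutoff)
  structure(list(features = feats[ok, , drop = FALSE],
                 labels = frs$middle_codon[ok],
                 gene_ids = frs$gene_id[ok],
                 fragments = frs$fragment[ok],
                 amino_acid = amino_acid,
                 window = csi$window,
                 cutoff = config$cutoff),
            class = "training_set",
            skipped = sum(!ok))
}

#' Train a codon classifier
#'
#' Multi-class random forest over the k + w features, predicting the codon
#' of the middle residue. A training set with a single distinct label yields
#' a constant predictor flagged `degenerate` (it always returns that codon).
#'
#' @param ts A `training_set`.
#' @param spec A `classifier_spec`.
#' @return Object of class `codon_model`.
#' @export
train_classifier <- function(ts, spec) {
  stopifnot(inherits(ts, "training_set"), inherits(spec, "classifier_spec"))
  k_w <- length(codons_for(spec$amino_acid)) + spec$window
  if (ncol(ts$features) != k_w)
    stop("feature dimension ", ncol(ts$features), " != k + w = ", k_w)
  labs <- ts$labels
  syn <- codons_for(spec$amino_acid)
  if (!all(labs %in% syn))
    stop("label not synonymous with ", spec$amino_acid)
  constant_model <- function(codon, reason) {
    structure(list(amino_acid = spec$amino_acid, window = spec$window,
                   cutoff = spec$cutoff, constant = codon,
                   degenerate = TRUE, reason = reason,
                   n = length(labs), spec = spec),
              class = "codon_model")
  }
  if (length(unique(labs)) < 2L)
    return(constant_model(labs[1L], "single label"))
  # zero-variance features cannot be split on (and a fully constant matrix
  # sends randomForest into an infinite search); keep informative columns,
  # or store the majority codon when nothing varies
  rng <- apply(ts$features, 2L, function(v) max(v) - min(v))
  keep <- colnames(ts$features)[rng > 0]
  if (length(keep) == 0L) {
    tab <- table(labs)   # majority label, ties codon-lexicographic
    return(constant_model(names(tab)[which.max(tab)], "constant features"))
  }
  y <- droplevels(factor(labs, levels = syn))
  set.seed(spec$seed)
  rf <- randomForest::randomForest(x = ts$features[, keep, drop = FALSE],
                                   y = y, ntree = spec$n_trees)
  structure(list(amino_acid = spec$amino_acid, window = spec$window,
                 cutoff = spec$cutoff, forest = rf, degenerate = FALSE,
                 n = length(labs), spec = spec, feature_cols = keep,
                 feature_names = colnames(ts$features)),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("<codon_model>", x$amino_acid, "w =", x$window, "c =", x$cutoff,
      if (x$degenerate) paste0("constant (", x$constant, ")")
    else paste0(x$spec$n_trees, " trees"),
      "n =", x$n, "\n")
  invisible(x)
}

#' Predict codons from feature vectors
#'
#' @param model A `codon_model`.
#' @param features Numeric matrix (rows = positions, k + w columns) or a
#'   single feature vector.
#' @return Character vector of predicted codons (always synonymous with the
#'   model's amino acid).
#' @export
predict_codon <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, names(features)))
  if (model$degenerate)
    return(rep(model$constant, nrow(features)))
  # predict from the vote matrix: predict()'s own vote-tie handling is
  # randomized, so resolve ties here, codon-lexicographically
  votes <- stats::predict(model$forest,
                          newdata = features[, model$feature_cols,
                                             drop = FALSE],
                          type = "vote")
  colnames(votes)[max.col(votes, ties.method = "first")]
}

#' Ten-fold cross-validation of a codon classifier
#'
#' Folds are stratified by label and assigned reproducibly from the spec's
#' seed; accuracy is the fraction of held-out positions whose predicted codon
#' equals the observed codon, averaged over folds.
#'
#' @param ts A `training_set`.
#' @param spec A `classifier_spec`.
#' @param folds Number of folds (default 10).
#' @return List with `accuracy` (mean over folds), `per_fold` (numeric),
#'   `n` (training-set size), and the spec fields.
#' @export
cross_validate <- function(ts, spec, folds = 10L) {
  n <- length(ts$labels)
  if (n < folds)
    stop("n = ", n, " < folds = ", folds, "; use fewer folds")
  set.seed(spec$seed)
  fold <- integer(n)
  for (lab in unique(ts$labels)) {
    idx <- which(ts$labels == lab)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    if (!any(test)) { per_fold[f] <- NA_real_; next }
    tr <- structure(list(features = ts$features[!test, , drop = FALSE],
                         labels = ts$labels[!test],
                         gene_ids = ts$gene_ids[!test],
                         fragments = ts$fragments[!test],
                         amino_acid = ts$amino_acid, window = ts$window,
                         cutoff = ts$cutoff),
                    class = "training_set")
    mdl <- train_classifier(tr, spec)
    pred <- predict_codon(mdl, ts$features[test, , drop = FALSE])
    per_fold[f] <- mean(pred == ts$labels[test])
  }
  list(amino_acid = spec$amino_acid, window = spec$window,
       cutoff = spec$cutoff, folds = folds,
       accuracy = mean(per_fold, na.rm = TRUE), per_fold = per_fold, n = n)
}

.model_key <- function(aa, window, cutoff) {
  sprintf("%s_w%d_c%s", aa, as.integer(window), format(cutoff))
}

# Deterministic per-cell seed below 2^31.
.cell_seed <- function(seed, aa, window, cutoff) {
  ai <- match(aa, AA_STANDARD)
  ci <- as.integer(round(cutoff * 100))
  (as.integer(seed) + 1000L * as.integer(window) + 7L * ci + 101L * ai) %% 2000000000L
}

#' Train the full classifier grid
#'
#' Trains one codon classifier per (degenerate amino acid x window x cutoff)
#' cell. The published grid (7 cut-offs, 2 windows, 18 amino acids) has
#' 7 x 2 x 18 = 252 slots. Cells whose training set is empty are recorded as
#' skipped; cells with a single observed codon get a constant predictor.
#'
#' @param corpus List of `coding_sequence` objects (the filtered training
#'   corpus).
#' @param windows Integer vector of odd window sizes (default `c(5, 7)`).
#' @param cutoffs Numeric vector of cut-offs (default the published grid
#'   `c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1)`).
#' @param n_trees Trees per forest (default 200; the published value is
#'   10,000).
#' @param seed Base seed; per-cell seeds are derived deterministically.
#' @param host_name Label stored with the bundle.
#' @return Object of class `classifier_bundle`: list with `host_name`,
#'   `models` (named by `aa_w<w>_c<c>`), `grid` (data frame with one row per
#'   slot: amino_acid, window, cutoff, n, n_skipped, status), `positional`
#'   (a `positional_codon_table`), `background` (`codon_usage_table`),
#'   `csis` (one `csi` per window, named `w<w>`), `windows`, `cutoffs`,
#'   `n_trees`, `seed`, `version`.
#' @export
train_grid <- function(corpus, windows = c(5L, 7L),
                       cutoffs = c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1),
                       n_trees = 200L, seed = 1L, host_name = "custom") {
  if (length(corpus) == 0L) stop("empty corpus")
  stopifnot(all(windows %% 2L == 1L), all(cutoffs > 0), all(cutoffs <= 1))
  code <- genetic_code()
  background <- usage_table_from_corpus(corpus)
  positional <- build_positional_tables(corpus, background)
  models <- list()
  grid <- list()
  csis <- list()
  for (w in as.integer(windows)) {
    csi <- build_csi(corpus, w, background)
    csis[[paste0("w", w)]] <- csi
    # gather all positions once per window
    frs <- lapply(corpus, function(g) {
      fr <- extract_fragments(g, w)
      fr <- fr[fr$degenerate, , drop = FALSE]
      if (nrow(fr)) fr$gene_id <- g$id
      fr
    })
    frs <- do.call(rbind, frs[vapply(frs, nrow, integer(1)) > 0L])
    for (aa in code$degenerate_aas) {
      sub <- frs[frs$middle_aa == aa, , drop = FALSE]
      uq <- if (nrow(sub)) sort(unique(sub$fragment)) else character(0)
      # score unique fragments once; reuse the pass matrix across cutoffs
      b <- csi$buckets[[aa]]
      sc <- NULL
      if (length(uq) && !is.null(b))
        sc <- .score_block(.encode_fragments(uq, w), b$frag_code, .matrix20())
      for (cutoff in cutoffs) {
        key <- .model_key(aa, w, cutoff)
        row <- list(amino_acid = aa, window = w, cutoff = cutoff,
                    n = 0L, n_skipped = nrow(sub), status = "skipped")
        if (!is.null(sc)) {
          pass <- .pass_matrix(sc$S, sc$m, cutoff)
          nm <- rowSums(pass)
          D <- b$counts / b$occurrences
          F <- (pass %*% cbind(D, b$pos_mean)) / nm
          colnames(F) <- c(colnames(b$counts), paste0("pos", seq_len(w)))
          ridx <- match(sub$fragment, uq)
          ok <- nm[ridx] > 0L
          if (any(ok)) {
            ts <- structure(list(features = F[ridx[ok], , drop = FALSE],
                                 labels = sub$middle_codon[ok],
                                 gene_ids = sub$gene_id[ok],
                                 fragments = sub$fragment[ok],
                                 amino_acid = aa, window = w, cutoff = cutoff),
                            class = "training_set",
                            skipped = sum(!ok))
            spec <- classifier_spec(aa, w, cutoff, n_trees = n_trees,
                                    seed = .cell_seed(seed, aa, w, cutoff))
            mdl <- train_classifier(ts, spec)
            models[[key]] <- mdl
            row$n <- length(ts$labels)
            row$n_skipped <- sum(!ok)
            row$status <- if (mdl$degenerate) "degenerate" else "trained"
          }
        }
        grid[[key]] <- as.data.frame(row, stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL
  if (length(models) == 0L) stop("no grid cell had training data")
  structure(list(host_name = host_name, models = models, grid = grid,
                 positional = positional, background = background,
                 csis = csis, windows = as.integer(windows),
                 cutoffs = cutoffs, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), version = "1"),
            class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat("<classifier_bundle>", x$host_name, "|", nrow(x$grid), "grid slots |",
      sum(x$grid$status != "skipped"), "models | windows",
      paste(x$windows, collapse = ","), "| cutoffs",
      paste(format(x$cutoffs), collapse = ","), "\n")
  invisible(x)
}

.BUNDLE_VERSION <- "1"

#' Save a classifier bundle to a directory
#'
#' Layout: `manifest.json` (host, grid, seeds, version), one serialized model
#' per grid cell under `models/`, one CSI text file per window under `csi/`,
#' plus `positional.tsv` and `background.tsv`.
#'
#' @param bundle A `classifier_bundle`.
#' @param path Directory to create/write.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  if (length(bundle$models) == 0L) stop("refusing to save an empty bundle")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "models"), showWarnings = FALSE)
  dir.create(file.path(path, "csi"), showWarnings = FALSE)
  manifest <- list(format = "syncodon-bundle", version = .BUNDLE_VERSION,
                   host_name = bundle$host_name,
                   windows = bundle$windows, cutoffs = bundle$cutoffs,
                   n_trees = bundle$n_trees, seed = bundle$seed,
                   model_keys = names(bundle$models),
                   grid = bundle$grid)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(bundle$models))
    saveRDS(bundle$models[[key]],
            file.path(path, "models", paste0(key, ".rds")))
  for (wn in names(bundle$csis))
    save_csi(bundle$csis[[wn]], file.path(path, "csi", paste0(wn, ".csi")))
  write_positional_tsv(bundle$positional, file.path(path, "positional.tsv"))
  bg <- data.frame(codon = names(bundle$background$counts),
                   count = unname(bundle$background$counts))
  utils::write.table(bg, file.path(path, "background.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a classifier bundle saved by [save_bundle()]
#'
#' @param path Bundle directory.
#' @return A `classifier_bundle`; predictions are identical to those of the
#'   bundle before saving. Errors on a missing manifest or version mismatch.
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a bundle directory (no manifest.json): ", path)
  manifest <- jsonlite::fromJSON(mf)
  if (!identical(manifest$format, "syncodon-bundle"))
    stop("not a syncodon bundle: ", path)
  if (!identical(as.character(manifest$version), .BUNDLE_VERSION))
    stop("unsupported bundle version '", manifest$version, "' (expected ",
         .BUNDLE_VERSION, ")")
  models <- list()
  for (key in manifest$model_keys)
    models[[key]] <- readRDS(file.path(path, "models", paste0(key, ".rds")))
  csis <- list()
  for (w in manifest$windows)
    csis[[paste0("w", w)]] <- load_csi(file.path(path, "csi",
                                                 paste0("w", w, ".csi")))
  bg <- utils::read.table(file.path(path, "background.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  background <- codon_usage_table(stats::setNames(bg$count, bg$codon))
  positional <- read_positional_tsv(file.path(path, "positional.tsv"))
  grid <- manifest$grid
  structure(list(host_name = manifest$host_name, models = models,
                 grid = grid, positional = positional,
                 background = background, csis = csis,
                 windows = as.integer(manifest$windows),
                 cutoffs = as.numeric(manifest$cutoffs),
                 n_trees = as.integer(manifest$n_trees),
                 seed = as.integer(manifest$seed),
                 version = as.character(manifest$version)),
            class = "classifier_bundle")
}
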