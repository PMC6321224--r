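# Synthetic CDS corpora with planted context-dependent codon-choice rules:
# known-answer inputs for every stage of the pipeline.

#' A planted context rule
#'
#' At every position holding `target_aa` whose neighbor at `offset` is
#' `trigger`, the generator emits `codon_if_trigger` with probability
#' `strength` and `codon_otherwise` with probability 1 - strength. Positions
#' without the trigger draw from the background usage. Strength 1 is a
#' deterministic rule; strength 0.5 carries no signal beyond a 50/50 split.
#'
#' @param target_aa Amino acid whose codon the rule governs (degenerate).
#' @param offset Nonzero context offset in residues (e.g. +1 = next residue).
#' @param trigger Amino acid that must occupy `position + offset`.
#' @param codon_if_trigger,codon_otherwise Synonymous codons of `target_aa`.
#' @param strength Probability in \[0.5, 1\] of emitting `codon_if_trigger`
#'   when the trigger is present.
#' @return Object of class `planted_rule`.
#' @export
planted_rule <- function(target_aa, offset, trigger, codon_if_trigger,
                         codon_otherwise, strength = 1) {
  code <- genetic_code()
  if (!target_aa %in% code$degenerate_aas)
    stop("target amino acid must be degenerate")
  syn <- codons_for(target_aa)
  stopifnot(codon_if_trigger %in% syn, codon_otherwise %in% syn,
            offset != 0, trigger %in% AA_STANDARD,
            strength >= 0.5, strength <= 1)
  structure(list(target_aa = target_aa, offset = as.integer(offset),
                 trigger = trigger, codon_if_trigger = codon_if_trigger,
                 codon_otherwise = codon_otherwise, strength = strength),
            class = "planted_rule")
}

#' Default non-uniform background codon usage
#'
#' Synthetic corpora need a background in which "rare codon" is meaningful,
#' so the default assigns each amino acid's codons geometrically decaying
#' weights with ratio 3/7 in codon-lexicographic order: a two-codon amino
#' acid gets 0.7/0.3, mirroring typical strong/weak synonymous bias.
#'
#' @return A `codon_usage_table`.
#' @export
default_background_usage <- function() {
  code <- genetic_code()
  counts <- numeric(0)
  for (aa in names(code$aa_to_codons)) {
    cods <- code$aa_to_codons[[aa]]
    w <- (3 / 7)^(seq_along(cods) - 1L)
    counts[cods] <- round(1e6 * w / sum(w))
  }
  codon_usage_table(counts)
}

#' Synthetic corpus configuration
#'
#' @param n_families Number of homolog families.
#' @param members_per_family Members per family (>= 3 exercises the corpus
#'   cluster-size filter end to end).
#' @param length_range Founder length range in codons (default 110-200, all
#'   above the 100-codon corpus filter).
#' @param rules List of [planted_rule()] objects.
#' @param background A `codon_usage_table` or `"default"` (see
#'   [default_background_usage()]) or `"uniform"`.
#' @param mutation_rate Per-residue substitution probability applied to each
#'   member relative to its family founder (default 0.075, giving roughly
#'   85% within-family pairwise identity).
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 30L, members_per_family = 5L,
                             length_range = c(110L, 200L), rules = list(),
                             background = "default", mutation_rate = 0.075,
                             seed = 1L) {
  stopifnot(n_families >= 1L, members_per_family >= 1L,
            length_range[1] >= 2L, length_range[2] >= length_range[1],
            mutation_rate >= 0, mutation_rate < 1)
  if (is.character(background)) {
    background <- switch(match.arg(background, c("default", "uniform")),
                         default = default_background_usage(),
                         uniform = codon_usage_table(stats::setNames(
                           rep(1, 61), names(genetic_code()$codon_to_aa))))
  }
  stopifnot(inherits(background, "codon_usage_table"))
  if (length(rules)) {
    stopifnot(all(vapply(rules, inherits, logical(1), "planted_rule")))
    key <- vapply(rules, function(r)
      paste(r$target_aa, r$offset, r$trigger), character(1))
    if (anyDuplicated(key))
      stop("contradictory rules: duplicate (amino acid, offset, trigger)")
  }
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 length_range = as.integer(length_range), rules = rules,
                 background = background, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# First rule (in list order) applying at position i of protein `chars`,
# or NULL.
.rule_at <- function(rules, chars, i) {
  for (r in rules) {
    j <- i + r$offset
    if (chars[i] == r$target_aa && j >= 1L && j <= length(chars) &&
        chars[j] == r$trigger)
      return(r)
  }
  NULL
}

#' Generate a synthetic CDS corpus with planted rules
#'
#' Family founder proteins start with Met and are otherwise uniform over the
#' 20 standard amino acids; members are founders with point substitutions at
#' `mutation_rate` (position 1 kept as Met). Codons are drawn from the
#' background usage except where a planted rule fires. Every rule-governed
#' position is recorded in the truth table.
#'
#' @param config A `synthetic_config`.
#' @return Object of class `synthetic_corpus`: list with `corpus` (list of
#'   `coding_sequence`), `truth` (data frame: gene_id, position, amino_acid,
#'   trigger, offset, rule_codon, strength, fired, codon), `founders`
#'   (protein strings) and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  code <- genetic_code()
  usage <- config$background$usage
  founders <- character(config$n_families)
  genes <- list()
  truth <- list()
  for (f in seq_len(config$n_families)) {
    len <- sample(config$length_range[1]:config$length_range[2], 1L)
    founder <- c("M", sample(AA_STANDARD, len - 1L, replace = TRUE))
    founders[f] <- paste(founder, collapse = "")
    for (m in seq_len(config$members_per_family)) {
      chars <- founder
      if (config$mutation_rate > 0) {
        mut <- which(stats::runif(len - 1L) < config$mutation_rate) + 1L
        for (i in mut)
          chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
      }
      id <- sprintf("fam%03d_m%02d", f, m)
      gene <- .assign_codons(chars, config$rules, usage, code)
      genes[[id]] <- coding_sequence(id, gene$codons)
      if (nrow(gene$truth)) {
        gene$truth$gene_id <- id
        truth[[length(truth) + 1L]] <- gene$truth
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(position = integer(0), amino_acid = character(0),
               trigger = character(0), offset = integer(0),
               rule_codon = character(0), strength = numeric(0),
               fired = logical(0), codon = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  truth <- truth[, c("gene_id", "position", "amino_acid", "trigger",
                     "offset", "rule_codon", "strength", "fired", "codon")]
  structure(list(corpus = unname(genes), truth = truth, founders = founders,
                 config = config),
            class = "synthetic_corpus")
}

# Assign codons to a protein under the background usage and planted rules.
.assign_codons <- function(chars, rules, usage, code) {
  n <- length(chars)
  codons <- character(n)
  # background draw, grouped by amino acid for speed
  for (aa in unique(chars)) {
    idx <- which(chars == aa)
    cods <- code$aa_to_codons[[aa]]
    codons[idx] <- if (length(cods) == 1L) cods else
      sample(cods, length(idx), replace = TRUE, prob = usage[cods])
  }
  truth <- list()
  if (length(rules)) {
    for (i in seq_len(n)) {
      r <- .rule_at(rules, chars, i)
      if (is.null(r)) next
      fired <- stats::runif(1L) < r$strength
      codons[i] <- if (fired) r$codon_if_trigger else r$codon_otherwise
      truth[[length(truth) + 1L]] <-
        data.frame(position = i, amino_acid = chars[i], trigger = r$trigger,
                   offset = r$offset, rule_codon = r$codon_if_trigger,
                   strength = r$strength, fired = fired, codon = codons[i],
                   stringsAsFactors = FALSE)
    }
  }
  list(codons = codons,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(position = integer(0), amino_acid = character(0),
                    trigger = character(0), offset = integer(0),
                    rule_codon = character(0), strength = numeric(0),
                    fired = logical(0), codon = character(0),
                    stringsAsFactors = FALSE))
}

#' Generate a held-out evaluation set from the same families
#'
#' Draws fresh members (new mutations, new codon assignments, same planted
#' rules) from the founders of an existing synthetic corpus, for held-out
#' evaluation of rule recovery.
#'
#' @param sc A `synthetic_corpus`.
#' @param members_per_family Members to draw per family.
#' @param seed Seed for the held-out draw (use a different seed than the
#'   training corpus).
#' @param mutation_rate Per-residue substitution rate for the held-out
#'   members; default the generator's own rate. `0` evaluates on the family
#'   founder ("wild-type") proteins themselves with fresh codon assignments —
#'   the method's natural query: a protein absent from the corpus whose
#'   homologs are in it.
#' @return A `synthetic_corpus` whose gene ids are prefixed `eval_`.
#' @export
generate_eval_set <- function(sc, members_per_family = 2L, seed = 2L,
                              mutation_rate = NULL) {
  stopifnot(inherits(sc, "synthetic_corpus"))
  config <- sc$config
  if (!is.null(mutation_rate)) config$mutation_rate <- mutation_rate
  set.seed(as.integer(seed))
  code <- genetic_code()
  usage <- config$background$usage
  genes <- list(); truth <- list()
  for (f in seq_along(sc$founders)) {
    founder <- strsplit(sc$founders[f], "", fixed = TRUE)[[1L]]
    len <- length(founder)
    for (m in seq_len(members_per_family)) {
      chars <- founder
      if (config$mutation_rate > 0) {
        mut <- which(stats::runif(len - 1L) < config$mutation_rate) + 1L
        for (i in mut)
          chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
      }
      id <- sprintf("eval_fam%03d_m%02d", f, m)
      gene <- .assign_codons(chars, config$rules, usage, code)
      genes[[id]] <- coding_sequence(id, gene$codons)
      if (nrow(gene$truth)) {
        gene$truth$gene_id <- id
        truth[[length(truth) + 1L]] <- gene$truth
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else sc$truth[0, ]
  if (nrow(truth))
    truth <- truth[, c("gene_id", "position", "amino_acid", "trigger",
                       "offset", "rule_codon", "strength", "fired", "codon")]
  structure(list(corpus = unname(genes), truth = truth,
                 founders = sc$founders, config = config),
            class = "synthetic_corpus")
}

#' Write the truth table of a synthetic corpus as TSV
#' @param sc A `synthetic_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sc, path) {
  utils::write.table(sc$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check truth-table consistency of a synthetic corpus
#'
#' Re-derives the rule-governed positions from the generated proteins and
#' verifies that the truth table lists exactly those positions with the
#' codons actually present in the genes.
#'
#' @param sc A `synthetic_corpus`.
#' @return `TRUE` invisibly; errors on any inconsistency.
#' @export
verify_truth <- function(sc) {
  rules <- sc$config$rules
  expected <- list()
  for (g in sc$corpus) {
    chars <- strsplit(g$protein, "", fixed = TRUE)[[1L]]
    for (i in seq_along(chars)) {
      if (!is.null(.rule_at(rules, chars, i)))
        expected[[length(expected) + 1L]] <-
          data.frame(gene_id = g$id, position = i, codon = g$codons[i],
                     stringsAsFactors = FALSE)
    }
  }
  expected <- if (length(expected)) do.call(rbind, expected) else
    data.frame(gene_id = character(0), position = integer(0),
               codon = character(0))
  got <- sc$truth[, c("gene_id", "position", "codon")]
  ord <- function(d) d[order(d$gene_id, d$position), , drop = FALSE]
  e <- ord(expected); o <- ord(got)
  rownames(e) <- rownames(o) <- NULL
  if (!identical(e, o)) stop("truth table inconsistent with generated genes")
  invisible(TRUE)
}

#' Evaluate planted-rule recovery of a trained bundle
#'
#' Designs the protein of every gene in a held-out synthetic set and
#' compares, at each rule-governed position, the designed codon with the
#' codon actually used in the held-out gene. The context-free baseline is
#' the accuracy of always choosing the background modal codon at those same
#' positions.
#'
#' @param bundle A `classifier_bundle` trained on a corpus from the same
#'   generator.
#' @param eval_set A `synthetic_corpus` (e.g. from [generate_eval_set()]).
#' @param config A `design_config`.
#' @return List with `recovery` (designed-codon accuracy at rule positions),
#'   `baseline` (modal-codon accuracy at the same positions), `n_positions`,
#'   and `by_source` (recovery split by design source). With an empty truth
#'   table, returns `n_positions = 0` and `NA` rates with a message.
#' @export
evaluate_recovery <- function(bundle, eval_set, config = design_config()) {
  stopifnot(inherits(eval_set, "synthetic_corpus"))
  truth <- eval_set$truth
  if (nrow(truth) == 0L) {
    message("no rule positions in evaluation set")
    return(list(recovery = NA_real_, baseline = NA_real_, n_positions = 0L,
                by_source = data.frame()))
  }
  designed <- character(nrow(truth))
  src <- character(nrow(truth))
  for (g in eval_set$corpus) {
    rows <- which(truth$gene_id == g$id)
    if (!length(rows)) next
    res <- design_gene(g$protein, bundle, config)
    designed[rows] <- res$per_position$codon[truth$position[rows]]
    src[rows] <- res$per_position$source[truth$position[rows]]
  }
  modal <- vapply(truth$amino_acid, modal_codon, character(1),
                  usage = bundle$background)
  hit <- designed == truth$codon
  by_source <- stats::aggregate(hit, by = list(source = src), FUN = mean)
  names(by_source)[2L] <- "recovery"
  by_source$n <- as.integer(table(src)[by_source$source])
  list(recovery = mean(hit),
       baseline = mean(modal == truth$codon),
       n_positions = nrow(truth),
       by_source = by_source)
}
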