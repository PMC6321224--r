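# Gene design: positional tables for gene termini, classifier-driven
# back-translation with a descending-cutoff cascade and usage fallback.

#' Positional codon tables for gene termini
#'
#' The windowed classifiers cannot cover the first and last two codons of a
#' gene, so those are designed from positional statistics: for each of the
#' four terminal slots (positions 1, 2, second-last, last) and each amino
#' acid observed there, the most frequently used codon at that slot across
#' the corpus (ties broken by higher background usage, then
#' codon-lexicographic).
#'
#' @param corpus List of `coding_sequence` objects.
#' @param background Optional `codon_usage_table` for tie-breaking; computed
#'   from the corpus if omitted.
#' @return Object of class `positional_codon_table`: list with `head`
#'   (slots `"1"`, `"2"`: named codon-per-amino-acid vectors), `tail` (slots
#'   `"n1"` = last, `"n2"` = second-last), and `counts` (long data frame of
#'   slot, amino acid, codon, count).
#' @export
build_positional_tables <- function(corpus, background = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(background)) background <- usage_table_from_corpus(corpus)
  code <- genetic_code()
  slot_codon <- list(`1` = character(0), `2` = character(0),
                     n2 = character(0), n1 = character(0))
  for (g in corpus) {
    n <- length(g$codons)
    slot_codon$`1` <- c(slot_codon$`1`, g$codons[1L])
    if (n >= 2L) slot_codon$`2` <- c(slot_codon$`2`, g$codons[2L])
    if (n >= 4L) {  # avoid double-counting termini of very short genes
      slot_codon$n2 <- c(slot_codon$n2, g$codons[n - 1L])
      slot_codon$n1 <- c(slot_codon$n1, g$codons[n])
    }
  }
  counts <- list()
  tabs <- list()
  for (slot in names(slot_codon)) {
    cods <- slot_codon[[slot]]
    if (!length(cods)) { tabs[[slot]] <- character(0); next }
    aas <- unname(code$codon_to_aa[cods])
    tb <- table(aas, cods)
    modal <- character(0)
    for (aa in rownames(tb)) {
      cand <- colnames(tb)[tb[aa, ] > 0]
      cnt <- tb[aa, cand]
      best <- cand[order(-cnt, -background$usage[cand], cand)][1L]
      modal[aa] <- best
      counts[[length(counts) + 1L]] <-
        data.frame(slot = slot, amino_acid = aa, codon = cand,
                   count = as.integer(cnt), stringsAsFactors = FALSE)
    }
    tabs[[slot]] <- modal
  }
  structure(list(head = list(`1` = tabs$`1`, `2` = tabs$`2`),
                 tail = list(n2 = tabs$n2, n1 = tabs$n1),
                 counts = do.call(rbind, counts)),
            class = "positional_codon_table")
}

#' Write a positional codon table as TSV
#' @param pt A `positional_codon_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positional_tsv <- function(pt, path) {
  utils::write.table(pt$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a positional codon table written by [write_positional_tsv()]
#' @param path TSV path.
#' @param background Optional `codon_usage_table` for modal tie-breaking.
#' @return A `positional_codon_table`.
#' @export
read_positional_tsv <- function(path, background = NULL) {
  counts <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (is.null(background))
    background <- codon_usage_table(stats::setNames(numeric(0), character(0)))
  tabs <- list()
  for (slot in c("1", "2", "n2", "n1")) {
    sub <- counts[counts$slot == slot, , drop = FALSE]
    modal <- character(0)
    for (aa in unique(sub$amino_acid)) {
      s2 <- sub[sub$amino_acid == aa, , drop = FALSE]
      modal[aa] <- s2$codon[order(-s2$count, -background$usage[s2$codon],
                                  s2$codon)][1L]
    }
    tabs[[slot]] <- modal
  }
  structure(list(head = list(`1` = tabs$`1`, `2` = tabs$`2`),
                 tail = list(n2 = tabs$n2, n1 = tabs$n1),
                 counts = counts),
            class = "positional_codon_table")
}

#' Design configuration
#'
#' @param window Window size used at design time (default 7; the validation
#'   of the classifier grid favors the longer window).
#' @param cutoff_cascade Strictly descending cut-offs tried in order at each
#'   interior position (default `c(0.9, 0.8, 0.7)`, preferring the
#'   higher-accuracy large-cutoff models); positions with no match at any
#'   cut-off fall back to the highest-background-usage codon.
#' @param fallback Fallback policy; only `"max-frequency-codon"` is defined.
#' @param append_stop Optional stop codon appended to designed genes (e.g.
#'   `"TAA"`); default none.
#' @param seed Reserved for future stochastic policies; the default design
#'   path is fully deterministic.
#' @return Object of class `design_config`.
#' @export
design_config <- function(window = 7L, cutoff_cascade = c(0.9, 0.8, 0.7),
                          fallback = "max-frequency-codon",
                          append_stop = NULL, seed = 1L) {
  stopifnot(window %% 2L == 1L, length(cutoff_cascade) >= 1L,
            all(cutoff_cascade > 0), all(cutoff_cascade <= 1))
  if (length(cutoff_cascade) > 1L && any(diff(cutoff_cascade) >= 0))
    stop("cutoff_cascade must be strictly descending")
  fallback <- match.arg(fallback, "max-frequency-codon")
  if (!is.null(append_stop))
    stopifnot(append_stop %in% genetic_code()$stop_codons)
  structure(list(window = as.integer(window),
                 cutoff_cascade = cutoff_cascade, fallback = fallback,
                 append_stop = append_stop, seed = as.integer(seed)),
            class = "design_config")
}

#' Back-translate a protein into a host-tuned gene
#'
#' Terminal positions (1, 2, second-last, last) take the modal codon from the
#' bundle's positional tables (falling back to the highest-usage codon when
#' the table has no entry for that amino acid at that slot). Met and Trp
#' positions emit ATG/TGG directly. Every other degenerate position with a
#' full window of context is predicted by the classifier cascade: the
#' `window`-residue fragment centered on the position is searched against the
#' bundle's CSI at each cascade cut-off in turn, and the first cut-off with
#' at least one match (and a trained model) supplies the prediction;
#' positions with no match at any cut-off, or without full window context,
#' use the background-usage fallback. The designed DNA always translates back
#' to the input protein.
#'
#' @param protein Amino-acid string (standard residues only).
#' @param bundle A `classifier_bundle`.
#' @param config A `design_config`; its window must be one of the bundle's.
#' @return Object of class `design_result`: list with `dna`, `per_position`
#'   (data frame: position, amino_acid, codon, source), `host`, `protein`.
#'   Sources are `non-degenerate`, `head-table`, `tail-table`,
#'   `model@<cutoff>`, `fallback`.
#' @export
design_gene <- function(protein, bundle, config = design_config()) {
  stopifnot(inherits(bundle, "classifier_bundle"),
            inherits(config, "design_config"))
  chars <- .check_residues(protein)
  n <- length(chars)
  csi <- bundle$csis[[paste0("w", config$window)]]
  if (is.null(csi))
    stop("bundle has no CSI for window ", config$window,
         " (available: ", paste(bundle$windows, collapse = ","), ")")
  code <- genetic_code()
  usage <- bundle$background
  codons <- character(n)
  source <- character(n)

  fallback_codon <- function(aa) modal_codon(aa, usage)

  # non-degenerate residues first
  nondeg <- !(chars %in% code$degenerate_aas)
  codons[nondeg] <- vapply(chars[nondeg], function(aa) codons_for(aa)[1L],
                           character(1))
  source[nondeg] <- "non-degenerate"

  # terminal slots
  head_pos <- seq_len(min(2L, n))
  tail_pos <- setdiff(c(n - 1L, n), head_pos)
  tail_pos <- tail_pos[tail_pos >= 1L]
  for (i in head_pos) {
    if (nondeg[i]) next
    tab <- bundle$positional$head[[as.character(i)]]
    hit <- tab[chars[i]]
    if (!is.null(tab) && !is.na(hit)) {
      codons[i] <- hit; source[i] <- "head-table"
    } else {
      codons[i] <- fallback_codon(chars[i]); source[i] <- "fallback"
    }
  }
  for (i in tail_pos) {
    if (nondeg[i]) next
    slot <- if (i == n) "n1" else "n2"
    tab <- bundle$positional$tail[[slot]]
    hit <- tab[chars[i]]
    if (!is.null(tab) && !is.na(hit)) {
      codons[i] <- hit; source[i] <- "tail-table"
    } else {
      codons[i] <- fallback_codon(chars[i]); source[i] <- "fallback"
    }
  }

  # interior degenerate positions
  h <- (config$window - 1L) %/% 2L
  interior <- setdiff(which(!nondeg), c(head_pos, tail_pos))
  full_win <- interior[(interior - h) >= 1L & (interior + h) <= n]
  no_win <- setdiff(interior, full_win)
  codons[no_win] <- vapply(chars[no_win], fallback_codon, character(1))
  source[no_win] <- "fallback"

  if (length(full_win)) {
    frags <- substring(protein, full_win - h, full_win + h)
    for (aa in unique(chars[full_win])) {
      pos <- full_win[chars[full_win] == aa]
      qfrags <- frags[chars[full_win] == aa]
      unresolved <- seq_along(pos)
      for (cutoff in config$cutoff_cascade) {
        if (!length(unresolved)) break
        mdl <- bundle$models[[.model_key(aa, config$window, cutoff)]]
        if (is.null(mdl)) next
        ff <- .features_for_queries(qfrags[unresolved], csi, cutoff, aa)
        got <- ff$n_matches > 0L
        if (any(got)) {
          pred <- predict_codon(mdl, ff$features[got, , drop = FALSE])
          idx <- pos[unresolved[got]]
          codons[idx] <- pred
          source[idx] <- paste0("model@", format(cutoff))
          unresolved <- unresolved[!got]
        }
      }
      if (length(unresolved)) {
        idx <- pos[unresolved]
        codons[idx] <- fallback_codon(aa)
        source[idx] <- "fallback"
      }
    }
  }

  stopifnot(all(nzchar(codons)),
            translate_codons(codons) == protein)  # round-trip invariant
  dna <- paste0(paste(codons, collapse = ""),
                if (is.null(config$append_stop)) "" else config$append_stop)
  structure(list(dna = dna,
                 per_position = data.frame(position = seq_len(n),
                                           amino_acid = chars,
                                           codon = codons, source = source,
                                           stringsAsFactors = FALSE),
                 host = bundle$host_name, protein = protein),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result>", nchar(x$protein), "aa | host", x$host, "\n")
  srcs <- table(x$per_position$source)
  for (s in names(srcs)) cat(" ", s, ":", srcs[[s]], "\n")
  invisible(x)
}

#' Per-position design report
#'
#' Summarizes a design: the per-position table, the fraction of positions by
#' codon source, and the predicted rare-codon positions (chosen codon whose
#' background relative usage is below 0.5/k, where k is the number of
#' synonymous codons of the amino acid).
#'
#' @param result A `design_result`.
#' @param background A `codon_usage_table` (the bundle's background) used for
#'   the rare-codon call.
#' @return List of class `design_report` with `per_position`, `summary`
#'   (data frame: source, n, fraction) and `rare_positions`.
#' @export
design_report <- function(result, background) {
  stopifnot(inherits(result, "design_result"))
  pp <- result$per_position
  tab <- table(pp$source)
  summary <- data.frame(source = names(tab), n = as.integer(tab),
                        fraction = as.numeric(tab) / nrow(pp),
                        stringsAsFactors = FALSE)
  k <- vapply(pp$amino_acid, function(a) length(codons_for(a)), integer(1))
  rare <- pp[background$usage[pp$codon] < 0.5 / k, , drop = FALSE]
  structure(list(per_position = pp, summary = summary,
                 rare_positions = rare),
            class = "design_report")
}

#' Design genes for a protein FASTA file
#'
#' Multi-record convenience wrapper: designs every record and optionally
#' writes the DNA FASTA and a combined per-position TSV report.
#'
#' @param protein_path Protein FASTA path.
#' @param bundle A `classifier_bundle`.
#' @param config A `design_config`.
#' @param out_fasta Optional output DNA FASTA path.
#' @param out_report Optional output TSV path (adds an `id` column).
#' @return Named list of `design_result` objects, invisibly.
#' @export
design_fasta <- function(protein_path, bundle, config = design_config(),
                         out_fasta = NULL, out_report = NULL) {
  set <- Biostrings::readAAStringSet(protein_path)
  if (length(set) == 0L) stop("no protein records in ", protein_path)
  ids <- sub("\\s.*$", "", names(set))
  results <- stats::setNames(vector("list", length(set)), ids)
  for (i in seq_along(set))
    results[[i]] <- design_gene(as.character(set[[i]]), bundle, config)
  if (!is.null(out_fasta)) {
    dna <- Biostrings::DNAStringSet(vapply(results, `[[`, character(1), "dna"))
    names(dna) <- ids
    Biostrings::writeXStringSet(dna, out_fasta)
  }
  if (!is.null(out_report)) {
    rep_df <- do.call(rbind, lapply(ids, function(id)
      cbind(id = id, results[[id]]$per_position)))
    utils::write.table(rep_df, out_report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(results)
}
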