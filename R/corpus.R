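# Corpus construction: CDS reading, validation, redundancy removal, filters.

#' A validated coding sequence
#'
#' @param id Record identifier.
#' @param codons Character vector of sense codons (no internal stop; a
#'   trailing stop, if present, must already have been dropped).
#' @return Object of class `coding_sequence` with fields `id`, `codons`,
#'   `protein` (cached translation).
#' @export
coding_sequence <- function(id, codons) {
  protein <- translate_codons(codons)
  structure(list(id = as.character(id), codons = unname(toupper(codons)),
                 protein = protein),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence>", x$id, "-", length(x$codons), "codons\n")
  invisible(x)
}

#' Corpus filter configuration
#'
#' Defaults follow the training-corpus filters of the method: genes longer
#' than 100 codons, redundancy removed at 40% protein identity, and only
#' clusters with at least three homologous members kept (which discards
#' singletons such as likely horizontal-transfer genes).
#'
#' @param min_codons Genes must have strictly more than this many sense
#'   codons (default 100).
#' @param identity_threshold Fraction in (0, 1]; two proteins above this
#'   global identity are redundant (default 0.40).
#' @param min_cluster_size Minimum homolog-cluster size to keep (default 3).
#' @return Object of class `corpus_config`.
#' @export
corpus_config <- function(min_codons = 100L, identity_threshold = 0.40,
                          min_cluster_size = 3L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_cluster_size >= 1L, min_codons >= 1L)
  structure(list(min_codons = as.integer(min_codons),
                 identity_threshold = identity_threshold,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "corpus_config")
}

.validate_cds_record <- function(id, seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    return(list(ok = FALSE, reason = "ambiguity or non-ACGT character"))
  if (nchar(seq) %% 3L != 0L)
    return(list(ok = FALSE, reason = "length not divisible by 3"))
  if (nchar(seq) < 3L)
    return(list(ok = FALSE, reason = "empty sequence"))
  codons <- split_codons(seq)
  code <- genetic_code()
  is_stop <- codons %in% code$stop_codons
  if (is_stop[length(codons)]) {
    codons <- codons[-length(codons)]
    is_stop <- is_stop[-length(is_stop)]
  }
  if (length(codons) == 0L)
    return(list(ok = FALSE, reason = "only a stop codon"))
  if (any(is_stop))
    return(list(ok = FALSE, reason = paste0("internal stop codon at position ",
                                            which(is_stop)[1L])))
  list(ok = TRUE, cs = coding_sequence(id, codons))
}

#' Read coding sequences from a nucleotide FASTA file
#'
#' Each record is split into codons and validated: records whose length is
#' not a multiple of 3, that contain ambiguity characters, or that contain an
#' internal stop codon are skipped with a reason; a trailing stop codon is
#' dropped. A summary of rejections is attached as the `rejected` attribute
#' (a data frame of id and reason) and reported via `message()`.
#'
#' @param path Path to a (optionally gzipped) multi-FASTA nucleotide file.
#' @return List of `coding_sequence` objects.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  rej_id <- character(0); rej_reason <- character(0)
  for (i in seq_along(set)) {
    v <- .validate_cds_record(ids[i], as.character(set[[i]]))
    if (v$ok) {
      out[[i]] <- v$cs
    } else {
      rej_id <- c(rej_id, ids[i]); rej_reason <- c(rej_reason, v$reason)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    stop("no valid coding sequences in ", path, " (", length(rej_id),
         " rejected)")
  if (length(rej_id))
    message(length(rej_id), " of ", length(set), " records rejected")
  attr(out, "rejected") <- data.frame(id = rej_id, reason = rej_reason,
                                      stringsAsFactors = FALSE)
  out
}

#' Write coding sequences as a nucleotide FASTA file
#'
#' @param corpus List of `coding_sequence` objects.
#' @param path Output path.
#' @param append_stop Optional stop codon to append to every record (e.g.
#'   `"TAA"`); `NULL` writes sense codons only.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(corpus, path, append_stop = NULL) {
  if (!is.null(append_stop))
    stopifnot(append_stop %in% genetic_code()$stop_codons)
  seqs <- vapply(corpus, function(g)
    paste0(paste(g$codons, collapse = ""), if (is.null(append_stop)) "" else append_stop),
    character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- vapply(corpus, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Global-identity greedy clustering of protein sequences
#'
#' Greedy longest-first clustering in the style of CD-HIT: sequences are
#' sorted by length descending (ties by id, lexicographic); each sequence
#' joins the first existing cluster whose founder (representative) shares
#' strictly more than `threshold` global identity with it, otherwise it
#' founds a new cluster. Identity is matches / alignment length (PID1) of a
#' Needleman-Wunsch global alignment under BLOSUM62 with gap open 10 /
#' extend 1. Deterministic for a given input.
#'
#' @param proteins Character vector of protein sequences.
#' @param threshold Identity fraction in (0, 1]; default 0.40.
#' @param ids Optional identifiers (default names of `proteins`, else
#'   positional).
#' @return A list with `cluster` (integer cluster index per input, in input
#'   order, named by id) and `representatives` (id of each cluster's founder,
#'   by cluster index).
#' @export
cluster_by_identity <- function(proteins, threshold = 0.40, ids = NULL) {
  if (length(proteins) == 0L) stop("no sequences to cluster")
  if (is.null(ids)) ids <- names(proteins)
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_along(proteins))
  stopifnot(length(ids) == length(proteins), !anyDuplicated(ids))
  ord <- order(-nchar(proteins), ids)
  assign <- integer(length(proteins))
  rep_seq <- character(0)
  rep_idx <- integer(0)
  for (i in ord) {
    k <- 0L
    if (length(rep_seq)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep_seq), Biostrings::AAString(proteins[i]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
        type = "global")
      pids <- Biostrings::pid(aln, type = "PID1") / 100
      hit <- which(pids > threshold)
      if (length(hit)) k <- hit[1L]
    }
    if (k == 0L) {
      rep_seq <- c(rep_seq, proteins[i])
      rep_idx <- c(rep_idx, i)
      k <- length(rep_seq)
    }
    assign[i] <- k
  }
  list(cluster = stats::setNames(assign, ids),
       representatives = ids[rep_idx])
}

#' Build a non-redundant training corpus
#'
#' Applies the corpus filters in order: (1) drop genes with `min_codons` or
#' fewer sense codons; (2) cluster the remainder by protein identity at
#' `identity_threshold`; (3) keep only clusters with at least
#' `min_cluster_size` members; (4) return one representative per kept
#' cluster (the founder: longest member, ties by lexicographic id). A
#' stage-by-stage attrition table is attached as the `attrition` attribute.
#'
#' @param raw List of `coding_sequence` objects.
#' @param config A `corpus_config`.
#' @return List of `coding_sequence` representatives.
#' @export
build_corpus <- function(raw, config = corpus_config()) {
  if (length(raw) == 0L) stop("empty input gene list")
  n_in <- length(raw)
  keep <- vapply(raw, function(g) length(g$codons) > config$min_codons, logical(1))
  long <- raw[keep]
  attrition <- data.frame(stage = "length_filter", in_count = n_in,
                          out_count = length(long), stringsAsFactors = FALSE)
  if (length(long) == 0L)
    stop("no genes longer than ", config$min_codons, " codons\n",
         paste(utils::capture.output(print(attrition)), collapse = "\n"))
  prots <- vapply(long, `[[`, character(1), "protein")
  ids <- vapply(long, `[[`, character(1), "id")
  cl <- cluster_by_identity(prots, config$identity_threshold, ids = ids)
  sizes <- table(cl$cluster)
  attrition <- rbind(attrition, data.frame(
    stage = "clustering", in_count = length(long), out_count = length(sizes)))
  keep_cl <- as.integer(names(sizes)[sizes >= config$min_cluster_size])
  attrition <- rbind(attrition, data.frame(
    stage = "cluster_size_filter", in_count = length(sizes),
    out_count = length(keep_cl)))
  rep_ids <- cl$representatives[keep_cl]
  out <- long[match(rep_ids, ids)]
  attrition <- rbind(attrition, data.frame(
    stage = "representatives", in_count = length(keep_cl),
    out_count = length(out)))
  if (length(out) == 0L)
    stop("corpus empty after filtering:\n",
         paste(utils::capture.output(print(attrition)), collapse = "\n"))
  attr(out, "attrition") <- attrition
  attr(out, "clusters") <- cl
  out
}

#' Write a corpus attrition report as TSV
#'
#' @param corpus Result of [build_corpus()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attrition_tsv <- function(corpus, path) {
  att <- attr(corpus, "attrition")
  if (is.null(att)) stop("corpus has no attrition attribute")
  utils::write.table(att, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
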