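# Standard genetic code and codon-usage tables.

.syncodon_env <- new.env(parent = emptyenv())

#' The 20 standard amino acids (one-letter codes)
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Standard genetic code
#'
#' Returns the standard genetic code (NCBI translation table 1) as the
#' package's core lookup structure: 61 sense codons, 3 stop codons, and the
#' degeneracy structure over the 20 standard amino acids. Of the 20, 18 are
#' encoded by two or more synonymous codons; Met (ATG) and Trp (TGG) are the
#' two single-codon exceptions.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector, 61 sense codons), `stop_codons`
#'   (character vector of 3), `aa_to_codons` (list mapping each amino acid to
#'   its codons, codon-lexicographic order), and `degenerate_aas` (the 18
#'   amino acids with at least two synonymous codons).
#' @examples
#' code <- genetic_code()
#' length(code$codon_to_aa)    # 61
#' length(code$degenerate_aas) # 18
#' @export
genetic_code <- function() {
  if (!is.null(.syncodon_env$code)) return(.syncodon_env$code)
  tab <- Biostrings::GENETIC_CODE
  stops <- sort(names(tab)[tab == "*"])
  sense <- tab[tab != "*"]
  sense <- sense[order(names(sense))]
  aa_to_codons <- split(names(sense), sense)
  aa_to_codons <- lapply(aa_to_codons, sort)
  code <- structure(
    list(
      codon_to_aa = sense,
      stop_codons = stops,
      aa_to_codons = aa_to_codons,
      degenerate_aas = sort(names(aa_to_codons)[lengths(aa_to_codons) >= 2L])
    ),
    class = "genetic_code"
  )
  stopifnot(length(code$codon_to_aa) == 61L,
            length(code$stop_codons) == 3L,
            length(code$degenerate_aas) == 18L)
  .syncodon_env$code <- code
  code
}

#' Synonymous codons of an amino acid
#'
#' @param aa One-letter amino-acid code.
#' @param code A `genetic_code` object.
#' @return Character vector of codons in codon-lexicographic order.
#' @export
codons_for <- function(aa, code = genetic_code()) {
  out <- code$aa_to_codons[[aa]]
  if (is.null(out)) stop("unknown amino acid: ", aa)
  out
}

#' Split a nucleotide string into codons
#'
#' @param dna A single DNA string whose length is a multiple of 3.
#' @return Character vector of 3-letter codons.
#' @export
split_codons <- function(dna) {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a codon sequence to protein
#'
#' Translates a vector of sense codons under the standard genetic code. A
#' single trailing stop codon is permitted and dropped; an internal stop
#' codon or an unrecognized codon is an error that reports the offending
#' codon position.
#'
#' @param codons Character vector of 3-letter codons, or a single nucleotide
#'   string (split into codons first).
#' @param code A `genetic_code` object.
#' @return Amino-acid string of length `length(codons)` minus any trailing
#'   stop.
#' @examples
#' translate_codons(c("ATG", "AAA", "TAA")) # "MK"
#' @export
translate_codons <- function(codons, code = genetic_code()) {
  if (length(codons) == 1L && nchar(codons) > 3L) codons <- split_codons(codons)
  codons <- toupper(codons)
  if (length(codons) == 0L) stop("no codons to translate")
  is_stop <- codons %in% code$stop_codons
  if (any(is_stop)) {
    first <- which(is_stop)[1L]
    if (first != length(codons) || sum(is_stop) > 1L)
      stop("internal stop codon '", codons[first], "' at codon position ", first)
    codons <- codons[-length(codons)]
    if (length(codons) == 0L) stop("sequence contains only a stop codon")
  }
  aa <- code$codon_to_aa[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("unknown codon '", codons[bad], "' at codon position ", bad)
  }
  paste(aa, collapse = "")
}

#' Construct a codon usage table from codon counts
#'
#' Relative synonymous frequency is per-amino-acid: the count of a codon
#' divided by the summed counts of all codons synonymous with it, so the
#' frequencies of each amino acid's codons sum to 1. An amino acid with no
#' observations gets a uniform distribution over its codons (and is recorded
#' in the `unseen` attribute).
#'
#' @param counts Named numeric vector of nonnegative codon counts; names are
#'   sense codons (missing codons count 0).
#' @return An object of class `codon_usage_table` with elements `usage`
#'   (named numeric over all 61 sense codons) and `counts`.
#' @export
codon_usage_table <- function(counts) {
  code <- genetic_code()
  all_codons <- names(code$codon_to_aa)
  full <- stats::setNames(numeric(length(all_codons)), all_codons)
  if (length(counts)) {
    bad <- setdiff(names(counts), all_codons)
    if (length(bad)) stop("not a sense codon: ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("negative codon count")
    full[names(counts)] <- as.numeric(counts)
  }
  usage <- full
  unseen <- character(0)
  for (aa in names(code$aa_to_codons)) {
    cods <- code$aa_to_codons[[aa]]
    tot <- sum(full[cods])
    if (tot > 0) {
      usage[cods] <- full[cods] / tot
    } else {
      usage[cods] <- 1 / length(cods)
      unseen <- c(unseen, aa)
    }
  }
  structure(list(usage = usage, counts = full),
            class = "codon_usage_table", unseen = unseen)
}

#' Codon usage of a coding-sequence corpus
#'
#' Counts every sense codon across all sequences and normalizes per amino
#' acid (see [codon_usage_table()]).
#'
#' @param corpus List of `coding_sequence` objects.
#' @return A `codon_usage_table`.
#' @export
usage_table_from_corpus <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  tab <- table(unlist(lapply(corpus, function(g) g$codons), use.names = FALSE))
  codon_usage_table(stats::setNames(as.numeric(tab), names(tab)))
}

#' Modal (highest-usage) codon of an amino acid
#'
#' Ties broken codon-lexicographically for determinism.
#'
#' @param aa One-letter amino-acid code.
#' @param usage A `codon_usage_table`.
#' @return A single codon.
#' @export
modal_codon <- function(aa, usage) {
  cods <- codons_for(aa)
  u <- usage$usage[cods]
  cods[which.max(u)]  # which.max takes the first (lexicographic) maximum
}
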