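# Codon selection index: per-fragment middle-codon distributions and
# per-position mean codon usage.

#' Extract sliding peptide windows from a gene
#'
#' Slides a window of `window` codons (stride 1) along a coding sequence and
#' reports, for every position, the peptide fragment, the codon of the middle
#' residue, and whether the middle residue is degenerate (Met and Trp carry
#' no codon choice and are excluded from CSI accumulation, but still counted
#' here for reporting).
#'
#' @param gene A `coding_sequence`.
#' @param window Odd window size in codons (5 or 7 in the standard grids).
#' @return A data frame with one row per window position: `start`,
#'   `fragment`, `middle_aa`, `middle_codon`, `degenerate`. A gene shorter
#'   than the window yields a zero-row data frame.
#' @export
extract_fragments <- function(gene, window) {
  stopifnot(inherits(gene, "coding_sequence"),
            window %% 2L == 1L, window >= 3L)
  n <- length(gene$codons)
  if (n < window) {
    return(data.frame(start = integer(0), fragment = character(0),
                      middle_aa = character(0), middle_codon = character(0),
                      degenerate = logical(0), stringsAsFactors = FALSE))
  }
  h <- (window - 1L) %/% 2L
  starts <- seq_len(n - window + 1L)
  mids <- starts + h
  frags <- substring(gene$protein, starts, starts + window - 1L)
  mid_aa <- substring(gene$protein, mids, mids)
  code <- genetic_code()
  data.frame(start = starts, fragment = frags, middle_aa = mid_aa,
             middle_codon = gene$codons[mids],
             degenerate = mid_aa %in% code$degenerate_aas,
             stringsAsFactors = FALSE)
}

# Encode peptide fragments as an integer matrix (rows = fragments, cols =
# window positions, values = index into AA_STANDARD). Errors on residues
# outside the 20 standard amino acids.
.encode_fragments <- function(fragments, window) {
  if (length(fragments) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = window))
  chars <- matrix(unlist(strsplit(fragments, "", fixed = TRUE), use.names = FALSE),
                  ncol = window, byrow = TRUE)
  idx <- match(chars, AA_STANDARD)
  if (anyNA(idx)) {
    bad <- chars[which(is.na(idx))[1L]]
    stop("non-standard amino acid '", bad, "' in fragment")
  }
  matrix(idx, ncol = window)
}

#' Build a codon selection index from a corpus
#'
#' For every distinct peptide fragment of `window` residues whose middle
#' residue is degenerate, accumulates (i) the observed codon counts of the
#' middle residue and (ii) the mean background relative usage of the codons
#' observed at each of the `window` positions, averaged over the fragment's
#' occurrences. The background codon-usage table is computed from the same
#' corpus unless supplied.
#'
#' @param corpus List of `coding_sequence` objects.
#' @param window Odd window size (default grids use 5 and 7).
#' @param background Optional `codon_usage_table`; default is
#'   [usage_table_from_corpus()] of `corpus`.
#' @return An object of class `csi`: list with `window`, `n_genes`,
#'   `background`, `n_positions` (total degenerate-middle window positions),
#'   and `buckets` — one entry per middle amino acid holding parallel,
#'   fragment-sorted structures: `fragments`, `occurrences`, `counts` (matrix
#'   of middle-codon counts, columns = the amino acid's codons), `pos_mean`
#'   (matrix of per-position mean usage), `frag_code` (integer-encoded
#'   fragments used by the matcher).
#' @export
build_csi <- function(corpus, window = 7L, background = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  stopifnot(window %% 2L == 1L, window >= 3L)
  if (is.null(background)) background <- usage_table_from_corpus(corpus)
  code <- genetic_code()

  frag_all <- character(0); mid_codon_all <- character(0)
  mid_aa_all <- character(0)
  usage_rows <- vector("list", length(corpus))
  n_used <- 0L
  for (gi in seq_along(corpus)) {
    gene <- corpus[[gi]]
    fr <- extract_fragments(gene, window)
    fr <- fr[fr$degenerate, , drop = FALSE]
    if (nrow(fr) == 0L) next
    n_used <- n_used + 1L
    # per-position observed-codon usage, one row per window position
    u <- background$usage[gene$codons]
    um <- vapply(seq_len(window),
                 function(j) u[fr$start + j - 1L],
                 numeric(nrow(fr)))
    if (nrow(fr) == 1L) um <- matrix(um, nrow = 1L)
    usage_rows[[gi]] <- um
    frag_all <- c(frag_all, fr$fragment)
    mid_codon_all <- c(mid_codon_all, fr$middle_codon)
    mid_aa_all <- c(mid_aa_all, fr$middle_aa)
  }
  if (length(frag_all) == 0L)
    stop("no degenerate-middle window positions in corpus (window ", window, ")")
  U <- do.call(rbind, usage_rows[!vapply(usage_rows, is.null, logical(1))])

  buckets <- list()
  for (aa in code$degenerate_aas) {
    sel <- mid_aa_all == aa
    if (!any(sel)) next
    f <- frag_all[sel]
    cods <- code$aa_to_codons[[aa]]
    ff <- factor(f)                      # levels sorted: fragment-lexicographic
    occ <- as.integer(table(ff))
    counts <- table(ff, factor(mid_codon_all[sel], levels = cods))
    counts <- matrix(as.integer(counts), nrow = nlevels(ff),
                     dimnames = list(NULL, cods))
    pm <- rowsum(U[sel, , drop = FALSE], ff) / occ
    frags <- levels(ff)
    buckets[[aa]] <- list(fragments = frags,
                          occurrences = occ,
                          counts = counts,
                          pos_mean = unname(pm),
                          frag_code = .encode_fragments(frags, window))
  }
  structure(list(window = as.integer(window), n_genes = length(corpus),
                 background = background,
                 n_positions = length(frag_all),
                 buckets = buckets),
            class = "csi")
}

#' @export
print.csi <- function(x, ...) {
  cat("<csi> window =", x$window, "| genes =", x$n_genes,
      "| entries =", csi_n_entries(x),
      "| positions =", x$n_positions, "\n")
  invisible(x)
}

#' Number of distinct fragments in a CSI
#' @param csi A `csi` object.
#' @return Integer count of entries.
#' @export
csi_n_entries <- function(csi) {
  sum(vapply(csi$buckets, function(b) length(b$fragments), integer(1)))
}

#' Look up one CSI entry
#'
#' @param csi A `csi` object.
#' @param fragment Peptide fragment of length `csi$window`.
#' @return `NULL` if absent, else a list with `fragment`, `occurrences`,
#'   `middle_codon_counts` (named, the middle amino acid's codons) and
#'   `position_mean_usage` (numeric of length `window`).
#' @export
csi_entry <- function(csi, fragment) {
  h <- (csi$window + 1L) %/% 2L
  aa <- substring(fragment, h, h)
  b <- csi$buckets[[aa]]
  if (is.null(b)) return(NULL)
  i <- match(fragment, b$fragments)
  if (is.na(i)) return(NULL)
  list(fragment = fragment,
       occurrences = b$occurrences[i],
       middle_codon_counts = stats::setNames(b$counts[i, ], colnames(b$counts)),
       position_mean_usage = b$pos_mean[i, ])
}

#' Merge two codon selection indices
#'
#' Count-additive merge of CSIs built with the same window and background:
#' building a CSI on the concatenation of two corpora equals merging the two
#' CSIs (occurrence-weighted means for the per-position usage).
#'
#' @param a,b `csi` objects with identical `window` and background usage.
#' @return Merged `csi`.
#' @export
merge_csi <- function(a, b) {
  stopifnot(inherits(a, "csi"), inherits(b, "csi"), a$window == b$window)
  if (max(abs(a$background$usage - b$background$usage)) > 1e-12)
    stop("cannot merge CSIs with different background usage tables")
  code <- genetic_code()
  buckets <- list()
  for (aa in code$degenerate_aas) {
    ba <- a$buckets[[aa]]; bb <- b$buckets[[aa]]
    if (is.null(ba) && is.null(bb)) next
    if (is.null(ba)) { buckets[[aa]] <- bb; next }
    if (is.null(bb)) { buckets[[aa]] <- ba; next }
    frags <- sort(unique(c(ba$fragments, bb$fragments)))
    ia <- match(frags, ba$fragments); ib <- match(frags, bb$fragments)
    occ_a <- ifelse(is.na(ia), 0L, ba$occurrences[pmax(ia, 1L)])
    occ_b <- ifelse(is.na(ib), 0L, bb$occurrences[pmax(ib, 1L)])
    k <- ncol(ba$counts); w <- a$window
    cts <- matrix(0L, length(frags), k, dimnames = list(NULL, colnames(ba$counts)))
    pm <- matrix(0, length(frags), w)
    ok_a <- !is.na(ia)
    cts[ok_a, ] <- cts[ok_a, ] + ba$counts[ia[ok_a], , drop = FALSE]
    pm[ok_a, ] <- pm[ok_a, ] + ba$pos_mean[ia[ok_a], , drop = FALSE] * occ_a[ok_a]
    ok_b <- !is.na(ib)
    cts[ok_b, ] <- cts[ok_b, ] + bb$counts[ib[ok_b], , drop = FALSE]
    pm[ok_b, ] <- pm[ok_b, ] + bb$pos_mean[ib[ok_b], , drop = FALSE] * occ_b[ok_b]
    occ <- occ_a + occ_b
    buckets[[aa]] <- list(fragments = frags, occurrences = as.integer(occ),
                          counts = cts, pos_mean = pm / occ,
                          frag_code = .encode_fragments(frags, a$window))
  }
  structure(list(window = a$window, n_genes = a$n_genes + b$n_genes,
                 background = a$background,
                 n_positions = a$n_positions + b$n_positions,
                 buckets = buckets),
            class = "csi")
}

#' Size of the full fragment space
#'
#' The number of distinct peptide fragments of a given window size whose
#' middle residue is degenerate: `n_degenerate * alphabet^(window - 1)`
#' (the middle position is constrained to the 18 degenerate amino acids; the
#' remaining `window - 1` context positions range over the full alphabet).
#' For windows 5 and 7 this is 2,880,000 and 1,152,000,000.
#'
#' @param window Odd window size.
#' @param n_degenerate Number of degenerate amino acids (18 in the standard
#'   code).
#' @param alphabet Amino-acid alphabet size (20).
#' @return Numeric count.
#' @export
fragment_space_size <- function(window, n_degenerate = 18, alphabet = 20) {
  stopifnot(window %% 2 == 1, window >= 3)
  n_degenerate * alphabet^(window - 1)
}

.CSI_MAGIC <- "#syncodon-csi"
.CSI_VERSION <- "v1"

#' Save a codon selection index to a text file
#'
#' Versioned text format: a magic/version header
#' `#syncodon-csi v1 window=<w> genes=<n> positions=<p>`, a second header
#' line carrying the background codon counts as JSON, then one TSV row per
#' fragment (fragment-lexicographic order): fragment, occurrences,
#' middle-codon counts as comma-separated `codon:count` pairs
#' (codon-lexicographic), and the `window` per-position mean usage values
#' (6 decimal places, comma-separated). Byte-stable across platforms.
#'
#' @param csi A `csi` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_csi <- function(csi, path) {
  stopifnot(inherits(csi, "csi"))
  header <- sprintf("%s %s window=%d genes=%d positions=%d",
                    .CSI_MAGIC, .CSI_VERSION, csi$window, csi$n_genes,
                    csi$n_positions)
  bg <- sprintf("#background %s",
                jsonlite::toJSON(as.list(csi$background$counts),
                                 auto_unbox = TRUE, digits = NA))
  rows <- character(0)
  for (aa in names(csi$buckets)) {
    b <- csi$buckets[[aa]]
    cods <- colnames(b$counts)
    pairs <- apply(b$counts, 1L, function(r)
      paste(sprintf("%s:%d", cods, r), collapse = ","))
    means <- apply(b$pos_mean, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = ","))
    rows <- c(rows, paste(b$fragments, b$occurrences, pairs, means, sep = "\t"))
  }
  rows <- rows[order(sub("\t.*$", "", rows))]
  writeLines(c(header, bg, rows), path)
  invisible(path)
}

#' Load a codon selection index saved by [save_csi()]
#'
#' @param path Path to a CSI file.
#' @return A `csi` object. Errors on a wrong magic string or format version.
#' @export
load_csi <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated CSI file: ", path)
  head1 <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  if (length(head1) < 4L || head1[1L] != .CSI_MAGIC)
    stop("not a CSI file (bad magic): ", path)
  if (head1[2L] != .CSI_VERSION)
    stop("unsupported CSI version '", head1[2L], "' (expected ",
         .CSI_VERSION, ")")
  kv <- function(key) {
    m <- grep(paste0("^", key, "="), head1, value = TRUE)
    as.integer(sub(paste0(key, "="), "", m[1L]))
  }
  window <- kv("window"); n_genes <- kv("genes"); n_pos <- kv("positions")
  if (!startsWith(lines[2L], "#background "))
    stop("missing background header in CSI file")
  bg_counts <- unlist(jsonlite::fromJSON(sub("^#background ", "", lines[2L])))
  background <- codon_usage_table(bg_counts)

  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  frag <- vapply(parts, `[[`, character(1), 1L)
  occ <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ctxt <- vapply(parts, `[[`, character(1), 3L)
  mtxt <- vapply(parts, `[[`, character(1), 4L)
  h <- (window + 1L) %/% 2L
  mid_aa <- substring(frag, h, h)
  code <- genetic_code()
  buckets <- list()
  for (aa in code$degenerate_aas) {
    sel <- which(mid_aa == aa)
    if (!length(sel)) next
    cods <- code$aa_to_codons[[aa]]
    cts <- matrix(0L, length(sel), length(cods),
                  dimnames = list(NULL, cods))
    for (r in seq_along(sel)) {
      pp <- strsplit(strsplit(ctxt[sel[r]], ",", fixed = TRUE)[[1L]],
                     ":", fixed = TRUE)
      for (p in pp) cts[r, p[1L]] <- as.integer(p[2L])
    }
    pm <- t(vapply(strsplit(mtxt[sel], ",", fixed = TRUE),
                   function(v) as.numeric(v), numeric(window)))
    ord <- order(frag[sel])
    buckets[[aa]] <- list(fragments = frag[sel][ord],
                          occurrences = occ[sel][ord],
                          counts = cts[ord, , drop = FALSE],
                          pos_mean = pm[ord, , drop = FALSE],
                          frag_code = .encode_fragments(frag[sel][ord], window))
  }
  structure(list(window = window, n_genes = n_genes, background = background,
                 n_positions = n_pos, buckets = buckets),
            class = "csi")
}
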