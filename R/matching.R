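# Fragment scoring against the CSI: matched score s, self score m,
# matched percent p = s/m; feature-vector assembly.

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comments, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1L]), integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

#' Bundled BLOSUM62 matrix
#'
#' The BLOSUM62 substitution matrix shipped with the package in NCBI text
#' format, parsed once and cached.
#'
#' @return Integer matrix including the 20 standard residues.
#' @export
blosum62 <- function() {
  if (!is.null(.syncodon_env$blosum62)) return(.syncodon_env$blosum62)
  path <- system.file("extdata", "BLOSUM62.txt", package = "syncodon",
                      mustWork = TRUE)
  m <- read_substitution_matrix(path)
  .syncodon_env$blosum62 <- m
  m
}

# 20x20 submatrix over AA_STANDARD, for integer-coded scoring.
.matrix20 <- function(matrix = blosum62()) {
  missing <- setdiff(AA_STANDARD, rownames(matrix))
  if (length(missing))
    stop("substitution matrix lacks residues: ", paste(missing, collapse = ", "))
  matrix[AA_STANDARD, AA_STANDARD]
}

#' Match configuration for CSI searches
#'
#' @param cutoff Matched-percent cut-off c in (0, 1]. The standard grid uses
#'   0.7, 0.75, 0.8, 0.85, 0.9, 0.95 and 1. A fragment passes when p = s/m
#'   exceeds the cut-off; exact matches (p = 1) always pass, so c = 1 selects
#'   exact fragment matches only.
#' @param substitution_matrix Matrix name (`"BLOSUM62"`) or an integer matrix
#'   as returned by [read_substitution_matrix()].
#' @param require_middle_identity Restrict candidates to CSI entries whose
#'   middle residue equals the query's (default `TRUE`; the middle residue
#'   defines the codon alphabet being predicted).
#' @return Object of class `match_config`.
#' @export
match_config <- function(cutoff = 0.7, substitution_matrix = "BLOSUM62",
                         require_middle_identity = TRUE) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (is.character(substitution_matrix)) {
    if (toupper(substitution_matrix) != "BLOSUM62")
      stop("unknown matrix name: ", substitution_matrix,
           " (pass a parsed matrix for other matrices)")
    substitution_matrix <- blosum62()
  }
  structure(list(cutoff = cutoff, matrix = substitution_matrix,
                 require_middle_identity = isTRUE(require_middle_identity)),
            class = "match_config")
}

.check_residues <- function(fragment) {
  chars <- strsplit(fragment, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_STANDARD))
  if (length(bad))
    stop("non-standard residue '", chars[bad[1L]], "' at position ", bad[1L])
  chars
}

#' Self score of a peptide fragment
#'
#' The expected maximal score m of a query: the sum over positions of the
#' matrix diagonal, i.e. the score of the fragment aligned to itself.
#'
#' @param fragment Peptide string (standard residues only).
#' @param matrix Substitution matrix (default bundled BLOSUM62).
#' @return Numeric score; strictly positive for BLOSUM62.
#' @export
self_score <- function(fragment, matrix = blosum62()) {
  chars <- .check_residues(fragment)
  sum(matrix[cbind(chars, chars)])
}

#' Positionwise similarity score of two equal-length fragments
#'
#' The matched score s: the sum over positions of `matrix[query[i],
#' candidate[i]]`. Symmetric for symmetric matrices.
#'
#' @param query,candidate Equal-length peptide strings.
#' @param matrix Substitution matrix.
#' @return Numeric score.
#' @export
score_pair <- function(query, candidate, matrix = blosum62()) {
  if (nchar(query) != nchar(candidate))
    stop("fragment length mismatch: ", nchar(query), " vs ", nchar(candidate))
  qc <- .check_residues(query)
  cc <- .check_residues(candidate)
  sum(matrix[cbind(qc, cc)])
}

# Vectorized scoring of encoded query fragments (q x w) against encoded
# candidate fragments (n x w) under a 20x20 integer matrix. Returns list
# with S (q x n score matrix) and m (length-q self scores).
.score_block <- function(qcode, ccode, m20) {
  w <- ncol(qcode)
  q <- nrow(qcode); n <- nrow(ccode)
  S <- matrix(0, q, n)
  m <- numeric(q)
  for (j in seq_len(w)) {
    S <- S + m20[qcode[, j], ccode[, j], drop = FALSE]
    m <- m + m20[cbind(qcode[, j], qcode[, j])]
  }
  list(S = S, m = m)
}

# Pass matrix for a given cutoff: p > cutoff, with exact matches (p >= 1)
# always passing (so cutoff 1 keeps exact matches), and s <= 0 discarded.
.pass_matrix <- function(S, m, cutoff) {
  P <- S / m
  (S > 0) & (P > cutoff | P >= 1 - 1e-9)
}

#' Search a codon selection index with a query fragment
#'
#' Scores the query against every CSI entry sharing its middle residue and
#' returns those whose matched percent p = s/m exceeds the cut-off (exact
#' matches always pass, so c = 1 returns exact fragment matches only).
#' Entries with non-positive s are discarded. Results are sorted by p
#' descending, ties broken fragment-lexicographically.
#'
#' @param query Peptide fragment of length `csi$window` with a degenerate
#'   middle residue.
#' @param csi A `csi` object.
#' @param config A `match_config`.
#' @return Data frame of class `csi_matches` with columns `fragment`,
#'   `occurrences`, `s`, `m`, `p`; attributes `middle_aa` and `window`. Zero
#'   rows is a valid (no-match) outcome.
#' @export
search_csi <- function(query, csi, config = match_config()) {
  stopifnot(inherits(csi, "csi"))
  if (nchar(query) != csi$window)
    stop("query length ", nchar(query), " != CSI window ", csi$window)
  .check_residues(query)
  h <- (csi$window + 1L) %/% 2L
  aa <- substring(query, h, h)
  code <- genetic_code()
  if (!aa %in% code$degenerate_aas)
    stop("middle residue '", aa, "' is not degenerate; nothing to predict")
  if (!config$require_middle_identity)
    warning("require_middle_identity = FALSE is for score exploration only; ",
            "feature vectors need a fixed middle residue")
  empty <- data.frame(fragment = character(0), occurrences = integer(0),
                      s = numeric(0), m = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  b <- csi$buckets[[aa]]
  if (is.null(b)) {
    res <- empty
  } else {
    m20 <- .matrix20(config$matrix)
    qcode <- .encode_fragments(query, csi$window)
    sc <- .score_block(qcode, b$frag_code, m20)
    pass <- .pass_matrix(sc$S, sc$m, config$cutoff)[1L, ]
    idx <- which(pass)
    res <- data.frame(fragment = b$fragments[idx],
                      occurrences = b$occurrences[idx],
                      s = sc$S[1L, idx], m = rep(sc$m[1L], length(idx)),
                      p = sc$S[1L, idx] / sc$m[1L],
                      stringsAsFactors = FALSE)
    res <- res[order(-res$p, res$fragment), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, class = c("csi_matches", "data.frame"),
            middle_aa = aa, window = csi$window)
}

#' Assemble the classifier feature vector from CSI matches
#'
#' The feature vector for a query with middle amino acid of k synonymous
#' codons at window w has k + w dimensions: the first k are the unweighted
#' arithmetic mean, over the selected entries, of their normalized
#' middle-codon distributions (codon-lexicographic order); the last w are
#' the mean of the entries' per-position mean codon usage.
#'
#' @param matches A `csi_matches` data frame from [search_csi()] (at least
#'   one row).
#' @param csi The `csi` the matches came from.
#' @return Named numeric vector of length k + w. With zero matches, signals
#'   a condition of class `syncodon_no_match` so callers can fall back.
#' @export
build_feature_vector <- function(matches, csi) {
  aa <- attr(matches, "middle_aa")
  if (nrow(matches) == 0L)
    stop(structure(class = c("syncodon_no_match", "error", "condition"),
                   list(message = paste0("no CSI match for middle residue ", aa),
                        call = sys.call())))
  b <- csi$buckets[[aa]]
  idx <- match(matches$fragment, b$fragments)
  D <- b$counts[idx, , drop = FALSE] / b$occurrences[idx]
  fv <- c(colMeans(D), colMeans(b$pos_mean[idx, , drop = FALSE]))
  names(fv) <- c(colnames(b$counts), paste0("pos", seq_len(csi$window)))
  fv
}

# Vectorized feature assembly for many query fragments of one middle amino
# acid at one cutoff. Returns a list: features (q x (k+w) matrix, NA rows
# where no entry passed) and n_matches (integer per query). Queries must all
# have middle residue == aa.
.features_for_queries <- function(queries, csi, cutoff, aa,
                                  matrix = blosum62()) {
  b <- csi$buckets[[aa]]
  w <- csi$window
  cods <- codons_for(aa)
  k <- length(cods)
  feat_names <- c(cods, paste0("pos", seq_len(w)))
  q <- length(queries)
  if (is.null(b)) {
    return(list(features = matrix(NA_real_, q, k + w,
                                  dimnames = list(NULL, feat_names)),
                n_matches = integer(q)))
  }
  m20 <- .matrix20(matrix)
  qcode <- .encode_fragments(queries, w)
  sc <- .score_block(qcode, b$frag_code, m20)
  pass <- .pass_matrix(sc$S, sc$m, cutoff)
  nm <- rowSums(pass)
  D <- b$counts / b$occurrences
  block <- cbind(D, b$pos_mean)
  F <- (pass %*% block) / nm
  F[nm == 0L, ] <- NA_real_
  colnames(F) <- feat_names
  list(features = F, n_matches = as.integer(nm))
}
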