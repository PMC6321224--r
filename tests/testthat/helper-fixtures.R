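# Shared fixture builders; everything is generated in code.

# A coding sequence from a protein string, choosing the lexicographically
# first codon everywhere (deterministic back-translation for fixtures).
first_codon_gene <- function(id, protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  coding_sequence(id, unname(vapply(chars, function(a) codons_for(a)[1L],
                                    character(1))))
}

# A gene with explicit codons given as a single spaced string.
gene_from_codons <- function(id, codon_string) {
  coding_sequence(id, strsplit(codon_string, " ", fixed = TRUE)[[1L]])
}

# Random protein of length n over the standard alphabet (seeded by caller).
random_protein <- function(n, start_met = TRUE) {
  chars <- sample(AA_STANDARD, n, replace = TRUE)
  if (start_met) chars[1L] <- "M"
  paste(chars, collapse = "")
}

# Families of mutated proteins: n_fam founders, members point-mutated at
# `rate`; returns character vector named fam<ff>_m<mm>.
protein_families <- function(n_fam, members, len, rate) {
  out <- character(0)
  for (f in seq_len(n_fam)) {
    founder <- sample(AA_STANDARD, len, replace = TRUE)
    for (m in seq_len(members)) {
      chars <- founder
      mut <- which(stats::runif(len) < rate)
      for (i in mut) chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
      out[sprintf("fam%02d_m%02d", f, m)] <- paste(chars, collapse = "")
    }
  }
  out
}

# Small planted-rule synthetic corpus used by several tests.
small_rule_corpus <- function(strength = 1, n_families = 10L, members = 3L,
                              seed = 11L) {
  rule <- planted_rule("K", 1L, "P", "AAG", "AAA", strength = strength)
  generate_corpus(synthetic_config(n_families = n_families,
                                   members_per_family = members,
                                   rules = list(rule), seed = seed))
}

# Brute-force CSI search oracle: score every same-middle entry directly with
# score_pair/self_score and apply the cut-off rule by hand.
brute_force_search <- function(query, csi, cutoff) {
  h <- (csi$window + 1L) %/% 2L
  aa <- substring(query, h, h)
  b <- csi$buckets[[aa]]
  if (is.null(b)) return(character(0))
  m <- self_score(query)
  keep <- character(0)
  for (frag in b$fragments) {
    s <- score_pair(query, frag)
    p <- s / m
    if (s > 0 && (p > cutoff || p >= 1 - 1e-9)) keep <- c(keep, frag)
  }
  keep
}
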