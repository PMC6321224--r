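---
title: "Context-dependent codon prediction and gene design with syncodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent codon prediction and gene design with syncodon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncodon)
```

## The problem

Eighteen of the twenty standard amino acids are encoded by two or more
synonymous codons, and genomes use those codons with strong, non-random
bias. Conventional codon optimizers back-translate a protein by picking each
amino acid's highest-frequency codon. That ignores a well-documented
phenomenon: some low-frequency ("rare") codons are evolutionarily conserved
at specific positions, where they modulate translation speed and
co-translational folding. A gene designed from frequency tables alone erases
that signal.

`syncodon` instead learns *context-dependent* codon choice from the coding
sequences of the intended expression host: which codon a genome uses for an
amino acid, given the short peptide neighborhood it sits in. Designed genes
then reproduce both the high-frequency choices and the contextually
conserved rare-codon choices of the host.

## The model

**Corpus.** Training starts from host CDS records. Genes are kept only if
they exceed 100 sense codons; redundancy is removed by greedy longest-first
clustering of the encoded proteins at 40% global identity (Needleman-Wunsch,
BLOSUM62, gap open 10 / extend 1; identity = matches / alignment length, the
strategy of CD-HIT implemented internally so no external binary is needed);
and only clusters with at least three homologous members contribute, which
drops singleton "peculiar" genes such as likely horizontal transfers. One
representative per cluster (its founder: the longest member) forms the
non-redundant corpus.

**Codon selection index (CSI).** Every corpus gene is slid over with windows
of w = 5 and w = 7 codons (stride 1). For each distinct peptide fragment
whose middle residue is degenerate, the CSI stores the codon-count
distribution of the middle residue and, per fragment position, the mean
background relative usage of the codons observed there. Met and Trp middles
carry no codon choice (k = 1) and are excluded; at design time those
positions are emitted directly as ATG/TGG.

**Fragment matching.** A query fragment is compared with every CSI fragment
sharing its middle residue by a positionwise substitution-matrix score
(BLOSUM62 by default): the matched score *s*, the query's self score *m*
(its expected maximal score), and the matched percent *p = s/m*. Fragments
with *p* above a cut-off *c* are selected; at *c* = 1 only exact fragment
matches pass (p = 1 is treated as passing, otherwise that grid point would
select nothing). Entries with *s* ≤ 0 are discarded; the usable cut-off grid
(0.7-1) sits far above that floor.

**Features and classifiers.** The feature vector for a middle amino acid
with k synonymous codons at window w has k + w dimensions: the arithmetic
mean of the selected entries' normalized middle-codon distributions
(codon-lexicographic order), followed by the mean of their per-position
usage vectors. One multi-class random forest per degenerate amino acid is
trained for every (window, cut-off) grid point — the full grid of 7 cut-offs
(0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1) and 2 windows (5, 7) gives
7 × 2 × 18 = 252 models — with the codon observed at the position as the
training label. Models are assessed by stratified ten-fold cross-validation.

**Design.** The first and last two codons of a gene cannot be covered by a
centered window, so they come from positional tables: the modal codon per
amino acid at gene positions 1, 2, n−1, n across the corpus. Every other
degenerate position is predicted by a descending cut-off cascade (default
0.9 → 0.8 → 0.7): the position's fragment is searched at the highest
cut-off first, and the first level with at least one match and a trained
model supplies the codon. Positions with no match at any level — and amino
acids never seen at a terminal slot — fall back to the highest-usage codon.
The designed DNA always translates back to the input protein exactly; this
round-trip invariant is enforced in code and fuzz-tested.

## Interpreting the per-position "average codon usage"

The CSI stores one scalar per fragment position: the mean background
relative usage of the codons observed at that position, averaged over the
fragment's occurrences. This reading makes the feature dimensionality come
out as k + w exactly, which is what the classifier grid requires; it is the
package's chosen reconstruction of the per-position usage vector, and the
substitution-matrix form of *s* (middle position included, candidates
restricted to identical middles) is likewise a documented reconstruction
with the matrix configurable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_codons` | 100 | corpus length filter (strictly greater) |
| `identity_threshold` | 0.40 | protein identity above which genes are redundant |
| `min_cluster_size` | 3 | smallest homolog cluster kept |
| `windows` | 5, 7 | peptide context sizes (odd) |
| `cutoffs` | 0.7 ... 1 | matched-percent grid for training |
| `n_trees` | 200 | random-forest size; `--paper` CLI flag restores 10,000, far past the accuracy plateau for k + w ≤ 13 features |
| `cutoff_cascade` | 0.9, 0.8, 0.7 | design-time cut-off order (validation favors long windows and large cut-offs) |
| `fallback` | max-frequency codon | used when no fragment passes any cascade level |

## The synthetic generator and what passing tests mean

Real host corpora require genome-scale downloads, so the package ships a
generator that emulates the statistical structure the method exploits:
homolog families (founder proteins with point-substituted members, default
7.5% per residue, i.e. roughly 85% within-family identity, so the
clustering and cluster-size filters are exercised rather than bypassed), a
non-uniform background codon usage (0.7/0.3 for two-codon amino acids, so
"rare codon" is meaningful), and planted context rules — e.g. "Lys uses AAG
when followed by Pro, else AAA" — with a stated strength that fixes the
Bayes-optimal prediction accuracy. Every rule-governed position is written
to a truth table, and generation is byte-reproducible from the seed.

Held-out evaluation designs the proteins of genes the corpus never saw and
scores the designed codons at rule positions against the codons actually
drawn there. Two evaluation designs are available. Drawing held-out members
at the family mutation rate measures combined protein-extrapolation and
codon prediction; at ~85% family identity roughly a fifth of held-out
windows fall below the 0.7 match floor of the cascade, so recovery is
bounded near 0.8 regardless of rule strength. The recovery analyses
therefore evaluate on the family *founder* sequences with fresh codon draws
(`generate_eval_set(mutation_rate = 0)`): founders never appear in the
corpus (every member is ~7.5% mutated away), their codon labels are newly
drawn, and the query mirrors the method's actual use case — designing a
wild-type protein whose homologs are in the host corpus. A deterministic
(strength 1) rule is then recovered essentially everywhere the model path
reaches, while a strength 0.5 rule — pure noise — is recovered no better
than the modal-codon baseline.

Two features of real data the generator does not emulate: phylogenetic
structure within families (members are independent point-mutation draws, not
a tree), and genome-scale heterogeneity of codon bias across genes (one
background table serves the whole corpus). Passing tests therefore
demonstrate that the machinery recovers context signal it can see, not that
any particular organism carries such signal at a given strength.

A property worth knowing when reading cross-validation numbers: the CSI is
built from the same corpus the classifiers are trained on, as in the
original workflow. At cut-off 1 a unique fragment's feature vector is
dominated by its own observed codon distribution, so cross-validated
accuracy rises toward the cut-off-1 end of the grid. The package reproduces
this qualitative trend (it is a property of the method's evaluation design);
absolute accuracies on synthetic corpora are not comparable to any real
host's.

## Numerical choices and degenerate inputs

* Ties everywhere (modal codons, equal matched percents) break
  codon- or fragment-lexicographically, making every output deterministic.
* Stratified cross-validation folds and per-grid-cell random-forest seeds
  derive from the user seed; repeated runs are byte-identical. Predictions
  are taken from the forest's vote matrix with first-maximum
  (codon-lexicographic) tie resolution, because the fitted forest's own
  tie handling is randomized.
* Training sets whose feature columns are all constant (possible on
  degenerate corpora, where no split exists) store the majority codon as a
  flagged constant predictor instead of fitting a forest.
* CSI files store per-position means at 6 decimals; counts are exact
  integers, so round-trips preserve distributions exactly and means to
  1e-6.
* Genes shorter than the window yield no fragments (logged, not an error);
  proteins shorter than 5 residues are designed entirely from tables and
  fallback. Training sets with a single observed codon produce a flagged
  constant predictor rather than a forest.
* Ambiguity codes (N etc.), internal stops, and lengths not divisible by 3
  reject the CDS record at corpus validation; non-standard residues in a
  design query are an error naming the position.
* An amino acid entirely absent from a corpus gets uniform usage over its
  codons (flagged), so the fallback is always defined.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run on seeded synthetic corpora of
30 families × 5 members (150 genes, ~22,000 window positions per window
size) for the grid, search-oracle, round-trip, and cross-validation checks,
and 40 × 4 with 15 founder-copies of held-out evaluation (~300 rule
positions) for rule recovery; forests use 50-100 trees. These sizes were
chosen as the smallest at which per-amino-acid training sets (~250-1,200
examples) support stable ten-fold cross-validation, and they keep the whole
analysis reproducible on a laptop.

## Known limitations

* The matched-score definition is a reconstruction (see above); other
  weightings of the context positions are possible and the matrix is
  configurable.
* "Typical gene" of a homolog cluster is implemented as the cluster founder
  (longest member); the concept has no unique definition.
* The corpus clusterer reproduces CD-HIT's greedy strategy but not its word
  filters; an external cd-hit can be substituted upstream by supplying its
  representatives as the corpus.
* No codon-adaptation index, GC targeting, restriction-site removal, or
  mRNA-structure optimization: the method predicts host codon choice, and
  post-processing beyond that is out of scope.
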