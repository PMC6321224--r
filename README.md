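# syncodon

Context-dependent synonymous codon prediction and host-tuned gene design.

## The problem

Eighteen of the twenty standard amino acids are encoded by several
synonymous codons, and genomes use them with strong bias. Standard codon
optimizers back-translate a protein with each amino acid's highest-frequency
codon — and thereby erase the evolutionarily conserved *rare* codons that
genomes place at specific positions, where they tune translation speed and
co-translational folding. `syncodon` is for protein engineers and synthetic
biologists who want designed genes to reproduce the host's actual,
context-dependent codon choices, rare codons included.

## The method

From a host CDS corpus (filtered to genes of >100 codons, redundancy removed
by greedy clustering at 40% protein identity, and only clusters with ≥3
homologs kept), every gene is slid over with peptide windows of w = 5 and
w = 7 residues. A **codon selection index (CSI)** maps each observed
fragment to the codon distribution of its middle residue plus the mean codon
usage at each fragment position. A query fragment is matched against all
same-middle CSI fragments by a BLOSUM62 positionwise score: matched score
*s*, query self score *m*, matched percent *p = s/m*; fragments with *p*
above a cut-off *c* are selected, and the (k + w)-dimensional feature vector
(k = number of synonymous codons of the middle amino acid) is the arithmetic
mean of the selected entries' codon distributions and per-position usage.
One multi-class random forest per degenerate amino acid is trained at every
grid point of 7 cut-offs (0.7–1) × 2 windows — 7 × 2 × 18 = 252 models —
with the observed codon as the label, and assessed by ten-fold
cross-validation. Designed genes take their first and last two codons from
positional codon tables (windowed models cannot cover gene termini), Met/Trp
positions directly, and every other position from a descending cut-off
cascade (0.9 → 0.8 → 0.7) over the classifiers, falling back to the
highest-usage codon when no fragment matches. Designed DNA always translates
back to the input protein.

## Worked example

No host genome is required to try the pipeline: the package ships a
generator that emulates a host corpus as homolog families with a planted
context rule (here: Lys uses the rare codon AAG when followed by Pro).

```r
library(syncodon)
rule <- planted_rule("K", 1L, "P", "AAG", "AAA", strength = 1)
cfg  <- synthetic_config(n_families = 30, members_per_family = 5,
                         rules = list(rule), seed = 7)
host   <- generate_corpus(cfg)          # 150 CDS records
corpus <- build_corpus(host$corpus)     # length/identity/cluster filters
attr(corpus, "attrition")
#>                 stage in_count out_count
#> 1       length_filter      150       150
#> 2          clustering      150        30
#> 3 cluster_size_filter       30        30
#> 4     representatives       30        30

bundle <- train_grid(corpus, windows = c(5, 7), cutoffs = c(0.7, 0.8, 0.9, 1),
                     n_trees = 200, seed = 7, host_name = "demo-host")
bundle
#> <classifier_bundle> demo-host | 144 grid slots | 144 models | windows 5,7 | cutoffs 0.7,0.8,0.9,1.0
bundle$csis$w7
#> <csi> window = 7 | genes = 30 | entries = 4074 | positions = 4074
```

The 150 genes collapse to their 30 family representatives (every cluster has
5 homologs, so none is dropped); the window-7 CSI holds one entry per
distinct degenerate-middle fragment. Designing a protein:

```r
protein <- substr(host$founders[1], 1, 40)
res <- design_gene(protein, bundle, design_config(window = 7))
res$dna
#> "ATGTGGCACTGCCGCATAGACATAAGAATAAATTGGTACATAGTAAGAGGAAGCGAAATGGGTTGTGAAGGTATGATAACACAGGAAGACCCCAAGATCCCAAGAAAGTGCAACATACTA"
head(res$per_position, 5)
#>   position amino_acid codon         source
#> 1        1          M   ATG non-degenerate
#> 2        2          W   TGG non-degenerate
#> 3        3          H   CAC       fallback
#> 4        4          C   TGC      model@0.9
#> 5        5          R   CGC      model@0.9

design_report(res, bundle$background)$summary
#>           source  n fraction
#> 1       fallback  6    0.150
#> 2      model@0.7  6    0.150
#> 3      model@0.8  2    0.050
#> 4      model@0.9 20    0.500
#> 5 non-degenerate  5    0.125
#> 6     tail-table  1    0.025
```

Half the positions are predicted by the strictest (0.9) models; positions
whose context never passes any cut-off use the modal-codon fallback. The
report also lists predicted rare-codon positions (chosen codon with
background usage below 0.5/k) — the positions a frequency-only optimizer
would design differently. `translate_codons(split_codons(res$dna))` returns
the input protein exactly, for every input.

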