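# orthopair

One-to-one ortholog assignment between two closely related annotated genomes
by **rearrangement + duplication (RD) parsimony**, with explicit handling of
tandemly duplicated inparalogs.

## The problem and the approach

Orthology between two genomes is in general many-to-many: each ancestral gene
may leave several inparalogs (post-speciation duplicates) in each genome. For
gene-function transfer, tree building and synteny work one usually wants the
one-to-one map between exemplar genes. Sequence similarity alone confuses
recent inparalogs with orthologs; gene order resolves most of these cases.
`orthopair` chooses, within sequence-derived gene families, the one-to-one
matching that (heuristically) minimises the **RD score**

> RD(M) = d_rev(π(M)) + #unmatched genes,

where π(M) is the signed permutation the matching induces between the two
gene orders and d_rev is the exact Hannenhalli–Pevzner signed reversal
distance `d = n + 1 − c + h + f` (breakpoint-graph cycles `c`, hurdles `h`,
fortress `f`); multichromosomal inputs fall back to the DCJ adjacency-graph
distance. RD parsimony by itself discards randomly inserted duplicates (they
cost reversals) but would keep matched *tandem* duplicate pairs, since
uncoupling those trades zero reversals for two duplications. The pipeline
therefore first dates duplications on per-family gene trees (codon
alignments, F84 distances, BIONJ rooted by an artificial outgroup at twice
the maximum distance) and deletes all but one member of every set of tandem
inparalogs before the rearrangement engine runs; a post-processing pass then
recovers extra pairs from single-gene "gaps" inside collinear blocks when at
least one gap gene is the other's best hit.

A genome-evolution simulator (duplications — tandem or random —, signed
reversals, and per-gene mutation bursts, with full ancestor tracking) makes
the whole pipeline testable without any external data.

## Worked example

```r
library(orthopair)

params <- sim_params(k = 10, p = 50, alpha = 0.75, beta = 0.5,
                     gene_len_codons = 200, seed = 11)
res <- run_pipeline(pipeline_config(sim = params))
res
#> ortholog assignment pipeline result
#>   genes_genome1                148
#>   genes_genome2                148
#>   families                     100
#>   inparalogs_removed_genome1   16
#>   inparalogs_removed_genome2   13
#>   core_pairs                   115
#>   final_pairs                  115
#>   sensitivity 1.000, specificity 0.957
```

Reading: each simulated genome carries 148 genes (100 ancestral + 10
pre-speciation + 38 post-speciation duplicates). The gene-tree stage
identified 16 and 13 tandem inparalogs on the two genomes and removed them;
the RD engine matched 115 one-to-one pairs; every one of the 110 assignable
ancestral lineages was recovered (sensitivity 1.0) and 110 of the 115
emitted pairs are credited true positives (specificity 0.957). Disabling the
tandem stage (`tag_removal = FALSE`) on the same input yields 118 pairs at
specificity 0.932 — the extra pairs are matched tandem inparalogs that RD
parsimony alone cannot reject.

Pieces are usable on their own, e.g.

```r
reversal_distance(c(1L, 5L, 2L, 3L, 4L))$distance   # 3
f84_formula(P = 0.1, Q = 0.05)                      # 0.1684...
bench <- run_benchmark(replicates = 5, seed = 1,
                       base = sim_params(gene_len_codons = 150))
autoplot(bench)
```

A command-line front end ships in `inst/cli/orthopair`
(`assign`, `simulate`, `evaluate`, `benchmark` subcommands).

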