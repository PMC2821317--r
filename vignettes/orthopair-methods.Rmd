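---
title: "Methods: one-to-one ortholog assignment by rearrangement and duplication parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-to-one ortholog assignment by rearrangement and duplication parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two closely related genomes share most of their genes through speciation
(orthologs), but each genome also carries paralogs — duplicates that arose
before the speciation (outparalogs) or after it (inparalogs). For many
comparative analyses one wants a *one-to-one* ortholog map: for every
ancestral gene present in both genomes, one representative pair. Sequence
similarity alone cannot always separate an ortholog from a recent inparalog,
because the duplicates are nearly identical in sequence. Gene order can:
under a parsimony model of genome evolution, the assignment that minimises
the number of rearrangements plus duplications needed to explain both gene
orders is the preferred reconstruction.

`orthopair` implements this idea in four stages:

1. **Families.** All-vs-all protein similarity over both genomes, clustered
   into gene families with Markov clustering (MCL).
2. **Tandem inparalogs.** For each family, a rooted DNA-level gene tree is
   built and its internal nodes are dated as duplication or speciation
   events. Sets of genes that duplicated after the speciation *and* sit in a
   tandem array (a TAG: a run of consecutive same-family genes) are reduced
   to one representative — the one most similar to the other genome — because
   at most one member of such a set can appear in a one-to-one pair, and for
   tandem neighbours the choice cannot change the rearrangement distance.
3. **RD-parsimony matching.** On the reduced genomes, a one-to-one matching
   within families is chosen to minimise the RD score: the signed reversal
   distance of the induced permutation plus one duplication unit per
   unmatched gene. Bidirectional best hits seed the matching, remaining genes
   are matched greedily by similarity, and a strict-improvement local search
   ("noise" pair detection) uncouples or swaps pairs while the RD total
   decreases.
4. **Gap recovery.** Inside collinear orthologous blocks, positions where a
   single unassigned gene sits between the same flanking pairs on both
   genomes are re-examined; the two gap genes are paired when at least one is
   the other's best hit.

The intuition for stage 2 is the asymmetry between duplication models.
Uncoupling a *randomly* inserted duplicate pair typically saves several
reversals at the cost of two duplications, so RD parsimony discards it on its
own. Uncoupling a pair of *tandem* duplicates changes no reversal count and
adds two duplications, so RD parsimony would keep it — which is exactly the
false-positive mode the phylogenetic pre-processing removes.

# The RD score

For a one-to-one matching, matched genome-1 genes are numbered `1..m` in gene
order and genome 2 is rewritten in those labels, negated where the strands of
a matched pair disagree. For single-chromosome inputs the rearrangement
component is the exact Hannenhalli–Pevzner signed reversal distance

    d = (m + 1) - c + h + f

with `c` the number of breakpoint-graph cycles, `h` the number of hurdles
(minimal unoriented components plus, when one component's span encloses all
others, the greatest hurdle; implemented via the circular-consecutiveness
test on unoriented-component endpoints) and `f` the fortress indicator (an
odd number of hurdles, all of which are superhurdles). The implementation is
validated exhaustively against breadth-first search over the reversal graph
for every signed permutation up to n = 5 (and n = 6 during development) and
on random n = 7 instances.

For multichromosomal inputs the package substitutes the DCJ
(double-cut-and-join) adjacency-graph distance, `N − C − I/2`, a standard
tight surrogate for the reversal/translocation/fusion/fission distance; the
`method` field of the RD score records which route was used. All simulated
data are unichromosomal, so the exact reversal distance is what the tests and
benchmarks exercise.

The duplication component counts one unit per unmatched gene. Genes whose
family has members on only one genome contribute a fixed cost and are never
search candidates.

# Gene trees and duplication dating

Families with at least two members get a rooted tree:

* **Alignment.** A built-in progressive aligner (guide tree from pairwise
  profile-alignment scores via BIONJ, then profile–profile global alignment
  with BLOSUM62, affine gaps open 11 / extend 1) keeps the pipeline free of
  external binaries; externally produced alignments can be imported instead.
  The dynamic program explores a diagonal band (half-width 60, widened by the
  profile length difference). For the closely related sequences inside a
  family this is exact in practice; the band can be disabled.
* **Codon mapping.** Protein rows are back-translated with the gene's CDS
  (one codon per residue, `---` per gap) after verifying that the CDS
  translates to the protein row.
* **Distances.** Pairwise F84 distances with pairwise deletion of gapped or
  ambiguous sites. Base frequencies are estimated from the pooled pair of
  rows by default (matching pairwise distance tools; a family-wide mode is
  available). Saturated pairs are capped at 10 substitutions/site — capping
  rather than dropping keeps the matrix complete for neighbor joining.
* **Tree and root.** BIONJ (classical NJ available) on the distance matrix,
  expanded by an artificial outgroup at distance twice the matrix maximum
  from every gene; the tree is rooted on the outgroup edge and the outgroup
  removed. On random additive matrices this root agrees with explicit
  midpoint rooting in the majority of cases (and exactly for two taxa); the
  agreement is approximate, not an identity, which is acceptable here because
  only the duplication/speciation labeling below consumes the root.
* **Dating.** With two species the reconciliation is linear-time: an internal
  node whose descendants all come from one genome is a duplication; the
  lowest nodes with descendants from both genomes are speciations; every
  ancestor of a speciation node is a duplication. This equals (and is tested
  against) the generic rule "duplication iff the children's species sets
  intersect".

Each maximal single-genome clade with two or more leaves is a *potential*
inparalog set. A set is confirmed where its genes are adjacent on the genome
(inside one TAG). By default each within-TAG subset with at least two members
is confirmed independently (`adjacent_subset`); an `all_or_nothing` switch
requires the whole set to share one TAG. Potential inparalogs separated by
other genes are left for the RD stage to resolve. TAG adjacency is strict; a
spacer tolerance is exposed but defaults to 0.

# Similarity and clustering

The built-in similarity stage scores gene pairs by Smith–Waterman local
alignment of the proteins (BLOSUM62, gap open 11 / extend 1) and keeps scores
at or above `edge_threshold` (default 60; random unrelated proteins of a few
hundred residues score far below this, genuine family members far above).
Aligning all ~n² pairs is wasteful, so candidate pairs are screened first:
equal-length CDS pairs by vectorised nucleotide identity (threshold 0.40,
against a random-sequence baseline of 0.25), all other pairs by shared
protein 5-mers. Pairs that fail the screen are exactly those that could not
reach the edge threshold, so the screened matrix coincides with the full one
with overwhelming probability on this data; on real proteomes users can
import BLAST tabular scores instead, which bypasses the screen entirely.

MCL runs with the canonical defaults (expansion 2, inflation 2.0) on the
symmetric score graph, one connected component at a time, with self-loops
weighted by each gene's maximum incident edge (a standard stabilisation).
Column stochasticity is asserted to 1e-12 after every inflation. Clusters are
read off the attractor systems; every tie-break (attractor assignment, family
numbering, and all sorting throughout the package) is lexicographic in
C-locale byte order so results are bit-for-bit reproducible across platforms.

# The simulator

The generator mirrors the evolutionary model the assignment method assumes,
with full ground truth:

* An ancestral genome `G` of `n_genes = 100` genes, each a uniform random
  coding sequence of `gene_len_codons = 1000` codons (the 61 sense codons, so
  the ancestral genes translate cleanly; point mutations may later create
  internal stops, which are carried through as `*`).
* `k` duplications turn `G` into `H`; a speciation copies `H` into two
  lineages; each lineage independently receives `p` genome-level events:
  `round(p*alpha)` duplications, of which `round(round(p*alpha)*beta)` are
  tandem (copy inserted immediately after its source, same strand) and the
  rest random (uniform position, uniform strand), plus `p - round(p*alpha)`
  signed reversals over uniformly chosen segments, all in uniformly shuffled
  order. Whether the `k` pre-speciation duplications are tandem is not pinned
  down by the model; each is tandem with probability `beta_pre` (default:
  `beta`).
* Between consecutive events — and once before the first and after the last —
  every gene independently receives `m ~ Uniform{0..round(3*gene_len_codons*mu)}`
  random substitutions (`mu = 0.01`, so up to 30 and 15 on average at the
  default length). Substitutions pick a uniformly random different base;
  repeated hits on one site within a burst resolve against the pre-burst
  base. No indels, no gene loss, one chromosome.

Ground truth maps every contemporary gene to its ancestor in `H` (the genome
at speciation), which is what "inparalog" is defined against. The number of
assignable one-to-one pairs is the number of ancestors with at least one
descendant in each lineage — `n_genes + k` here, since nothing is lost.

**What passing simulations does and does not show.** The simulator realises
exactly the model the method optimises: substitution-only sequence evolution,
single chromosomes, uniform event positions. Real genomes add indels,
unequal gene lengths, domain shuffling, gene loss, segmental duplications and
multi-chromosome rearrangements; performance there is constrained by the
imported-similarity and imported-alignment paths and is not certified by
these tests.

# Evaluation

Against simulation truth, a predicted pair is eligible as a true positive
when both genes share a speciation-time ancestor; at most one TP is credited
per ancestor (first pair in deterministic id order) and all further pairs —
eligible or not — count as false positives. This generalises the rule that
within a pair of orthologous tandem arrays any single cross pair is
acceptable but only one. Sensitivity is TP/assignable; specificity in
simulation mode is TP/assigned. Against gene-symbol tables, pairs are
classified TP (identical official symbols, case-insensitively — mouse symbols
are mixed-case), FP (different symbols, or a symbol whose true partner is
elsewhere), or unknown; symbols matching configurable junk patterns
(`^LOC`, `^OTTMUSG`, `RIK$`) are treated as absent, and specificity is
TP/(TP+FP), ignoring unknowns.

The benchmark harness runs, per replicate, the full pipeline and an ablation
with stage 2 disabled on the same simulated pair (sharing the similarity
matrix and families), so the measured specificity difference isolates the
contribution of tandem-inparalog removal.

# Problem sizes and defaults used in the shipped checks

The package's own test suite exercises the benchmark at reduced sequence
length (150–200 codons) with 20 replicates per parameter point — the
specificity gap from tandem-inparalog removal is robust to sequence length,
and the reduced length keeps the default test run quick. The acceptance
script (`scripts/acceptance.R`) uses the full default conditions (1000
codons, 20 replicates). Sweeps vary one parameter at a time around the
default set (k=10, p=50, alpha=0.75, beta=0.5): sensitivity falls as `p`
grows (parsimony reconstruction degrades with event load) and specificity
rises with `beta` (tandem duplicates are exactly what stage 2 removes).

# Numerical and design choices

* **Rounding** of event counts is half-up; the model states fractions only.
* **Tie-breaks** everywhere are score-then-lexicographic; sorting is
  C-locale.
* **Edge scores** are raw local-alignment scores, not E-values; the MCL graph
  needs only a monotone similarity measure.
* **Noise search moves**: uncouple one pair; swap partners between two pairs
  of one family. Moves are accepted only on strict RD decrease, so the search
  terminates (integer objective, bounded below). Re-coupling removed pairs is
  not attempted; the swap move covers the common mis-pairing case.
* **Gap recovery** does not require family agreement — the best-hit condition
  stands alone (families can split a true pair across clusters when one gene
  has diverged); a flag can enforce same-family pairs.
* **Degenerate inputs**: empty genomes and empty assignments evaluate to
  zero-count reports flagged `degenerate`; all-zero distance matrices root
  deterministically; saturated F84 distances are capped, not dropped.

# Limitations

* Exact reversal distance assumes one chromosome per genome; real
  multichromosomal inputs use the DCJ surrogate and are flagged.
* The built-in aligner is a banded progressive aligner intended for
  close-to-identical family members; for deep families import a dedicated
  MSA tool's output.
* The greedy + local-search matching is a documented heuristic for the RD
  objective, not an exact optimiser; its behaviour is pinned by the
  accounting tests (tandem pairs kept, costly random-duplicate pairs
  uncoupled) and the reversal-only recovery property.
* Dating assumes exactly two genomes; no gene-loss inference.
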