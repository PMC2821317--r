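# Small fixture builders shared across test files.

# genome of single-chromosome genes in the given order
toy_genome <- function(ids, genome_id, strands = NULL, proteins = NULL,
                       cds = NULL, chromosomes = NULL) {
  n <- length(ids)
  genome_tbl(tibble::tibble(
    gene_id = ids,
    chromosome = chromosomes %||% rep("chr1", n),
    index = if (is.null(chromosomes)) seq_len(n) - 1L else
      as.integer(stats::ave(seq_len(n), chromosomes, FUN = seq_along) - 1),
    strand = strands %||% rep(1L, n),
    protein = if (is.null(proteins)) NA_character_ else unname(proteins[ids]),
    cds = if (is.null(cds)) NA_character_ else unname(cds[ids])
  ), genome_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_assignment <- function(gene1, gene2, provenance = "core") {
  validate_assignment(tibble::tibble(gene1 = gene1, gene2 = gene2,
                                     provenance = provenance))
}

toy_families <- function(...) {
  fams <- list(...)
  tibble::tibble(gene_id = unlist(fams),
                 family = rep(seq_along(fams), lengths(fams)))
}

toy_similarity <- function(gene1, gene2, score) {
  orthopair:::new_similarity(
    tibble::tibble(gene1 = gene1, gene2 = gene2, score = score), "built-in")
}

# random CDS of L codons without internal stops, plus mutated copies
random_cds <- function(len_codons, n_mut = 0) {
  codons <- orthopair:::sense_codons()
  s <- paste(sample(codons, len_codons, replace = TRUE), collapse = "")
  if (n_mut > 0) s <- mutate_cds(s, n_mut)
  s
}

mutate_cds <- function(s, n_mut) {
  r <- strsplit(s, "")[[1]]
  pos <- sample(length(r), n_mut)
  for (p in pos) r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1)
  paste(r, collapse = "")
}

protein_of <- function(cds) orthopair:::translate_cds(cds)

# enumerate all signed permutations of 1..n
all_signed_perms <- function(n) {
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perm_list(v[-i]), function(p) c(v[i], p))
    }))
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  do.call(rbind, lapply(perm_list(seq_len(n)), function(p) {
    t(t(signs) * p)
  }))
}

# independent brute-force duplication/speciation labeling: a node is a
# duplication iff its two children's species sets intersect
lca_reconcile_oracle <- function(tree, species_of) {
  k <- ape::Ntip(tree)
  labs <- character(tree$Nnode)
  spset <- function(node) {
    if (node <= k) return(unname(species_of[tree$tip.label[node]]))
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    sets <- lapply(ch, spset)
    inter <- Reduce(intersect, sets)
    labs[node - k] <<- if (length(inter) > 0) "D" else "S"
    unique(unlist(sets))
  }
  spset(k + 1L)
  labs
}
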