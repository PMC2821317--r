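# Duplication dating on rooted gene trees (two species), identification of
# tandemly arrayed genes (TAGs), and removal of confirmed tandem inparalogs.

#' Date duplications on a rooted gene tree
#'
#' Linear-time labeling for the two-species case: every internal node whose
#' descendant genes all come from one species is a duplication; the lowest
#' internal nodes with descendants from both species are speciation events;
#' all ancestors of a speciation node are duplications.
#'
#' @param tree Rooted binary `ape::phylo`; tips are gene ids.
#' @param species_of Named character vector mapping gene id to genome id
#'   (exactly two distinct genome ids may occur).
#' @return The tree with `node.label` set to `"D"` or `"S"` for every internal
#'   node.
#' @export
date_duplications <- function(tree, species_of) {
  sp <- species_of[tree$tip.label]
  if (anyNA(sp)) {
    abort_op("tip '%s' has no genome id", tree$tip.label[which(is.na(sp))[1]])
  }
  lv <- sort_c(unique(unname(species_of)))
  if (length(lv) > 2L) abort_op("more than two genomes in species map")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ## species bitmask per node: 1, 2 or 3 (both)
  mask <- integer(ntip + nnode)
  mask[seq_len(ntip)] <- match(sp, lv)
  has_mixed_desc <- logical(ntip + nnode)
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  ## postorder over internal nodes (ape internal nodes are ntip+1 .. ntip+nnode;
  ## use ape's reordering for a proper traversal)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    parent <- po[r, 1]; child <- po[r, 2]
    m <- mask[child]
    mask[parent] <- bitwOr(mask[parent], if (m == 0L) 0L else ifelse(m > 2L, 3L, m))
    if (mask[child] == 3L || has_mixed_desc[child]) {
      has_mixed_desc[parent] <- TRUE
    }
  }
  lab <- character(nnode)
  for (v in seq_len(nnode)) {
    node <- ntip + v
    if (mask[node] != 3L) {
      lab[v] <- "D"                       # single-species subtree
    } else if (!has_mixed_desc[node]) {
      lab[v] <- "S"                       # lowest mixed node
    } else {
      lab[v] <- "D"                       # ancestor of a speciation node
    }
  }
  tree$node.label <- lab
  tree
}

#' Potential inparalog sets from a dated gene tree
#'
#' Each maximal single-species clade with at least two leaves (whose root is
#' necessarily labeled duplication) is one potential set of inparalogs.
#'
#' @param tree A tree labeled by [date_duplications()].
#' @param species_of Named character vector, gene id to genome id.
#' @return Tibble with columns `set_id`, `genome_id`, `gene_id`.
#' @export
potential_inparalog_sets <- function(tree, species_of) {
  ntip <- length(tree$tip.label)
  sp <- species_of[tree$tip.label]
  lv <- sort_c(unique(unname(species_of)))
  mask <- integer(ntip + tree$Nnode)
  mask[seq_len(ntip)] <- match(sp, lv)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    mask[po[r, 1]] <- bitwOr(mask[po[r, 1]], mask[po[r, 2]])
  }
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  out <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    if (mask[node] == 3L) next
    is_maximal <- node == root || mask[parent[node]] == 3L
    if (!is_maximal) next
    tips <- tips_under(tree, node, ntip)
    if (length(tips) < 2L) next
    out[[length(out) + 1L]] <- tibble(
      set_id = length(out) + 1L,
      genome_id = lv[mask[node]],
      gene_id = sort_c(tree$tip.label[tips])
    )
  }
  if (!length(out)) {
    return(tibble(set_id = integer(), genome_id = character(),
                  gene_id = character()))
  }
  bind_rows(out)
}

tips_under <- function(tree, node, ntip) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- node
  tips <- integer()
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v <= ntip) {
      tips <- c(tips, v)
    } else {
      stack <- c(kids[[as.character(v)]], stack)
    }
  }
  tips
}

#' Find tandemly arrayed genes (TAGs)
#'
#' A TAG is a maximal run of consecutive order indices on one chromosome whose
#' genes all belong to one family. Runs of length 1 are omitted. A spacer
#' tolerance `spacer > 0` allows up to that many intervening genes of other
#' families inside a run (default 0: strict adjacency).
#'
#' @param genome A [genome_tbl()].
#' @param families Family tibble (`gene_id`, `family`).
#' @param spacer Maximum number of intervening other-family genes allowed.
#' @return Tibble with columns `tag_id`, `chromosome`, `family`, `gene_id`.
#' @export
find_tags <- function(genome, families, spacer = 0L) {
  fam <- setNames(families$family, families$gene_id)
  g <- genome[order_c(genome$chromosome, genome$index), ]
  g$family <- unname(fam[g$gene_id])
  out <- list()
  for (chr in split(g, g$chromosome)) {
    n <- nrow(chr)
    i <- 1L
    while (i <= n) {
      f <- chr$family[i]
      if (is.na(f)) { i <- i + 1L; next }
      members <- i
      last <- i
      j <- i + 1L
      while (j <= n && !is.na(f)) {
        if (!is.na(chr$family[j]) && chr$family[j] == f) {
          members <- c(members, j)
          last <- j
          j <- j + 1L
        } else if (j - last <= spacer) {
          j <- j + 1L
        } else break
      }
      if (length(members) >= 2L) {
        out[[length(out) + 1L]] <- tibble(
          tag_id = length(out) + 1L, chromosome = chr$chromosome[1],
          family = f, gene_id = chr$gene_id[members])
      }
      i <- if (length(members) >= 2L) last + 1L else i + 1L
    }
  }
  if (!length(out)) {
    return(tibble(tag_id = integer(), chromosome = character(),
                  family = integer(), gene_id = character()))
  }
  bind_rows(out)
}

#' Confirm tandem inparalog sets and remove all but one gene
#'
#' A potential inparalog set is confirmed where its genes are adjacent on the
#' genome, i.e. appear in the same TAG. Under the default
#' `rule = "adjacent_subset"`, each within-TAG subset of a potential set with
#' at least two members is confirmed on its own; `rule = "all_or_nothing"`
#' confirms a set only when all its genes share one TAG. For each confirmed
#' set the gene with the highest similarity score against any gene of the
#' other genome is kept (ties: lexicographically smallest id) and the rest are
#' removed; order indices are recompacted.
#'
#' @param genome A [genome_tbl()] (the genome the sets live on).
#' @param potential_sets Tibble from [potential_inparalog_sets()] (may pool
#'   several families/trees; `set_id` must be unique per set).
#' @param tags Tibble from [find_tags()] for this genome.
#' @param similarity Similarity tibble.
#' @param other_genome The other [genome_tbl()].
#' @return List with `genome` (reduced, recompacted), `removed` (tibble
#'   `gene_id`, `representative`, `set_id`), `confirmed` (tibble `set_id`,
#'   `gene_id`, `kept`).
#' @export
confirm_and_remove <- function(genome, potential_sets, tags, similarity,
                               other_genome,
                               rule = c("adjacent_subset", "all_or_nothing")) {
  rule <- match.arg(rule)
  sets <- potential_sets[potential_sets$gene_id %in% genome$gene_id, ]
  cross <- cross_genome_max_score(similarity, genome, other_genome)
  tag_of <- setNames(tags$tag_id, tags$gene_id)
  removed <- list()
  confirmed <- list()
  for (s in split(sets, sets$set_id)) {
    if (nrow(s) < 2L) next
    tg <- tag_of[s$gene_id]
    if (rule == "all_or_nothing") {
      ok <- !anyNA(tg) && length(unique(tg)) == 1L
      groups <- if (ok) list(s$gene_id) else list()
    } else {
      grp <- split(s$gene_id, tg)          # drops NA (not in any TAG)
      groups <- grp[lengths(grp) >= 2L]
    }
    for (members in groups) {
      sc <- cross[members]
      sc[is.na(sc)] <- 0
      keep <- members[order(-sc, members, method = "radix")][1]
      drop <- setdiff(members, keep)
      removed[[length(removed) + 1L]] <- tibble(
        gene_id = drop, representative = keep, set_id = s$set_id[1])
      confirmed[[length(confirmed) + 1L]] <- tibble(
        set_id = s$set_id[1], gene_id = members, kept = members == keep)
    }
  }
  removed <- if (length(removed)) bind_rows(removed) else
    tibble(gene_id = character(), representative = character(),
           set_id = integer())
  confirmed <- if (length(confirmed)) bind_rows(confirmed) else
    tibble(set_id = integer(), gene_id = character(), kept = logical())
  reduced <- recompact_genome(genome[!genome$gene_id %in% removed$gene_id, ])
  list(genome = reduced, removed = removed, confirmed = confirmed)
}

# max similarity score of each gene of `genome` against any gene of `other`
cross_genome_max_score <- function(similarity, genome, other) {
  edges <- bind_rows(
    tibble(a = similarity$gene1, b = similarity$gene2, score = similarity$score),
    tibble(a = similarity$gene2, b = similarity$gene1, score = similarity$score)
  )
  edges <- edges[edges$a %in% genome$gene_id & edges$b %in% other$gene_id, ]
  if (!nrow(edges)) return(setNames(double(), character()))
  agg <- edges |>
    group_by(.data$a) |>
    summarise(score = max(.data$score), .groups = "drop")
  setNames(agg$score, agg$a)
}
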