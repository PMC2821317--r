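# All-vs-all protein similarity. Built-in mode screens gene pairs cheaply
# (nucleotide identity for equal-length CDS, shared protein k-mers otherwise)
# and computes BLOSUM62 local alignment scores for the surviving candidates;
# pairs that cannot reach edge_threshold are never aligned. Imported mode
# loads BLAST tabular output.

new_similarity <- function(tbl, source) {
  tbl <- as_tibble(tbl)[, c("gene1", "gene2", "score")]
  swap <- tbl$gene1 > tbl$gene2
  tmp <- tbl$gene1[swap]
  tbl$gene1[swap] <- tbl$gene2[swap]
  tbl$gene2[swap] <- tmp
  tbl <- tbl[order_c(tbl$gene1, tbl$gene2), ]
  structure(tbl, class = c("similarity_tbl", class(tibble())),
            source = source)
}

#' Similarity-stage options
#'
#' @param edge_threshold Minimum local-alignment score kept as a graph edge.
#' @param screen_min_identity Minimum nucleotide identity for equal-length CDS
#'   pairs to become alignment candidates (random sequences sit near 0.25).
#' @param kmer_k Protein k-mer size used to screen unequal-length pairs.
#' @param kmer_min_shared Minimum count of distinct shared protein k-mers.
#' @return A list of class `similarity_params`.
#' @export
similarity_params <- function(edge_threshold = 60,
                              screen_min_identity = 0.40,
                              kmer_k = 5L, kmer_min_shared = 2L) {
  structure(list(edge_threshold = edge_threshold,
                 screen_min_identity = screen_min_identity,
                 kmer_k = as.integer(kmer_k),
                 kmer_min_shared = as.integer(kmer_min_shared)),
            class = "similarity_params")
}

#' Compute (or import) the all-vs-all similarity matrix
#'
#' Built-in mode scores candidate gene pairs across and within both genomes by
#' Smith-Waterman local alignment of the protein sequences (BLOSUM62, affine
#' gaps open 11 / extend 1) and keeps scores at or above
#' `params$edge_threshold`. Imported mode reads NCBI BLAST tabular output.
#' Scores are symmetric by construction (max over directions for imports).
#'
#' @param genome1,genome2 [genome_tbl()]s with `protein` (and preferably
#'   `cds`) sequences.
#' @param mode `"builtin"` or `"imported"`.
#' @param path BLAST tabular file for imported mode.
#' @param params [similarity_params()].
#' @return A similarity tibble (`gene1`, `gene2`, `score`), `gene1 < gene2`.
#' @export
similarity_matrix <- function(genome1, genome2, mode = c("builtin", "imported"),
                              path = NULL, params = similarity_params()) {
  mode <- match.arg(mode)
  if (mode == "imported") {
    return(read_blast_tab(path))
  }
  genes <- bind_rows(
    tibble(gene_id = genome1$gene_id, protein = genome1$protein,
           cds = genome1$cds),
    tibble(gene_id = genome2$gene_id, protein = genome2$protein,
           cds = genome2$cds)
  )
  genes <- genes[order_c(genes$gene_id), ]
  if (nrow(genes) < 2L) {
    return(new_similarity(tibble(gene1 = character(), gene2 = character(),
                                 score = double()), "built-in"))
  }
  cand <- candidate_pairs(genes, params)
  if (nrow(cand) == 0L) {
    return(new_similarity(tibble(gene1 = character(), gene2 = character(),
                                 score = double()), "built-in"))
  }
  score <- local_alignment_scores(genes$protein[cand$i], genes$protein[cand$j])
  keep <- score >= params$edge_threshold
  new_similarity(tibble(gene1 = genes$gene_id[cand$i[keep]],
                        gene2 = genes$gene_id[cand$j[keep]],
                        score = score[keep]), "built-in")
}

# candidate pair indices (i < j) into `genes`
candidate_pairs <- function(genes, params) {
  n <- nrow(genes)
  have_cds <- !is.na(genes$cds) & nzchar(genes$cds)
  out <- list()

  ## equal-length CDS pairs: vectorised nucleotide identity
  if (any(have_cds)) {
    for (idx in split(which(have_cds), nchar(genes$cds[have_cds]))) {
      if (length(idx) < 2L) next
      len <- nchar(genes$cds[idx[1]])
      m <- matrix(unlist(strsplit(genes$cds[idx], "", fixed = TRUE),
                         use.names = FALSE), nrow = len)
      matches <- matrix(0, length(idx), length(idx))
      for (b in c("A", "C", "G", "T")) {
        ind <- (m == b) + 0
        matches <- matches + crossprod(ind)
      }
      hit <- which(matches / len >= params$screen_min_identity, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit)) {
        out[[length(out) + 1L]] <- tibble(i = idx[hit[, 1]], j = idx[hit[, 2]])
      }
    }
  }

  ## remaining pairs: shared protein k-mer screen
  k <- params$kmer_k
  plen <- nchar(genes$protein)
  rows <- which(plen >= k)
  if (length(rows) >= 2L) {
    km <- purrr::map_dfr(rows, function(r) {
      s <- genes$protein[r]
      tibble(idx = r,
             kmer = unique(substring(s, 1:(nchar(s) - k + 1L),
                                     k:nchar(s))))
    })
    shared <- km |>
      inner_join(km, by = "kmer", relationship = "many-to-many") |>
      filter(.data$idx.x < .data$idx.y) |>
      dplyr::count(.data$idx.x, .data$idx.y, name = "shared") |>
      filter(.data$shared >= params$kmer_min_shared)
    if (nrow(shared)) {
      same_len_cds <- have_cds[shared$idx.x] & have_cds[shared$idx.y] &
        nchar(genes$cds[shared$idx.x]) == nchar(genes$cds[shared$idx.y])
      shared <- shared[!same_len_cds, ]  # those were screened by identity
      if (nrow(shared)) {
        out[[length(out) + 1L]] <- tibble(i = shared$idx.x, j = shared$idx.y)
      }
    }
  }
  if (!length(out)) return(tibble(i = integer(), j = integer()))
  distinct(bind_rows(out))
}

local_alignment_scores <- function(p1, p2) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(p1), Biostrings::AAStringSet(p2),
    type = "local", substitutionMatrix = mat,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

#' Best hits and bidirectional best hits across genomes
#'
#' The best hit of a gene is its highest-scoring gene on the other genome
#' (ties broken by lexicographically smallest gene id); a BBH is a mutually
#' best pair.
#'
#' @param similarity A similarity tibble.
#' @param genome1,genome2 [genome_tbl()]s.
#' @return Tibble with one row per gene that has a cross-genome hit:
#'   `gene_id`, `genome_id`, `best_hit`, `score`, `bbh`.
#' @export
best_hits <- function(similarity, genome1, genome2) {
  side <- c(setNames(rep(genome1$genome_id[1] %||% "1", nrow(genome1)),
                     genome1$gene_id),
            setNames(rep(genome2$genome_id[1] %||% "2", nrow(genome2)),
                     genome2$gene_id))
  edges <- bind_rows(
    tibble(gene_id = similarity$gene1, other = similarity$gene2,
           score = similarity$score),
    tibble(gene_id = similarity$gene2, other = similarity$gene1,
           score = similarity$score)
  )
  edges <- edges[!is.na(side[edges$gene_id]) & !is.na(side[edges$other]) &
                   side[edges$gene_id] != side[edges$other], ]
  if (nrow(edges) == 0L) {
    return(tibble(gene_id = character(), genome_id = character(),
                  best_hit = character(), score = double(), bbh = logical()))
  }
  best <- edges |>
    arrange(.data$gene_id, dplyr::desc(.data$score), .data$other) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    mutate(genome_id = unname(side[.data$gene_id])) |>
    select("gene_id", "genome_id", best_hit = "other", "score")
  mutual <- setNames(best$best_hit, best$gene_id)
  best$bbh <- !is.na(mutual[best$best_hit]) &
    mutual[best$best_hit] == best$gene_id
  best[order_c(best$gene_id), ]
}
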