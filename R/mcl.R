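# Markov clustering of the similarity graph into gene families.
# Deterministic: genes are processed in C-locale id order, connected
# components are clustered independently, and every tie-break is lexicographic.

#' MCL parameters
#'
#' The canonical defaults (expansion 2, inflation 2.0) are used.
#'
#' @param expansion Matrix power used in the expansion step.
#' @param inflation Elementwise power used in the inflation step (> 1).
#' @param max_iter Iteration cap.
#' @param convergence_tol Convergence threshold on the max absolute change.
#' @param prune_tol Entries below this are zeroed between iterations.
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0, max_iter = 100L,
                       convergence_tol = 1e-9, prune_tol = 1e-14) {
  stopifnot(expansion >= 2L, inflation > 1)
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol, prune_tol = prune_tol),
            class = "mcl_params")
}

#' Cluster genes into families by Markov clustering
#'
#' Builds a column-stochastic transition matrix from the similarity scores
#' (self-loop weight of each gene equal to its maximum incident edge weight),
#' iterates expansion and inflation to convergence, and reads families off the
#' attractor systems. Every gene in `genes` is assigned to exactly one family;
#' genes without edges become singletons.
#'
#' @param similarity A similarity tibble (`gene1`, `gene2`, `score`).
#' @param genes Character vector of all gene ids to partition (defaults to the
#'   genes present in `similarity`).
#' @param params [mcl_params()].
#' @return A family tibble (`gene_id`, `family`) of class `family_tbl`;
#'   families are numbered in order of their lexicographically smallest
#'   member.
#' @export
mcl_cluster <- function(similarity, genes = NULL, params = mcl_params()) {
  edges <- as_tibble(similarity)
  if (is.null(genes)) genes <- union(edges$gene1, edges$gene2)
  genes <- sort_c(unique(genes))
  edges <- edges[edges$gene1 %in% genes & edges$gene2 %in% genes &
                   edges$gene1 != edges$gene2 & edges$score > 0, ]

  comp <- connected_components(genes, edges)
  fam_members <- list()
  for (cc in comp) {
    if (length(cc) == 1L) {
      fam_members[[length(fam_members) + 1L]] <- cc
    } else {
      sub <- edges[edges$gene1 %in% cc, ]
      for (cl in mcl_component(cc, sub, params)) {
        fam_members[[length(fam_members) + 1L]] <- cl
      }
    }
  }
  first <- vapply(fam_members, function(g) sort_c(g)[1], character(1))
  fam_members <- fam_members[order_c(first)]
  out <- tibble(gene_id = unlist(fam_members),
                family = rep(seq_along(fam_members), lengths(fam_members)))
  out <- out[order_c(out$gene_id), ]
  class(out) <- c("family_tbl", class(tibble()))
  out
}

# union-find over the edge list
connected_components <- function(genes, edges) {
  parent <- seq_along(genes)
  idx <- setNames(seq_along(genes), genes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(idx[[edges$gene1[r]]])
    b <- find(idx[[edges$gene2[r]]])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(genes), find, integer(1))
  unname(split(genes, roots))
}

mcl_component <- function(ids, edges, params) {
  ids <- sort_c(ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(edges$gene1, ids), match(edges$gene2, ids))] <- edges$score
  A <- pmax(A, t(A))
  diag(A) <- apply(A, 1, max)          # self-loops stabilise attractors
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(params$max_iter)) {
    Me <- M
    for (e in seq_len(params$expansion - 1L)) Me <- Me %*% M
    Mi <- Me^params$inflation
    Mi[Mi < params$prune_tol] <- 0
    Mi <- sweep(Mi, 2, colSums(Mi), "/")
    if (max(abs(colSums(Mi) - 1)) > 1e-12) {
      abort_op("internal error: inflation broke column stochasticity")
    }
    delta <- max(abs(Mi - M))
    M <- Mi
    if (delta < params$convergence_tol) break
  }
  interpret_mcl(M, ids)
}

# read clusters off the limit matrix: attractors are rows with positive
# diagonal; attractor systems are connected attractor sets; other genes join
# the system where they hold the largest mass (ties: lexicographic).
interpret_mcl <- function(M, ids) {
  eps <- 1e-7
  attract <- which(diag(M) > eps)
  if (!length(attract)) attract <- seq_along(ids)   # degenerate safeguard
  amat <- M[attract, attract, drop = FALSE]
  link <- which(amat > eps | t(amat) > eps, arr.ind = TRUE)
  sys_edges <- tibble(gene1 = ids[attract[link[, 1]]],
                      gene2 = ids[attract[link[, 2]]], score = 1)
  systems <- connected_components(ids[attract], sys_edges)
  sys_of <- integer(length(ids))
  names(sys_of) <- ids
  for (s in seq_along(systems)) sys_of[systems[[s]]] <- s
  rest <- setdiff(seq_along(ids), attract)
  for (j in rest) {
    w <- M[attract, j]
    best <- attract[w == max(w)]
    sys_of[j] <- sys_of[ids[best[order_c(ids[best])[1]]]]
  }
  unname(split(ids, sys_of))
}
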