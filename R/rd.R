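# The RD (rearrangement + duplication) engine: exact Hannenhalli-Pevzner
# signed reversal distance (breakpoint graph with hurdles and fortress) for
# unichromosomal inputs, a DCJ adjacency-graph surrogate for multichromosomal
# ones, RD scoring of a one-to-one matching, an initial BBH-first assignment,
# and "noise" pair detection by strict-improvement local search.

#' Signed reversal distance (Hannenhalli-Pevzner)
#'
#' Computes the exact minimum number of signed reversals sorting `perm` to
#' the identity: `d = n + 1 - c + h + f`, with `c` the number of breakpoint
#' graph cycles, `h` the number of hurdles (minimal unoriented components
#' plus, when applicable, the greatest one) and `f` the fortress indicator.
#'
#' @param perm Integer vector: a signed permutation of 1..n.
#' @return List with `distance` and `summary` (a list with `n`, `c`, `h`,
#'   `f`).
#' @export
reversal_distance <- function(perm) {
  perm <- as.integer(perm)
  n <- length(perm)
  if (n > 0L && !identical(sort(abs(perm)), seq_len(n))) {
    abort_op("not a signed permutation of 1..%d", n)
  }
  r <- .hp_reversal(perm)
  list(distance = as.integer(r$distance),
       summary = list(n = n, c = as.integer(r$c), h = as.integer(r$h),
                      f = as.integer(r$f)))
}

#' Induced signed permutation of a matching
#'
#' Matched genome-1 genes are numbered 1..m in gene order; the genome-2 gene
#' order is rewritten in those labels, with a negative sign where the strands
#' of the matched genes disagree. Unmatched genes are skipped. Only defined
#' when the matched genes lie on a single chromosome in each genome.
#'
#' @param assignment Assignment tibble (`gene1`, `gene2`).
#' @param genome1,genome2 [genome_tbl()]s.
#' @return Integer vector (signed permutation), possibly empty.
#' @export
induced_permutation <- function(assignment, genome1, genome2) {
  if (!all(assignment$gene1 %in% genome1$gene_id) ||
      !all(assignment$gene2 %in% genome2$gene_id)) {
    abort_op("assignment references genes absent from the genomes")
  }
  g1 <- genome1[genome1$gene_id %in% assignment$gene1, ]
  g1 <- g1[order_c(g1$chromosome, g1$index), ]
  g2 <- genome2[genome2$gene_id %in% assignment$gene2, ]
  g2 <- g2[order_c(g2$chromosome, g2$index), ]
  if (nrow(g1) == 0L) return(integer())
  if (length(unique(g1$chromosome)) > 1L ||
      length(unique(g2$chromosome)) > 1L) {
    abort_op("matched genes span several chromosomes; use rd_distance()")
  }
  partner <- setNames(assignment$gene1, assignment$gene2)
  label <- setNames(seq_len(nrow(g1)), g1$gene_id)
  strand1 <- setNames(g1$strand, g1$gene_id)
  p1 <- partner[g2$gene_id]
  as.integer(label[p1] * g2$strand * strand1[p1])
}

#' RD score of a one-to-one matching
#'
#' The reversal component is the exact signed reversal distance of the induced
#' permutation when the matched genes are unichromosomal in both genomes, and
#' the DCJ adjacency-graph distance otherwise (a standard tight surrogate for
#' the reversal/translocation/fusion/fission distance; flagged in `method`).
#' The duplication component counts one unit per unmatched gene of either
#' genome.
#'
#' @param assignment Assignment tibble (`gene1`, `gene2`).
#' @param genome1,genome2 [genome_tbl()]s.
#' @return List of class `rd_score`: `reversals`, `duplications`, `total`,
#'   `method`.
#' @export
rd_distance <- function(assignment, genome1, genome2) {
  m <- nrow(assignment)
  uni <- length(unique(genome1$chromosome)) <= 1L &&
    length(unique(genome2$chromosome)) <= 1L
  if (uni) {
    perm <- induced_permutation(assignment, genome1, genome2)
    rev <- reversal_distance(perm)$distance
    method <- "hp_reversal"
  } else {
    rev <- dcj_distance(assignment, genome1, genome2)
    method <- "dcj"
  }
  dup <- (nrow(genome1) + nrow(genome2)) - 2L * m
  structure(list(reversals = as.integer(rev), duplications = as.integer(dup),
                 total = as.integer(rev + dup), method = method),
            class = "rd_score")
}

#' @export
print.rd_score <- function(x, ...) {
  cat(sprintf("RD score: %d reversals (%s) + %d duplications = %d\n",
              x$reversals, x$method, x$duplications, x$total))
  invisible(x)
}

# DCJ distance over the matched markers: d = N - C - I/2 on the adjacency
# graph (C cycles, I odd paths), chromosomes treated as linear.
dcj_distance <- function(assignment, genome1, genome2) {
  m <- nrow(assignment)
  if (m == 0L) return(0L)
  lab1 <- setNames(seq_len(m), assignment$gene1)
  lab2 <- setNames(seq_len(m), assignment$gene2)
  adjacencies <- function(genome, lab) {
    g <- genome[genome$gene_id %in% names(lab), ]
    g <- g[order_c(g$chromosome, g$index), ]
    out <- list()
    for (chr in split(g, g$chromosome)) {
      k <- lab[chr$gene_id]
      s <- chr$strand
      ## extremities: gene i -> tail 2i-1, head 2i; '+' reads tail..head
      left <- ifelse(s > 0L, 2L * k - 1L, 2L * k)
      right <- ifelse(s > 0L, 2L * k, 2L * k - 1L)
      n <- length(k)
      ends <- c(0L, right)      # 0 = telomere marker
      starts <- c(left, 0L)
      out[[length(out) + 1L]] <- cbind(ends, starts)
    }
    do.call(rbind, out)
  }
  a1 <- adjacencies(genome1, lab1)
  a2 <- adjacencies(genome2, lab2)
  ## neighbor map per genome: each extremity pairs with one other extremity
  ## or with a telomere (0)
  nb <- function(adj) {
    v <- integer(2L * m)
    for (r in seq_len(nrow(adj))) {
      x <- adj[r, 1]; y <- adj[r, 2]
      if (x > 0L) v[x] <- y
      if (y > 0L) v[y] <- x
    }
    v
  }
  n1 <- nb(a1); n2 <- nb(a2)
  ## connected components over extremities; a component with any telomeric
  ## extremity is a path (odd iff its extremity count is odd), else a cycle
  parent <- seq_len(2L * m)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  for (x in seq_len(2L * m)) {
    for (y in c(n1[x], n2[x])) {
      if (y > 0L) {
        rx <- find(x); ry <- find(y)
        if (rx != ry) parent[max(rx, ry)] <- min(rx, ry)
      }
    }
  }
  roots <- vapply(seq_len(2L * m), find, integer(1))
  is_pathy <- n1 == 0L | n2 == 0L
  cycles <- 0L; odd_paths <- 0L
  for (members in split(seq_len(2L * m), roots)) {
    if (any(is_pathy[members])) {
      if (length(members) %% 2L == 1L) odd_paths <- odd_paths + 1L
    } else {
      cycles <- cycles + 1L
    }
  }
  as.integer(m - cycles - odd_paths %/% 2L)
}

#' Initial one-to-one assignment within families
#'
#' Within each family, bidirectional best hits are matched first; remaining
#' genes are matched greedily by descending similarity score with
#' deterministic tie-breaking (score, then gene-id pair). Cross-genome family
#' pairs without a recorded score are matched last (score 0) so that family
#' membership alone suffices for a candidate pair.
#'
#' @param families Family tibble (`gene_id`, `family`).
#' @param similarity Similarity tibble.
#' @param genome1,genome2 [genome_tbl()]s.
#' @param bh Optional precomputed [best_hits()] table.
#' @return Assignment tibble with `provenance = "core"`.
#' @export
initial_assignment <- function(families, similarity, genome1, genome2,
                               bh = NULL) {
  if (is.null(bh)) bh <- best_hits(similarity, genome1, genome2)
  fam <- setNames(families$family, families$gene_id)
  in1 <- genome1$gene_id
  in2 <- genome2$gene_id
  used1 <- new.env(parent = emptyenv())
  used2 <- new.env(parent = emptyenv())
  pairs <- list()
  take <- function(a, b) {
    assign(a, TRUE, envir = used1)
    assign(b, TRUE, envir = used2)
    pairs[[length(pairs) + 1L]] <<- c(a, b)
  }
  ## BBH pairs first (same family, genome1 gene listed first)
  bbh <- bh[bh$bbh & bh$gene_id %in% in1 & bh$best_hit %in% in2, ]
  bbh <- bbh[!is.na(fam[bbh$gene_id]) & !is.na(fam[bbh$best_hit]) &
               fam[bbh$gene_id] == fam[bbh$best_hit], ]
  bbh <- bbh[order_c(bbh$gene_id), ]
  for (r in seq_len(nrow(bbh))) take(bbh$gene_id[r], bbh$best_hit[r])
  ## greedy on remaining cross-genome family pairs
  score_of <- setNames(similarity$score, pair_key(similarity$gene1,
                                                  similarity$gene2))
  fam_tbl <- tibble(gene_id = c(in1, in2),
                    side = rep(c(1L, 2L), c(length(in1), length(in2))),
                    family = unname(fam[c(in1, in2)]))
  fam_tbl <- fam_tbl[!is.na(fam_tbl$family), ]
  cand <- fam_tbl |>
    filter(.data$side == 1L) |>
    inner_join(fam_tbl |> filter(.data$side == 2L),
               by = "family", relationship = "many-to-many")
  if (nrow(cand)) {
    cand$score <- unname(score_of[pair_key(cand$gene_id.x, cand$gene_id.y)])
    cand$score[is.na(cand$score)] <- 0
    cand <- cand[order(-cand$score, cand$gene_id.x, cand$gene_id.y,
                       method = "radix"), ]
    for (r in seq_len(nrow(cand))) {
      a <- cand$gene_id.x[r]; b <- cand$gene_id.y[r]
      if (!exists(a, envir = used1) && !exists(b, envir = used2)) take(a, b)
    }
  }
  if (!length(pairs)) {
    return(validate_assignment(tibble(gene1 = character(), gene2 = character(),
                                      provenance = character())))
  }
  mat <- do.call(rbind, pairs)
  validate_assignment(tibble(gene1 = mat[, 1], gene2 = mat[, 2],
                             provenance = "core"))
}

#' Noise pair detection by strict-improvement local search
#'
#' Scans the assignment in deterministic order (pairs sorted by id) and
#' applies two move types: uncoupling one pair, and swapping partners between
#' two pairs of the same family. A move is accepted only when the RD total
#' strictly decreases; the search runs to a fixpoint, so the returned
#' assignment's RD never exceeds the input's.
#'
#' @param assignment Assignment tibble.
#' @param genome1,genome2 [genome_tbl()]s.
#' @param families Optional family tibble enabling swap moves.
#' @return The improved assignment tibble.
#' @export
noise_pair_detection <- function(assignment, genome1, genome2,
                                 families = NULL) {
  cur <- validate_assignment(assignment)
  fam <- if (!is.null(families)) {
    setNames(families$family, families$gene_id)
  } else NULL
  uni <- length(unique(genome1$chromosome)) <= 1L &&
    length(unique(genome2$chromosome)) <= 1L
  total_genes <- nrow(genome1) + nrow(genome2)
  if (uni) {
    p1 <- setNames(genome1$index, genome1$gene_id)
    s1 <- setNames(genome1$strand, genome1$gene_id)
    p2 <- setNames(genome2$index, genome2$gene_id)
    s2 <- setNames(genome2$strand, genome2$gene_id)
    score <- function(g1v, g2v) {
      m <- length(g1v)
      if (m == 0L) return(total_genes)
      lab <- integer(m)
      lab[order(p1[g1v])] <- seq_len(m)
      perm <- (lab * s1[g1v] * s2[g2v])[order(p2[g2v])]
      reversal_distance(perm)$distance + (total_genes - 2L * m)
    }
  } else {
    score <- function(g1v, g2v) {
      rd_distance(tibble(gene1 = g1v, gene2 = g2v),
                  genome1, genome2)$total
    }
  }
  g1v <- cur$gene1
  g2v <- cur$gene2
  best <- score(g1v, g2v)
  repeat {
    improved <- FALSE
    ## uncouple moves
    r <- 1L
    while (r <= length(g1v)) {
      tot <- score(g1v[-r], g2v[-r])
      if (tot < best) {
        g1v <- g1v[-r]
        g2v <- g2v[-r]
        best <- tot
        improved <- TRUE
      } else {
        r <- r + 1L
      }
    }
    ## swap moves within families
    if (!is.null(fam) && length(g1v) >= 2L) {
      groups <- split(seq_along(g1v), unname(fam[g1v]))
      for (g in groups) {
        if (length(g) < 2L) next
        done <- FALSE
        for (ii in seq_along(g)[-length(g)]) {
          for (jj in (ii + 1L):length(g)) {
            a <- g[ii]; b <- g[jj]
            cand2 <- g2v
            cand2[c(a, b)] <- cand2[c(b, a)]
            tot <- score(g1v, cand2)
            if (tot < best) {
              g2v <- cand2
              best <- tot
              improved <- TRUE
              done <- TRUE
              break
            }
          }
          if (done) break
        }
      }
    }
    if (!improved) break
  }
  prov <- setNames(cur$provenance, cur$gene1)
  validate_assignment(tibble(gene1 = g1v, gene2 = g2v,
                             provenance = unname(prov[g1v])))
}
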