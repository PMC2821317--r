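# Post-processing: find collinear orthologous blocks (allowing single-gene
# gaps) and recover additional one-to-one pairs from corresponding gaps.

#' Find orthologous blocks of an assignment
#'
#' A block is a maximal run of assigned pairs that are consecutive on both
#' genomes in the same or exactly reversed orientation; one unassigned gene
#' between two consecutive assigned pairs on either genome does not break the
#' block (such positions are the "gaps" the post-processing step inspects).
#' Blocks have at least two pairs.
#'
#' @param assignment Assignment tibble.
#' @param genome1,genome2 [genome_tbl()]s.
#' @return Tibble with one row per pair in a block: `block_id`, `orientation`
#'   (+1 or -1), `gene1`, `gene2`, plus the order indices `index1`, `index2`
#'   and chromosomes.
#' @export
find_blocks <- function(assignment, genome1, genome2) {
  if (nrow(assignment) == 0L) return(empty_blocks())
  ix1 <- genome1[, c("gene_id", "chromosome", "index")]
  ix2 <- genome2[, c("gene_id", "chromosome", "index")]
  p <- assignment |>
    inner_join(ix1, by = c(gene1 = "gene_id")) |>
    rename(chr1 = "chromosome", index1 = "index") |>
    inner_join(ix2, by = c(gene2 = "gene_id")) |>
    rename(chr2 = "chromosome", index2 = "index") |>
    arrange(.data$chr1, .data$index1)
  out <- list()
  bid <- 0L
  for (chr in split(p, p$chr1)) {
    n <- nrow(chr)
    run_start <- 1L
    run_orient <- 0L
    flush <- function(from, to, orient) {
      if (to - from < 1L) return()
      bid <<- bid + 1L
      blk <- chr[from:to, ]
      blk$block_id <- bid
      blk$orientation <- if (orient == 0L) 1L else orient
      out[[length(out) + 1L]] <<- blk
    }
    if (n >= 2L) {
      for (t in 2L:n) {
        step1 <- chr$index1[t] - chr$index1[t - 1L]
        step2 <- chr$index2[t] - chr$index2[t - 1L]
        same_chr2 <- chr$chr2[t] == chr$chr2[t - 1L]
        ok_fwd <- same_chr2 && step1 %in% 1:2 && step2 %in% 1:2
        ok_rev <- same_chr2 && step1 %in% 1:2 && step2 %in% -(1:2)
        dir <- if (ok_fwd) 1L else if (ok_rev) -1L else 0L
        compatible <- dir != 0L && (run_orient == 0L || run_orient == dir)
        if (!compatible) {
          flush(run_start, t - 1L, run_orient)
          run_start <- t
          run_orient <- 0L
        } else {
          run_orient <- dir
        }
      }
    }
    flush(run_start, n, run_orient)
  }
  if (!length(out)) return(empty_blocks())
  res <- bind_rows(out)
  res[, c("block_id", "orientation", "gene1", "gene2",
          "chr1", "index1", "chr2", "index2")]
}

empty_blocks <- function() {
  tibble(block_id = integer(), orientation = integer(),
         gene1 = character(), gene2 = character(),
         chr1 = character(), index1 = integer(),
         chr2 = character(), index2 = integer())
}

#' Recover one-to-one pairs from corresponding single-gene gaps
#'
#' Inside each block, a candidate gap is a position where exactly one
#' unassigned gene sits between the same two flanking assigned pairs on both
#' genomes (orientation-adjusted). The gap pair is added when at least one of
#' the two genes is the best hit of the other; additions carry
#' `provenance = "postprocess"` and the result remains one-to-one. Family
#' agreement is not required unless `require_same_family = TRUE`.
#'
#' @param blocks Output of [find_blocks()].
#' @param assignment Assignment tibble.
#' @param genome1,genome2 [genome_tbl()]s.
#' @param bh [best_hits()] table.
#' @param families Optional family tibble (used only with
#'   `require_same_family`).
#' @param require_same_family Require gap genes to share a family.
#' @return The augmented assignment tibble.
#' @export
recover_gap_pairs <- function(blocks, assignment, genome1, genome2, bh,
                              families = NULL, require_same_family = FALSE) {
  if (nrow(blocks) == 0L) return(validate_assignment(assignment))
  assigned1 <- assignment$gene1
  assigned2 <- assignment$gene2
  by_pos1 <- setNames(genome1$gene_id, paste(genome1$chromosome,
                                             genome1$index))
  by_pos2 <- setNames(genome2$gene_id, paste(genome2$chromosome,
                                             genome2$index))
  best <- setNames(bh$best_hit, bh$gene_id)
  fam <- if (!is.null(families)) {
    setNames(families$family, families$gene_id)
  } else NULL
  added <- list()
  used1 <- character(); used2 <- character()
  for (blk in split(blocks, blocks$block_id)) {
    n <- nrow(blk)
    if (n < 2L) next
    for (t in 2L:n) {
      gap1 <- blk$index1[t] - blk$index1[t - 1L] == 2L
      gap2 <- abs(blk$index2[t] - blk$index2[t - 1L]) == 2L
      if (!gap1 || !gap2) next
      x <- by_pos1[[paste(blk$chr1[t], blk$index1[t - 1L] + 1L)]]
      mid2 <- (blk$index2[t] + blk$index2[t - 1L]) %/% 2L
      y <- by_pos2[[paste(blk$chr2[t], mid2)]]
      if (is.null(x) || is.null(y)) next
      if (x %in% assigned1 || x %in% assigned2 ||
          y %in% assigned1 || y %in% assigned2) next
      if (x %in% used1 || y %in% used2) next
      hit <- (!is.na(best[x]) && best[x] == y) ||
        (!is.na(best[y]) && best[y] == x)
      if (!hit) next
      if (require_same_family && !is.null(fam)) {
        if (is.na(fam[x]) || is.na(fam[y]) || fam[x] != fam[y]) next
      }
      used1 <- c(used1, x); used2 <- c(used2, y)
      added[[length(added) + 1L]] <- tibble(gene1 = x, gene2 = y,
                                            provenance = "postprocess")
    }
  }
  out <- bind_rows(assignment, bind_rows(added))
  validate_assignment(out)
}
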