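# Readers and writers for the external formats the pipeline touches:
# FASTA, BLAST tabular (outfmt 6), newick, pair/family/truth TSVs.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased. For protein input, `*` stop characters are
#' stripped. Duplicate record ids are an error; an empty file gives an empty
#' map. Record ids are the first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param type `"dna"` or `"protein"`; controls `*` stripping.
#' @return Named character vector, id to sequence.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (file.info(path)$size == 0) return(setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort_op("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  seqs <- toupper(as.character(set))
  if (type == "protein") seqs <- gsub("*", "", seqs, fixed = TRUE)
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    writeLines(paste0(">", id), con)
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Write / read an ortholog pair table
#'
#' Three-column TSV: `gene1`, `gene2`, `provenance` (`core` or `postprocess`).
#'
#' @param assignment An assignment tibble (see [validate_assignment()]).
#' @param path File path.
#' @return `write_pairs()` returns the path invisibly; `read_pairs()` returns
#'   the assignment tibble.
#' @export
write_pairs <- function(assignment, path) {
  readr::write_tsv(assignment[, c("gene1", "gene2", "provenance")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  validate_assignment(out)
}

#' Validate a one-to-one ortholog assignment
#'
#' Checks that each gene appears in at most one pair and, when a family map is
#' supplied, that both genes of every pair belong to the same family.
#'
#' @param pairs Data frame with columns `gene1`, `gene2` (and optionally
#'   `provenance`, filled with `"core"` if absent).
#' @param families Optional family tibble (`gene_id`, `family`).
#' @return The validated assignment tibble (columns `gene1`, `gene2`,
#'   `provenance`), sorted by `gene1`.
#' @export
validate_assignment <- function(pairs, families = NULL) {
  pairs <- as_tibble(pairs)
  if (!"provenance" %in% names(pairs)) pairs$provenance <- "core"
  pairs <- pairs[, c("gene1", "gene2", "provenance")]
  if (anyDuplicated(pairs$gene1) || anyDuplicated(pairs$gene2)) {
    abort_op("assignment is not one-to-one")
  }
  if (!is.null(families)) {
    fam <- setNames(families$family, families$gene_id)
    bad <- fam[pairs$gene1] != fam[pairs$gene2]
    if (any(bad, na.rm = TRUE) || anyNA(fam[pairs$gene1]) || anyNA(fam[pairs$gene2])) {
      abort_op("pair (%s, %s) spans two families or unknown genes",
               pairs$gene1[which(bad)[1]], pairs$gene2[which(bad)[1]])
    }
  }
  pairs[order_c(pairs$gene1), ]
}

#' Import a similarity matrix from NCBI BLAST tabular output
#'
#' Reads the 12-column `-outfmt 6` dialect; the score is the bit-score column,
#' symmetrised by taking the maximum over both directions. Self hits are
#' dropped.
#'
#' @param path BLAST tabular file.
#' @return A similarity tibble (`gene1`, `gene2`, `score`) with `gene1 <
#'   gene2`, attribute `source = "imported"`.
#' @export
read_blast_tab <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) return(new_similarity(tibble(
    gene1 = character(), gene2 = character(), score = double()), "imported"))
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 12L)
  if (length(bad)) abort_op("malformed BLAST tabular line %d in %s", bad[1], path)
  q <- vapply(f, `[`, character(1), 1L)
  s <- vapply(f, `[`, character(1), 2L)
  bit <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 12L)))
  if (anyNA(bit)) abort_op("malformed bit score on line %d in %s",
                           which(is.na(bit))[1], path)
  keep <- q != s
  edges <- tibble(key = pair_key(q[keep], s[keep]), score = bit[keep])
  agg <- edges |>
    group_by(.data$key) |>
    summarise(score = max(.data$score), .groups = "drop")
  parts <- stringr::str_split_fixed(agg$key, "\r", 2)
  new_similarity(tibble(gene1 = parts[, 1], gene2 = parts[, 2],
                        score = agg$score), "imported")
}

#' Write a tree in newick format
#'
#' Branch lengths and internal D/S node labels are preserved.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read gene families in MCL "abc" style
#'
#' One family per line, member gene ids separated by tabs.
#'
#' @param families Family tibble (`gene_id`, `family`).
#' @param path File path.
#' @export
write_families <- function(families, path) {
  fam <- split(families$gene_id, families$family)
  writeLines(vapply(fam, function(g) paste(sort_c(g), collapse = "\t"),
                    character(1)), path)
  invisible(path)
}

#' @rdname write_families
#' @export
read_families <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  members <- strsplit(ln, "\t", fixed = TRUE)
  tibble(gene_id = unlist(members),
         family = rep(seq_along(members), lengths(members)))
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a per-genome gene-symbol table
#'
#' Two-column TSV `gene_id`, `symbol` used by [evaluate_symbols()].
#'
#' @param path File path.
#' @return Tibble with columns `gene_id`, `symbol`.
#' @export
read_symbol_table <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
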