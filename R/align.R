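# Per-family protein multiple alignment (built-in progressive aligner or
# imported aligned FASTA) and back-translation to codon alignments.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Align a family of protein sequences
#'
#' Built-in mode is a progressive aligner: a BIONJ guide tree is built from
#' pairwise global alignment scores, then profiles are merged bottom-up with
#' profile-profile global alignment (BLOSUM62, affine gaps open 11 / extend
#' 1). Imported mode loads an externally produced aligned FASTA and checks
#' that it covers the family.
#'
#' @param proteins Named character vector, gene id to protein sequence.
#' @param mode `"builtin"` or `"imported"`.
#' @param path Aligned FASTA path for imported mode.
#' @param band Half-width of the diagonal band explored by the alignment DP
#'   (widened automatically by the profile length difference); 0 disables
#'   banding. Families of closely related genes are insensitive to this.
#' @return Named character vector of aligned rows (equal lengths), in the
#'   input order.
#' @export
align_family <- function(proteins, mode = c("builtin", "imported"),
                         path = NULL, band = 60L) {
  mode <- match.arg(mode)
  if (mode == "imported") {
    aln <- read_fasta(path, type = "dna")   # keep '*' as-is in imports
    if (length(unique(nchar(aln))) > 1L) {
      abort_op("imported alignment rows have unequal lengths in %s", path)
    }
    missing <- setdiff(names(proteins), names(aln))
    if (length(missing)) {
      abort_op("imported alignment lacks gene '%s'", missing[1])
    }
    return(aln[names(proteins)])
  }
  n <- length(proteins)
  if (n == 0L) return(character())
  if (n == 1L) return(proteins)
  sub <- blosum62_matrix()
  if (n == 2L) {
    return(merge_alignments(proteins[1], proteins[2], sub, band = band))
  }
  ## guide tree from pairwise global alignment scores
  ids <- names(proteins)
  profs <- lapply(proteins, profile_of, sub = sub)
  scores <- matrix(0, n, n, dimnames = list(ids, ids))
  combs <- utils::combn(n, 2)
  for (cix in seq_len(ncol(combs))) {
    i <- combs[1, cix]; j <- combs[2, cix]
    scores[i, j] <- .profile_align_path(profs[[i]], profs[[j]], sub,
                                        11, 1, band)$score
  }
  scores <- scores + t(scores)
  self <- vapply(seq_len(n), function(i) {
    ch <- strsplit(proteins[i], "", fixed = TRUE)[[1]]
    sum(sub[cbind(ch, ch)])
  }, double(1))
  d <- outer(self, self, "+") / 2 - scores
  d <- pmax(d, 0)
  diag(d) <- 0
  if (max(d) > 0) d <- d / max(d)   # guide tree only needs relative distances
  dimnames(d) <- list(ids, ids)
  guide <- nj_tree(d, variant = "bionj")
  merge_by_guide(proteins, guide, sub, band)
}

merge_by_guide <- function(proteins, guide, sub, band = 0L) {
  ntip <- length(guide$tip.label)
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  aln_at <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip)) {
    aln_at[[i]] <- proteins[guide$tip.label[i]]
  }
  do_node <- function(node) {
    if (node <= ntip) return(aln_at[[node]])
    parts <- lapply(kids[[as.character(node)]], do_node)
    acc <- parts[[1]]
    for (k in seq_along(parts)[-1]) {
      acc <- merge_alignments(acc, parts[[k]], sub, band = band)
    }
    acc
  }
  out <- do_node(ntip + 1L)
  out[names(proteins)]
}

# merge two alignments (named character vectors of equal-length rows)
merge_alignments <- function(a, b, sub, band = 0L) {
  pa <- profile_of(a, sub)
  pb <- profile_of(b, sub)
  path <- .profile_align_path(pa, pb, sub, 11, 1, band)$path
  la <- strsplit(a, "", fixed = TRUE)
  lb <- strsplit(b, "", fixed = TRUE)
  ia <- cumsum(path != 2L)   # consumed column of A at each step (0 if gap)
  ib <- cumsum(path != 1L)
  rows_a <- vapply(la, function(ch) {
    out <- rep("-", length(path))
    take <- path != 2L
    out[take] <- ch[ia[take]]
    paste(out, collapse = "")
  }, character(1))
  rows_b <- vapply(lb, function(ch) {
    out <- rep("-", length(path))
    take <- path != 1L
    out[take] <- ch[ib[take]]
    paste(out, collapse = "")
  }, character(1))
  c(setNames(rows_a, names(a)), setNames(rows_b, names(b)))
}

# residue frequency profile (alphabet x columns); gaps contribute no mass
profile_of <- function(rows, sub) {
  alpha <- rownames(sub)
  K <- length(alpha)
  L <- nchar(rows[1])
  m <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
              ncol = L, byrow = TRUE)
  code <- match(m, alpha)                      # NA for gaps/unknowns
  colix <- rep(seq_len(L), each = nrow(m))
  keep <- !is.na(code)
  counts <- tabulate(code[keep] + K * (colix[keep] - 1L), nbins = K * L)
  matrix(counts / nrow(m), K, L, dimnames = list(alpha, NULL))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column becomes a 3-nucleotide codon column; protein gaps
#' become `---`. Every CDS must translate exactly to its (ungapped) protein
#' row; a trailing stop codon is stripped first.
#'
#' @param protein_alignment Named character vector of aligned protein rows.
#' @param cds_map Named character vector, gene id to CDS.
#' @return Named character vector of aligned codon rows (class
#'   `codon_alignment`).
#' @export
back_translate <- function(protein_alignment, cds_map) {
  out <- vapply(names(protein_alignment), function(id) {
    row <- protein_alignment[[id]]
    cds <- cds_map[[id]]
    if (is.null(cds) || is.na(cds)) abort_op("no CDS for gene '%s'", id)
    if (nchar(cds) %% 3L != 0L) {
      abort_op("CDS length of gene '%s' is not divisible by 3", id)
    }
    aa <- strsplit(row, "", fixed = TRUE)[[1]]
    ungapped <- aa[aa != "-"]
    if (nchar(cds) == 3L * (length(ungapped) + 1L)) {
      cds <- strip_trailing_stop(cds)   # protein lacks the terminal stop
    }
    if (nchar(cds) != 3L * length(ungapped)) {
      abort_op("CDS/protein length mismatch for gene '%s'", id)
    }
    trans <- translate_cds(cds)
    trans_aa <- strsplit(trans, "", fixed = TRUE)[[1]]
    mism <- which(trans_aa != ungapped)
    if (length(mism)) {
      abort_op("CDS of gene '%s' does not translate to its protein at position %d",
               id, mism[1])
    }
    codons <- substring(cds, 3L * seq_along(ungapped) - 2L,
                        3L * seq_along(ungapped))
    cod <- rep("---", length(aa))
    cod[aa != "-"] <- codons
    paste(cod, collapse = "")
  }, character(1))
  structure(out, class = "codon_alignment")
}
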