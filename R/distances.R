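# F84 pairwise distances on codon alignments, neighbor-joining trees, and
# rooting by an artificial outgroup.

#' F84 distance from observed proportions and base frequencies
#'
#' With `A`, `B`, `C` the composite frequency terms (`piR = piA + piG`,
#' `piY = piC + piT`; `A = piC piT / piY + piA piG / piR`;
#' `B = piC piT + piA piG`; `C = piR piY`), the distance is
#' `-2A log(1 - P/(2A) - (A - B) Q / (2AC)) + 2(A - B - C) log(1 - Q/(2C))`
#' where `P` and `Q` are the observed transition and transversion difference
#' proportions. Returns `NA` when a logarithm argument is non-positive
#' (saturation).
#'
#' @param P,Q Transition / transversion difference proportions.
#' @param freqs Numeric vector of base frequencies named `A`, `C`, `G`, `T`.
#' @return The F84 distance (possibly `NA` on saturation).
#' @export
f84_formula <- function(P, Q, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  freqs <- freqs / sum(freqs)
  piA <- freqs[["A"]]; piC <- freqs[["C"]]
  piG <- freqs[["G"]]; piT <- freqs[["T"]]
  piR <- piA + piG; piY <- piC + piT
  A <- piC * piT / piY + piA * piG / piR
  B <- piC * piT + piA * piG
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  ifelse(arg1 <= 0 | arg2 <= 0, NA_real_,
         -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2))
}

#' Pairwise F84 distance matrix from a codon alignment
#'
#' Sites with a gap or ambiguity in either row of a pair are excluded
#' (pairwise deletion). Base frequencies are estimated from the pooled pair of
#' rows by default, or from the whole alignment with `freq_mode = "family"`.
#' Saturated pairs are capped at `max_dist` with a warning so the matrix stays
#' complete.
#'
#' @param codon_alignment Named character vector of equal-length aligned
#'   nucleotide rows.
#' @param freq_mode `"pair"` or `"family"` frequency estimation.
#' @param max_dist Ceiling used for saturated distances.
#' @return Symmetric distance matrix with row/column names.
#' @export
f84_distance <- function(codon_alignment, freq_mode = c("pair", "family"),
                         max_dist = 10.0) {
  freq_mode <- match.arg(freq_mode)
  ids <- names(codon_alignment)
  n <- length(ids)
  if (n < 2L) abort_op("need at least two rows")
  if (length(unique(nchar(codon_alignment))) != 1L) {
    abort_op("alignment rows have unequal lengths")
  }
  codes <- lapply(codon_alignment, function(s) {
    x <- utf8ToInt(s)
    out <- integer(length(x))
    out[x == utf8ToInt("A")] <- 1L
    out[x == utf8ToInt("C")] <- 2L
    out[x == utf8ToInt("G")] <- 3L
    out[x == utf8ToInt("T")] <- 4L
    out
  })
  fam_freq <- NULL
  if (freq_mode == "family") {
    all <- unlist(codes)
    all <- all[all > 0L]
    fam_freq <- tabulate(all, 4L) / length(all)
    names(fam_freq) <- c("A", "C", "G", "T")
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- codes[[i]]; b <- codes[[j]]
      use <- a > 0L & b > 0L
      if (!any(use)) abort_op("no comparable sites between '%s' and '%s'",
                              ids[i], ids[j])
      a <- a[use]; b <- b[use]
      diff <- a != b
      transition <- diff & ((a + b == 4L) | (a + b == 6L & a != b & (a %% 2L == 0L)))
      ## transitions: A(1)<->G(3) sum 4; C(2)<->T(4) sum 6 with both even
      P <- sum(transition) / length(a)
      Q <- sum(diff) / length(a) - P
      freqs <- if (freq_mode == "pair") {
        f <- tabulate(c(a, b), 4L) / (2L * length(a))
        names(f) <- c("A", "C", "G", "T")
        f
      } else fam_freq
      if (any(freqs == 0)) {
        freqs <- (freqs + 1e-6) / sum(freqs + 1e-6)  # guard degenerate pairs
      }
      dij <- f84_formula(P, Q, freqs)
      if (is.na(dij) || dij > max_dist) {
        saturated <- saturated + 1L
        dij <- max_dist
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (saturated > 0L) {
    warning(sprintf("%d saturated pair(s) capped at %.1f", saturated, max_dist),
            call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' A thin deterministic surface over `ape::bionj()` (variance-weighted BIONJ,
#' the default) and `ape::nj()` (classical neighbor joining): taxa are
#' canonicalised to lexicographic order before agglomeration so the output is
#' reproducible, and the two-taxon case is handled directly.
#'
#' @param d Symmetric non-negative distance matrix with dimnames.
#' @param variant `"bionj"` or `"nj"`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d, variant = c("bionj", "nj")) {
  variant <- match.arg(variant)
  if (anyNA(d)) abort_op("distance matrix contains NA/NaN")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort_op("distance matrix is not symmetric")
  }
  ids <- sort_c(rownames(d))
  d <- d[ids, ids, drop = FALSE]
  if (length(ids) < 2L) abort_op("need at least two taxa")
  if (length(ids) == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         ids[1], d[1, 2] / 2,
                                         ids[2], d[1, 2] / 2)))
  }
  if (variant == "bionj") ape::bionj(d) else ape::nj(d)
}

OUTGROUP_ID <- ".artificial_outgroup"

#' Root a family tree with an artificial outgroup
#'
#' The distance matrix is expanded by an artificial outgroup at distance
#' twice the maximum entry from every gene, a BIONJ tree is built, rooted on
#' the outgroup edge, and the outgroup removed; the retained root is
#' equivalent to mid-point rooting. For an all-zero matrix the root falls
#' deterministically between the first taxon pair.
#'
#' @param d Symmetric distance matrix (>= 2 taxa).
#' @param variant Neighbor-joining variant, see [nj_tree()].
#' @return A rooted binary `ape::phylo` with unlabeled internal nodes.
#' @export
root_by_artificial_outgroup <- function(d, variant = "bionj") {
  ids <- sort_c(rownames(d))
  d <- d[ids, ids, drop = FALSE]
  n <- length(ids)
  if (n < 2L) abort_op("need at least two taxa to root")
  w <- 2 * max(d)
  if (w <= 0) w <- 1           # all-zero matrix: deterministic arbitrary root
  dx <- rbind(cbind(d, rep(w, n)), c(rep(w, n), 0))
  dimnames(dx) <- list(c(ids, OUTGROUP_ID), c(ids, OUTGROUP_ID))
  tr <- nj_tree(dx, variant = variant)
  tr <- ape::root(tr, outgroup = OUTGROUP_ID, resolve.root = TRUE)
  tr <- ape::drop.tip(tr, OUTGROUP_ID, collapse.singles = TRUE)
  if (!ape::is.rooted(tr)) abort_op("internal error: rooting failed")
  tr$node.label <- rep("", tr$Nnode)
  tr
}
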