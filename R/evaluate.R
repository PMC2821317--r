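# Evaluation of a predicted assignment against simulation truth or gene
# symbols, with sensitivity = TP / assignable and specificity as defined per
# mode (TP / assigned for simulations, TP / (TP + FP) for symbols).

new_eval_report <- function(mode, tp, fp, unknown, assignable, total_assigned,
                            pairs) {
  sens <- if (assignable > 0) tp / assignable else 0
  spec <- if (mode == "simulation") {
    if (total_assigned > 0) tp / total_assigned else 0
  } else {
    if (tp + fp > 0) tp / (tp + fp) else 0
  }
  out <- tibble(mode = mode, tp = tp, fp = fp, unknown = unknown,
                assignable = assignable, total_assigned = total_assigned,
                sensitivity = sens, specificity = spec,
                degenerate = total_assigned == 0L)
  structure(out, class = c("ortho_eval", class(tibble())),
            pair_classification = pairs)
}

#' Evaluate an assignment against simulation truth
#'
#' A predicted pair is TP-eligible when both genes descend from the same
#' speciation-time ancestor; at most one TP is credited per ancestor (first
#' pair in deterministic id order), and any further eligible pair for the same
#' ancestor counts as a false positive, as does any pair of unrelated genes.
#' `assignable` is the number of ancestors with at least one descendant in
#' each genome. Sensitivity is TP / assignable and specificity TP / assigned.
#'
#' @param assignment Assignment tibble.
#' @param truth Truth tibble from [simulate_pair()] (`gene_id`,
#'   `ancestor_id`, `genome_id`).
#' @return A one-row `ortho_eval` tibble; the per-pair classification is in
#'   `attr(, "pair_classification")` and via [generics::tidy()].
#' @export
evaluate_simulation <- function(assignment, truth) {
  anc <- setNames(truth$ancestor_id, truth$gene_id)
  missing <- setdiff(c(assignment$gene1, assignment$gene2), names(anc))
  if (length(missing)) {
    abort_op("gene '%s' is missing from the simulation truth", missing[1])
  }
  gid <- split(truth$ancestor_id, truth$genome_id)
  assignable <- length(Reduce(intersect, gid))
  p <- assignment[order_c(assignment$gene1, assignment$gene2), ]
  a1 <- unname(anc[p$gene1])
  a2 <- unname(anc[p$gene2])
  eligible <- a1 == a2
  credited <- eligible & !duplicated(ifelse(eligible, a1, NA_character_),
                                     incomparables = NA)
  cls <- ifelse(credited, "TP", "FP")
  pairs <- tibble(gene1 = p$gene1, gene2 = p$gene2, ancestor1 = a1,
                  ancestor2 = a2, class = cls)
  new_eval_report("simulation", sum(credited), sum(!credited), 0L,
                  assignable, nrow(p), pairs)
}

#' Evaluate an assignment against gene-symbol tables
#'
#' Classification per pair (case-insensitive): identical official symbols are
#' a true positive; different symbols a false positive; a pair where only one
#' gene has a symbol is a false positive when some other gene on the other
#' genome carries that symbol, and unknown otherwise; pairs without usable
#' symbols are unknown. Symbols matching the junk patterns are treated as
#' absent. `assignable` counts the distinct symbols present on both genomes.
#' Sensitivity is TP / assignable and specificity TP / (TP + FP).
#'
#' @param assignment Assignment tibble.
#' @param symbols1,symbols2 Tibbles (`gene_id`, `symbol`) per genome.
#' @param junk_patterns Regexes of non-informative symbols.
#' @return A one-row `ortho_eval` tibble (see [evaluate_simulation()]).
#' @export
evaluate_symbols <- function(assignment, symbols1, symbols2,
                             junk_patterns = c("^LOC", "^OTTMUSG", "RIK$")) {
  clean <- function(tbl) {
    s <- toupper(tbl$symbol)
    s[!nzchar(s) | is.na(s)] <- NA_character_
    for (pat in junk_patterns) s[grepl(pat, s)] <- NA_character_
    setNames(s, tbl$gene_id)
  }
  s1 <- clean(symbols1)
  s2 <- clean(symbols2)
  sym1 <- unname(s1[assignment$gene1])
  sym2 <- unname(s2[assignment$gene2])
  pool1 <- s1[!is.na(s1)]
  pool2 <- s2[!is.na(s2)]
  cls <- character(nrow(assignment))
  for (r in seq_len(nrow(assignment))) {
    a <- sym1[r]; b <- sym2[r]
    if (!is.na(a) && !is.na(b)) {
      cls[r] <- if (a == b) "TP" else "FP"
    } else if (!is.na(a)) {
      other <- pool2[names(pool2) != assignment$gene2[r]]
      cls[r] <- if (a %in% other) "FP" else "unknown"
    } else if (!is.na(b)) {
      other <- pool1[names(pool1) != assignment$gene1[r]]
      cls[r] <- if (b %in% other) "FP" else "unknown"
    } else {
      cls[r] <- "unknown"
    }
  }
  pairs <- tibble(gene1 = assignment$gene1, gene2 = assignment$gene2,
                  symbol1 = sym1, symbol2 = sym2, class = cls)
  new_eval_report("symbol", sum(cls == "TP"), sum(cls == "FP"),
                  sum(cls == "unknown"),
                  length(intersect(unique(pool1), unique(pool2))),
                  nrow(assignment), pairs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-pair classification of an evaluation report
#' @param x An `ortho_eval` report.
#' @param ... Unused.
#' @return Tibble with one row per assigned pair and its TP/FP/unknown class.
#' @export
tidy.ortho_eval <- function(x, ...) {
  attr(x, "pair_classification")
}

#' One-row summary of an evaluation report
#' @param x An `ortho_eval` report.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @export
glance.ortho_eval <- function(x, ...) {
  out <- x
  attr(out, "pair_classification") <- NULL
  class(out) <- class(tibble())
  out
}
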