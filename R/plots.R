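# ggplot2 displays for benchmark tables and evaluation reports.

#' Plot a benchmark table
#'
#' Mean sensitivity and specificity per parameter set and pipeline variant,
#' against whichever grid parameter varies (or replicate index when none
#' does).
#'
#' @param object An `ortho_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ortho_benchmark <- function(object, ...) {
  summ <- benchmark_summary(object)
  varying <- c("k", "p", "alpha", "beta")[vapply(
    c("k", "p", "alpha", "beta"),
    function(v) length(unique(summ[[v]])) > 1L, logical(1))]
  xvar <- if (length(varying)) varying[1] else "p"
  long <- tidyr::pivot_longer(summ, c("sensitivity", "specificity"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[xvar]], y = .data$value, colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = xvar, y = NULL,
                  title = "Ortholog assignment accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-pair evaluation classes along the genome
#'
#' Shows each assigned pair as a point at its gene-order positions, coloured
#' by TP/FP/unknown class — a quick dot-plot style view of where errors sit.
#'
#' @param eval An `ortho_eval` report.
#' @param genome1,genome2 The [genome_tbl()]s the assignment refers to.
#' @return A ggplot object.
#' @export
plot_pair_classes <- function(eval, genome1, genome2) {
  pairs <- tidy(eval)
  ix1 <- setNames(genome1$index, genome1$gene_id)
  ix2 <- setNames(genome2$index, genome2$gene_id)
  pairs$index1 <- unname(ix1[pairs$gene1])
  pairs$index2 <- unname(ix2[pairs$gene2])
  ggplot2::ggplot(pairs, ggplot2::aes(
    x = .data$index1, y = .data$index2, colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "gene order, genome 1", y = "gene order, genome 2") +
    ggplot2::theme_minimal()
}
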