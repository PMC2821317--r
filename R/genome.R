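#' Build a genome table
#'
#' A genome is represented as a tibble with one row per gene, ordered along
#' each chromosome. All rearrangement computations use the 0-based `index`
#' column (gene order), never base-pair coordinates.
#'
#' @param genes A data frame with at least `gene_id`, `chromosome`, `index`
#'   and `strand` columns. Optional columns: `protein`, `cds`, `symbol`.
#' @param genome_id Single string identifying the genome.
#' @return A tibble of class `genome_tbl` with columns `gene_id`, `genome_id`,
#'   `chromosome`, `index` (0-based, consecutive per chromosome), `strand`
#'   (+1/-1), `protein`, `cds`, `symbol`.
#' @export
genome_tbl <- function(genes, genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  genes <- as_tibble(genes)
  for (col in c("protein", "cds", "symbol")) {
    if (!col %in% names(genes)) genes[[col]] <- NA_character_
  }
  genes$genome_id <- genome_id
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$strand <- as.integer(genes$strand)
  genes$index <- as.integer(genes$index)
  out <- genes[order_c(genes$chromosome, genes$index), c(
    "gene_id", "genome_id", "chromosome", "index", "strand",
    "protein", "cds", "symbol"
  )]
  class(out) <- c("genome_tbl", class(tibble()))
  validate_genome(out)
  out
}

validate_genome <- function(genome) {
  if (anyDuplicated(genome$gene_id)) {
    abort_op("duplicate gene ids in genome '%s'", genome$genome_id[1])
  }
  if (!all(genome$strand %in% c(1L, -1L))) {
    abort_op("strand must be +1 or -1")
  }
  ok <- vapply(split(genome$index, genome$chromosome),
               function(ix) identical(sort(ix), seq_along(ix) - 1L),
               logical(1))
  if (!all(ok)) {
    abort_op("gene indices must be consecutive 0..n-1 within each chromosome")
  }
  invisible(genome)
}

# Recompute consecutive 0-based order indices after gene removal,
# preserving the existing relative order.
recompact_genome <- function(genome) {
  genome <- genome[order_c(genome$chromosome, genome$index), ]
  genome$index <- as.integer(
    stats::ave(genome$index, genome$chromosome, FUN = seq_along) - 1
  )
  genome
}

#' Read a gene table (TSV or GFF3) into a genome
#'
#' TSV input needs columns `gene_id`, `chromosome`, `start`, `end`, `strand`
#' and optionally `symbol`. GFF3 input (detected by a `##gff-version` header
#' or a `.gff`/`.gff3` extension) is restricted to `gene` features, with the
#' gene id taken from the `ID` attribute. Coordinates are 1-based inclusive;
#' genes are sorted by start per chromosome (ties broken by gene id) and
#' assigned 0-based order indices.
#'
#' @param path File path.
#' @param genome_id Identifier for the genome.
#' @return A [genome_tbl()] (without sequences; see [add_gene_sequences()]).
#' @export
read_gene_table <- function(path, genome_id) {
  first <- readLines(path, n = 1L)
  is_gff <- grepl("^##gff-version", first) || grepl("\\.gff3?$", path)
  if (is_gff) {
    tab <- read_gff_genes(path)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("gene_id", "chromosome", "start", "end", "strand")
    if (!all(req %in% names(tab))) {
      abort_op("gene table must have columns: %s", paste(req, collapse = ", "))
    }
  }
  if (nrow(tab) == 0L) {
    return(genome_tbl(tibble(gene_id = character(), chromosome = character(),
                             index = integer(), strand = integer()), genome_id))
  }
  tab$strand <- parse_strand(tab$strand)
  tab <- tab[order_c(tab$chromosome, tab$start, tab$gene_id), ]
  tab$index <- as.integer(
    stats::ave(tab$start, tab$chromosome, FUN = seq_along) - 1
  )
  if (!"symbol" %in% names(tab)) tab$symbol <- NA_character_
  genome_tbl(tab[, c("gene_id", "chromosome", "index", "strand", "symbol")],
             genome_id)
}

parse_strand <- function(s) {
  s <- as.character(s)
  out <- ifelse(s %in% c("+", "1", "+1"), 1L,
                ifelse(s %in% c("-", "-1"), -1L, NA_integer_))
  if (anyNA(out)) {
    abort_op("unknown strand symbol: '%s'", s[which(is.na(out))[1]])
  }
  out
}

read_gff_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::readGFF(path, filter = list(type = "gene"))
    return(tibble(gene_id = as.character(g$ID),
                  chromosome = as.character(g$seqid),
                  start = as.integer(g$start), end = as.integer(g$end),
                  strand = as.character(g$strand)))
  }
  # minimal fallback: 9-column GFF3, gene features only
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) abort_op("malformed GFF3 line %d", bad[1])
  f <- f[vapply(f, function(x) x[3] == "gene", logical(1))]
  ids <- vapply(f, function(x) {
    m <- regmatches(x[9], regexec("(?:^|;)ID=([^;]+)", x[9]))[[1]]
    if (length(m) < 2) abort_op("GFF3 gene feature without ID attribute")
    m[2]
  }, character(1))
  tibble(gene_id = ids,
         chromosome = vapply(f, `[`, character(1), 1L),
         start = as.integer(vapply(f, `[`, character(1), 4L)),
         end = as.integer(vapply(f, `[`, character(1), 5L)),
         strand = vapply(f, `[`, character(1), 7L))
}

#' Attach protein and CDS sequences to a genome
#'
#' A single trailing stop codon is stripped from each CDS before the
#' 3:1 CDS/protein length invariant is checked. Internal stop codons raise a
#' warning but the gene is kept.
#'
#' @param genome A [genome_tbl()].
#' @param proteins,cds Named character vectors (gene id to sequence), e.g.
#'   from [read_fasta()]. Either may be `NULL`.
#' @return The genome with `protein`/`cds` columns filled.
#' @export
add_gene_sequences <- function(genome, proteins = NULL, cds = NULL) {
  if (!is.null(proteins)) {
    genome$protein <- unname(proteins[genome$gene_id])
  }
  if (!is.null(cds)) {
    x <- unname(cds[genome$gene_id])
    x <- ifelse(is.na(x), x, strip_trailing_stop(x))
    genome$cds <- x
  }
  both <- !is.na(genome$protein) & !is.na(genome$cds)
  if (any(both)) {
    bad <- both & nchar(genome$cds) != 3L * nchar(genome$protein)
    if (any(bad)) {
      ## tolerate proteins whose internal stop characters were stripped on
      ## input: if the CDS translation matches after removing '*', restore it
      fixable <- bad
      fixable[bad] <- vapply(which(bad), function(r) {
        tr <- translate_cds(genome$cds[r])
        gsub("*", "", tr, fixed = TRUE) == genome$protein[r]
      }, logical(1))
      genome$protein[fixable] <- translate_cds(genome$cds[fixable])
      bad <- bad & !fixable
    }
    if (any(bad)) {
      abort_op("CDS length != 3 x protein length for gene '%s'",
               genome$gene_id[which(bad)[1]])
    }
    internal_stop <- both &
      grepl("\\*", substr(genome$protein, 1L, nchar(genome$protein) - 1L))
    if (any(internal_stop)) {
      warning(sprintf("%d gene(s) contain internal stop codons (kept)",
                      sum(internal_stop)), call. = FALSE)
    }
  }
  genome
}

#' Keep the longest transcript per gene
#'
#' For genes with alternative splicing variants only the longest transcript is
#' retained; ties are broken by the lexicographically smallest transcript id.
#'
#' @param records A data frame with columns `transcript_id`, `gene_id`,
#'   `sequence`.
#' @return The filtered records, one row per gene.
#' @export
filter_longest_transcript <- function(records) {
  records <- as_tibble(records)
  records$.len <- nchar(records$sequence)
  records <- records[order_c(records$gene_id, -records$.len,
                             records$transcript_id), ]
  out <- records[!duplicated(records$gene_id), ]
  out$.len <- NULL
  out
}

#' Drop genes listed in an exclusion table
#'
#' Annotation-status filters (novel / supercontig / mitochondrial gene removal
#' and the like) are dataset-specific, so they are expressed as a plain
#' exclusion list of gene ids.
#'
#' @param genome A [genome_tbl()].
#' @param exclude Character vector of gene ids to remove.
#' @return The reduced genome with recompacted order indices.
#' @export
exclude_genes <- function(genome, exclude) {
  out <- genome[!genome$gene_id %in% exclude, ]
  recompact_genome(out)
}
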