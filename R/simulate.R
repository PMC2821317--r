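# Genome-evolution simulator: an ancestral single-chromosome genome accumulates
# tandem/random duplications, signed reversals and point-mutation bursts, with
# full ground-truth lineage tracking relative to the speciation-time genome.

#' Simulation parameters
#'
#' @param k Number of duplications in the ancestral genome before speciation.
#' @param p Number of genome-level events (duplications + reversals) applied to
#'   each lineage after speciation.
#' @param alpha Fraction of the `p` events that are duplications.
#' @param beta Fraction of duplications that are tandem (the rest are random).
#' @param n_genes Ancestral gene count.
#' @param gene_len_codons Gene length in codons (CDS length is 3x this).
#' @param mu Per-nucleotide mutation rate parameter: between consecutive
#'   events each gene receives `m ~ Uniform{0, ..., round(3 * gene_len_codons
#'   * mu)}` random substitutions (mean `1.5 * gene_len_codons * mu * 3 / 3`).
#' @param beta_pre Fraction of the `k` pre-speciation duplications that are
#'   tandem; defaults to `beta`.
#' @param seed Optional RNG seed used by [simulate_pair()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(k = 10, p = 50, alpha = 0.75, beta = 0.5,
                       n_genes = 100, gene_len_codons = 1000, mu = 0.01,
                       beta_pre = beta, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            k >= 0, p >= 0, n_genes >= 0)
  structure(list(k = k, p = p, alpha = alpha, beta = beta, n_genes = n_genes,
                 gene_len_codons = gene_len_codons, mu = mu,
                 beta_pre = beta_pre, seed = seed), class = "sim_params")
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Generate the ancestral genome
#'
#' Each gene is an i.i.d. random coding sequence (uniform over the 61 sense
#' codons) of `gene_len_codons` codons, all on the + strand.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with columns `gene_id`, `ancestor`, `strand`, `cds` in
#'   gene order (one chromosome).
#' @export
generate_ancestral <- function(params) {
  n <- params$n_genes
  if (n == 0L) {
    return(tibble(gene_id = character(), ancestor = character(),
                  strand = integer(), cds = character()))
  }
  codons <- sense_codons()
  ids <- sprintf("g%04d", seq_len(n))
  cds <- vapply(seq_len(n), function(i) {
    paste(sample(codons, params$gene_len_codons, replace = TRUE), collapse = "")
  }, character(1))
  tibble(gene_id = ids, ancestor = ids, strand = 1L, cds = cds)
}

#' Apply one gene duplication
#'
#' A tandem duplication copies a random gene and inserts the copy immediately
#' after the source with the same strand. A random duplication inserts the
#' copy at a uniformly random inter-gene position with a uniformly random
#' strand. The copy inherits the source's ancestor id.
#'
#' @param genes Gene-order tibble (`gene_id`, `ancestor`, `strand`, `cds`).
#' @param tandem Logical; tandem or random duplication.
#' @param new_id Id to mint for the copy.
#' @param source Optional source row index (1-based); random if `NULL`.
#' @param position For random duplications, optional insertion slot
#'   (0 = before the first gene, ..., n = after the last); random if `NULL`.
#' @return `list(genes = <updated tibble>, event = <record>)`.
#' @export
apply_duplication <- function(genes, tandem, new_id, source = NULL,
                              position = NULL) {
  n <- nrow(genes)
  if (n == 0L) abort_op("cannot duplicate in an empty genome")
  if (is.null(source)) source <- sample.int(n, 1L)
  copy <- genes[source, ]
  copy$gene_id <- new_id
  if (tandem) {
    at <- source          # insert immediately after the source
  } else {
    if (is.null(position)) position <- sample.int(n + 1L, 1L) - 1L
    at <- position
    copy$strand <- sample(c(1L, -1L), 1L)
  }
  out <- bind_rows(head(genes, at), copy, tail(genes, n - at))
  list(genes = out,
       event = list(type = "duplication", tandem = tandem,
                    source = genes$gene_id[source], new_id = new_id,
                    position = at))
}

#' Apply one signed reversal
#'
#' The segment `i..j` (1-based row positions, `i <= j`, chosen uniformly over
#' all such pairs when not given) is reversed in order with all strands
#' flipped.
#'
#' @param genes Gene-order tibble.
#' @param i,j Optional segment bounds.
#' @return `list(genes = <updated tibble>, event = <record>)`.
#' @export
apply_reversal <- function(genes, i = NULL, j = NULL) {
  n <- nrow(genes)
  if (n == 0L) abort_op("cannot reverse in an empty genome")
  if (is.null(i) || is.null(j)) {
    ii <- sample.int(n, 1L)
    jj <- sample.int(n, 1L)
    i <- min(ii, jj); j <- max(ii, jj)
  }
  stopifnot(i >= 1L, j <= n, i <= j)
  seg <- rev(seq(i, j))
  out <- genes
  out[i:j, ] <- genes[seg, ]
  out$strand[i:j] <- -out$strand[i:j]
  list(genes = out, event = list(type = "reversal", i = i, j = j))
}

#' Apply one mutation burst to every gene
#'
#' Independently for each gene, `m ~ Uniform{0..round(3 * gene_len_codons *
#' mu)}` positions are chosen uniformly with replacement and substituted by a
#' uniformly random different nucleotide.
#'
#' @param genes Gene-order tibble.
#' @param params A [sim_params()] object (uses `gene_len_codons` and `mu`).
#' @return The mutated tibble.
#' @export
mutate_between_events <- function(genes, params) {
  m_max <- round_half_up(3 * params$gene_len_codons * params$mu)
  n <- nrow(genes)
  if (m_max == 0L || n == 0L) return(genes)
  bases <- charToRaw("ACGT")
  base_code <- integer(256)
  base_code[as.integer(bases)] <- 0:3
  lens <- nchar(genes$cds)
  m <- sample.int(m_max + 1L, n, replace = TRUE) - 1L
  tot <- sum(m)
  if (tot == 0L) return(genes)
  big <- charToRaw(paste(genes$cds, collapse = ""))
  offsets <- cumsum(c(0L, lens[-n]))
  gene_ix <- rep.int(seq_len(n), m)
  ## positions uniform with replacement within each gene; substitutions are
  ## to a uniformly random different base (repeated hits on one site resolve
  ## against the pre-burst base; last write wins)
  pos <- offsets[gene_ix] + floor(stats::runif(tot) * lens[gene_ix]) + 1L
  cur <- base_code[as.integer(big[pos])]
  new <- (cur + sample.int(3L, tot, replace = TRUE)) %% 4L
  big[pos] <- bases[new + 1L]
  s <- rawToChar(big)
  genes$cds <- substring(s, offsets + 1L, offsets + lens)
  genes
}

#' Simulate a pair of genomes with ground truth
#'
#' The ancestral genome receives `k` duplications (each tandem with
#' probability `beta_pre`), a speciation happens, and each lineage
#' independently receives `round(p * alpha)` duplications (of which
#' `round(round(p * alpha) * beta)` are tandem) and the remaining
#' `p - round(p * alpha)` events as reversals, in uniformly shuffled order.
#' Mutation bursts are applied before the first event, between consecutive
#' events, and after the last. Ground truth maps every contemporary gene to
#' its ancestor in the speciation-time genome.
#'
#' @param params A [sim_params()] object.
#' @param genome_ids Length-2 character vector of genome identifiers.
#' @return A list of class `sim_pair`: `genome1`, `genome2` ([genome_tbl()]s
#'   with sequences), `truth` (tibble `gene_id`, `ancestor_id`, `genome_id`),
#'   `assignable` (ancestors with descendants in both genomes), `events`
#'   (event log tibble), `params`.
#' @export
simulate_pair <- function(params, genome_ids = c("A", "B")) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  log <- list()
  push <- function(lineage, ev) {
    log[[length(log) + 1L]] <<- c(list(lineage = lineage), ev)
  }

  ## pre-speciation phase: G -> H
  g <- generate_ancestral(params)
  g <- mutate_between_events(g, params)
  if (params$k > 0) {
    for (t in seq_len(params$k)) {
      tandem <- stats::runif(1) < params$beta_pre
      res <- apply_duplication(g, tandem, new_id = sprintf("k%04d", t))
      g <- res$genes
      push("pre", res$event)
      g <- mutate_between_events(g, params)
    }
  }
  ## speciation: reset ancestry to H
  g$ancestor <- g$gene_id

  evolve <- function(h, lineage) {
    pref <- tolower(lineage)
    h$gene_id <- paste0(pref, "_", h$gene_id)
    d <- round_half_up(params$p * params$alpha)
    t <- round_half_up(d * params$beta)
    r <- params$p - d
    events <- c(rep("tdup", t), rep("rdup", d - t), rep("rev", r))
    if (length(events)) events <- sample(events)
    h <- mutate_between_events(h, params)
    ndup <- 0L
    for (e in events) {
      if (e == "rev") {
        res <- apply_reversal(h)
      } else {
        ndup <- ndup + 1L
        res <- apply_duplication(h, tandem = (e == "tdup"),
                                 new_id = sprintf("%s_d%04d", pref, ndup))
      }
      h <- res$genes
      push(lineage, res$event)
      h <- mutate_between_events(h, params)
    }
    h
  }

  g1 <- evolve(g, genome_ids[1])
  g2 <- evolve(g, genome_ids[2])

  finish <- function(h, gid) {
    gt <- tibble(gene_id = h$gene_id, chromosome = "chr1",
                 index = seq_len(nrow(h)) - 1L, strand = h$strand,
                 protein = translate_cds(h$cds), cds = h$cds)
    genome_tbl(gt, gid)
  }
  truth <- bind_rows(
    tibble(gene_id = g1$gene_id, ancestor_id = g1$ancestor,
           genome_id = genome_ids[1]),
    tibble(gene_id = g2$gene_id, ancestor_id = g2$ancestor,
           genome_id = genome_ids[2])
  )
  assignable <- length(intersect(g1$ancestor, g2$ancestor))
  events <- purrr::map_dfr(log, function(e) {
    tibble(lineage = e$lineage, type = e$type,
           tandem = e$tandem %||% NA,
           source = e$source %||% NA_character_,
           new_id = e$new_id %||% NA_character_,
           position = e$position %||% NA_integer_,
           i = e$i %||% NA_integer_, j = e$j %||% NA_integer_)
  })
  structure(list(genome1 = finish(g1, genome_ids[1]),
                 genome2 = finish(g2, genome_ids[2]),
                 truth = truth, assignable = assignable,
                 events = events, params = params),
            class = "sim_pair")
}

#' Write a simulated pair to disk in pipeline input formats
#'
#' Emits per-genome protein and CDS FASTA plus gene tables (TSV with synthetic
#' 1-based coordinates that reproduce the simulated gene order), the truth
#' table as TSV and the event log as JSON.
#'
#' @param sim A [simulate_pair()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in list(sim$genome1, sim$genome2)) {
    gid <- g$genome_id[1] %||% "g"
    write_fasta(setNames(g$cds, g$gene_id),
                file.path(dir, paste0(gid, "_cds.fa")))
    write_fasta(setNames(g$protein, g$gene_id),
                file.path(dir, paste0(gid, "_protein.fa")))
    tab <- tibble(gene_id = g$gene_id, chromosome = g$chromosome,
                  start = 1000L * g$index + 1L,
                  end = 1000L * g$index + 3L * nchar(g$protein),
                  strand = ifelse(g$strand > 0, "+", "-"))
    readr::write_tsv(tab, file.path(dir, paste0(gid, "_genes.tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(sim$events, file.path(dir, "events.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}
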