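# End-to-end orchestration of the four stages: (i) family construction,
# (ii) identification and removal of tandem inparalogs via gene-tree dating,
# (iii) RD-parsimony matching with noise-pair detection, (iv) gap recovery
# inside orthologous blocks. Plus the simulation benchmark harness.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a pair of genomes, or simulation
#' parameters.
#'
#' @param genome1,genome2 [genome_tbl()]s with sequences.
#' @param sim A [sim_params()] object (simulated input).
#' @param similarity Optional precomputed similarity tibble (e.g. from
#'   [read_blast_tab()]); otherwise the built-in scorer runs.
#' @param similarity_opts [similarity_params()].
#' @param mcl [mcl_params()].
#' @param tag_removal Run stage (ii) (tandem-inparalog removal).
#' @param tag_rule Confirmation rule, see [confirm_and_remove()].
#' @param tag_spacer Spacer tolerance for [find_tags()].
#' @param freq_mode F84 frequency estimation, see [f84_distance()].
#' @param nj_variant `"bionj"` or `"nj"`.
#' @param require_same_family_gaps Restrict gap recovery to same-family genes.
#' @param seed Optional RNG seed (simulated input).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome1 = NULL, genome2 = NULL, sim = NULL,
                            similarity = NULL,
                            similarity_opts = similarity_params(),
                            mcl = mcl_params(),
                            tag_removal = TRUE,
                            tag_rule = "adjacent_subset",
                            tag_spacer = 0L,
                            freq_mode = "pair",
                            nj_variant = "bionj",
                            require_same_family_gaps = FALSE,
                            seed = NULL) {
  have_genomes <- !is.null(genome1) && !is.null(genome2)
  have_sim <- !is.null(sim)
  if (have_genomes == have_sim) {
    abort_op("give either genome1+genome2 or sim, not both")
  }
  structure(list(genome1 = genome1, genome2 = genome2, sim = sim,
                 similarity = similarity, similarity_opts = similarity_opts,
                 mcl = mcl, tag_removal = tag_removal, tag_rule = tag_rule,
                 tag_spacer = tag_spacer, freq_mode = freq_mode,
                 nj_variant = nj_variant,
                 require_same_family_gaps = require_same_family_gaps,
                 seed = seed),
            class = "pipeline_config")
}

# stage (i): similarity + families
build_homology <- function(genome1, genome2, config) {
  sim <- config$similarity
  if (is.null(sim)) {
    sim <- similarity_matrix(genome1, genome2, mode = "builtin",
                             params = config$similarity_opts)
  }
  families <- mcl_cluster(sim, genes = c(genome1$gene_id, genome2$gene_id),
                          params = config$mcl)
  list(similarity = sim, families = families)
}

# stage (ii): per-family dated trees -> potential sets -> TAG confirmation
tag_inparalog_stage <- function(genome1, genome2, hom, config) {
  species_of <- c(setNames(rep(genome1$genome_id[1], nrow(genome1)),
                           genome1$gene_id),
                  setNames(rep(genome2$genome_id[1], nrow(genome2)),
                           genome2$gene_id))
  prot <- c(setNames(genome1$protein, genome1$gene_id),
            setNames(genome2$protein, genome2$gene_id))
  cds <- c(setNames(genome1$cds, genome1$gene_id),
           setNames(genome2$cds, genome2$gene_id))
  sets <- list()
  trees <- list()
  next_set <- 0L
  for (members in split(hom$families$gene_id, hom$families$family)) {
    if (length(members) < 2L) next
    members <- sort_c(members)
    aln <- align_family(prot[members])
    codon <- back_translate(aln, cds[members])
    d <- suppressWarnings(f84_distance(codon, freq_mode = config$freq_mode))
    tr <- root_by_artificial_outgroup(d, variant = config$nj_variant)
    tr <- date_duplications(tr, species_of)
    trees[[length(trees) + 1L]] <- tr
    ps <- potential_inparalog_sets(tr, species_of)
    if (nrow(ps)) {
      ps$set_id <- ps$set_id + next_set
      next_set <- max(ps$set_id)
      sets[[length(sets) + 1L]] <- ps
    }
  }
  sets <- if (length(sets)) bind_rows(sets) else
    tibble(set_id = integer(), genome_id = character(), gene_id = character())
  res <- list(trees = trees, potential_sets = sets)
  for (side in 1:2) {
    g <- if (side == 1L) genome1 else genome2
    other <- if (side == 1L) genome2 else genome1
    gsets <- sets[sets$genome_id == g$genome_id[1], ]
    tags <- find_tags(g, hom$families, spacer = config$tag_spacer)
    cr <- confirm_and_remove(g, gsets, tags, hom$similarity, other,
                             rule = config$tag_rule)
    res[[paste0("genome", side)]] <- cr$genome
    res[[paste0("removed", side)]] <- cr$removed
  }
  res
}

# stages (iii) + (iv) on (possibly reduced) genomes
match_and_postprocess <- function(genome1, genome2, hom, config) {
  sim <- hom$similarity
  keep <- sim$gene1 %in% c(genome1$gene_id, genome2$gene_id) &
    sim$gene2 %in% c(genome1$gene_id, genome2$gene_id)
  sim <- sim[keep, ]
  bh <- best_hits(sim, genome1, genome2)
  core <- initial_assignment(hom$families, sim, genome1, genome2, bh = bh)
  core <- noise_pair_detection(core, genome1, genome2,
                               families = hom$families)
  blocks <- find_blocks(core, genome1, genome2)
  final <- recover_gap_pairs(blocks, core, genome1, genome2, bh,
                             families = hom$families,
                             require_same_family =
                               config$require_same_family_gaps)
  list(core_assignment = core, blocks = blocks, assignment = final, bh = bh)
}

#' Run the full ortholog-assignment pipeline
#'
#' Executes family construction, tandem-inparalog removal (unless disabled),
#' RD-parsimony matching with noise-pair detection, and gap recovery, in that
#' order. With simulated input the result also carries the ground truth and
#' an evaluation report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `ortho_result`: `assignment`, `core_assignment`,
#'   `families`, `similarity`, `best_hits`, `removed_inparalogs`, `blocks`,
#'   `genome1`, `genome2` (post-removal), `stage_counts`, and for simulated
#'   input `truth` and `evaluation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    simp <- config$sim
    if (!is.null(config$seed)) simp$seed <- config$seed
    sim <- simulate_pair(simp)
    genome1 <- sim$genome1
    genome2 <- sim$genome2
    truth <- sim$truth
  } else {
    genome1 <- config$genome1
    genome2 <- config$genome2
  }
  hom <- build_homology(genome1, genome2, config)
  removed <- tibble(gene_id = character(), representative = character(),
                    set_id = integer(), genome_id = character())
  g1 <- genome1; g2 <- genome2
  trees <- list()
  if (config$tag_removal) {
    ts <- tag_inparalog_stage(genome1, genome2, hom, config)
    g1 <- ts$genome1
    g2 <- ts$genome2
    trees <- ts$trees
    removed <- bind_rows(
      mutate(ts$removed1, genome_id = genome1$genome_id[1]),
      mutate(ts$removed2, genome_id = genome2$genome_id[1])
    )
  }
  mp <- match_and_postprocess(g1, g2, hom, config)
  counts <- tibble(
    metric = c("genes_genome1", "genes_genome2", "families",
               "inparalogs_removed_genome1", "inparalogs_removed_genome2",
               "core_pairs", "final_pairs"),
    value = c(nrow(genome1), nrow(genome2), max(hom$families$family),
              sum(removed$genome_id == genome1$genome_id[1]),
              sum(removed$genome_id == genome2$genome_id[1]),
              nrow(mp$core_assignment), nrow(mp$assignment))
  )
  out <- list(assignment = mp$assignment, core_assignment = mp$core_assignment,
              families = hom$families, similarity = hom$similarity,
              best_hits = mp$bh, removed_inparalogs = removed,
              blocks = mp$blocks, trees = trees,
              genome1 = g1, genome2 = g2,
              stage_counts = counts, config = config)
  if (!is.null(truth)) {
    out$truth <- truth
    out$evaluation <- evaluate_simulation(mp$assignment, truth)
  }
  structure(out, class = "ortho_result")
}

#' @export
print.ortho_result <- function(x, ...) {
  cat("ortholog assignment pipeline result\n")
  for (r in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-28s %d\n", x$stage_counts$metric[r],
                x$stage_counts$value[r]))
  }
  if (!is.null(x$evaluation)) {
    cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
                x$evaluation$sensitivity, x$evaluation$specificity))
  }
  invisible(x)
}

#' Simulation benchmark over a parameter grid
#'
#' For every parameter set and replicate, simulates a genome pair, runs the
#' full pipeline and the ablation without the tandem-inparalog stage (both
#' sharing the similarity matrix and families), and evaluates both against
#' the simulation truth.
#'
#' @param grid Data frame with columns `k`, `p`, `alpha`, `beta`; defaults to
#'   the single default parameter set (10, 50, 0.75, 0.5).
#' @param replicates Replicates per parameter set.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param base [sim_params()] supplying the non-grid parameters (gene count,
#'   gene length, mutation rate).
#' @param config Optional [pipeline_config()] template for stage options.
#' @return A tibble of class `ortho_benchmark` with one row per run and
#'   variant (`full` / `ablation`).
#' @export
run_benchmark <- function(grid = NULL, replicates = 20, seed = 1,
                          base = sim_params(), config = NULL) {
  if (is.null(grid)) {
    grid <- tibble(k = 10, p = 50, alpha = 0.75, beta = 0.5)
  }
  grid <- as_tibble(grid)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid) * replicates)
  rows <- list()
  run <- 0L
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(replicates)) {
      run <- run + 1L
      params <- sim_params(k = grid$k[i], p = grid$p[i], alpha = grid$alpha[i],
                           beta = grid$beta[i], n_genes = base$n_genes,
                           gene_len_codons = base$gene_len_codons,
                           mu = base$mu, beta_pre = grid$beta[i],
                           seed = seeds[run])
      evals <- benchmark_one(params, config)
      for (variant in names(evals)) {
        ev <- evals[[variant]]
        rows[[length(rows) + 1L]] <- tibble(
          k = grid$k[i], p = grid$p[i], alpha = grid$alpha[i],
          beta = grid$beta[i], replicate = j, variant = variant,
          tp = ev$tp, fp = ev$fp, assigned = ev$total_assigned,
          assignable = ev$assignable,
          sensitivity = ev$sensitivity, specificity = ev$specificity)
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("ortho_benchmark", class(tibble()))
  out
}

benchmark_one <- function(params, config = NULL) {
  sim <- simulate_pair(params)
  cfg <- config %||% pipeline_config(sim = params)
  cfg$sim <- params
  hom <- build_homology(sim$genome1, sim$genome2, cfg)
  ts <- tag_inparalog_stage(sim$genome1, sim$genome2, hom, cfg)
  full <- match_and_postprocess(ts$genome1, ts$genome2, hom, cfg)
  abl <- match_and_postprocess(sim$genome1, sim$genome2, hom, cfg)
  list(full = evaluate_simulation(full$assignment, sim$truth),
       ablation = evaluate_simulation(abl$assignment, sim$truth))
}

#' Mean accuracy per parameter set and variant
#'
#' @param bench An `ortho_benchmark` tibble.
#' @return Tibble of means over replicates.
#' @export
benchmark_summary <- function(bench) {
  bench |>
    group_by(.data$k, .data$p, .data$alpha, .data$beta, .data$variant) |>
    summarise(replicates = n(),
              sensitivity = mean(.data$sensitivity),
              specificity = mean(.data$specificity),
              .groups = "drop")
}
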