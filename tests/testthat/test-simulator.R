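test_that("ancestral genome has the stated size and composition", {
  set.seed(1)
  g <- generate_ancestral(sim_params())
  expect_equal(nrow(g), 100)
  expect_true(all(nchar(g$cds) == 3000))
  expect_true(all(g$strand == 1L))
  expect_false(any(grepl("[^ACGT]", g$cds)))

  expect_equal(nrow(generate_ancestral(sim_params(n_genes = 0))), 0)
})

test_that("tandem duplication inserts the copy next to its source", {
  g <- tibble::tibble(gene_id = c("a", "b", "c"), ancestor = c("a", "b", "c"),
                      strand = c(1L, -1L, 1L), cds = c("AAA", "CCC", "GGG"))
  res <- apply_duplication(g, tandem = TRUE, new_id = "b2", source = 2L)
  expect_equal(res$genes$gene_id, c("a", "b", "b2", "c"))
  expect_equal(res$genes$ancestor[3], "b")      # lineage inherited
  expect_equal(res$genes$strand[3], -1L)        # tandem keeps the strand
  expect_equal(res$genes$cds[3], "CCC")

  one <- g[1, ]
  res2 <- apply_duplication(one, tandem = FALSE, new_id = "a2")
  expect_equal(nrow(res2$genes), 2)
  expect_setequal(res2$genes$gene_id, c("a", "a2"))
  expect_equal(res2$genes$ancestor, c("a", "a"))

  expect_error(apply_duplication(g[0, ], TRUE, "x"), "empty")
})

test_that("reversal flips order and strands and is an involution", {
  g <- tibble::tibble(gene_id = c("a", "b", "c"), ancestor = c("a", "b", "c"),
                      strand = c(1L, 1L, 1L), cds = c("AAA", "CCC", "GGG"))
  r <- apply_reversal(g, 1, 3)$genes
  expect_equal(r$gene_id, c("c", "b", "a"))
  expect_equal(r$strand, c(-1L, -1L, -1L))

  single <- apply_reversal(g, 2, 2)$genes
  expect_equal(single$gene_id, g$gene_id)
  expect_equal(single$strand, c(1L, -1L, 1L))

  back <- apply_reversal(r, 1, 3)$genes
  expect_equal(as.data.frame(back), as.data.frame(g))
})

test_that("mutation bursts are bounded and have the stated mean", {
  params <- sim_params(gene_len_codons = 1000, mu = 0.01)
  set.seed(2)
  g <- generate_ancestral(sim_params(n_genes = 100, gene_len_codons = 1000))
  # mu = 0: unchanged
  expect_equal(mutate_between_events(g, sim_params(mu = 0))$cds, g$cds)
  # Monte-Carlo: per gene-burst substitutions ~ Uniform{0..30}, mean 15;
  # observed changed positions are slightly below the event count because of
  # repeated hits on one site
  diffs <- c()
  cur <- g
  for (round in 1:100) {
    nxt <- mutate_between_events(cur, params)
    d <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                cur$cds, nxt$cds)
    diffs <- c(diffs, unname(d))
    cur <- nxt
  }
  expect_true(all(diffs <= 30))
  expect_gt(mean(diffs), 13.8)
  expect_lt(mean(diffs), 15.5)
})

test_that("gene counts are conserved exactly and ancestry stays in H", {
  for (par in list(c(k = 0, p = 0), c(k = 10, p = 50), c(k = 3, p = 7))) {
    params <- sim_params(k = par[["k"]], p = par[["p"]], alpha = 0.75,
                         beta = 0.5, n_genes = 40, gene_len_codons = 10,
                         seed = 101 + par[["p"]])
    sim <- simulate_pair(params)
    expected <- 40 + par[["k"]] + floor(par[["p"]] * 0.75 + 0.5)
    expect_equal(nrow(sim$genome1), expected)
    expect_equal(nrow(sim$genome2), expected)
    h_ids <- unique(sim$truth$ancestor_id)
    expect_equal(length(h_ids), 40 + par[["k"]])
    expect_equal(sim$assignable, 40 + par[["k"]])
    expect_true(all(sim$truth$ancestor_id %in% h_ids))
  }
})

test_that("the default parameter set yields 148 genes per genome", {
  sim <- simulate_pair(sim_params(gene_len_codons = 10, seed = 7))
  expect_equal(nrow(sim$genome1), 148)  # 100 + 10 + round(50 * 0.75)
  expect_equal(nrow(sim$genome2), 148)
  expect_equal(sim$assignable, 110)
})

test_that("simulation is deterministic given the seed", {
  p <- sim_params(k = 2, p = 6, n_genes = 15, gene_len_codons = 15, seed = 33)
  s1 <- simulate_pair(p)
  s2 <- simulate_pair(p)
  expect_identical(s1$genome1$cds, s2$genome1$cds)
  expect_identical(s1$genome2$gene_id, s2$genome2$gene_id)
  expect_identical(s1$events, s2$events)
})

test_that("reversals change neither gene content nor ancestry", {
  p <- sim_params(k = 0, p = 10, alpha = 0, n_genes = 25,
                  gene_len_codons = 10, seed = 9)
  sim <- simulate_pair(p)   # reversals only
  expect_equal(nrow(sim$genome1), 25)
  anc <- sim$truth$ancestor_id[sim$truth$genome_id == "A"]
  expect_setequal(sub("^a_", "", sim$genome1$gene_id), unique(anc))
})

test_that("with beta = 1 every new duplicate lands next to its source", {
  p <- sim_params(k = 0, p = 10, alpha = 1, beta = 1, n_genes = 20,
                  gene_len_codons = 10, seed = 13)
  sim <- simulate_pair(p)
  ev <- sim$events[sim$events$type == "duplication", ]
  expect_true(all(ev$tandem))
  # tandem copies appear adjacent to a same-ancestor gene in the final order
  anc <- setNames(sim$truth$ancestor_id, sim$truth$gene_id)
  for (g in list(sim$genome1, sim$genome2)) {
    a <- unname(anc[g$gene_id])
    dup_rows <- grepl("_d", g$gene_id)
    nb_same <- vapply(which(dup_rows), function(i) {
      any(a[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 &
                              c(i - 1, i + 1) <= length(a)]] == a[i])
    }, logical(1))
    expect_true(all(nb_same))
  }
})

test_that("ortholog sequence divergence grows with p", {
  set.seed(21)
  mean_identity <- function(p_events, seeds) {
    vals <- vapply(seeds, function(s) {
      sim <- simulate_pair(sim_params(k = 0, p = p_events, alpha = 0.5,
                                      n_genes = 12, gene_len_codons = 60,
                                      seed = s))
      anc <- split(sim$truth$gene_id, sim$truth$ancestor_id)
      cds <- c(setNames(sim$genome1$cds, sim$genome1$gene_id),
               setNames(sim$genome2$cds, sim$genome2$gene_id))
      ids <- vapply(anc, function(gs) {
        g1 <- gs[startsWith(gs, "a_")][1]
        g2 <- gs[startsWith(gs, "b_")][1]
        mean(utf8ToInt(cds[[g1]]) == utf8ToInt(cds[[g2]]))
      }, double(1))
      mean(ids)
    }, double(1))
    mean(vals)
  }
  seeds <- 1:20
  id_low <- mean_identity(2, seeds)
  id_high <- mean_identity(30, seeds + 500)
  expect_gt(id_low, id_high)
})
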