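test_that("identical proteins score maximally; scores are symmetric", {
  set.seed(4)
  base <- random_cds(80)
  far <- random_cds(80)
  cds <- c(a = base, b = base, c = far)
  prot <- setNames(protein_of(cds), names(cds))
  g1 <- toy_genome(c("a"), "G1", proteins = prot, cds = cds)
  g2 <- toy_genome(c("b", "c"), "G2", proteins = prot, cds = cds)
  m <- similarity_matrix(g1, g2)
  s_ab <- m$score[m$gene1 == "a" & m$gene2 == "b"]
  self <- orthopair:::local_alignment_scores(prot[["a"]], prot[["a"]])
  expect_equal(s_ab, self)           # identity is the best local alignment
  expect_true(all(m$gene1 < m$gene2))  # canonical symmetric storage
  if (any(m$gene1 == "a" & m$gene2 == "c")) {
    expect_lt(m$score[m$gene1 == "a" & m$gene2 == "c"], s_ab)
  }
})

test_that("unrelated random proteins score below the edge threshold", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function() paste(sample(aa, 100, replace = TRUE), collapse = "")
  p1 <- replicate(500, mk())
  p2 <- replicate(500, mk())
  s <- orthopair:::local_alignment_scores(p1, p2)
  expect_gte(mean(s < similarity_params()$edge_threshold), 0.99)
})

test_that("best hits and BBHs follow the argmax definition with id ties", {
  g1 <- toy_genome(c("a", "b"), "G1")
  g2 <- toy_genome(c("x", "y"), "G2")
  m <- toy_similarity(c("a", "a", "b", "x"), c("x", "y", "x", "y"),
                      c(100, 50, 80, 10))
  bh <- best_hits(m, g1, g2)
  expect_equal(bh$best_hit[bh$gene_id == "a"], "x")
  expect_true(bh$bbh[bh$gene_id == "a"])          # mutual best
  expect_false(bh$bbh[bh$gene_id == "b"])         # b's best is x, x's best is a
  # tie on score: lexicographically smaller id wins
  m2 <- toy_similarity(c("a", "a"), c("x", "y"), c(50, 50))
  bh2 <- best_hits(m2, g1, g2)
  expect_equal(bh2$best_hit[bh2$gene_id == "a"], "x")
})

test_that("within-genome edges never produce best hits", {
  g1 <- toy_genome(c("a", "b"), "G1")
  g2 <- toy_genome(c("x"), "G2")
  m <- toy_similarity(c("a", "a"), c("b", "x"), c(500, 60))
  bh <- best_hits(m, g1, g2)
  expect_equal(bh$best_hit[bh$gene_id == "a"], "x")
})

test_that("MCL separates disconnected cliques and keeps singletons", {
  ed <- toy_similarity(c("a", "a", "b", "d", "d", "e"),
                       c("b", "c", "c", "e", "f", "f"),
                       rep(10, 6))
  fam <- mcl_cluster(ed, genes = c("a", "b", "c", "d", "e", "f", "lone"))
  groups <- split(fam$gene_id, fam$family)
  expect_equal(length(groups), 3)
  expect_true(list(c("a", "b", "c")) %in% groups ||
                any(vapply(groups, identical, logical(1), c("a", "b", "c"))))
  expect_true(any(vapply(groups, identical, logical(1), "lone")))
})

test_that("MCL splits a weakly bridged barbell at inflation 2", {
  ed <- toy_similarity(c("a", "a", "b", "d", "d", "e", "c"),
                       c("b", "c", "c", "e", "f", "f", "d"),
                       c(10, 10, 10, 10, 10, 10, 1))
  fam <- mcl_cluster(ed)
  groups <- unname(split(fam$gene_id, fam$family))
  expect_equal(length(groups), 2)
  expect_equal(groups[[1]], c("a", "b", "c"))
  expect_equal(groups[[2]], c("d", "e", "f"))
})

test_that("families partition the gene set and are permutation invariant", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 12
    ids <- sprintf("g%02d", 1:n)
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.25
    ed <- toy_similarity(pairs[keep, 1], pairs[keep, 2],
                         round(runif(sum(keep), 5, 50)))
    fam <- mcl_cluster(ed, genes = ids)
    expect_setequal(fam$gene_id, ids)              # partition, all covered
    expect_equal(anyDuplicated(fam$gene_id), 0)

    # relabel gene ids; clustering must follow the relabeling
    relab <- setNames(sprintf("h%02d", sample(n)), ids)
    ed2 <- toy_similarity(unname(relab[ed$gene1]), unname(relab[ed$gene2]),
                          ed$score)
    fam2 <- mcl_cluster(ed2, genes = unname(relab))
    g1 <- lapply(unname(split(fam$gene_id, fam$family)),
                 function(g) sort(unname(relab[g])))
    g2 <- lapply(unname(split(fam2$gene_id, fam2$family)), sort)
    expect_setequal(vapply(g1, paste, "", collapse = ","),
                    vapply(g2, paste, "", collapse = ","))
  }
})

test_that("on an event-free simulation every family is a true ortholog pair", {
  sim <- simulate_pair(sim_params(k = 0, p = 0, n_genes = 20,
                                  gene_len_codons = 60, seed = 3))
  cfg <- pipeline_config(sim = sim_params(k = 0, p = 0))
  hom <- orthopair:::build_homology(sim$genome1, sim$genome2, cfg)
  sizes <- table(hom$families$family)
  expect_true(all(sizes == 2))
  anc <- setNames(sim$truth$ancestor_id, sim$truth$gene_id)
  for (members in split(hom$families$gene_id, hom$families$family)) {
    expect_equal(anc[[members[1]]], anc[[members[2]]])
  }
})

test_that("equal-length screening plus alignment matches the full matrix", {
  set.seed(31)
  base <- vapply(1:6, function(i) random_cds(50), character(1))
  cds <- c(setNames(base[1:3], c("a", "b", "c")),
           setNames(vapply(base[1:3], mutate_cds, character(1), n_mut = 15),
                    c("x", "y", "z")))
  prot <- setNames(protein_of(cds), names(cds))
  g1 <- toy_genome(c("a", "b", "c"), "G1", proteins = prot, cds = cds)
  g2 <- toy_genome(c("x", "y", "z"), "G2", proteins = prot, cds = cds)
  m <- similarity_matrix(g1, g2)
  # brute force: align all 15 pairs, keep >= threshold
  ids <- c("a", "b", "c", "x", "y", "z")
  cmb <- t(combn(ids, 2))
  s <- orthopair:::local_alignment_scores(prot[cmb[, 1]], prot[cmb[, 2]])
  keep <- s >= similarity_params()$edge_threshold
  want <- tibble::tibble(gene1 = cmb[keep, 1], gene2 = cmb[keep, 2],
                         score = s[keep])
  got <- as.data.frame(m)[, c("gene1", "gene2", "score")]
  expect_equal(got[order(got$gene1, got$gene2), ],
               as.data.frame(want)[order(want$gene1, want$gene2), ],
               ignore_attr = TRUE)
})
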