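test_that("induced permutations relabel by genome-1 order with strand signs", {
  g1 <- toy_genome(c("a", "b", "c", "d"), "G1")
  g2 <- toy_genome(c("a2", "b2", "c2", "d2"), "G2")
  full <- toy_assignment(c("a", "b", "c", "d"), c("a2", "b2", "c2", "d2"))
  expect_equal(induced_permutation(full, g1, g2), 1:4)

  # genome 2 with the middle segment inverted
  g2r <- toy_genome(c("a2", "c2", "b2", "d2"), "G2",
                    strands = c(1L, -1L, -1L, 1L))
  expect_equal(induced_permutation(full, g1, g2r), c(1L, -3L, -2L, 4L))

  empty <- toy_assignment(character(), character())
  expect_equal(induced_permutation(empty, g1, g2), integer())

  expect_error(induced_permutation(toy_assignment("zz", "a2"), g1, g2),
               "absent")
})

test_that("reversal distance basics: identity, sign flip, symmetry, bounds", {
  expect_equal(reversal_distance(1:8)$distance, 0)
  expect_equal(reversal_distance(c(-1L))$distance, 1)
  expect_error(reversal_distance(c(1L, 1L)), "permutation")

  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    perm <- sample(1:n) * sample(c(1L, -1L), n, replace = TRUE)
    d <- reversal_distance(perm)$distance
    # inverse permutation has the same distance
    inv <- integer(n)
    inv[abs(perm)] <- seq_len(n) * sign(perm)
    expect_equal(reversal_distance(inv)$distance, d)
    # bounds: breakpoints/2 <= d <= n+1
    ext <- c(0L, perm, n + 1L)
    b <- sum(diff(ext) != 1L)
    expect_gte(d, ceiling(b / 2))
    expect_lte(d, n + 1)
  }
})

test_that("uncoupling a tandem pair costs 2 duplications, 0 reversals", {
  # genome 1 = [a1 a2 a4 b c], genome 2 = [a1 a3 a5 b c], all strands +
  g1 <- toy_genome(c("a1", "a2", "a4", "b", "c"), "G1")
  g2 <- toy_genome(c("a1x", "a3", "a5", "bx", "cx"), "G2")
  full <- toy_assignment(c("a1", "a2", "a4", "b", "c"),
                         c("a1x", "a3", "a5", "bx", "cx"))
  before <- rd_distance(full, g1, g2)
  expect_equal(before$reversals, 0)
  expect_equal(before$duplications, 0)
  expect_equal(before$total, 0)

  after <- rd_distance(full[full$gene1 != "a2", ], g1, g2)
  expect_equal(after$reversals - before$reversals, 0)
  expect_equal(after$duplications - before$duplications, 2)
})

test_that("uncoupling a costly random-duplicate pair saves 3 reversals", {
  # genome 1 = [a1 b c d a2], genome 2 = [a1 a3 b c d]: matching (a2, a3)
  # induces the permutation (1 5 2 3 4) with reversal distance 3
  g1 <- toy_genome(c("a1", "b", "c", "d", "a2"), "G1")
  g2 <- toy_genome(c("a1x", "a3", "bx", "cx", "dx"), "G2")
  full <- toy_assignment(c("a1", "a2", "b", "c", "d"),
                         c("a1x", "a3", "bx", "cx", "dx"))
  before <- rd_distance(full, g1, g2)
  expect_equal(before$reversals, 3)
  expect_equal(before$duplications, 0)

  after <- rd_distance(full[full$gene1 != "a2", ], g1, g2)
  expect_equal(after$reversals - before$reversals, -3)
  expect_equal(after$duplications - before$duplications, 2)
  expect_equal(after$total - before$total, -1)
})

test_that("noise detection uncouples random duplicates but keeps tandems", {
  fam <- toy_families(c("a1", "a2", "a1x", "a3"), c("b", "bx"),
                      c("c", "cx"), c("d", "dx"))
  # random-duplicate configuration: pair (a2, a3) is uncoupled
  g1 <- toy_genome(c("a1", "b", "c", "d", "a2"), "G1")
  g2 <- toy_genome(c("a1x", "a3", "bx", "cx", "dx"), "G2")
  full <- toy_assignment(c("a1", "a2", "b", "c", "d"),
                         c("a1x", "a3", "bx", "cx", "dx"))
  out <- noise_pair_detection(full, g1, g2, families = fam)
  expect_false("a2" %in% out$gene1)
  expect_equal(nrow(out), 4)

  # tandem configuration: uncoupling would increase RD, pairs are kept
  fam2 <- toy_families(c("a1", "a2", "a4", "a1x", "a3", "a5"),
                       c("b", "bx"), c("c", "cx"))
  g1t <- toy_genome(c("a1", "a2", "a4", "b", "c"), "G1")
  g2t <- toy_genome(c("a1x", "a3", "a5", "bx", "cx"), "G2")
  fullt <- toy_assignment(c("a1", "a2", "a4", "b", "c"),
                          c("a1x", "a3", "a5", "bx", "cx"))
  outt <- noise_pair_detection(fullt, g1t, g2t, families = fam2)
  expect_equal(nrow(outt), 5)   # already RD-optimal: fixpoint, unchanged

  # monotonicity: RD never increases
  expect_lte(rd_distance(out, g1, g2)$total, rd_distance(full, g1, g2)$total)
})

test_that("initial assignment is BBH-first, then greedy by score", {
  g1 <- toy_genome(c("a", "b"), "G1")
  g2 <- toy_genome(c("x", "y"), "G2")

  # singleton family with any positive score is matched
  fam <- toy_families(c("a", "x"))
  sim <- toy_similarity("a", "x", 5)
  out <- initial_assignment(fam, sim, g1, g2)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene2[out$gene1 == "a"], "x")

  # family with 2 vs 1 genes: exactly one pair, the higher-scoring one
  fam2 <- toy_families(c("a", "b", "x"))
  sim2 <- toy_similarity(c("a", "b"), c("x", "x"), c(40, 90))
  out2 <- initial_assignment(fam2, sim2, g1, g2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$gene1, "b")

  # BBH pairs beat a higher-scoring non-BBH pairing:
  # scores: a-x 100 (mutual best), a-y 90, b-y 10 -> (a,x) kept
  fam3 <- toy_families(c("a", "b", "x", "y"))
  sim3 <- toy_similarity(c("a", "a", "b"), c("x", "y", "y"), c(100, 90, 10))
  out3 <- initial_assignment(fam3, sim3, g1, g2)
  expect_equal(out3$gene2[out3$gene1 == "a"], "x")
  expect_equal(out3$gene2[out3$gene1 == "b"], "y")
})

test_that("DCJ surrogate agrees with reversal distance on unichromosomal toys", {
  g1 <- toy_genome(c("a", "b", "c", "d"), "G1")
  pairs <- toy_assignment(c("a", "b", "c", "d"), c("a2", "b2", "c2", "d2"))
  for (i in 1:10) {
    set.seed(i)
    ord <- sample(c("a2", "b2", "c2", "d2"))
    strands <- sample(c(1L, -1L), 4, replace = TRUE)
    g2 <- toy_genome(ord, "G2", strands = strands)
    hp <- rd_distance(pairs, g1, g2)$reversals
    dcj <- orthopair:::dcj_distance(pairs, g1, g2)
    # DCJ is a lower bound on the reversal distance, tight absent hurdles
    expect_lte(dcj, hp)
    expect_gte(dcj, hp - 2L)
  }
  # multichromosomal inputs switch to the DCJ surrogate
  g1m <- toy_genome(c("a", "b", "c", "d"), "G1",
                    chromosomes = c("1", "1", "2", "2"))
  g2m <- toy_genome(c("a2", "b2", "c2", "d2"), "G2",
                    chromosomes = c("1", "1", "2", "2"))
  sc <- rd_distance(pairs, g1m, g2m)
  expect_equal(sc$method, "dcj")
  expect_equal(sc$reversals, 0)
  expect_equal(sc$total, 0)
})

test_that("RD parsimony recovers the true reversal count on reversal-only data", {
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    params <- sim_params(k = 0, p = 8, alpha = 0, n_genes = 60,
                         gene_len_codons = 60, seed = 4000 + i)
    sim <- simulate_pair(params)
    applied <- sum(sim$events$type == "reversal" &
                     sim$events$lineage %in% c("A", "B"))
    cfg <- pipeline_config(sim = params)
    res <- run_pipeline(cfg)
    rd <- rd_distance(res$assignment, res$genome1, res$genome2)
    if (rd$total == applied) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
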