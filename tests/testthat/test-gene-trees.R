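test_that("progressive alignment handles identity and single-gap cases", {
  a <- align_family(c(s1 = "MKLV", s2 = "MKLV"))
  expect_equal(unname(a), c("MKLV", "MKLV"))

  b <- align_family(c(x = "ACDE", y = "ACE"))
  expect_equal(unname(b), c("ACDE", "AC-E"))  # optimal global alignment

  expect_equal(align_family(c(only = "MKL")), c(only = "MKL"))
})

test_that("imported alignments are validated", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "AC-E", ">y", "ACDE"), f)
  aln <- align_family(c(x = "ACE", y = "ACDE"), mode = "imported", path = f)
  expect_equal(aln, c(x = "AC-E", y = "ACDE"))

  writeLines(c(">x", "AC-E", ">y", "ACDEF"), f)
  expect_error(align_family(c(x = "ACE", y = "ACDEF"), mode = "imported",
                            path = f), "unequal")
})

test_that("banded and full alignment agree on related sequences", {
  set.seed(44)
  cds <- random_cds(120)
  prot1 <- protein_of(cds)
  prot2 <- protein_of(mutate_cds(cds, 30))
  full <- align_family(c(a = prot1, b = prot2), band = 0)
  banded <- align_family(c(a = prot1, b = prot2))
  expect_equal(full, banded)
})

test_that("back_translate maps residues to codons and gaps to ---", {
  out <- back_translate(c(g = "M-K"), c(g = "ATGAAA"))
  expect_equal(unname(out["g"]), "ATG---AAA")

  expect_error(back_translate(c(g = "M-K"), c(g = "ATGAA")), "divisible")
  expect_error(back_translate(c(g = "MW"), c(g = "ATGAAA")), "translate")

  # full family round trip: ungapped codon rows translate back to proteins
  set.seed(15)
  cds <- c(a = random_cds(40), b = mutate_cds(random_cds(40), 6))
  prot <- setNames(protein_of(cds), names(cds))
  aln <- align_family(prot)
  codon <- back_translate(aln, cds)
  ungapped <- gsub("-", "", codon, fixed = TRUE)
  expect_equal(unname(protein_of(ungapped)),
               unname(gsub("-", "", aln, fixed = TRUE)))
})

test_that("trailing stop codons are stripped during back-translation", {
  out <- back_translate(c(g = "MK"), c(g = "ATGAAATGA"))
  expect_equal(unname(out["g"]), "ATGAAA")
})

test_that("F84 reduces to Kimura 2-parameter at equal frequencies", {
  k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  for (P in seq(0.01, 0.25, by = 0.04)) {
    for (Q in seq(0.01, 0.2, by = 0.04)) {
      expect_equal(f84_formula(P, Q), k2p(P, Q), tolerance = 1e-12)
    }
  }
})

test_that("F84 distances: zero on identity, monotone in P, capped when saturated", {
  aln <- structure(c(a = strrep("ACGT", 30), b = strrep("ACGT", 30)),
                   class = "codon_alignment")
  d <- f84_distance(aln)
  expect_equal(d["a", "b"], 0)

  expect_true(f84_formula(0.10, 0.05) > f84_formula(0.05, 0.05))
  expect_true(is.na(f84_formula(0.6, 0.3)))   # saturated

  sat <- c(a = strrep("A", 60), b = strrep("G", 60))
  expect_warning(ds <- f84_distance(sat), "saturated")
  expect_equal(ds["a", "b"], 10)
})

test_that("pairwise deletion excludes gapped sites", {
  aln <- c(a = "AAA---GGG", b = "AAACCCGGG")
  d <- f84_distance(aln)
  expect_equal(d["a", "b"], 0)   # only ungapped-in-both sites compared
})

test_that("alignment-level F84 equals the closed form on constructed data", {
  # 100 sites: 10 transitions (A<->G), 5 transversions (A<->C), 85 identical A/A
  # plus balancing composition so pooled frequencies are known
  row1 <- paste0(strrep("A", 95), strrep("C", 2), strrep("G", 2), "T")
  row2 <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 80),
                 strrep("C", 2), strrep("G", 2), "T")
  d <- f84_distance(c(a = row1, b = row2))
  a <- utf8ToInt(row1); b <- utf8ToInt(row2)
  P <- mean((a != b) & (abs(a - b) == utf8ToInt("G") - utf8ToInt("A")) &
              (a + b == utf8ToInt("A") + utf8ToInt("G")))
  freqs <- table(factor(strsplit(paste0(row1, row2), "")[[1]],
                        c("A", "C", "G", "T"))) / 200
  Q <- mean(a != b) - P
  expect_equal(unname(d["a", "b"]),
               unname(f84_formula(P, Q, setNames(as.numeric(freqs),
                                                 names(freqs)))),
               tolerance = 1e-12)
})

test_that("neighbor joining recovers additive topologies deterministically", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  D <- ape::cophenetic.phylo(tr)
  for (v in c("bionj", "nj")) {
    out <- nj_tree(D, variant = v)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(out)), 0,
                 ignore_attr = TRUE)
  }
  # permuting taxon order gives the identical topology
  perm <- D[c("c", "a", "d", "b"), c("c", "a", "d", "b")]
  expect_equal(ape::write.tree(nj_tree(D)), ape::write.tree(nj_tree(perm)))

  # three taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["a"]], 1)
  expect_equal(el[["b"]], 2)
  expect_equal(el[["c"]], 4)

  Dn <- D3; Dn[1, 2] <- NaN
  expect_error(nj_tree(Dn), "NA")
})

test_that("artificial outgroup rooting uses twice the maximum distance", {
  # 2 taxa at distance 4: forced midpoint root, two branches of 2
  D <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- root_by_artificial_outgroup(D)
  expect_true(ape::is.rooted(r))
  dep <- ape::node.depth.edgelength(r)
  expect_equal(unname(dep[1:2]), c(2, 2))

  # all-zero matrix: deterministic arbitrary root
  D0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_silent(r0 <- root_by_artificial_outgroup(D0))
  expect_true(ape::is.rooted(r0))
})

test_that("outgroup rooting mostly agrees with explicit midpoint rooting", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  root_split <- function(t) {
    k <- ape::Ntip(t)
    ch <- t$edge[t$edge[, 1] == k + 1L, 2]
    sets <- lapply(ch, function(x) {
      if (x <= k) t$tip.label[x] else sort(ape::extract.clade(t, x)$tip.label)
    })
    sort(vapply(lapply(sets, sort), paste, "", collapse = "|"))[1]
  }
  agree <- 0L
  trials <- 60L
  for (i in seq_len(trials)) {
    tr <- ape::rtree(8)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
    D <- ape::cophenetic.phylo(tr)
    mid <- phangorn::midpoint(nj_tree(D))
    r <- root_by_artificial_outgroup(D)
    agree <- agree + identical(root_split(r), root_split(mid))
  }
  expect_gt(agree / trials, 0.5)
})
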