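test_that("heterozygosity matches hand enumeration with the 2n/(2n-1) factor", {
  # genotypes: 100/102, 100/100, 102/104, 100/104
  ds <- one_group_dataset(list(c(100L, 102L), c(100L, 100L),
                               c(102L, 104L), c(100L, 104L)))
  fr <- allele_frequencies(ds)
  h <- heterozygosity(fr, ds, "g")
  # hand: p = (4/8, 2/8, 2/8); He = (1 - 0.375) * 8/7; Ho = 3/4
  expect_equal(h[["He"]], (1 - (0.5^2 + 0.25^2 + 0.25^2)) * 8 / 7,
               tolerance = 1e-12)
  expect_equal(h[["Ho"]], 0.75)

  mono <- one_group_dataset(list(c(100L, 100L), c(100L, 100L)))
  hm <- heterozygosity(allele_frequencies(mono), mono, "g")
  expect_equal(unname(hm), c(0, 0))

  # biallelic 50/50 at large n approaches 0.5
  big <- one_group_dataset(rep(list(c(100L, 102L)), 200))
  hb <- heterozygosity(allele_frequencies(big), big, "g")
  expect_equal(hb[["He"]], 0.5 * 400 / 399, tolerance = 1e-12)
})

test_that("FIS follows (He - Ho)/He with He = 0 undefined", {
  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(fis(0, 0.5), 1)
  expect_equal(fis(0.75, 0.5), -0.5)
  expect_warning(out <- fis(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("pairwise FST matches the direct (HT-HS)/HT oracle", {
  ids <- paste0("i", 1:8)
  # two groups fixed for different alleles -> FST = 1
  a_fix <- matrix(rep(c(100L, 120L), each = 4), 8, 1)
  ds_fix <- genotype_dataset(ids, "L1", a_fix, a_fix,
                             stats::setNames(rep(c("g1", "g2"), each = 4), ids))
  expect_equal(pairwise_fst(allele_frequencies(ds_fix), c("g1", "g2")), 1)

  # identical frequency vectors -> 0
  a_same <- matrix(rep(c(100L, 102L), 4), 8, 1)
  b_same <- matrix(rep(c(102L, 100L), 4), 8, 1)
  ds_same <- genotype_dataset(ids, "L1", a_same, b_same,
                              stats::setNames(rep(c("g1", "g2"), each = 4), ids))
  expect_equal(pairwise_fst(allele_frequencies(ds_same), c("g1", "g2")), 0)

  # random 2-locus toy vs brute-force flat-count formula
  set.seed(21)
  a1 <- matrix(sample(c(100L, 102L, 104L), 16, TRUE), 8, 2)
  a2 <- matrix(sample(c(100L, 102L, 104L), 16, TRUE), 8, 2)
  grp <- stats::setNames(rep(c("g1", "g2"), each = 4), ids)
  ds <- genotype_dataset(ids, c("L1", "L2"), a1, a2, grp)
  hs <- ht <- numeric(2)
  for (l in 1:2) {
    f1 <- table(factor(c(a1[1:4, l], a2[1:4, l]), levels = c(100, 102, 104))) / 8
    f2 <- table(factor(c(a1[5:8, l], a2[5:8, l]), levels = c(100, 102, 104))) / 8
    hs[l] <- mean(c(1 - sum(f1^2), 1 - sum(f2^2)))
    ht[l] <- 1 - sum(((f1 + f2) / 2)^2)
  }
  oracle <- (mean(ht) - mean(hs)) / mean(ht)
  expect_equal(pairwise_fst(allele_frequencies(ds), c("g1", "g2")),
               max(0, oracle), tolerance = 1e-9)

  # symmetry and invariance under allele relabeling
  fr <- allele_frequencies(ds)
  expect_equal(pairwise_fst(fr, c("g1", "g2")), pairwise_fst(fr, c("g2", "g1")))
  relab <- genotype_dataset(ids, c("L1", "L2"), a1 + 50L, a2 + 50L, grp)
  expect_equal(pairwise_fst(allele_frequencies(relab), c("g1", "g2")),
               pairwise_fst(fr, c("g1", "g2")), tolerance = 1e-12)
})

test_that("Nei distance follows -ln(mean identity) and flags disjoint groups", {
  ids <- paste0("i", 1:12)
  grp <- stats::setNames(rep(c("g1", "g2", "g3"), each = 4), ids)
  set.seed(5)
  a1 <- matrix(sample(c(100L, 102L), 24, TRUE), 12, 2)
  a2 <- matrix(sample(c(100L, 102L), 24, TRUE), 12, 2)
  ds <- genotype_dataset(ids, c("L1", "L2"), a1, a2, grp)
  fr <- allele_frequencies(ds)
  D <- nei_distance_matrix(fr)
  # hand oracle for the g1-g2 entry
  ident <- numeric(2)
  for (l in 1:2) {
    f1 <- table(factor(c(a1[1:4, l], a2[1:4, l]), levels = c(100, 102))) / 8
    f2 <- table(factor(c(a1[5:8, l], a2[5:8, l]), levels = c(100, 102))) / 8
    ident[l] <- sum(f1 * f2) / sqrt(sum(f1^2) * sum(f2^2))
  }
  expect_equal(D["g1", "g2"], -log(mean(ident)), tolerance = 1e-9)
  expect_true(isSymmetric(unclass(unname(D))))

  # identical groups -> 0; disjoint allele sets -> Inf, flagged
  same <- genotype_dataset(ids[1:8], "L1",
                           matrix(rep(c(100L, 102L), 4), 8, 1),
                           matrix(rep(c(100L, 102L), 4), 8, 1),
                           stats::setNames(rep(c("g1", "g2"), each = 4),
                                           ids[1:8]))
  D2 <- nei_distance_matrix(allele_frequencies(same))
  expect_equal(D2["g1", "g2"], 0)
  disj <- genotype_dataset(ids[1:8], "L1",
                           matrix(rep(c(100L, 130L), each = 4), 8, 1),
                           matrix(rep(c(100L, 130L), each = 4), 8, 1),
                           stats::setNames(rep(c("g1", "g2"), each = 4), ids[1:8]))
  D3 <- nei_distance_matrix(allele_frequencies(disj))
  expect_true(is.infinite(D3["g1", "g2"]))
  expect_length(attr(D3, "infinite_pairs"), 1)
})

test_that("UPGMA agglomerates by average linkage with half-distance heights", {
  m2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  u2 <- upgma(m2)
  expect_equal(u2$merge_heights, 3)

  m3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u3 <- upgma(m3)
  expect_equal(u3$merge_heights, c(1, 4))
  expect_equal(u3$newick, "((A:1,B:1):3,C:4);")

  # random 8-taxon matrix vs an independent implementation
  m8 <- rand_sym(8, seed = 4) * 10
  rownames(m8) <- colnames(m8) <- paste0("t", 1:8)
  u8 <- upgma(m8)
  ref <- phangorn::upgma(stats::as.dist(m8))
  expect_equal(phangorn::RF.dist(u8$phylo, ref), 0)
  expect_equal(sort(unname(ape::branching.times(u8$phylo))),
               sort(unname(ape::branching.times(ref))), tolerance = 1e-8)
  # ultrametric: all leaves equidistant from the root
  depths <- ape::node.depth.edgelength(u8$phylo)[1:8]
  expect_lt(diff(range(depths)), 1e-9)

  m_bad <- m3; m_bad[1, 2] <- m_bad[2, 1] <- Inf
  expect_error(upgma(m_bad), "NaN/Inf")
})

test_that("HWE permutation test flags heterozygote deficit, passes monomorphic", {
  n <- 20
  all_hom <- one_group_dataset(lapply(rep(c(100L, 102L), each = n / 2),
                                      function(a) c(a, a)))
  expect_lte(hwe_test(all_hom, "g", "L1", n_perm = 999, seed = 2), 0.01)

  mono <- one_group_dataset(rep(list(c(100L, 100L)), 10))
  expect_equal(hwe_test(mono, "g", "L1", n_perm = 99, seed = 1), 1)
})

test_that("LD permutation test detects perfect association, passes degenerate", {
  set.seed(8)
  g <- sample(list(c(100L, 100L), c(100L, 102L), c(102L, 102L)), 30, TRUE)
  a1 <- cbind(vapply(g, `[`, integer(1), 1), vapply(g, `[`, integer(1), 1))
  a2 <- cbind(vapply(g, `[`, integer(1), 2), vapply(g, `[`, integer(1), 2))
  ids <- paste0("i", 1:30)
  dup <- genotype_dataset(ids, c("L1", "L2"), a1, a2,
                          stats::setNames(rep("g", 30), ids))
  expect_lte(ld_test(dup, "g", c("L1", "L2"), n_perm = 999, seed = 3), 0.01)

  single <- genotype_dataset(ids, c("L1", "L2"),
                             cbind(a1[, 1], rep(100L, 30)),
                             cbind(a2[, 1], rep(100L, 30)),
                             stats::setNames(rep("g", 30), ids))
  expect_equal(ld_test(single, "g", c("L1", "L2"), n_perm = 99, seed = 1), 1)
})

test_that("Garza-Williamson M covers the ladder conventions", {
  expect_equal(garza_williamson_m(c(10L)), 1)
  expect_equal(garza_williamson_m(c(10L, 12L)), 2 / 3)
  expect_equal(garza_williamson_m(8:12), 1)
})

test_that("diversity summary is consistent with per-group heterozygosity", {
  fx <- gen_hierarchical_genotypes(3, 10, 4, 0.05, 0.02, 2, seed = 9)
  div <- diversity_summary(fx$dataset)
  expect_equal(nrow(div), 3)
  expect_true(all(div$Ho >= 0 & div$Ho <= 1 & div$He >= 0 & div$He <= 1))
  expect_equal(div$FIS, (div$He - div$Ho) / div$He, tolerance = 1e-12)
  per_locus <- attr(div, "per_locus")
  expect_equal(nrow(per_locus), 4)
  expect_true(all(per_locus$richness >= 1))
})
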