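test_that("population tree models validate their ordering invariants", {
  expect_error(pop_tree_model(c("A", "B"), matrix(c(1L, 2L), 1), -5, c(1, 1, 1)),
               "positive")
  m4 <- pop_tree_model(c("A", "B", "C"),
                       rbind(c(1L, 2L), c(4L, 3L)), c(100, 500),
                       rep(1000, 5))
  expect_s3_class(m4, "pop_tree_model")
  expect_error(pop_tree_model(c("A", "B", "C"),
                              rbind(c(1L, 2L), c(4L, 3L)), c(500, 100),
                              rep(1000, 5)),
               "ascending")
})

test_that("zero mutation yields identical root-sized alleles; instant split ~ no FST", {
  mod1 <- pop_tree_model("A", matrix(integer(0), 0, 2), numeric(0), 1000)
  ds <- simulate_coalescent_msats(mod1, 10, 3, 0, seed = 1)
  expect_true(all(ds$a1 == 100L) && all(ds$a2 == 100L))

  # two populations split 1 generation ago with large N: FST near zero
  mod2 <- two_pop_model(t = 1, N = 50000)
  ds2 <- simulate_coalescent_msats(mod2, c(25, 25), 8, 5e-4, seed = 2)
  f <- pairwise_fst(allele_frequencies(ds2), c("A", "B"))
  expect_lt(f, 0.02)
})

test_that("stepwise-mutation allele-size variance matches the theta/2 closed form", {
  mod <- pop_tree_model("A", matrix(integer(0), 0, 2), numeric(0), 1000)
  for (theta in c(1, 5)) {
    mu <- theta / (4 * 1000)
    vs <- vapply(1:200, function(r) {
      ds <- simulate_coalescent_msats(mod, 20, 5, mu, seed = 5000 + r)
      mean(vapply(seq_len(5), function(l)
        stats::var(c(ds$a1[, l], ds$a2[, l])), numeric(1)))
    }, numeric(1))
    se <- stats::sd(vs) / sqrt(length(vs))
    expect_lt(abs(mean(vs) - theta / 2), 3 * se)
  }
})

test_that("within-population heterozygosity increases with theta", {
  mod <- pop_tree_model("A", matrix(integer(0), 0, 2), numeric(0), 1000)
  hets <- vapply(c(0.5, 2, 8), function(theta) {
    mean(vapply(1:30, function(r) {
      ds <- simulate_coalescent_msats(mod, 15, 4, theta / 4000,
                                      seed = 900 + r)
      heterozygosity(allele_frequencies(ds), ds, "A")[["He"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hets) > 0))
})

test_that("summary statistics match hand computation on a built dataset", {
  # pop A: (100/100),(100/102); pop B: (104/104),(104/104)
  ids <- c("a1", "a2", "b1", "b2")
  a1 <- matrix(c(100L, 100L, 104L, 104L, 100L, 102L, 104L, 104L), 4, 2)
  a2 <- matrix(c(100L, 102L, 104L, 104L, 100L, 102L, 104L, 104L), 4, 2)
  ds <- genotype_dataset(ids, c("L1", "L2"), a1, a2,
                         stats::setNames(c("A", "A", "B", "B"), ids))
  sb <- summary_beaumont(ds)
  expect_equal(attr(sb, "set_id"), "beaumont")
  expect_length(sb, 6)
  # pop A, L1: alleles 100,100,100,102 -> k=2, He=(1-(9/16+1/16))*4/3=0.5,
  # var({100,100,100,102})=1; L2: 100,100,102,102 -> k=2, He=(1-0.5)*4/3=2/3,
  # var = 4/3
  expect_equal(unname(sb["A.mean_k"]), 2)
  expect_equal(unname(sb["A.het"]), mean(c(0.5, 2 / 3)), tolerance = 1e-12)
  expect_equal(unname(sb["A.var"]), mean(c(1, 4 / 3)), tolerance = 1e-12)
  # monomorphic pop B -> (1, 0, 0)
  expect_equal(unname(sb[c("B.mean_k", "B.het", "B.var")]), c(1, 0, 0))

  sc <- summary_cornuet_miller(ds)
  # B monomorphic: M = 1; A: L1 k=2 range 2 -> 2/3, L2 2/3
  expect_equal(unname(sc["B.M"]), 1)
  expect_equal(unname(sc["A.M"]), 2 / 3, tolerance = 1e-12)
  # fixed-ish difference: high FST
  expect_gt(unname(sc["fst.A.B"]), 0.5)
  # assignment log-likelihood oracle: individual b1 under pop A's frequencies
  # L1 freqs A: 100 -> 0.75, 102 -> 0.25, 104 unseen -> floor 1/5
  # L2 freqs A: 100 -> 0.5, 102 -> 0.5, 104 unseen -> floor 1/5
  expect_equal(unname(sc["lik.B.A"]),
               2 * log(1 / 5) + 2 * log(1 / 5), tolerance = 1e-12)
})

test_that("the C++ summary kernel agrees with the R summary functions", {
  m2 <- two_pop_model(3000, 1500)
  ds <- simulate_coalescent_msats(m2, c(12, 15), 6, 4e-4, seed = 7)
  S <- matrix(0L, 2 * length(ds$individuals), length(ds$loci))
  S[seq(1, nrow(S), 2), ] <- ds$a1
  S[seq(2, nrow(S), 2), ] <- ds$a2
  pop <- rep(ifelse(ds$site_of == "A", 1L, 2L), each = 2)
  expect_equal(as.numeric(summary_beaumont(ds)),
               landgen:::cpp_msat_summaries(S, pop, 1L), tolerance = 1e-10)
  expect_equal(as.numeric(summary_cornuet_miller(ds)),
               landgen:::cpp_msat_summaries(S, pop, 2L), tolerance = 1e-10)
})

test_that("rejection with tolerance 1 returns the prior and respects bounds", {
  obs <- gen_abc_observed(two_pop_model(5000, 2000), 10, 5, 5e-4, seed = 3)
  post <- abc_rejection(obs$beaumont, two_pop_model(1, 1000), 10, 5,
                        n_sims = 2000, tolerance = 1, seed = 4,
                        stats = "beaumont", shared_N = TRUE)
  med_t <- post$summary$median[post$summary$parameter == "t1"]
  expect_equal(med_t, 10000, tolerance = 0.08)  # prior median of U[1, 20000]
  expect_true(all(post$accepted[, "t1"] >= 1 & post$accepted[, "t1"] <= 20000))
  expect_true(all(post$accepted[, "N"] >= 1 & post$accepted[, "N"] <= 20000))
  expect_true(all(post$accepted[, "mu_bar"] >= 1e-4 &
                    post$accepted[, "mu_bar"] <= 1e-3))
  # median lies inside the credible interval
  expect_true(all(post$summary$median >= post$summary$ci_lo &
                    post$summary$median <= post$summary$ci_hi))
  expect_error(abc_rejection(obs$beaumont, two_pop_model(1, 1000), 10, 5,
                             n_sims = 2000, tolerance = 0, seed = 1),
               "tolerance")
})

test_that("posterior medians for t are rank-consistent in the true t", {
  # the two-sample (Cornuet-Miller) statistics carry the divergence signal;
  # per-population statistics alone are invariant to the split time when
  # all branch sizes are equal
  tab <- abc_reference_table(two_pop_model(1, 1000), 10, 6, n_sims = 8000,
                             seed = 42, shared_N = TRUE)
  med_at <- function(t_true) {
    meds <- vapply(1:10, function(r) {
      obs <- gen_abc_observed(two_pop_model(t_true, 2000), 10, 6, 5e-4,
                              seed = 100 * t_true + r)
      post <- abc_rejection(obs$cornuet_miller, two_pop_model(1, 1000),
                            10, 6, tolerance = 0.02, seed = 1,
                            stats = "cornuet_miller", shared_N = TRUE,
                            ref_table = tab)
      post$summary$median[post$summary$parameter == "t1"]
    }, numeric(1))
    mean(meds)
  }
  meds <- vapply(c(500, 4000, 15000), med_at, numeric(1))
  expect_identical(order(meds), 1:3)
})

test_that("local-linear adjustment stays inside the prior support", {
  obs <- gen_abc_observed(two_pop_model(5000, 2000), 10, 5, 5e-4, seed = 9)
  post <- abc_rejection(obs$beaumont, two_pop_model(1, 1000), 10, 5,
                        n_sims = 3000, tolerance = 0.05, seed = 10,
                        adjust = "loclinear", stats = "beaumont",
                        shared_N = TRUE)
  expect_true(all(post$accepted[, "t1"] >= 1 & post$accepted[, "t1"] <= 20000))
  expect_equal(post$adjust, "loclinear")
})

test_that("generation-time conversion is linear", {
  expect_equal(generations_to_years(13600), 13600)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(100, generation_time = 2), 200)
})
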