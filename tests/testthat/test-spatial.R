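test_that("great-circle distances hit the haversine constants", {
  st <- flat_site_table(lon = c(10, 10, 11), lat = c(40, 41, 40))
  d <- geographic_distance_matrix(st)
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], 111.1949, tolerance = 1e-4)   # 1 degree of latitude
  # triangle inequality on random triples
  set.seed(3)
  for (i in 1:20) {
    st3 <- flat_site_table(lon = runif(3, -10, 10), lat = runif(3, -60, 60))
    d3 <- geographic_distance_matrix(st3)
    expect_lte(d3[1, 2], d3[1, 3] + d3[3, 2] + 1e-9)
  }
})

test_that("Mantel r equals the brute-force upper-triangle correlation", {
  A <- rand_sym(5, 1); B <- rand_sym(5, 2)
  mt <- mantel(A, B, n_perm = 99, seed = 3)
  expect_equal(mt$r, stats::cor(A[upper.tri(A)], B[upper.tri(B)]),
               tolerance = 1e-12)
  expect_equal(mantel(A, A, n_perm = 99, seed = 1)$r, 1)
  expect_error(mantel(matrix(1, 5, 5) - diag(5) * 0, B, 99), "constant")
})

test_that("partial Mantel nulls out B = C and matches plain Mantel for inert C", {
  A <- rand_sym(10, 4); B <- rand_sym(10, 5)
  pm_bc <- partial_mantel(A, B, B, n_perm = 99, seed = 1)
  expect_lt(abs(pm_bc$r), 1e-9)
  # C uncorrelated with A and B: r close to the plain Mantel r
  C <- rand_sym(10, 6)
  pm <- partial_mantel(A, B, C, n_perm = 99, seed = 1)
  mt <- mantel(A, B, n_perm = 99, seed = 1)
  expect_equal(pm$r, mt$r, tolerance = 0.15)
})

test_that("barrier matrix is binary, symmetric and keyed to river side", {
  st <- flat_site_table(lon = 1:4, lat = rep(45, 4),
                        river_side = c("E", "E", "W", "E"))
  b <- barrier_matrix(st)
  expect_equal(unname(b[1, 2]), 0)
  expect_equal(unname(b[1, 3]), 1)
  expect_true(isSymmetric(unclass(unname(b))))
})

test_that("connection network row-standardises inverse-square weights", {
  st2 <- flat_site_table(lon = c(0, 1), lat = c(45, 45))
  net2 <- connection_network(st2)
  expect_equal(unname(net2$L), matrix(c(0, 1, 1, 0), 2))
  # L invariant to rescaling all distances; W scales by the square
  st4 <- flat_site_table(lon = c(0, 0.1, 0.25, 0.7), lat = rep(45, 4))
  sth <- st4; sth$lon <- sth$lon / 2
  n1 <- connection_network(st4); n2 <- connection_network(sth)
  expect_equal(n2$L, n1$L, tolerance = 1e-6)
  expect_equal(n2$W / n1$W, matrix(4, 4, 4) - diag(NaN, 4),
               tolerance = 1e-4, ignore_attr = TRUE)
  dup <- flat_site_table(lon = c(0, 0), lat = c(45, 45))
  expect_error(connection_network(dup), "jitter")
})

test_that("Moran's I is positive on gradients, negative when alternating", {
  st <- flat_site_table(lon = seq(0, 2, length.out = 10), lat = rep(45, 10))
  net <- connection_network(st)
  expect_gt(moran_i(seq_len(10), net), 0)
  expect_lt(moran_i(rep(c(1, -1), 5), net), 0)
  # null mean approx -1/(n-1)
  set.seed(12)
  v <- rnorm(10)
  Is <- replicate(3000, moran_i(sample(v), net))
  expect_lt(abs(mean(Is) - (-1 / 9)), 0.02)
})

test_that("sPCA eigenvalues decompose into variance times Moran's I", {
  set.seed(14)
  st <- flat_site_table(lon = runif(12), lat = 45 + runif(12))
  net <- connection_network(st)
  X <- matrix(rnorm(12 * 8), 12, 8)
  sp <- spca(X, net, n_axes_pos = 3, n_axes_neg = 2)
  const <- sum(sp$H) / nrow(X)
  dec <- sp$axis_decomposition
  expect_equal(dec$eigenvalue, dec$variance * dec$moran_i * const,
               tolerance = 1e-6)
  # duplicated columns leave scores identical up to scale
  sp2 <- spca(cbind(X, X), net, n_axes_pos = 2)
  cors <- abs(diag(stats::cor(sp$scores[, 1:2], sp2$scores[, 1:2])))
  expect_equal(unname(cors), c(1, 1), tolerance = 1e-8)
  expect_error(spca(X[1:2, ], net), "3 sites")
})

test_that("sPCA detects a two-patch cline and its Monte Carlo test calibrates", {
  set.seed(15)
  st <- flat_site_table(lon = c(runif(8, 0, 0.4), runif(8, 1.6, 2)),
                        lat = 45 + runif(16, 0, 0.1))
  net <- connection_network(st)
  patch <- rep(c(0, 4), each = 8)
  X <- matrix(rnorm(16 * 6), 16, 6) + patch
  sp <- spca(X, net, n_axes_pos = 1)
  # first global score separates the patches
  expect_gt(abs(stats::cor(sp$scores[, 1], patch)), 0.9)
  mc <- spca_monte_carlo(X, net, "global", n_perm = 199, seed = 2)
  expect_lte(mc$p, 0.01)
  # permuted data: global statistic shrinks toward the null
  Xp <- X[sample(16), ]
  mc_null <- spca_monte_carlo(Xp, net, "global", n_perm = 99, seed = 3)
  expect_gt(mc_null$p, 0.05)
  expect_error(spca_monte_carlo(X, net, "global", n_perm = 0), "n_perm")
})

test_that("RDA explained fractions hit the exact endpoints", {
  set.seed(16)
  Y <- matrix(rnorm(40), 20, 2)
  expect_equal(rda(Y, Y)$explained, 1)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(rda(Y, X, Z = X)$explained, 0)
  # orthogonal noise explains about q/(n-1)
  expl <- replicate(50, rda(matrix(rnorm(40), 20, 2),
                            matrix(rnorm(60), 20, 3))$explained)
  expect_equal(mean(expl), 3 / 19, tolerance = 0.05)
  # aliased columns dropped with a warning
  expect_warning(rda(Y, cbind(X, X[, 1])), "aliased")
})

test_that("PERMANOVA attains its minimum p and detects built-in effects", {
  set.seed(17)
  X <- matrix(rnorm(30), 15, 2)
  Y <- X %*% matrix(c(1, 0.5, -0.5, 1), 2) + matrix(rnorm(30, sd = 0.1), 15, 2)
  m <- rda(Y, X)
  p <- permanova(m, n_perm = 999, seed = 1)
  expect_equal(p, 1 / 1000)
  expect_error(permanova(m, n_perm = 0), "n_perm")
})

test_that("variance partition recovers a single-factor truth and sums to ~100%", {
  set.seed(18)
  n <- 30
  f1 <- rnorm(n); f2 <- rnorm(n)
  coords <- cbind(lon = rnorm(n), lat = rnorm(n))
  Y <- cbind(2 * f1 + rnorm(n, sd = 0.2), -f1 + rnorm(n, sd = 0.2))
  vp <- variance_partition(Y, list(signal = f1, noise = f2), coords,
                           n_perm = 99, seed = 1)
  sig <- vp[vp$factor == "signal", ]
  noi <- vp[vp$factor == "noise", ]
  expect_gt(sig$pct_variance, 50)
  expect_lte(sig$p, 0.05)
  expect_lt(noi$pct_variance, 10)
  full <- attr(vp, "full_model")
  expect_equal(100 * full$explained +
                 vp$pct_variance[vp$factor == "unexplained"], 100,
               tolerance = 1e-9)
})

test_that("land-use buffering returns proportions that sum to one", {
  grid <- matrix(1L, 40, 40)            # uniform single class
  grid[, 21:40] <- 2L                   # eastern half is class 2
  lon <- seq(-100.5, -99.5, length.out = 40)
  lat <- seq(47.5, 46.5, length.out = 40)
  lc <- climate_stack(list(landcover = grid), lon, lat)
  st <- flat_site_table(lon = c(-100.25, -100), lat = c(47, 47))
  pr <- landuse_buffer(lc, st, radius_km = 15)
  expect_equal(rowSums(pr), c(s01 = 1, s02 = 1))
  expect_equal(unname(pr[1, "water"]), 1)        # deep in class 1
  # site on the split: about half and half (cell quantisation allowed)
  expect_equal(unname(pr[2, "water"]), 0.5, tolerance = 0.1)
  expect_equal(unname(pr[2, "urban"]), 0.5, tolerance = 0.1)
  expect_error(landuse_buffer(lc, st, radius_km = -1), "positive")
})
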