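test_that("occurrence cleaning drops duplicates, flags and excluded regions", {
  rec <- data.frame(lon = c(1, 1, 2, 3, 4), lat = c(1, 1, 2, 3, 4),
                    fossil = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                    captive = FALSE)
  poly <- cbind(c(3.5, 4.5, 4.5, 3.5), c(3.5, 3.5, 4.5, 4.5))
  out <- clean_occurrences(rec, excluded_regions = list(poly))
  expect_equal(nrow(out), 2)           # dup dropped, fossil dropped, in-poly dropped
  expect_equal(out$lon, c(1, 3))

  # synthetic 850-record set with 30 duplicates and 19 flagged -> 801 retained
  set.seed(30)
  base <- data.frame(lon = runif(820, -110, -90), lat = runif(820, 40, 50),
                     fossil = FALSE, captive = FALSE)
  base$fossil[1:10] <- TRUE
  base$captive[11:19] <- TRUE
  recs <- rbind(base, base[21:50, ])   # 30 exact duplicates
  expect_equal(nrow(recs), 850)
  expect_equal(nrow(clean_occurrences(recs)), 801)
})

test_that("background sampling is uniform over valid cells and seeded", {
  g <- matrix(1, 20, 20); g[1:5, 1:5] <- NA
  st <- climate_stack(list(a = g), lon = 1:20, lat = 20:1)
  expect_equal(nrow(sample_background(st, 0)), 0)
  bg <- sample_background(st, 500, seed = 2)
  v <- extract_values(st, bg)
  expect_equal(attr(v, "n_dropped"), 0)   # all points on valid cells
  expect_identical(sample_background(st, 50, seed = 7),
                   sample_background(st, 50, seed = 7))
  # chi-square uniformity over a 4-quadrant partition of the valid region
  big <- climate_stack(list(a = matrix(1, 40, 40)), lon = 1:40, lat = 40:1)
  b2 <- sample_background(big, 8000, seed = 3)
  quad <- 1L + (b2$lon > 20.5) + 2L * (b2$lat > 20.5)
  expect_gt(stats::chisq.test(table(quad))$p.value, 0.01)
})

test_that("value extraction is nearest-cell with nodata rows dropped", {
  g1 <- matrix(seq_len(12), 3, 4); g2 <- g1 * 10
  g1[2, 2] <- NA; g2[2, 2] <- NA
  st <- climate_stack(list(a = g1, b = g2), lon = c(10, 20, 30, 40),
                      lat = c(3, 2, 1))
  X <- extract_values(st, data.frame(lon = c(10, 20, 100), lat = c(3, 2, 1)))
  expect_equal(colnames(X), c("a", "b"))       # stack layer order
  expect_equal(unname(X[1, ]), c(1, 10))       # exact cell value
  expect_equal(attr(X, "n_dropped"), 2)        # nodata cell + off-grid point
})

test_that("VIF pruning drops collinear variables per the 1/(1-R2) definition", {
  set.seed(31)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_setequal(vif_prune(X), c("a", "b", "c"))   # orthogonal: all kept
  Xd <- cbind(X, d = X[, "a"])                      # duplicate
  kept <- vif_prune(Xd)
  expect_equal(length(kept), 3)
  expect_true(xor("a" %in% kept, "d" %in% kept))
  # hand value: regress c on a,b with known R2
  Xk <- X; Xk[, "c"] <- X[, "a"] + rnorm(100, sd = 0.5)
  r2 <- summary(stats::lm(Xk[, "c"] ~ Xk[, c("a", "b")]))$r.squared
  expect_equal(1 / (1 - r2) >= 10, !("c" %in% vif_prune(Xk, threshold = 10)))
})

test_that("BIC-averaged logistic regression finds the informative variable", {
  set.seed(32)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- stats::rbinom(n, 1, stats::plogis(2 * X[, "v2"]))   # 2-sigma effect
  fit <- glm_bic_average(X, y)
  expect_true(all(vapply(fit$subsets, function(s) "v2" %in% s, logical(1))))
  expect_gte(length(fit$members), 1)    # the window always holds the minimum
  pr <- predict(fit, as.data.frame(X))
  expect_true(all(pr >= 0 & pr <= 1))
  # p = 1: the average is the single model itself
  f1 <- glm_bic_average(X[, 1, drop = FALSE], y)
  expect_equal(length(f1$members), 1)
  g <- stats::glm(y ~ X[, 1], family = stats::binomial())
  expect_equal(unname(predict(f1, as.data.frame(X[, 1, drop = FALSE]))),
               unname(stats::fitted(g)), tolerance = 1e-6)
  expect_error(glm_bic_average(matrix(0, 4, 13), rep(0:1, 2)), "12")
})

test_that("BIOCLIM envelope scores are two-tailed percentiles with hard limits", {
  P <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "a"))
  fit <- bioclim_fit(P)
  pr <- predict(fit, matrix(c(3, 2, 1, 0.5, 6), 5, 1,
                            dimnames = list(NULL, "a")))
  expect_equal(pr, c(1, 0.6, 0.2, 0, 0))   # median, rank 2/5, min, outside
  # multi-variable: prediction is the min over variables
  P2 <- cbind(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50))
  x <- matrix(c(3, 20), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(bioclim_fit(P2), x), min(1, 0.6))
})

test_that("Mahalanobis suitability is 1 at the centroid and rank-monotone", {
  set.seed(33)
  P <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  fit <- mahalanobis_fit(P)
  expect_equal(predict(fit, matrix(fit$mu, 1, 2,
                                   dimnames = list(NULL, c("a", "b")))), 1)
  # with identity covariance, D2 is the squared Euclidean distance
  Pid <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  colnames(Pid) <- c("a", "b")
  fit_id <- mahalanobis_fit(Pid)
  x <- rbind(c(0.5, 0), c(1, 1), c(2, 2)); colnames(x) <- c("a", "b")
  d2 <- stats::mahalanobis(x, fit_id$mu, fit_id$sigma)
  expect_true(all(diff(predict(fit_id, x)) < 0))   # decreasing in distance
  expect_equal(predict(fit_id, x), stats::pchisq(d2, 2, lower.tail = FALSE))
})

test_that("k-fold assignment partitions points; AUC matches enumeration", {
  f <- kfold_assign(103, K = 4, seed = 5)
  expect_setequal(unique(f), 1:4)
  expect_equal(length(f), 103)
  expect_error(kfold_assign(10, K = 1), "K")

  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)  # 3 wins of 4 pairs
  expect_equal(auc(c(1, 1), c(0, 0)), 1)
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)    # all ties
})

test_that("ensemble weights and combination follow the weighted-average rule", {
  expect_equal(ensemble_weight(0.5), 0)
  g0 <- matrix(0, 2, 2); g1 <- matrix(1, 2, 2)
  # constant grids rescale to 0.5 each; weights {1, 3} -> 0.5
  comb <- ensemble_combine(list(g0, g1), c(1, 3))
  expect_equal(comb, matrix(0.5, 2, 2))
  # identical components: combination equals the rescaled component
  gr <- matrix(runif(9), 3, 3)
  expect_equal(ensemble_combine(list(gr, gr), c(1, 1)),
               (gr - min(gr)) / diff(range(gr)))
  # zero-weight component has no influence
  other <- matrix(runif(9), 3, 3)
  expect_equal(ensemble_combine(list(gr, other), c(1, 0)),
               ensemble_combine(list(gr, gr), c(2, 0)))
  expect_error(ensemble_combine(list(gr), 0), "zero")
})

test_that("range thresholding maximises sensitivity plus specificity", {
  suit <- matrix(seq(0, 1, length.out = 16), 4, 4)
  th <- threshold_range(suit, pres_scores = c(0.8, 0.9, 0.95),
                        bg_scores = c(0.1, 0.2, 0.3))
  expect_equal(th$threshold, 0.8)       # perfect separation
  expect_true(all(th$range == (suit >= 0.8)))
  # monotone transform leaves the binary map unchanged
  th2 <- threshold_range(suit^3, c(0.8, 0.9, 0.95)^3, c(0.1, 0.2, 0.3)^3)
  expect_identical(th$range, th2$range)
  expect_warning(threshold_range(matrix(0.5, 2, 2), 0.5, 0.5), "degenerate")
})

test_that("projection reproduces the training map and validates layers", {
  cs <- gen_climate_stack(shape = c(30, 30), n_layers = 4,
                          autocorrelation_length = 2, seed = 40)
  occ <- gen_occurrences(cs$stack, beta = c(bio1 = 8, bio2 = -6),
                         n_presence = 80, seed = 41, intercept = -10)
  bg <- sample_background(cs$stack, 200, seed = 42)
  ens <- suppressWarnings(
    fit_sdm_ensemble(cs$stack, occ$presences, bg, K = 4, seed = 43))
  proj <- project_ensemble(ens, cs$stack)
  expect_equal(unname(proj), unname(ens$suitability), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(ens$suitability >= 0 & ens$suitability <= 1, na.rm = TRUE))
  bad <- cs$stack; bad$layers <- bad$layers[-1]
  expect_error(project_ensemble(ens, bad), "bio1")
})

test_that("the plugin slot accepts external per-point scores", {
  cs <- gen_climate_stack(shape = c(25, 25), n_layers = 3,
                          autocorrelation_length = 2, seed = 50)
  occ <- gen_occurrences(cs$stack, beta = c(bio1 = 8), n_presence = 60,
                         seed = 51, intercept = -8)
  bg <- sample_background(cs$stack, 150, seed = 52)
  ens <- suppressWarnings(fit_sdm_ensemble(
    cs$stack, occ$presences, bg, methods = c("bioclim", "plugin"), K = 3,
    plugin = function(X) stats::plogis(as.matrix(X)[, "bio1"]), seed = 53))
  expect_equal(nrow(ens$components), 6)   # 2 methods x 3 folds
  expect_true(all(ens$components$weight ==
                    (ens$components$auc - 0.5)^2))
})

test_that("ESRI ASCII grids round-trip through the climate stack", {
  g <- matrix(runif(35), 5, 7); g[2, 3] <- NA
  st <- climate_stack(list(x = g), lon = seq(-103, -97, by = 1),
                      lat = seq(49, 45, by = -1))
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(st, "x", path)
  st2 <- read_esri_ascii(path, name = "x")
  expect_equal(st2$layers$x, st$layers$x, tolerance = 1e-6)
  expect_equal(st2$lon, st$lon, tolerance = 1e-9)
  expect_equal(st2$lat, st$lat, tolerance = 1e-9)
})
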