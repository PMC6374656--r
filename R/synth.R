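## Synthetic-data generators with known truth: hierarchically structured
## microsatellite genotypes (Balding-Nichols construction), isolation-by-
## distance site layouts, river-barrier effects, autocorrelated climate
## stacks, and presences sampled from a known suitability surface.  Every
## generator returns a truth record sufficient to regenerate its output.

## Dirichlet draw
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

## Balding-Nichols daughter frequencies around p with divergence F
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  rdirichlet1(p * (1 - F) / F)
}

## map a pairwise-GST target to the Balding-Nichols total divergence that
## produces it between two independently drawn daughters:
## E[GST] = (F/2)/(1 - F/2)  =>  F = 2 G/(1 + G)
gst_to_bn <- function(G) 2 * G / (1 + G)

#' Truth record accompanying a generated dataset
#'
#' @param generator generator name.
#' @param params named list of all generator parameters (including seed).
#' @param truth named list of derived ground-truth labels/surfaces.
#' @return a `truth_record`.
#' @export
truth_record <- function(generator, params, truth) {
  structure(list(generator = generator, params = params, truth = truth),
            class = "truth_record")
}

#' Serialize / restore a truth record as structured text
#' @param x a `truth_record`; @param path file path.
#' @return `path` invisibly (write) or the restored record (read).
#' @export
write_truth_record <- function(x, path) {
  dput(unclass(x), file = path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  x <- dget(path)
  structure(x, class = "truth_record")
}

#' Hierarchically structured multi-population microsatellite genotypes
#'
#' Balding-Nichols construction: per locus an ancestral frequency vector
#' over 5-25 alleles on a two-repeat ladder; major-cluster frequencies
#' drawn around the ancestor with divergence calibrated so the realized
#' pairwise Nei FST between majors matches `fst_between_major`; optionally
#' a nested subpopulation level; site frequencies drawn within their parent
#' with divergence calibrated to `fst_within_major` (between sites of the
#' same major, different subpopulations) and `fst_within_subpop` (same
#' subpopulation).  Diploid genotypes are then sampled per site.
#'
#' @param n_sites number of sampling sites.
#' @param inds_per_site diploid individuals per site.
#' @param n_loci number of loci.
#' @param fst_between_major target pairwise FST between major clusters.
#' @param fst_within_major target pairwise FST within a major cluster
#'   (between subpopulations when `n_subpop` is set, between sites
#'   otherwise).
#' @param n_major number of major clusters.
#' @param seed RNG seed.
#' @param n_subpop optional total number of nested subpopulations (split
#'   evenly among majors); `NULL` for a two-level hierarchy.
#' @param fst_within_subpop target FST between sites of the same
#'   subpopulation (default a third of `fst_within_major`).
#' @return list with `dataset` (a [genotype_dataset()]) and `truth` (a
#'   `truth_record` carrying the major/subpopulation of every site and
#'   individual).
#' @export
gen_hierarchical_genotypes <- function(n_sites, inds_per_site, n_loci,
                                       fst_between_major, fst_within_major,
                                       n_major = 2L, seed = 1L,
                                       n_subpop = NULL,
                                       fst_within_subpop = fst_within_major / 3) {
  set.seed(seed)
  ## calibrate nested Balding-Nichols divergences from the GST targets
  if (is.null(n_subpop)) {
    F_site <- gst_to_bn(fst_within_major)
    F_major <- max(0, (gst_to_bn(fst_between_major) - F_site) / (1 - F_site))
    F_sub <- 0
    sub_of_site <- NULL
  } else {
    F_site <- gst_to_bn(fst_within_subpop)
    F_sub <- max(0, (gst_to_bn(fst_within_major) - F_site) / (1 - F_site))
    below_major <- F_sub + (1 - F_sub) * F_site
    F_major <- max(0, (gst_to_bn(fst_between_major) - below_major) /
                     (1 - below_major))
  }
  major_of_site <- rep_len(seq_len(n_major), n_sites)
  if (!is.null(n_subpop)) {
    sub_major <- rep_len(seq_len(n_major), n_subpop)
    sub_of_site <- integer(n_sites)
    for (m in seq_len(n_major)) {
      subs <- which(sub_major == m)
      sub_of_site[major_of_site == m] <-
        rep_len(subs, sum(major_of_site == m))
    }
  }
  site_ids <- sprintf("s%02d", seq_len(n_sites))
  n_ind <- n_sites * inds_per_site
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci)
  site_of <- rep(site_ids, each = inds_per_site)
  ladders <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    A <- sample(5:25, 1L)
    sizes <- 100L + 2L * (seq_len(A) - 1L)
    ladders[[l]] <- sizes
    p0 <- rdirichlet1(rep(1, A))
    p_major <- lapply(seq_len(n_major), function(m) bn_draw(p0, F_major))
    if (is.null(n_subpop)) {
      p_parent_of_site <- lapply(major_of_site, function(m) p_major[[m]])
    } else {
      p_sub <- lapply(seq_len(n_subpop), function(s)
        bn_draw(p_major[[sub_major[s]]], F_sub))
      p_parent_of_site <- lapply(sub_of_site, function(s) p_sub[[s]])
    }
    for (s in seq_len(n_sites)) {
      p_site <- bn_draw(p_parent_of_site[[s]], F_site)
      rows <- (s - 1L) * inds_per_site + seq_len(inds_per_site)
      a1[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p_site)
      a2[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p_site)
    }
  }
  ids <- paste0(site_of, "_i", rep(seq_len(inds_per_site), n_sites))
  ds <- genotype_dataset(ids, paste0("L", seq_len(n_loci)), a1, a2,
                         stats::setNames(site_of, ids))
  tr <- truth_record(
    "gen_hierarchical_genotypes",
    list(n_sites = n_sites, inds_per_site = inds_per_site, n_loci = n_loci,
         fst_between_major = fst_between_major,
         fst_within_major = fst_within_major, n_major = n_major,
         n_subpop = n_subpop, fst_within_subpop = fst_within_subpop,
         seed = seed),
    list(major_of_site = stats::setNames(major_of_site, site_ids),
         subpop_of_site = if (is.null(n_subpop)) NULL else
           stats::setNames(sub_of_site, site_ids),
         major_of_individual = stats::setNames(
           major_of_site[match(site_of, site_ids)], ids)))
  list(dataset = ds, truth = tr)
}

#' The default study-shaped synthetic fixture
#'
#' 41 sites x 30 individuals x 11 loci with 2 major clusters and 10 nested
#' subpopulations, calibrated so between-major pairwise FST is about 0.09 —
#' the shape used by the integration tests.
#'
#' @param seed RNG seed.
#' @return as [gen_hierarchical_genotypes()].
#' @export
default_fixture <- function(seed = 1L) {
  gen_hierarchical_genotypes(n_sites = 41L, inds_per_site = 30L,
                             n_loci = 11L, fst_between_major = 0.09,
                             fst_within_major = 0.03, n_major = 2L,
                             seed = seed, n_subpop = 10L)
}

#' Sites on a rectangle with an isolation-by-distance frequency cline
#'
#' Sites are placed uniformly on an `extent_km` square (centred near
#' 47N, -100E); per locus, two endpoint frequency vectors are drawn and
#' each site's frequencies interpolate between them along the west-east
#' axis with weight `cline_strength` (0 = no cline, panmixia), plus a small
#' amount of site-level Balding-Nichols noise.  Genotypes are then sampled
#' per site, so linearized FST increases with distance when the cline is
#' strong.
#'
#' @param n_sites number of sites.
#' @param extent_km side of the square study area.
#' @param cline_strength in `[0, 1]`.
#' @param seed RNG seed.
#' @param inds_per_site diploids per site.
#' @param n_loci loci.
#' @param site_noise_fst Balding-Nichols site-level noise (default 0.01).
#' @return list with `sites` (a `site_table`), `dataset`, `truth`.
#' @export
gen_ibd_sites <- function(n_sites, extent_km = 600, cline_strength = 0.8,
                          seed = 1L, inds_per_site = 20L, n_loci = 8L,
                          site_noise_fst = 0.01) {
  set.seed(seed)
  lat0 <- 47; lon0 <- -100
  dlat <- extent_km / 111.2
  dlon <- extent_km / (111.2 * cos(lat0 * pi / 180))
  x <- stats::runif(n_sites); y <- stats::runif(n_sites)
  site_ids <- sprintf("s%02d", seq_len(n_sites))
  river_x <- 0.5                      # north-south barrier line
  lu <- t(vapply(seq_len(n_sites), function(i) rdirichlet1(rep(2, 6)),
                 numeric(6)))
  colnames(lu) <- landuse_classes()
  sites <- as_site_table(data.frame(
    site_id = site_ids,
    lon = lon0 - dlon / 2 + x * dlon,
    lat = lat0 - dlat / 2 + y * dlat,
    basin = paste0("basin_", 1L + (x > 0.5) + 2L * (y > 0.5)),
    river_side = ifelse(x < river_x, "W", "E"),
    lu))
  F_site <- gst_to_bn(site_noise_fst)
  n_ind <- n_sites * inds_per_site
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci)
  site_of <- rep(site_ids, each = inds_per_site)
  freqs <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    A <- sample(6:15, 1L)
    sizes <- 100L + 2L * (seq_len(A) - 1L)
    pA <- rdirichlet1(rep(1, A)); pB <- rdirichlet1(rep(1, A))
    fmat <- matrix(NA_real_, n_sites, A)
    for (s in seq_len(n_sites)) {
      w <- 0.5 + cline_strength * (x[s] - 0.5)
      p <- (1 - w) * pA + w * pB
      p_site <- bn_draw(p, F_site)
      fmat[s, ] <- p_site
      rows <- (s - 1L) * inds_per_site + seq_len(inds_per_site)
      a1[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p_site)
      a2[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p_site)
    }
    freqs[[l]] <- list(sizes = sizes, site_freqs = fmat)
  }
  ids <- paste0(site_of, "_i", rep(seq_len(inds_per_site), n_sites))
  ds <- genotype_dataset(ids, paste0("L", seq_len(n_loci)), a1, a2,
                         stats::setNames(site_of, ids))
  tr <- truth_record(
    "gen_ibd_sites",
    list(n_sites = n_sites, extent_km = extent_km,
         cline_strength = cline_strength, seed = seed,
         inds_per_site = inds_per_site, n_loci = n_loci,
         site_noise_fst = site_noise_fst),
    list(x = x, y = y, river_x = river_x, site_freqs = freqs))
  list(sites = sites, dataset = ds, truth = tr)
}

#' Inject a river-barrier divergence into site frequencies
#'
#' Regenerates the genotypes of an isolation-by-distance layout after
#' perturbing each river side's frequencies with an independent
#' Balding-Nichols draw whose divergence is calibrated so that
#' cross-barrier pairs gain about `extra_fst` while within-side pairs are
#' unchanged (both sides share their side's perturbation).
#'
#' @param ibd output of [gen_ibd_sites()].
#' @param extra_fst FST increment for cross-barrier pairs.
#' @param seed RNG seed.
#' @return list with `sites`, `dataset`, `truth` (as [gen_ibd_sites()]).
#' @export
gen_barrier_effect <- function(ibd, extra_fst, seed = 1L) {
  set.seed(seed)
  sites <- ibd$sites
  tr <- ibd$truth
  n_sites <- tr$params$n_sites
  inds_per_site <- tr$params$inds_per_site
  n_loci <- tr$params$n_loci
  ## each side diverges by F_half so the pair diverges by ~2*F_half,
  ## matching a GST increment of extra_fst
  F_half <- gst_to_bn(extra_fst) / 2
  side <- as.character(sites$river_side)
  a1 <- a2 <- matrix(NA_integer_, n_sites * inds_per_site, n_loci)
  site_of <- rep(sites$site_id, each = inds_per_site)
  new_freqs <- tr$truth$site_freqs
  for (l in seq_len(n_loci)) {
    fl <- tr$truth$site_freqs[[l]]
    sizes <- fl$sizes
    pbar <- colMeans(fl$site_freqs)
    shift <- list(W = bn_draw(pbar, F_half) - pbar,
                  E = bn_draw(pbar, F_half) - pbar)
    fmat <- fl$site_freqs
    for (s in seq_len(n_sites)) {
      p <- fmat[s, ] + shift[[side[s]]]
      p <- pmax(p, 1e-6); p <- p / sum(p)
      fmat[s, ] <- p
      rows <- (s - 1L) * inds_per_site + seq_len(inds_per_site)
      a1[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p)
      a2[rows, l] <- sample(sizes, inds_per_site, replace = TRUE, prob = p)
    }
    new_freqs[[l]]$site_freqs <- fmat
  }
  ids <- paste0(site_of, "_i", rep(seq_len(inds_per_site), n_sites))
  ds <- genotype_dataset(ids, paste0("L", seq_len(n_loci)), a1, a2,
                         stats::setNames(site_of, ids))
  tr2 <- truth_record(
    "gen_barrier_effect",
    c(tr$params, list(extra_fst = extra_fst, barrier_seed = seed)),
    c(tr$truth, list(site_freqs_barrier = new_freqs)))
  list(sites = sites, dataset = ds, truth = tr2)
}

## separable Gaussian smoothing of a matrix (reflective padding)
gauss_smooth <- function(m, len) {
  if (len <= 0) return(m)
  r <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(-r:r, sd = len); k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  smooth_vec <- function(v) {
    out <- stats::filter(pad(v), k, sides = 2)
    as.numeric(out[r + seq_along(v)])
  }
  m1 <- apply(m, 2, smooth_vec)
  t(apply(t(m1), 2, smooth_vec))
}

#' Generate a synthetic climate stack
#'
#' Gaussian-filtered white-noise fields with optional west-east linear
#' gradients, mixed through a configurable matrix so layers can be made
#' collinear (to exercise VIF pruning).  Layers are standardised to zero
#' mean and unit variance.
#'
#' @param shape `c(n_lat, n_lon)` grid size.
#' @param n_layers number of layers (named `bio1`, `bio2`, ...).
#' @param autocorrelation_length Gaussian smoothing length in cells (0 for
#'   independent noise).
#' @param seed RNG seed.
#' @param gradients numeric vector (recycled) of west-east gradient
#'   strengths added per layer.
#' @param mixing optional `n_layers x n_layers` matrix; output layer i is
#'   `sum_j mixing[i, j] * field_j`.
#' @return list with `stack` (a [climate_stack()]) and `truth`.
#' @export
gen_climate_stack <- function(shape = c(60L, 60L), n_layers = 5L,
                              autocorrelation_length = 3, seed = 1L,
                              gradients = 0, mixing = NULL) {
  set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  gradients <- rep_len(gradients, n_layers)
  gx <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  fields <- lapply(seq_len(n_layers), function(i) {
    f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                      autocorrelation_length)
    f + gradients[i] * gx
  })
  if (!is.null(mixing)) {
    mixed <- lapply(seq_len(n_layers), function(i)
      Reduce(`+`, Map(`*`, mixing[i, ], fields)))
    fields <- mixed
  }
  fields <- lapply(fields, function(f) (f - mean(f)) / stats::sd(f))
  names(fields) <- paste0("bio", seq_len(n_layers))
  lon <- seq(-105, -96, length.out = nc)
  lat <- seq(49, 45, length.out = nr)
  st <- climate_stack(fields, lon, lat)
  list(stack = st,
       truth = truth_record("gen_climate_stack",
                            list(shape = shape, n_layers = n_layers,
                                 autocorrelation_length = autocorrelation_length,
                                 seed = seed, gradients = gradients,
                                 mixing = mixing),
                            list()))
}

#' Sample presences from a known logistic suitability surface
#'
#' Suitability is `plogis(intercept + sum(beta_i * layer_i))`; presences
#' are drawn over valid cells with probability proportional to suitability
#' (without replacement when possible), at cell centres.
#'
#' @param stack a `climate_stack`.
#' @param beta named coefficient vector over (a subset of) layer names.
#' @param n_presence number of presences.
#' @param seed RNG seed.
#' @param intercept logistic intercept (default 0).
#' @return list with `presences` (data.frame lon/lat), `truth` (carries
#'   beta and the full suitability matrix).
#' @export
gen_occurrences <- function(stack, beta, n_presence, seed = 1L,
                            intercept = 0) {
  set.seed(seed)
  nr <- length(stack$lat)
  eta <- matrix(intercept, nr, length(stack$lon))
  for (nm in names(beta)) eta <- eta + beta[[nm]] * stack$layers[[nm]]
  suit <- stats::plogis(eta)
  valid <- which(!is.na(suit))
  cells <- sample(valid, n_presence, replace = n_presence > length(valid),
                  prob = suit[valid])
  lat_i <- (cells - 1L) %% nr + 1L
  lon_i <- (cells - 1L) %/% nr + 1L
  list(presences = data.frame(lon = stack$lon[lon_i], lat = stack$lat[lat_i]),
       truth = truth_record("gen_occurrences",
                            list(beta = beta, n_presence = n_presence,
                                 seed = seed, intercept = intercept),
                            list(suitability = suit)))
}

#' Simulate an observed summary vector from a known population tree
#'
#' Ground truth for ABC recovery experiments: simulates one dataset from a
#' fixed `pop_tree_model` and returns its summary vectors together with the
#' generating parameters.
#'
#' @param model a `pop_tree_model`.
#' @param sample_sizes diploids per leaf; @param n_loci loci.
#' @param mutation_rates per-locus rates; @param seed RNG seed.
#' @return list with `dataset`, `beaumont`, `cornuet_miller`, `truth`.
#' @export
gen_abc_observed <- function(model, sample_sizes, n_loci, mutation_rates,
                             seed = 1L) {
  ds <- simulate_coalescent_msats(model, sample_sizes, n_loci,
                                  mutation_rates, seed = seed)
  list(dataset = ds,
       beaumont = summary_beaumont(ds),
       cornuet_miller = summary_cornuet_miller(ds),
       truth = truth_record("gen_abc_observed",
                            list(times = model$times,
                                 branch_N = model$branch_N,
                                 sample_sizes = sample_sizes,
                                 n_loci = n_loci,
                                 mutation_rates = mutation_rates,
                                 seed = seed),
                            list()))
}
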