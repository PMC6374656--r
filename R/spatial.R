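## Spatially explicit attribution of genetic structure: Mantel and partial
## Mantel tests, inverse-square-distance connection networks, Moran's I,
## spatial PCA with Monte Carlo tests, RDA / partial RDA variance
## partitioning with permutation ANOVA, and land-use buffering on a grid.

#' Great-circle distance matrix between sites (km)
#'
#' Haversine distances on a sphere of radius 6371 km (about 111.2 km per
#' degree of latitude).
#'
#' @param sites a `site_table` (or data.frame with `lon`, `lat`,
#'   `site_id`).
#' @return a `dist_matrix` of kind `geographic_km`.
#' @export
geographic_distance_matrix <- function(sites) {
  co <- as.matrix(sites[, c("lon", "lat")])
  m <- geosphere::distm(co, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(m) <- list(sites$site_id, sites$site_id)
  dist_matrix(m, "geographic_km")
}

#' Binary river-barrier matrix
#'
#' 0 for site pairs on the same side of the river, 1 for pairs on opposite
#' sides, from the `river_side` flag of the site table.
#'
#' @param sites a `site_table`.
#' @return a `dist_matrix` of kind `barrier_binary`.
#' @export
barrier_matrix <- function(sites) {
  side <- as.character(sites$river_side)
  m <- outer(side, side, FUN = "!=") * 1
  dimnames(m) <- list(sites$site_id, sites$site_id)
  dist_matrix(m, "barrier_binary")
}

## strict upper triangle as a vector, in a fixed order
upper_vec <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the off-diagonal upper triangles; the
#' null distribution permutes the rows and columns of `B` jointly.  The
#' p-value is one-sided greater with the +1 correction,
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param A,B symmetric matrices over the same sites.
#' @param n_perm number of permutations (must be >= 1).
#' @param seed RNG seed.
#' @return list `(r, p, n_perm)`.
#' @export
mantel <- function(A, B, n_perm = 999L, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  a <- upper_vec(A)
  if (stats::sd(a) == 0 || stats::sd(upper_vec(B)) == 0)
    stop("Mantel r undefined for a constant matrix")
  r_obs <- stats::cor(a, upper_vec(B))
  set.seed(seed)
  n <- nrow(B)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(a, upper_vec(B[p, p])) >= r_obs - 1e-12) ge <- ge + 1L
  }
  list(r = r_obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
}

## residualize the upper triangle of A on that of C (with intercept),
## returned as a full symmetric matrix so rows/cols can be permuted jointly
residual_matrix <- function(A, C) {
  a <- upper_vec(A); cc <- upper_vec(C)
  res <- stats::resid(stats::lm(a ~ cc))
  m <- matrix(0, nrow(A), ncol(A))
  m[upper.tri(m)] <- res
  m + t(m)
}

#' Partial Mantel test of A and B controlling for C
#'
#' The statistic is the Pearson correlation between the residuals of A|C
#' and B|C over the off-diagonal pairs.  The null permutes the rows and
#' columns of the residual matrix of A|C (residual-permutation scheme,
#' which controls type-I error better than raw-matrix permutation).
#'
#' @param A,B,C symmetric matrices over the same sites.
#' @inheritParams mantel
#' @return list `(r, p, n_perm)`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999L, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  RA <- residual_matrix(A, C)
  rb <- stats::resid(stats::lm(upper_vec(B) ~ upper_vec(C)))
  ## fully partialled-out B (e.g. B = C) leaves only numerical noise
  if (stats::var(rb) < 1e-12 * max(stats::var(upper_vec(B)), 1e-300) ||
      stats::var(upper_vec(RA)) < 1e-12 * max(stats::var(upper_vec(A)), 1e-300))
    return(list(r = 0, p = 1, n_perm = n_perm))
  r_obs <- stats::cor(upper_vec(RA), rb)
  set.seed(seed)
  n <- nrow(A); ge <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(upper_vec(RA[p, p]), rb) >= r_obs - 1e-12) ge <- ge + 1L
  }
  list(r = r_obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
}

#' Inverse-square-distance connection network
#'
#' Weights `W_ij = 1/d_ij^2` (km) between distinct sites, and the
#' row-standardised lag matrix `L` whose rows sum to 1.  `L` is invariant
#' to rescaling all distances.
#'
#' @param sites a `site_table`.
#' @return a `connection_network`: list with `sites`, `W`, `L`.
#' @export
connection_network <- function(sites) {
  d <- geographic_distance_matrix(sites)
  d <- matrix(as.numeric(d), nrow(d), dimnames = dimnames(d))
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("duplicated coordinates give zero distance; jitter the sites")
  W <- 1 / d^2
  diag(W) <- 0
  L <- W / rowSums(W)
  structure(list(sites = sites$site_id, W = W, L = L),
            class = "connection_network")
}

#' Moran's I spatial autocorrelation
#'
#' Standard form `I = n/sum(W) * (z' W z)/(z' z)` with `z` the centred
#' values.  Under spatial randomness `E[I] = -1/(n-1)`.
#'
#' @param values numeric vector over sites.
#' @param network a `connection_network` (its `W` is used) or a weight
#'   matrix.
#' @return scalar I.
#' @export
moran_i <- function(values, network) {
  W <- if (inherits(network, "connection_network")) network$W else
    as.matrix(network)
  z <- values - mean(values)
  n <- length(z)
  (n / sum(W)) * drop(z %*% W %*% z) / sum(z^2)
}

#' Spatial PCA of site-level allele frequencies
#'
#' Finds axes maximising the product of the variance of site scores and
#' their spatial autocorrelation: eigen-decomposition of
#' `(1/n) X' H X` with `H = (L + L')/2` the symmetrised row-standardised
#' lag matrix and `X` the column-centred site x allele-frequency matrix.
#' Positive eigenvalues capture global structure (clines, patches),
#' negative ones local structure (neighbour contrasts).  Each eigenvalue
#' satisfies `lambda_k = var(s_k) * I(s_k) * sum(H)/n` for its score
#' vector `s_k = X u_k`.
#'
#' @param X site x allele-frequency matrix (sites in network order).
#' @param network a `connection_network` over the same sites.
#' @param n_axes_pos,n_axes_neg number of positive/negative axes to retain
#'   in `scores` (default 3 positive, 0 negative).
#' @return an `spca_result`: list with `eigenvalues` (all, descending),
#'   `scores`, `loadings`, `axis_decomposition` (variance, Moran's I per
#'   retained axis).
#' @export
spca <- function(X, network, n_axes_pos = 3L, n_axes_neg = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 sites")
  X <- scale(X, center = TRUE, scale = FALSE)
  H <- (network$L + t(network$L)) / 2
  C <- crossprod(X, H %*% X) / n
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos_idx <- which(vals > 0)
  neg_idx <- rev(which(vals < 0))
  keep <- c(utils::head(pos_idx, n_axes_pos), utils::head(neg_idx, n_axes_neg))
  U <- eig$vectors[, keep, drop = FALSE]
  S <- X %*% U
  colnames(S) <- paste0("sPC", seq_len(ncol(S)))
  decomp <- data.frame(
    axis = colnames(S),
    eigenvalue = vals[keep],
    variance = apply(S, 2, function(s) mean((s - mean(s))^2)),
    moran_i = apply(S, 2, function(s) moran_i(s, H)))
  structure(list(eigenvalues = vals, scores = S, loadings = U,
                 axis_decomposition = decomp, H = H),
            class = "spca_result")
}

#' Global / local Monte Carlo test for sPCA structure
#'
#' The statistic is the largest positive eigenvalue (global side) or the
#' largest absolute negative eigenvalue (local side) of the sPCA operator;
#' the null permutes the site rows of `X`, destroying any association
#' between genotype and location.
#'
#' @inheritParams spca
#' @param side `"global"` or `"local"`.
#' @param n_perm permutations; @param seed RNG seed.
#' @return list `(stat, p, side, n_perm)`.
#' @export
spca_monte_carlo <- function(X, network, side = c("global", "local"),
                             n_perm = 999L, seed = 1L) {
  side <- match.arg(side)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  H <- (network$L + t(network$L)) / 2
  n <- nrow(X)
  stat_of <- function(M) {
    vals <- eigen(crossprod(M, H %*% M) / n, symmetric = TRUE,
                  only.values = TRUE)$values
    if (side == "global") max(vals, 0) else max(-vals, 0)
  }
  obs <- stat_of(X)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (stat_of(X[sample.int(n), , drop = FALSE]) >= obs - 1e-12) ge <- ge + 1L
  }
  list(stat = obs, p = (1 + ge) / (1 + n_perm), side = side, n_perm = n_perm)
}

## column-centre and drop aliased (linearly dependent) columns, warning
drop_aliased <- function(X) {
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    drop <- colnames(Xc)[q$pivot[-seq_len(q$rank)]]
    warning("dropping aliased columns: ", paste(drop, collapse = ", "))
    Xc <- Xc[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  Xc
}

#' Redundancy analysis (RDA), optionally partial
#'
#' Multivariate least squares of response scores `Y` on a design matrix
#' `X`, optionally after residualising both on conditioning covariates `Z`
#' (partial RDA).  The explained fraction is
#' `tr(Yhat' Yhat) / tr(Y' Y)` on the (residualised, centred) response, and
#' the pseudo-F follows the constrained-ordination convention
#' `(explained/df_x) / (residual/df_res)`.
#'
#' @param Y numeric matrix of responses (e.g., retained sPCA site scores).
#' @param X design matrix of constraints.
#' @param Z optional conditioning matrix.
#' @return an `rda_model`: list with `explained` (fraction), `pseudo_F`,
#'   `df_x`, `df_res`, plus the residualised `Y`, `X`, `Z` needed for
#'   permutation tests.
#' @export
rda <- function(Y, X, Z = NULL) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- drop_aliased(X)
  n <- nrow(Y)
  rank_z <- 0L
  Zc <- NULL
  resid_mat <- function(M, B) {
    r <- stats::lm.fit(B, M)$residuals
    if (is.null(dim(r))) r <- matrix(r, ncol = 1L, dimnames = dimnames(M))
    r
  }
  if (!is.null(Z)) {
    Zc <- drop_aliased(Z)
    rank_z <- qr(Zc)$rank
    Y <- resid_mat(Y, cbind(1, Zc))
    pre_norm <- sqrt(colSums(X^2))
    X <- resid_mat(X, cbind(1, Zc))
    ## a constraint absorbed by the conditioning leaves only numerical
    ## noise behind; treat it as aliased rather than fitting the noise
    keep <- sqrt(colSums(X^2)) > 1e-8 * pmax(pre_norm, 1)
    X <- X[, keep, drop = FALSE]
    if (ncol(X)) X <- drop_aliased(X)
  }
  if (ncol(X) == 0L) {
    return(structure(list(explained = 0, pseudo_F = 0, df_x = 0L,
                          df_res = n - 1L - rank_z, Y = Y,
                          X = matrix(0, n, 0L), Z = Zc, n = n),
                     class = "rda_model"))
  }
  fit <- stats::lm.fit(X, Y)            # both already centred
  Yhat <- Y - fit$residuals
  tot <- sum(Y^2)
  expl <- if (tot > 0) sum(Yhat^2) / tot else 0
  df_x <- qr(X)$rank
  df_res <- n - 1L - df_x - rank_z
  pf <- if (expl < 1 && df_res > 0)
    (expl / df_x) / ((1 - expl) / df_res) else Inf
  structure(list(explained = expl, pseudo_F = pf, df_x = df_x,
                 df_res = df_res, Y = Y, X = X, Z = Zc, n = n),
            class = "rda_model")
}

#' Permutation ANOVA for an RDA model
#'
#' Freedman-Lane scheme: because the stored `Y` is already the residual of
#' the reduced (conditioned-only) model, rows of `Y` are permuted and the
#' pseudo-F recomputed; p is one-sided greater with the +1 correction.
#'
#' @param model an `rda_model`.
#' @param n_perm permutations (default 999 as in the reference protocol).
#' @param seed RNG seed.
#' @return p-value.
#' @export
permanova <- function(model, n_perm = 999L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (model$df_x == 0L) return(1)   # constraint fully absorbed: nothing to test
  set.seed(seed)
  Y <- model$Y; X <- model$X
  n <- nrow(Y)
  pf_of <- function(Yp) {
    fit <- stats::lm.fit(X, Yp)
    expl <- sum((Yp - fit$residuals)^2) / sum(Yp^2)
    (expl / model$df_x) / ((1 - expl) / model$df_res)
  }
  obs <- model$pseudo_F
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (pf_of(Y[sample.int(n), , drop = FALSE]) >= obs - 1e-12) ge <- ge + 1L
  }
  (1 + ge) / (1 + n_perm)
}

#' Variance partitioning of spatial genetic structure across landscape factors
#'
#' One row per landscape factor: the partial RDA of that factor conditioned
#' on all the other factors plus the site coordinates, with its permutation
#' p-value.  An isolation-by-distance row reports the unconditioned share
#' of the coordinates, and an `unexplained` row completes the table
#' (100% minus the full-model share).
#'
#' @param Y response matrix (retained sPCA scores).
#' @param factors named list of design matrices/vectors, one per factor.
#' @param coords two-column matrix of site lon/lat (the IBD term).
#' @param n_perm permutations; @param seed RNG seed.
#' @return data.frame of class `variance_partition`: `factor`,
#'   `pct_variance`, `pseudo_F`, `p`.
#' @export
variance_partition <- function(Y, factors, coords, n_perm = 999L, seed = 1L) {
  as_mat <- function(v) {
    if (is.factor(v) || is.character(v)) {
      f <- as.factor(v)
      stats::model.matrix(~ f)[, -1, drop = FALSE]
    } else as.matrix(v)
  }
  Xs <- lapply(factors, as_mat)
  coords <- as.matrix(coords)
  ibd <- rda(Y, coords)
  rows <- list(data.frame(factor = "coordinates (isolation by distance)",
                          pct_variance = 100 * ibd$explained,
                          pseudo_F = NA_real_, p = NA_real_))
  for (i in seq_along(Xs)) {
    others <- do.call(cbind, c(Xs[-i], list(coords)))
    m <- rda(Y, Xs[[i]], Z = others)
    rows[[length(rows) + 1L]] <-
      data.frame(factor = names(Xs)[i],
                 pct_variance = 100 * m$explained,
                 pseudo_F = m$pseudo_F,
                 p = permanova(m, n_perm = n_perm, seed = seed + i))
  }
  full <- rda(Y, do.call(cbind, c(Xs, list(coords))))
  rows[[length(rows) + 1L]] <-
    data.frame(factor = "unexplained", pct_variance = 100 * (1 - full$explained),
               pseudo_F = NA_real_, p = NA_real_)
  out <- do.call(rbind, rows)
  attr(out, "full_model") <- full
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Land-use proportions within a buffer around each site
#'
#' Counts grid cells of a categorical land-cover layer whose centres fall
#' within a great-circle radius of each site and converts class counts to
#' proportions.
#'
#' @param landcover a `climate_stack` whose single layer holds integer
#'   class codes 1..6 (order of [landuse_classes()]).
#' @param sites a `site_table` (coordinates used).
#' @param radius_km buffer radius in km (> 0).
#' @return matrix sites x 6 classes of proportions summing to 1.
#' @export
landuse_buffer <- function(landcover, sites, radius_km) {
  if (radius_km <= 0) stop("radius must be positive")
  grid <- landcover$layers[[1L]]
  cells <- expand.grid(lat = landcover$lat, lon = landcover$lon)
  vals <- as.vector(grid)           # column-major: lat varies fastest
  ok <- !is.na(vals)
  cells <- cells[ok, ]; vals <- vals[ok]
  out <- matrix(0, nrow(sites), 6,
                dimnames = list(sites$site_id, landuse_classes()))
  for (i in seq_len(nrow(sites))) {
    d <- geosphere::distHaversine(
      cbind(cells$lon, cells$lat),
      c(sites$lon[i], sites$lat[i]), r = 6371000) / 1000
    inside <- vals[d <= radius_km]
    if (!length(inside)) stop("no land-cover cells within the buffer of site ",
                              sites$site_id[i])
    tab <- tabulate(inside, nbins = 6)
    out[i, ] <- tab / sum(tab)
  }
  out
}
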