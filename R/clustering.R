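## Multivariate population clustering: genotype PCA, K-means with BIC model
## selection, the iterative majority-merge collapse of fine-scale clusters,
## and DAPC (PCA -> LDA) with a-score optimisation.

#' PCA of a genotype dosage matrix
#'
#' Centres (and optionally scales) the matrix and decomposes it by SVD.
#' Components can be retained by count or by cumulative explained variance;
#' requesting more components than the matrix rank truncates with a warning.
#'
#' @param dosage numeric matrix from [individual_dosage_matrix()].
#' @param n_components number of components to retain (default: all).
#' @param variance_target retain the smallest m with cumulative explained
#'   variance >= this fraction (overrides `n_components`).
#' @param scale. scale columns to unit variance before decomposition.
#' @return list with `scores`, `loadings`, `eigenvalues` (variances of the
#'   scores), `explained` (fractions), `center`, `scale`.
#' @export
pca_genotypes <- function(dosage, n_components = NULL, variance_target = NULL,
                          scale. = FALSE) {
  X <- scale(dosage, center = TRUE, scale = scale.)
  sv <- svd(X)
  n <- nrow(X)
  keep_rank <- sum(sv$d > sv$d[1L] * 1e-10)
  eig <- (sv$d^2) / (n - 1)
  expl <- eig / sum(eig)
  m <- keep_rank
  if (!is.null(variance_target)) {
    m <- which(cumsum(expl) >= variance_target - 1e-12)[1L]
  } else if (!is.null(n_components)) {
    if (n_components > keep_rank) {
      warning(sprintf("requested %d components but rank is %d; truncated",
                      n_components, keep_rank))
      m <- keep_rank
    } else m <- n_components
  }
  scores <- sv$u[, seq_len(m), drop = FALSE] %*%
    diag(sv$d[seq_len(m)], m, m)
  rownames(scores) <- rownames(dosage)
  colnames(scores) <- paste0("PC", seq_len(m))
  list(scores = scores,
       loadings = sv$v[, seq_len(m), drop = FALSE],
       eigenvalues = eig[seq_len(m)],
       explained = expl[seq_len(m)],
       center = attr(X, "scaled:center"),
       scale = attr(X, "scaled:scale"))
}

## k-means++ seeding: spread initial centres by squared-distance sampling
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    nd <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' K-means scan over K with BIC model selection
#'
#' For each candidate K the best of `n_restarts` k-means++ fits (by
#' within-cluster sum of squares) is kept and scored with the spherical
#' Gaussian-mixture BIC (the X-means formulation: pooled spherical variance
#' `WSS/(d (n - K))`, mixing-proportion term, `(K - 1) + dK + 1` free
#' parameters), and the K minimising BIC is returned together with the full
#' BIC curve.  Unlike the bare `n log(WSS/n) + penalty` heuristics, this
#' criterion both recovers well-separated groups and resists splitting
#' homogeneous data.
#'
#' @param scores numeric matrix (e.g., retained PCA scores).
#' @param K_range integer vector of candidate K values within `[1, n-1]`.
#' @param n_restarts random restarts per K.
#' @param seed RNG seed.
#' @return a `cluster_solution`: list with `K`, `assignment` (named integer
#'   vector, labels contiguous 1..K), `bic` (named by K), `seed`,
#'   `n_restarts`.
#' @export
kmeans_bic_scan <- function(scores, K_range, n_restarts = 20L, seed = 1L) {
  X <- as.matrix(scores)
  n <- nrow(X); d <- ncol(X)
  if (any(K_range < 1L) || any(K_range > n - 1L))
    stop("K_range must lie within [1, n-1]")
  set.seed(seed)
  bic <- stats::setNames(rep(NA_real_, length(K_range)), K_range)
  assignments <- vector("list", length(K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    if (K == 1L) {
      wss <- sum(scale(X, scale = FALSE)^2)
      assignments[[ki]] <- rep(1L, n)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- tryCatch(
          stats::kmeans(X, centers = kmeanspp_centers(X, K),
                        iter.max = 50L),
          error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      if (is.null(best)) stop("k-means failed for K = ", K,
                              " (persistent empty clusters)")
      wss <- best$tot.withinss
      assignments[[ki]] <- best$cluster
    }
    bic[ki] <- spherical_gmm_bic(wss, table(assignments[[ki]]), n, d, K)
  }
  pick <- which.min(bic)
  assignment <- relabel_contiguous(assignments[[pick]])
  names(assignment) <- rownames(X)
  structure(list(K = max(assignment), assignment = assignment, bic = bic,
                 seed = seed, n_restarts = n_restarts),
            class = "cluster_solution")
}

## spherical Gaussian-mixture BIC of a k-means partition (X-means form)
spherical_gmm_bic <- function(wss, nk, n, d, K) {
  sig2 <- max(wss / (d * (n - K)), 1e-12)
  ll <- sum(nk * log(nk / n)) - n * d / 2 * log(2 * pi * sig2) -
    d * (n - K) / 2
  n_par <- (K - 1) + d * K + 1
  -2 * ll + n_par * log(n)
}

## relabel cluster ids to contiguous 1..K preserving order of first appearance
relabel_contiguous <- function(a) {
  u <- unique(a)
  match(a, u)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: K = %d over %d individuals\n",
              x$K, length(x$assignment)))
  invisible(x)
}

#' Iterative majority-merge of clusters across sampling sites
#'
#' Implements the collapse rule used to reconcile fine-scale K-means
#' clusters with sampling sites: while any site lacks a strict-majority
#' cluster (> 50% of its individuals), take the first such site in
#' ascending site-ID order, find its two most frequent clusters (ties broken
#' by the smaller cluster index), and union those two clusters across the
#' whole dataset, keeping the smaller label.  Each iteration reduces the
#' number of clusters by one, so the procedure terminates in at most K - 1
#' merges; final clusters are unions of initial clusters.
#'
#' @param assignment integer cluster labels named by individual.
#' @param site_of site of each individual (named by individual).
#' @return list with `assignment` (relabelled contiguous 1..K'),
#'   `site_population` (named character: each site's majority cluster),
#'   `n_merges`, and `merge_log` (data.frame of the unions performed).
#' @export
majority_merge <- function(assignment, site_of) {
  ind <- names(assignment)
  if (is.null(ind)) stop("assignment must be named by individual")
  site_of <- site_of[ind]
  a <- as.integer(assignment)
  sites <- sort(unique(site_of))
  log_rows <- list()
  repeat {
    offender <- NA_character_
    for (s in sites) {
      tab <- table(a[site_of == s])
      if (max(tab) / sum(tab) <= 0.5) { offender <- s; break }
    }
    if (is.na(offender)) break
    tab <- table(a[site_of == offender])
    cl <- as.integer(names(tab))
    ord <- order(-as.integer(tab), cl)       # by count desc, then index asc
    top2 <- sort(cl[ord[1:2]])
    a[a == top2[2L]] <- top2[1L]
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(site = offender, kept = top2[1L], absorbed = top2[2L])
  }
  a <- relabel_contiguous(a)
  names(a) <- ind
  site_population <- vapply(sites, function(s) {
    tab <- table(a[site_of == s])
    names(tab)[which.max(tab)]
  }, character(1))
  list(assignment = a,
       site_population = stats::setNames(site_population, sites),
       n_merges = length(log_rows),
       merge_log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(site = character(), kept = integer(),
                    absorbed = integer()))
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the dosage matrix to `n_pcs` principal components and fits a
#' linear discriminant analysis between the given groups with equal priors.
#' Group membership probabilities (the Q-matrix) are the LDA posterior
#' probabilities of each individual.  A singular within-group scatter is
#' ridge-regularised by jittering the PC scores with a logged epsilon.
#'
#' @param dosage dosage matrix (individuals x alleles).
#' @param groups factor/character of group labels per individual.
#' @param n_pcs number of principal components to retain.
#' @return a `dapc_model`: list with `n_pcs`, `lda` fit, `scores`
#'   (discriminant coordinates), `explained` (per-function fraction of
#'   between-group variance), `centroids`, `Q` (individuals x groups),
#'   `pca` (the reduction, for projecting new data).
#' @export
dapc_fit <- function(dosage, groups, n_pcs) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("DAPC needs at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 members")
  pca <- pca_genotypes(dosage, n_components = n_pcs)
  X <- pca$scores
  K <- nlevels(groups)
  prior <- rep(1 / K, K)
  fit <- tryCatch(
    MASS::lda(X, grouping = groups, prior = prior),
    error = function(e) {
      message("within-group scatter singular; ridge-regularising (eps = 1e-6)")
      Xr <- X + matrix(stats::rnorm(length(X), sd = 1e-6), nrow(X))
      MASS::lda(Xr, grouping = groups, prior = prior)
    })
  pred <- stats::predict(fit, X)
  expl <- fit$svd^2 / sum(fit$svd^2)
  centroids <- apply(pred$x, 2, function(v) tapply(v, groups, mean))
  Q <- pred$posterior
  rownames(Q) <- rownames(dosage)
  structure(list(n_pcs = n_pcs, lda = fit, scores = pred$x,
                 explained = expl, centroids = centroids, Q = Q,
                 groups = groups, pca = pca),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d PCs, %d discriminant functions (first explains %.1f%%)\n",
              x$n_pcs, length(x$explained), 100 * x$explained[1L]))
  invisible(x)
}

## proportion of individuals whose max-posterior group matches truth,
## averaged over groups
reassignment_rate <- function(Q, groups) {
  pred <- colnames(Q)[max.col(Q, ties.method = "first")]
  mean(tapply(pred == as.character(groups), groups, mean))
}

#' a-score optimisation of the number of retained PCs for DAPC
#'
#' The a-score of a DAPC fit is the observed reassignment success minus its
#' expectation under random permutations of the group labels — an
#' overfitting penalty that is maximised at an intermediate number of PCs.
#'
#' @param dosage dosage matrix.
#' @param groups group labels.
#' @param n_pcs_grid integer vector of candidate PC counts.
#' @param n_perm permutations per grid point.
#' @param seed RNG seed.
#' @return list with `optimal` (argmax n_pcs), `a_scores` (named by grid).
#' @export
a_score_optimize <- function(dosage, groups, n_pcs_grid, n_perm = 10L,
                             seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("a-score undefined for a single group")
  set.seed(seed)
  a <- stats::setNames(rep(NA_real_, length(n_pcs_grid)), n_pcs_grid)
  for (i in seq_along(n_pcs_grid)) {
    np <- n_pcs_grid[i]
    obs <- reassignment_rate(dapc_fit(dosage, groups, np)$Q, groups)
    null <- vapply(seq_len(n_perm), function(b) {
      gp <- sample(groups)
      reassignment_rate(dapc_fit(dosage, gp, np)$Q, gp)
    }, numeric(1))
    a[i] <- obs - mean(null)
  }
  list(optimal = n_pcs_grid[which.max(a)], a_scores = a)
}

#' Summary of Q-matrix membership assignments
#'
#' @param Q individuals x populations membership-probability matrix.
#' @param threshold membership threshold (default 0.5).
#' @param site_of optional site per individual (named), used with
#'   `site_population` to compute per-population cross-assignment.
#' @param site_population optional named map site -> population label.
#' @return list with `frac_assigned` (fraction of individuals whose maximum
#'   Q exceeds the threshold), `mean_assignment` (per population, mean
#'   probability of its own members, if population truth supplied),
#'   `cross_assignment` (matrix of rates: fraction of population i's
#'   individuals whose max-Q population is j).
#' @export
assignment_summary <- function(Q, threshold = 0.5, site_of = NULL,
                               site_population = NULL) {
  maxq <- apply(Q, 1, max)
  pred <- colnames(Q)[max.col(Q, ties.method = "first")]
  out <- list(frac_assigned = mean(maxq > threshold))
  if (!is.null(site_of) && !is.null(site_population)) {
    truth <- as.character(site_population[site_of[rownames(Q)]])
    pops <- colnames(Q)
    out$mean_assignment <- vapply(pops, function(p) {
      idx <- truth == p
      if (!any(idx)) return(NA_real_)
      mean(Q[idx, p])
    }, numeric(1))
    cm <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (p in pops) {
      idx <- truth == p
      if (!any(idx)) next
      cm[p, ] <- vapply(pops, function(q) mean(pred[idx] == q), numeric(1))
    }
    out$cross_assignment <- cm
  }
  out
}
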