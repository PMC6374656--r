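## Coalescent simulation of microsatellites on a fixed population tree under
## strict single-step stepwise mutation, summary-statistic sets, and
## rejection ABC with optional local-linear regression adjustment.

#' Construct a fixed population-tree model
#'
#' A binary, fully resolved tree over leaf populations.  Branches are
#' indexed 1..P for the leaves and P+j for the branch created by merge
#' event j; merge events must be given in ascending time order and every
#' parent must be older than both children.
#'
#' @param leaves character vector of leaf population names.
#' @param merges (P-1) x 2 matrix of child branch indices per merge event.
#' @param times numeric vector of merge times (generations, > 0), ascending.
#' @param branch_N diploid effective size per branch (length 2P-1).
#' @return a `pop_tree_model`.
#' @export
pop_tree_model <- function(leaves, merges, times, branch_N) {
  P <- length(leaves)
  merges <- matrix(as.integer(merges), ncol = 2)
  if (nrow(merges) != P - 1L) stop("a binary tree over P leaves has P-1 merges")
  if (length(times) != P - 1L) stop("one time per merge event")
  if (any(times <= 0)) stop("merge times must be strictly positive")
  if (is.unsorted(times)) stop("merge events must be in ascending time order")
  for (j in seq_len(nrow(merges))) for (c in 1:2) {
    child <- merges[j, c]
    if (child > P && times[child - P] >= times[j])
      stop("parent time must exceed both child times")
  }
  if (length(branch_N) != 2L * P - 1L)
    stop("need one effective size per branch (2P-1)")
  if (any(branch_N < 1)) stop("effective sizes must be >= 1")
  structure(list(leaves = leaves, merges = merges, times = as.numeric(times),
                 branch_N = as.numeric(branch_N)),
            class = "pop_tree_model")
}

#' Two-population split model
#'
#' @param t divergence time in generations.
#' @param N diploid effective size, shared by the two daughter populations
#'   and the ancestor (or length-3 vector `c(N1, N2, N_anc)`).
#' @param leaves leaf names.
#' @return a `pop_tree_model`.
#' @export
two_pop_model <- function(t, N, leaves = c("A", "B")) {
  if (length(N) == 1L) N <- rep(N, 3L)
  pop_tree_model(leaves, matrix(c(1L, 2L), 1), t, N)
}

#' Simulate microsatellite genotypes on a population tree
#'
#' Backward-in-time coalescent within each branch (rate `k(k-1)/(4N)` per
#' generation, continuous-time approximation); lineages pool at merge
#' events; mutations are Poisson on gene-tree branches and shift the repeat
#' size by +/-1 with equal probability (strict stepwise model); the root
#' allele is 100 repeats.  Diploid genotypes are formed by pairing gene
#' copies within each population.
#'
#' @param model a `pop_tree_model`.
#' @param sample_sizes diploid individuals sampled per leaf (recycled).
#' @param n_loci number of independent loci.
#' @param mutation_rates per-locus mutation rates (recycled to `n_loci`).
#' @param seed RNG seed.
#' @return a [genotype_dataset()] with one site per leaf population.
#' @export
simulate_coalescent_msats <- function(model, sample_sizes, n_loci,
                                      mutation_rates, seed = 1L) {
  P <- length(model$leaves)
  sample_sizes <- rep_len(as.integer(sample_sizes), P)
  if (any(sample_sizes < 1L)) stop("sample sizes must be >= 1 per leaf")
  mus <- rep_len(as.numeric(mutation_rates), n_loci)
  set.seed(seed)
  sizes <- cpp_sim_msat(sample_sizes, model$merges - 1L, model$times,
                        model$branch_N, mus)
  pops <- rep(model$leaves, times = 2L * sample_sizes)
  odd <- seq(1L, nrow(sizes), by = 2L)
  ids <- paste0(pops[odd], "_", unlist(lapply(sample_sizes, seq_len)))
  loci <- paste0("L", seq_len(n_loci))
  genotype_dataset(ids, loci, sizes[odd, , drop = FALSE],
                   sizes[odd + 1L, , drop = FALSE],
                   stats::setNames(pops[odd], ids))
}

## per-population, per-locus building blocks shared by the two summary sets
pop_locus_table <- function(dataset) {
  freqs <- allele_frequencies(dataset)
  pops <- freqs$groups
  list(freqs = freqs, pops = pops)
}

#' Beaumont-style summary statistics
#'
#' Per population, averaged over loci: mean number of alleles, expected
#' heterozygosity (unbiased), and the variance of allele sizes.
#'
#' @param dataset a `genotype_dataset` (sites are the populations).
#' @return named numeric vector of length `3 * n_pops` with attribute
#'   `set_id = "beaumont"`.
#' @export
summary_beaumont <- function(dataset) {
  pt <- pop_locus_table(dataset)
  out <- c()
  for (g in pt$pops) {
    idx <- which(dataset$site_of == g)
    k <- he <- v <- c()
    for (l in seq_along(dataset$loci)) {
      fr <- pt$freqs$freqs[[g]][[dataset$loci[l]]]
      if (is.null(fr)) next
      n2 <- pt$freqs$n[g, l]
      k <- c(k, length(fr))
      he <- c(he, (1 - sum(as.numeric(fr)^2)) * n2 / (n2 - 1))
      copies <- c(dataset$a1[idx, l], dataset$a2[idx, l])
      v <- c(v, stats::var(copies[!is.na(copies)]))
    }
    out <- c(out, stats::setNames(c(mean(k), mean(he), mean(v)),
                                  paste0(g, c(".mean_k", ".het", ".var"))))
  }
  structure(out, set_id = "beaumont")
}

#' Cornuet-Miller-style summary statistics
#'
#' Per population: mean number of alleles, expected heterozygosity, and
#' Garza-Williamson M, averaged over loci.  Per unordered population pair:
#' Nei pairwise FST.  Per ordered pair (i, j), i != j: the mean over
#' individuals of population i of the log-likelihood of their genotypes
#' under population j's allele frequencies, with unseen alleles floored at
#' `1/(2 n_j + 1)`.
#'
#' @param dataset a `genotype_dataset`.
#' @return named numeric vector with attribute `set_id = "cornuet_miller"`.
#' @export
summary_cornuet_miller <- function(dataset) {
  pt <- pop_locus_table(dataset)
  pops <- pt$pops
  out <- c()
  for (g in pops) {
    k <- he <- m <- c()
    idx <- which(dataset$site_of == g)
    for (l in seq_along(dataset$loci)) {
      fr <- pt$freqs$freqs[[g]][[dataset$loci[l]]]
      if (is.null(fr)) next
      n2 <- pt$freqs$n[g, l]
      k <- c(k, length(fr))
      he <- c(he, (1 - sum(as.numeric(fr)^2)) * n2 / (n2 - 1))
      copies <- c(dataset$a1[idx, l], dataset$a2[idx, l])
      m <- c(m, garza_williamson_m(copies))
    }
    out <- c(out, stats::setNames(c(mean(k), mean(he), mean(m)),
                                  paste0(g, c(".mean_k", ".het", ".M"))))
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    out <- c(out, stats::setNames(pairwise_fst(pt$freqs, pops[c(i, j)]),
                                  paste0("fst.", pops[i], ".", pops[j])))
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i == j) next
    out <- c(out, stats::setNames(
      assignment_loglik(dataset, pt$freqs, pops[i], pops[j]),
      paste0("lik.", pops[i], ".", pops[j])))
  }
  structure(out, set_id = "cornuet_miller")
}

#' Mean genotype log-likelihood of population i under population j
#'
#' @param dataset a `genotype_dataset`.
#' @param freqs its site-grouped `allele_freq_table`.
#' @param pop_i,pop_j population labels; when equal, leave-one-out
#'   frequencies are used for each focal individual.
#' @return mean over individuals of the summed per-locus genotype
#'   log-likelihood.
#' @export
assignment_loglik <- function(dataset, freqs, pop_i, pop_j) {
  idx <- which(dataset$site_of == pop_i)
  loo <- identical(pop_i, pop_j)
  lls <- vapply(idx, function(i) {
    ll <- 0
    for (l in seq_along(dataset$loci)) {
      a <- dataset$a1[i, l]; b <- dataset$a2[i, l]
      if (is.na(a)) next
      fr <- freqs$freqs[[pop_j]][[dataset$loci[l]]]
      n2 <- freqs$n[pop_j, l]
      if (loo) {
        counts <- fr * n2
        counts[as.character(a)] <- counts[as.character(a)] - 1
        counts[as.character(b)] <- counts[as.character(b)] - 1
        n2 <- n2 - 2
        fr <- counts / n2
      }
      floor_f <- 1 / (n2 + 1)
      pa <- fr[as.character(a)]; pb <- fr[as.character(b)]
      pa <- if (is.na(pa) || pa <= 0) floor_f else as.numeric(pa)
      pb <- if (is.na(pb) || pb <= 0) floor_f else as.numeric(pb)
      ll <- ll + if (a == b) 2 * log(pa) else log(2 * pa * pb)
    }
    ll
  }, numeric(1))
  mean(lls)
}

#' Rejection ABC for divergence times and population sizes
#'
#' Draws parameters from uniform priors (population sizes and divergence
#' times as integers on their ranges, divergence times resampled until
#' consistent with the tree ordering; mean mutation rate log-uniform on
#' `[1e-4, 1e-3]` with per-locus rates log-uniform within a factor of 10 of
#' the mean, truncated to `[1e-5, 1e-2]`), simulates a reference table,
#' standardises every summary statistic by its simulation-wide MAD
#' (zero-MAD statistics are dropped with a warning), and accepts the
#' `tolerance` fraction of draws closest to the observed vector in
#' Euclidean distance.  Optionally applies the local-linear regression
#' adjustment (Epanechnikov-weighted) to the accepted draws, clamped to the
#' prior support.
#'
#' @param observed summary vector from [summary_beaumont()] or
#'   [summary_cornuet_miller()].
#' @param model_template a `pop_tree_model` giving topology and leaf order
#'   (its times/sizes are ignored; they are drawn from the priors).
#' @param sample_sizes diploids per leaf (must match the observed data).
#' @param n_loci number of loci (must match the observed data).
#' @param n_sims number of prior draws (>= 1000 for meaningful quantiles).
#' @param tolerance accepted fraction in (0, 1].
#' @param seed RNG seed.
#' @param adjust `"none"` or `"loclinear"`.
#' @param stats which summary set the observed vector uses.
#' @param shared_N draw a single effective size shared by all branches
#'   rather than one per branch.
#' @param priors list with elements `N` and `t`, each `c(min, max)`.
#' @param ref_table optional reference table from [abc_reference_table()]
#'   (avoids re-simulating when several rejections share one table, e.g.
#'   the two summary sets on the same observed data).
#' @return an `abc_posterior`: list with `accepted` (draws x parameters),
#'   `distances`, `summary` (median and central 95% interval per
#'   parameter), `tolerance`, `n_sims`, `adjust`.
#' @export
abc_rejection <- function(observed, model_template, sample_sizes, n_loci,
                          n_sims = 100000L, tolerance = 0.005, seed = 1L,
                          adjust = c("none", "loclinear"),
                          stats = c("beaumont", "cornuet_miller"),
                          shared_N = FALSE,
                          priors = list(N = c(1, 20000), t = c(1, 20000)),
                          ref_table = NULL) {
  adjust <- match.arg(adjust)
  stats <- match.arg(stats)
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  if (n_sims < 1000L) stop("n_sims must be >= 1000 for meaningful quantiles")
  P <- length(model_template$leaves)
  sample_sizes <- rep_len(as.integer(sample_sizes), P)
  if (is.null(ref_table)) {
    tab <- abc_reference_table(model_template, sample_sizes, n_loci,
                               n_sims, seed, shared_N, priors)
  } else {
    tab <- ref_table
    n_sims <- nrow(tab)
  }
  nN <- if (shared_N) 1L else 2L * P - 1L
  par_names <- c(paste0("t", seq_len(P - 1L)),
                 if (shared_N) "N" else paste0("N", seq_len(2L * P - 1L)),
                 "mu_bar")
  n_par <- length(par_names)
  params <- tab[, seq_len(n_par), drop = FALSE]
  colnames(params) <- par_names
  nb <- 3L * P
  stat_cols <- if (stats == "beaumont") n_par + seq_len(nb) else
    n_par + nb + seq_len(3L * P + P * (P - 1L) / 2L + P * (P - 1L))
  S <- tab[, stat_cols, drop = FALSE]
  obs <- as.numeric(observed)
  if (length(obs) != ncol(S))
    stop(sprintf("observed vector has %d statistics; the '%s' set needs %d",
                 length(obs), stats, ncol(S)))
  mads <- apply(S, 2, stats::mad)
  keep <- mads > 0
  if (!all(keep)) {
    warning(sum(!keep), " degenerate statistic(s) with zero MAD dropped")
    S <- S[, keep, drop = FALSE]; obs <- obs[keep]; mads <- mads[keep]
  }
  Ss <- sweep(S, 2, mads, "/")
  obss <- obs / mads
  d <- sqrt(rowSums(sweep(Ss, 2, obss, "-")^2))
  n_acc <- max(2L, ceiling(tolerance * n_sims))
  acc_idx <- order(d)[seq_len(n_acc)]
  accepted <- params[acc_idx, , drop = FALSE]
  if (adjust == "loclinear") {
    dmax <- max(d[acc_idx])
    w <- 1 - (d[acc_idx] / dmax)^2
    w[w <= 0] <- min(w[w > 0]) / 2
    X <- cbind(1, sweep(Ss[acc_idx, , drop = FALSE], 2, obss, "-"))
    for (p in seq_len(ncol(accepted))) {
      fit <- stats::lm.wfit(X, accepted[, p], w)
      accepted[, p] <- fit$coefficients[1L] + fit$residuals
    }
    lo <- c(rep(priors$t[1], P - 1L), rep(priors$N[1], nN), 1e-4)
    hi <- c(rep(priors$t[2], P - 1L), rep(priors$N[2], nN), 1e-3)
    accepted <- pmin(pmax(accepted, matrix(lo, nrow(accepted), n_par,
                                           byrow = TRUE)),
                     matrix(hi, nrow(accepted), n_par, byrow = TRUE))
  }
  qs <- apply(accepted, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(parameter = par_names, median = qs[2L, ],
                        ci_lo = qs[1L, ], ci_hi = qs[3L, ],
                        row.names = NULL)
  structure(list(accepted = accepted, distances = d[acc_idx],
                 summary = summary, tolerance = tolerance, n_sims = n_sims,
                 adjust = adjust, stats = stats),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior (%s stats, %d sims, tol %.3g, adjust %s)\n",
              x$stats, x$n_sims, x$tolerance, x$adjust))
  print(x$summary)
  invisible(x)
}

#' Simulate an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the priors described in
#' [abc_rejection()], simulates each dataset, and returns the parameters
#' together with both summary-statistic sets as one matrix (parameters
#' first, then the Beaumont block, then the Cornuet-Miller block).
#'
#' @inheritParams abc_rejection
#' @return numeric matrix, one row per simulation.
#' @export
abc_reference_table <- function(model_template, sample_sizes, n_loci,
                                n_sims = 100000L, seed = 1L,
                                shared_N = FALSE,
                                priors = list(N = c(1, 20000),
                                              t = c(1, 20000))) {
  P <- length(model_template$leaves)
  sample_sizes <- rep_len(as.integer(sample_sizes), P)
  set.seed(seed)
  cpp_abc_table(as.integer(n_sims), sample_sizes,
                model_template$merges - 1L, as.integer(n_loci),
                priors$N[1], priors$N[2], priors$t[1], priors$t[2],
                shared_N)
}

#' Convert generations to calendar years
#'
#' @param t time in generations.
#' @param generation_time years per generation (default 1, the northern
#'   leopard frog's approximate generation time).
#' @return time in years.
#' @export
generations_to_years <- function(t, generation_time = 1) t * generation_time
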