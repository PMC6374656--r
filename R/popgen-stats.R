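## Classical diversity and differentiation statistics over allele-frequency
## tables, permutation HWE/LD screens, Nei distances and UPGMA trees.

#' Observed and expected heterozygosity of a group
#'
#' Expected heterozygosity (gene diversity) per locus is
#' `(1 - sum p_i^2) * 2n/(2n - 1)` — the small-sample unbiased estimator —
#' and is averaged over loci with data.  Observed heterozygosity is the
#' fraction of heterozygous non-missing calls per locus, averaged over loci.
#'
#' @param freqs an `allele_freq_table` containing `group`.
#' @param dataset the `genotype_dataset` the frequencies came from.
#' @param group group label.
#' @param grouping the grouping used to build `freqs` (defaults to site).
#' @return named numeric `c(Ho, He)`.
#' @export
heterozygosity <- function(freqs, dataset, group, grouping = dataset$site_of) {
  if (is.null(names(grouping))) names(grouping) <- dataset$individuals
  idx <- which(as.character(grouping[dataset$individuals]) == group)
  if (!length(idx)) stop("no individuals in group ", group)
  he_l <- ho_l <- rep(NA_real_, length(dataset$loci))
  any_data <- FALSE
  for (l in seq_along(dataset$loci)) {
    fr <- freqs$freqs[[group]][[dataset$loci[l]]]
    if (is.null(fr)) next
    any_data <- TRUE
    n2 <- freqs$n[group, l]                      # observed gene copies
    he_l[l] <- (1 - sum(as.numeric(fr)^2)) * n2 / (n2 - 1)
    a1 <- dataset$a1[idx, l]; a2 <- dataset$a2[idx, l]
    ok <- !is.na(a1)
    ho_l[l] <- mean(a1[ok] != a2[ok])
  }
  if (!any_data) stop("group ", group, " has no non-missing calls")
  c(Ho = mean(ho_l, na.rm = TRUE), He = mean(he_l, na.rm = TRUE))
}

#' Inbreeding coefficient
#'
#' @param Ho,He observed and expected heterozygosity.
#' @return `(He - Ho)/He`; `NA` with a warning when `He = 0` (undefined).
#' @export
fis <- function(Ho, He) {
  if (He == 0) { warning("FIS undefined for He = 0"); return(NA_real_) }
  (He - Ho) / He
}

#' Per-group diversity summary
#'
#' @param dataset a `genotype_dataset`.
#' @param grouping grouping vector (defaults to sampling site).
#' @return data.frame with one row per group: `group, n, Ho, He, FIS`, plus
#'   attribute `"per_locus"` holding locus-wise allelic richness (raw allele
#'   counts), He and Ho over the whole dataset.
#' @export
diversity_summary <- function(dataset, grouping = dataset$site_of) {
  freqs <- allele_frequencies(dataset, grouping)
  rows <- lapply(freqs$groups, function(g) {
    h <- heterozygosity(freqs, dataset, g, grouping)
    data.frame(group = g, n = sum(grouping == g),
               Ho = h[["Ho"]], He = h[["He"]],
               FIS = if (h[["He"]] > 0) (h[["He"]] - h[["Ho"]]) / h[["He"]]
                     else NA_real_)
  })
  out <- do.call(rbind, rows)
  all_grp <- stats::setNames(rep("all", length(dataset$individuals)),
                             dataset$individuals)
  gf <- allele_frequencies(dataset, all_grp)
  per_locus <- do.call(rbind, lapply(seq_along(dataset$loci), function(l) {
    fr <- gf$freqs[["all"]][[dataset$loci[l]]]
    if (is.null(fr))
      return(data.frame(locus = dataset$loci[l], richness = 0L,
                        He = NA_real_, Ho = NA_real_))
    n2 <- gf$n["all", l]
    a1 <- dataset$a1[, l]; a2 <- dataset$a2[, l]; ok <- !is.na(a1)
    data.frame(locus = dataset$loci[l], richness = length(fr),
               He = (1 - sum(as.numeric(fr)^2)) * n2 / (n2 - 1),
               Ho = mean(a1[ok] != a2[ok]))
  }))
  attr(out, "per_locus") <- per_locus
  out
}

## uncorrected gene diversity of a frequency vector
gene_diversity <- function(p) 1 - sum(p^2)

## align two named frequency vectors onto the union of their allele names
align_freqs <- function(...) {
  vs <- list(...)
  alleles <- sort(unique(unlist(lapply(vs, names))))
  lapply(vs, function(v) {
    out <- stats::setNames(numeric(length(alleles)), alleles)
    out[names(v)] <- v
    out
  })
}

#' Pairwise FST between two groups (Nei GST-style estimator)
#'
#' Multilocus Nei estimator: per locus, `HS` is the mean within-group gene
#' diversity and `HT` the gene diversity of the pooled mean frequencies;
#' both are averaged over shared loci and `FST = (HT - HS)/HT`, clipped at
#' zero.  When both groups are monomorphic for the same allele (`HT = 0`)
#' the value is defined as 0.
#'
#' @param freqs an `allele_freq_table`.
#' @param pair character vector of two group labels.
#' @return scalar FST in `[0, 1]`.
#' @export
pairwise_fst <- function(freqs, pair) {
  stopifnot(length(pair) == 2L)
  hs <- ht <- c()
  for (l in freqs$loci) {
    f1 <- freqs$freqs[[pair[1L]]][[l]]
    f2 <- freqs$freqs[[pair[2L]]][[l]]
    if (is.null(f1) || is.null(f2)) next
    al <- align_freqs(f1, f2)
    hs <- c(hs, mean(c(gene_diversity(al[[1L]]), gene_diversity(al[[2L]]))))
    ht <- c(ht, gene_diversity((al[[1L]] + al[[2L]]) / 2))
  }
  if (!length(hs)) stop("groups share no typed locus")
  HS <- mean(hs); HT <- mean(ht)
  if (HT == 0) return(0)
  max(0, (HT - HS) / HT)
}

#' All pairwise FST values as a distance matrix
#'
#' @param freqs an `allele_freq_table`.
#' @param linearized if `TRUE`, return Rousset's linearization
#'   `FST/(1 - FST)` used for distance regressions.
#' @return symmetric matrix over groups (class `dist_matrix` with a `kind`
#'   attribute).
#' @export
fst_matrix <- function(freqs, linearized = FALSE) {
  g <- freqs$groups
  m <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    f <- pairwise_fst(freqs, c(g[i], g[j]))
    m[i, j] <- m[j, i] <- if (linearized) f / (1 - f) else f
  }
  dist_matrix(m, if (linearized) "pairwise_fst_linearized" else "pairwise_fst")
}

#' Tag a symmetric matrix as a typed distance matrix
#' @param m symmetric numeric matrix with zero diagonal.
#' @param kind one of `nei_gst_distance`, `pairwise_fst`,
#'   `pairwise_fst_linearized`, `geographic_km`, `barrier_binary`.
#' @return `m` with class `dist_matrix`.
#' @export
dist_matrix <- function(m, kind) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  structure(m, kind = kind, class = c("dist_matrix", class(m)))
}

#' Nei standard genetic distance matrix
#'
#' Nei's 1972-family distance `D = -ln(I)` with the normalized identity
#' `I = sum(x_i y_i) / sqrt(sum(x_i^2) sum(y_i^2))` averaged across loci.
#' Pairs sharing no alleles at any locus get `+Inf`, flagged in the
#' `"infinite_pairs"` attribute.
#'
#' @param freqs an `allele_freq_table` with at least two groups.
#' @return a `dist_matrix` of kind `nei_gst_distance`.
#' @export
nei_distance_matrix <- function(freqs) {
  g <- freqs$groups
  if (length(g) < 2L) stop("need at least two groups")
  m <- matrix(0, length(g), length(g), dimnames = list(g, g))
  inf_pairs <- character()
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    ident <- c()
    for (l in freqs$loci) {
      f1 <- freqs$freqs[[g[i]]][[l]]; f2 <- freqs$freqs[[g[j]]][[l]]
      if (is.null(f1) || is.null(f2)) next
      al <- align_freqs(f1, f2)
      ident <- c(ident, sum(al[[1L]] * al[[2L]]) /
                   sqrt(sum(al[[1L]]^2) * sum(al[[2L]]^2)))
    }
    I <- mean(ident)
    d <- if (I <= 0) Inf else -log(I)
    if (!is.finite(d)) inf_pairs <- c(inf_pairs, paste(g[i], g[j], sep = "|"))
    m[i, j] <- m[j, i] <- d
  }
  out <- dist_matrix(m, "nei_gst_distance")
  attr(out, "infinite_pairs") <- inf_pairs
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with node height equal to half the merge
#' distance, so the tree is ultrametric in the input distance units.  Ties
#' are broken by the lexicographically lowest index pair, making the output
#' deterministic.
#'
#' @param d a symmetric distance matrix (matrix or `dist_matrix`) with
#'   finite entries.
#' @return list with `phylo` (an [ape::read.tree()] tree), `newick` string,
#'   `merge_heights` (heights of internal nodes in merge order).
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (any(!is.finite(m))) stop("distance matrix contains NaN/Inf entries")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  n <- nrow(m)
  if (n < 2L) stop("need at least two taxa")
  active <- seq_len(n)
  sizes <- rep(1L, n)
  node_newick <- labels
  node_height <- rep(0, n)
  heights <- numeric(0)
  D <- m
  repeat {
    k <- length(active)
    if (k == 1L) break
    ## lowest-index pair among minima (row-major over the active submatrix)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      dij <- D[active[i], active[j]]
      if (dij < bestd - 1e-15) { bestd <- dij; best <- c(i, j) }
    }
    a <- active[best[1L]]; b <- active[best[2L]]
    h <- bestd / 2
    heights <- c(heights, h)
    new_nw <- sprintf("(%s:%.10g,%s:%.10g)",
                      node_newick[a], h - node_height[a],
                      node_newick[b], h - node_height[b])
    ## average-linkage update into slot a
    for (x in active) {
      if (x == a || x == b) next
      D[a, x] <- D[x, a] <-
        (sizes[a] * D[a, x] + sizes[b] * D[b, x]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    node_newick[a] <- new_nw
    node_height[a] <- h
    active <- setdiff(active, b)
  }
  newick <- paste0(node_newick[active], ";")
  list(phylo = ape::read.tree(text = newick), newick = newick,
       merge_heights = heights)
}

## ---------------------------------------------------------------------------
## Permutation HWE / LD screens

## alleles and heterozygosity statistic for one group x locus
group_locus_alleles <- function(dataset, group, locus, grouping) {
  if (is.null(names(grouping))) names(grouping) <- dataset$individuals
  idx <- which(as.character(grouping[dataset$individuals]) == group)
  l <- match(locus, dataset$loci)
  a1 <- dataset$a1[idx, l]; a2 <- dataset$a2[idx, l]
  ok <- !is.na(a1)
  list(a1 = a1[ok], a2 = a2[ok])
}

#' Permutation test for Hardy-Weinberg equilibrium at one locus
#'
#' The statistic is `|Ho - He|` in the group; the null is generated by
#' re-pairing the observed allele pool at random among individuals (which
#' holds He fixed), and the p-value is `(1 + #{perm >= obs}) / (1 + n_perm)`
#' (one-sided).  Monomorphic loci return 1 by convention.
#'
#' @param dataset a `genotype_dataset`.
#' @param group group label; @param locus locus name.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param grouping grouping vector (defaults to site).
#' @return p-value.
#' @export
hwe_test <- function(dataset, group, locus, n_perm = 999L, seed = 1L,
                     grouping = dataset$site_of) {
  al <- group_locus_alleles(dataset, group, locus, grouping)
  n <- length(al$a1)
  if (n < 5L) stop("need >= 5 non-missing individuals")
  pool <- c(al$a1, al$a2)
  if (length(unique(pool)) < 2L) return(1)
  he <- gene_diversity(as.numeric(table(pool)) / length(pool))
  obs <- abs(mean(al$a1 != al$a2) - he)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    ho_p <- mean(perm[seq_len(n)] != perm[n + seq_len(n)])
    if (abs(ho_p - he) >= obs - 1e-12) ge <- ge + 1L
  }
  (1 + ge) / (1 + n_perm)
}

## G statistic of a two-way contingency table (0 log 0 = 0)
g_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

#' Permutation test for linkage disequilibrium between two loci
#'
#' The statistic is the G-statistic of the two-locus genotype contingency
#' table; the null shuffles one locus's genotypes among individuals,
#' breaking any association while preserving both single-locus genotype
#' distributions.
#'
#' @inheritParams hwe_test
#' @param locus_pair character vector of two locus names.
#' @return p-value; 1 when either locus has a single genotype.
#' @export
ld_test <- function(dataset, group, locus_pair, n_perm = 999L, seed = 1L,
                    grouping = dataset$site_of) {
  stopifnot(length(locus_pair) == 2L)
  if (is.null(names(grouping))) names(grouping) <- dataset$individuals
  idx <- which(as.character(grouping[dataset$individuals]) == group)
  l1 <- match(locus_pair[1L], dataset$loci)
  l2 <- match(locus_pair[2L], dataset$loci)
  g1 <- paste(pmin(dataset$a1[idx, l1], dataset$a2[idx, l1]),
              pmax(dataset$a1[idx, l1], dataset$a2[idx, l1]))
  g2 <- paste(pmin(dataset$a1[idx, l2], dataset$a2[idx, l2]),
              pmax(dataset$a1[idx, l2], dataset$a2[idx, l2]))
  ok <- !is.na(dataset$a1[idx, l1]) & !is.na(dataset$a1[idx, l2])
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L) return(1)
  obs <- g_statistic(table(g1, g2))
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (g_statistic(table(g1, sample(g2))) >= obs - 1e-12) ge <- ge + 1L
  }
  (1 + ge) / (1 + n_perm)
}

#' Garza-Williamson M ratio
#'
#' `M = k/(r + 1)` with `k` the number of distinct alleles and `r` the
#' allele-size range in repeat units; values near 1 indicate a full allele
#' ladder, low values signal bottlenecks.
#'
#' @param alleles integer vector of observed allele sizes (repeat units).
#' @return scalar M in `(0, 1]`.
#' @export
garza_williamson_m <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) stop("no observed alleles")
  u <- unique(alleles)
  length(u) / (max(u) - min(u) + 1)
}
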