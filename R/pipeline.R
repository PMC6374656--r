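## End-to-end orchestration of the analysis workflow on synthetic or user
## data, with file-based stage outputs and a serialized run configuration.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_perm permutations for the spatial tests.
#' @param k_max largest K for the K-means scan.
#' @param abc_n_sims,abc_tolerance ABC settings.
#' @param sdm settings list (`n_background`, `K`, `vif`).
#' @param fixture settings list passed to [gen_hierarchical_genotypes()]
#'   via [default_fixture()]-like shapes; `NULL` uses the default fixture.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, n_perm = 199L, k_max = 15L,
                       abc_n_sims = 20000L, abc_tolerance = 0.01,
                       sdm = list(n_background = 400L, K = 4L, vif = 10),
                       fixture = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), k_max = as.integer(k_max),
                 abc_n_sims = as.integer(abc_n_sims),
                 abc_tolerance = abc_tolerance, sdm = sdm,
                 fixture = fixture),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, on a synthetic fixture with known truth (or user inputs wired
#' through the per-stage functions): diversity statistics and a UPGMA tree;
#' PCA, K-means/BIC clustering, majority merging and DAPC; Mantel tests,
#' sPCA and RDA variance partitioning; a two-population ABC divergence-time
#' estimate; and the ensemble species distribution model.  Every stage
#' writes CSV/Newick/grid outputs plus a run log carrying the
#' configuration and seeds, and any stage failure aborts with the stage
#' name while retaining earlier outputs.
#'
#' @param config a [run_config()].
#' @return named list of the per-stage results, invisibly; outputs under
#'   `config$out_dir`.
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat(sprintf("landgen run\nseed: %d\nn_perm: %d\nstarted: %s\n",
              config$seed, config$n_perm, format(Sys.time())),
      file = log_path)
  stage <- function(name, expr) {
    cat(sprintf("stage %s: start\n", name), file = log_path, append = TRUE)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    cat(sprintf("stage %s: done\n", name), file = log_path, append = TRUE)
    res
  }
  out <- list()

  fx <- stage("synthetic_data", {
    if (is.null(config$fixture)) {
      ibd <- gen_ibd_sites(20L, cline_strength = 0.6,
                           seed = config$seed, inds_per_site = 15L,
                           n_loci = 6L)
      gen_barrier_effect(ibd, extra_fst = 0.05, seed = config$seed + 1L)
    } else config$fixture
  })
  write_genepop(fx$dataset, file.path(config$out_dir, "genotypes.gen"))
  utils::write.csv(as.data.frame(fx$sites),
                   file.path(config$out_dir, "sites.csv"), row.names = FALSE)
  out$fixture <- fx

  out$stats <- stage("popgen_stats", {
    div <- diversity_summary(fx$dataset)
    utils::write.csv(div, file.path(config$out_dir, "diversity.csv"),
                     row.names = FALSE)
    freqs <- allele_frequencies(fx$dataset)
    nei <- nei_distance_matrix(freqs)
    tree <- upgma(nei)
    writeLines(tree$newick, file.path(config$out_dir, "upgma.nwk"))
    fstm <- fst_matrix(freqs, linearized = TRUE)
    utils::write.csv(as.data.frame(unclass(fstm)),
                     file.path(config$out_dir, "linearized_fst.csv"))
    list(diversity = div, nei = nei, tree = tree, fst_lin = fstm,
         freqs = freqs)
  })

  out$clustering <- stage("clustering", {
    dosage <- individual_dosage_matrix(fx$dataset)
    pca <- pca_genotypes(dosage, variance_target = 0.95)
    ks <- kmeans_bic_scan(pca$scores,
                          seq_len(min(config$k_max,
                                      nrow(pca$scores) - 1L)),
                          seed = config$seed)
    mm <- majority_merge(ks$assignment, fx$dataset$site_of)
    n_pcs <- min(20L, ncol(pca$scores))
    dapc <- dapc_fit(dosage, mm$assignment, n_pcs)
    utils::write.csv(data.frame(K = names(ks$bic), BIC = ks$bic),
                     file.path(config$out_dir, "bic_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(individual = names(mm$assignment),
                                population = mm$assignment),
                     file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(dapc$Q, file.path(config$out_dir, "qmatrix.csv"))
    list(kscan = ks, merged = mm, dapc = dapc,
         summary = assignment_summary(dapc$Q, site_of = fx$dataset$site_of,
                                      site_population = mm$site_population))
  })

  out$spatial <- stage("spatial_structure", {
    if (config$n_perm < 1L) stop("n_perm must be >= 1")
    dgeo <- geographic_distance_matrix(fx$sites)
    dbar <- barrier_matrix(fx$sites)
    flin <- out$stats$fst_lin
    mt <- mantel(flin, dgeo, n_perm = config$n_perm, seed = config$seed)
    pm <- partial_mantel(flin, dbar, dgeo, n_perm = config$n_perm,
                         seed = config$seed)
    net <- connection_network(fx$sites)
    sfm <- site_frequency_matrix(out$stats$freqs)
    sp <- spca(sfm, net)
    gl <- spca_monte_carlo(sfm, net, "global", n_perm = config$n_perm,
                           seed = config$seed)
    factors <- list(
      river = as.integer(fx$sites$river_side ==
                           fx$sites$river_side[1L]),
      basin = fx$sites$basin,
      landuse = as.matrix(fx$sites[, landuse_classes()])[, -1L])
    vp <- variance_partition(sp$scores, factors,
                             coords = fx$sites[, c("lon", "lat")],
                             n_perm = config$n_perm, seed = config$seed)
    utils::write.csv(vp, file.path(config$out_dir, "variance_partition.csv"),
                     row.names = FALSE)
    list(mantel = mt, partial_mantel = pm, spca = sp, spca_global = gl,
         partition = vp)
  })

  out$abc <- stage("abc_coalescence", {
    truth <- two_pop_model(t = 5000, N = 2000)
    obs <- gen_abc_observed(truth, sample_sizes = 15L, n_loci = 8L,
                            mutation_rates = 5e-4, seed = config$seed)
    post <- abc_rejection(obs$beaumont, two_pop_model(1, 1000),
                          sample_sizes = 15L, n_loci = 8L,
                          n_sims = config$abc_n_sims,
                          tolerance = config$abc_tolerance,
                          seed = config$seed, stats = "beaumont",
                          shared_N = TRUE)
    utils::write.csv(post$summary,
                     file.path(config$out_dir, "abc_posterior.csv"),
                     row.names = FALSE)
    post
  })

  out$sdm <- stage("sdm_ensemble", {
    cs <- gen_climate_stack(seed = config$seed)
    occ <- gen_occurrences(cs$stack, beta = c(bio1 = 2, bio2 = -1.5),
                           n_presence = 150L, seed = config$seed)
    bg <- sample_background(cs$stack, n = config$sdm$n_background,
                            seed = config$seed)
    ens <- fit_sdm_ensemble(cs$stack, occ$presences, bg,
                            K = config$sdm$K,
                            vif_threshold = config$sdm$vif,
                            seed = config$seed)
    utils::write.csv(ens$components,
                     file.path(config$out_dir, "sdm_components.csv"),
                     row.names = FALSE)
    suit_stack <- climate_stack(list(suitability = ens$suitability),
                                cs$stack$lon, cs$stack$lat)
    write_esri_ascii(suit_stack, "suitability",
                     file.path(config$out_dir, "suitability.asc"))
    ens
  })

  cat(sprintf("finished: %s\n", format(Sys.time())), file = log_path,
      append = TRUE)
  invisible(out)
}

#' Site-by-allele frequency matrix for sPCA
#'
#' Flattens an `allele_freq_table` into a sites x (locus, allele) numeric
#' matrix with zero for unobserved alleles — the response for spatial PCA.
#'
#' @param freqs an `allele_freq_table` grouped by site.
#' @return numeric matrix.
#' @export
site_frequency_matrix <- function(freqs) {
  cols <- list()
  for (l in freqs$loci) {
    alleles <- sort(unique(unlist(lapply(freqs$groups, function(g)
      names(freqs$freqs[[g]][[l]])))))
    if (!length(alleles)) next
    m <- matrix(0, length(freqs$groups), length(alleles),
                dimnames = list(freqs$groups, paste(l, alleles, sep = ".")))
    for (g in freqs$groups) {
      fr <- freqs$freqs[[g]][[l]]
      if (!is.null(fr)) m[g, paste(l, names(fr), sep = ".")] <- as.numeric(fr)
    }
    cols[[l]] <- m
  }
  do.call(cbind, cols)
}
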