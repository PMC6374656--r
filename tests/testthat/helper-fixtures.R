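# Small fixtures built in code and shared across test files.

# tiny two-site dataset with known genotypes and one missing call
tiny_dataset <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  a1 <- matrix(c(100L, 100L, 102L, 104L,
                 100L, 102L, NA, NA), 4, 2)
  a2 <- matrix(c(102L, 100L, 104L, 104L,
                 104L, 104L, NA, NA), 4, 2)
  genotype_dataset(ids, c("L1", "L2"), a1, a2,
                   stats::setNames(c("s1", "s1", "s2", "s2"), ids))
}

# site table of n sites at given coordinates, no landscape structure
flat_site_table <- function(lon, lat, river_side = "E", basin = "b1") {
  n <- length(lon)
  as_site_table(data.frame(
    site_id = sprintf("s%02d", seq_len(n)), lon = lon, lat = lat,
    basin = rep_len(basin, n), river_side = rep_len(river_side, n),
    water = 0.2, urban = 0.1, forest = 0.3, scrub = 0.15, agri = 0.15,
    wetland = 0.1))
}

# random symmetric zero-diagonal matrix
rand_sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

# dataset with one group whose genotypes are given as a list of c(a, b)
one_group_dataset <- function(calls, locus = "L1") {
  n <- length(calls)
  ids <- paste0("i", seq_len(n))
  a1 <- matrix(vapply(calls, `[`, integer(1), 1L), n, 1)
  a2 <- matrix(vapply(calls, `[`, integer(1), 2L), n, 1)
  genotype_dataset(ids, locus, a1, a2,
                   stats::setNames(rep("g", n), ids))
}
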