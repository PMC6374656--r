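#' Construct a multi-population microsatellite genotype dataset
#'
#' The central container of the package: diploid allele-size calls (in
#' repeat-unit scale) for a set of individuals at a set of loci, together
#' with the sampling site each individual belongs to.  Missing calls are
#' encoded as `NA` in both allele matrices.
#'
#' @param individuals character vector of unique individual IDs.
#' @param loci character vector of unique locus names.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   sizes of each call.  A missing call has `NA` in both matrices; a
#'   non-missing call must have two positive integers.
#' @param site_of character vector, one site ID per individual (named by
#'   individual ID or in the same order as `individuals`).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(individuals, loci, a1, a2, site_of) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (is.null(names(site_of))) names(site_of) <- individuals
  site_of <- as.character(site_of[individuals])
  names(site_of) <- individuals
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  obj <- structure(
    list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
         site_of = site_of),
    class = "genotype_dataset")
  validate_genotype_dataset(obj)
  obj
}

#' Validate a genotype dataset's invariants
#'
#' Checks ID uniqueness, matrix shapes, positivity of allele sizes, and the
#' pairing of missing markers (a call is either fully present or fully
#' missing).
#'
#' @param x a `genotype_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (anyDuplicated(x$individuals)) stop("duplicate individual IDs")
  if (anyDuplicated(x$loci)) stop("duplicate locus names")
  n <- length(x$individuals); L <- length(x$loci)
  if (!all(dim(x$a1) == c(n, L)) || !all(dim(x$a2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  if (!identical(is.na(x$a1), is.na(x$a2)))
    stop("half-missing calls: both alleles of a call must be present or missing")
  ok <- is.na(x$a1) | (x$a1 > 0L & x$a2 > 0L)
  if (!all(ok)) stop("allele sizes must be positive integers")
  if (length(x$site_of) != n || any(is.na(x$site_of)))
    stop("every individual must map to exactly one site")
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d sites (%.1f%% missing)\n",
              length(x$individuals), length(x$loci),
              length(unique(x$site_of)), 100 * miss))
  invisible(x)
}

#' Number of sites in a genotype dataset
#' @param x a `genotype_dataset`.
#' @return character vector of site IDs in order of first appearance.
#' @export
dataset_sites <- function(x) unique(x$site_of)

## ---------------------------------------------------------------------------
## GENEPOP I/O

#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), and `POP`-delimited blocks of
#' `id , 001002 003003 ...` sample rows.  Both 2- and 3-digit allele coding
#' are accepted and autodetected per locus from the code width; `00`/`000`
#' codes mark missing alleles.  Each `POP` block becomes one sampling site
#' (named `pop_1`, `pop_2`, ... unless individual IDs carry a shared prefix).
#'
#' @param path path to a GENEPOP text file.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  body <- lines[-1L]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP line found")
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in header")
  L <- length(loci)

  ids <- character(); sites <- character()
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L; pop_count <- 0L
  for (k in seq(first_pop, length(body))) {
    ln <- body[k]
    if (is_pop[k]) {
      if (pop_i > 0L && pop_count == 0L)
        stop(sprintf("empty POP block ending before line %d", k + 1L))
      pop_i <- pop_i + 1L; pop_count <- 0L
      next
    }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop(sprintf("malformed sample row at line %d: no comma separator", k + 1L))
    id <- trimws(parts[1L])
    calls <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    calls <- calls[nzchar(calls)]
    if (length(calls) != L)
      stop(sprintf("line %d: expected %d locus calls, found %d",
                   k + 1L, L, length(calls)))
    al <- genepop_decode(calls, k + 1L)
    pop_count <- pop_count + 1L
    ids <- c(ids, id); sites <- c(sites, paste0("pop_", pop_i))
    rows1[[length(rows1) + 1L]] <- al[1L, ]
    rows2[[length(rows2) + 1L]] <- al[2L, ]
  }
  if (pop_count == 0L) stop("empty POP block at end of file")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  genotype_dataset(ids, loci, a1, a2, stats::setNames(sites, ids))
}

## decode a vector of GENEPOP genotype codes into a 2 x L matrix of alleles
genepop_decode <- function(calls, line_no) {
  w <- nchar(calls)
  if (!all(w %in% c(4L, 6L)))
    stop(sprintf("line %d: genotype codes must be 4 or 6 digits wide", line_no))
  half <- w %/% 2L
  a1 <- as.integer(substr(calls, 1L, half))
  a2 <- as.integer(substr(calls, half + 1L, w))
  if (anyNA(a1) || anyNA(a2))
    stop(sprintf("line %d: non-numeric genotype code", line_no))
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  both_na <- is.na(a1) & is.na(a2)
  if (any(xor(is.na(a1), is.na(a2))))
    stop(sprintf("line %d: half-missing genotype code", line_no))
  rbind(a1, a2)
}

#' Write a genotype dataset as a GENEPOP file
#'
#' Always writes 3-digit allele codes (lossless for repeat-unit sizes below
#' 1000) with `000000` for missing calls, one `POP` block per site in order
#' of first appearance.
#'
#' @param x a `genotype_dataset`.
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "landgen export") {
  validate_genotype_dataset(x)
  if (any(x$a1 > 999L | x$a2 > 999L, na.rm = TRUE))
    stop("allele size > 999 cannot be written in 3-digit GENEPOP coding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (s in dataset_sites(x)) {
    writeLines("POP", con)
    for (i in which(x$site_of == s)) {
      a1 <- x$a1[i, ]; a2 <- x$a2[i, ]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      writeLines(sprintf("%s ,  %s", x$individuals[i],
                         paste0(sprintf("%03d%03d", a1, a2), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Site tables

#' Read and validate a site table
#'
#' A site table holds one row per sampling site: coordinates in decimal
#' degrees, a basin label (HUC-6 analogue), a river-side flag (`E`/`W` or
#' 0/1), and six land-use proportions (open water, urban, forest,
#' scrub/grassland, agriculture, wetlands) that must sum to one.
#'
#' @param path CSV file with columns `site_id, lon, lat, basin, river_side,
#'   water, urban, forest, scrub, agri, wetland`.
#' @return a data.frame of class `site_table`.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_site_table(df)
}

#' Coerce a data.frame to a validated site table
#' @param df data.frame with the columns documented in [read_site_table()].
#' @return `df` with class `site_table` prepended.
#' @export
as_site_table <- function(df) {
  req <- c("site_id", "lon", "lat", "basin", "river_side",
           landuse_classes())
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in site table")
  lu <- as.matrix(df[, landuse_classes()])
  if (any(lu < 0 | lu > 1)) stop("land-use proportions must lie in [0, 1]")
  if (any(abs(rowSums(lu) - 1) > 1e-9))
    stop("land-use proportions must sum to 1 per site")
  df$site_id <- as.character(df$site_id)
  class(df) <- c("site_table", "data.frame")
  df
}

#' The six land-use classes carried by a site table
#' @return character vector of column names.
#' @export
landuse_classes <- function()
  c("water", "urban", "forest", "scrub", "agri", "wetland")

#' Check that a site table covers a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param sites a `site_table`.
#' @return `TRUE` invisibly; errors if any sampled site is absent.
#' @export
check_site_coverage <- function(dataset, sites) {
  missing_sites <- setdiff(dataset_sites(dataset), sites$site_id)
  if (length(missing_sites))
    stop("sites sampled but absent from site table: ",
         paste(missing_sites, collapse = ", "))
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Allele frequencies and dosage matrices

#' Per-group allele frequencies
#'
#' Tallies observed alleles per group per locus; missing calls are excluded
#' from the denominators.  A group with no observed alleles at a locus is
#' flagged absent (`NULL` frequency vector, zero sample size) rather than
#' producing a zero-length division.
#'
#' @param dataset a `genotype_dataset`.
#' @param grouping character vector assigning every individual to a group
#'   (named by individual or in dataset order).  Defaults to sampling site.
#' @return an `allele_freq_table`: list with `groups`, `loci`, `freqs`
#'   (freqs[[group]][[locus]] = named frequency vector over observed allele
#'   sizes), and `n` (group x locus matrix of observed gene copies).
#' @export
allele_frequencies <- function(dataset, grouping = dataset$site_of) {
  if (is.null(names(grouping))) names(grouping) <- dataset$individuals
  grouping <- as.character(grouping[dataset$individuals])
  if (anyNA(grouping)) stop("grouping must assign every individual")
  groups <- unique(grouping)
  loci <- dataset$loci
  n <- matrix(0L, length(groups), length(loci),
              dimnames = list(groups, loci))
  freqs <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    idx <- which(grouping == g)
    fg <- stats::setNames(vector("list", length(loci)), loci)
    for (l in seq_along(loci)) {
      al <- c(dataset$a1[idx, l], dataset$a2[idx, l])
      al <- al[!is.na(al)]
      if (length(al) == 0L) { fg[[l]] <- NULL; next }
      tab <- table(al)
      fg[[loci[l]]] <- stats::setNames(as.numeric(tab) / length(al),
                                       names(tab))
      n[g, l] <- length(al)
    }
    freqs[[g]] <- fg
  }
  structure(list(groups = groups, loci = loci, freqs = freqs, n = n),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d groups x %d loci\n",
              length(x$groups), length(x$loci)))
  invisible(x)
}

#' Individual-by-allele dosage matrix
#'
#' Expands genotypes into one column per (locus, allele) combination holding
#' the allele count 0/1/2 of each individual — the substrate for PCA, DAPC
#' and sPCA.  Missing calls are imputed with twice the dataset-wide allele
#' frequency (`mean_frequency`, the multivariate-toolchain convention) or
#' with zero.
#'
#' @param dataset a `genotype_dataset`.
#' @param impute `"mean_frequency"` or `"zero"`.
#' @return numeric matrix, individuals x allele columns, column names
#'   `locus.allele`.
#' @export
individual_dosage_matrix <- function(dataset,
                                     impute = c("mean_frequency", "zero")) {
  impute <- match.arg(impute)
  global <- allele_frequencies(
    dataset, stats::setNames(rep("all", length(dataset$individuals)),
                             dataset$individuals))
  blocks <- vector("list", length(dataset$loci))
  for (l in seq_along(dataset$loci)) {
    fr <- global$freqs[["all"]][[dataset$loci[l]]]
    if (is.null(fr)) { blocks[[l]] <- NULL; next }
    alleles <- as.integer(names(fr))
    m <- matrix(0, length(dataset$individuals), length(alleles))
    a1 <- dataset$a1[, l]; a2 <- dataset$a2[, l]
    for (j in seq_along(alleles)) {
      m[, j] <- (a1 == alleles[j]) + (a2 == alleles[j])
    }
    na_row <- is.na(a1)
    if (any(na_row)) {
      fill <- if (impute == "mean_frequency") 2 * as.numeric(fr) else
        rep(0, length(alleles))
      m[na_row, ] <- matrix(fill, sum(na_row), length(alleles), byrow = TRUE)
    }
    colnames(m) <- paste(dataset$loci[l], alleles, sep = ".")
    blocks[[l]] <- m
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- dataset$individuals
  out
}

#' Subset a genotype dataset by individuals
#' @param x a `genotype_dataset`.
#' @param keep logical or index vector over individuals.
#' @return a `genotype_dataset` restricted to `keep`.
#' @export
subset_individuals <- function(x, keep) {
  idx <- seq_along(x$individuals)[keep]
  genotype_dataset(x$individuals[idx], x$loci,
                   x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE],
                   x$site_of[idx])
}
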