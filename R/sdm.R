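## Ensemble species distribution modelling: occurrence cleaning, background
## sampling, VIF pruning, BIC-averaged logistic regression, BIOCLIM and
## Mahalanobis component models, k-fold AUC validation, (AUC-0.5)^2
## weighting, weighted-average suitability, range thresholding, and
## projection onto alternative climate stacks.

#' Construct a climate stack
#'
#' Co-registered gridded environmental variables on a shared lon/lat grid.
#' Layers are matrices indexed `[lat, lon]` with `NA` as nodata; the nodata
#' mask must be consistent across layers.
#'
#' @param layers named list of numeric matrices (rows = latitudes, columns =
#'   longitudes).
#' @param lon,lat vectors of cell-centre coordinates (lat descending or
#'   ascending, but consistent with the matrices).
#' @return a `climate_stack`.
#' @export
climate_stack <- function(layers, lon, lat) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != length(lat)) || any(dims[2, ] != length(lon)))
    stop("all layers must be lat x lon matrices matching the coordinates")
  mask <- is.na(layers[[1L]])
  for (l in layers) if (!identical(is.na(l), mask))
    stop("nodata mask differs across layers")
  structure(list(layers = layers, lon = as.numeric(lon),
                 lat = as.numeric(lat)),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d layers on a %d x %d grid (%s)\n",
              length(x$layers), length(x$lat), length(x$lon),
              paste(utils::head(names(x$layers), 5), collapse = ", ")))
  invisible(x)
}

#' Read an ESRI ASCII grid as a one-layer climate stack
#'
#' Parses the plain-text `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows from north to south.
#'
#' @param path path to an `.asc` file.
#' @param name layer name.
#' @return a `climate_stack` with one layer.
#' @export
read_esri_ascii <- function(path, name = "layer") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + cs * (seq_len(nc) - 0.5)
  lat <- hdr$yllcorner + cs * (nr - seq_len(nr) + 0.5)  # row 1 = north
  cl <- stats::setNames(list(m), name)
  climate_stack(cl, lon, lat)
}

#' Write one layer of a climate stack as an ESRI ASCII grid
#'
#' @param stack a `climate_stack`.
#' @param layer layer name; @param path output path.
#' @param nodata nodata code written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(stack, layer, path, nodata = -9999) {
  m <- stack$layers[[layer]]
  if (is.null(m)) stop("no layer named ", layer)
  cs <- abs(diff(stack$lon[1:2]))
  north_first <- stack$lat[1L] > stack$lat[length(stack$lat)]
  if (!north_first) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", min(stack$lon) - cs / 2),
               sprintf("yllcorner %.10g", min(stack$lat) - cs / 2),
               sprintf("cellsize %.10g", cs),
               sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## nearest-cell indices of lon/lat points; NA when off-grid
nearest_cells <- function(stack, points) {
  lon_i <- vapply(points[, 1L], function(x) which.min(abs(stack$lon - x)),
                  integer(1))
  lat_i <- vapply(points[, 2L], function(y) which.min(abs(stack$lat - y)),
                  integer(1))
  csx <- max(abs(diff(stack$lon))); csy <- max(abs(diff(stack$lat)))
  off <- abs(stack$lon[lon_i] - points[, 1L]) > csx / 2 + 1e-9 |
    abs(stack$lat[lat_i] - points[, 2L]) > csy / 2 + 1e-9
  cbind(lat = ifelse(off, NA_integer_, lat_i),
        lon = ifelse(off, NA_integer_, lon_i))
}

#' Clean occurrence records
#'
#' Drops records flagged as fossil or captive, exact-coordinate duplicates,
#' and records falling inside excluded polygons.
#'
#' @param records data.frame with `lon`, `lat` and optional logical
#'   `fossil`, `captive` columns.
#' @param excluded_regions list of polygons (two-column lon/lat matrices),
#'   may be empty.
#' @param dedupe drop exact-coordinate duplicates (first record kept).
#' @return data.frame of retained presence points (`lon`, `lat`).
#' @export
clean_occurrences <- function(records, excluded_regions = list(),
                              dedupe = TRUE) {
  keep <- rep(TRUE, nrow(records))
  for (fl in c("fossil", "captive"))
    if (fl %in% names(records)) keep <- keep & !isTRUE_vec(records[[fl]])
  for (poly in excluded_regions)
    keep <- keep & !point_in_polygon(records$lon, records$lat, poly)
  out <- records[keep, c("lon", "lat"), drop = FALSE]
  if (dedupe) out <- out[!duplicated(out[, c("lon", "lat")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(v) !is.na(v) & as.logical(v)

## even-odd ray casting; boundary points count as inside
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1L]; py <- poly[, 2L]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Sample background points uniformly over valid cells
#'
#' @param stack a `climate_stack`; cells with nodata are never sampled.
#' @param n number of background points.
#' @param seed RNG seed.
#' @return data.frame of cell-centre `lon`, `lat`.
#' @export
sample_background <- function(stack, n = 800L, seed = 1L) {
  if (n == 0L) return(data.frame(lon = numeric(), lat = numeric()))
  valid <- which(!is.na(stack$layers[[1L]]))
  set.seed(seed)
  cells <- sample(valid, n, replace = n > length(valid))
  nr <- length(stack$lat)
  lat_i <- (cells - 1L) %% nr + 1L
  lon_i <- (cells - 1L) %/% nr + 1L
  data.frame(lon = stack$lon[lon_i], lat = stack$lat[lat_i])
}

#' Extract climate values at points
#'
#' Nearest-cell lookup; rows with any nodata (or off-grid points) are
#' dropped, with the count recorded in the `"n_dropped"` attribute.
#'
#' @param stack a `climate_stack`.
#' @param points data.frame/matrix with lon, lat in the first two columns.
#' @return numeric matrix, one column per layer (in stack order), with the
#'   retained row indices in attribute `"rows"`.
#' @export
extract_values <- function(stack, points) {
  pts <- as.matrix(points[, 1:2])
  idx <- nearest_cells(stack, pts)
  X <- sapply(stack$layers, function(l) l[idx])
  if (!is.matrix(X)) X <- matrix(X, ncol = length(stack$layers),
                                 dimnames = list(NULL, names(stack$layers)))
  ok <- stats::complete.cases(X) & !is.na(idx[, 1L])
  out <- X[ok, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "rows") <- which(ok)
  out
}

#' Iterative VIF pruning of collinear predictors
#'
#' Computes the variance inflation factor `1/(1 - R^2)` of each variable
#' regressed on the others and removes the largest until all fall below the
#' threshold.  Perfectly collinear variables (infinite VIF) are removed
#' first.
#'
#' @param X numeric design matrix with column names.
#' @param threshold VIF threshold (default 10).
#' @return character vector of retained column names.
#' @export
vif_prune <- function(X, threshold = 10) {
  X <- as.matrix(X)
  vars <- colnames(X)
  repeat {
    if (length(vars) < 2L) break
    vifs <- vapply(vars, function(v) {
      ## perfect fits are expected here (that is what VIF screens for), so
      ## summary.lm's perfect-fit warning is noise
      r2 <- suppressWarnings(summary(
        stats::lm(X[, v] ~ X[, setdiff(vars, v), drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) < threshold) break
    vars <- setdiff(vars, names(which.max(vifs)))
  }
  vars
}

#' BIC-averaged binomial logistic regression
#'
#' Fits all non-empty variable subsets by maximum-likelihood logistic
#' regression, keeps those within `delta` BIC of the minimum (the
#' standard "models with delta-BIC < 2 are averaged" convention), and
#' predicts with the unweighted mean of member-model probabilities.  A fit
#' with complete separation is replaced by a ridge-penalised refit, with a
#' warning.
#'
#' @param X numeric predictor matrix (at most 12 columns).
#' @param y binary response (presence = 1, background = 0).
#' @param delta BIC window (default 2).
#' @return a `glm_bic_model`: list with `members` (fitted glms), `subsets`,
#'   `bic`, `delta`.
#' @export
glm_bic_average <- function(X, y, delta = 2) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 12L) stop("more than 12 predictors: prune first (enumeration guard)")
  df <- data.frame(y = y, X)
  vars <- colnames(df)[-1L]
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
  fits <- vector("list", length(subsets))
  bic <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    fo <- stats::reformulate(subsets[[i]], "y")
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fo, data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep) {
      warning("separation in subset {", paste(subsets[[i]], collapse = ","),
              "}; ridge-penalised refit used")
      fit <- ridge_logistic(df[, subsets[[i]], drop = FALSE], y)
    }
    fits[[i]] <- fit
    bic[i] <- if (inherits(fit, "glm")) stats::BIC(fit) else fit$bic
  }
  keep <- which(bic - min(bic) < delta)
  structure(list(members = fits[keep], subsets = subsets[keep],
                 bic = bic[keep], all_bic = bic, delta = delta),
            class = "glm_bic_model")
}

## minimal ridge-penalised logistic fit by IRLS with an L2 penalty
ridge_logistic <- function(X, y, lambda = 1e-2) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    pen <- diag(lambda, ncol(X)); pen[1L, 1L] <- 0
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-8) { beta <- drop(new); break }
    beta <- drop(new)
  }
  ll <- sum(y * log(pmax(stats::plogis(X %*% beta), 1e-12)) +
              (1 - y) * log(pmax(1 - stats::plogis(X %*% beta), 1e-12)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 bic = -2 * ll + ncol(X) * log(length(y))),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, names(object$coefficients)[-1L],
                                  drop = FALSE]))
  drop(stats::plogis(X %*% object$coefficients))
}

#' Predict averaged probability from a BIC-averaged logistic model
#' @param object a `glm_bic_model`.
#' @param newdata data.frame/matrix with the predictor columns.
#' @param ... unused.
#' @return vector of averaged presence probabilities.
#' @export
predict.glm_bic_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  preds <- vapply(object$members, function(m) {
    if (inherits(m, "glm")) stats::predict(m, nd, type = "response")
    else predict(m, nd)
  }, numeric(nrow(nd)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' BIOCLIM climate-envelope model
#'
#' Per variable, a point scores the two-tailed percentile of its value
#' among the presence values, `2 * min(p, 1 - p)` (1 at the presence
#' median, 0 outside the presence range); the prediction is the minimum
#' score over variables, the classic envelope convention.
#'
#' @param X_presence presence design matrix.
#' @return a `bioclim_model`.
#' @export
bioclim_fit <- function(X_presence) {
  structure(list(presence = as.matrix(X_presence)), class = "bioclim_model")
}

#' @export
predict.bioclim_model <- function(object, newdata, ...) {
  P <- object$presence
  X <- as.matrix(newdata)[, colnames(P), drop = FALSE]
  n <- nrow(P)
  scores <- matrix(NA_real_, nrow(X), ncol(P))
  for (j in seq_len(ncol(P))) {
    v <- P[, j]
    p <- (colSums(outer(v, X[, j], "<")) +
            colSums(outer(v, X[, j], "<="))) / (2 * n)  # midrank percentile
    s <- 2 * pmin(p, 1 - p)
    s[X[, j] < min(v) | X[, j] > max(v)] <- 0
    scores[, j] <- s
  }
  apply(scores, 1, min)
}

#' Mahalanobis-distance suitability model
#'
#' Suitability is the chi-squared survival function (d degrees of freedom)
#' of the squared Mahalanobis distance to the presence centroid — a bounded,
#' rank-equivalent mapping of the classic distance score (1 at the
#' centroid, strictly decreasing in distance).  A near-singular presence
#' covariance is ridge-regularised.
#'
#' @param X_presence presence design matrix.
#' @return a `mahalanobis_model`.
#' @export
mahalanobis_fit <- function(X_presence) {
  X <- as.matrix(X_presence)
  mu <- colMeans(X)
  S <- stats::cov(X)
  if (rcond_psd(S) < 1e-10) S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
  structure(list(mu = mu, sigma = S, d = ncol(X), vars = colnames(X)),
            class = "mahalanobis_model")
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @export
predict.mahalanobis_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$vars, drop = FALSE]
  d2 <- stats::mahalanobis(X, object$mu, object$sigma)
  stats::pchisq(d2, df = object$d, lower.tail = FALSE)
}

#' Random k-fold assignment
#'
#' @param n number of points; @param K folds (>= 2); @param seed RNG seed.
#' @return integer fold labels 1..K covering all folds.
#' @export
kfold_assign <- function(n, K = 4L, seed = 1L) {
  if (K < 2L) stop("K must be >= 2")
  set.seed(seed)
  sample(rep_len(seq_len(K), n))
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence outscores a random background point,
#' with ties counted one half.
#'
#' @param pred_presence,pred_background numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pred_presence, pred_background) {
  np <- length(pred_presence); nb <- length(pred_background)
  r <- rank(c(pred_presence, pred_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Ensemble weight from a validation AUC
#'
#' @param auc validation AUC.
#' @return `(AUC - 0.5)^2`.
#' @export
ensemble_weight <- function(auc) (auc - 0.5)^2

## min-max rescale a vector to [0, 1] over its finite entries
minmax_rescale <- function(v) {
  r <- range(v, na.rm = TRUE, finite = TRUE)
  if (diff(r) == 0) return(ifelse(is.na(v), NA_real_, 0.5))
  (v - r[1L]) / diff(r)
}

#' Weighted-average combination of component predictions
#'
#' Each component grid is min-max rescaled to `[0, 1]` over the prediction
#' extent; the combination is `sum(w * pred) / sum(w)`.
#'
#' @param component_predictions list of numeric vectors/matrices on the
#'   same grid.
#' @param weights numeric weights, one per component; must not all be 0.
#' @return combined suitability on the same grid, entries in `[0, 1]`.
#' @export
ensemble_combine <- function(component_predictions, weights) {
  if (all(weights == 0)) stop("all component weights are zero")
  acc <- NULL
  for (i in seq_along(component_predictions)) {
    r <- minmax_rescale(component_predictions[[i]])
    acc <- if (is.null(acc)) weights[i] * r else acc + weights[i] * r
  }
  acc / sum(weights)
}

#' Threshold a suitability surface into a binary range map
#'
#' Picks the threshold maximising sensitivity + specificity over the
#' training presence/background scores (max-SSS rule); cells at or above
#' the threshold are in-range.  The rule depends only on score ranks, so
#' monotone transforms of the suitability leave the binary map unchanged.
#'
#' @param suitability numeric grid (vector or matrix).
#' @param pres_scores,bg_scores suitability at presences and background.
#' @return list with `threshold` and `range` (logical grid).
#' @export
threshold_range <- function(suitability, pres_scores, bg_scores) {
  cand <- sort(unique(c(pres_scores, bg_scores)))
  if (length(cand) == 1L) {
    warning("constant suitability: degenerate threshold")
    return(list(threshold = cand, range = suitability >= cand))
  }
  sss <- vapply(cand, function(th)
    mean(pres_scores >= th) + mean(bg_scores < th), numeric(1))
  th <- cand[which.max(sss)]
  list(threshold = th, range = suitability >= th)
}

#' Fit the AUC-weighted ensemble species distribution model
#'
#' For each method and each of K folds, fits on the other K-1 folds and
#' validates on the held-out fold (rank AUC), giving `methods x K`
#' component models weighted by `(AUC - 0.5)^2`.  Component grid
#' predictions are min-max rescaled and combined by the weighted average;
#' the combined surface is thresholded by the max-SSS rule.
#'
#' @param stack training `climate_stack`.
#' @param presences,backgrounds data.frames of lon/lat points.
#' @param methods subset of `c("glm", "bioclim", "mahalanobis", "plugin")`.
#' @param K folds (default 4).
#' @param vif_threshold collinearity threshold for predictor pruning.
#' @param plugin optional function `(X) -> scores` filling the plugin slot
#'   (e.g., externally computed Maxent output).
#' @param seed RNG seed (folds).
#' @return an `ensemble_sdm`: list with `components` (data.frame: method,
#'   fold, auc, weight), `models`, `variables`, `suitability` (grid
#'   matrix), `threshold`, `range`, `stack_template`.
#' @export
fit_sdm_ensemble <- function(stack, presences, backgrounds,
                             methods = c("glm", "bioclim", "mahalanobis"),
                             K = 4L, vif_threshold = 10, plugin = NULL,
                             seed = 1L) {
  Xp <- extract_values(stack, presences)
  Xb <- extract_values(stack, backgrounds)
  keep_vars <- vif_prune(rbind(Xp, Xb), vif_threshold)
  Xp <- Xp[, keep_vars, drop = FALSE]; Xb <- Xb[, keep_vars, drop = FALSE]
  X <- rbind(Xp, Xb)
  y <- c(rep(1L, nrow(Xp)), rep(0L, nrow(Xb)))
  folds <- kfold_assign(length(y), K = K, seed = seed)
  grid_df <- grid_design(stack, keep_vars)

  comp <- list(); models <- list(); grids <- list()
  for (m in methods) {
    for (k in seq_len(K)) {
      tr <- folds != k; va <- folds == k
      fit <- switch(
        m,
        glm = glm_bic_average(X[tr, , drop = FALSE], y[tr]),
        bioclim = bioclim_fit(X[tr & y == 1L, , drop = FALSE]),
        mahalanobis = mahalanobis_fit(X[tr & y == 1L, , drop = FALSE]),
        plugin = {
          if (is.null(plugin)) stop("plugin method requested but no plugin supplied")
          structure(list(fun = plugin), class = "plugin_model")
        },
        stop("unknown method: ", m))
      sc <- predict_component(fit, X[va, , drop = FALSE])
      a <- auc(sc[y[va] == 1L], sc[y[va] == 0L])
      comp[[length(comp) + 1L]] <-
        data.frame(method = m, fold = k, auc = a, weight = ensemble_weight(a))
      models[[length(models) + 1L]] <- fit
      grids[[length(grids) + 1L]] <- predict_component(fit, grid_df$X)
    }
  }
  comp <- do.call(rbind, comp)
  suit_valid <- ensemble_combine(grids, comp$weight)
  suitability <- matrix(NA_real_, length(stack$lat), length(stack$lon))
  suitability[grid_df$valid] <- suit_valid
  ## threshold on the combined surface itself, read off at the point cells
  pres_scores <- suitability[nearest_cells(stack, as.matrix(presences))]
  bg_scores <- suitability[nearest_cells(stack, as.matrix(backgrounds))]
  pres_scores <- pres_scores[!is.na(pres_scores)]
  bg_scores <- bg_scores[!is.na(bg_scores)]
  thr <- threshold_range(suitability, pres_scores, bg_scores)
  structure(list(components = comp, models = models, variables = keep_vars,
                 suitability = suitability, threshold = thr$threshold,
                 range = thr$range, folds = folds, seed = seed),
            class = "ensemble_sdm")
}

predict_component <- function(fit, newdata) {
  if (inherits(fit, "plugin_model")) fit$fun(newdata) else
    predict(fit, newdata)
}

## design matrix of all valid grid cells of a stack, restricted to vars
grid_design <- function(stack, vars) {
  X <- sapply(stack$layers[vars], as.vector)
  valid <- stats::complete.cases(X)
  list(X = as.data.frame(X[valid, , drop = FALSE]), valid = which(valid))
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("ensemble_sdm: %d component models, mean AUC %.3f, threshold %.3f\n",
              nrow(x$components), mean(x$components$auc), x$threshold))
  invisible(x)
}

#' Project a fitted ensemble onto another climate stack
#'
#' Applies the stored component models to the new stack (which must carry
#' the variables the ensemble uses), rescales each component over the new
#' extent and combines with the stored weights.
#'
#' @param ensemble an `ensemble_sdm`.
#' @param other_stack a `climate_stack`.
#' @return suitability matrix on the new grid, with the stored range
#'   threshold applied in attribute `"range"`.
#' @export
project_ensemble <- function(ensemble, other_stack) {
  missing_layers <- setdiff(ensemble$variables, names(other_stack$layers))
  if (length(missing_layers))
    stop("projection stack lacks required layer(s): ",
         paste(missing_layers, collapse = ", "))
  gd <- grid_design(other_stack, ensemble$variables)
  grids <- lapply(ensemble$models, predict_component, newdata = gd$X)
  suit_valid <- ensemble_combine(grids, ensemble$components$weight)
  out <- matrix(NA_real_, length(other_stack$lat), length(other_stack$lon))
  out[gd$valid] <- suit_valid
  attr(out, "range") <- out >= ensemble$threshold
  out
}
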