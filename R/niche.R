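#' Occurrence set for niche modelling
#'
#' Geographic occurrences of one dormancy group (N, R or D) together
#' with the background definition: a great-circle buffer (default
#' 300 km) around the points within which the niche model is evaluated.
#'
#' @param group group label.
#' @param lon,lat occurrence coordinates (decimal degrees, WGS-84).
#' @param buffer_km background buffer radius (default 300).
#' @return Object of class `"occurrence_set"`.
#' @export
occurrence_set <- function(group, lon, lat, buffer_km = 300) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (length(lon) != length(lat)) stop("lon/lat lengths differ", call. = FALSE)
  if (length(lon) < 3) stop("need at least 3 occurrences", call. = FALSE)
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of range", call. = FALSE)
  structure(list(group = as.character(group), lon = lon, lat = lat,
                 buffer_km = buffer_km),
            class = "occurrence_set")
}

## Logical matrix of cells within buffer_km of any occurrence point.
background_mask <- function(surface, occ) {
  ctr <- grid_centers(surface)
  inside <- rep(FALSE, nrow(ctr))
  for (i in seq_along(occ$lon)) {
    d <- geosphere::distHaversine(cbind(occ$lon[i], occ$lat[i]),
                                  cbind(ctr$lon, ctr$lat), r = 6371.0088)
    inside <- inside | d <= occ$buffer_km
  }
  m <- matrix(FALSE, nrow(surface$values), ncol(surface$values))
  m[cbind(ctr$row, ctr$col)] <- inside
  m
}

#' Normalize a suitability surface to a probability surface
#'
#' Divides by the total over unmasked, non-missing cells so values sum
#' to 1; cells outside the optional mask (and no-data cells) are set to
#' `NA`.
#'
#' @param surface a [suitability_surface()] with non-negative values.
#' @param mask optional logical matrix (TRUE = keep).
#' @return A [suitability_surface()] whose unmasked values sum to 1.
#' @export
normalize_surface <- function(surface, mask = NULL) {
  stopifnot(inherits(surface, "suitability_surface"))
  v <- surface$values
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v)))
      stop("mask shape does not match the grid", call. = FALSE)
    v[!mask] <- NA
  }
  if (any(v < 0, na.rm = TRUE))
    stop("suitability values must be non-negative", call. = FALSE)
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("all-zero surface cannot be normalized", call. = FALSE)
  suitability_surface(v / tot, surface$xll, surface$yll, surface$cellsize,
                      surface$crs)
}

#' Niche overlap indices D and I
#'
#' Schoener's D = 1 - 0.5 * sum |p1 - p2| and the Hellinger-based
#' I = 1 - 0.5 * sum (sqrt(p1) - sqrt(p2))^2, both over the cells where
#' at least one surface is defined (missing values in one surface count
#' as probability 0 there). Both indices are 1 iff the probability
#' surfaces are identical and 0 iff their supports are disjoint.
#'
#' @param p1,p2 normalized [suitability_surface()]s on identical grids.
#' @return Named numeric vector `c(D = , I = )`.
#' @export
overlap_indices <- function(p1, p2) {
  stopifnot(inherits(p1, "suitability_surface"),
            inherits(p2, "suitability_surface"))
  if (!identical(dim(p1$values), dim(p2$values)) ||
      abs(p1$xll - p2$xll) > 1e-9 || abs(p1$yll - p2$yll) > 1e-9 ||
      abs(p1$cellsize - p2$cellsize) > 1e-12)
    stop("surfaces are on different grids", call. = FALSE)
  v1 <- p1$values; v2 <- p2$values
  both_na <- is.na(v1) & is.na(v2)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  v1 <- v1[!both_na]; v2 <- v2[!both_na]
  c(D = 1 - 0.5 * sum(abs(v1 - v2)),
    I = 1 - 0.5 * sum((sqrt(v1) - sqrt(v2))^2))
}

#' Climate-envelope suitability model
#'
#' Built-in baseline niche model: for each environmental raster, cells
#' score 1 inside the central percentile envelope (default 5th-95th) of
#' the variable's values at the occurrence points, taper linearly to 0
#' at the observed minimum/maximum, and score 0 beyond. Per-cell
#' suitability is the product across variables, restricted to the
#' background buffer. Externally fitted suitability rasters (e.g., from
#' a maximum-entropy model) can be supplied anywhere a
#' [suitability_surface()] is accepted; this model is the pluggable
#' default, not a re-implementation of any external tool.
#'
#' @param occ an [occurrence_set()].
#' @param env_rasters list of [suitability_surface()] predictors on a
#'   common grid.
#' @param percentiles envelope percentiles (default `c(0.05, 0.95)`).
#' @return A [suitability_surface()] of raw (unnormalized) suitability,
#'   `NA` outside the background.
#' @export
envelope_model <- function(occ, env_rasters, percentiles = c(0.05, 0.95)) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (!length(env_rasters)) stop("need at least 1 env raster", call. = FALSE)
  if (inherits(env_rasters, "suitability_surface"))
    env_rasters <- list(env_rasters)
  r1 <- env_rasters[[1]]
  ok <- in_extent(r1, occ$lon, occ$lat)
  if (!all(ok)) {
    warning(sum(!ok), " occurrence(s) outside the raster extent dropped",
            call. = FALSE)
    if (!any(ok)) stop("all occurrences outside the rasters", call. = FALSE)
    occ$lon <- occ$lon[ok]; occ$lat <- occ$lat[ok]
  }
  suit <- matrix(1, nrow(r1$values), ncol(r1$values))
  for (r in env_rasters) {
    at_occ <- extract_value(r, occ$lon, occ$lat)
    at_occ <- at_occ[!is.na(at_occ)]
    if (!length(at_occ))
      stop("no occurrence falls on valid cells of a predictor raster",
           call. = FALSE)
    qs <- stats::quantile(at_occ, probs = percentiles, names = FALSE)
    lo <- min(at_occ); hi <- max(at_occ)
    v <- r$values
    s <- matrix(0, nrow(v), ncol(v))
    core <- !is.na(v) & v >= qs[1] & v <= qs[2]
    s[core] <- 1
    if (qs[1] > lo) {
      left <- !is.na(v) & v >= lo & v < qs[1]
      s[left] <- (v[left] - lo) / (qs[1] - lo)
    }
    if (hi > qs[2]) {
      right <- !is.na(v) & v > qs[2] & v <= hi
      s[right] <- (hi - v[right]) / (hi - qs[2])
    }
    s[is.na(v)] <- NA
    suit <- suit * s
  }
  suit[!background_mask(r1, occ)] <- NA
  suitability_surface(suit, r1$xll, r1$yll, r1$cellsize, r1$crs)
}

#' Niche equivalency test
#'
#' Warren-style pooling randomization: the observed Schoener's D and
#' Hellinger I are computed between niche models fitted to the two
#' occurrence sets (normalized over the union of their backgrounds);
#' under the null the pooled occurrences are randomly repartitioned
#' preserving group sizes, models are refitted and D, I recomputed.
#' One-sided p-values per index, p = (1 + #\{null <= observed\}) /
#' (1 + n_reps): lower-than-null overlap signals niche divergence.
#'
#' @param occ1,occ2 [occurrence_set()]s.
#' @param env_rasters list of predictor [suitability_surface()]s.
#' @param model fitting function `(occ, env_rasters) -> suitability
#'   surface`; default [envelope_model()].
#' @param n_reps null replicates (default 100).
#' @param seed optional integer seed.
#' @return Object of class `"overlap_result"`: `observed` (D, I),
#'   `null` (n_reps x 2 matrix), `p_value` (per index), group labels.
#' @export
equivalency_test <- function(occ1, occ2, env_rasters,
                             model = envelope_model, n_reps = 100,
                             seed = NULL) {
  stopifnot(inherits(occ1, "occurrence_set"),
            inherits(occ2, "occurrence_set"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(env_rasters, "suitability_surface"))
    env_rasters <- list(env_rasters)
  r1 <- env_rasters[[1]]
  union_mask <- background_mask(r1, occ1) | background_mask(r1, occ2)
  pair_di <- function(o1, o2) {
    s1 <- model(o1, env_rasters)
    s2 <- model(o2, env_rasters)
    v1 <- s1$values; v1[is.na(v1)] <- 0; v1[!union_mask] <- NA
    v2 <- s2$values; v2[is.na(v2)] <- 0; v2[!union_mask] <- NA
    p1 <- normalize_surface(suitability_surface(v1, s1$xll, s1$yll,
                                                s1$cellsize, s1$crs))
    p2 <- normalize_surface(suitability_surface(v2, s2$xll, s2$yll,
                                                s2$cellsize, s2$crs))
    overlap_indices(p1, p2)
  }
  observed <- pair_di(occ1, occ2)
  n1 <- length(occ1$lon)
  pool_lon <- c(occ1$lon, occ2$lon); pool_lat <- c(occ1$lat, occ2$lat)
  n_pool <- length(pool_lon)
  null_mat <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("D", "I")))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(n_pool, n1)
    o1 <- occurrence_set(occ1$group, pool_lon[idx], pool_lat[idx],
                         occ1$buffer_km)
    o2 <- occurrence_set(occ2$group, pool_lon[-idx], pool_lat[-idx],
                         occ2$buffer_km)
    null_mat[b, ] <- tryCatch(pair_di(o1, o2), error = function(e) c(NA, NA))
  }
  ok <- stats::complete.cases(null_mat)
  p <- vapply(c("D", "I"), function(j)
    (1 + sum(null_mat[ok, j] <= observed[j])) / (1 + sum(ok)), numeric(1))
  structure(list(observed = observed, null = null_mat, p_value = p,
                 groups = c(occ1$group, occ2$group), n_reps = n_reps),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Niche equivalency test: %s vs %s (%d replicates)\n",
              x$groups[1], x$groups[2], x$n_reps))
  cat(sprintf("  observed D = %.3f (p = %.3f), I = %.3f (p = %.3f)\n",
              x$observed["D"], x$p_value["D"],
              x$observed["I"], x$p_value["I"]))
  invisible(x)
}
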