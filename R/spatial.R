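#' Great-circle distance matrix
#'
#' Symmetric haversine (spherical) distances in kilometres between
#' WGS-84 points, Earth radius 6371.0088 km. Spherical geometry is
#' adequate at the buffer (5 km) and distance-class (continental)
#' scales used here.
#'
#' @param coords matrix or data frame with columns `lon`, `lat`
#'   (decimal degrees); rownames/`accession_id` become dimnames.
#' @return n x n distance matrix (km).
#' @export
haversine_distances <- function(coords) {
  coords <- as.data.frame(coords)
  if (!all(c("lon", "lat") %in% names(coords))) {
    if (ncol(coords) >= 2) names(coords)[1:2] <- c("lon", "lat")
    else stop("coords needs `lon` and `lat` columns", call. = FALSE)
  }
  if (any(coords$lat < -90 | coords$lat > 90) ||
      any(coords$lon < -180 | coords$lon > 180))
    stop("coordinates out of range (lat [-90,90], lon [-180,180])",
         call. = FALSE)
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371.0088))
  ids <- if (!is.null(coords$accession_id)) coords$accession_id else
    rownames(coords)
  dimnames(m) <- list(ids, ids)
  m
}

#' Distance classes for correlogram analysis
#'
#' Partitions the observed pairwise distances into `n_classes` classes.
#' The default `"equal_pairs"` scheme uses quantile boundaries so classes
#' have (near-)equal pair counts, the standard choice for stable
#' correlogram estimates when class widths are unequal; `"equal_width"`
#' slices the distance range evenly. The largest class is flagged for
#' exclusion from testing (its pairs still contribute to covariance
#' binning).
#'
#' @param d symmetric distance matrix (km).
#' @param n_classes number of classes (default 10).
#' @param scheme `"equal_pairs"` or `"equal_width"`.
#' @param exclude_largest flag the largest class as untested (default TRUE).
#' @return Object of class `"distance_classes"`: `breaks`, `class_matrix`
#'   (n x n integer, NA diagonal), `pair_counts`, `n_classes`,
#'   `tested` (logical per class).
#' @export
make_distance_classes <- function(d, n_classes = 10,
                                  scheme = c("equal_pairs", "equal_width"),
                                  exclude_largest = TRUE) {
  scheme <- match.arg(scheme)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  dv <- d[lower.tri(d)]
  breaks <- if (scheme == "equal_pairs")
    unname(stats::quantile(dv, probs = seq(0, 1, length.out = n_classes + 1)))
  else seq(min(dv), max(dv), length.out = n_classes + 1)
  ub <- unique(breaks)
  if (length(ub) < length(breaks)) {
    warning("fewer distinct distances than classes; classes merged",
            call. = FALSE)
    breaks <- ub
  }
  k <- length(breaks) - 1
  cm <- matrix(NA_integer_, n, n)
  cl <- cut(d[lower.tri(d)], breaks = breaks, include.lowest = TRUE,
            labels = FALSE)
  cm[lower.tri(cm)] <- cl
  cm[upper.tri(cm)] <- t(cm)[upper.tri(cm)]
  tested <- rep(TRUE, k)
  if (exclude_largest) tested[k] <- FALSE
  structure(list(breaks = breaks, class_matrix = cm,
                 pair_counts = tabulate(cl, nbins = k),
                 n_classes = k, tested = tested),
            class = "distance_classes")
}

## Moran's I for a binary weight structure given as a pair index matrix.
## pairs: 2-column matrix of (i, j) with i < j; each unordered pair once.
morans_i_pairs <- function(z, pairs, n) {
  s0 <- 2 * nrow(pairs)                       # symmetric binary weights
  num <- 2 * sum(z[pairs[, 1]] * z[pairs[, 2]])
  (n / s0) * num / sum(z^2)
}

#' Moran's I spatial correlogram
#'
#' Moran's I per distance class with binary weights (pair in class), its
#' null expectation E\[I\] = -1/(n-1), a two-sided randomization p-value
#' (default 999 permutations of the values over locations), and a global
#' Bonferroni verdict: the correlogram is globally significant iff at
#' least one tested class has p <= alpha / (number of tested classes).
#' The largest class is excluded from testing when the class set says so.
#'
#' @param values numeric vector, one value per point.
#' @param classes a [make_distance_classes()] object.
#' @param alpha global significance level (default 0.05).
#' @param n_permutations randomization count (default 999).
#' @return Object of class `"correlogram"`: data frame `classes` with
#'   `class`, `lower`, `upper`, `n_pairs`, `moran_i`, `expectation`,
#'   `p_value`, `tested`; `global_significant`; `alpha`;
#'   `bonferroni_alpha`.
#' @export
morans_i_correlogram <- function(values, classes, alpha = 0.05,
                                 n_permutations = 999) {
  stopifnot(inherits(classes, "distance_classes"))
  values <- as.numeric(values)
  n <- nrow(classes$class_matrix)
  if (length(values) != n)
    stop("length(values) must match the class matrix", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (stats::var(values) == 0)
    stop("constant surface; Moran's I undefined", call. = FALSE)
  z <- values - mean(values)
  e_i <- -1 / (n - 1)
  perm <- replicate(n_permutations, sample.int(n))
  k <- classes$n_classes
  res <- lapply(seq_len(k), function(cc) {
    sel <- which(classes$class_matrix == cc & lower.tri(classes$class_matrix),
                 arr.ind = TRUE)
    if (!nrow(sel))
      return(data.frame(class = cc, lower = classes$breaks[cc],
                        upper = classes$breaks[cc + 1], n_pairs = 0,
                        moran_i = NA_real_, expectation = e_i,
                        p_value = NA_real_, tested = FALSE))
    colnames(sel) <- NULL
    i_obs <- morans_i_pairs(z, sel, n)
    # permutation null: z'z is permutation-invariant, vectorize the numerator
    Zi <- matrix(z[perm[sel[, 1], ]], nrow = nrow(sel))
    Zj <- matrix(z[perm[sel[, 2], ]], nrow = nrow(sel))
    i_null <- (n / (2 * nrow(sel))) * 2 * colSums(Zi * Zj) / sum(z^2)
    p <- (1 + sum(abs(i_null - e_i) >= abs(i_obs - e_i) - 1e-12)) /
      (n_permutations + 1)
    data.frame(class = cc, lower = classes$breaks[cc],
               upper = classes$breaks[cc + 1], n_pairs = nrow(sel),
               moran_i = i_obs, expectation = e_i, p_value = p,
               tested = classes$tested[cc])
  })
  tab <- do.call(rbind, res)
  n_tested <- sum(tab$tested & !is.na(tab$p_value))
  bonf <- alpha / max(n_tested, 1)
  glob <- any(tab$p_value[tab$tested] <= bonf, na.rm = TRUE)
  structure(list(classes = tab, global_significant = glob, alpha = alpha,
                 bonferroni_alpha = bonf, n_permutations = n_permutations),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Moran's I correlogram (%d permutations)\n", x$n_permutations))
  print(x$classes, digits = 3)
  cat(sprintf("Global Bonferroni verdict at alpha = %g (per-class %g): %s\n",
              x$alpha, x$bonferroni_alpha,
              if (x$global_significant) "significant" else "not significant"))
  invisible(x)
}

#' Dutilleul's modified t-test for correlation of two spatial processes
#'
#' Tests the Pearson correlation between two variables observed at the
#' same locations while correcting for spatial autocorrelation in both.
#' The spatial covariance of each process is estimated empirically by
#' distance-class binning (same class set as the correlogram); an
#' effective sample size is then obtained from trace operations on the
#' two centered covariance matrices,
#' n_eff = 1 + 1 / (tr(B Sx B Sy) / (tr(B Sx) tr(B Sy))) with
#' B = I - 11'/n, and the t statistic r * sqrt((n_eff - 2)/(1 - r^2)) is
#' referred to a t distribution with n_eff - 2 df. Under independence and
#' no autocorrelation n_eff is close to n; shared positive autocorrelation
#' shrinks it.
#'
#' @param x,y numeric vectors at the same points.
#' @param coords lon/lat coordinates (see [haversine_distances()]), or
#'   `NULL` when `classes` is given.
#' @param classes optional precomputed [make_distance_classes()] object.
#' @param n_classes classes used when binning from `coords`.
#' @return List: `r`, `t`, `df`, `n`, `n_eff`, `p_corrected`,
#'   `p_classical`.
#' @export
dutilleul_modified_t <- function(x, y, coords = NULL, classes = NULL,
                                 n_classes = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("variables must be finite", call. = FALSE)
  if (is.null(classes)) {
    if (is.null(coords)) stop("supply `coords` or `classes`", call. = FALSE)
    classes <- make_distance_classes(haversine_distances(coords),
                                     n_classes = n_classes,
                                     exclude_largest = FALSE)
  }
  cm <- classes$class_matrix
  est_cov <- function(v) {
    zv <- v - mean(v)
    S <- matrix(0, n, n)
    diag(S) <- mean(zv^2)
    for (cc in seq_len(classes$n_classes)) {
      sel <- cm == cc & lower.tri(cm)
      if (!any(sel)) next
      idx <- which(sel, arr.ind = TRUE)
      chat <- mean(zv[idx[, 1]] * zv[idx[, 2]])
      S[cm == cc] <- chat
    }
    S
  }
  Sx <- est_cov(x); Sy <- est_cov(y)
  B <- diag(n) - matrix(1 / n, n, n)
  BSx <- B %*% Sx; BSy <- B %*% Sy
  sigma2_r <- sum(t(BSx) * BSy) / (sum(diag(BSx)) * sum(diag(BSy)))
  n_eff <- if (is.finite(sigma2_r) && sigma2_r > 0) 1 + 1 / sigma2_r else n
  n_eff <- min(n_eff, n)
  r <- stats::cor(x, y)
  if (n_eff < 3)
    stop("insufficient effective sample size (n_eff < 3)", call. = FALSE)
  tt <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt((n_eff - 2) / (1 - r^2))
  t_cl <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, df = n_eff - 2, n = n, n_eff = n_eff,
       p_corrected = 2 * stats::pt(abs(tt), n_eff - 2, lower.tail = FALSE),
       p_classical = 2 * stats::pt(abs(t_cl), n - 2, lower.tail = FALSE))
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: eigenvectors of the
#' double-centered, truncated great-circle distance matrix, used as
#' spatial predictors in constrained ordination. The default truncation
#' is the longest edge of the minimum spanning tree of the distance
#' matrix; beyond-truncation distances are replaced by 4 x truncation.
#' Only eigenvectors with positive eigenvalues are returned, ordered by
#' decreasing eigenvalue.
#'
#' @param coords lon/lat coordinates (see [haversine_distances()]).
#' @param truncation optional truncation distance (km).
#' @return List: `vectors` (n x k matrix, columns `PCNM1`, ...),
#'   `values` (positive eigenvalues), `truncation` (km used).
#' @export
pcnm_eigenvectors <- function(coords, truncation = NULL) {
  d <- haversine_distances(coords)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (max(d) <= 0) stop("all points identical; PCNM undefined", call. = FALSE)
  p <- if (is.null(truncation)) vegan::pcnm(stats::as.dist(d)) else
    vegan::pcnm(stats::as.dist(d), threshold = truncation)
  k <- ncol(p$vectors)            # vegan keeps positive-eigenvalue vectors
  list(vectors = p$vectors, values = p$values[seq_len(k)],
       truncation = p$threshold)
}
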