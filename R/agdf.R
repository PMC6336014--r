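#' Germination record
#'
#' Container for one daily cumulative germination (imbibition) series:
#' one accession under one alternating-temperature treatment, one replicate
#' (or the replicate sum). Counts are cumulative numbers of imbibed seeds,
#' scored daily; imbibition is the water-entry event that marks release of
#' physical dormancy, and every imbibed seed germinated in the assay, so the
#' imbibed count is the germination measure.
#'
#' @param accession_id character scalar label.
#' @param treatment `"T25_15"` or `"T35_15"` (day/night temperature regime).
#' @param replicate small positive integer; `0` conventionally marks a
#'   replicate sum.
#' @param days strictly increasing observation times in days, within
#'   `(0, horizon]`.
#' @param counts cumulative counts, non-decreasing, between 0 and
#'   `seeds_total`.
#' @param seeds_total number of seeds plated (25 per dish in the reference
#'   design; a replicate sum carries the summed total).
#' @param horizon end of the observation window in days (default 28).
#' @return An object of class `"germination_record"`.
#' @export
germination_record <- function(accession_id, treatment, replicate,
                               days, counts, seeds_total, horizon = 28) {
  treatment <- match.arg(treatment, c("T25_15", "T35_15"))
  days <- as.numeric(days)
  counts <- as.numeric(counts)
  if (length(days) != length(counts))
    stop("`days` and `counts` must have equal length", call. = FALSE)
  if (length(days) < 1 || any(!is.finite(days)) || any(!is.finite(counts)))
    stop("non-finite or empty observation series", call. = FALSE)
  if (any(diff(days) <= 0))
    stop("`days` must be strictly increasing", call. = FALSE)
  if (days[1] <= 0 || days[length(days)] > horizon)
    stop("`days` must lie in (0, horizon]", call. = FALSE)
  if (any(diff(counts) < 0))
    stop(sprintf("cumulative counts decrease (accession %s)", accession_id),
         call. = FALSE)
  if (any(counts < 0) || any(counts > seeds_total))
    stop(sprintf("counts outside [0, seeds_total] (accession %s)", accession_id),
         call. = FALSE)
  structure(
    list(accession_id = as.character(accession_id), treatment = treatment,
         replicate = as.integer(replicate), days = days, counts = counts,
         seeds_total = as.numeric(seeds_total), horizon = as.numeric(horizon)),
    class = "germination_record")
}

#' Spline settings for AGDF fitting
#'
#' Controls the penalized B-spline smoother. The default basis uses degree-4
#' polynomial pieces with equally spaced interior knots every 2 days on
#' \[0, 28\] (13 interior knots, an 18-dimensional basis). Roughness is
#' penalized through the squared L2 norm of the first derivative; the
#' smoothing parameter `lambda` is chosen by generalized cross-validation
#' over a log-spaced grid unless fixed.
#'
#' @param degree polynomial degree of the spline pieces (default 4).
#' @param knot_spacing spacing of equally spaced interior knots, in days.
#' @param interior_knots explicit interior knots overriding `knot_spacing`.
#' @param horizon right end of the fitting domain (days).
#' @param lambda fixed non-negative smoothing parameter, or `NULL` to select
#'   by GCV.
#' @param lambda_grid candidate grid used when `lambda` is `NULL`.
#' @param anchor prepend a (t = 0, y = 0) observation so all fits share the
#'   full domain and seeds start ungerminated.
#' @param monotone_tol soft monotonicity tolerance: warn if the fitted first
#'   derivative dips below `-monotone_tol * seeds_total` anywhere on a
#'   0.1-day grid.
#' @return A list of class `"agdf_control"`.
#' @export
agdf_control <- function(degree = 4, knot_spacing = 2, interior_knots = NULL,
                         horizon = 28, lambda = NULL,
                         lambda_grid = 10^seq(-4, 4, length.out = 25),
                         anchor = TRUE, monotone_tol = 0.02) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  if (!is.null(lambda) && (!is.finite(lambda) || lambda < 0))
    stop("lambda must be a non-negative number", call. = FALSE)
  structure(list(degree = degree, knot_spacing = knot_spacing,
                 interior_knots = interior_knots, horizon = horizon,
                 lambda = lambda, lambda_grid = lambda_grid,
                 anchor = anchor, monotone_tol = monotone_tol),
            class = "agdf_control")
}

## Full (replicated-boundary) knot vector for the configured basis.
agdf_knots <- function(control, a = 0, b = control$horizon) {
  ik <- control$interior_knots
  if (is.null(ik)) {
    ik <- seq(a, b, by = control$knot_spacing)
    ik <- ik[ik > a & ik < b]
  }
  if (any(ik <= a) || any(ik >= b))
    stop("interior knots must lie strictly inside the domain", call. = FALSE)
  ord <- control$degree + 1
  c(rep(a, ord), sort(ik), rep(b, ord))
}

bspline_design <- function(knots, x, degree, deriv = 0) {
  splines::splineDesign(knots, x, ord = degree + 1,
                        derivs = rep(deriv, length(x)))
}

## Exact Gram matrix of first derivatives, int B_i'(t) B_j'(t) dt, by
## Gauss-Legendre quadrature per inter-knot interval (exact: the integrand is
## piecewise polynomial of degree 2(degree-1)).
penalty_matrix_d1 <- function(knots, degree) {
  ord <- degree + 1
  nb <- length(knots) - ord
  brk <- unique(knots)
  q <- max(2, degree)           # 2q-1 >= 2(degree-1) for degree >= 1
  G <- matrix(0, nb, nb)
  for (i in seq_len(length(brk) - 1)) {
    gl <- pracma::gaussLegendre(q, brk[i], brk[i + 1])
    D <- bspline_design(knots, gl$x, degree, deriv = 1)
    G <- G + crossprod(D * sqrt(gl$w), D * sqrt(gl$w))
  }
  (G + t(G)) / 2
}

penalized_solve <- function(X, y, G, lambda) {
  XtX <- crossprod(X)
  A <- XtX + lambda * G
  if (lambda == 0) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("normal system is rank deficient at lambda = 0 (more basis ",
           "functions than informative observations); use lambda > 0",
           call. = FALSE)
  }
  coef <- solve(A, crossprod(X, y))
  H_tr <- sum(diag(solve(A, XtX)))
  fitted <- drop(X %*% coef)
  list(coefficients = drop(coef), fitted = fitted,
       rss = sum((y - fitted)^2), edf = H_tr)
}

gcv_select <- function(X, y, G, grid) {
  n <- length(y)
  scores <- vapply(grid, function(l) {
    f <- penalized_solve(X, y, G, l)
    n * f$rss / (n - f$edf)^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Fit an absolute germination distribution function (AGDF)
#'
#' Fits a smooth, in-principle non-decreasing function of time giving the
#' absolute cumulative number of imbibed seeds, by penalized least squares in
#' a B-spline basis: minimize sum_i (y_i - s(t_i))^2 +
#' lambda * int s'(t)^2 dt over splines of the configured degree and knots.
#' A (0, 0) anchor is prepended by default. The fit is unconstrained; a
#' diagnostic warns when the fitted derivative dips materially below zero
#' (see `agdf_control()`).
#'
#' @param record a [germination_record()].
#' @param control an [agdf_control()].
#' @return Object of class `"agdf"`: degree, knots, B-spline `coefficients`,
#'   `domain`, `lambda`, effective degrees of freedom, residual sum of
#'   squares, and the anchored data.
#' @export
fit_agdf <- function(record, control = agdf_control()) {
  stopifnot(inherits(record, "germination_record"))
  t <- record$days; y <- record$counts
  if (control$anchor) { t <- c(0, t); y <- c(0, y) }
  if (length(unique(t)) < 2)
    stop("need at least 2 distinct observation times", call. = FALSE)
  knots <- agdf_knots(control, 0, control$horizon)
  X <- bspline_design(knots, t, control$degree)
  G <- penalty_matrix_d1(knots, control$degree)
  lambda <- control$lambda
  if (is.null(lambda))
    lambda <- gcv_select(X, y, G, control$lambda_grid)
  fit <- penalized_solve(X, y, G, lambda)
  out <- structure(
    list(degree = control$degree, knots = knots,
         coefficients = fit$coefficients, domain = c(0, control$horizon),
         lambda = lambda, edf = fit$edf, rss = fit$rss,
         times = t, values = y, accession_id = record$accession_id,
         treatment = record$treatment, seeds_total = record$seeds_total),
    class = "agdf")
  dgrid <- seq(0, control$horizon, by = 0.1)
  dmin <- min(bspline_design(knots, dgrid, control$degree, deriv = 1) %*%
                fit$coefficients)
  out$min_derivative <- dmin
  if (dmin < -control$monotone_tol * record$seeds_total)
    warning(sprintf(
      "fitted AGDF decreases (min derivative %.3f seeds/day, accession %s)",
      dmin, record$accession_id), call. = FALSE)
  out
}

#' Evaluate an AGDF
#'
#' Basis-expansion evaluation `sum_j b_j B_j(t)`; linear in the coefficients.
#' No extrapolation: times outside the fitted domain are an error.
#'
#' @param agdf an `"agdf"` object.
#' @param times evaluation times within the domain.
#' @param deriv derivative order (0 = function value).
#' @return Numeric vector of evaluations.
#' @export
evaluate_agdf <- function(agdf, times, deriv = 0) {
  stopifnot(inherits(agdf, "agdf"))
  if (any(times < agdf$domain[1] - 1e-12) || any(times > agdf$domain[2] + 1e-12))
    stop("evaluation time outside the AGDF domain; no extrapolation",
         call. = FALSE)
  times <- pmin(pmax(times, agdf$domain[1]), agdf$domain[2])
  drop(bspline_design(agdf$knots, times, agdf$degree, deriv = deriv) %*%
         agdf$coefficients)
}

#' @export
predict.agdf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- seq(object$domain[1], object$domain[2], by = 0.1)
  evaluate_agdf(object, newdata)
}

#' @export
print.agdf <- function(x, ...) {
  cat(sprintf("AGDF fit: accession %s, treatment %s\n", x$accession_id, x$treatment))
  cat(sprintf("  degree %d, %d basis functions, lambda = %.4g, edf = %.2f\n",
              x$degree, length(x$coefficients), x$lambda, x$edf))
  cat(sprintf("  AUC = %.2f seed-days, RSS = %.3f\n", agdf_area(x), x$rss))
  invisible(x)
}

#' Area under an AGDF or a raw count series
#'
#' Composite trapezoidal approximation of the Riemann integral of the
#' germination curve over its domain. Larger area means higher final
#' germination and/or faster germination. For an `"agdf"` the curve is
#' evaluated on `grid` (default 0.1-day steps); for a numeric vector of
#' values, `grid` gives the matching abscissae; a raw count series should be
#' passed with the (0, 0) anchor included so areas share a common domain.
#'
#' @param x an `"agdf"` or a numeric vector of curve values.
#' @param grid strictly increasing evaluation times.
#' @param monotone if `TRUE` (AGDF input), apply an isotonic (non-decreasing)
#'   projection of the evaluated curve before integrating.
#' @return Non-negative scalar area (seed-days).
#' @export
agdf_area <- function(x, grid = NULL, monotone = FALSE) {
  if (inherits(x, "agdf")) {
    if (is.null(grid)) grid <- seq(x$domain[1], x$domain[2], by = 0.1)
    v <- evaluate_agdf(x, grid)
    if (monotone) v <- stats::isoreg(grid, v)$yf
  } else {
    v <- as.numeric(x)
    if (is.null(grid)) stop("`grid` is required for raw values", call. = FALSE)
  }
  if (length(grid) < 2) stop("evaluation grid is empty or degenerate", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  if (length(v) != length(grid)) stop("values and grid lengths differ", call. = FALSE)
  sum(diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Classical germination indices
#'
#' The scalar summaries in common use: final germination proportion, area
#' under the (piecewise-linear, anchored) count curve, LT50 (first time the
#' cumulative count reaches 50% of its final value, linearly interpolated),
#' mean germination time (daily-increment-weighted mean time) and the
#' coefficient of velocity (100 / MGT, percent per day). When the final
#' count is zero, LT50, MGT and CV are undefined and returned as `NA`.
#'
#' @param record a [germination_record()].
#' @return A one-row data frame: `final_proportion`, `auc`, `lt50`, `mgt`,
#'   `cv`.
#' @export
classical_indices <- function(record) {
  stopifnot(inherits(record, "germination_record"))
  t <- c(0, record$days); y <- c(0, record$counts)
  final <- y[length(y)]
  auc <- agdf_area(y, t)
  if (final <= 0) {
    lt50 <- mgt <- cv <- NA_real_
  } else {
    half <- final / 2
    k <- which(y >= half)[1]                      # anchored: y[1] = 0 < half
    lt50 <- if (y[k] == half) t[k] else
      t[k - 1] + (half - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
    g <- diff(y)
    mgt <- sum(g * t[-1]) / sum(g)
    cv <- 100 / mgt
  }
  data.frame(accession_id = record$accession_id, treatment = record$treatment,
             final_proportion = final / record$seeds_total, auc = auc,
             lt50 = lt50, mgt = mgt, cv = cv, stringsAsFactors = FALSE)
}

#' Penalized-spline scatterplot smoother
#'
#' The same penalized B-spline engine as [fit_agdf()], applied in regression
#' mode to scattered (x, y) pairs: no (0,0) anchor, no monotonicity
#' diagnostic, knots spread over the range of `x`. Returns the smooth
#' together with residual and null deviance and an approximate F test
#' against the intercept-only model, playing the role of a Gaussian
#' additive-model fit of a response on a single smooth predictor.
#'
#' @details The reported F test compares the *unpenalized* projection onto
#' the spline basis with the intercept-only model, an exact Gaussian F test
#' with (K - 1, n - K) degrees of freedom for a rank-K basis. Using the
#' unpenalized basis keeps the test's size exact regardless of how the
#' smoothing parameter was selected (a data-driven lambda would otherwise
#' bias an effective-degrees-of-freedom test anti-conservatively).
#'
#' @param x,y numeric vectors, `length(x) == length(y) >= 5`.
#' @param n_knots requested number of equally spaced interior knots; reduced
#'   automatically so the basis stays well below n.
#' @param degree spline degree.
#' @param lambda fixed smoothing parameter or `NULL` for GCV.
#' @param lambda_grid GCV grid.
#' @return Object of class `"agdf_smooth"`: the spline (reusable through
#'   [evaluate_agdf()]), `deviance`, `null_deviance`, `edf`, `f_statistic`,
#'   `p_value`.
#' @export
smooth_regression <- function(x, y, n_knots = 8, degree = 3, lambda = NULL,
                              lambda_grid = 10^seq(-4, 6, length.out = 30)) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (diff(range(x)) <= 0) stop("`x` is constant", call. = FALSE)
  n <- length(y)
  n_knots <- max(0, min(n_knots, n - degree - 2))
  a <- min(x); b <- max(x)
  ik <- if (n_knots > 0)
    seq(a, b, length.out = n_knots + 2)[-c(1, n_knots + 2)] else numeric(0)
  ord <- degree + 1
  knots <- c(rep(a, ord), ik, rep(b, ord))
  X <- bspline_design(knots, x, degree)
  G <- penalty_matrix_d1(knots, degree)
  if (is.null(lambda)) lambda <- gcv_select(X, y, G, lambda_grid)
  fit <- penalized_solve(X, y, G, lambda)
  dev0 <- sum((y - mean(y))^2)
  # exact F test on the unpenalized basis projection
  qx <- qr(X)
  K <- qx$rank
  rss_full <- sum(qr.resid(qx, y)^2)
  df1 <- K - 1
  df2 <- max(n - K, 1)
  f <- ((dev0 - rss_full) / df1) / (rss_full / df2)
  structure(
    list(degree = degree, knots = knots, coefficients = fit$coefficients,
         domain = c(a, b), lambda = lambda, edf = fit$edf,
         deviance = fit$rss, null_deviance = dev0,
         f_statistic = f, df1 = df1, df2 = df2,
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
         times = x, values = y),
    class = c("agdf_smooth", "agdf"))
}
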