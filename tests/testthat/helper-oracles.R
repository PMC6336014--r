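# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths.

# Cox-de Boor recurrence evaluation of a single B-spline basis function.
bspline_recurrence <- function(knots, j, k, x) {
  if (k == 0)
    return(as.numeric(knots[j] <= x &
                        (x < knots[j + 1] |
                           (x == knots[j + 1] &
                              knots[j + 1] == knots[length(knots)]))))
  d1 <- knots[j + k] - knots[j]
  d2 <- knots[j + k + 1] - knots[j + 1]
  t1 <- if (d1 > 0)
    (x - knots[j]) / d1 * bspline_recurrence(knots, j, k - 1, x) else 0
  t2 <- if (d2 > 0)
    (knots[j + k + 1] - x) / d2 * bspline_recurrence(knots, j + 1, k - 1, x) else 0
  t1 + t2
}

# Full basis matrix from the recurrence.
recurrence_basis <- function(knots, degree, x) {
  nb <- length(knots) - degree - 1
  sapply(seq_len(nb), function(j) bspline_recurrence(knots, j, degree, x))
}

# Composite Simpson weights on an even-interval grid.
simpson_weights <- function(n_points, h) {
  stopifnot(n_points %% 2 == 1)
  w <- rep(c(2, 4), length.out = n_points)
  w[1] <- 1; w[n_points] <- 1
  w * h / 3
}

# Dense-grid quadratic-programming oracle for the penalized spline problem:
# the roughness integral is discretized by composite Simpson quadrature on a
# fine grid and the resulting QP is solved by conjugate gradients (exact for
# a quadratic in <= dim iterations), independently of the package's
# Gauss-Legendre / normal-equations route.
qp_spline_oracle <- function(knots, degree, t, y, lambda, h = 0.004) {
  a <- knots[1]; b <- knots[length(knots)]
  npt <- round((b - a) / h)
  if (npt %% 2 == 1) npt <- npt + 1
  grid <- seq(a, b, length.out = npt + 1)
  X <- splines::splineDesign(knots, t, ord = degree + 1)
  D <- splines::splineDesign(knots, grid, ord = degree + 1,
                             derivs = rep(1, length(grid)))
  w <- simpson_weights(npt + 1, (b - a) / npt)
  amul <- function(v)
    drop(crossprod(X, X %*% v)) + lambda * drop(crossprod(D, w * (D %*% v)))
  rhs <- drop(crossprod(X, y))
  bvec <- rep(0, ncol(X))
  r <- rhs - amul(bvec); p <- r
  rs <- sum(r * r)
  for (it in seq_len(10 * ncol(X))) {
    Ap <- amul(p)
    alpha <- rs / sum(p * Ap)
    bvec <- bvec + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (rs_new < 1e-24) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  bvec
}

# Brute-force Moran's I: explicit double sum over the full weight matrix.
moran_double_sum <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Multinomial log-likelihood of a proportional-odds model at (beta, zeta).
polr_loglik <- function(beta, zeta, x, y_int) {
  eta <- as.matrix(x) %*% beta
  k <- length(zeta) + 1
  cum <- cbind(matrix(stats::plogis(rep(zeta, each = nrow(eta)) -
                                      as.vector(eta)), nrow(eta)), 1)
  pr <- cbind(cum[, 1], cum[, -1, drop = FALSE] -
                cum[, -ncol(cum), drop = FALSE])
  sum(log(pmax(pr[cbind(seq_along(y_int), y_int)], 1e-300)))
}

# Small deterministic germination record builders.
make_record <- function(counts, days = seq_along(counts), seeds = 25,
                        treatment = "T25_15", id = "A1", rep = 1) {
  germination_record(id, treatment, rep, days, counts, seeds)
}

logistic_counts <- function(seeds = 25, p = 0.8, mid = 10, rate = 0.6,
                            days = 1:28, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- seeds * p * stats::plogis(rate * (days - mid))
  y <- mu + stats::rnorm(length(days), 0, noise_sd)
  y <- cummax(pmin(pmax(round(y), 0), seeds))
  y
}
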