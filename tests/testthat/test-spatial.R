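test_that("haversine distances: zero, half great circle, symmetry", {
  co <- data.frame(lon = c(0, 0, 180), lat = c(0, 0, 0))
  d <- haversine_distances(co)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], pi * 6371.0088, tolerance = 1e-6)
  set.seed(2)
  co2 <- data.frame(lon = runif(8, -30, 40), lat = runif(8, 20, 60))
  d2 <- haversine_distances(co2)
  expect_equal(d2, t(d2))
  expect_true(all(diag(d2) == 0))
  expect_error(haversine_distances(data.frame(lon = 0, lat = 95)),
               "out of range")
})

test_that("equal-frequency distance classes match a sort-and-slice oracle", {
  set.seed(12)
  co <- data.frame(lon = runif(12, 0, 20), lat = runif(12, 30, 45))
  d <- haversine_distances(co)
  cls <- make_distance_classes(d, n_classes = 10)
  dv <- d[lower.tri(d)]
  expect_equal(cls$breaks,
               unname(quantile(dv, probs = seq(0, 1, length.out = 11))))
  # 66 pairs over 10 classes: 6 or 7 per class
  expect_true(all(cls$pair_counts %in% 6:7))
  expect_equal(sum(cls$pair_counts), 66)
  # collinear equally spaced points: strictly increasing boundaries
  co3 <- data.frame(lon = seq(0, 9), lat = rep(0, 10))
  cls3 <- make_distance_classes(haversine_distances(co3), n_classes = 5)
  expect_true(all(diff(cls3$breaks) > 0))
  # 45 distinct pairwise distances over 10 classes: 4 or 5 per class
  set.seed(71)
  co4 <- data.frame(lon = runif(10, 0, 20), lat = runif(10, 30, 45))
  cls45 <- make_distance_classes(haversine_distances(co4), n_classes = 10,
                                 exclude_largest = FALSE)
  expect_true(all(cls45$pair_counts %in% 4:5))
  # tied distances trigger class merging with a warning
  expect_warning(make_distance_classes(haversine_distances(co3),
                                       n_classes = 10), "merged")
})

test_that("Moran's I equals the brute-force double sum and its analytic expectation", {
  # 1-D transect, alternating +/-1, adjacent-pair weights: hand case
  n <- 6
  co <- data.frame(lon = seq_len(n), lat = rep(0, n))
  vals <- rep(c(1, -1), 3)
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  i_brute <- moran_double_sum(vals, W)
  pairs <- cbind(1:(n - 1), 2:n)
  expect_equal(seedfda:::morans_i_pairs(vals - mean(vals), pairs, n), i_brute)
  expect_equal(i_brute, -1)               # perfect alternation on a transect
  # expectation -1/(n-1): n = 11 -> -0.1; check the correlogram reports it
  set.seed(5)
  co11 <- data.frame(lon = runif(11), lat = runif(11))
  cls <- make_distance_classes(haversine_distances(co11), n_classes = 3,
                               exclude_largest = FALSE)
  cg <- morans_i_correlogram(rnorm(11), cls, n_permutations = 49)
  expect_equal(unique(cg$classes$expectation), -0.1)
})

test_that("per-class Moran's I matches the brute-force double sum on random fields", {
  set.seed(33)
  co <- data.frame(lon = runif(15, 0, 10), lat = runif(15, 40, 50))
  d <- haversine_distances(co)
  cls <- make_distance_classes(d, n_classes = 4, exclude_largest = FALSE)
  vals <- rnorm(15)
  cg <- morans_i_correlogram(vals, cls, n_permutations = 49)
  for (cc in 1:4) {
    W <- (cls$class_matrix == cc) * 1
    W[is.na(W)] <- 0
    diag(W) <- 0
    expect_equal(cg$classes$moran_i[cc], moran_double_sum(vals, W),
                 tolerance = 1e-12)
  }
})

test_that("correlogram is centering-invariant and its verdict monotone in alpha", {
  set.seed(44)
  co <- data.frame(lon = runif(20, 0, 15), lat = runif(20, 35, 45))
  cls <- make_distance_classes(haversine_distances(co), n_classes = 5)
  v <- rnorm(20)
  set.seed(99); cg1 <- morans_i_correlogram(v, cls, n_permutations = 99)
  set.seed(99); cg2 <- morans_i_correlogram(v + 100, cls, n_permutations = 99)
  expect_equal(cg1$classes$moran_i, cg2$classes$moran_i)
  expect_equal(cg1$classes$p_value, cg2$classes$p_value)
  pmin_tested <- min(cg1$classes$p_value[cg1$classes$tested])
  k <- sum(cg1$classes$tested)
  strict <- morans_i_correlogram(v, cls, alpha = pmin_tested * k * 0.99,
                                 n_permutations = 99)
  loose <- morans_i_correlogram(v, cls, alpha = min(1, pmin_tested * k * 1.01),
                                n_permutations = 99)
  expect_true(loose$global_significant || !strict$global_significant)
  expect_error(morans_i_correlogram(rep(1, 20), cls), "constant")
})

test_that("Dutilleul test: exact-zero correlation gives t = 0, p = 1", {
  set.seed(3)
  co <- data.frame(lon = runif(10, 0, 5), lat = runif(10, 40, 44))
  x <- rnorm(10)
  y0 <- rnorm(10)
  y <- residuals(lm(y0 ~ x))          # cor(x, y) == 0 exactly
  dt <- dutilleul_modified_t(x, y, coords = co)
  expect_lt(abs(dt$t), 1e-10)
  expect_equal(dt$p_corrected, 1, tolerance = 1e-8)
})

test_that("Dutilleul effective sample size is near n for white noise and below n under shared autocorrelation", {
  set.seed(77)
  n <- 50
  co <- data.frame(lon = runif(n, 0, 10), lat = runif(n, 35, 45))
  d <- haversine_distances(co)
  cls <- make_distance_classes(d, exclude_largest = FALSE)
  neff_white <- replicate(60, {
    dutilleul_modified_t(rnorm(n), rnorm(n), classes = cls)$n_eff
  })
  expect_lt(abs(mean(neff_white) - n) / n, 0.10)
  # shared strong exponential autocorrelation, range = half extent
  L <- chol(exp(-d / (max(d) / 2)) + diag(1e-8, n))
  neff_auto <- replicate(60, {
    dutilleul_modified_t(drop(crossprod(L, rnorm(n))),
                         drop(crossprod(L, rnorm(n))), classes = cls)$n_eff
  })
  expect_lt(mean(neff_auto), n)
})

test_that("PCNM eigenvectors are centered, orthogonal, and match a dense eigensolver", {
  set.seed(21)
  co <- data.frame(lon = runif(15, 0, 10), lat = runif(15, 40, 48))
  p <- pcnm_eigenvectors(co)
  v <- p$vectors
  expect_lt(max(abs(colMeans(v))), 1e-10)
  g <- crossprod(v)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # oracle: explicit truncated-distance PCoA
  d <- haversine_distances(co)
  thr <- p$truncation
  dt <- d; dt[dt > thr] <- 4 * thr
  A <- -0.5 * dt^2
  n <- nrow(A)
  B <- (diag(n) - matrix(1 / n, n, n)) %*% A %*% (diag(n) - matrix(1 / n, n, n))
  ev <- eigen(B, symmetric = TRUE)$values
  expect_equal(p$values, ev[seq_along(p$values)], tolerance = 1e-8)
  # eigenvector count + non-positive count = n - 1
  expect_equal(length(p$values) + sum(ev < max(ev) * 1e-10) - 1, n - 1)
})

test_that("PCNMs on a regular transect are wave-ordered by sign changes", {
  co <- data.frame(lon = seq(0, 19), lat = rep(45, 20))
  p <- pcnm_eigenvectors(co)
  sign_changes <- unname(apply(p$vectors, 2,
                               function(v) sum(diff(sign(v)) != 0)))
  expect_equal(sign_changes[1], 1)
  expect_true(all(diff(sign_changes) >= 0))
  expect_error(pcnm_eigenvectors(data.frame(lon = rep(1, 5), lat = rep(2, 5))),
               "identical")
})

test_that("buffer means handle constant, mixed and masked rasters", {
  # ~0.01 deg cells near the equator: cell ~1.1 km
  m <- matrix(7, 10, 10)
  s <- suitability_surface(m, 0, 0, 0.01)
  expect_equal(buffer_mean_extract(s, 0.05, 0.05, radius_km = 3), 7)
  # 1-row strip: 3 cells valued 1,2,3 within radius -> 2
  s2 <- suitability_surface(matrix(c(1, 2, 3), 1, 3), 0, 0, 0.01)
  expect_equal(buffer_mean_extract(s2, 0.015, 0.005, radius_km = 2), 2)
  # masked cell excluded: values 4, NA, 6 -> 5
  s3 <- suitability_surface(matrix(c(4, NA, 6), 1, 3), 0, 0, 0.01)
  expect_equal(buffer_mean_extract(s3, 0.015, 0.005, radius_km = 2), 5)
  expect_error(buffer_mean_extract(s, 5, 5), "extent")
  s4 <- suitability_surface(matrix(NA_real_, 3, 3), 0, 0, 0.01)
  expect_error(buffer_mean_extract(s4, 0.015, 0.015, radius_km = 1), "empty buffer")
})

test_that("ESRI ASCII grids round-trip including no-data cells", {
  set.seed(6)
  m <- matrix(round(runif(12), 3), 3, 4)
  m[2, 3] <- NA
  s <- suitability_surface(m, -5.25, 40, 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(s, path)
  s2 <- read_ascii_grid(path)
  expect_equal(s2$values, m)
  expect_equal(s2$xll, -5.25)
  expect_equal(s2$yll, 40)
  expect_equal(s2$cellsize, 0.5)
})
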