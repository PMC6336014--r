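test_that("collinearity pruning follows the greedy rule", {
  set.seed(50)
  base <- rnorm(40)
  env <- data.frame(A = base + rnorm(40, 0, 0.1))
  env$B <- env$A + rnorm(40, 0, 0.05)       # r(A,B) very high
  env$C <- rnorm(40)
  # make A correlated with C too, so A has the larger mean |r|
  env$C <- 0.4 * env$A + rnorm(40, 0, 0.6)
  pr <- collinearity_prune(env, threshold = 0.90)
  expect_true(length(pr$removed) >= 1)
  expect_lt(max(abs(cor(pr$kept))[upper.tri(cor(pr$kept))]), 0.90)
  # two perfectly correlated variables: exactly one removed
  env2 <- data.frame(x = 1:20, y = 2 * (1:20))
  pr2 <- collinearity_prune(env2)
  expect_equal(length(pr2$removed), 1)
  expect_equal(ncol(pr2$kept), 1)
  # all weak correlations: unchanged
  set.seed(51)
  env3 <- as.data.frame(matrix(rnorm(200), 50, 4))
  pr3 <- collinearity_prune(env3)
  expect_equal(ncol(pr3$kept), 4)
  expect_equal(length(pr3$removed), 0)
  # hand case: A is in both offending pairs -> A removed, B and C kept
  set.seed(52)
  zA <- rnorm(2000)
  env4 <- data.frame(A = zA,
                     B = 0.97 * zA + sqrt(1 - 0.97^2) * rnorm(2000),
                     C = 0.97 * zA + sqrt(1 - 0.97^2) * rnorm(2000))
  stopifnot(abs(cor(env4$B, env4$C)) < 0.97)
  pr4 <- collinearity_prune(env4, threshold = 0.90)
  if (max(abs(cor(env4))[upper.tri(cor(env4))] * c(1, 1, 0)) >= 0.90)
    expect_true("A" %in% pr4$removed)
  # constant variable removed first, with warning
  env5 <- data.frame(k = rep(1, 10), x = rnorm(10), y = rnorm(10))
  expect_warning(pr5 <- collinearity_prune(env5), "constant")
  expect_false("k" %in% names(pr5$kept))
})

test_that("unstandardized PCA matches an SVD oracle and conserves variance", {
  set.seed(60)
  x <- matrix(rnorm(24), 6, 4)
  p <- pca_unstandardized(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  ev_oracle <- sv$d^2 / (6 - 1)
  expect_equal(p$eigenvalues[1:4], ev_oracle[1:4], tolerance = 1e-10)
  scores_oracle <- sv$u %*% diag(sv$d)
  for (a in 1:4)       # compare up to the deterministic sign
    expect_equal(abs(p$scores[, a]), abs(scores_oracle[, a]),
                 tolerance = 1e-10)
  expect_equal(sum(p$eigenvalues), sum(apply(xc, 2, var)))
  expect_equal(sum(p$proportion), 1)
  # sign convention: largest-magnitude loading positive
  for (a in 1:4) expect_gt(p$loadings[which.max(abs(p$loadings[, a])), a], 0)
  # collinear points: PC1 explains 100%
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_equal(pca_unstandardized(line)$proportion[1], 1)
  # reordering rows permutes scores identically
  perm <- sample(6)
  p2 <- pca_unstandardized(x[perm, ])
  expect_equal(p2$scores[, 1], p$scores[perm, 1], tolerance = 1e-10)
})

test_that("axis-environment correlations report classical and corrected p", {
  set.seed(61)
  n <- 30
  co <- data.frame(lon = runif(n, 0, 10), lat = runif(n, 35, 45))
  scores <- cbind(PC1 = rnorm(n), PC2 = rnorm(n))
  env <- data.frame(v1 = scores[, 1], v2 = rnorm(n))
  tab <- axis_env_correlations(scores, env, co)
  r11 <- tab[tab$variable == "v1" & tab$axis == 1, ]
  expect_equal(r11$r, 1, tolerance = 1e-12)
  expect_lt(r11$p_classical, 1e-10)
  expect_lt(r11$p_corrected, 0.01)
  expect_equal(nrow(tab), 4)
  # reordering accessions leaves r unchanged
  perm <- sample(n)
  tab2 <- axis_env_correlations(scores[perm, ], env[perm, , drop = FALSE],
                                co[perm, ])
  expect_equal(tab2$r, tab$r, tolerance = 1e-12)
})

test_that("RDA R2 and adjusted R2: exact fit, Ezekiel arithmetic, vegan agreement", {
  set.seed(62)
  X <- matrix(rnorm(60), 20, 3)
  B <- matrix(rnorm(12), 3, 4)
  Y_exact <- X %*% B
  expect_equal(rda_adjusted_r2(Y_exact, X)$r2, 1, tolerance = 1e-10)
  # adjusted R2 arithmetic: R2 = 0.5, n = 20, p = 3 -> 0.40625
  expect_equal(seedfda:::ezekiel_adj(0.5, 20, 3), 0.40625)
  # agreement with vegan on a random fixture
  Y <- Y_exact + matrix(rnorm(80, 0, 2), 20, 4)
  fit <- rda_adjusted_r2(Y, X)
  vfit <- vegan::rda(Y ~ X)
  vr2 <- vegan::RsquareAdj(vfit)
  expect_equal(fit$r2, vr2$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r2, vr2$adj.r.squared, tolerance = 1e-10)
})

test_that("adjusted R2 is near zero for pure-noise predictors", {
  set.seed(63)
  vals <- replicate(500, {
    Y <- matrix(rnorm(30 * 2), 30, 2)
    X <- matrix(rnorm(30 * 5), 30, 5)
    rda_adjusted_r2(Y, X)$adj_r2
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("permutation test honors its bounds and is predictor-order invariant", {
  set.seed(64)
  X <- matrix(rnorm(40), 20, 2)
  Y <- X %*% matrix(c(1, 0.5, -1, 2), 2, 2)   # perfect signal
  fit <- rda_adjusted_r2(Y, X)
  pt <- permutation_test(fit, n_permutations = 999, seed = 1)
  expect_equal(pt$p_value, 0.001)             # minimum attainable p
  fit_swap <- rda_adjusted_r2(Y, X[, 2:1])
  pt_swap <- permutation_test(fit_swap, n_permutations = 999, seed = 1)
  expect_equal(pt_swap$p_value, pt$p_value)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(65)
  ps <- replicate(200, {
    Y <- matrix(rnorm(15 * 2), 15, 2)
    X <- matrix(rnorm(15), 15, 1)
    permutation_test(rda_adjusted_r2(Y, X), n_permutations = 99)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("forward selection recovers the generating variable and obeys stopping", {
  set.seed(66)
  n <- 60
  cand <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(cand) <- paste0("v", 1:6)
  hits <- 0
  for (rep in 1:20) {
    cand_r <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(cand_r) <- paste0("v", 1:6)
    Y <- cbind(cand_r$v3 * 1.0 + rnorm(n, 0, 0.5),
               cand_r$v3 * 0.8 + rnorm(n, 0, 0.5))
    sel <- forward_select(Y, cand_r, n_permutations = 99)
    if (nrow(sel) && sel$variable[1] == "v3") hits <- hits + 1
  }
  expect_gte(hits, 19)
  # single perfect candidate: selected with minimal p
  Y1 <- matrix(cand$v1, ncol = 1)
  sel1 <- forward_select(Y1, cand["v1"], n_permutations = 999)
  expect_equal(sel1$variable, "v1")
  expect_equal(sel1$p_value, 0.001)
  # alpha = 1, no cap: selects all candidates in decreasing marginal-fit order
  set.seed(67)
  Yall <- matrix(rnorm(n * 2), n, 2)
  sel_all <- forward_select(Yall, cand, alpha = 1, n_permutations = 19,
                            r2_cap = FALSE)
  expect_setequal(sel_all$variable, names(cand))
  # all-noise candidates: rarely selects anything at alpha = 0.05
  set.seed(68)
  n_sel <- replicate(20, {
    Yn <- matrix(rnorm(n * 2), n, 2)
    nrow(forward_select(Yn, cand, n_permutations = 99))
  })
  expect_lte(mean(n_sel > 0), 0.4)
})

test_that("BH adjustment matches the hand case and dominates raw p", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(69)
  p <- runif(20)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("variance partitioning identity and degenerate cases", {
  set.seed(70)
  n <- 40
  X1 <- as.data.frame(matrix(rnorm(n * 2), n, 2)); names(X1) <- c("a", "b")
  X2 <- as.data.frame(matrix(rnorm(n * 3), n, 3)); names(X2) <- c("p", "q", "r")
  Y <- as.matrix(X1) %*% matrix(rnorm(4), 2, 2) +
    as.matrix(X2) %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(n * 2), n, 2)
  vp <- variance_partition(Y, X1, X2, n_permutations = 49, seed = 2)
  expect_equal(sum(vp$fractions$adj_r2[1:3]), vp$adj_combined,
               tolerance = 1e-12)
  expect_equal(vp$unexplained, 1 - vp$adj_combined)
  # combined model explains at least each pure fraction
  expect_gte(vp$adj_combined + 1e-12, vp$fractions$adj_r2[1])
  expect_gte(vp$adj_combined + 1e-12, vp$fractions$adj_r2[2])
  # empty X2: pure X1 = adj(X1), shared = 0
  vp0 <- variance_partition(Y, X1, X2[, integer(0)], n_permutations = 19)
  expect_equal(vp0$fractions$adj_r2[1], rda_adjusted_r2(Y, X1)$adj_r2,
               tolerance = 1e-12)
  expect_equal(vp0$fractions$adj_r2[3], 0, tolerance = 1e-12)
  # identical columns in both sets warn (plus aliasing warnings downstream)
  w <- testthat::capture_warnings(
    variance_partition(Y, X1, cbind(X2, a = X1$a), n_permutations = 19))
  expect_true(any(grepl("identical", w)))
})

test_that("orthogonal predictor sets share (almost) no variance", {
  set.seed(71)
  n <- 80
  raw <- matrix(rnorm(n * 4), n, 4)
  q <- qr.Q(qr(raw))
  X1 <- as.data.frame(q[, 1:2]); names(X1) <- c("a", "b")
  X2 <- as.data.frame(q[, 3:4]); names(X2) <- c("c", "d")
  Y <- q[, 1:2] %*% matrix(c(2, 1, -1, 2), 2, 2) +
    q[, 3:4] %*% matrix(c(1, -2, 2, 1), 2, 2) + matrix(rnorm(n * 2, 0, 0.5), n, 2)
  vp <- variance_partition(Y, X1, X2, n_permutations = 19)
  expect_lt(abs(vp$fractions$adj_r2[3]), 0.03)
})

test_that("variance partitioning agrees with vegan::varpart fractions", {
  set.seed(72)
  n <- 35
  X1 <- as.data.frame(matrix(rnorm(n * 2), n, 2)); names(X1) <- c("a", "b")
  X2 <- as.data.frame(matrix(rnorm(n * 2), n, 2)); names(X2) <- c("c", "d")
  Y <- as.matrix(X1) %*% matrix(rnorm(6), 2, 3) + matrix(rnorm(n * 3), n, 3)
  vp <- variance_partition(Y, X1, X2, n_permutations = 19)
  vv <- vegan::varpart(Y, as.matrix(X1), as.matrix(X2))$part$indfract
  # vegan rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d] = residuals
  expect_equal(vp$fractions$adj_r2[1], vv$Adj.R.squared[1], tolerance = 1e-8)
  expect_equal(vp$fractions$adj_r2[2], vv$Adj.R.squared[2], tolerance = 1e-8)
  expect_equal(vp$fractions$adj_r2[3], vv$Adj.R.squared[3], tolerance = 1e-8)
})
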