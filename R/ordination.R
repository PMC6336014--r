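#' Greedy collinearity pruning
#'
#' Removes environmental variables until no pair exceeds the absolute
#' Pearson correlation threshold (default |r| >= 0.90). At each step the
#' worst offending pair is found and the member with the larger mean
#' absolute correlation to all other remaining variables is dropped.
#' Constant variables (undefined correlations) are removed first with a
#' warning. Every removal is logged with the triggering pair.
#'
#' @param env data frame or matrix, variables in columns.
#' @param threshold absolute correlation threshold (default 0.90).
#' @return List: `kept` (reduced data frame), `removed` (character),
#'   `log` (data frame: `removed`, `against`, `r`).
#' @export
collinearity_prune <- function(env, threshold = 0.90) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) stop("need at least 2 variables", call. = FALSE)
  log <- data.frame(removed = character(), against = character(),
                    r = numeric(), stringsAsFactors = FALSE)
  const <- names(env)[vapply(env, function(v) stats::var(v) == 0, logical(1))]
  if (length(const)) {
    warning("constant variable(s) removed: ", paste(const, collapse = ", "),
            call. = FALSE)
    log <- rbind(log, data.frame(removed = const, against = NA_character_,
                                 r = NA_real_))
    env <- env[, setdiff(names(env), const), drop = FALSE]
  }
  repeat {
    if (ncol(env) < 2) break
    cm <- abs(stats::cor(env))
    diag(cm) <- 0
    if (max(cm) < threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- colnames(cm)[worst]
    # drop the pair member with the larger mean |r| to all other variables
    cma <- abs(stats::cor(env)); diag(cma) <- NA
    mean_abs <- rowMeans(cma[pair, , drop = FALSE], na.rm = TRUE)
    drop_var <- pair[which.max(mean_abs)]
    log <- rbind(log, data.frame(removed = drop_var,
                                 against = setdiff(pair, drop_var)[1],
                                 r = stats::cor(env[[pair[1]]], env[[pair[2]]])))
    env <- env[, setdiff(names(env), drop_var), drop = FALSE]
  }
  list(kept = env, removed = log$removed, log = log)
}

#' Unstandardized (covariance) PCA
#'
#' Column-centered, unscaled PCA of a descriptor matrix (the B-spline
#' coefficient matrix in the reference workflow; coefficients share a
#' common seed-count scale so no standardization is applied). Axis signs
#' follow a deterministic convention: each axis is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param x numeric matrix, accessions in rows.
#' @return Object of class `"ordination_result"`: `scores`, `loadings`,
#'   `eigenvalues`, `proportion` (variance share per axis).
#' @export
pca_unstandardized <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 accessions and >= 2 descriptors", call. = FALSE)
  if (any(!is.finite(x))) stop("missing values in descriptor matrix", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop("descriptor matrix has rank 0", call. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2
  structure(list(scores = scores, loadings = loadings, eigenvalues = ev,
                 proportion = ev / sum(ev)),
            class = "ordination_result")
}

#' Correlations of environmental variables with ordination axes
#'
#' Per variable x axis: Pearson r, the classical t-test p-value, and the
#' spatially corrected p-value from [dutilleul_modified_t()]. Used to
#' screen supplementary variables against the germination-responsivity
#' axes while accounting for shared spatial structure.
#'
#' @param scores matrix/data frame of axis scores, rownames = accession ids.
#' @param env data frame of environmental variables, same accession order
#'   (rownames checked when present on both).
#' @param coords lon/lat coordinates in the same order.
#' @param axes which axes to report (default first two).
#' @return Data frame: `variable`, `axis`, `r`, `p_classical`,
#'   `p_corrected`, `n_eff`.
#' @export
axis_env_correlations <- function(scores, env, coords, axes = 1:2) {
  scores <- as.matrix(scores)
  env <- as.data.frame(env)
  if (nrow(env) != nrow(scores))
    stop("scores and env have different numbers of accessions", call. = FALSE)
  if (!is.null(rownames(scores)) && !is.null(rownames(env)) &&
      !all(rownames(scores) == rownames(env))) {
    bad <- rownames(scores)[rownames(scores) != rownames(env)]
    stop("mismatched accession ids: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  classes <- make_distance_classes(haversine_distances(coords),
                                   exclude_largest = FALSE)
  axes <- intersect(axes, seq_len(ncol(scores)))
  out <- list()
  for (v in names(env)) for (a in axes) {
    dt <- dutilleul_modified_t(env[[v]], scores[, a], classes = classes)
    out[[length(out) + 1]] <- data.frame(
      variable = v, axis = a, r = dt$r, p_classical = dt$p_classical,
      p_corrected = dt$p_corrected, n_eff = dt$n_eff,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Center Y, optionally residualize Y and X on covariates, drop aliased
## X columns; shared low-level step for the RDA machinery.
rda_prepare <- function(Y, X, covariates = NULL) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- as.matrix(X)
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    qz <- qr(Z)
    Y <- qr.resid(qz, Y)
    X <- qr.resid(qz, X)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("dropping aliased predictor column(s): ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
    qx <- qr(X)
  }
  list(Y = Y, X = X, qx = qx)
}

ezekiel_adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Redundancy analysis with adjusted R-squared
#'
#' RDA as multivariate least squares: the centered response matrix is
#' projected on the predictor space (after residualizing both on
#' covariates, when given: partial RDA) and the explained share of total
#' variance is reported raw and Ezekiel-adjusted,
#' adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1), the unbiased estimator of
#' explained variation. Canonical axes are the principal components of
#' the fitted values.
#'
#' @param Y response matrix (accessions x descriptors).
#' @param X predictor matrix/data frame.
#' @param covariates optional conditioning matrix (partial RDA).
#' @return Object of class `"rda_fit"`: `r2`, `adj_r2`, `f_statistic`,
#'   `df`, canonical `axes` (site scores), `eigenvalues`, and the
#'   prepared matrices for permutation testing.
#' @export
rda_adjusted_r2 <- function(Y, X, covariates = NULL) {
  n <- nrow(as.matrix(Y))
  prep <- rda_prepare(Y, X, covariates)
  p <- prep$qx$rank
  q <- if (is.null(covariates)) 0 else qr(cbind(1, as.matrix(covariates)))$rank - 1
  fitted <- qr.fitted(prep$qx, prep$Y)
  ss_tot <- sum(prep$Y^2)
  ss_fit <- sum(fitted^2)
  r2 <- if (ss_tot > 0) ss_fit / ss_tot else 0
  adj <- ezekiel_adj(r2, n - q, p)
  if (n <= p + q + 1)
    warning("n <= p + q + 1; adjusted R2 unreliable", call. = FALSE)
  df2 <- n - p - q - 1
  f <- (ss_fit / p) / ((ss_tot - ss_fit) / df2)
  sv <- svd(fitted)
  keep <- sv$d > 1e-10 * max(sv$d, 1e-300)
  structure(list(r2 = r2, adj_r2 = adj, f_statistic = f, df = c(p, df2),
                 axes = sv$u[, keep, drop = FALSE] %*%
                   diag(sv$d[keep], sum(keep)),
                 eigenvalues = sv$d[keep]^2 / (n - 1),
                 Y = prep$Y, X = prep$X, covariates = covariates, n = n),
            class = "rda_fit")
}

## F statistic of X given already-residualized Y (covariates handled by
## the caller through residualization).
rda_f_stat <- function(Y, qx, n, q) {
  fitted <- qr.fitted(qx, Y)
  ss_fit <- sum(fitted^2); ss_tot <- sum(Y^2)
  p <- qx$rank
  (ss_fit / p) / ((ss_tot - ss_fit) / (n - p - q - 1))
}

#' Monte Carlo permutation test for an RDA fit
#'
#' Permutes rows of the (residualized) response and recomputes the F
#' statistic; for partial models this is the Freedman-Lane scheme,
#' permuting residuals of the reduced (covariates-only) model. The
#' p-value is (1 + #\{F* >= F\}) / (1 + n_permutations).
#'
#' @param fit an [rda_adjusted_r2()] result.
#' @param n_permutations default 999.
#' @param seed optional integer seed for reproducibility.
#' @return List: `p_value`, `f_statistic`, `f_null`.
#' @export
permutation_test <- function(fit, n_permutations = 999, seed = NULL) {
  stopifnot(inherits(fit, "rda_fit"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fit$Y)
  q <- if (is.null(fit$covariates)) 0 else
    qr(cbind(1, as.matrix(fit$covariates)))$rank - 1
  qx <- qr(fit$X)
  f_obs <- rda_f_stat(fit$Y, qx, n, q)
  f_null <- vapply(seq_len(n_permutations), function(i) {
    rda_f_stat(fit$Y[sample.int(n), , drop = FALSE], qx, n, q)
  }, numeric(1))
  list(p_value = (1 + sum(f_null >= f_obs)) / (1 + n_permutations),
       f_statistic = f_obs, f_null = f_null)
}

#' Forward selection of RDA predictors
#'
#' Classic forward selection with the double stopping rule: at each step
#' the candidate with the highest partial F (given variables already in
#' the model) is tested by permutation; selection stops when that test's
#' p-value exceeds `alpha` or when the cumulative adjusted R2 of the
#' selected set exceeds the adjusted R2 of the model with all
#' candidates.
#'
#' @param Y response matrix.
#' @param candidates data frame/matrix of candidate predictors.
#' @param alpha stopping significance level (default 0.05).
#' @param n_permutations permutations per step test (default 999).
#' @param seed optional integer seed.
#' @param r2_cap apply the global adjusted-R2 stopping rule
#'   (default TRUE).
#' @return Data frame, one row per selected variable in order:
#'   `variable`, `f_statistic`, `p_value`, `adj_r2_cum`; zero rows when
#'   nothing is significant.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05,
                           n_permutations = 999, seed = NULL,
                           r2_cap = TRUE) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("need at least 1 candidate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  adj_full <- rda_adjusted_r2(Yc, candidates)$adj_r2
  selected <- character()
  out <- data.frame(variable = character(), f_statistic = numeric(),
                    p_value = numeric(), adj_r2_cum = numeric(),
                    stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    Z <- if (length(selected))
      as.matrix(candidates[, selected, drop = FALSE]) else NULL
    # residualize response and candidates on current model
    if (is.null(Z)) {
      Yr <- Yc
      resid_fun <- function(v) v - mean(v)
    } else {
      qz <- qr(cbind(1, Z))
      Yr <- qr.resid(qz, Yc)
      resid_fun <- function(v) qr.resid(qz, v)
    }
    q <- length(selected)
    stats_rem <- vapply(remaining, function(v) {
      xr <- resid_fun(candidates[[v]])
      if (sum(xr^2) < 1e-12) return(-Inf)
      rda_f_stat(Yr, qr(matrix(xr)), n, q)
    }, numeric(1))
    best <- remaining[which.max(stats_rem)]
    f_obs <- stats_rem[best]
    if (!is.finite(f_obs)) break
    xr <- matrix(resid_fun(candidates[[best]]))
    qxr <- qr(xr)
    f_null <- vapply(seq_len(n_permutations), function(i)
      rda_f_stat(Yr[sample.int(n), , drop = FALSE], qxr, n, q), numeric(1))
    p <- (1 + sum(f_null >= f_obs)) / (1 + n_permutations)
    if (p > alpha) break
    selected <- c(selected, best)
    adj_cum <- rda_adjusted_r2(Yc,
                               candidates[, selected, drop = FALSE])$adj_r2
    out <- rbind(out, data.frame(variable = best, f_statistic = f_obs,
                                 p_value = p, adj_r2_cum = adj_cum,
                                 stringsAsFactors = FALSE))
    if (r2_cap && adj_cum > adj_full) break
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pure and shared variance partitioning between two predictor sets
#'
#' Partitions the adjusted explained variation of a response matrix
#' between an environmental set X1 and a spatial (PCNM) set X2:
#' pure(X1) = adj(X1 u X2) - adj(X2), symmetrically for X2, and
#' shared = adj(X1) + adj(X2) - adj(X1 u X2); the identity
#' pure1 + pure2 + shared = adj(X1 u X2) holds exactly. The pure
#' fractions are testable by partial-RDA permutation (Freedman-Lane);
#' the shared fraction is not permutable and is reported untested.
#'
#' @param Y response matrix.
#' @param X1,X2 the two predictor sets.
#' @param n_permutations permutations for the pure-fraction tests.
#' @param seed optional integer seed.
#' @return Object of class `"partition_result"`: `fractions` data frame
#'   (`fraction`, `adj_r2`, `df`, `f_statistic`, `p_value`),
#'   `adj_combined`, `unexplained`.
#' @export
variance_partition <- function(Y, X1, X2, n_permutations = 999, seed = NULL) {
  X1 <- as.data.frame(X1); X2 <- as.data.frame(X2)
  if (nrow(X1) != nrow(as.matrix(Y)) || nrow(X2) != nrow(as.matrix(Y)))
    stop("Y, X1, X2 must share the same accessions", call. = FALSE)
  shared_cols <- intersect(names(X1), names(X2))
  if (length(shared_cols) &&
      any(vapply(shared_cols, function(v) identical(X1[[v]], X2[[v]]),
                 logical(1))))
    warning("X1 and X2 share identical column(s): ",
            paste(shared_cols, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  empty1 <- ncol(X1) == 0; empty2 <- ncol(X2) == 0
  adj1 <- if (empty1) 0 else rda_adjusted_r2(Y, X1)$adj_r2
  adj2 <- if (empty2) 0 else rda_adjusted_r2(Y, X2)$adj_r2
  Xb <- cbind(X1, X2)
  adj12 <- if (ncol(Xb) == 0) 0 else rda_adjusted_r2(Y, Xb)$adj_r2
  pure1 <- adj12 - adj2
  pure2 <- adj12 - adj1
  shared <- adj1 + adj2 - adj12
  test_pure <- function(X, Z) {
    if (ncol(X) == 0 || ncol(Z) == 0) {
      f <- if (ncol(X)) rda_adjusted_r2(Y, X) else NULL
      if (is.null(f)) return(c(NA, NA, NA))
      pt <- permutation_test(f, n_permutations)
      return(c(f$df[1], pt$f_statistic, pt$p_value))
    }
    f <- rda_adjusted_r2(Y, X, covariates = Z)
    pt <- permutation_test(f, n_permutations)
    c(f$df[1], pt$f_statistic, pt$p_value)
  }
  t1 <- if (empty1) c(NA, NA, NA) else test_pure(X1, X2)
  t2 <- if (empty2) c(NA, NA, NA) else test_pure(X2, X1)
  fractions <- data.frame(
    fraction = c("pure_X1", "pure_X2", "shared", "unexplained"),
    adj_r2 = c(pure1, pure2, shared, 1 - adj12),
    df = c(t1[1], t2[1], NA, NA),
    f_statistic = c(t1[2], t2[2], NA, NA),
    p_value = c(t1[3], t2[3], NA, NA),
    stringsAsFactors = FALSE)
  structure(list(fractions = fractions, adj_combined = adj12,
                 adj_X1 = adj1, adj_X2 = adj2,
                 unexplained = 1 - adj12),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Variance partitioning (Ezekiel-adjusted R2)\n")
  print(x$fractions, digits = 4)
  cat(sprintf("Combined adjusted R2: %.4f\n", x$adj_combined))
  invisible(x)
}
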