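#' Kruskal-Wallis rank test across dormancy categories
#'
#' Rank-based H statistic with tie correction, referred to a chi-square
#' distribution with k - 1 df; the standard test for seed-coat (testa)
#' thickness differences between dormancy categories.
#'
#' @param values numeric trait values.
#' @param groups group labels (factor or character), one per value.
#' @return List: `h_statistic`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups lengths differ", call. = FALSE)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  if (length(unique(values)) == 1)   # fully tied sample: no evidence, H = 0
    return(list(h_statistic = 0, df = nlevels(groups) - 1, p_value = 1,
                n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  list(h_statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Distribution-free confidence interval for a median
#'
#' Binomial order-statistic interval: the (conservative) central
#' interval whose order-statistic coverage is at least `conf`.
#'
#' @param x numeric sample.
#' @param conf coverage (default 0.95).
#' @return Named vector `median`, `lower`, `upper`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) return(c(median = stats::median(x), lower = NA, upper = NA))
  alpha <- 1 - conf
  lo <- stats::qbinom(alpha / 2, n, 0.5)
  lo <- max(lo, 1)
  hi <- n - lo + 1
  c(median = stats::median(x), lower = x[lo], upper = x[hi])
}

#' Proportional-odds ordinal logistic regression with AIC comparison
#'
#' Fits proportional-odds models of an ordered dormancy response
#' (D < R < N, increasing germination propensity) on seed-morphology
#' covariates by maximum likelihood, one fit per formula in
#' `model_set`, and ranks them by AIC. Wald z-tests are reported per
#' coefficient. With a two-level response the model collapses to binary
#' logistic regression and is fitted as such.
#'
#' @param response ordered factor (or values coercible to one via
#'   `levels`).
#' @param covariates data frame of covariates.
#' @param model_set list of RHS formulas (default: one simple model per
#'   covariate plus the full additive model).
#' @param levels response ordering used when `response` is not already
#'   an ordered factor (default `c("D", "R", "N")`).
#' @return Object of class `"ordinal_fits"`: `fits` (list with
#'   `coefficients`, `se`, `z`, `p_value`, `logLik`, `aic`, `formula`),
#'   `aic_table` ranked by AIC.
#' @export
ordinal_logistic <- function(response, covariates,
                             model_set = NULL, levels = c("D", "R", "N")) {
  covariates <- as.data.frame(covariates)
  if (!is.ordered(response))
    response <- factor(response, levels = levels, ordered = TRUE)
  response <- droplevels(response)
  if (any(is.na(response)) || anyNA(covariates))
    stop("missing response or covariate values", call. = FALSE)
  if (nlevels(response) < 2)
    stop("response needs at least 2 observed levels", call. = FALSE)
  if (is.null(model_set)) {
    model_set <- lapply(names(covariates), function(v)
      stats::as.formula(paste("response ~", v)))
    if (ncol(covariates) > 1)
      model_set <- c(model_set, stats::as.formula(
        paste("response ~", paste(names(covariates), collapse = " + "))))
  }
  dat <- cbind(response = response, covariates)
  fit_one <- function(fm) {
    if (nlevels(response) == 2) {
      dat2 <- dat; dat2$response <- as.integer(dat2$response) - 1L
      g <- stats::glm(fm, family = stats::binomial(), data = dat2)
      cf <- stats::coef(g)[-1]; se <- sqrt(diag(stats::vcov(g)))[-1]
      ll <- as.numeric(stats::logLik(g)); aic <- stats::AIC(g)
      conv <- g$converged
      zeta <- stats::coef(g)[1]
    } else {
      g <- tryCatch(
        MASS::polr(fm, data = dat, method = "logistic", Hess = TRUE),
        error = function(e)
          stop("proportional-odds fit failed (possible complete separation): ",
               conditionMessage(e), call. = FALSE))
      cf <- stats::coef(g)
      se <- sqrt(diag(stats::vcov(g)))[seq_along(cf)]
      ll <- as.numeric(stats::logLik(g)); aic <- stats::AIC(g)
      conv <- g$convergence == 0
      zeta <- g$zeta
      if (any(!is.finite(se)) || any(se > 1e3))
        warning("very large standard errors; possible complete separation",
                call. = FALSE)
    }
    z <- cf / se
    list(formula = fm, coefficients = cf, se = se, z = z,
         p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         thresholds = zeta, logLik = ll, aic = aic, converged = conv)
  }
  fits <- lapply(model_set, fit_one)
  names(fits) <- vapply(model_set, function(f) deparse(f[[3]]), character(1))
  aic_table <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) length(f$coefficients), numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE)
  aic_table <- aic_table[order(aic_table$aic), ]
  structure(list(fits = fits, aic_table = aic_table),
            class = "ordinal_fits")
}

#' AN(C)OVA of the soluble/insoluble proanthocyanidin ratio
#'
#' Compares the sPA/inPA ratio across dormancy categories with and
#' without the total proanthocyanidin content as a covariate:
#' `ratio ~ category + total` (ANCOVA, type-III F by default) and
#' `ratio ~ category` (ANOVA). Least-squares adjusted category means are
#' predictions at the covariate grand mean, with confidence intervals.
#' An optional custom contrast on the LS means (e.g., dormant plus
#' responsive versus non-dormant, weights (1/2, 1/2, -1)) is tested by
#' F.
#'
#' @param ratio numeric sPA/inPA ratio per accession.
#' @param category dormancy category factor.
#' @param total total PA covariate (mg per g dry seed coat).
#' @param contrast optional named numeric vector of contrast weights
#'   over the category levels.
#' @param type `"III"` (default) or `"I"` sums of squares for the
#'   ANCOVA table.
#' @return List: `ancova` (F table), `anova` (covariate-free F table),
#'   `ls_means` (category, estimate, lower, upper), `covariate_f`,
#'   `category_f`, `contrast` (F, p) when requested.
#' @export
ancova_ratio <- function(ratio, category, total, contrast = NULL,
                         type = c("III", "I")) {
  type <- match.arg(type)
  category <- droplevels(factor(category))
  if (nlevels(category) < 2) stop("need at least 2 categories", call. = FALSE)
  if (any(!is.finite(total))) stop("covariate must be finite", call. = FALSE)
  singletons <- names(which(table(category) < 2))
  if (length(singletons))
    warning("category with a single observation: ",
            paste(singletons, collapse = ", "), "; CI suppressed",
            call. = FALSE)
  dat <- data.frame(ratio = ratio, category = category, total = total)
  fit_anc <- stats::lm(ratio ~ category + total, data = dat,
                       contrasts = list(category = "contr.sum"))
  fit_anova <- stats::lm(ratio ~ category, data = dat)
  tab <- if (type == "III") car::Anova(fit_anc, type = "III") else
    stats::anova(fit_anc)
  rn <- rownames(tab)
  category_f <- tab[grep("category", rn), "F value"]
  covariate_f <- tab[grep("total", rn), "F value"]
  category_p <- tab[grep("category", rn), "Pr(>F)"]
  covariate_p <- tab[grep("total", rn), "Pr(>F)"]
  emm <- emmeans::emmeans(fit_anc, "category")
  emm_df <- as.data.frame(emm)
  ls_means <- data.frame(category = emm_df$category,
                         estimate = emm_df$emmean,
                         se = emm_df$SE,
                         lower = emm_df$lower.CL, upper = emm_df$upper.CL)
  if (length(singletons))
    ls_means[ls_means$category %in% singletons, c("lower", "upper")] <- NA
  contrast_res <- NULL
  if (!is.null(contrast)) {
    w <- contrast[as.character(ls_means$category)]
    if (any(is.na(w)))
      stop("contrast weights must name every category level", call. = FALSE)
    ct <- emmeans::contrast(emm, method = list(custom = unname(w)))
    ct_df <- as.data.frame(ct)
    contrast_res <- list(estimate = ct_df$estimate,
                         f_statistic = ct_df$t.ratio^2,
                         df = c(1, ct_df$df),
                         p_value = ct_df$p.value, weights = w)
  }
  list(ancova = tab, anova = stats::anova(fit_anova),
       ls_means = ls_means,
       category_f = category_f, category_p = category_p,
       covariate_f = covariate_f, covariate_p = covariate_p,
       contrast = contrast_res, fit = fit_anc)
}
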