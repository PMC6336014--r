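#' Configuration of a synthetic dormancy study
#'
#' Defines the study conditions the generator emulates: 97 accessions in
#' three latent dormancy classes (28 non-dormant N / 41 responsive R /
#' 29 dormant D), 25 seeds x 2 replicate dishes per accession and
#' treatment, daily scoring over 28 days under two alternating
#' temperature regimes; spatially autocorrelated environmental fields
#' over a Mediterranean-scale extent with one field (a temperature
#' annual range analogue) linked to class membership; and
#' class-structured seed-coat traits (testa thickness, proanthocyanidin
#' content, morphology weakly linked through the length-to-width
#' ratio).
#'
#' Per-class final germination fractions default to
#' N (0.92, 0.95), R (0.15, 0.75), D (0.15, 0.20) for the
#' (25/15, 35/15) regimes, echoing the reference group means; willing
#' seeds imbibe at a log-normal time (median `m` days, log-sd `s`),
#' censored at the horizon.
#'
#' @param n_accessions number of accessions (default 97).
#' @param class_counts named counts for N, R, D (must sum to
#'   `n_accessions`).
#' @param seeds_total seeds per dish (default 25).
#' @param replicates dishes per accession x treatment (default 2).
#' @param horizon scoring horizon in days (default 28).
#' @param germ_p list per class of final-fraction pairs
#'   (T25_15, T35_15).
#' @param germ_m list per class of median imbibition day pairs.
#' @param germ_s log-sd of the imbibition-time distribution.
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param n_clusters spatial clusters of collection sites.
#' @param cluster_sd site scatter around cluster centers (degrees).
#' @param gp_range_km exponential-covariance range of the environmental
#'   fields (km).
#' @param n_env number of environmental fields; the first
#'   (`bio7_analog`) is class-linked.
#' @param link_strength log-odds of class membership per SD of the
#'   linked field (default 2, odds ratio ~7 per SD).
#' @param grid_cellsize raster cell size in degrees (default 0.5).
#' @param thickness_median,thickness_sdlog per-class testa thickness
#'   log-normal parameters (um).
#' @param pa_mean,pa_sd,pa_range per-class total proanthocyanidin
#'   normal parameters, truncated to `pa_range` (mg per g).
#' @param soluble_frac range of the soluble PA fraction.
#' @param lwr_mean,lwr_sd per-class seed length-to-width ratio.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n_accessions = 97,
    class_counts = c(N = 28, R = 40, D = 29),
    seeds_total = 25, replicates = 2, horizon = 28,
    germ_p = list(N = c(0.92, 0.95), R = c(0.15, 0.75), D = c(0.15, 0.20)),
    germ_m = list(N = c(6, 5), R = c(12, 9), D = c(14, 12)),
    germ_s = 0.35,
    extent = c(-10, 40, 30, 45), n_clusters = 8, cluster_sd = 1.2,
    gp_range_km = 400, n_env = 6, link_strength = 2,
    grid_cellsize = 0.5,
    thickness_median = c(D = 138, R = 140, N = 84),
    thickness_sdlog = c(D = 0.12, R = 0.15, N = 0.35),
    pa_mean = c(D = 2.18, R = 1.87, N = 1.77), pa_sd = 0.6,
    pa_range = c(1.21, 4.70), soluble_frac = c(0.94, 0.99),
    lwr_mean = c(D = 1.35, R = 1.38, N = 1.50), lwr_sd = 0.12) {
  if (sum(class_counts) != n_accessions)
    stop("class_counts must sum to n_accessions", call. = FALSE)
  for (cl in names(germ_p))
    if (any(germ_p[[cl]] < 0 | germ_p[[cl]] > 1))
      stop("germination probabilities must lie in [0, 1]", call. = FALSE)
  for (cl in names(germ_m))
    if (any(germ_m[[cl]] <= 0 | germ_m[[cl]] >= horizon))
      stop("median imbibition days must lie in (0, horizon)", call. = FALSE)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

## Exact Gaussian-process draw (exponential covariance) at given points.
gp_draw <- function(d_km, range_km, n_draws = 1) {
  C <- exp(-d_km / range_km)
  diag(C) <- diag(C) + 1e-8
  L <- chol(C)
  crossprod(L, matrix(stats::rnorm(nrow(C) * n_draws), nrow(C)))
}

#' Simulate collection sites and environmental fields
#'
#' Draws clustered accession coordinates over the configured extent and
#' samples each environmental field from a Gaussian process with
#' exponential covariance (range `gp_range_km`) at the sites, and
#' optionally on an export raster grid (sites then take their cell's
#' value so point and raster values agree). Latent dormancy classes are
#' assigned from the first ("bio7_analog") field through a logistic
#' latent score: `link_strength` times the standardized field plus
#' standard logistic noise, ranked so the configured class counts are
#' respected with dormant accessions at low field values. Link strength
#' 0 gives class assignment independent of the environment.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @param make_rasters also export each field as a
#'   [suitability_surface()] (default FALSE; slower).
#' @return List: `coords` (accession_id, lon, lat), `env` (data frame
#'   of fields), `classes` (accession_id, class), `rasters` (named list
#'   or NULL), `linked_field` (= `"bio7_analog"`).
#' @export
simulate_landscape <- function(config, seed = NULL, make_rasters = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_accessions
  ex <- config$extent
  ctr_lon <- stats::runif(config$n_clusters, ex[1], ex[2])
  ctr_lat <- stats::runif(config$n_clusters, ex[3], ex[4])
  who <- sample.int(config$n_clusters, n, replace = TRUE)
  lon <- pmin(pmax(ctr_lon[who] + stats::rnorm(n, 0, config$cluster_sd), ex[1]), ex[2])
  lat <- pmin(pmax(ctr_lat[who] + stats::rnorm(n, 0, config$cluster_sd), ex[3]), ex[4])
  ids <- sprintf("ACC%03d", seq_len(n))
  coords <- data.frame(accession_id = ids, lon = lon, lat = lat,
                       stringsAsFactors = FALSE)
  field_names <- c("bio7_analog",
                   if (config$n_env > 1) paste0("env", 2:config$n_env))
  rasters <- NULL
  if (make_rasters) {
    nc <- ceiling((ex[2] - ex[1]) / config$grid_cellsize)
    nr <- ceiling((ex[4] - ex[3]) / config$grid_cellsize)
    base <- suitability_surface(matrix(0, nr, nc), ex[1], ex[3],
                                config$grid_cellsize)
    ctr <- grid_centers(base)
    dg <- haversine_distances(ctr[, c("lon", "lat")])
    draws <- gp_draw(dg, config$gp_range_km, config$n_env)
    rasters <- lapply(seq_len(config$n_env), function(j) {
      m <- matrix(NA_real_, nr, nc)
      m[cbind(ctr$row, ctr$col)] <- draws[, j]
      suitability_surface(m, ex[1], ex[3], config$grid_cellsize)
    })
    names(rasters) <- field_names
    env <- as.data.frame(lapply(rasters, function(r)
      extract_value(r, coords$lon, coords$lat)))
  } else {
    dpts <- haversine_distances(coords[, c("lon", "lat")])
    env <- as.data.frame(gp_draw(dpts, config$gp_range_km, config$n_env))
    names(env) <- field_names
  }
  rownames(env) <- ids
  z1 <- as.numeric(scale(env[[1]]))
  latent <- config$link_strength * z1 + stats::rlogis(n)
  rk <- rank(latent, ties.method = "first")
  cls <- character(n)
  nd <- config$class_counts[["D"]]; nr_ <- config$class_counts[["R"]]
  cls[rk <= nd] <- "D"
  cls[rk > nd & rk <= nd + nr_] <- "R"
  cls[rk > nd + nr_] <- "N"
  list(coords = coords, env = env,
       classes = data.frame(accession_id = ids, class = cls,
                            stringsAsFactors = FALSE),
       rasters = rasters, linked_field = "bio7_analog")
}

#' Simulate daily cumulative germination counts
#'
#' For each accession x treatment x replicate, each of the
#' `seeds_total` seeds is independently willing to imbibe with the
#' class- and treatment-specific final fraction; willing seeds draw a
#' log-normal imbibition time (median `m`, log-sd `s`) censored at the
#' horizon, and daily cumulative counts are assembled.
#'
#' @param config a [simulation_config()].
#' @param classes data frame `accession_id`, `class` (N/R/D).
#' @param seed optional integer seed.
#' @return List of [germination_record()]s.
#' @export
simulate_germination <- function(config, classes, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  days <- seq_len(config$horizon)
  records <- list()
  for (i in seq_len(nrow(classes))) {
    cl <- classes$class[i]
    for (tr_i in 1:2) {
      tr <- c("T25_15", "T35_15")[tr_i]
      p <- config$germ_p[[cl]][tr_i]
      m <- config$germ_m[[cl]][tr_i]
      for (rep_i in seq_len(config$replicates)) {
        willing <- stats::rbinom(1, config$seeds_total, p)
        times <- if (willing > 0)
          stats::rlnorm(willing, log(m), config$germ_s) else numeric(0)
        counts <- vapply(days, function(d) sum(times <= d), numeric(1))
        records[[length(records) + 1]] <- germination_record(
          classes$accession_id[i], tr, rep_i, days, counts,
          config$seeds_total, config$horizon)
      }
    }
  }
  records
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0
  while (length(bad) && guard < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- which(out < lo | out > hi)
    guard <- guard + 1
  }
  pmin(pmax(out, lo), hi)
}

#' Simulate seed-coat and morphology traits
#'
#' Testa thickness follows class-specific log-normals (medians
#' 138 / 140 / 84 um for D / R / N, the non-dormant class with the
#' larger spread); total proanthocyanidin content follows class-specific
#' normals truncated to the observed range (1.21-4.70 mg per g), split
#' into a dominant soluble fraction (94-99%) and the insoluble
#' remainder; morphology is linked to class only through the
#' length-to-width ratio.
#'
#' @param config a [simulation_config()].
#' @param classes data frame `accession_id`, `class`.
#' @param seed optional integer seed.
#' @return Data frame of class `"trait_table"` columns: `accession_id`,
#'   `class`, `thickness_um`, `pa_total`, `pa_soluble`, `pa_insoluble`,
#'   `pa_ratio`, `as_mm2`, `pl_mm`, `w_mm`, `l_mm`, `lwr`, `cs`,
#'   `ds_mm`, `hsw_g`.
#' @export
simulate_traits <- function(config, classes, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  cl <- classes$class
  n <- length(cl)
  thickness <- stats::rlnorm(n, log(config$thickness_median[cl]),
                             config$thickness_sdlog[cl])
  pa_total <- rnorm_trunc(n, config$pa_mean[cl], config$pa_sd,
                          config$pa_range[1], config$pa_range[2])
  # soluble fraction rises with total PA and is slightly higher for D and R,
  # so the sPA/inPA ratio shows the covariate dependence and the
  # dormant+responsive > non-dormant contrast the analysis tests for
  fr <- config$soluble_frac
  sol_frac <- fr[1] + diff(fr) * stats::plogis(
    0.8 * as.numeric(scale(pa_total)) + 0.5 * (cl %in% c("D", "R")) - 0.25 +
      stats::rnorm(n, 0, 0.6))
  pa_sol <- pa_total * sol_frac
  pa_insol <- pa_total - pa_sol
  w <- stats::rnorm(n, 4.6, 0.35)
  lwr <- pmax(stats::rnorm(n, config$lwr_mean[cl], config$lwr_sd), 1)
  l <- w * lwr
  as_mm2 <- pi * (l / 2) * (w / 2) * exp(stats::rnorm(n, 0, 0.03))
  pl <- pi * (l + w) / 2 * exp(stats::rnorm(n, 0, 0.02))
  cs <- pmin(4 * pi * as_mm2 / pl^2, 1)
  structure(
    data.frame(accession_id = classes$accession_id, class = cl,
               thickness_um = thickness, pa_total = pa_total,
               pa_soluble = pa_sol, pa_insoluble = pa_insol,
               pa_ratio = pa_sol / pa_insol,
               as_mm2 = as_mm2, pl_mm = pl, w_mm = w, l_mm = l,
               lwr = lwr, cs = cs,
               ds_mm = abs(stats::rnorm(n, 0.18, 0.06)),
               hsw_g = stats::rnorm(n, 12, 3),
               stringsAsFactors = FALSE),
    class = c("trait_table", "data.frame"))
}

#' Simulate a complete synthetic dormancy study
#'
#' Orchestrates [simulate_landscape()], [simulate_germination()] and
#' [simulate_traits()] under a single seed, producing every input the
#' analysis pipeline reads.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (reproducible given the seed).
#' @param make_rasters export environmental rasters (default FALSE).
#' @return List: `config`, `coords`, `env`, `classes`, `records`,
#'   `traits`, `rasters`, `linked_field`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1,
                           make_rasters = FALSE) {
  set.seed(seed)
  land <- simulate_landscape(config, make_rasters = make_rasters)
  records <- simulate_germination(config, land$classes)
  traits <- simulate_traits(config, land$classes)
  c(land, list(config = config, records = records, traits = traits,
               seed = seed))
}
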