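#' Read a long-format germination CSV
#'
#' Expected columns: `accession_id`, `treatment` (T25_15 / T35_15),
#' `replicate`, `day`, `cumulative_count`, `seeds_total`. Rows are
#' validated: duplicate (accession, treatment, replicate, day) rows,
#' counts exceeding `seeds_total` and cumulative counts that decrease
#' from one day to the next are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param horizon observation horizon in days (default 28).
#' @return List of [germination_record()]s.
#' @export
read_germination_csv <- function(path, horizon = 28) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "treatment", "replicate", "day",
            "cumulative_count", "seeds_total")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  key <- paste(df$accession_id, df$treatment, df$replicate, df$day)
  if (anyDuplicated(key))
    stop("duplicate rows for (accession, treatment, replicate, day): ",
         key[duplicated(key)][1], call. = FALSE)
  split_key <- paste(df$accession_id, df$treatment, df$replicate)
  out <- lapply(split(df, split_key), function(g) {
    g <- g[order(g$day), ]
    dec <- which(diff(g$cumulative_count) < 0)
    if (length(dec))
      stop(sprintf("cumulative count decreases at day %g (accession %s, %s, rep %s)",
                   g$day[dec[1] + 1], g$accession_id[1], g$treatment[1],
                   g$replicate[1]), call. = FALSE)
    if (any(g$cumulative_count > g$seeds_total))
      stop(sprintf("count exceeds seeds_total (accession %s, %s)",
                   g$accession_id[1], g$treatment[1]), call. = FALSE)
    germination_record(g$accession_id[1], g$treatment[1], g$replicate[1],
                       g$day, g$cumulative_count, g$seeds_total[1], horizon)
  })
  names(out) <- NULL
  out
}

#' Write germination records as a long-format CSV
#'
#' Inverse of [read_germination_csv()]: round-trips exactly.
#'
#' @param records list of [germination_record()]s.
#' @param path output path.
#' @export
write_germination_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(accession_id = r$accession_id, treatment = r$treatment,
               replicate = r$replicate, day = r$days,
               cumulative_count = r$counts, seeds_total = r$seeds_total,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sum replicate dishes into one series per accession x treatment
#'
#' The analysis operates on one count series per accession and
#' treatment; replicate dishes observed on the same days are summed
#' (counts and seed totals), marked `replicate = 0`.
#'
#' @param records list of [germination_record()]s.
#' @return List of summed [germination_record()]s.
#' @export
sum_replicates <- function(records) {
  key <- vapply(records, function(r) paste(r$accession_id, r$treatment),
                character(1))
  out <- lapply(split(records, key), function(g) {
    days <- g[[1]]$days
    for (r in g) if (!identical(r$days, days))
      stop("replicates observed on different days cannot be summed",
           call. = FALSE)
    germination_record(g[[1]]$accession_id, g[[1]]$treatment, 0L, days,
                       Reduce(`+`, lapply(g, `[[`, "counts")),
                       sum(vapply(g, `[[`, numeric(1), "seeds_total")),
                       g[[1]]$horizon)
  })
  names(out) <- NULL
  out
}

#' Fit AGDFs for a set of records and tabulate descriptors
#'
#' Fits one AGDF per record and returns the per-series descriptor
#' table: B-spline coefficients `b1..bK`, area under the fitted curve
#' (seed-days, 0.1-day trapezoid), and the classical indices.
#'
#' @param records list of [germination_record()]s (typically replicate
#'   sums).
#' @param control an [agdf_control()].
#' @return List: `table` (data frame), `fits` (list of `"agdf"`).
#' @export
agdf_descriptors <- function(records, control = agdf_control()) {
  fits <- lapply(records, function(r)
    suppressWarnings(fit_agdf(r, control)))
  rows <- lapply(seq_along(records), function(i) {
    f <- fits[[i]]
    ci <- classical_indices(records[[i]])
    b <- as.data.frame(t(f$coefficients))
    names(b) <- paste0("b", seq_along(f$coefficients))
    cbind(ci[, c("accession_id", "treatment")], b,
          data.frame(auc_seed_days = agdf_area(f),
                     final_proportion = ci$final_proportion,
                     lt50_days = ci$lt50, mgt_days = ci$mgt,
                     cv_pct_per_day = ci$cv))
  })
  list(table = do.call(rbind, rows), fits = fits)
}

#' Wide matrices of descriptors for ordination and clustering
#'
#' @param desc the `table` from [agdf_descriptors()].
#' @return List: `coefficients` (accessions x concatenated per-treatment
#'   B-spline coefficients), `auc` (accessions x 2 AUC matrix),
#'   `final` (data frame `accession_id`, `final_25_15`, `final_35_15`).
#' @export
descriptor_matrices <- function(desc) {
  bcols <- grep("^b[0-9]+$", names(desc), value = TRUE)
  ids <- sort(unique(desc$accession_id))
  treats <- c("T25_15", "T35_15")
  blocks <- lapply(treats, function(tr) {
    d <- desc[desc$treatment == tr, , drop = FALSE]
    m <- as.matrix(d[match(ids, d$accession_id), bcols, drop = FALSE])
    colnames(m) <- paste0(sub("T", "t", tolower(tr)), "_", bcols)
    m
  })
  coef_mat <- do.call(cbind, blocks)
  rownames(coef_mat) <- ids
  getcol <- function(tr, col) {
    d <- desc[desc$treatment == tr, , drop = FALSE]
    d[match(ids, d$accession_id), col]
  }
  auc <- cbind(auc_25_15 = getcol("T25_15", "auc_seed_days"),
               auc_35_15 = getcol("T35_15", "auc_seed_days"))
  rownames(auc) <- ids
  final <- data.frame(accession_id = ids,
                      final_25_15 = getcol("T25_15", "final_proportion"),
                      final_35_15 = getcol("T35_15", "final_proportion"),
                      stringsAsFactors = FALSE)
  list(coefficients = coef_mat, auc = auc, final = final)
}

#' Run configuration for the full analysis
#'
#' Validates paths and collects the tunable parameters of every stage.
#' Inputs may be given as CSV/ASCII-grid paths or as in-memory objects
#' (a [simulate_study()] bundle via `study`).
#'
#' @param study optional in-memory study bundle (see
#'   [simulate_study()]); when given, the path arguments are ignored.
#' @param germination_csv,coords_csv,env_csv,traits_csv input CSV paths.
#' @param raster_paths named character vector of ASCII-grid paths for
#'   the niche stage (optional).
#' @param output_dir directory for result CSVs and the run log.
#' @param control an [agdf_control()].
#' @param k combined-treatment cluster count (default 3).
#' @param thresholds a [label_thresholds()] list.
#' @param n_distance_classes correlogram classes (default 10).
#' @param n_permutations Monte Carlo permutations (default 999).
#' @param equivalency_reps niche equivalency replicates (default 99).
#' @param seed integer seed controlling every stochastic stage.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(study = NULL, germination_csv = NULL,
                       coords_csv = NULL, env_csv = NULL,
                       traits_csv = NULL, raster_paths = NULL,
                       output_dir = tempfile("seedfda_run_"),
                       control = agdf_control(), k = 3,
                       thresholds = label_thresholds(),
                       n_distance_classes = 10, n_permutations = 999,
                       equivalency_reps = 99, seed = 1) {
  for (p in c(germination_csv, coords_csv, env_csv, traits_csv,
              unname(raster_paths)))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  if (is.null(study) && is.null(germination_csv))
    stop("either `study` or `germination_csv` is required", call. = FALSE)
  if (seed != as.integer(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(study = study, germination_csv = germination_csv,
                 coords_csv = coords_csv, env_csv = env_csv,
                 traits_csv = traits_csv, raster_paths = raster_paths,
                 output_dir = output_dir, control = control, k = k,
                 thresholds = thresholds,
                 n_distance_classes = n_distance_classes,
                 n_permutations = n_permutations,
                 equivalency_reps = equivalency_reps,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full dormancy analysis pipeline
#'
#' Executes, in order: AGDF fitting and descriptor extraction, UPGMA
#' dormancy classification (per-treatment coefficient clustering and
#' combined AUC-pair clustering), unstandardized PCA with the first
#' axis oriented as germination responsivity, a Moran's I correlogram
#' of responsivity, spatially corrected environment-axis correlations,
#' collinearity pruning, PCNM construction, forward selection of
#' environmental predictors, environment/space variance partitioning,
#' niche-overlap equivalency tests (when rasters are available), and
#' the seed-trait statistics. Result CSVs and a parameter/seed log are
#' written to `output_dir`; any stage failure halts with a stage-named
#' error, retaining partial outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the full result bundle (list).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(config$output_dir, name), row.names = FALSE)

  # --- inputs ---------------------------------------------------------
  stage("inputs", {
    if (!is.null(config$study)) {
      st <- config$study
      res$records <- st$records
      res$coords <- st$coords
      res$env <- st$env
      res$traits <- st$traits
      res$rasters <- st$rasters
    } else {
      res$records <- read_germination_csv(config$germination_csv)
      if (!is.null(config$coords_csv))
        res$coords <- utils::read.csv(config$coords_csv,
                                      stringsAsFactors = FALSE)
      if (!is.null(config$env_csv)) {
        res$env <- utils::read.csv(config$env_csv, stringsAsFactors = FALSE)
        rownames(res$env) <- res$env$accession_id
        res$env$accession_id <- NULL
      }
      if (!is.null(config$traits_csv))
        res$traits <- utils::read.csv(config$traits_csv,
                                      stringsAsFactors = FALSE)
      if (!is.null(config$raster_paths))
        res$rasters <- lapply(config$raster_paths, read_ascii_grid)
    }
  })

  # --- AGDF fitting and descriptors ----------------------------------
  stage("fit", {
    summed <- sum_replicates(res$records)
    res$descriptors <- agdf_descriptors(summed, config$control)
    res$matrices <- descriptor_matrices(res$descriptors$table)
    wcsv(res$descriptors$table, "descriptors.csv")
  })

  # --- dormancy classification ---------------------------------------
  stage("classify", {
    res$classification <- classify_dormancy(
      res$matrices$auc, res$matrices$final, k = config$k,
      thresholds = config$thresholds)
    ids <- rownames(res$matrices$coefficients)
    per_tr <- lapply(c("T25_15", "T35_15"), function(tr) {
      cols <- grep(tolower(sub("T", "t", tr)),
                   colnames(res$matrices$coefficients))
      upgma(pairwise_euclidean(
        res$matrices$coefficients[, cols, drop = FALSE]))
    })
    names(per_tr) <- c("T25_15", "T35_15")
    res$per_treatment_trees <- per_tr
    wcsv(res$classification$assignment, "dormancy_assignment.csv")
    writeLines(write_newick(res$classification$tree),
               file.path(config$output_dir, "combined_upgma.nwk"))
  })

  # --- ordination -----------------------------------------------------
  stage("ordinate", {
    pca <- pca_unstandardized(res$matrices$coefficients)
    resp <- rowMeans(cbind(res$matrices$final$final_25_15,
                           res$matrices$final$final_35_15))
    if (stats::cor(pca$scores[, 1], resp) < 0) {  # responsivity points N-ward
      pca$scores[, 1] <- -pca$scores[, 1]
      pca$loadings[, 1] <- -pca$loadings[, 1]
    }
    res$pca <- pca
    wcsv(data.frame(accession_id = rownames(pca$scores),
                    pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
         "pca_scores.csv")
  })

  # --- spatial statistics --------------------------------------------
  if (!is.null(res$coords)) {
    stage("correlogram", {
      d <- haversine_distances(res$coords)
      res$distance_classes <- make_distance_classes(
        d, n_classes = config$n_distance_classes)
      res$responsivity_correlogram <- morans_i_correlogram(
        res$pca$scores[, 1], res$distance_classes,
        n_permutations = config$n_permutations)
      wcsv(res$responsivity_correlogram$classes, "correlogram_pc1.csv")
    })
    if (!is.null(res$env)) stage("env_correlations", {
      pruned <- collinearity_prune(res$env)
      res$env_pruned <- pruned$kept
      res$prune_log <- pruned$log
      res$env_axis_cor <- axis_env_correlations(
        res$pca$scores, res$env_pruned, res$coords)
      res$env_axis_cor$p_fdr <- fdr_bh(res$env_axis_cor$p_corrected)
      wcsv(res$env_axis_cor, "env_axis_correlations.csv")
    })
    stage("partition", {
      pcnm <- pcnm_eigenvectors(res$coords)
      sel_sp <- forward_select(res$matrices$coefficients,
                               as.data.frame(pcnm$vectors),
                               n_permutations = config$n_permutations)
      res$pcnm_selected <- if (nrow(sel_sp))
        as.data.frame(pcnm$vectors)[, sel_sp$variable, drop = FALSE]
      else as.data.frame(pcnm$vectors[, 1, drop = FALSE])
      if (!is.null(res$env_pruned)) {
        res$env_forward <- forward_select(
          res$matrices$coefficients, res$env_pruned,
          n_permutations = config$n_permutations)
        wcsv(res$env_forward, "forward_selection_env.csv")
        env_sel <- if (nrow(res$env_forward))
          res$env_pruned[, res$env_forward$variable, drop = FALSE]
        else res$env_pruned
        res$partition <- variance_partition(
          res$matrices$coefficients, env_sel, res$pcnm_selected,
          n_permutations = config$n_permutations)
        wcsv(res$partition$fractions, "variance_partition.csv")
      }
    })
  }

  # --- niche overlap --------------------------------------------------
  if (!is.null(res$rasters) && !is.null(res$coords)) stage("niche", {
    asg <- res$classification$assignment
    coord <- res$coords[match(asg$accession_id, res$coords$accession_id), ]
    groups <- split(coord, asg$category)
    groups <- groups[vapply(groups, nrow, integer(1)) >= 3]
    res$niche <- list()
    combos <- utils::combn(names(groups), 2, simplify = FALSE)
    for (cb in combos) {
      o1 <- occurrence_set(cb[1], groups[[cb[1]]]$lon, groups[[cb[1]]]$lat)
      o2 <- occurrence_set(cb[2], groups[[cb[2]]]$lon, groups[[cb[2]]]$lat)
      res$niche[[paste(cb, collapse = "_vs_")]] <- equivalency_test(
        o1, o2, res$rasters, n_reps = config$equivalency_reps)
    }
    wcsv(do.call(rbind, lapply(names(res$niche), function(nm) {
      x <- res$niche[[nm]]
      data.frame(pair = nm, D = x$observed["D"], I = x$observed["I"],
                 p_D = x$p_value["D"], p_I = x$p_value["I"])
    })), "niche_overlap.csv")
  })

  # --- seed traits ----------------------------------------------------
  if (!is.null(res$traits)) stage("traits", {
    tr <- res$traits
    asg <- res$classification$assignment
    cat_vec <- asg$category[match(tr$accession_id, asg$accession_id)]
    res$kw_thickness <- kruskal_wallis(tr$thickness_um, cat_vec)
    res$ordinal <- ordinal_logistic(
      cat_vec, tr[, c("lwr", "as_mm2", "hsw_g"), drop = FALSE])
    lev <- levels(droplevels(factor(cat_vec)))
    wts <- if (all(c("D", "R", "N") %in% lev))
      c(D = 0.5, R = 0.5, N = -1) else NULL
    res$pa <- ancova_ratio(tr$pa_ratio, cat_vec, tr$pa_total,
                           contrast = wts)
    wcsv(data.frame(
      test = c("kruskal_wallis_thickness", "ancova_category",
               "ancova_covariate",
               if (!is.null(res$pa$contrast)) "contrast_DR_vs_N"),
      statistic = c(res$kw_thickness$h_statistic, res$pa$category_f,
                    res$pa$covariate_f,
                    if (!is.null(res$pa$contrast))
                      res$pa$contrast$f_statistic),
      p_value = c(res$kw_thickness$p_value, res$pa$category_p,
                  res$pa$covariate_p,
                  if (!is.null(res$pa$contrast)) res$pa$contrast$p_value)),
      "trait_tests.csv")
  })

  # --- run log --------------------------------------------------------
  writeLines(c(
    sprintf("seedfda %s | R %s", as.character(utils::packageVersion("seedfda")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", config$seed),
    sprintf("spline: degree %d, knot spacing %g d, lambda %s",
            config$control$degree, config$control$knot_spacing,
            if (is.null(config$control$lambda)) "GCV" else
              format(config$control$lambda)),
    sprintf("clusters k = %d; distance classes = %d; permutations = %d; equivalency reps = %d",
            config$k, config$n_distance_classes, config$n_permutations,
            config$equivalency_reps)),
    file.path(config$output_dir, "run_log.txt"))
  invisible(res)
}
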