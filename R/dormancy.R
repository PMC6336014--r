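#' Pairwise Euclidean distances between accession descriptors
#'
#' Thin validated wrapper around [stats::dist()] producing the symmetric
#' distance matrix used for UPGMA clustering of germination descriptors
#' (B-spline coefficient vectors per treatment, or AUC pairs for the
#' combined-treatment analysis).
#'
#' @param x numeric matrix, accessions in rows (rownames = accession ids).
#' @return A symmetric matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(x) {
  x <- as.matrix(x)
  bad <- rownames(x)[!stats::complete.cases(x) | apply(x, 1, function(r) any(!is.finite(r)))]
  if (length(bad))
    stop("non-finite descriptor values for accession(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' UPGMA clustering
#'
#' Average-linkage (unweighted pair-group method with arithmetic mean)
#' agglomeration of a distance matrix. UPGMA merge heights are monotone
#' non-decreasing and the induced cophenetic distances are ultrametric. The
#' result wraps the agglomeration tree with a cophenetic accessor and a
#' Newick exporter.
#'
#' @param d symmetric distance matrix (or `dist`) with labelled rows.
#' @return Object of class `"upgma"`: the `hclust` tree, `merge` heights,
#'   `labels`, and a `cophenetic` matrix.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric", call. = FALSE)
  if (nrow(d) < 2) stop("need at least 2 leaves", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 labels = hc$labels,
                 cophenetic = as.matrix(stats::cophenetic(hc))),
            class = "upgma")
}

#' Export a UPGMA dendrogram as Newick
#'
#' @param tree an `"upgma"` object.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "upgma"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) ape::write.tree(phy) else ape::write.tree(phy, file = path)
}

#' Thresholds for labelling dormancy clusters
#'
#' The published verbal definitions translated to defaults: a cluster whose
#' mean final germination at 35/15 degC stays below `dormant_max` is dormant
#' (D); a cluster above `nondormant_min` at both regimes is non-dormant (N);
#' anything else (low at 25/15 but elevated at 35/15) is temperature
#' responsive (R).
#'
#' @param dormant_max upper bound on 35/15 final germination for D
#'   (default 0.20).
#' @param nondormant_min lower bound on final germination at both regimes
#'   for N (default 0.80).
#' @param responsive_gain minimum rise in final germination from 25/15 to
#'   35/15 that marks a cluster as temperature responsive (default 0.25;
#'   the reference responsive group rose from about 15% to 60-80%).
#' @export
label_thresholds <- function(dormant_max = 0.20, nondormant_min = 0.80,
                             responsive_gain = 0.25) {
  list(dormant_max = dormant_max, nondormant_min = nondormant_min,
       responsive_gain = responsive_gain)
}

#' Cut a dendrogram and label dormancy categories
#'
#' Cuts the UPGMA tree into `k` clusters and assigns each cluster a dormancy
#' category from its mean final germination per temperature regime:
#' D (dormant at both), R (responsive to the increased temperature range),
#' N (non-dormant). Equal labelling criteria are broken deterministically by
#' cluster size then lexicographic smallest accession id, with a warning.
#'
#' @param tree an `"upgma"` object.
#' @param k number of clusters, `2 <= k <= n`.
#' @param germination data frame with columns `accession_id`,
#'   `final_25_15`, `final_35_15` (final germination proportions).
#' @param thresholds a [label_thresholds()] list.
#' @return Data frame: `accession_id`, `cluster`, `category` (factor
#'   D < R < N), `subgroup` (cluster-wise label like D1, R2),
#'   `final_25_15`, `final_35_15`.
#' @export
cut_and_label <- function(tree, k, germination,
                          thresholds = label_thresholds()) {
  stopifnot(inherits(tree, "upgma"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  cl <- stats::cutree(tree$hclust, k = k)
  idx <- match(tree$labels, germination$accession_id)
  if (any(is.na(idx)))
    stop("germination summary missing accession(s): ",
         paste(tree$labels[is.na(idx)], collapse = ", "), call. = FALSE)
  g25 <- germination$final_25_15[idx]
  g35 <- germination$final_35_15[idx]
  cl_means <- do.call(rbind, lapply(sort(unique(cl)), function(cc) {
    data.frame(cluster = cc,
               mean_25 = mean(g25[cl == cc]), mean_35 = mean(g35[cl == cc]),
               size = sum(cl == cc),
               first_id = min(tree$labels[cl == cc]))
  }))
  if (anyDuplicated(cl_means[, c("mean_25", "mean_35")])) {
    warning("tied labelling criteria; breaking ties by cluster size then id",
            call. = FALSE)
    cl_means <- cl_means[order(-cl_means$size, cl_means$first_id), ]
  }
  # responsive: low at 25/15 but clearly elevated at 35/15; non-dormant:
  # high at both; dormant: low at both; borderline clusters fall back on
  # which archetype their lower mean is nearer to
  cat_of <- function(m25, m35) {
    if (m25 <= thresholds$nondormant_min &&
        (m35 - m25) >= thresholds$responsive_gain) "R"
    else if (m25 > thresholds$nondormant_min &&
             m35 > thresholds$nondormant_min) "N"
    else if (m35 < thresholds$dormant_max) "D"
    else if (min(m25, m35) < 0.5) "D" else "N"
  }
  cl_means$category <- mapply(cat_of, cl_means$mean_25, cl_means$mean_35)
  # subgroup numbering within category, ordered by decreasing mean germination
  cl_means <- cl_means[order(cl_means$category,
                             -(cl_means$mean_25 + cl_means$mean_35)), ]
  cl_means$subgroup <- stats::ave(seq_len(nrow(cl_means)), cl_means$category,
                                  FUN = seq_along)
  cl_means$subgroup <- paste0(cl_means$category, cl_means$subgroup)
  m <- match(cl, cl_means$cluster)
  data.frame(accession_id = tree$labels, cluster = cl,
             category = factor(cl_means$category[m], levels = c("D", "R", "N")),
             subgroup = cl_means$subgroup[m],
             final_25_15 = g25, final_35_15 = g35,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combined-treatment dormancy classification from AUC pairs
#'
#' Convenience pipeline for the combined analysis: per accession the
#' 2-vector (AUC at 25/15, AUC at 35/15) is clustered by UPGMA/Euclidean
#' and the k-cluster cut is labelled N / R / D.
#'
#' @param auc_matrix numeric matrix, one row per accession, columns
#'   `auc_25_15`, `auc_35_15`, rownames = accession ids.
#' @param germination see [cut_and_label()].
#' @param k number of clusters (default 3).
#' @param thresholds a [label_thresholds()] list.
#' @return List: `tree` (upgma), `assignment` (from [cut_and_label()]).
#' @export
classify_dormancy <- function(auc_matrix, germination, k = 3,
                              thresholds = label_thresholds()) {
  tree <- upgma(pairwise_euclidean(auc_matrix))
  list(tree = tree,
       assignment = cut_and_label(tree, k, germination, thresholds))
}
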