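# Ward agglomerative clustering on isotope features, with the
# goodness-of-variance-fit (GVF) quality score used to judge cuts.

#' Squared Euclidean distance matrix
#'
#' @param features Numeric matrix (samples x tracers), no missing
#'   entries; row names identify samples.
#' @return Symmetric n x n matrix with zero diagonal, entry (a, b) equal
#'   to the sum over tracers of the squared coordinate differences.
#' @export
squared_euclidean_matrix <- function(features) {
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1, , drop = TRUE]
    rn <- rownames(features)[bad[1]]
    cn <- colnames(features)[bad[2]]
    stop("missing/non-finite feature value for sample '",
         if (is.null(rn)) bad[1] else rn, "', tracer '",
         if (is.null(cn)) bad[2] else cn, "'")
  }
  as.matrix(stats::dist(features, method = "euclidean"))^2
}

#' Ward hierarchical linkage
#'
#' Agglomerates samples by Ward's minimum-variance criterion on squared
#' Euclidean distances: at each step the pair of clusters whose merger
#' least increases the total within-cluster sum of squares is joined.
#' The merge cost recorded is that increase in within-cluster SS itself.
#'
#' @param features Numeric matrix (samples x tracers) with at least two
#'   rows and no missing entries.
#' @return An object of class `"linkage_tree"`: a list with `merges` (a
#'   data.frame with columns `left`, `right`, `cost`, `size`, in
#'   `stats::hclust` merge notation where negative entries are leaves),
#'   `n_leaves`, `labels`, and the underlying `hclust` object.
#' @export
ward_linkage <- function(features) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("ward_linkage needs at least 2 samples")
  d2 <- stats::as.dist(squared_euclidean_matrix(features))
  hc <- stats::hclust(d2, method = "ward.D")
  # sizes of the newly formed clusters
  size <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    l <- hc$merge[m, 1]; r <- hc$merge[m, 2]
    size[m] <- (if (l < 0) 1L else size[l]) + (if (r < 0) 1L else size[r])
  }
  structure(list(
    merges = data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                        cost = hc$height / 2, size = size),
    n_leaves = n,
    labels = rownames(features),
    hclust = hc
  ), class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("Ward linkage tree:", x$n_leaves, "leaves,",
      nrow(x$merges), "merges\n")
  cat("total within-SS at full merge:", sum(x$merges$cost), "\n")
  invisible(x)
}

#' Cut a linkage tree into k flat clusters
#'
#' Undoes the last k - 1 merges.  Labels are assigned 1..k in order of
#' each cluster's first member in the original sample order.
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Integer vector of cluster labels, named by sample if the
#'   feature matrix had row names.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (k < 1 || k > tree$n_leaves) {
    stop("k must be between 1 and ", tree$n_leaves)
  }
  a <- stats::cutree(tree$hclust, k = k)
  # cutree already numbers clusters by first appearance; enforce anyway
  relabel <- match(a, unique(a))
  names(relabel) <- tree$labels
  relabel
}

#' Goodness of variance fit of a partition
#'
#' GVF = 1 - SDCM/SDAM, where SDAM is the total sum of squared
#' deviations of every sample (pooled across tracers) from the grand
#' per-tracer mean and SDCM is the same quantity taken about each
#' class's own per-tracer mean.  Tracers are pooled by summation,
#' consistent with the squared Euclidean geometry of the linkage.
#' Degenerate input where all samples are identical (SDAM = 0) is
#' defined as GVF = 1 with a notice.
#'
#' @param features Numeric matrix (samples x tracers).
#' @param assignments Cluster label per sample (same order as rows).
#' @return GVF in \[0, 1\].
#' @export
gvf_partition <- function(features, assignments) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(assignments), nrow(features) >= 1)
  sdam <- sum(scale(features, scale = FALSE)^2)
  if (sdam == 0) {
    message("gvf_partition: all samples identical (SDAM = 0); GVF defined as 1")
    return(1)
  }
  sdcm <- 0
  for (lab in unique(assignments)) {
    sub <- features[assignments == lab, , drop = FALSE]
    sdcm <- sdcm + sum(scale(sub, scale = FALSE)^2)
  }
  1 - sdcm / sdam
}

#' Goodness of variance fit of one group
#'
#' A per-group variance-explained score: 1 minus the ratio of the
#' group's within-group sum of squares (about the group mean) to the
#' sum of squares of the same members about the grand mean of the full
#' sample set passed in `features`.  This is this package's
#' interpretation of per-group GVF reporting; a group identical to the
#' whole set scores 0, a group with zero internal spread scores 1.
#'
#' @param features Full feature matrix the grand mean is taken over
#'   (e.g. all samples of one water type).
#' @param assignments Cluster label per row of `features`.
#' @param label The group to score.
#' @return Per-group GVF (at most 1; 1 for singleton groups, with a
#'   notice).
#' @export
gvf_per_group <- function(features, assignments, label) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(assignments))
  if (!label %in% assignments) stop("label not present in assignments: ", label)
  grand <- colMeans(features)
  sub <- features[assignments == label, , drop = FALSE]
  if (nrow(sub) == 1) {
    message("gvf_per_group: group ", label, " is a singleton; GVF defined as 1")
    return(1)
  }
  ss_grand <- sum(sweep(sub, 2, grand)^2)
  if (ss_grand == 0) {
    message("gvf_per_group: group ", label,
            " coincides with the grand mean exactly; GVF defined as 1")
    return(1)
  }
  ss_within <- sum(scale(sub, scale = FALSE)^2)
  1 - ss_within / ss_grand
}

#' Cluster water samples per water type
#'
#' Runs Ward linkage on the configured tracers separately for surface
#' and ground water, cuts each tree at the configured k, and scores the
#' partition and each group by GVF.  Samples with missing tracer values
#' are excluded with a notice.
#'
#' @param samples Canonical sample data.frame.
#' @param config An [analysis_config()].
#' @return Named list (by water type) of `"cluster_result"` objects:
#'   each has `assignments` (named integer vector), `k`,
#'   `partition_gvf`, `per_group_gvf`, `feature_matrix` and `tree`.
#' @export
cluster_water_samples <- function(samples, config = analysis_config()) {
  out <- list()
  for (wt in intersect(c("surface", "ground"), unique(samples$water_type))) {
    sub <- samples[samples$water_type == wt, , drop = FALSE]
    feats <- as.matrix(sub[, config$tracers, drop = FALSE])
    rownames(feats) <- sub$sample_id
    keep <- stats::complete.cases(feats)
    if (any(!keep)) {
      message("excluding ", sum(!keep), " ", wt,
              " sample(s) with missing tracer values from clustering")
      feats <- feats[keep, , drop = FALSE]
    }
    if (config$standardize_features) feats <- scale(feats)
    k <- if (wt == "surface") config$k_surface else config$k_ground
    tree <- ward_linkage(feats)
    assignments <- cut_tree(tree, k)
    per_group <- vapply(sort(unique(assignments)), function(lab) {
      gvf_per_group(feats, assignments, lab)
    }, numeric(1))
    names(per_group) <- sort(unique(assignments))
    out[[wt]] <- structure(list(
      assignments = assignments, k = k,
      partition_gvf = gvf_partition(feats, assignments),
      per_group_gvf = per_group,
      feature_matrix = feats, tree = tree,
      water_type = wt
    ), class = "cluster_result")
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Ward clustering (", x$water_type, "): ", length(x$assignments),
      " samples into k = ", x$k, " groups\n", sep = "")
  cat("  sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  cat("  partition GVF:", round(x$partition_gvf, 3), "\n")
  cat("  per-group GVF:",
      paste(sprintf("%s=%.3f", names(x$per_group_gvf), x$per_group_gvf),
            collapse = ", "), "\n")
  invisible(x)
}
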