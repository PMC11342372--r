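#' Complete-linkage clustering under a distance threshold
#'
#' Agglomerative clustering in which the pair of clusters with the smallest
#' complete-linkage (maximum inter-point) distance is merged repeatedly until
#' that distance exceeds `threshold`. Every resulting cluster therefore has
#' diameter at most `threshold`. Complete linkage is the setting that, on
#' fingerprint distance matrices of quinoline-like libraries, avoids one
#' large central cluster surrounded by tiny outliers; the default threshold
#' 0.026 was tuned for that system and is not expected to transfer to other
#' chemistries unchanged.
#'
#' @param d square symmetric non-negative distance matrix with zero diagonal.
#' @param threshold positive linkage cutoff.
#' @param linkage linkage rule; complete is the supported default, the other
#'   `stats::hclust` rules are exposed for comparison only.
#' @return object of class `cluster_assignment`: list with integer `labels`
#'   (1-based, contiguous), `misfit_id` (NA until
#'   [merge_small_clusters()] is applied), `threshold` and `sizes`.
#' @export
cluster_complete_linkage <- function(d, threshold,
                                     linkage = c("complete", "average",
                                                 "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("d must be a square matrix")
  }
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")
  if (threshold <= 0) stop("threshold must be > 0")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- stats::cutree(hc, h = threshold)
  # renumber contiguously in order of first appearance
  labels <- match(labels, unique(labels))
  structure(list(labels = as.integer(labels), misfit_id = NA_integer_,
                 threshold = threshold,
                 sizes = as.integer(table(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " structures in ",
      length(x$sizes), " clusters (threshold ", x$threshold, ")\n", sep = "")
  cat("  sizes:", x$sizes, "\n")
  if (!is.na(x$misfit_id)) {
    cat("  misfit cluster:", x$misfit_id,
        "(size", x$sizes[x$misfit_id], ")\n")
  }
  invisible(x)
}

#' Pool undersized clusters into a single misfit cluster
#'
#' Structures whose natural clusters fall below `min_size` are all
#' relabelled into one pooled "misfit" cluster; the remaining clusters are
#' renumbered contiguously. The misfit cluster participates in the EA like
#' any other cluster. With no undersized clusters the assignment is returned
#' unchanged (no misfit id set). The operation conserves the structure count
#' and is idempotent.
#'
#' @param assignment a `cluster_assignment`.
#' @param min_size minimum cluster size (default 20).
#' @return a `cluster_assignment` with `misfit_id` set when pooling occurred.
#' @export
merge_small_clusters <- function(assignment, min_size = 20L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  labels <- assignment$labels
  sizes <- tabulate(labels)
  small <- which(sizes < min_size)
  if (length(small) == 0) return(assignment)
  big <- which(sizes >= min_size)
  new_labels <- integer(length(labels))
  for (k in seq_along(big)) new_labels[labels == big[k]] <- k
  misfit_id <- length(big) + 1L
  new_labels[labels %in% small] <- misfit_id
  assignment$labels <- new_labels
  assignment$misfit_id <- misfit_id
  assignment$sizes <- as.integer(tabulate(new_labels))
  assignment
}

#' Cluster a structure library end to end
#'
#' Computes the fingerprint distance matrix, applies complete-linkage
#' clustering at `threshold`, and pools undersized clusters.
#'
#' @param structures list of `mol_structure`.
#' @param cfg a [fingerprint_config()].
#' @param threshold linkage cutoff (default 0.026).
#' @param min_size minimum cluster size for [merge_small_clusters()]; use 1
#'   to disable pooling.
#' @return a `cluster_assignment`.
#' @export
cluster_structures <- function(structures, cfg = fingerprint_config(),
                               threshold = 0.026, min_size = 20L) {
  d <- distance_matrix(structures, cfg)
  a <- cluster_complete_linkage(d, threshold)
  merge_small_clusters(a, min_size)
}

#' Split a structure list by cluster assignment
#' @param structures list of `mol_structure`.
#' @param assignment a `cluster_assignment` over the same structures.
#' @return list of structure lists, one per cluster id.
#' @export
split_by_cluster <- function(structures, assignment) {
  stopifnot(length(structures) == length(assignment$labels))
  lapply(seq_along(assignment$sizes), function(k)
    structures[assignment$labels == k])
}

#' Write a cluster assignment to CSV
#'
#' Columns: `structure_index`, `cluster_id`, `is_misfit`.
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  df <- data.frame(structure_index = seq_along(assignment$labels),
                   cluster_id = assignment$labels,
                   is_misfit = !is.na(assignment$misfit_id) &
                     assignment$labels == assignment$misfit_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
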