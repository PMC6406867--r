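#' Subject-by-channel degree feature matrix
#'
#' Stacks the per-subject degree vectors into a subjects x channels matrix,
#' the feature space in which subjects are clustered.  A channel that is
#' invalid in any subject is dropped from the feature space for all subjects
#' (recorded in the `dropped_channels` attribute), so the matrix is complete
#' by construction.
#'
#' @param degs List (length >= 2) of `degree_vector` objects.
#' @param subject_ids Optional row names.
#' @return Numeric matrix with attribute `dropped_channels`.
#' @export
subject_features <- function(degs, subject_ids = NULL) {
  if (!is.list(degs) || length(degs) < 2L)
    stop("need degree vectors for at least 2 subjects")
  k <- do.call(rbind, lapply(degs, function(d) {
    stopifnot(inherits(d, "degree_vector")); d$k
  }))
  dropped <- which(apply(k, 2L, anyNA))
  if (length(dropped) > 0L) {
    message("dropping channel(s) ", paste(dropped, collapse = ", "),
            " from the feature space (invalid in at least one subject)")
    k <- k[, -dropped, drop = FALSE]
    colnames(k) <- paste0("ch", setdiff(seq_len(ncol(k) + length(dropped)),
                                        dropped))
  } else {
    colnames(k) <- paste0("ch", seq_len(ncol(k)))
  }
  rownames(k) <- if (!is.null(subject_ids)) subject_ids
                 else paste0("s", seq_len(nrow(k)))
  attr(k, "dropped_channels") <- dropped
  k
}

#' Ward hierarchical clustering of subjects
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between the subjects' degree profiles.  Features are
#' not standardized: all columns are degree counts and share a unit.
#'
#' @param features Subjects x channels matrix from [subject_features()].
#' @return Object of class `subject_clustering`: list with `hclust` (the
#'   full merge tree), `heights`, `feature_matrix`, and (after
#'   [cut_largest_gap()]) `labels`, `n_clusters`, `gap_profile`.
#' @export
ward_cluster <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 subjects")
  if (ncol(features) < 1L) stop("need at least 1 feature")
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "ward.D2")
  if (any(diff(hc$height) < -1e-8))
    stop("non-monotone merge heights; Ward linkage violated")
  structure(list(hclust = hc, heights = hc$height,
                 feature_matrix = features,
                 labels = NULL, n_clusters = NULL, gap_profile = NULL),
            class = "subject_clustering")
}

#' Cut the dendrogram at the largest merge-height gap
#'
#' Chooses the number of clusters k in `[k_min, k_max]` that maximizes the
#' gap between successive merge heights — the height of the merge that
#' would reduce k+... clusters to k, minus the height of the previous merge.
#' Equivalently: cut where the dendrogram's vertical jump is largest, which
#' formalizes "split at the largest between-cluster distance".  Gap ties
#' pick the smallest k (with a warning).
#'
#' @param clustering A `subject_clustering` from [ward_cluster()].
#' @param k_min,k_max Bounds on the number of clusters (defaults 2 and 5).
#' @return The `subject_clustering` with `labels` (named integer vector),
#'   `n_clusters` and `gap_profile` filled in.
#' @export
cut_largest_gap <- function(clustering, k_min = 2, k_max = 5) {
  stopifnot(inherits(clustering, "subject_clustering"))
  n <- nrow(clustering$feature_matrix)
  if (!(k_min >= 1 && k_min <= k_max && k_max < n))
    stop("need 1 <= k_min <= k_max < n_subjects")
  h <- clustering$heights                       # n - 1 merge heights
  # cutting into k clusters undoes the last k - 1 merges; the gap for k is
  # the height jump between merge (n - k) and merge (n - k + 1)
  ks <- seq.int(k_min, k_max)
  gaps <- vapply(ks, function(k) {
    upper <- h[n - k + 1L]
    lower <- if (n - k >= 1L) h[n - k] else 0
    upper - lower
  }, numeric(1))
  best <- ks[which.max(gaps)]                   # which.max takes smallest on ties
  if (sum(abs(gaps - max(gaps)) < 1e-12) > 1L)
    warning("tie in the merge-height gap profile; smallest k (", best,
            ") chosen")
  labels <- stats::cutree(clustering$hclust, k = best)
  clustering$labels <- labels
  clustering$n_clusters <- best
  clustering$gap_profile <- data.frame(k = ks, gap = gaps)
  clustering
}

#' @export
print.subject_clustering <- function(x, ...) {
  cat(sprintf("subject_clustering: %d subjects, %d features (Ward/Euclidean)\n",
              nrow(x$feature_matrix), ncol(x$feature_matrix)))
  if (!is.null(x$n_clusters)) {
    cat(sprintf("cut at k = %d (largest merge-height gap):\n", x$n_clusters))
    print(table(cluster = x$labels))
  }
  invisible(x)
}

#' @export
#' @param x A `subject_clustering`.
#' @param ... Passed on to [plot.hclust()].
#' @rdname ward_cluster
plot.subject_clustering <- function(x, ...) {
  graphics::plot(x$hclust, hang = -1, xlab = "subject",
                 ylab = "merge height (Ward)", main = "", sub = "", ...)
  if (!is.null(x$n_clusters) && x$n_clusters > 1L)
    stats::rect.hclust(x$hclust, k = x$n_clusters, border = "red3")
  invisible(x)
}

#' Serialize a clustering as JSON
#'
#' Writes the merge tree (children, heights), the feature channels used and,
#' if present, the cluster labels.
#'
#' @param clustering A `subject_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  stopifnot(inherits(clustering, "subject_clustering"))
  hc <- clustering$hclust
  out <- list(merge = hc$merge, heights = hc$height,
              subjects = rownames(clustering$feature_matrix),
              features = colnames(clustering$feature_matrix),
              labels = clustering$labels, n_clusters = clustering$n_clusters)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
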