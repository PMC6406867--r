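#' Run the full network analysis end to end
#'
#' For every subject: motion-artifact screening on the raw Oxy-Hb, zero-phase
#' band-pass, task-block Pearson/Fisher connectivity, proportional
#' thresholding, degree.  Across subjects: degree-profile feature matrix,
#' Ward clustering with the largest-gap cut, per-cluster top-degree hubs
#' (on the cluster-mean degree profile), per-cluster consensus edges and,
#' when behavioral records are given, per-cluster synchronization-error
#' summaries and the between-cluster t-test on per-subject mean SE.
#'
#' @param series_list List of raw [hb_series()] (one per subject).
#' @param behavior_list Optional list of [behavioral_record()]s.
#' @param density Edge density kept by thresholding (default 0.15).
#' @param hub_fraction Hub selection fraction (default 0.10).
#' @param block Block analyzed (default `"task"`).
#' @param preprocess_cfg A [preprocess_config()].
#' @param k_min,k_max Cluster-count bounds for the dendrogram cut.
#' @param consensus_prevalence Prevalence threshold for consensus edges
#'   (default 0.60).
#' @param map A `channel_map` for region labels (`NULL` to skip labels).
#' @return Object of class `fnirs_pipeline`: list with `adjacency`,
#'   `degrees`, `features`, `clustering`, `labels`, `cluster_hubs`,
#'   `cluster_consensus`, `se_summary`, `se_test`, `params`.
#' @export
run_pipeline <- function(series_list, behavior_list = NULL,
                         density = 0.15, hub_fraction = 0.10,
                         block = "task",
                         preprocess_cfg = preprocess_config(),
                         k_min = 2, k_max = 5,
                         consensus_prevalence = 0.60,
                         map = channel_map()) {
  stopifnot(is.list(series_list), length(series_list) >= 2L)
  ids <- vapply(series_list, `[[`, "", "subject_id")

  adjacency <- vector("list", length(series_list))
  degrees <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    pre <- preprocess(series_list[[i]], preprocess_cfg, which = "oxy")
    conn <- task_block_correlation(pre, block)
    adjacency[[i]] <- proportional_threshold(conn, density)
    degrees[[i]] <- degree(adjacency[[i]])
  }
  names(adjacency) <- names(degrees) <- ids

  features <- suppressMessages(subject_features(degrees, subject_ids = ids))
  k_max <- min(k_max, length(series_list) - 1L)
  k_min <- min(k_min, k_max)
  clustering <- cut_largest_gap(ward_cluster(features), k_min, k_max)
  labels <- stats::setNames(clustering$labels, ids)

  dropped <- attr(features, "dropped_channels")
  cluster_hubs <- lapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    mean_k <- Reduce(`+`, lapply(degrees[members], `[[`, "k")) / length(members)
    if (length(dropped) > 0L) mean_k[dropped] <- NA_real_
    dv <- structure(list(k = mean_k, n_valid = sum(!is.na(mean_k)),
                         edge_count = sum(mean_k, na.rm = TRUE) / 2),
                    class = "degree_vector")
    suppressWarnings(top_degree_hubs(dv, hub_fraction, map = map))
  })
  names(cluster_hubs) <- as.character(sort(unique(labels)))

  cluster_consensus <- lapply(sort(unique(labels)), function(cl) {
    consensus_edges(adjacency[labels == cl], consensus_prevalence)
  })
  names(cluster_consensus) <- names(cluster_hubs)

  se_summary <- NULL; se_test <- NULL
  if (!is.null(behavior_list)) {
    stopifnot(length(behavior_list) == length(series_list))
    se_summary <- cluster_se_summary(behavior_list, labels)
    if (clustering$n_clusters == 2L) {
      subj_mean <- vapply(behavior_list,
                          function(r) mean(record_se(r), na.rm = TRUE),
                          numeric(1))
      cls <- sort(unique(labels))
      se_test <- group_ttest(subj_mean[labels == cls[1L]],
                             subj_mean[labels == cls[2L]],
                             measure = "per-subject mean SE (ms)")
    }
  }

  structure(list(adjacency = adjacency, degrees = degrees,
                 features = features, clustering = clustering,
                 labels = labels, cluster_hubs = cluster_hubs,
                 cluster_consensus = cluster_consensus,
                 se_summary = se_summary, se_test = se_test,
                 params = list(density = density,
                               hub_fraction = hub_fraction, block = block,
                               k_min = k_min, k_max = k_max,
                               consensus_prevalence = consensus_prevalence)),
            class = "fnirs_pipeline")
}

#' @export
print.fnirs_pipeline <- function(x, ...) {
  cat(sprintf("fnirs_pipeline: %d subjects, density %.2f, block '%s'\n",
              length(x$adjacency), x$params$density, x$params$block))
  cat(sprintf("clusters (k = %d): %s\n", x$clustering$n_clusters,
              paste(sprintf("%s(n=%d)", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  for (cl in names(x$cluster_hubs)) {
    hs <- x$cluster_hubs[[cl]]
    cat(sprintf("cluster %s hubs (top %.0f%% degree): %s\n", cl,
                100 * hs$fraction, paste(hs$channels, collapse = ", ")))
    if (!is.null(hs$regions))
      cat("  regions: ", paste(unique(hs$regions), collapse = "; "), "\n")
  }
  if (!is.null(x$se_summary)) {
    cat("synchronization error by cluster:\n")
    print(x$se_summary, row.names = FALSE)
  }
  if (!is.null(x$se_test))
    cat(sprintf("SE cluster difference: t = %.3f, p = %.4f\n",
                x$se_test$statistic, x$se_test$p_value))
  invisible(x)
}

#' Between-cluster t-test on region-of-interest degree
#'
#' Per subject the mean degree over the region's channels, compared between
#' two clusters with an unpaired t-test.
#'
#' @param pipeline An `fnirs_pipeline` with a 2-cluster solution.
#' @param region Region label(s) defining the ROI.
#' @param map A `channel_map`.
#' @param ... Passed to [group_ttest()].
#' @return A `group_comparison`.
#' @export
roi_degree_test <- function(pipeline, region, map = channel_map(), ...) {
  stopifnot(inherits(pipeline, "fnirs_pipeline"))
  cls <- sort(unique(pipeline$labels))
  if (length(cls) != 2L)
    stop("ROI test needs exactly 2 clusters; found ", length(cls))
  vals <- vapply(pipeline$degrees, roi_degree, numeric(1),
                 region = region, map = map)
  group_ttest(vals[pipeline$labels == cls[1L]],
              vals[pipeline$labels == cls[2L]],
              measure = paste("ROI degree:", paste(region, collapse = "+")),
              ...)
}
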