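#' Degree centrality of every node
#'
#' k_i = sum_j a_ij, the number of edges incident to node i — the count of
#' channels a channel is functionally connected with in the binarized graph.
#' Invalid channels get `NA`.
#'
#' @param adj An `adjacency_matrix` (from [proportional_threshold()]) or a
#'   plain binary symmetric matrix.
#' @return Object of class `degree_vector`: list with `k` (per-node degree,
#'   `NA` for invalid channels), `n_valid`, `edge_count`.
#' @export
degree <- function(adj) {
  if (!inherits(adj, "adjacency_matrix")) {
    m <- as.matrix(adj)
    adj <- list(a = m, n_nodes = nrow(m), valid_channels = rep(TRUE, nrow(m)),
                edge_count = sum(m) / 2)
  }
  a <- adj$a
  if (!isTRUE(all.equal(a, t(a))) || any(diag(a) != 0))
    stop("adjacency must be symmetric with zero diagonal")
  k <- rowSums(a)
  k[!adj$valid_channels] <- NA_real_
  ec <- sum(k, na.rm = TRUE) / 2
  # handshake lemma: twice the edge count equals the degree sum
  stopifnot(isTRUE(all.equal(sum(k, na.rm = TRUE), 2 * ec)))
  structure(list(k = k, n_valid = sum(adj$valid_channels),
                 edge_count = ec),
            class = "degree_vector")
}

#' @export
print.degree_vector <- function(x, ...) {
  cat(sprintf("degree_vector: %d valid nodes, %g edges, degree range [%g, %g]\n",
              x$n_valid, x$edge_count, min(x$k, na.rm = TRUE),
              max(x$k, na.rm = TRUE)))
  invisible(x)
}

#' Top-degree hub channels
#'
#' The `ceiling(fraction * n_valid)` valid channels with the highest degree.
#' Ties at the cutoff are resolved by ascending channel index (and flagged
#' with a warning), so the selection is deterministic.
#'
#' @param deg A `degree_vector`.
#' @param fraction Selection fraction in (0, 1\]; default 0.10.
#' @param map Optional `channel_map` used to attach region labels.
#' @return Object of class `hub_set`: list with `channels` (sorted indices),
#'   `fraction`, `regions` (labels, if a map was given), `tied` (logical).
#' @export
top_degree_hubs <- function(deg, fraction = 0.10, map = NULL) {
  stopifnot(inherits(deg, "degree_vector"))
  if (!(fraction > 0 && fraction <= 1))
    stop("'fraction' must lie in (0, 1]")
  m <- ceiling(fraction * deg$n_valid)
  valid_idx <- which(!is.na(deg$k))
  ord <- valid_idx[order(-deg$k[valid_idx], valid_idx)]
  chosen <- ord[seq_len(m)]
  cutoff <- deg$k[ord[m]]
  tied <- m < length(ord) && deg$k[ord[m + 1L]] == cutoff
  if (tied)
    warning("degree ties at the hub cutoff (k = ", cutoff,
            "); lower channel indices preferred")
  channels <- sort(chosen)
  structure(list(channels = channels, fraction = fraction,
                 regions = if (!is.null(map)) region_of(channels, map),
                 tied = tied),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set: top %.0f%% degree, %d channels%s\n", 100 * x$fraction,
              length(x$channels), if (x$tied) " (ties at cutoff)" else ""))
  if (!is.null(x$regions)) {
    print(data.frame(channel = x$channels, region = x$regions),
          row.names = FALSE)
  } else cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Consensus (prevalence) edges over a set of subjects
#'
#' For each channel pair, the prevalence is the fraction of subjects — among
#' those in which both channels are valid — whose graph contains the edge.
#' Pairs at or above the prevalence threshold are returned.
#'
#' @param adjs Non-empty list of `adjacency_matrix` objects on a common
#'   node indexing.
#' @param prevalence Inclusion threshold (default 0.60, inclusive).
#' @return data.frame with columns `channel_i`, `channel_j`, `prevalence`,
#'   `n_subjects` (denominator per pair), sorted by decreasing prevalence.
#' @export
consensus_edges <- function(adjs, prevalence = 0.60) {
  if (!is.list(adjs) || length(adjs) == 0L)
    stop("'adjs' must be a non-empty list of adjacency matrices")
  nc <- adjs[[1L]]$n_nodes
  if (!all(vapply(adjs, function(a) a$n_nodes == nc, logical(1))))
    stop("all adjacency matrices must share the node indexing")
  present <- matrix(0, nc, nc)
  denom <- matrix(0, nc, nc)
  for (adj in adjs) {
    v <- adj$valid_channels
    both <- outer(v, v, "&")
    denom <- denom + both
    present <- present + adj$a * both
  }
  prev <- ifelse(denom > 0, present / denom, NA_real_)
  ut <- which(upper.tri(prev), arr.ind = TRUE)
  out <- data.frame(channel_i = ut[, 1L], channel_j = ut[, 2L],
                    prevalence = prev[ut], n_subjects = denom[ut])
  out <- out[!is.na(out$prevalence) & out$prevalence >= prevalence, ]
  out <- out[order(-out$prevalence, out$channel_i, out$channel_j), ]
  rownames(out) <- NULL
  out
}

#' Mean degree over a region of interest
#'
#' Per-subject scalar: the mean degree over the (valid) channels that the
#' anatomical lookup assigns to the requested region label(s).  Used as the
#' unit for between-cluster t-tests on ROI centrality.
#'
#' @param deg A `degree_vector`.
#' @param region Region label or vector of labels.
#' @param map A `channel_map`.
#' @return Numeric scalar (NA, with a message, if every channel of the
#'   region is invalid for this subject).
#' @export
roi_degree <- function(deg, region, map = channel_map()) {
  stopifnot(inherits(deg, "degree_vector"))
  ch <- channels_of_region(region, map)
  vals <- deg$k[ch]
  if (all(is.na(vals))) {
    message("all channels of region '", paste(region, collapse = "+"),
            "' are invalid for this subject")
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}
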