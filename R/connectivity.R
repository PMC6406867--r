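#' Fisher z-transformation of correlation coefficients
#'
#' z = atanh(r), the variance-stabilizing transform that approximately
#' normalizes the sampling distribution of Pearson correlations.  Values at
#' or beyond |r| = 1 (degenerate, e.g. a channel correlated with itself) are
#' clipped to atanh(1 - eps) so the transform stays finite.
#'
#' @param r Numeric vector or matrix of correlations in \[-1, 1\].
#' @param eps Clipping margin (default 1e-7).
#' @return Same shape as `r`, Fisher z values.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  clipped <- abs(r) >= 1 - eps & !is.na(r)
  if (any(clipped))
    warning(sum(clipped), " correlation(s) at |r| >= 1 - eps were clipped")
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Task-block functional connectivity matrix
#'
#' Pairwise Pearson correlations of the Oxy-Hb traces over the samples of
#' the requested block, Fisher z-transformed.  Entries touching an invalid
#' channel, or a channel with zero variance inside the block, are `NA`.
#'
#' @param series An [hb_series()] (normally preprocessed).
#' @param block Block label (default `"task"`).
#' @return Object of class `connectivity_matrix`: list with `values`
#'   (symmetric channels x channels Fisher-z matrix, `NA` diagonal),
#'   `valid_channels`, `block_used`, `n_samples_used`.
#' @export
task_block_correlation <- function(series, block = "task") {
  stopifnot(inherits(series, "hb_series"))
  idx <- block_samples(series, block)
  if (length(idx) < 3L)
    stop("block '", block, "' has fewer than 3 samples")
  nc <- n_channels(series)
  x <- t(series$oxy[, idx, drop = FALSE])        # samples x channels
  valid <- series$valid_channels
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0
  if (any(flat & valid))
    warning("zero-variance trace in block '", block, "' on channel(s) ",
            paste(which(flat & valid), collapse = ", "),
            "; entries marked missing")
  usable <- valid & !flat
  vals <- matrix(NA_real_, nc, nc)
  if (sum(usable) >= 2L) {
    r <- stats::cor(x[, usable, drop = FALSE])
    diag(r) <- NA_real_
    vals[usable, usable] <- suppressWarnings(fisher_z(r))
  }
  diag(vals) <- NA_real_
  structure(list(values = vals, valid_channels = valid & !flat,
                 block_used = block, n_samples_used = length(idx)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d channels (%d valid), block '%s', %d samples\n",
              nrow(x$values), sum(x$valid_channels), x$block_used,
              x$n_samples_used))
  invisible(x)
}

#' Binarize a connectivity matrix at a fixed edge density
#'
#' Proportional thresholding: among the M available (non-missing) channel
#' pairs, the `round(density * M)` pairs with the largest Fisher z become
#' edges (round half up; ties at the cutoff resolved by ascending (i, j)
#' index order).  Ranking is on signed z by default, so strong negative
#' correlations are never selected; set `absolute = TRUE` to rank |z|.
#'
#' @param conn A `connectivity_matrix` (or a plain symmetric matrix, in
#'   which case all channels are taken as valid).
#' @param density Target edge density in (0, 1); default 0.15.
#' @param absolute Rank by absolute z (default `FALSE`).
#' @return Object of class `adjacency_matrix`: list with `a` (binary
#'   symmetric matrix, zero diagonal), `n_nodes`, `valid_channels`,
#'   `target_density`, `edge_count`, `achieved_density`.
#' @export
proportional_threshold <- function(conn, density = 0.15, absolute = FALSE) {
  if (!inherits(conn, "connectivity_matrix")) {
    m <- as.matrix(conn)
    conn <- list(values = m, valid_channels = rep(TRUE, nrow(m)))
  }
  if (!(density > 0 && density < 1))
    stop("'density' must lie strictly between 0 and 1")
  vals <- conn$values
  nc <- nrow(vals)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  z <- vals[ut]
  avail <- !is.na(z)
  M <- sum(avail)
  if (M < 1L) stop("no available channel pairs to threshold")
  quota <- floor(density * M + 0.5)              # round half up
  if (quota < 1L)
    stop("density ", density, " keeps zero of ", M, " pairs")
  rank_z <- if (absolute) abs(z) else z
  ord <- order(-rank_z, ut[, 1L], ut[, 2L], na.last = TRUE)
  keep <- ord[seq_len(quota)]
  a <- matrix(0L, nc, nc)
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  structure(list(a = a, n_nodes = nc,
                 valid_channels = conn$valid_channels,
                 target_density = density,
                 edge_count = as.integer(quota),
                 achieved_density = quota / M),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("adjacency_matrix: %d nodes (%d valid), %d edges, density %.4f (target %.2f)\n",
              x$n_nodes, sum(x$valid_channels), x$edge_count,
              x$achieved_density, x$target_density))
  invisible(x)
}

#' Edge density of a binary graph
#'
#' Edge count divided by the number of possible pairs among valid nodes.
#'
#' @param adj An `adjacency_matrix`.
#' @return Fraction in \[0, 1\].
#' @export
density_of <- function(adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  nv <- sum(adj$valid_channels)
  if (nv < 2L) stop("need at least 2 valid nodes")
  sum(adj$a[adj$valid_channels, adj$valid_channels]) / 2 / (nv * (nv - 1) / 2)
}

#' Write a connectivity or adjacency matrix as delimited text
#'
#' Square matrix with channel-id headers, plus an edge-list file
#' (channel_i, channel_j, z, kept) when both objects are supplied.
#'
#' @param conn A `connectivity_matrix` or `NULL`.
#' @param adj An `adjacency_matrix` or `NULL`.
#' @param path_matrix,path_edges Output file paths (`NULL` to skip).
#' @return `NULL`, invisibly.
#' @export
write_connectivity <- function(conn = NULL, adj = NULL,
                               path_matrix = NULL, path_edges = NULL) {
  if (!is.null(path_matrix)) {
    m <- if (!is.null(conn)) conn$values else adj$a
    dimnames(m) <- list(paste0("ch", seq_len(nrow(m))),
                        paste0("ch", seq_len(ncol(m))))
    utils::write.table(m, path_matrix, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(path_edges) && !is.null(conn) && !is.null(adj)) {
    ut <- which(upper.tri(conn$values), arr.ind = TRUE)
    el <- data.frame(channel_i = ut[, 1L], channel_j = ut[, 2L],
                     z = conn$values[ut], kept = adj$a[ut])
    el <- el[!is.na(el$z), ]
    utils::write.table(el, path_edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
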