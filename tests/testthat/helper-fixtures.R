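# Small fixtures shared across test files; everything is built in code.

# minimal hb_series with given channel traces (rows) and a single task block
toy_series <- function(traces, fs = 10, id = "toy") {
  traces <- as.matrix(traces)
  n <- ncol(traces)
  blocks <- data.frame(block = "task", start = 1L, end = n)
  hb_series(traces, -traces / 3, fs, blocks, subject_id = id)
}

# standard-length (101 s @ 10 Hz) series from a channels x 1010 matrix
full_series <- function(traces, id = "toy") {
  hb_series(as.matrix(traces), -as.matrix(traces) / 3, 10,
            block_annotation(), subject_id = id)
}

# a small reproducible dataset for end-to-end smoke tests: fewer subjects
# than the study default to keep the suite fast
small_dataset <- function(seed = 5, n_per_group = 3, coupling = 0.9) {
  generate_dataset(generator_config(
    n_subjects = 2 * n_per_group,
    group_assignment = rep(c("A", "B"), each = n_per_group),
    coupling_strength = coupling,
    artifact_spec = data.frame(subject = integer(0), channel = integer(0),
                               sample = integer(0), amplitude = numeric(0)),
    seed = seed))
}

# independent brute-force degree: explicit per-node neighbour count
brute_force_degree <- function(a) {
  vapply(seq_len(nrow(a)), function(i) sum(a[i, -i] != 0), numeric(1))
}

# independent Ward criterion: increase in total within-cluster sum of
# squares when merging clusters A and B (Lance-Williams-free formulation)
ward_delta_ss <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  na <- nrow(xa); nb <- nrow(xb)
  d <- colMeans(xa) - colMeans(xb)
  na * nb / (na + nb) * sum(d^2)
}

# exhaustive-agglomeration Ward oracle: returns the partition sequence
# obtained by always merging the pair with the smallest delta-SS
ward_oracle_merges <- function(x) {
  x <- as.matrix(x)
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- ward_delta_ss(x[clusters[[i]], , drop = FALSE],
                         x[clusters[[j]], , drop = FALSE])
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}
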