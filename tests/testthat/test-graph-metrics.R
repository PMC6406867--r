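test_that("degree matches hand-checked small graphs", {
  k4 <- matrix(1, 4, 4) - diag(4)                 # complete graph
  expect_equal(degree(k4)$k, rep(3, 4))
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(degree(path)$k, c(1, 2, 1))
})

test_that("degree equals the brute-force oracle on random graphs up to 8 nodes", {
  set.seed(80)
  for (nn in 2:8) {
    for (rep in 1:25) {
      a <- matrix(0L, nn, nn)
      a[upper.tri(a)] <- rbinom(nn * (nn - 1) / 2, 1, runif(1, 0.1, 0.9))
      a <- a + t(a)
      dv <- degree(a)
      expect_equal(dv$k, brute_force_degree(a))
      expect_equal(sum(dv$k), 2 * dv$edge_count)  # handshake lemma
    }
  }
})

test_that("degree cross-checks against igraph on a larger random graph", {
  skip_if_not_installed("igraph")
  set.seed(81)
  a <- matrix(0L, 30, 30)
  a[upper.tri(a)] <- rbinom(435, 1, 0.2)
  a <- a + t(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_equal(degree(a)$k, as.numeric(igraph::degree(g)))
})

test_that("degree rejects asymmetric or self-looped matrices", {
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1
  expect_error(degree(bad), "symmetric")
  loop <- diag(3)
  expect_error(degree(loop), "symmetric|diagonal")
})

test_that("hub selection takes the ceiling of the fraction with index tie-break", {
  # 116 valid nodes at 10% -> ceil(11.6) = 12 hubs
  set.seed(82)
  a <- matrix(0L, 116, 116)
  a[upper.tri(a)] <- rbinom(6670, 1, 0.15)
  a <- a + t(a)
  hubs <- suppressWarnings(top_degree_hubs(degree(a), 0.10))
  expect_equal(length(hubs$channels), 12)
  k <- degree(a)$k
  expect_true(min(k[hubs$channels]) >= max(k[-hubs$channels]) ||
              hubs$tied)
  # hub-set size formula across all valid node counts
  for (nv in c(2, 5, 20, 116))
    expect_equal(ceiling(0.10 * nv),
                 length(suppressWarnings(
                   top_degree_hubs(degree(matrix(1, nv, nv) - diag(nv)),
                                   0.10))$channels))
})

test_that("equal degrees select the lowest-indexed channels with a warning", {
  a <- matrix(1L, 10, 10) - diag(10L)             # all degrees equal
  expect_warning(hubs <- top_degree_hubs(degree(a), 0.3), "tie")
  expect_equal(hubs$channels, 1:3)
})

test_that("fraction 1 returns every valid channel", {
  a <- matrix(1L, 6, 6) - diag(6L)
  expect_equal(top_degree_hubs(degree(a), 1)$channels, 1:6)
})

test_that("hub sets carry region labels when a channel map is supplied", {
  a <- matrix(0L, 116, 116)
  a[7, 8] <- a[8, 7] <- 1L; a[7, 9] <- a[9, 7] <- 1L
  hubs <- suppressWarnings(top_degree_hubs(degree(a), 0.005, channel_map()))
  expect_equal(hubs$channels, 7)
  expect_equal(hubs$regions, "left middle frontal gyrus")
})

test_that("consensus edges respect the inclusive prevalence boundary", {
  mk <- function(pairs, nn = 5) {
    a <- matrix(0L, nn, nn)
    for (p in pairs) { a[p[1], p[2]] <- 1L; a[p[2], p[1]] <- 1L }
    structure(list(a = a, n_nodes = nn, valid_channels = rep(TRUE, nn),
                   target_density = 0.5, edge_count = length(pairs),
                   achieved_density = 0.5), class = "adjacency_matrix")
  }
  # edge (1,2) in 3/5 subjects, edge (3,4) in 2/5
  adjs <- list(mk(list(c(1, 2), c(3, 4))), mk(list(c(1, 2))),
               mk(list(c(1, 2), c(3, 4))), mk(list(c(4, 5))),
               mk(list(c(2, 3))))
  ce <- consensus_edges(adjs, 0.60)
  expect_true(any(ce$channel_i == 1 & ce$channel_j == 2))
  expect_equal(ce$prevalence[ce$channel_i == 1 & ce$channel_j == 2], 0.6)
  expect_false(any(ce$channel_i == 3 & ce$channel_j == 4))
  # identical graphs give prevalence 1 everywhere
  same <- consensus_edges(list(mk(list(c(1, 2))), mk(list(c(1, 2)))), 0.6)
  expect_equal(same$prevalence, 1)
  expect_error(consensus_edges(list()), "non-empty")
})

test_that("consensus edge count is monotone non-increasing in the threshold", {
  set.seed(83)
  adjs <- lapply(1:6, function(i) {
    a <- matrix(0L, 10, 10)
    a[upper.tri(a)] <- rbinom(45, 1, 0.3)
    a <- a + t(a)
    structure(list(a = a, n_nodes = 10, valid_channels = rep(TRUE, 10),
                   target_density = 0.3, edge_count = sum(a) / 2,
                   achieved_density = 0.3), class = "adjacency_matrix")
  })
  counts <- vapply(seq(0.1, 1, by = 0.1),
                   function(th) nrow(consensus_edges(adjs, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus denominators skip subjects with invalid channels", {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 1] <- 1L
  good <- structure(list(a = a, n_nodes = 3, valid_channels = rep(TRUE, 3),
                         target_density = 0.3, edge_count = 1,
                         achieved_density = 0.3), class = "adjacency_matrix")
  masked <- good
  masked$a[] <- 0L
  masked$valid_channels <- c(FALSE, TRUE, TRUE)
  ce <- consensus_edges(list(good, masked), 0.9)
  # pair (1,2) valid only in the first subject: prevalence 1/1
  expect_equal(ce$prevalence[ce$channel_i == 1 & ce$channel_j == 2], 1)
  expect_equal(ce$n_subjects[ce$channel_i == 1 & ce$channel_j == 2], 1)
})

test_that("ROI degree averages the region's channels and handles missing", {
  a <- matrix(0L, 116, 116)
  # give channels 7 and 8 (both LMFG) degrees 2 and 4
  a[7, c(1, 2)] <- 1L; a[c(1, 2), 7] <- 1L
  a[8, c(1, 2, 3, 4)] <- 1L; a[c(1, 2, 3, 4), 8] <- 1L
  dv <- degree(a)
  lmfg <- "left middle frontal gyrus"
  expect_equal(roi_degree(dv, "right supramarginal gyrus"), dv$k[10])
  expect_equal(mean(dv$k[channels_of_region(lmfg)]),
               roi_degree(dv, lmfg))
  # all-invalid region gives NA with a message
  dv$k[channels_of_region("right postcentral gyrus")] <- NA
  expect_message(v <- roi_degree(dv, "right postcentral gyrus"), "invalid")
  expect_true(is.na(v))
})
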