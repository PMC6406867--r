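test_that("generator config validates its fields by name", {
  expect_error(generator_config(n_subjects = 3), "group_assignment")
  expect_error(generator_config(hub_channels_per_group = list(
    A = c(7, 200), B = c(59))), "hub_channels_per_group")
  expect_error(generator_config(coupling_strength = 1.2), "coupling_strength")
  expect_error(generator_config(block_durations = c(pre_scan = -1, control = 30,
                                                    task = 21, post_control = 30)),
               "block_durations")
  expect_error(generator_config(
    se_params_per_group = list(A = c(mean = 0, sd = -1),
                               B = c(mean = 0, sd = 1))), "se_params")
})

test_that("default dataset has the study dimensions", {
  ds <- small_dataset(seed = 1, n_per_group = 1)
  s <- ds$series[[1]]
  expect_equal(n_channels(s), 116)
  expect_equal(n_samples(s), 1010)           # 101 s at 10 Hz
  expect_equal(s$blocks$block, c("pre_scan", "control", "task", "post_control"))
  expect_equal(s$blocks$end - s$blocks$start + 1L, c(200L, 300L, 210L, 300L))
  expect_equal(dim(s$oxy), dim(s$deoxy))
})

test_that("equal seeds give bit-identical datasets", {
  d1 <- small_dataset(seed = 42, n_per_group = 2)
  d2 <- small_dataset(seed = 42, n_per_group = 2)
  expect_identical(d1$series, d2$series)
  expect_identical(d1$behavior, d2$behavior)
  d3 <- small_dataset(seed = 43, n_per_group = 2)
  expect_false(identical(d1$series[[1]]$oxy, d3$series[[1]]$oxy))
})

test_that("adding subjects does not reshuffle earlier subjects", {
  base <- generator_config(n_subjects = 4,
                           group_assignment = rep(c("A", "B"), each = 2),
                           seed = 7)
  more <- generator_config(n_subjects = 6,
                           group_assignment = rep(c("A", "B"), each = 3),
                           seed = 7)
  d4 <- generate_dataset(base)
  d6 <- generate_dataset(more)
  expect_identical(d4$series[[1]]$oxy, d6$series[[1]]$oxy)
  expect_identical(d4$series[[2]]$oxy, d6$series[[2]]$oxy)
})

test_that("network signal: zero coupling gives near-zero mean correlation", {
  x <- generate_network_signal(6, hub_set = 1:3, coupling_strength = 0,
                               n_samples = 10000, seed = 9)
  cm <- cor(t(x))
  offdiag <- cm[upper.tri(cm)]
  expect_true(all(abs(offdiag) < 0.1))
})

test_that("network signal: full coupling makes connected channels identical", {
  x <- generate_network_signal(4, hub_set = c(1, 2), coupling_strength = 1,
                               n_samples = 2000, seed = 10)
  expect_equal(cor(x[1, ], x[2, ]), 1.0, tolerance = 1e-12)
  expect_lt(abs(cor(x[1, ], x[3, ])), 0.2)
})

test_that("connected pairs correlate more than unconnected at moderate coupling", {
  x <- generate_network_signal(20, hub_set = 1:5, coupling_strength = 0.7,
                               n_samples = 10000, seed = 11)
  cm <- cor(t(x))
  conn <- cm[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  unconn <- cm[6:20, 6:20][upper.tri(matrix(0, 15, 15))]
  expect_gt(mean(conn), mean(unconn) + 0.3)
  expect_equal(mean(conn), 0.7, tolerance = 0.1)
})

test_that("mean connected-pair correlation is non-decreasing in coupling", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid, function(cs) {
    x <- generate_network_signal(10, hub_set = 1:4, coupling_strength = cs,
                                 n_samples = 5000, seed = 12)
    cm <- cor(t(x))
    mean(cm[1:4, 1:4][upper.tri(matrix(0, 4, 4))])
  }, numeric(1))
  expect_true(all(diff(means) > -0.02))
  expect_gt(means[5], 0.95)
})

test_that("network signal rejects bad inputs", {
  expect_error(generate_network_signal(5, integer(0), 0.5, 100), "non-empty")
  expect_error(generate_network_signal(5, 1:2, 1.5, 100), "coupling")
  expect_error(generate_network_signal(5, c(1, 9), 0.5, 100), "out of range")
})

test_that("band-limited noise is confined to its band", {
  set.seed(13)
  x <- band_limited_noise(4000, 3, sampling_rate = 10, band = c(0.01, 0.3))
  sp <- stats::spec.pgram(x[, 1], plot = FALSE, taper = 0)
  inband <- sp$freq * 10 >= 0.01 & sp$freq * 10 <= 0.3
  expect_gt(sum(sp$spec[inband]), 0.99 * sum(sp$spec))
  expect_equal(apply(x, 2, sd), rep(1, 3), tolerance = 1e-9)
})

test_that("behavior generator plants the requested SE distribution", {
  # degenerate sd: every SE exactly the planted mean
  st <- stimulus_schedule(seq(1, 7))
  r0 <- generate_behavior(st, 100, 0, seed = 1)
  expect_equal((r0$responses - st$onsets) * 1000, rep(100, 7))
  # large-sample moments approach the planted parameters (sd/sqrt(n) scale)
  st_big <- stimulus_schedule(seq(10, 10 + 9999 * 5, by = 5))
  rA <- generate_behavior(st_big, 90.0, 154.9, seed = 2)
  seA <- (rA$responses - st_big$onsets) * 1000
  expect_lt(abs(mean(seA) - 90.0), 5)
  expect_equal(sd(seA), 154.9, tolerance = 0.05)
  rB <- generate_behavior(st_big, -8.9, 261.5, seed = 3)
  expect_lt(mean((rB$responses - st_big$onsets) * 1000), 0)
})

test_that("responses outside the recording window are clipped and flagged", {
  st <- stimulus_schedule(c(0.5, 1))
  r <- generate_behavior(st, 5000, 0, window = c(0, 2))
  expect_true(all(r$responses <= 2))
  expect_true(any(r$clipped))
})

test_that("motion step injection is a persistent step of the stated height", {
  s <- full_series(matrix(0, 2, 1010))
  s2 <- inject_motion_step(s, 1, 100, 0.12)
  d <- diff(s2$oxy[1, ])
  expect_equal(d[99], 0.12)
  expect_equal(sum(d != 0), 1)
  expect_equal(s2$oxy[1, 100:1010], rep(0.12, 911))
  # zero amplitude leaves the series unchanged
  expect_identical(inject_motion_step(s, 1, 100, 0)$oxy, s$oxy)
  expect_error(inject_motion_step(s, 3, 100, 0.1), "channel")
  expect_error(inject_motion_step(s, 1, 2000, 0.1), "sample")
})

test_that("injected artifacts are caught by the screening stage", {
  cfg <- generator_config(
    n_subjects = 2, group_assignment = c("A", "B"),
    artifact_spec = data.frame(subject = 1L, channel = 50L,
                               sample = 300L, amplitude = 0.12),
    seed = 3)
  ds <- generate_dataset(cfg)
  valid <- detect_motion_channels(ds$series[[1]])
  expect_false(valid[50])
  expect_true(all(valid[-50]))
  expect_true(all(detect_motion_channels(ds$series[[2]])))
})

test_that("ground truth records groups, hubs, peripherals and seeds", {
  ds <- small_dataset(seed = 4, n_per_group = 2)
  gt <- ds$ground_truth
  expect_equal(unname(gt$group), c("A", "A", "B", "B"))
  expect_equal(sort(names(gt$hubs)), c("A", "B"))
  expect_equal(length(gt$peripherals$A), 47)
  expect_equal(length(intersect(gt$peripherals$A, gt$peripherals$B)), 0)
  expect_equal(length(intersect(unlist(gt$hubs), unlist(gt$peripherals))), 0)
  a <- gt$planted_adjacency$A
  expect_true(all(a == t(a)) && all(diag(a) == 0))
  expect_equal(length(gt$subject_seeds), 4)
})

test_that("subject data survive a plain-text write/read round trip", {
  ds <- small_dataset(seed = 6, n_per_group = 1)
  dir <- file.path(tempdir(), "fnirsnet-roundtrip")
  write_dataset(ds, dir)
  back <- read_subject_data(dir, "sub01")
  expect_equal(back$series$oxy, ds$series[[1]]$oxy, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$series$blocks$block, ds$series[[1]]$blocks$block)
  expect_equal(back$series$sampling_rate, 10)
  ev <- back$events
  expect_true(all(c("onset_s", "event_type", "block") %in% names(ev)))
  expect_equal(sum(ev$event_type == "stimulus"), 7)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  unlink(dir, recursive = TRUE)
})
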