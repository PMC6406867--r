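test_that("schedules enforce strictly increasing onsets", {
  expect_error(stimulus_schedule(c(1, 1, 2)), "increasing")
  expect_error(stimulus_schedule(numeric(0)), "at least one")
  s <- control_schedule(50, 30, 0.5)
  expect_equal(length(s$onsets), 59)
  expect_equal(diff(s$onsets), rep(0.5, 58))
})

test_that("task schedule has lengthening intervals and the right count", {
  set.seed(1)
  s <- task_schedule(50, n_stimuli = 7, jitter = 0.03)
  expect_equal(length(s$onsets), 7)
  iv <- diff(s$onsets)
  expect_true(all(diff(iv) > 0))                  # intervals grow
  expect_equal(iv, (1:6) * 0.6, tolerance = 0.1)  # ~0.6 s increments
  expect_true(max(s$onsets) - 50 < 21)            # fits the 21 s block
})

test_that("responses at the stimuli give SE exactly zero", {
  st <- stimulus_schedule(c(1, 2, 3.5))
  pairs <- match_responses(st, c(1, 2, 3.5))
  expect_equal(synchronization_error(pairs, drop_first = FALSE), c(0, 0, 0))
})

test_that("SE arithmetic and sign convention", {
  st <- stimulus_schedule(c(1.0))
  expect_equal(synchronization_error(match_responses(st, 1.2),
                                     drop_first = FALSE), 200)
  expect_equal(synchronization_error(match_responses(st, 0.9),
                                     drop_first = FALSE), -100)
})

test_that("a missing response yields one missing SE, others unaffected", {
  st <- stimulus_schedule(c(1, 2, 3))
  pairs <- match_responses(st, c(1.05, 3.1))
  se <- synchronization_error(pairs, drop_first = FALSE)
  expect_equal(se, c(50, NA, 100))
})

test_that("equidistant responses go to the earlier stimulus and are flagged", {
  st <- stimulus_schedule(c(1, 2))
  pairs <- match_responses(st, 1.5)
  expect_equal(pairs$response, c(1.5, NA))
  expect_true(pairs$tie[1])
})

test_that("each response is used at most once", {
  st <- stimulus_schedule(c(1, 2))
  pairs <- match_responses(st, c(1.9))
  # single response near stimulus 2: only one SE
  expect_equal(sum(!is.na(pairs$response)), 1)
  expect_equal(pairs$response[2], 1.9)
})

test_that("all-unmatched responses warn and give empty SE", {
  st <- stimulus_schedule(c(1, 2))
  expect_warning(pairs <- match_responses(st, c(10)), "no responses")
  expect_true(all(is.na(pairs$response)))
})

test_that("seven task stimuli give six SE values after first-cue exclusion", {
  set.seed(2)
  sched <- task_schedule(50)
  rec <- generate_behavior(sched, 100, 0, subject_id = "s1")
  expect_equal(length(record_se(rec)), 6)
  expect_equal(record_se(rec), rep(100, 6), tolerance = 1e-9)
})

test_that("cluster SE summary aggregates within subject first", {
  st <- stimulus_schedule(c(1, 2, 3))
  mk <- function(se_ms, id) behavioral_record(id, st, st$onsets + se_ms / 1000)
  records <- list(mk(10, "a1"), mk(-10, "a2"), mk(50, "b1"), mk(70, "b2"))
  out <- cluster_se_summary(records, c("A", "A", "B", "B"))
  expect_equal(out$mean_ms[out$cluster == "A"], 0)
  expect_equal(out$mean_ms[out$cluster == "B"], 60)
  expect_equal(out$sd_ms[out$cluster == "B"], sd(c(50, 70)))
  # invariant to subject order
  out2 <- cluster_se_summary(records[c(3, 1, 4, 2)], c("B", "A", "B", "A"))
  expect_equal(out2, out)
  expect_error(cluster_se_summary(records, c("A", "A", "B")), "one entry")
})

test_that("single subject with SE +10/-10 averages to zero; equal SEs give sd 0", {
  st <- stimulus_schedule(c(1, 2))
  r <- behavioral_record("s", st, c(1.010, 1.990))
  expect_equal(mean(synchronization_error(
    match_responses(st, r$responses), drop_first = FALSE)), 0)
  same <- list(behavioral_record("x", st, c(1.02, 2.02)),
               behavioral_record("y", st, c(1.02, 2.02)))
  out <- cluster_se_summary(same, c("A", "A"))
  expect_equal(out$sd_ms, 0)
})

test_that("t-test matches the closed-form pooled statistic", {
  a <- c(0.1, -0.2, 0.05, 0)
  b <- c(1.1, 0.9, 1.05, 1.0)
  cmp <- group_ttest(a, b)
  # textbook pooled-variance formula, computed independently
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_manual), df = 6), tolerance = 1e-12)
  expect_true(cmp$significant)
})

test_that("identical samples give t = 0, p = 1; swap flips the sign only", {
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  a <- rnorm(5); b <- rnorm(5) + 1
  ab <- group_ttest(a, b); ba <- group_ttest(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("degenerate zero-variance samples follow the stated convention", {
  expect_warning(same <- group_ttest(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(same$p_value, 1)
  expect_warning(diff <- group_ttest(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(diff$p_value, 0)
  expect_true(diff$degenerate)
})

test_that("Welch option is honoured", {
  set.seed(9)
  a <- rnorm(10, sd = 1); b <- rnorm(10, sd = 5) + 1
  welch <- group_ttest(a, b, var_equal = FALSE)
  ref <- t.test(a, b)
  expect_equal(welch$statistic, unname(ref$statistic))
  expect_equal(welch$p_value, ref$p.value)
})
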