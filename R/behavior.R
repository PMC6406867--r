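#' Auditory stimulus schedule
#'
#' Ordered onset times of the tapping cues within one block.  In the control
#' block cues are isochronous (0.5 s inter-stimulus interval); in the task
#' block the seven cues have intervals that grow by roughly 0.6 s per
#' stimulus, so the subject must extrapolate the accelerating-interval rule
#' rather than a fixed beat.
#'
#' @param onsets Strictly increasing onset times in seconds (relative to the
#'   start of the recording).
#' @param block Block label the cues belong to.
#' @param tone_frequency Cue tone frequency in Hz (default 500).
#' @param tone_duration Cue tone duration in seconds (default 0.1).
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(onsets, block = "task",
                              tone_frequency = 500, tone_duration = 0.1) {
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0L) stop("schedule must contain at least one onset")
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  structure(list(onsets = onsets, block = block,
                 tone_frequency = tone_frequency,
                 tone_duration = tone_duration),
            class = "stimulus_schedule")
}

#' Build the task-block stimulus schedule
#'
#' The first cue (a start reminder, later excluded from synchronization-error
#' analysis) is placed `start_delay` seconds into the task block; the k-th
#' inter-stimulus interval is `k * base_increment` plus a uniform jitter of
#' half-width `jitter`, giving a regularly lengthening cue train.
#'
#' @param task_start Task-block start time in seconds.
#' @param n_stimuli Number of cues (default 7).
#' @param base_increment Interval growth per stimulus in seconds (default 0.6).
#' @param jitter Half-width of the uniform interval jitter in seconds
#'   (default 0.03); drawn from the current RNG state.
#' @param start_delay Delay of the first cue after block start (default 0.5 s).
#' @return A [stimulus_schedule()] for the task block.
#' @export
task_schedule <- function(task_start, n_stimuli = 7, base_increment = 0.6,
                          jitter = 0.03, start_delay = 0.5) {
  if (n_stimuli < 1) stop("'n_stimuli' must be at least 1")
  k <- seq_len(n_stimuli - 1L)
  intervals <- k * base_increment +
    if (jitter > 0) stats::runif(length(k), -jitter, jitter) else 0
  onsets <- task_start + start_delay + c(0, cumsum(intervals))
  stimulus_schedule(onsets, block = "task")
}

#' Build the isochronous control-block schedule
#'
#' @param control_start,control_duration Block start and length in seconds.
#' @param isi Inter-stimulus interval in seconds (default 0.5).
#' @return A [stimulus_schedule()] for the control block.
#' @export
control_schedule <- function(control_start, control_duration = 30, isi = 0.5) {
  onsets <- seq(control_start + isi, control_start + control_duration - 1e-9,
                by = isi)
  stimulus_schedule(onsets, block = "control")
}

#' Tapping record for one subject
#'
#' @param subject_id Identifier.
#' @param stimuli A [stimulus_schedule()].
#' @param responses Numeric vector of button-press times in seconds (sorted).
#' @param clipped Logical vector marking responses that had to be clipped to
#'   the recording window (optional).
#' @return An object of class `behavioral_record`.
#' @export
behavioral_record <- function(subject_id, stimuli, responses, clipped = NULL) {
  stopifnot(inherits(stimuli, "stimulus_schedule"))
  responses <- sort(as.numeric(responses))
  if (is.null(clipped)) clipped <- rep(FALSE, length(responses))
  structure(list(subject_id = as.character(subject_id), stimuli = stimuli,
                 responses = responses, clipped = as.logical(clipped)),
            class = "behavioral_record")
}

#' Pair responses with stimuli
#'
#' Each stimulus is matched to the nearest response lying within plus/minus
#' half of the local inter-stimulus interval; each response is used at most
#' once, with assignment greedy by proximity and, on exact distance ties, the
#' earlier stimulus winning.  Unmatched stimuli yield `NA` responses.
#'
#' @param stimuli A [stimulus_schedule()] or numeric onset vector.
#' @param responses Sorted numeric response times in seconds.
#' @return data.frame with columns `stimulus`, `response` (NA if unmatched)
#'   and `tie` (response was equidistant between two stimuli).
#' @export
match_responses <- function(stimuli, responses) {
  onsets <- if (inherits(stimuli, "stimulus_schedule")) stimuli$onsets
            else as.numeric(stimuli)
  responses <- sort(as.numeric(responses))
  ns <- length(onsets)
  # local half-window per stimulus: half the smaller neighbouring interval
  iv <- diff(onsets)
  halfwin <- if (ns == 1L) Inf else
    pmin(c(iv[1], iv), c(iv, iv[length(iv)])) / 2
  matched <- rep(NA_real_, ns)
  tie <- rep(FALSE, ns)
  if (length(responses) > 0L) {
    cand <- expand.grid(s = seq_len(ns), r = seq_along(responses))
    cand$dist <- abs(onsets[cand$s] - responses[cand$r])
    cand <- cand[cand$dist <= halfwin[cand$s] + 1e-12, , drop = FALSE]
    # greedy: closest pair first; on distance ties the earlier stimulus wins
    cand <- cand[order(cand$dist, cand$s), , drop = FALSE]
    used_r <- logical(length(responses)); used_s <- logical(ns)
    for (i in seq_len(nrow(cand))) {
      s <- cand$s[i]; r <- cand$r[i]
      if (!used_s[s] && !used_r[r]) {
        dup <- cand$r == r & abs(cand$dist - cand$dist[i]) < 1e-12 & cand$s != s
        if (any(dup)) tie[s] <- TRUE
        matched[s] <- responses[r]
        used_s[s] <- TRUE; used_r[r] <- TRUE
      }
    }
  }
  if (all(is.na(matched)))
    warning("no responses could be matched to any stimulus")
  data.frame(stimulus = onsets, response = matched, tie = tie)
}

#' Synchronization error per tap
#'
#' SE(n) = Response(n) - Stimulus(n), in milliseconds: negative when the
#' subject pressed before the cue (predictive tapping), positive when after
#' it (reactive tapping).  The first task-block stimulus is a start reminder
#' rather than a cue to synchronize with, so its SE is dropped.
#'
#' @param pairs data.frame from [match_responses()].
#' @param drop_first Drop the first stimulus's SE (default `TRUE`).
#' @return Numeric vector of SE values in ms (`NA` for unmatched stimuli).
#' @export
synchronization_error <- function(pairs, drop_first = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("stimulus", "response") %in% names(pairs)))
  se <- (pairs$response - pairs$stimulus) * 1000
  if (drop_first && length(se) >= 1L) se <- se[-1L]
  se
}

#' Synchronization error of a behavioral record
#'
#' Convenience wrapper: match responses, compute SE, drop the first stimulus.
#'
#' @param record A [behavioral_record()].
#' @return Numeric vector of SE values in ms.
#' @export
record_se <- function(record) {
  stopifnot(inherits(record, "behavioral_record"))
  synchronization_error(match_responses(record$stimuli, record$responses))
}

#' Per-cluster synchronization-error summary
#'
#' Aggregates within subject first (mean SE per subject), then summarizes
#' across the subjects of each cluster, so subjects -- not taps -- are the
#' unit of analysis.
#'
#' @param records List of [behavioral_record()]s.
#' @param labels Named vector (or vector aligned with `records`) of cluster
#'   labels, one per subject.
#' @return data.frame with columns `cluster`, `n_subjects`, `mean_ms`, `sd_ms`.
#' @export
cluster_se_summary <- function(records, labels) {
  if (length(labels) != length(records))
    stop("'labels' must have one entry per record")
  subj_mean <- vapply(records, function(r) mean(record_se(r), na.rm = TRUE),
                      numeric(1))
  labs <- as.character(labels)
  out <- do.call(rbind, lapply(sort(unique(labs)), function(cl) {
    v <- subj_mean[labs == cl]
    if (length(v) == 0L) stop("empty cluster '", cl, "'")
    data.frame(cluster = cl, n_subjects = length(v),
               mean_ms = mean(v), sd_ms = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample t-test between clusters
#'
#' Student's (pooled-variance) t-test by default, with a Welch option.  Used
#' both for per-subject mean SE and for region-of-interest mean degree.
#' Degenerate inputs (zero pooled variance) are resolved by convention:
#' equal means give p = 1, unequal means give p = 0, both flagged.
#'
#' @param values_a,values_b Numeric samples (each of length >= 2).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @param measure Label describing what is being compared.
#' @return List of class `group_comparison`: `statistic`, `p_value`,
#'   `significant`, `group_means` (mean and sd per group), `measure`,
#'   `degenerate`.
#' @export
group_ttest <- function(values_a, values_b, alpha = 0.05, var_equal = TRUE,
                        measure = "measure") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each sample must contain at least 2 non-missing values")
  degenerate <- stats::var(values_a) == 0 && stats::var(values_b) == 0
  if (degenerate) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    tstat <- if (same) 0 else sign(mean(values_a) - mean(values_b)) * Inf
    pval <- if (same) 1 else 0
    warning("zero variance in both samples; degenerate t-test convention applied")
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
    tstat <- unname(ht$statistic)
    pval <- ht$p.value
  }
  structure(list(
    statistic = tstat, p_value = pval, significant = pval < alpha,
    group_means = data.frame(
      group = c("a", "b"),
      mean = c(mean(values_a), mean(values_b)),
      sd = c(stats::sd(values_a), stats::sd(values_b)),
      n = c(length(values_a), length(values_b))),
    measure = measure, alpha = alpha, degenerate = degenerate),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, p = %.4f (%ssignificant at alpha = %g)\n",
              x$measure, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  print(x$group_means, row.names = FALSE)
  invisible(x)
}
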