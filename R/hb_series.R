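#' Hemoglobin concentration time series for one subject
#'
#' Container for channel-wise oxy- and deoxy-hemoglobin concentration changes
#' (mM.mm, i.e. concentration times optical path length) sampled at a fixed
#' rate, together with the block structure of the recording and a
#' valid-channel mask.  Channels are rows; samples are columns.  Channels are
#' never deleted, only masked, so the 1..116 indexing stays aligned with the
#' anatomical lookup table throughout the pipeline.
#'
#' @param oxy,deoxy Numeric matrices, channels x samples, identical shape.
#' @param sampling_rate Sampling rate in Hz.
#' @param blocks data.frame with columns `block` (one of `pre_scan`,
#'   `control`, `task`, `post_control`), `start`, `end` (1-based sample
#'   indices, inclusive).  Blocks must be contiguous, non-overlapping and
#'   cover the whole recording.
#' @param subject_id Identifier string.
#' @param valid_channels Logical vector, one flag per channel (default all
#'   `TRUE`).
#' @return An object of class `hb_series`.
#' @export
hb_series <- function(oxy, deoxy, sampling_rate, blocks,
                      subject_id = "subject", valid_channels = NULL) {
  oxy <- as.matrix(oxy); deoxy <- as.matrix(deoxy)
  if (!identical(dim(oxy), dim(deoxy)))
    stop("'oxy' and 'deoxy' must have identical dimensions")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be positive")
  blocks <- as.data.frame(blocks)
  if (!all(c("block", "start", "end") %in% names(blocks)))
    stop("'blocks' needs columns block, start, end")
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  known_blocks <- c("pre_scan", "control", "task", "post_control")
  if (!all(blocks$block %in% known_blocks))
    stop("block labels must be among: ", paste(known_blocks, collapse = ", "))
  n <- ncol(oxy)
  if (blocks$start[1] != 1L || blocks$end[nrow(blocks)] != n ||
      (nrow(blocks) > 1L && any(blocks$start[-1] != blocks$end[-nrow(blocks)] + 1L)))
    stop("blocks must be contiguous, non-overlapping, and cover samples 1..", n)
  if (is.null(valid_channels)) valid_channels <- rep(TRUE, nrow(oxy))
  if (length(valid_channels) != nrow(oxy))
    stop("'valid_channels' length must equal the channel count")
  structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = sampling_rate,
         oxy = oxy, deoxy = deoxy,
         blocks = blocks,
         valid_channels = as.logical(valid_channels)),
    class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("hb_series '%s': %d channels x %d samples @ %g Hz (%d valid channels)\n",
              x$subject_id, n_channels(x), n_samples(x), x$sampling_rate,
              sum(x$valid_channels)))
  cat("blocks:", paste(sprintf("%s[%d-%d]", x$blocks$block, x$blocks$start,
                               x$blocks$end), collapse = " "), "\n")
  invisible(x)
}

#' @rdname hb_series
#' @param series An `hb_series`.
#' @export
n_channels <- function(series) nrow(series$oxy)

#' @rdname hb_series
#' @export
n_samples <- function(series) ncol(series$oxy)

#' Sample indices covered by a named block
#'
#' @param series An `hb_series`.
#' @param block Block label.
#' @return Integer vector of sample indices.
#' @export
block_samples <- function(series, block) {
  stopifnot(inherits(series, "hb_series"))
  row <- series$blocks[series$blocks$block == block, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("no block labelled '", block, "' in this recording")
  seq.int(row$start[1], row$end[1])
}

#' Standard block annotation from block durations
#'
#' @param durations Named numeric vector of seconds for
#'   `pre_scan`, `control`, `task`, `post_control`.
#' @param sampling_rate Hz.
#' @return data.frame suitable for [hb_series()].
#' @export
block_annotation <- function(durations = c(pre_scan = 20, control = 30,
                                           task = 21, post_control = 30),
                             sampling_rate = 10) {
  if (any(durations <= 0) || sampling_rate <= 0)
    stop("durations and sampling_rate must be strictly positive")
  ns <- round(durations * sampling_rate)
  ends <- cumsum(ns)
  data.frame(block = names(durations),
             start = as.integer(c(1L, ends[-length(ends)] + 1L)),
             end = as.integer(ends),
             stringsAsFactors = FALSE)
}

#' Write one subject's data as plain-text files
#'
#' Writes `<id>_oxy.tsv` and `<id>_deoxy.tsv` (rows = samples, columns =
#' channels, header row of channel ids), `<id>_meta.json` (sampling rate,
#' block annotation, valid-channel mask) and, if a behavioral record is
#' given, `<id>_events.tsv` (onset_s, event_type, block).
#'
#' @param series An [hb_series()].
#' @param dir Output directory (created if missing).
#' @param behavior Optional [behavioral_record()].
#' @return The directory, invisibly.
#' @export
write_subject_data <- function(series, dir, behavior = NULL) {
  stopifnot(inherits(series, "hb_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- series$subject_id
  for (what in c("oxy", "deoxy")) {
    m <- t(series[[what]])
    colnames(m) <- paste0("ch", seq_len(ncol(m)))
    utils::write.table(m, file.path(dir, sprintf("%s_%s.tsv", id, what)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(subject_id = id,
               sampling_rate = series$sampling_rate,
               blocks = series$blocks,
               valid_channels = series$valid_channels)
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", id)),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(behavior)) {
    stopifnot(inherits(behavior, "behavioral_record"))
    ev <- rbind(
      data.frame(onset_s = behavior$stimuli$onsets, event_type = "stimulus",
                 block = behavior$stimuli$block, stringsAsFactors = FALSE),
      data.frame(onset_s = behavior$responses, event_type = "response",
                 block = behavior$stimuli$block, stringsAsFactors = FALSE))
    ev <- ev[order(ev$onset_s), ]
    utils::write.table(ev, file.path(dir, sprintf("%s_events.tsv", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read one subject's data back from plain-text files
#'
#' Counterpart of [write_subject_data()].
#'
#' @param dir Directory holding the files.
#' @param id Subject identifier used in the filenames.
#' @return List with elements `series` (an [hb_series()]) and `events`
#'   (data.frame or `NULL`).
#' @export
read_subject_data <- function(dir, id) {
  rd <- function(what) {
    f <- file.path(dir, sprintf("%s_%s.tsv", id, what))
    t(as.matrix(utils::read.delim(f, sep = "\t", check.names = FALSE)))
  }
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", id)),
                              simplifyVector = TRUE)
  series <- hb_series(rd("oxy"), rd("deoxy"),
                      sampling_rate = meta$sampling_rate,
                      blocks = meta$blocks, subject_id = meta$subject_id,
                      valid_channels = meta$valid_channels)
  evf <- file.path(dir, sprintf("%s_events.tsv", id))
  events <- if (file.exists(evf))
    utils::read.delim(evf, sep = "\t", stringsAsFactors = FALSE) else NULL
  list(series = series, events = events)
}
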