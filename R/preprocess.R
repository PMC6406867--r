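#' Preprocessing configuration
#'
#' @param passband_low,passband_high Band-pass corner frequencies in Hz
#'   (defaults 0.010 and 0.33: keeps task-related hemodynamics, removes slow
#'   drift below and respiratory/cardiac oscillations above the band).
#' @param artifact_step_threshold Motion-artifact step threshold in mM.mm on
#'   the per-sample first difference of the raw Oxy-Hb trace (default 0.1).
#' @param filter_order Butterworth band-pass order (default 4).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(passband_low = 0.010, passband_high = 0.33,
                              artifact_step_threshold = 0.1,
                              filter_order = 4) {
  if (!(passband_low > 0 && passband_low < passband_high))
    stop("need 0 < passband_low < passband_high")
  if (artifact_step_threshold <= 0)
    stop("'artifact_step_threshold' must be positive")
  if (filter_order < 1 || filter_order != round(filter_order))
    stop("'filter_order' must be a positive integer")
  structure(list(passband_low = passband_low, passband_high = passband_high,
                 artifact_step_threshold = artifact_step_threshold,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

# One IIR pass of filter (b, a) down the columns of matrix x (samples x
# series).  stats::filter handles the convolution and recursion
# column-wise, so all channels are filtered in one call.  The input history
# is continued as a constant (first row), so a high-pass section (B(1) = 0)
# has exactly zero start-up transient on a constant input.
.iir_pass <- function(x, b, a) {
  nb <- length(b)
  xp <- rbind(matrix(x[1L, ], nb - 1L, ncol(x), byrow = TRUE), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.matrix(v)[nb:(nb - 1L + nrow(x)), , drop = FALSE]
  y <- stats::filter(v, -a[-1], method = "recursive")
  matrix(as.numeric(y), nrow = nrow(x), ncol = ncol(x))
}

# Zero-phase (forward-backward) filtering of every column of x, with odd
# reflection padding at both ends to suppress edge transients.  The pad is
# generous because the 0.01 Hz high-pass corner has a slow impulse-response
# tail (~16 s at 10 Hz sampling).
.filtfilt_mat <- function(x, b, a) {
  x <- as.matrix(x)
  n <- nrow(x)
  npad <- min(300L, n - 1L)
  front <- 2 * matrix(x[1L, ], npad, ncol(x), byrow = TRUE) -
    x[seq(npad + 1L, 2L), , drop = FALSE]
  back <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[seq(n - 1L, n - npad), , drop = FALSE]
  xp <- rbind(front, x, back)
  y <- .iir_pass(xp, b, a)
  y <- .iir_pass(y[nrow(y):1L, , drop = FALSE], b, a)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[seq(npad + 1L, npad + n), , drop = FALSE]
}

# Band-pass filter coefficients: a Butterworth band-pass realized as a
# cascade of a low-pass and a high-pass section.  The cascade keeps the
# high-pass corner (0.001 of Nyquist at 10 Hz sampling) numerically well
# conditioned, which a direct-form 8th-order band-pass at such a narrow
# normalized corner is not.
.bandpass_coefs <- function(low, high, fs, order) {
  nyq <- fs / 2
  if (!(low > 0 && high > low && high < nyq))
    stop("passband [", low, ", ", high, "] Hz infeasible for sampling rate ",
         fs, " Hz")
  lp <- signal::butter(order, high / nyq, type = "low")
  hp <- signal::butter(max(1L, order %/% 2L), low / nyq, type = "high")
  list(lp = lp, hp = hp)
}

#' Zero-phase band-pass filter of an hb_series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass,
#' independently per channel, to the oxy and deoxy matrices.  Block
#' annotations, validity mask and shape are preserved.
#'
#' @param series An [hb_series()].
#' @param config A [preprocess_config()].
#' @param which Which matrices to filter (default both).
#' @return The filtered [hb_series()].
#' @export
bandpass <- function(series, config = preprocess_config(),
                     which = c("oxy", "deoxy")) {
  stopifnot(inherits(series, "hb_series"), inherits(config, "preprocess_config"))
  cf <- .bandpass_coefs(config$passband_low, config$passband_high,
                        series$sampling_rate, config$filter_order)
  out <- series
  for (what in which) {
    x <- t(series[[what]])                      # samples x channels
    y <- .filtfilt_mat(x, cf$hp$b, cf$hp$a)     # high-pass first: exact DC kill
    y <- .filtfilt_mat(y, cf$lp$b, cf$lp$a)
    out[[what]] <- t(y)
  }
  out
}

#' Flag motion-contaminated channels
#'
#' A channel is rejected when any absolute single-sample first difference of
#' its raw Oxy-Hb trace exceeds the step threshold; abrupt probe movement
#' produces such steps while hemodynamics cannot.  Screening is done on the
#' unfiltered trace (filtering would smear the step); the deoxy trace
#' inherits the channel flag.
#'
#' @param series An [hb_series()] holding raw (unfiltered) data.
#' @param config A [preprocess_config()].
#' @return Logical vector, `TRUE` for channels that stay valid.
#' @export
detect_motion_channels <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "hb_series"))
  steps <- abs(t(diff(t(series$oxy))))
  max_step <- if (ncol(series$oxy) < 2L) rep(0, nrow(series$oxy))
              else apply(steps, 1L, max)
  unname(max_step <= config$artifact_step_threshold)
}

#' Apply (conjoin) a validity mask to an hb_series
#'
#' Data are retained but marked invalid; downstream stages skip masked
#' channels.  Successive masks compose by logical AND.
#'
#' @param series An [hb_series()].
#' @param mask Logical vector, length equal to the channel count.
#' @return The [hb_series()] with an updated `valid_channels` mask.
#' @export
apply_channel_mask <- function(series, mask) {
  stopifnot(inherits(series, "hb_series"))
  if (length(mask) != n_channels(series))
    stop("mask length (", length(mask), ") != channel count (",
         n_channels(series), ")")
  series$valid_channels <- series$valid_channels & as.logical(mask)
  series
}

#' Standard preprocessing: artifact screening, then band-pass
#'
#' @param series An [hb_series()] with raw data.
#' @param config A [preprocess_config()].
#' @param which Which matrices to band-pass (default `"oxy"`; the
#'   connectivity analysis uses Oxy-Hb only).
#' @return The screened, filtered [hb_series()].
#' @export
preprocess <- function(series, config = preprocess_config(), which = "oxy") {
  mask <- detect_motion_channels(series, config)
  apply_channel_mask(bandpass(series, config, which = which), mask)
}
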