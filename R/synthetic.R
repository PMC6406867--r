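#' Band-limited Gaussian noise
#'
#' Generates columns of Gaussian noise whose power is confined to a
#' frequency band, by zeroing the out-of-band Fourier coefficients of white
#' noise.  Each column is standardized to unit variance.  Used both for the
#' shared network signal and for per-channel background activity, so the
#' coupling structure designed into the generator survives the pipeline's
#' band-pass unchanged.
#'
#' @param n_samples,n_series Output dimensions.
#' @param sampling_rate Hz.
#' @param band Two-element vector, pass band in Hz (default 0.01 to 0.30).
#' @return Matrix `n_samples` x `n_series`; draws from the current RNG state.
#' @export
band_limited_noise <- function(n_samples, n_series, sampling_rate = 10,
                               band = c(0.01, 0.30)) {
  stopifnot(n_samples >= 4L, n_series >= 1L)
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  W <- stats::mvfft(w)
  k <- 0:(n_samples - 1L)
  f <- pmin(k, n_samples - k) / n_samples * sampling_rate
  keep <- f >= band[1L] & f <= band[2L]
  if (!any(keep))
    stop("no Fourier bins inside band [", band[1L], ", ", band[2L],
         "] Hz at this length/sampling rate")
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n_samples
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

#' Multi-channel signal with a planted hub network
#'
#' Hub channels load with weight `sqrt(coupling)` on a shared latent
#' band-limited (0.01-0.30 Hz) signal; peripheral channels load weakly on
#' the same latent (`sqrt(coupling * periph_loading)`); all remaining
#' channels receive independent band-limited noise.  Designed pairwise
#' correlations are therefore `coupling` (hub-hub),
#' `coupling * sqrt(periph_loading)` (hub-peripheral) and
#' `coupling * periph_loading` (peripheral-peripheral) — every one strictly
#' increasing in the coupling strength.
#'
#' @param n_channels Total channels.
#' @param hub_set Non-empty integer vector of hub channel indices.
#' @param coupling_strength Coupling in \[0, 1\].
#' @param n_samples Samples per channel.
#' @param seed Optional integer; if given, seeds the RNG first.
#' @param sampling_rate Hz (default 10).
#' @param band Latent/noise band in Hz (default 0.01-0.30).
#' @param periph_set Integer vector of peripheral channels (default none).
#' @param periph_loading Squared relative loading of peripherals in (0, 1\]
#'   (default 0.25).
#' @return Matrix channels x samples, each row unit variance.
#' @export
generate_network_signal <- function(n_channels, hub_set, coupling_strength,
                                    n_samples, seed = NULL,
                                    sampling_rate = 10, band = c(0.01, 0.30),
                                    periph_set = integer(0),
                                    periph_loading = 0.25) {
  if (length(hub_set) == 0L) stop("'hub_set' must be non-empty")
  if (any(hub_set < 1L | hub_set > n_channels))
    stop("'hub_set' indices out of range 1..", n_channels)
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("'coupling_strength' must lie in [0, 1]")
  if (length(periph_set) > 0L) {
    if (any(periph_set < 1L | periph_set > n_channels))
      stop("'periph_set' indices out of range 1..", n_channels)
    if (length(intersect(hub_set, periph_set)) > 0L)
      stop("'hub_set' and 'periph_set' must be disjoint")
  }
  if (!(periph_loading > 0 && periph_loading <= 1))
    stop("'periph_loading' must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  e <- band_limited_noise(n_samples, n_channels + 1L, sampling_rate, band)
  latent <- e[, 1L]
  eps <- e[, -1L, drop = FALSE]
  load <- numeric(n_channels)
  load[hub_set] <- sqrt(coupling_strength)
  load[periph_set] <- sqrt(coupling_strength * periph_loading)
  x <- outer(latent, load) + sweep(eps, 2L, sqrt(1 - load^2), "*")
  t(x)
}

#' Configuration of the synthetic fNIRS study generator
#'
#' Defaults reproduce the study design the package analyzes: 20 subjects in
#' two equal groups, a 116-channel whole-head montage sampled at 10 Hz, one
#' 20 s pre-scan / 30 s control / 21 s task / 30 s post-control run, seven
#' task cues with lengthening intervals, and per-group planted
#' synchronization-error distributions of 90.0 +/- 154.9 ms and
#' -8.9 +/- 261.5 ms.  Group network hubs default to left middle frontal +
#' left triangular inferior frontal channels (group A) and to a
#' representative set of left middle occipital, left postcentral, left
#' supramarginal and right middle temporal channels (group B).
#'
#' @param n_subjects Number of subjects (default 20).
#' @param group_assignment Character vector of group labels, one per
#'   subject (default 10 "A" then 10 "B").
#' @param sampling_rate Hz (default 10).
#' @param block_durations Named seconds for pre_scan, control, task,
#'   post_control (defaults 20, 30, 21, 30).
#' @param hub_channels_per_group Named list (one entry per group label) of
#'   hub channel indices in 1..n_channels.
#' @param coupling_strength Network coupling in \[0, 1\] (default 0.85).
#' @param periph_per_group Peripheral channels attached to each group's
#'   network (default 40).
#' @param periph_loading Squared relative loading of peripherals
#'   (default 0.25).
#' @param noise_components List with `sinusoids` (data.frame
#'   `frequency` Hz / `amplitude` mM.mm: cardiac 1.2 Hz, respiratory
#'   0.25 Hz, Mayer 0.1 Hz), `freq_jitter` (relative per-channel frequency
#'   spread of the oscillations; physiological rhythms are not phase-locked
#'   across the scalp), `white_sd` (mM.mm) and `drift_amplitude`
#'   (mM.mm over the run).
#' @param hb_scale Std. dev. of the network signal in mM.mm (default 0.03).
#' @param artifact_spec data.frame `subject`, `channel`, `sample`,
#'   `amplitude` of motion-artifact steps to inject.
#' @param se_params_per_group Named list of `c(mean, sd)` in ms per group.
#' @param task_n_stimuli,task_interval_increment,task_interval_jitter,task_start_delay
#'   Task cue-train parameters (defaults 7, 0.6 s, 0.03 s, 0.5 s).
#' @param control_isi Control-block inter-stimulus interval (default 0.5 s).
#' @param n_channels Channel count (default 116).
#' @param seed Global seed, expanded into per-subject substreams.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 20,
    group_assignment = rep(c("A", "B"), each = 10),
    sampling_rate = 10,
    block_durations = c(pre_scan = 20, control = 30, task = 21,
                        post_control = 30),
    hub_channels_per_group = list(
      A = c(7, 26, 45,                     # left middle frontal gyrus
            27, 46),                       # left triangular part of IFG
      B = c(59, 61,                        # left middle occipital gyrus
            19,                            # left postcentral gyrus
            48,                            # left supramarginal gyrus
            75)),                          # right middle temporal gyrus
    coupling_strength = 0.9,
    periph_per_group = 47,
    periph_loading = 0.25,
    noise_components = list(
      sinusoids = data.frame(frequency = c(1.2, 0.25, 0.1),
                             amplitude = c(0.04, 0.01, 0.01)),
      freq_jitter = 0.1,
      white_sd = 0.005,
      drift_amplitude = 0.02),
    hb_scale = 0.03,
    artifact_spec = data.frame(subject = c(5L, 13L),
                               channel = c(103L, 72L),
                               sample = c(400L, 650L),
                               amplitude = c(0.15, -0.18)),
    se_params_per_group = list(A = c(mean = 90.0, sd = 154.9),
                               B = c(mean = -8.9, sd = 261.5)),
    task_n_stimuli = 7, task_interval_increment = 0.6,
    task_interval_jitter = 0.03, task_start_delay = 0.5,
    control_isi = 0.5,
    n_channels = 116,
    seed = 1) {
  if (length(group_assignment) != n_subjects)
    stop("'group_assignment' length (", length(group_assignment),
         ") must equal n_subjects (", n_subjects, ")")
  groups <- unique(group_assignment)
  if (!all(groups %in% names(hub_channels_per_group)))
    stop("'hub_channels_per_group' is missing group(s): ",
         paste(setdiff(groups, names(hub_channels_per_group)), collapse = ", "))
  if (!all(groups %in% names(se_params_per_group)))
    stop("'se_params_per_group' is missing group(s): ",
         paste(setdiff(groups, names(se_params_per_group)), collapse = ", "))
  all_hubs <- unlist(hub_channels_per_group)
  if (any(all_hubs < 1L | all_hubs > n_channels))
    stop("'hub_channels_per_group' indices must lie in 1..", n_channels)
  if (any(block_durations <= 0) || sampling_rate <= 0)
    stop("'block_durations' and 'sampling_rate' must be strictly positive")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("'coupling_strength' must lie in [0, 1]")
  for (g in groups)
    if (se_params_per_group[[g]]["sd"] < 0)
      stop("'se_params_per_group' sd must be >= 0 for group ", g)
  if (missing(artifact_spec))                    # default spec targets the
    artifact_spec <-                             # 20-subject study design
      artifact_spec[artifact_spec$subject <= n_subjects, , drop = FALSE]
  if (nrow(artifact_spec) > 0L &&
      (any(artifact_spec$channel < 1L | artifact_spec$channel > n_channels) ||
       any(artifact_spec$subject < 1L | artifact_spec$subject > n_subjects)))
    stop("'artifact_spec' subject/channel indices out of range")
  if (seed != round(seed)) stop("'seed' must be an integer")
  structure(list(
    n_subjects = as.integer(n_subjects),
    group_assignment = as.character(group_assignment),
    sampling_rate = sampling_rate,
    block_durations = block_durations,
    hub_channels_per_group = lapply(hub_channels_per_group, as.integer),
    coupling_strength = coupling_strength,
    periph_per_group = as.integer(periph_per_group),
    periph_loading = periph_loading,
    noise_components = noise_components,
    hb_scale = hb_scale,
    artifact_spec = artifact_spec,
    se_params_per_group = se_params_per_group,
    task_n_stimuli = as.integer(task_n_stimuli),
    task_interval_increment = task_interval_increment,
    task_interval_jitter = task_interval_jitter,
    task_start_delay = task_start_delay,
    control_isi = control_isi,
    n_channels = as.integer(n_channels),
    seed = as.integer(seed)), class = "generator_config")
}

# deterministic per-subject substream seed (< 2^31), so changing the subject
# count never reshuffles earlier subjects
.subject_seed <- function(seed, i) {
  (abs(seed) %% 60000L) * 33013L + i * 101L
}

# peripheral channels per group: round-robin over the non-hub pool, so the
# groups' peripheral sets are deterministic and disjoint
.assign_peripherals <- function(config) {
  groups <- unique(config$group_assignment)
  pool <- setdiff(seq_len(config$n_channels),
                  unlist(config$hub_channels_per_group))
  out <- list()
  for (gi in seq_along(groups)) {
    idx <- pool[seq(gi, length(pool), by = length(groups))]
    if (length(idx) < config$periph_per_group)
      stop("not enough non-hub channels for periph_per_group = ",
           config$periph_per_group)
    out[[groups[gi]]] <- sort(idx[seq_len(config$periph_per_group)])
  }
  out
}

#' Tapping behavior with a planted synchronization-error distribution
#'
#' Each response is its stimulus onset plus an independent draw from
#' Normal(`se_mean`, `se_sd`) (both in ms).  Responses falling outside the
#' recording window are clipped to it and flagged.
#'
#' @param schedule A [stimulus_schedule()].
#' @param se_mean,se_sd Planted SE mean and sd in ms (`se_sd >= 0`).
#' @param seed Optional integer seed.
#' @param window Two-element recording window in seconds (default none).
#' @param subject_id Identifier for the record.
#' @return A [behavioral_record()].
#' @export
generate_behavior <- function(schedule, se_mean, se_sd, seed = NULL,
                              window = NULL, subject_id = "subject") {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (se_sd < 0) stop("'se_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(schedule$onsets)
  responses <- schedule$onsets +
    stats::rnorm(n, mean = se_mean, sd = se_sd) / 1000
  clipped <- rep(FALSE, n)
  if (!is.null(window)) {
    clipped <- responses < window[1L] | responses > window[2L]
    responses <- pmin(pmax(responses, window[1L]), window[2L])
  }
  behavioral_record(subject_id, schedule, responses, clipped)
}

#' Inject a persistent motion-artifact step
#'
#' Adds a constant offset to one channel from a given sample onward (both
#' oxy and deoxy), emulating the baseline shift left by abrupt probe
#' movement — the signature the artifact screen looks for.
#'
#' @param series An [hb_series()].
#' @param channel,sample Where the step starts (1-based, in range).
#' @param amplitude Step height in mM.mm.
#' @return The modified [hb_series()].
#' @export
inject_motion_step <- function(series, channel, sample, amplitude) {
  stopifnot(inherits(series, "hb_series"))
  if (channel < 1L || channel > n_channels(series))
    stop("'channel' out of range 1..", n_channels(series))
  if (sample < 1L || sample > n_samples(series))
    stop("'sample' out of range 1..", n_samples(series))
  idx <- seq.int(sample, n_samples(series))
  series$oxy[channel, idx] <- series$oxy[channel, idx] + amplitude
  series$deoxy[channel, idx] <- series$deoxy[channel, idx] + amplitude
  series
}

#' Generate a complete synthetic multi-subject dataset
#'
#' One hemoglobin time series and one behavioral record per subject, with
#' the statistical structure the downstream analysis assumes: a planted
#' group-specific hub network carried by a shared band-limited latent
#' signal, physiological sinusoidal noise (cardiac, respiratory, Mayer
#' waves) with per-channel random phases, linear drift, white measurement
#' noise, optional motion-artifact steps, and planted per-group
#' synchronization-error distributions.  A single global seed is expanded
#' into per-subject substreams, so equal seeds give bit-identical datasets
#' and adding subjects never changes earlier ones.
#'
#' @param config A [generator_config()].
#' @return Object of class `fnirs_dataset`: list with `series` (list of
#'   [hb_series()]), `behavior` (list of [behavioral_record()]) and
#'   `ground_truth` (groups, per-group hub and peripheral sets, designed
#'   pairwise correlations, planted network adjacency per group, SE
#'   parameters, artifact spec, per-subject substream seeds).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  fs <- config$sampling_rate
  blocks <- block_annotation(config$block_durations, fs)
  n_total <- blocks$end[nrow(blocks)]
  task_start_s <- (blocks$start[blocks$block == "task"] - 1L) / fs
  periph <- .assign_peripherals(config)
  groups <- unique(config$group_assignment)

  planted_adjacency <- lapply(groups, function(g) {
    members <- c(config$hub_channels_per_group[[g]], periph[[g]])
    a <- matrix(0L, config$n_channels, config$n_channels)
    a[members, members] <- 1L
    diag(a) <- 0L
    a
  })
  names(planted_adjacency) <- groups

  series <- vector("list", config$n_subjects)
  behavior <- vector("list", config$n_subjects)
  sub_seeds <- integer(config$n_subjects)
  nchan <- config$n_channels
  tsec <- (seq_len(n_total) - 1L) / fs
  sin_spec <- config$noise_components$sinusoids

  for (i in seq_len(config$n_subjects)) {
    g <- config$group_assignment[i]
    id <- sprintf("sub%02d", i)
    sub_seeds[i] <- .subject_seed(config$seed, i)
    set.seed(sub_seeds[i])

    net <- generate_network_signal(
      nchan, config$hub_channels_per_group[[g]], config$coupling_strength,
      n_total, seed = NULL, sampling_rate = fs,
      periph_set = periph[[g]], periph_loading = config$periph_loading)
    oxy <- config$hb_scale * net

    jit <- config$noise_components$freq_jitter
    if (is.null(jit)) jit <- 0
    for (s in seq_len(nrow(sin_spec))) {
      phase <- stats::runif(nchan, 0, 2 * pi)
      freq <- sin_spec$frequency[s] *
        (1 + stats::runif(nchan, -jit, jit))
      oxy <- oxy + sin_spec$amplitude[s] *
        sin(2 * pi * outer(freq, tsec) + phase)
    }
    slope <- stats::runif(nchan, -1, 1) * config$noise_components$drift_amplitude
    oxy <- oxy + outer(slope, tsec / max(tsec))
    oxy <- oxy + config$noise_components$white_sd *
      matrix(stats::rnorm(nchan * n_total), nchan, n_total)

    # deoxy: anticorrelated with oxy at roughly a third of its amplitude,
    # plus its own noise; the network analysis itself uses oxy only
    deoxy <- -oxy / 3 + config$noise_components$white_sd *
      matrix(stats::rnorm(nchan * n_total), nchan, n_total)

    sub <- hb_series(oxy, deoxy, fs, blocks, subject_id = id)

    art <- config$artifact_spec
    if (nrow(art) > 0L) {
      for (r in which(art$subject == i))
        sub <- inject_motion_step(sub, art$channel[r], art$sample[r],
                                  art$amplitude[r])
    }

    sched <- task_schedule(task_start_s, config$task_n_stimuli,
                           config$task_interval_increment,
                           config$task_interval_jitter,
                           config$task_start_delay)
    p <- config$se_params_per_group[[g]]
    behavior[[i]] <- generate_behavior(sched, p[["mean"]], p[["sd"]],
                                       window = c(0, n_total / fs),
                                       subject_id = id)
    series[[i]] <- sub
  }

  structure(list(
    series = series,
    behavior = behavior,
    ground_truth = list(
      group = stats::setNames(config$group_assignment,
                              vapply(series, `[[`, "", "subject_id")),
      hubs = config$hub_channels_per_group[groups],
      peripherals = periph,
      planted_adjacency = planted_adjacency,
      designed_correlations = list(
        hub_hub = config$coupling_strength,
        hub_periph = config$coupling_strength * sqrt(config$periph_loading),
        periph_periph = config$coupling_strength * config$periph_loading),
      se_params = config$se_params_per_group[groups],
      artifact_spec = config$artifact_spec,
      subject_seeds = sub_seeds),
    config = config), class = "fnirs_dataset")
}

#' @export
print.fnirs_dataset <- function(x, ...) {
  cat(sprintf("fnirs_dataset: %d subjects (%s), %d channels x %d samples @ %g Hz\n",
              length(x$series),
              paste(sprintf("%s=%d", names(table(x$ground_truth$group)),
                            table(x$ground_truth$group)), collapse = ", "),
              n_channels(x$series[[1L]]), n_samples(x$series[[1L]]),
              x$series[[1L]]$sampling_rate))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Per subject the files of [write_subject_data()], plus
#' `ground_truth.json` so downstream tests never re-derive the planted
#' structure.
#'
#' @param dataset An `fnirs_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(dataset$series))
    write_subject_data(dataset$series[[i]], dir, dataset$behavior[[i]])
  gt <- dataset$ground_truth
  gt$planted_adjacency <- NULL                 # large; reconstructable
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
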