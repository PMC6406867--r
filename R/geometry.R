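#' Probe grid geometry
#'
#' An fNIRS probe set is a rectangular grid of optodes in which emitters and
#' detectors alternate in a checkerboard pattern; every orthogonally adjacent
#' emitter-detector pair at the fixed 30 mm separation forms one measurement
#' channel.
#'
#' @param rows,cols Grid dimensions (optode counts per side), both >= 1.
#' @param inter_probe_distance Optode separation in mm (fixed hardware
#'   property; default 30).
#' @return An object of class `probe_grid`.
#' @examples
#' channel_count(probe_grid(3, 10))  # 47
#' @export
probe_grid <- function(rows, cols, inter_probe_distance = 30) {
  if (!is.numeric(rows) || length(rows) != 1L || rows < 1 || rows != round(rows))
    stop("'rows' must be a positive integer")
  if (!is.numeric(cols) || length(cols) != 1L || cols < 1 || cols != round(cols))
    stop("'cols' must be a positive integer")
  if (inter_probe_distance <= 0)
    stop("'inter_probe_distance' must be positive")
  n <- rows * cols
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         inter_probe_distance = inter_probe_distance,
         n_emitters = as.integer(ceiling(n / 2)),
         n_detectors = as.integer(floor(n / 2))),
    class = "probe_grid")
}

#' @export
print.probe_grid <- function(x, ...) {
  cat(sprintf("probe_grid: %d x %d optodes (%d emitters, %d detectors), %g mm spacing, %d channels\n",
              x$rows, x$cols, x$n_emitters, x$n_detectors,
              x$inter_probe_distance, channel_count(x)))
  invisible(x)
}

#' Number of measurement channels of a probe grid
#'
#' In the alternating emitter/detector checkerboard every horizontally or
#' vertically adjacent optode pair is an emitter-detector pair, so the channel
#' count equals the number of orthogonal adjacencies:
#' `rows * (cols - 1) + (rows - 1) * cols`.
#'
#' @param grid A [probe_grid()].
#' @return Integer channel count.
#' @examples
#' channel_count(probe_grid(3, 5))   # 22
#' channel_count(probe_grid(1, 2))   # 1
#' @export
channel_count <- function(grid) {
  stopifnot(inherits(grid, "probe_grid"))
  grid$rows * (grid$cols - 1L) + (grid$rows - 1L) * grid$cols
}

#' Total channels over a montage of several probe grids
#'
#' @param grids Non-empty list of [probe_grid()] objects.
#' @return Integer sum of per-grid channel counts.
#' @examples
#' montage_total(list(probe_grid(3, 10), probe_grid(3, 10), probe_grid(3, 5)))  # 116
#' @export
montage_total <- function(grids) {
  if (!is.list(grids) || length(grids) == 0L)
    stop("'grids' must be a non-empty list of probe_grid objects")
  sum(vapply(grids, channel_count, integer(1)))
}

#' The standard whole-head montage
#'
#' Two 3 x 10 grids (forehead and occiput) plus one 3 x 5 grid (vertex),
#' 116 channels in total.
#'
#' @return List of three [probe_grid()] objects.
#' @export
standard_montage <- function() {
  list(frontal = probe_grid(3, 10), occipital = probe_grid(3, 10),
       vertex = probe_grid(3, 5))
}

#' Channel-to-brain-region lookup table
#'
#' Loads the packaged 116-channel anatomical lookup (channel index, region
#' label, hemisphere) that stands in for subject-wise probabilistic MNI
#' registration.  A user-supplied table with the same three columns can be
#' given instead via `path`.
#'
#' @param path Optional path to a tab-separated file with columns
#'   `channel`, `region`, `hemisphere`.
#' @return A `channel_map` data.frame with 116 rows (or as many as the file
#'   provides), channels unique and contiguous from 1.
#' @export
channel_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "channel_regions.tsv", package = "fnirsnet",
                        mustWork = TRUE)
  map <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("channel", "region", "hemisphere")
  if (!all(required %in% names(map)))
    stop("channel map must have columns: ", paste(required, collapse = ", "))
  map <- map[order(map$channel), required]
  if (anyDuplicated(map$channel) || !identical(as.integer(map$channel), seq_len(nrow(map))))
    stop("channel indices must be unique and contiguous from 1")
  if (!all(map$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be one of 'left', 'right', 'midline'")
  class(map) <- c("channel_map", "data.frame")
  map
}

#' Write a channel map to a tab-separated file
#'
#' @param map A `channel_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_map <- function(map, path) {
  stopifnot(inherits(map, "channel_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Brain region of a channel
#'
#' @param channel Channel index (1-based, may be a vector).
#' @param map A `channel_map` (default: the packaged standard map).
#' @return Character vector of region labels.
#' @examples
#' region_of(7)    # "left middle frontal gyrus"
#' region_of(104)  # "supplementary motor area"
#' @export
region_of <- function(channel, map = channel_map()) {
  stopifnot(inherits(map, "channel_map"))
  if (any(channel < 1L | channel > nrow(map) | channel != round(channel)))
    stop("channel index out of range 1..", nrow(map))
  map$region[channel]
}

#' Channels belonging to one or more regions
#'
#' Inverse lookup of [region_of()]; with several labels the union of their
#' channel sets is returned.
#'
#' @param region Character vector of region labels (exact match).
#' @param map A `channel_map`.
#' @return Sorted integer vector of channel indices.
#' @examples
#' channels_of_region("left triangular part of inferior frontal gyrus")  # 27 36 37 46
#' @export
channels_of_region <- function(region, map = channel_map()) {
  stopifnot(inherits(map, "channel_map"))
  known <- unique(map$region)
  bad <- setdiff(region, known)
  if (length(bad) > 0L)
    stop("unknown region label(s): ", paste(sQuote(bad), collapse = ", "),
         "\nKnown labels: ", paste(sQuote(known), collapse = ", "))
  sort(map$channel[map$region %in% region])
}
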