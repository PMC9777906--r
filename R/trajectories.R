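#' Read a raw detection table
#'
#' Reads columnar trajectory data with header
#' `individual_id,timestamp,x,y` (comma- or tab-separated; the dialect is
#' auto-detected from the header line). Timestamps are absolute seconds
#' (e.g. UNIX epoch); positions are planar coordinates in arbitrary units.
#'
#' @param path Path to a delimited text file.
#' @return A tibble with columns `individual_id` (character), `timestamp`,
#'   `x`, `y` (numeric).
#' @export
read_detections <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "numeric", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "x", "y")
  if (!all(need %in% names(df)))
    abort(paste("detection file must have columns:", paste(need, collapse = ", ")))
  out <- tibble::as_tibble(df[need])
  if (!all(is.finite(out$timestamp)) || !all(is.finite(out$x)) || !all(is.finite(out$y)))
    abort("detections contain non-finite timestamps or coordinates")
  out
}

#' Write a detection table
#'
#' @param detections Tibble with columns `individual_id,timestamp,x,y`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resample_one <- function(ts, xs, ys, dt, t_start, t_end) {
  # de-duplicate timestamps: keep first detection at each time
  ord <- order(ts)
  ts <- ts[ord]; xs <- xs[ord]; ys <- ys[ord]
  keep <- !duplicated(ts)
  ts <- ts[keep]; xs <- xs[keep]; ys <- ys[keep]
  if (length(ts) < 2) return(NULL)
  grid <- seq(t_start, t_end, by = dt)
  x_i <- approx(ts, xs, xout = grid, rule = 2)$y
  y_i <- approx(ts, ys, xout = grid, rule = 2)$y
  covered <- grid >= ts[1] & grid <= ts[length(ts)]
  tibble::tibble(t = grid, x = x_i, y = y_i, covered = covered)
}

#' Resample trajectories onto a uniform time grid
#'
#' Re-samples each individual's detections at uniform intervals `dt` by
#' linear interpolation between bracketing detections. Grid points outside an
#' individual's observed time span are filled by holding the nearest observed
#' endpoint and flagged as not covered, so that coverage — the fraction of
#' grid points lying within the observed span — can be used to filter poorly
#' tracked individuals. Duplicate timestamps keep the first detection.
#' Individuals with fewer than two usable detections are dropped (reported
#' via the `dropped` attribute).
#'
#' @param detections Tibble with columns `individual_id,timestamp,x,y`.
#' @param dt Sampling interval in seconds (default 1).
#' @param t_start,t_end Grid limits in seconds. Default: the global
#'   detection span, so all tracks share one grid (required downstream).
#' @return A tibble with columns `individual_id`, `t`, `x`, `y`, `covered`
#'   (logical), carrying attributes `dt` and `dropped` (ids with < 2 usable
#'   detections).
#' @export
#' @examples
#' det <- tibble::tibble(individual_id = "a", timestamp = c(0, 2),
#'                       x = c(0, 4), y = c(0, 0))
#' resample_tracks(det, dt = 1)
resample_tracks <- function(detections, dt = 1,
                            t_start = NULL, t_end = NULL) {
  stopifnot(dt > 0)
  if (nrow(detections) == 0)
    return(structure(tibble::tibble(individual_id = character(), t = numeric(),
                                    x = numeric(), y = numeric(), covered = logical()),
                     dt = dt, dropped = character()))
  if (is.null(t_start)) t_start <- min(detections$timestamp)
  if (is.null(t_end)) t_end <- max(detections$timestamp)
  parts <- split(detections, detections$individual_id)
  res <- purrr::map(parts, function(d) {
    resample_one(d$timestamp, d$x, d$y, dt, t_start, t_end)
  })
  dropped <- names(res)[vapply(res, is.null, logical(1))]
  res <- res[!vapply(res, is.null, logical(1))]
  out <- dplyr::bind_rows(res, .id = "individual_id")
  attr(out, "dt") <- dt
  attr(out, "dropped") <- dropped
  out
}

track_stats <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      coverage = mean(.data$covered),
      total_displacement = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      .groups = "drop"
    )
}

#' Filter inactive or poorly tracked individuals
#'
#' Retains exactly the tracks whose coverage (fraction of grid points inside
#' the observed detection span) is at least `min_coverage` AND whose summed
#' per-step displacement is at least `min_total_displacement`. Track order is
#' preserved. Individuals that never move (or were barely detected) carry no
#' usable activity signal and would otherwise contribute degenerate
#' zero-variance series downstream.
#'
#' @param tracks Resampled track tibble from [resample_tracks()].
#' @param min_coverage Coverage threshold in `[0, 1]` (default 0.8).
#' @param min_total_displacement Minimum summed step displacement, position
#'   units (default 0: any movement at all qualifies; strictly immobile
#'   tracks with displacement 0 are retained only when the threshold is 0).
#' @return The filtered track tibble; attribute `removed` lists dropped ids.
#' @export
filter_inactive <- function(tracks, min_coverage = 0.8,
                            min_total_displacement = 0) {
  stopifnot(min_coverage >= 0, min_coverage <= 1, min_total_displacement >= 0)
  st <- track_stats(tracks)
  keep <- st$individual_id[st$coverage >= min_coverage &
                             st$total_displacement >= min_total_displacement]
  out <- tracks[tracks$individual_id %in% keep, , drop = FALSE]
  attr(out, "dt") <- attr(tracks, "dt")
  attr(out, "removed") <- setdiff(st$individual_id, keep)
  out
}

#' Kinetic-energy transform of resampled tracks
#'
#' Converts each track's positions to a per-interval activity proxy:
#' `k[i] = (x[i+1]-x[i])^2 + (y[i+1]-y[i])^2`, the squared displacement over
#' one sampling interval. No mass or 1/2 factor is included — the quantity is
#' an activity measure, not a physical energy. Each energy value is stamped
#' with the time of the start of its interval; a track of `n` points yields
#' `n - 1` energies.
#'
#' @param tracks Resampled track tibble (a single-individual track works too).
#' @return A tibble with columns `individual_id`, `t`, `k`.
#' @export
#' @examples
#' tr <- tibble::tibble(individual_id = "a", t = 0:1, x = c(0, 3), y = c(0, 4),
#'                      covered = TRUE)
#' kinetic_energy(tr)  # k = 25
kinetic_energy <- function(tracks) {
  if (any(table(tracks$individual_id) < 2))
    abort("each track needs at least 2 points to compute displacements")
  out <- tracks |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::reframe(t = .data$t[-dplyr::n()],
                   k = diff(.data$x)^2 + diff(.data$y)^2)
  attr(out, "dt") <- attr(tracks, "dt")
  out
}

#' Colony-level activity series
#'
#' Aggregates per-individual kinetic-energy series, elementwise across
#' individuals, into one scalar activity series for the whole group. All
#' series must share the same time grid. The default is the arithmetic mean;
#' `aggregate = "sum"` gives the plain sum. Every downstream statistic used
#' here (Pearson correlation, Hurst slope) is invariant to the positive
#' constant factor separating the two.
#'
#' @param energies Tibble from [kinetic_energy()] (columns
#'   `individual_id`, `t`, `k`).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return A tibble with columns `t`, `value`; attribute `n_individuals`.
#' @export
hive_activity <- function(energies, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(energies) == 0) abort("empty energy collection")
  grids <- energies |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(key = paste(range(.data$t), dplyr::n(), collapse = "|"),
                     .groups = "drop")
  if (length(unique(grids$key)) != 1)
    abort("all energy series must share the same time grid")
  out <- energies |>
    dplyr::group_by(t = .data$t) |>
    dplyr::summarise(value = if (aggregate == "mean") mean(.data$k) else sum(.data$k),
                     .groups = "drop") |>
    dplyr::arrange(t)
  attr(out, "n_individuals") <- length(unique(energies$individual_id))
  attr(out, "aggregate") <- aggregate
  out
}

#' Partition a time-series into labelled windows
#'
#' Splits a series with a `t` column into segments according to half-open
#' windows `[start, end)`; a sample on a boundary between abutting windows
#' belongs to the later window. Windows outside the series span produce
#' empty segments, not errors.
#'
#' @param series Tibble with a `t` column (e.g. from [hive_activity()] or
#'   [kinetic_energy()]).
#' @param windows Tibble with columns `label`, `start`, `end`
#'   (seconds; `start < end`, non-overlapping).
#' @return The input rows falling in some window, with a `window` column
#'   added; rows outside every window are dropped.
#' @export
partition_windows <- function(series, windows) {
  stopifnot(all(windows$start < windows$end))
  ov <- outer(windows$start, windows$end, function(a, b) a < b)
  for (i in seq_len(nrow(windows))) for (j in seq_len(nrow(windows))) {
    if (i != j && windows$start[i] < windows$end[j] && windows$start[j] < windows$end[i])
      abort("windows overlap")
  }
  segs <- purrr::pmap(windows, function(label, start, end, ...) {
    seg <- series[series$t >= start & series$t < end, , drop = FALSE]
    if (nrow(seg) > 0) seg$window <- label
    seg
  })
  dplyr::bind_rows(segs[vapply(segs, nrow, integer(1)) > 0])
}

#' Alternating day/night window table
#'
#' Convenience constructor for a day/night partition: starting at `t0`
#' (interpreted as a sunrise), alternates day windows of length `day_hours`
#' and night windows filling the rest of each 24 h cycle.
#'
#' @param t0 Start time in seconds (first sunrise).
#' @param n_days Number of solar days.
#' @param day_hours Daylight duration in hours (default 12).
#' @return A window tibble usable with [partition_windows()].
#' @export
day_night_windows <- function(t0, n_days, day_hours = 12) {
  day_s <- day_hours * 3600
  cyc <- 24 * 3600
  starts <- t0 + (seq_len(n_days) - 1) * cyc
  tibble::tibble(
    label = rep(c("day", "night"), n_days),
    start = as.vector(rbind(starts, starts + day_s)),
    end = as.vector(rbind(starts + day_s, starts + cyc))
  )
}
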