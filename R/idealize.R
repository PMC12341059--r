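#' All-points amplitude histogram of a sweep
#'
#' Histogram of every sample of the current trace. Peaks of this histogram
#' locate the closed (baseline) and open current levels used for
#' half-amplitude event detection.
#'
#' @param sweep A `sweep` (from [render_sweep()] or a read bundle) or a
#'   numeric vector of currents in pA.
#' @param bin_width Bin width in pA; `NULL` chooses half the robust noise SD
#'   of the trace (Freedman-Diaconis-like floor of 0.05 pA).
#' @return A tibble of class `all_points_histogram` with columns
#'   `bin_center`, `count`; attributes `bin_edges`, `n_samples`.
#' @export
all_points_histogram <- function(sweep, bin_width = NULL) {
  x <- if (inherits(sweep, "sweep")) sweep$current else as.numeric(sweep)
  if (length(x) == 0) stop("empty sweep: no samples to histogram")
  if (is.null(bin_width)) {
    # robust local noise estimate from first differences
    bin_width <- max(0.05, stats::mad(diff(x)) / sqrt(2) / 2)
  }
  stopifnot(bin_width > 0)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  out <- tibble::tibble(bin_center = (edges[-1] + edges[-length(edges)]) / 2,
                        count = counts)
  structure(out, bin_edges = edges, n_samples = length(x),
            class = c("all_points_histogram", class(out)))
}

#' Detect closed/open current levels from an all-points histogram
#'
#' Finds histogram peaks by local-maximum search subject to a prominence
#' floor and a minimum peak separation, then refines each peak position by
#' three-point parabolic interpolation. The baseline is the peak nearest zero
#' driving force (lowest |amplitude| once rectified); the unitary amplitude
#' is the median spacing of consecutive peaks, and `n_levels` is the number
#' of open levels (peaks - 1).
#'
#' @param hist An [all_points_histogram()].
#' @param min_separation Minimum distance between peaks, pA. `NULL` chooses
#'   `max(4 * bin width, 2.5 pA)`.
#' @param min_prominence Minimum peak height as a fraction of the tallest
#'   peak (default 0.05).
#' @param direction +1 if open channels carry outward (positive) current,
#'   -1 for inward; flips the level ordering for sweeps below the reversal
#'   potential.
#' @return A list of class `level_set`: `baseline` (pA), `unitary_amplitude`
#'   (pA, > 0, measured along `direction`), `n_levels`, `peaks` (pA),
#'   `direction`.
#' @export
detect_levels <- function(hist, min_separation = NULL, min_prominence = 0.05,
                          direction = 1) {
  stopifnot(inherits(hist, "all_points_histogram"), direction %in% c(-1, 1))
  bw <- diff(attr(hist, "bin_edges"))[1]
  if (is.null(min_separation)) min_separation <- max(4 * bw, 2.5)
  x <- hist$bin_center * direction
  o <- order(x)
  x <- x[o]; y <- hist$count[o]
  n <- length(y)
  is_max <- y > 0 &
    y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf) &
    y >= min_prominence * max(y)
  cand <- which(is_max)
  # greedy separation: keep tallest first, drop neighbours closer than min_separation
  keep <- integer(0)
  for (i in cand[order(-y[cand])]) {
    if (all(abs(x[i] - x[keep]) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # parabolic refinement of peak positions
  peak_pos <- vapply(keep, function(i) {
    if (i <= 1 || i >= n) return(x[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom >= 0) return(x[i])
    x[i] + 0.5 * bw * (y[i - 1] - y[i + 1]) / denom
  }, numeric(1))
  baseline <- peak_pos[1]
  n_levels <- length(peak_pos) - 1L
  unit_amp <- if (n_levels >= 1) stats::median(diff(peak_pos)) else NA_real_
  structure(list(baseline = baseline * direction,
                 unitary_amplitude = unit_amp,
                 n_levels = n_levels,
                 peaks = peak_pos * direction,
                 direction = direction),
            class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat("<level_set> baseline ", signif(x$baseline, 4), " pA, ",
      x$n_levels, " open level(s), unitary amplitude ",
      signif(x$unitary_amplitude, 4), " pA\n", sep = "")
  invisible(x)
}

#' Half-amplitude detection thresholds
#'
#' Threshold k (k = 1..n_levels) sits midway between level k-1 and level k:
#' `baseline + (k - 0.5) * unitary_amplitude`, measured along the driving
#' force direction.
#'
#' @param levels A [detect_levels()] result.
#' @return Numeric vector of thresholds in pA along the rectified axis
#'   (strictly increasing); empty when `n_levels = 0`.
#' @export
half_amplitude_thresholds <- function(levels) {
  stopifnot(inherits(levels, "level_set"))
  if (levels$n_levels < 1) return(numeric(0))
  levels$baseline * levels$direction +
    (seq_len(levels$n_levels) - 0.5) * levels$unitary_amplitude
}

#' Idealize a sweep by threshold crossing
#'
#' Classifies every sample by the number of thresholds it exceeds (after
#' rectifying by the driving-force direction), compresses runs into events,
#' and merges events shorter than the dead time into the longer adjacent
#' event. The dead time default, `0.179 / filter_cutoff`, is the rise-time
#' resolution bound of a Gaussian-type filter.
#'
#' @param sweep A `sweep` or numeric current vector (pA).
#' @param thresholds Strictly increasing thresholds, pA (rectified axis),
#'   from [half_amplitude_thresholds()]. Empty => one all-closed event.
#' @param dead_time s; events shorter than this (other than a sole event)
#'   are merged. `NULL` uses `0.179 / filter_cutoff` when the sweep carries a
#'   config cutoff, else 0.
#' @param sampling_rate Hz; required when `sweep` is a bare numeric vector.
#' @param direction +1/-1 driving-force sign (see [detect_levels()]).
#' @return A tibble of class `event_list` with columns `level` (integer >= 0),
#'   `start` (s), `duration` (s); attributes `sweep_duration`, `dead_time`.
#' @export
idealize_sweep <- function(sweep, thresholds, dead_time = NULL,
                           sampling_rate = NULL, direction = 1) {
  if (inherits(sweep, "sweep")) {
    x <- sweep$current
    sampling_rate <- sweep$sampling_rate
  } else {
    x <- as.numeric(sweep)
    if (is.null(sampling_rate)) stop("sampling_rate required for bare vectors")
  }
  stopifnot(length(x) > 0, direction %in% c(-1, 1),
            !is.unsorted(thresholds, strictly = TRUE))
  if (is.null(dead_time)) dead_time <- 0
  stopifnot(dead_time >= 0)
  dt <- 1 / sampling_rate
  lev <- sample_levels(x * direction, thresholds)
  r <- rle(lev)
  level <- r$values
  duration <- r$lengths * dt
  # merge sub-dead-time events into the longer adjacent event, shortest first
  repeat {
    if (length(level) <= 1) break
    short <- which(duration < dead_time)
    short <- setdiff(short, c(1L, length(level)))  # keep truncated edge events
    if (length(short) == 0) break
    i <- short[which.min(duration[short])]
    nb <- if (duration[i - 1] >= duration[i + 1]) i - 1L else i + 1L
    duration[nb] <- duration[nb] + duration[i]
    level <- level[-i]; duration <- duration[-i]
    # re-fuse neighbours that now share a level
    r2 <- rle_merge(level, duration)
    level <- r2$level; duration <- r2$duration
  }
  out <- tibble::tibble(level = as.integer(level),
                        start = cumsum(c(0, duration[-length(duration)])),
                        duration = duration)
  structure(out, sweep_duration = length(x) * dt, dead_time = dead_time,
            class = c("event_list", class(out)))
}

#' Per-sample occupancy level given thresholds
#'
#' The brute-force classification underlying idealization: a sample's level
#' is the number of thresholds lying below it.
#'
#' @param x Rectified current samples, pA.
#' @param thresholds Strictly increasing thresholds, pA.
#' @return Integer vector of levels.
#' @export
sample_levels <- function(x, thresholds) {
  if (length(thresholds) == 0) return(rep(0L, length(x)))
  findInterval(x, thresholds)
}

rle_merge <- function(level, duration) {
  same <- c(FALSE, level[-1] == level[-length(level)])
  grp <- cumsum(!same)
  list(level = level[!same],
       duration = as.numeric(tapply(duration, factor(grp, levels = unique(grp)),
                                    sum)))
}

#' Idealize every sweep of a recording
#'
#' Convenience wrapper running [all_points_histogram()], [detect_levels()],
#' [half_amplitude_thresholds()] and [idealize_sweep()] per sweep. Sweeps at
#' (or within `skip_window` mV of) the reversal potential carry no resolvable
#' driving force and yield `NULL` level sets with an all-closed event list.
#'
#' @param recording A `recording`.
#' @param dead_time s; `NULL` uses `0.179 / filter_cutoff`.
#' @param bin_width Histogram bin width, pA (`NULL` = auto).
#' @param min_separation Peak separation floor, pA (`NULL` = auto).
#' @param skip_window mV; sweeps with |V - reversal| below this are skipped.
#' @return A list of class `idealized_recording`: per-voltage elements with
#'   `voltage`, `levels`, `events`; plus `config`, `patch_id`.
#' @export
idealize_recording <- function(recording, dead_time = NULL, bin_width = NULL,
                               min_separation = NULL, skip_window = 10) {
  stopifnot(inherits(recording, "recording"))
  cfg <- recording$config
  if (is.null(dead_time)) {
    dead_time <- if (is.finite(cfg$filter_cutoff)) 0.179 / cfg$filter_cutoff
                 else 0
  }
  per <- lapply(recording$sweeps, function(sw) {
    drive <- sw$voltage - cfg$reversal_potential
    if (abs(drive) < skip_window) {
      ev <- tibble::tibble(level = 0L, start = 0,
                           duration = cfg$sweep_duration)
      ev <- structure(ev, sweep_duration = cfg$sweep_duration,
                      dead_time = dead_time,
                      class = c("event_list", class(ev)))
      return(list(voltage = sw$voltage, levels = NULL, events = ev))
    }
    dirn <- sign(drive)
    h <- all_points_histogram(sw, bin_width = bin_width)
    lv <- detect_levels(h, min_separation = min_separation, direction = dirn)
    th <- half_amplitude_thresholds(lv)
    ev <- idealize_sweep(sw, th, dead_time = dead_time, direction = dirn)
    list(voltage = sw$voltage, levels = lv, events = ev)
  })
  structure(list(sweeps = per, config = cfg, patch_id = recording$patch_id),
            class = "idealized_recording")
}
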