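#' NPo and time-at-level of an idealized sweep
#'
#' NPo is the expected number of simultaneously open channels,
#' `sum_k k * t_k / T`, where `t_k` is the time spent with k channels open
#' over the sweep of duration T.
#'
#' @param events An `event_list` from [idealize_sweep()].
#' @param voltage Optional membrane potential recorded with the metrics, mV.
#' @return A one-row tibble: `voltage`, `npo`, `total_time`, plus a
#'   `time_at_level` list-column (tibble level/time).
#' @export
npo <- function(events, voltage = NA_real_) {
  stopifnot(inherits(events, "event_list"))
  total <- attr(events, "sweep_duration")
  if (!isTRUE(total > 0)) stop("zero-duration sweep")
  tal <- events |>
    dplyr::group_by(level) |>
    dplyr::summarise(time = sum(duration), .groups = "drop")
  tibble::tibble(voltage = voltage,
                 npo = sum(tal$level * tal$time) / total,
                 total_time = total,
                 time_at_level = list(tal))
}

#' Estimate the number of channels in a patch
#'
#' N is the maximum simultaneous open level observed across sweeps at the two
#' highest protocol voltages, where open probability is maximal. This is the
#' standard (downward-biased at low Po) stacking estimate.
#'
#' @param ideal An `idealized_recording`, or a list of `event_list`s paired
#'   with a `voltages` vector.
#' @param voltages Voltages per event list (only for the list form).
#' @param top_k Number of highest voltages to inspect (default 2).
#' @return Integer channel count (0 when no openings anywhere).
#' @export
estimate_n <- function(ideal, voltages = NULL, top_k = 2) {
  if (inherits(ideal, "idealized_recording")) {
    voltages <- vapply(ideal$sweeps, `[[`, numeric(1), "voltage")
    evs <- lapply(ideal$sweeps, `[[`, "events")
  } else {
    evs <- ideal
    stopifnot(length(voltages) == length(evs))
  }
  stopifnot(length(evs) >= 1)
  use <- voltages >= sort(voltages, decreasing = TRUE)[min(top_k, length(voltages))]
  max(0L, vapply(evs[use], function(e) max(0L, e$level), integer(1)))
}

#' Single-channel open probability from NPo
#'
#' `Po = NPo / N`, clipped to `[0, 1]`. For a single-channel patch this is
#' exactly O/(O+C).
#'
#' @param metrics A tibble from [npo()] (any number of rows).
#' @param n Channel count N (>= 1).
#' @return `metrics` with a `po` column appended.
#' @export
po_from_npo <- function(metrics, n) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (n < 1) stop("po_from_npo() undefined for n = 0 channels")
  dplyr::mutate(metrics, po = pmin(1, pmax(0, npo / n)))
}

#' Unitary current point(s) for the I-V relation
#'
#' Emits the signed unitary current at a voltage from a detected level set.
#' Voltages without a resolvable open level (no driving force, or no openings)
#' emit no point.
#'
#' @param levels A `level_set` (or `NULL`).
#' @param voltage Membrane potential, mV.
#' @return A tibble with columns `voltage`, `unitary_current` (pA); zero rows
#'   when no amplitude is resolvable.
#' @export
unitary_current <- function(levels, voltage) {
  if (is.null(levels) || levels$n_levels < 1 ||
      !is.finite(levels$unitary_amplitude)) {
    return(tibble::tibble(voltage = numeric(0), unitary_current = numeric(0)))
  }
  tibble::tibble(voltage = voltage,
                 unitary_current = levels$unitary_amplitude * levels$direction)
}

#' Slope conductance from unitary I-V points
#'
#' Ordinary least-squares line through (V, i) inside `[v_min, v_max]`; the
#' slope in pA/mV is reported in pS (x 1000).
#'
#' @param points Tibble with `voltage` (mV) and `unitary_current` (pA).
#' @param v_min,v_max Fit window, mV (defaults -40 and +100, the standard
#'   single-channel window).
#' @return A list of class `conductance_fit`: `slope_conductance` (pS),
#'   `intercept` (pA), `r_squared`, `n_points`, `points`.
#' @export
slope_conductance <- function(points, v_min = -40, v_max = 100) {
  pts <- dplyr::filter(points, voltage >= v_min, voltage <= v_max)
  if (nrow(pts) < 3)
    stop("slope_conductance() needs >= 3 I-V points in [", v_min, ", ",
         v_max, "] mV; got ", nrow(pts))
  fit <- stats::lm(unitary_current ~ voltage, data = pts)
  # noiseless I-V points give an exactly singular residual; the perfect-fit
  # warning from summary.lm is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope_conductance = unname(stats::coef(fit)[2]) * 1000,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = nrow(pts),
                 points = pts),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat("<conductance_fit> ", signif(x$slope_conductance, 4), " pS (",
      x$n_points, " points, r2 = ", signif(x$r_squared, 3), ")\n", sep = "")
  invisible(x)
}

#' Summarise a patch: N, NPo-V, Po-V, I-V and slope conductance
#'
#' Runs the per-sweep metrics over an idealized recording and assembles the
#' per-patch summary used by the group-comparison stage.
#'
#' @param ideal An `idealized_recording`.
#' @param v_min,v_max Slope-conductance fit window, mV.
#' @return A list of class `patch_summary`: `patch_id`, `n_channels`,
#'   `metrics` (tibble voltage/npo/po), `iv` (tibble voltage/unitary_current),
#'   `conductance` (a `conductance_fit`, or `NULL` if < 3 I-V points),
#'   `is_single_channel`.
#' @export
summarize_patch <- function(ideal, v_min = -40, v_max = 100) {
  stopifnot(inherits(ideal, "idealized_recording"))
  mets <- purrr::map_dfr(ideal$sweeps,
                         function(s) npo(s$events, voltage = s$voltage))
  n <- estimate_n(ideal)
  mets <- if (n >= 1) po_from_npo(mets, n) else
    dplyr::mutate(mets, po = NA_real_)
  iv <- purrr::map_dfr(ideal$sweeps,
                       function(s) unitary_current(s$levels, s$voltage))
  cond <- tryCatch(slope_conductance(iv, v_min, v_max),
                   error = function(e) NULL)
  structure(list(patch_id = ideal$patch_id, n_channels = n,
                 metrics = dplyr::select(mets, voltage, npo, po),
                 iv = iv, conductance = cond,
                 is_single_channel = n == 1L),
            class = "patch_summary")
}

#' @export
print.patch_summary <- function(x, ...) {
  cat("<patch_summary> ", x$patch_id, ": N = ", x$n_channels, sep = "")
  if (!is.null(x$conductance))
    cat(", slope conductance ", signif(x$conductance$slope_conductance, 4),
        " pS", sep = "")
  cat("\n")
  print(x$metrics, n = 5)
  invisible(x)
}
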