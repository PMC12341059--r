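#' Run the full simulation-to-statistics pipeline
#'
#' Orchestrates the study-style workflow over several groups of simulated
#' patches: simulate (or ingest) recordings, idealize every sweep, compute
#' per-patch NPo/Po/N and slope conductance, collect dwell fits from
#' single-channel patches, and run the group-comparison ladder on NPo at a
#' reference voltage, channels per patch, and the NPo-voltage curves. The
#' whole run is deterministic given `seed`.
#'
#' @param groups A named list: each element a list with `preset` (a
#'   [scheme_preset()] name or `"blocked"`), optional `n_channels`
#'   (default 3; blocked groups keep their channels shut by the paxilline
#'   flag), and optional `n_patches` (default 5).
#' @param seed Integer master seed.
#' @param sweep_duration s per voltage step (default 3; the full protocol
#'   uses 15).
#' @param protocol_voltages mV.
#' @param sampling_rate,filter_cutoff,noise_sd Acquisition settings.
#' @param unitary_conductance pS used for all groups (gating, not
#'   conductance, distinguishes the presets).
#' @param reference_voltage mV at which scalar NPo group comparisons are made
#'   (default 140).
#' @param out_dir Optional directory: tables are written as CSV and the
#'   summary as JSON.
#' @return A list of class `pipeline_report`: `patches` (tibble of per-patch
#'   scalars), `npo_curves`, `po_curves`, `dwell_taus`, `comparisons` (list),
#'   `per_voltage` (list of per-voltage comparison tibbles), `seed`.
#' @export
run_pipeline <- function(groups,
                         seed = 1L,
                         sweep_duration = 3,
                         protocol_voltages = seq(-40, 160, by = 20),
                         sampling_rate = 50000,
                         filter_cutoff = 6000,
                         noise_sd = 1,
                         unitary_conductance = 165,
                         reference_voltage = 140,
                         out_dir = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  patch_rows <- list(); curve_rows <- list(); tau_rows <- list()
  patch_idx <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    preset <- g$preset %||% "wt"
    blocked <- identical(preset, "blocked")
    scheme <- scheme_preset(if (blocked) "wt" else preset)
    n_patches <- g$n_patches %||% 5L
    n_channels <- g$n_channels %||% 3L
    for (i in seq_len(n_patches)) {
      patch_idx <- patch_idx + 1L
      cfg <- acquisition_config(
        sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
        sweep_duration = sweep_duration,
        protocol_voltages = protocol_voltages,
        unitary_conductance = unitary_conductance,
        noise_sd = noise_sd, n_channels = n_channels,
        paxilline_block = blocked,
        seed = seed * 10000L + patch_idx)
      ref_v <- protocol_voltages[which.min(abs(protocol_voltages -
                                                 reference_voltage))]
      pid <- sprintf("%s_%02d", gname, i)
      rec <- simulate_recording(scheme, cfg, patch_id = pid)
      ideal <- idealize_recording(rec)
      ps <- summarize_patch(ideal)
      patch_rows[[pid]] <- tibble::tibble(
        group = gname, patch_id = pid, n_channels = ps$n_channels,
        slope_conductance = ps$conductance$slope_conductance %||% NA_real_,
        npo_ref = ps$metrics$npo[ps$metrics$voltage == ref_v])
      curve_rows[[pid]] <- dplyr::mutate(ps$metrics, group = gname,
                                         patch_id = pid)
      if (ps$is_single_channel && !blocked) {
        top_v <- max(protocol_voltages)
        ev <- ideal$sweeps[[as.character(top_v)]]$events
        taus <- tryCatch({
          op <- collect_dwells(ev, "open", voltage = top_v, source_patch = pid)
          cl <- collect_dwells(ev, "closed", voltage = top_v,
                               source_patch = pid)
          fo <- if (nrow(op) >= 20)
            suppressWarnings(fit_open(log_bin(op))) else NULL
          fc <- if (nrow(cl) >= 20)
            suppressWarnings(fit_closed(log_bin(cl))) else NULL
          tibble::tibble(
            group = gname, patch_id = pid,
            tau_open = if (!is.null(fo) && fo$converged)
              fo$components$tau[1] else NA_real_,
            tau_closed1 = if (!is.null(fc) && fc$converged)
              fc$components$tau[1] else NA_real_,
            tau_closed2 = if (!is.null(fc) && fc$converged)
              fc$components$tau[2] else NA_real_)
        }, error = function(e) NULL)
        if (!is.null(taus)) tau_rows[[pid]] <- taus
      }
    }
  }
  patches <- dplyr::bind_rows(patch_rows)
  curves <- dplyr::bind_rows(curve_rows)
  taus <- dplyr::bind_rows(tau_rows)

  degenerate <- function(tab) stats::sd(tab$value) == 0
  npo_tab <- dplyr::transmute(patches, group, patch_id, value = npo_ref)
  n_tab <- dplyr::transmute(patches, group, patch_id,
                            value = as.numeric(n_channels))
  comparisons <- list()
  comparisons$npo_at_reference <-
    if (degenerate(npo_tab)) "degenerate: constant NPo across all patches"
    else suppressWarnings(compare_groups(npo_tab))
  comparisons$channels_per_patch <-
    if (degenerate(n_tab)) "degenerate: constant N across all patches"
    else suppressWarnings(compare_groups(n_tab))

  per_voltage <- list()
  gl <- names(groups)
  if (length(gl) >= 2) {
    pairs <- utils::combn(gl, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste(pr, collapse = "_vs_")
      tab <- dplyr::transmute(curves, group, voltage, value = npo)
      tab <- dplyr::filter(tab, group %in% pr)
      per_voltage[[key]] <- tryCatch(
        if (stats::sd(tab$value) == 0)
          "degenerate: constant NPo in both groups"
        else per_voltage_compare(tab, pair = pr),
        error = function(e) paste("skipped:", conditionMessage(e)))
    }
  }

  report <- structure(
    list(patches = patches,
         npo_curves = dplyr::select(curves, group, patch_id, voltage, npo),
         po_curves = dplyr::select(curves, group, patch_id, voltage, po),
         dwell_taus = taus,
         comparisons = comparisons,
         per_voltage = per_voltage,
         seed = as.integer(seed)),
    class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' CSV tables plus a JSON summary (scalar metrics, comparison p values, run
#' seed); the JSON is written with fixed formatting so identical runs are
#' byte-identical.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$patches, file.path(dir, "patches.csv"))
  readr::write_csv(report$npo_curves, file.path(dir, "npo_by_voltage.csv"))
  readr::write_csv(report$po_curves, file.path(dir, "po_by_voltage.csv"))
  if (nrow(report$dwell_taus %||% tibble::tibble()) > 0)
    readr::write_csv(report$dwell_taus, file.path(dir, "dwell_taus.csv"))
  summarize_cmp <- function(cmp) {
    if (is.character(cmp)) return(list(status = cmp))
    list(test = cmp$test_name, route = cmp$route,
         omnibus_p = cmp$omnibus_p,
         pairwise = as.data.frame(cmp$pairwise))
  }
  json <- list(
    seed = report$seed,
    groups = sort(unique(report$patches$group)),
    mean_n_channels = lapply(
      split(report$patches$n_channels, report$patches$group), mean),
    mean_npo_at_reference = lapply(
      split(report$patches$npo_ref, report$patches$group), mean),
    comparisons = lapply(report$comparisons, summarize_cmp),
    per_voltage = lapply(report$per_voltage, function(pv) {
      if (is.character(pv)) list(status = pv) else as.data.frame(pv)
    }))
  jsonlite::write_json(json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$seed, ", ",
      nrow(x$patches), " patches in ",
      length(unique(x$patches$group)), " group(s)\n", sep = "")
  print(dplyr::count(x$patches, group))
  invisible(x)
}
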