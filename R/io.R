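#' Write a recording bundle to disk
#'
#' Package-native on-disk form of a recording: one CSV per sweep (columns
#' `time_s`, `current_pA`), a JSON sidecar with the acquisition
#' configuration, and (when ground-truth gating paths are present) a CSV
#' event table (`channel`, `state`, `start_s`, `duration_s`) per sweep.
#'
#' @param recording A `recording`.
#' @param dir Output directory (created if needed).
#' @param truth Write ground-truth event tables when available (default
#'   TRUE).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, truth = TRUE) {
  stopifnot(inherits(recording, "recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- recording$config
  jsonlite::write_json(
    c(unclass(cfg), list(patch_id = recording$patch_id)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  for (sw in recording$sweeps) {
    stem <- sprintf("sweep_%+04d_mV", as.integer(sw$voltage))
    readr::write_csv(
      tibble::tibble(time_s = sw$time, current_pA = sw$current),
      file.path(dir, paste0(stem, ".csv")))
    if (truth && !is.null(sw$truth)) {
      tr <- purrr::imap_dfr(sw$truth, function(p, ch)
        tibble::tibble(channel = ch, state = p$state,
                       start_s = p$start, duration_s = p$duration))
      readr::write_csv(tr, file.path(dir, paste0(stem, "_truth.csv")))
    }
  }
  invisible(dir)
}

#' Read a recording bundle from disk
#'
#' Inverse of [write_recording()]. Ground-truth event tables, when present,
#' are re-attached to the sweeps.
#'
#' @param dir Directory holding `config.json` and `sweep_*.csv` files.
#' @return A `recording`.
#' @export
read_recording <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  patch_id <- cfg_raw$patch_id %||% "patch"
  cfg <- acquisition_config(
    sampling_rate = cfg_raw$sampling_rate,
    filter_cutoff = cfg_raw$filter_cutoff %||% Inf,
    sweep_duration = cfg_raw$sweep_duration,
    protocol_voltages = cfg_raw$protocol_voltages,
    holding_voltage = cfg_raw$holding_voltage %||% 0,
    unitary_conductance = cfg_raw$unitary_conductance,
    reversal_potential = cfg_raw$reversal_potential %||% 0,
    noise_sd = cfg_raw$noise_sd %||% 0,
    n_channels = cfg_raw$n_channels %||% 1,
    paxilline_block = isTRUE(cfg_raw$paxilline_block),
    seed = cfg_raw$seed %||% 1L)
  sweeps <- lapply(cfg$protocol_voltages, function(v) {
    stem <- sprintf("sweep_%+04d_mV", as.integer(v))
    d <- readr::read_csv(file.path(dir, paste0(stem, ".csv")),
                         col_types = "dd", progress = FALSE)
    truth <- NULL
    tf <- file.path(dir, paste0(stem, "_truth.csv"))
    if (file.exists(tf)) {
      tr <- readr::read_csv(tf, col_types = "icdd", progress = FALSE)
      truth <- lapply(split(tr, tr$channel), function(p) {
        pt <- tibble::tibble(state = p$state, class = NA_character_,
                             start = p$start_s, duration = p$duration_s)
        structure(pt, total_duration = cfg$sweep_duration, voltage = v,
                  class = c("state_path", class(pt)))
      })
    }
    structure(list(voltage = v, time = d$time_s, current = d$current_pA,
                   sampling_rate = cfg$sampling_rate, truth = truth),
              class = "sweep")
  })
  names(sweeps) <- as.character(cfg$protocol_voltages)
  structure(list(sweeps = sweeps, config = cfg, patch_id = patch_id),
            class = "recording")
}

#' Serialize an event list to CSV
#'
#' @param events An `event_list`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_events <- function(events, file) {
  stopifnot(inherits(events, "event_list"))
  readr::write_csv(
    tibble::tibble(level = events$level, start_s = events$start,
                   duration_s = events$duration), file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
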