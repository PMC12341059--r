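#' Acquisition configuration for simulated cell-attached recordings
#'
#' Defaults follow the standard fibroblast cell-attached protocol: 15 s sweeps
#' at command potentials from -40 to +160 mV in 20 mV increments, digitised at
#' 50 kHz and low-pass filtered at 6 kHz, with a ~165 pS unitary conductance
#' and a reversal potential near 0 mV (high-K+ bath).
#'
#' @param sampling_rate Hz; must exceed twice `filter_cutoff`.
#' @param filter_cutoff Hz; `Inf` disables filtering.
#' @param sweep_duration s.
#' @param protocol_voltages Membrane potentials, mV (strictly increasing).
#' @param holding_voltage mV (metadata only; sweeps are recorded at the
#'   protocol potentials).
#' @param unitary_conductance pS.
#' @param reversal_potential mV.
#' @param noise_sd Gaussian current noise SD before filtering, pA.
#' @param n_channels Channels in the patch (>= 1).
#' @param paxilline_block If `TRUE`, all channels are pinned closed,
#'   emulating a 100 nM paxilline application.
#' @param seed Integer seed controlling all randomness of the recording.
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 50000,
                               filter_cutoff = 6000,
                               sweep_duration = 15,
                               protocol_voltages = seq(-40, 160, by = 20),
                               holding_voltage = 0,
                               unitary_conductance = 165,
                               reversal_potential = 0,
                               noise_sd = 1,
                               n_channels = 1,
                               paxilline_block = FALSE,
                               seed = 1L) {
  stopifnot(sampling_rate > 2 * filter_cutoff || is.infinite(filter_cutoff),
            sampling_rate > 0, sweep_duration > 0,
            length(protocol_voltages) >= 1,
            !is.unsorted(protocol_voltages, strictly = TRUE),
            unitary_conductance > 0, noise_sd >= 0,
            n_channels >= 1, n_channels == round(n_channels))
  structure(list(sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 sweep_duration = sweep_duration,
                 protocol_voltages = protocol_voltages,
                 holding_voltage = holding_voltage,
                 unitary_conductance = unitary_conductance,
                 reversal_potential = reversal_potential,
                 noise_sd = noise_sd,
                 n_channels = as.integer(n_channels),
                 paxilline_block = isTRUE(paxilline_block),
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Sample a gating path by the Gillespie algorithm
#'
#' Simulates the continuous-time Markov chain of a gating scheme at one
#' membrane potential: sojourns are exponential with state-specific means and
#' jumps follow the embedded chain (probabilities proportional to outgoing
#' rates). The final sojourn is truncated at `duration`.
#'
#' @inheritParams rate_matrix
#' @param duration Path duration, s.
#' @param seed Integer seed (the path is reproducible per seed).
#' @param start Starting state label; default the first closed state.
#' @return A tibble of class `state_path` with columns `state`, `class`
#'   (closed/open), `start`, `duration` (s), and attributes `total_duration`
#'   and `voltage`.
#' @export
sample_path <- function(scheme, voltage, duration, seed = NULL, start = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0)
  q <- rate_matrix(scheme, voltage)
  states <- scheme$states
  if (is.null(start)) start <- states[scheme$classes == "closed"][1]
  stopifnot(start %in% states)
  if (!is.null(seed)) set.seed(seed)

  out_rate <- rowSums(q)
  if (any(out_rate <= 0)) stop("absorbing state in scheme: invalid scheme")
  # pre-normalised jump probabilities per state
  jump <- sweep(q, 1, out_rate, "/")

  cap <- 256L
  st <- integer(cap); dw <- numeric(cap)
  n <- 0L
  cur <- match(start, states)
  t_now <- 0
  while (t_now < duration) {
    sj <- stats::rexp(1, rate = out_rate[cur])
    sj <- min(sj, duration - t_now)
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      st <- c(st, integer(cap / 2L)); dw <- c(dw, numeric(cap / 2L))
    }
    st[n] <- cur; dw[n] <- sj
    t_now <- t_now + sj
    if (t_now >= duration) break
    cur <- sample.int(length(states), 1L, prob = jump[cur, ])
  }
  st <- st[seq_len(n)]; dw <- dw[seq_len(n)]
  path <- tibble::tibble(
    state = states[st],
    class = unname(scheme$classes[st]),
    start = cumsum(c(0, dw[-n])),
    duration = dw)
  structure(path, total_duration = duration, voltage = voltage,
            class = c("state_path", class(path)))
}

#' Per-sample open-channel count of one or more gating paths
#'
#' @param paths A `state_path` or list of them (one per channel).
#' @param times Sample times, s.
#' @return Integer vector: number of channels open at each time.
#' @keywords internal
open_count_at <- function(paths, times) {
  if (inherits(paths, "state_path")) paths <- list(paths)
  counts <- integer(length(times))
  for (p in paths) {
    idx <- findInterval(times, p$start)
    idx[idx < 1L] <- 1L
    counts <- counts + as.integer(p$class[idx] == "open")
  }
  counts
}

#' Zero-phase Gaussian low-pass filter
#'
#' Standard single-channel-analysis smoothing filter: a Gaussian FIR kernel
#' with sigma = 0.1325 / f_c (so the -3 dB cutoff is f_c), applied by
#' symmetric convolution, hence zero phase shift and no distortion of dwell
#' boundaries. Edges are handled by replication padding.
#'
#' @param x Numeric samples.
#' @param sampling_rate Hz.
#' @param cutoff -3 dB cutoff, Hz; `Inf` returns `x` unchanged.
#' @return Filtered samples, same length.
#' @export
gaussian_lowpass <- function(x, sampling_rate, cutoff) {
  if (is.infinite(cutoff)) return(x)
  sigma <- 0.1325 / cutoff * sampling_rate    # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Render a noisy current sweep from gating paths
#'
#' Converts channel gating paths into a sampled current trace: the unitary
#' current is ohmic, `i = gamma * (V - V_rev) / 1000` pA, multiplied by the
#' number of simultaneously open channels, plus Gaussian noise, then low-pass
#' filtered.
#'
#' @param paths A `state_path` or list of them (one per channel); all must
#'   share `config$sweep_duration`.
#' @param voltage Membrane potential of the sweep, mV.
#' @param config An [acquisition_config()].
#' @return A list of class `sweep`: `voltage`, `time` (s), `current` (pA),
#'   `sampling_rate`, `truth` (the generating paths).
#' @export
render_sweep <- function(paths, voltage, config) {
  stopifnot(inherits(config, "acquisition_config"))
  if (inherits(paths, "state_path")) paths <- list(paths)
  durs <- vapply(paths, function(p) attr(p, "total_duration"), numeric(1))
  if (any(abs(durs - config$sweep_duration) > 1 / config$sampling_rate))
    stop("path durations do not match config$sweep_duration")
  n <- round(config$sweep_duration * config$sampling_rate)
  tt <- (seq_len(n) - 1) / config$sampling_rate
  i_unit <- unitary_current_pa(config$unitary_conductance, voltage,
                               config$reversal_potential)
  cur <- open_count_at(paths, tt) * i_unit
  if (config$noise_sd > 0) cur <- cur + stats::rnorm(n, sd = config$noise_sd)
  cur <- gaussian_lowpass(cur, config$sampling_rate, config$filter_cutoff)
  structure(list(voltage = voltage, time = tt, current = cur,
                 sampling_rate = config$sampling_rate, truth = paths),
            class = "sweep")
}

#' Build a sweep from bare samples
#'
#' Constructor for ingesting externally produced traces (or hand-built test
#' signals) into the analysis pipeline.
#'
#' @param current Sampled current, pA.
#' @param sampling_rate Hz.
#' @param voltage Membrane potential of the sweep, mV.
#' @param truth Optional list of ground-truth `state_path`s.
#' @return A `sweep`.
#' @export
as_sweep <- function(current, sampling_rate, voltage = NA_real_,
                     truth = NULL) {
  stopifnot(is.numeric(current), length(current) > 0, all(is.finite(current)),
            sampling_rate > 0)
  structure(list(voltage = voltage,
                 time = (seq_along(current) - 1) / sampling_rate,
                 current = as.numeric(current),
                 sampling_rate = sampling_rate, truth = truth),
            class = "sweep")
}

#' Ohmic unitary current
#'
#' @param conductance pS.
#' @param voltage Membrane potential, mV.
#' @param reversal Reversal potential, mV.
#' @return Current in pA (signed: negative below the reversal potential).
#' @export
unitary_current_pa <- function(conductance, voltage, reversal = 0) {
  conductance * (voltage - reversal) / 1000
}

#' Simulate a full cell-attached recording
#'
#' One sweep per protocol voltage, each with independent gating paths per
#' channel. With `config$paxilline_block` every channel is pinned closed for
#' the whole sweep (the pharmacological identity control). All randomness is
#' driven by `config$seed`, so identical inputs give bit-identical
#' recordings.
#'
#' @param scheme A [kinetic_scheme()].
#' @param config An [acquisition_config()].
#' @param patch_id Identifier stored with the recording.
#' @return A list of class `recording`: `sweeps` (list of `sweep`, named by
#'   voltage), `config`, `patch_id`.
#' @export
simulate_recording <- function(scheme, config = acquisition_config(),
                               patch_id = "patch1") {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(config, "acquisition_config"))
  set.seed(config$seed)
  closed0 <- scheme$states[scheme$classes == "closed"][1]
  sweeps <- lapply(config$protocol_voltages, function(v) {
    paths <- lapply(seq_len(config$n_channels), function(ch) {
      if (config$paxilline_block) {
        p <- tibble::tibble(state = closed0, class = "closed",
                            start = 0, duration = config$sweep_duration)
        structure(p, total_duration = config$sweep_duration, voltage = v,
                  class = c("state_path", class(p)))
      } else {
        sample_path(scheme, v, config$sweep_duration)
      }
    })
    render_sweep(paths, v, config)
  })
  names(sweeps) <- as.character(config$protocol_voltages)
  structure(list(sweeps = sweeps, config = config, patch_id = patch_id),
            class = "recording")
}

#' @export
print.sweep <- function(x, ...) {
  cat("<sweep> ", x$voltage, " mV, ", length(x$current), " samples @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", x$patch_id, ": ", length(x$sweeps), " sweeps (",
      paste(range(x$config$protocol_voltages), collapse = " to "),
      " mV), ", x$config$n_channels, " channel(s)\n", sep = "")
  invisible(x)
}
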