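#' Collect open or closed dwell times from a single-channel event list
#'
#' Dwell-time analysis is restricted to single-channel patches (levels 0/1
#' only); the first and last events of a sweep are boundary-truncated and are
#' excluded.
#'
#' @param events An `event_list` with levels in \{0, 1\}.
#' @param kind `"open"` or `"closed"`.
#' @param voltage,source_patch Optional metadata carried on the result.
#' @return A tibble of class `dwell_sample` with column `duration` (s);
#'   attributes `kind`, `voltage`, `source_patch`.
#' @export
collect_dwells <- function(events, kind = c("open", "closed"),
                           voltage = NA_real_, source_patch = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(inherits(events, "event_list"))
  if (any(events$level > 1))
    stop("multi-level event list: dwell analysis requires single-channel ",
         "patches (levels 0/1); use recordings with one channel")
  keep <- events[-c(1, nrow(events)), , drop = FALSE]
  want <- if (kind == "open") 1L else 0L
  out <- tibble::tibble(duration = keep$duration[keep$level == want])
  structure(out, kind = kind, voltage = voltage, source_patch = source_patch,
            class = c("dwell_sample", class(out)))
}

#' Make a dwell sample from bare durations
#'
#' @param durations Positive dwell durations, s.
#' @inheritParams collect_dwells
#' @return A `dwell_sample`.
#' @export
dwell_sample <- function(durations, kind = c("open", "closed"),
                         voltage = NA_real_, source_patch = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(all(durations > 0))
  out <- tibble::tibble(duration = as.numeric(durations))
  structure(out, kind = kind, voltage = voltage, source_patch = source_patch,
            class = c("dwell_sample", class(out)))
}

#' Log-binned dwell-time histogram
#'
#' Bins of constant width on a logarithmic time axis. In this coordinate an
#' exponential dwell component appears as a skewed peak whose maximum lies
#' exactly at its time constant, which is what makes the transform useful for
#' reading time constants off the histogram.
#'
#' @param dwells A `dwell_sample` (or positive numeric durations, s).
#' @param bins_per_decade Bins per factor-of-ten of time (>= 5; default 10).
#' @return A tibble of class `log_histogram` with `log10_center`, `count`;
#'   attributes `log10_edges`, `bins_per_decade`, `n_dwells`, `kind`.
#' @export
log_bin <- function(dwells, bins_per_decade = 10) {
  x <- if (inherits(dwells, "dwell_sample")) dwells$duration
       else as.numeric(dwells)
  if (length(x) == 0) stop("empty dwell sample")
  stopifnot(all(x > 0), bins_per_decade >= 5)
  w <- 1 / bins_per_decade
  lo <- floor(min(log10(x)) / w) * w - w
  hi <- ceiling(max(log10(x)) / w) * w + w
  edges <- seq(lo, hi + w / 2, by = w)
  counts <- tabulate(pmin(findInterval(log10(x), edges,
                                       rightmost.closed = TRUE),
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  out <- tibble::tibble(log10_center = (edges[-1] + edges[-length(edges)]) / 2,
                        count = counts)
  structure(out, log10_edges = edges, bins_per_decade = bins_per_decade,
            n_dwells = length(x),
            kind = if (inherits(dwells, "dwell_sample")) attr(dwells, "kind")
                   else NA_character_,
            class = c("log_histogram", class(out)))
}

# peak-at-tau component: count density (per log10 bin) of an exponential
# dwell distribution on the log-time axis. z = ln(t) - ln(tau); the component
# A * exp(z - exp(z)) peaks exactly at t = tau and integrates (over ln t) to A.
peak_component <- function(log10_center, log_tau, amplitude) {
  z <- log(10) * log10_center - log_tau
  amplitude * exp(z - exp(z))
}

#' Fit a single peak-at-tau component to an open-time histogram
#'
#' Least-squares fit of `A * exp(z - exp(z))`, `z = ln(t) - ln(tau)`, to the
#' log-binned counts. This is the log-time transform of the exponential dwell
#' density, whose peak sits exactly at the time constant tau.
#'
#' @param hist A [log_bin()] histogram.
#' @param min_dwells Below this dwell count a warning is attached (default
#'   50).
#' @return A list of class `dwell_fit`: `components` (tibble tau/weight),
#'   `kind = "open"`, `sse`, `converged`, `n_dwells`, `hist`.
#' @export
fit_open <- function(hist, min_dwells = 50) {
  stopifnot(inherits(hist, "log_histogram"))
  nd <- attr(hist, "n_dwells")
  if (nd < min_dwells)
    warning("only ", nd, " dwells; open-time fit may be unstable")
  x <- hist$log10_center; y <- hist$count
  i0 <- which.max(y)
  # peak height of the component is A / e, so A starts at e * max count
  start <- list(log_tau = log(10) * x[i0], a = max(y) * exp(1))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ peak_component(x, log_tau, a),
                      start = start,
                      lower = c(min(log(10) * x) - 2, 0),
                      upper = c(max(log(10) * x) + 2, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(components = tibble::tibble(tau = numeric(0),
                                                      weight = numeric(0)),
                          kind = "open", sse = NA_real_, converged = FALSE,
                          n_dwells = nd, hist = hist),
                     class = "dwell_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(components = tibble::tibble(tau = exp(cf[["log_tau"]]),
                                             weight = 1),
                 kind = "open",
                 sse = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv,
                 n_dwells = nd, hist = hist),
            class = "dwell_fit")
}

#' Fit two peak-at-tau components to a closed-time histogram
#'
#' Least-squares fit of a two-component mixture of log-time exponential peaks
#' to estimate the fast and slow closed-time constants. Components are
#' initialised at the two most prominent histogram maxima (ties broken toward
#' smaller tau) and reported sorted tau1 < tau2 with weights normalised to 1.
#' When the fitted second component carries < 1% of the weight or collapses
#' onto the first, the result is flagged effectively single-component.
#'
#' @inheritParams fit_open
#' @return A list of class `dwell_fit` with two components (`kind =
#'   "closed"`) and an `effectively_single` flag.
#' @export
fit_closed <- function(hist, min_dwells = 50) {
  stopifnot(inherits(hist, "log_histogram"))
  nd <- attr(hist, "n_dwells")
  if (nd < min_dwells)
    warning("only ", nd, " dwells; closed-time fit may be unstable")
  x <- hist$log10_center; y <- hist$count
  n <- length(y)
  is_max <- y > 0 & y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  cand <- which(is_max)
  cand <- cand[order(-y[cand], x[cand])][seq_len(min(2, length(cand)))]
  cand <- sort(cand)
  if (length(cand) == 1) {
    # single visible peak: seed the second component from the upper tail
    q75 <- x[min(n, which(cumsum(y) >= 0.95 * sum(y))[1])]
    starts <- c(x[cand], max(q75, x[cand] + 1))
  } else starts <- x[cand]
  start <- list(lt1 = log(10) * starts[1], lt2 = log(10) * starts[2],
                a1 = exp(1) * max(1, y[which.min(abs(x - starts[1]))]),
                a2 = exp(1) * max(1, y[which.min(abs(x - starts[2]))]))
  lo <- min(log(10) * x) - 2; hi <- max(log(10) * x) + 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ peak_component(x, lt1, a1) +
                        peak_component(x, lt2, a2),
                      start = start,
                      lower = c(lo, lo, 0, 0), upper = c(hi, hi, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # two components collapsed (singular gradient): the distribution is
    # effectively single-exponential, so fall back to the one-peak fit
    single <- suppressWarnings(fit_open(hist, min_dwells = 0))
    return(structure(list(components = single$components,
                          kind = "closed", sse = single$sse,
                          converged = single$converged,
                          effectively_single = TRUE,
                          n_dwells = nd, hist = hist),
                     class = "dwell_fit"))
  }
  cf <- stats::coef(fit)
  taus <- exp(c(cf[["lt1"]], cf[["lt2"]]))
  amps <- c(cf[["a1"]], cf[["a2"]])
  o <- order(taus)
  taus <- taus[o]; amps <- amps[o]
  w <- amps / sum(amps)
  eff_single <- w[2] < 0.01 || w[1] < 0.01 ||
    abs(log(taus[2] / taus[1])) < 0.05
  structure(list(components = tibble::tibble(tau = taus, weight = w),
                 kind = "closed",
                 sse = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv,
                 effectively_single = eff_single,
                 n_dwells = nd, hist = hist),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat("<dwell_fit> ", x$kind, ", ", nrow(x$components), " component(s), ",
      "converged: ", x$converged, "\n", sep = "")
  if (nrow(x$components)) {
    with(x$components,
         cat(sprintf("  tau = %.4g s (weight %.2f)\n", tau, weight)))
  }
  invisible(x)
}

#' Draw dwell durations from an exponential mixture
#'
#' Generator for dwell-fit validation: durations from
#' `sum_i w_i * Exp(tau_i)`.
#'
#' @param n Number of dwells.
#' @param tau Component time constants, s.
#' @param weight Mixture weights (normalised internally).
#' @param kind Dwell kind tag.
#' @param seed Optional integer seed.
#' @return A `dwell_sample`.
#' @export
simulate_dwells <- function(n, tau, weight = rep(1, length(tau)),
                            kind = c("closed", "open"), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, all(tau > 0), all(weight > 0),
            length(weight) == length(tau))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(tau), n, replace = TRUE,
                     prob = weight / sum(weight))
  dwell_sample(stats::rexp(n, rate = 1 / tau[comp]), kind = kind)
}
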