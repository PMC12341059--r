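#' Voltage-dependent transition rate
#'
#' A transition rate of a gating scheme, parameterised as
#' `rate(V) = base_rate * exp(V / voltage_efold)`. `base_rate` is the rate at
#' 0 mV in transitions/s; `voltage_efold` is the membrane potential change (mV)
#' producing an e-fold change in the rate. A positive `voltage_efold` makes the
#' rate grow with depolarisation, a negative one makes it shrink, and
#' `voltage_efold = Inf` (or `-Inf`) gives a voltage-independent rate.
#'
#' @param base_rate Rate at 0 mV, transitions/s. Must be finite and positive.
#' @param voltage_efold mV per e-fold change (signed); `Inf` for no voltage
#'   dependence.
#' @return An object of class `rate_fn`.
#' @examples
#' r <- rate_fn(100, Inf)
#' eval_rate(r, 120) # 100
#' @export
rate_fn <- function(base_rate, voltage_efold = Inf) {
  stopifnot(is.numeric(base_rate), length(base_rate) == 1,
            is.finite(base_rate), base_rate > 0,
            is.numeric(voltage_efold), length(voltage_efold) == 1,
            voltage_efold != 0)
  structure(list(base_rate = base_rate, voltage_efold = voltage_efold),
            class = "rate_fn")
}

#' Evaluate a transition rate at a membrane potential
#'
#' @param rate A [rate_fn()].
#' @param voltage Membrane potential, mV.
#' @return Rate in transitions/s (vectorised over `voltage`).
#' @export
eval_rate <- function(rate, voltage) {
  stopifnot(inherits(rate, "rate_fn"))
  if (is.infinite(rate$voltage_efold)) {
    rep(rate$base_rate, length(voltage))
  } else {
    rate$base_rate * exp(voltage / rate$voltage_efold)
  }
}

#' Continuous-time Markov gating scheme
#'
#' Defines the kinetic states of a channel (each labelled closed or open) and
#' the voltage-dependent transition rates between them. All simulated gating,
#' dwell-time spectra and stationary open probabilities derive from this
#' object.
#'
#' @param states Character vector of state labels (length >= 2, unique).
#' @param classes Character vector, one of `"closed"`/`"open"` per state; at
#'   least one of each.
#' @param transitions A data frame with columns `from`, `to`, `base_rate`,
#'   `voltage_efold` (one row per allowed transition; no self-transitions).
#' @param name Scheme name (free text).
#' @return An object of class `kinetic_scheme`.
#' @examples
#' two_state <- kinetic_scheme(
#'   states = c("C", "O"), classes = c("closed", "open"),
#'   transitions = tibble::tribble(
#'     ~from, ~to, ~base_rate, ~voltage_efold,
#'     "C", "O", 100, Inf,
#'     "O", "C", 100, Inf
#'   ),
#'   name = "symmetric two-state"
#' )
#' stationary_po(two_state, 120) # 0.5
#' @export
kinetic_scheme <- function(states, classes, transitions, name = "scheme") {
  stopifnot(is.character(states), length(states) >= 2, !anyDuplicated(states))
  classes <- match.arg(classes, c("closed", "open"), several.ok = TRUE)
  stopifnot(length(classes) == length(states),
            any(classes == "closed"), any(classes == "open"))
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("from", "to", "base_rate", "voltage_efold") %in%
                  names(transitions)),
            all(transitions$from %in% states),
            all(transitions$to %in% states),
            all(transitions$from != transitions$to),
            all(is.finite(transitions$base_rate)),
            all(transitions$base_rate > 0))
  scheme <- structure(
    list(states = states, classes = stats::setNames(classes, states),
         transitions = transitions, name = name),
    class = "kinetic_scheme")
  # connectivity of the undirected transition graph
  adj <- rate_matrix(scheme, 0) != 0
  adj <- adj | t(adj)
  reached <- logical(length(states)); reached[1] <- TRUE
  repeat {
    new <- reached | apply(adj[, reached, drop = FALSE], 1, any)
    if (identical(new, reached)) break
    reached <- new
  }
  if (!all(reached)) stop("transition graph of scheme is not connected")
  scheme
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$name, "\n", sep = "")
  cat("states: ", paste0(x$states, " (", substr(x$classes, 1, 1), ")",
                         collapse = ", "), "\n", sep = "")
  print(x$transitions)
  invisible(x)
}

#' Transition-rate (generator) matrix at a voltage
#'
#' @param scheme A [kinetic_scheme()].
#' @param voltage Membrane potential, mV.
#' @param generator If `TRUE` set the diagonal to minus the row sums (the
#'   infinitesimal generator Q); if `FALSE` leave the diagonal at zero.
#' @return A square numeric matrix with dimnames = state labels.
#' @export
rate_matrix <- function(scheme, voltage, generator = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n <- length(scheme$states)
  q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    q[tr$from[i], tr$to[i]] <-
      eval_rate(rate_fn(tr$base_rate[i], tr$voltage_efold[i]), voltage)
  }
  if (any(!is.finite(q)) || any(q < 0))
    stop("rates must evaluate positive and finite at ", voltage, " mV")
  if (generator) diag(q) <- -rowSums(q)
  q
}

#' Analytic mean sojourn time in a state
#'
#' The mean dwell in a state of a continuous-time Markov chain is the
#' reciprocal of the sum of its outgoing rates.
#'
#' @inheritParams rate_matrix
#' @param state A state label of `scheme`.
#' @return Mean sojourn duration, s.
#' @export
mean_dwell <- function(scheme, state, voltage) {
  stopifnot(inherits(scheme, "kinetic_scheme"), state %in% scheme$states)
  out <- sum(rate_matrix(scheme, voltage)[state, ])
  if (out <= 0) stop("state '", state, "' is absorbing: invalid scheme")
  1 / out
}

#' Stationary open probability of a gating scheme
#'
#' Solves the stationary distribution pi of the generator (pi Q = 0,
#' sum(pi) = 1) and returns the summed probability of the open-class states.
#' This is the analytic counterpart of the empirical Po = O/(O+C).
#'
#' @inheritParams rate_matrix
#' @return Stationary open probability in `[0, 1]`.
#' @export
stationary_po <- function(scheme, voltage) {
  q <- rate_matrix(scheme, voltage, generator = TRUE)
  n <- nrow(q)
  # irreducibility: every state reachable from every other in the directed graph
  adj <- (q > 0)
  reach <- diag(TRUE, n) | adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  if (!all(reach)) stop("scheme is reducible at ", voltage, " mV")
  a <- rbind(t(q), rep(1, n))
  pi_hat <- stats::setNames(
    as.vector(qr.solve(a, c(rep(0, n), 1))), rownames(q))
  sum(pi_hat[scheme$classes[names(pi_hat)] == "open"])
}

#' Dwell-time spectrum of the closed (or open) state class
#'
#' Eigenvalues of the sub-generator restricted to one conductance class give
#' the exponential components of that class's aggregate dwell-time
#' distribution (time constants = -1/eigenvalue). Used as the analytic oracle
#' for histogram-fitted closed-time constants.
#'
#' @inheritParams rate_matrix
#' @param class `"closed"` or `"open"`.
#' @return Sorted vector of time constants, s (fast first).
#' @export
dwell_spectrum <- function(scheme, class = c("closed", "open"), voltage) {
  class <- match.arg(class)
  q <- rate_matrix(scheme, voltage, generator = TRUE)
  keep <- scheme$classes == class
  sub <- q[keep, keep, drop = FALSE]
  ev <- eigen(sub, only.values = TRUE)$values
  sort(-1 / Re(ev))
}

#' Built-in gating scheme presets
#'
#' All presets share the linear topology C2 <-> C1 <-> O, the minimal scheme
#' with one open and two closed exponential dwell components. Voltage
#' dependence sits on the C1->O and O->C1 rates so that the wild-type-like
#' scheme activates only above about +80 mV at endogenous calcium
#' (stationary Po < 0.01 at +60 mV, > 0.1 at +140 mV).
#'
#' * `"wt"` — wild-type-like gating.
#' * `"n999s"` — gain-of-function via faster closed->open transitions
#'   (shortened closed sojourns, left-shifted activation), unchanged
#'   conductance.
#' * `"e656a"` — gain-of-function via slowed open->closed transitions
#'   (lengthened open sojourns); in the study-like pipeline it is paired with
#'   fewer channels per patch.
#' * `"two_state"` — voltage-independent C <-> O with 10 ms mean dwells and
#'   Po = 0.5 at every voltage; used for conductance assays where openings
#'   must be resolvable across the whole I-V range.
#'
#' @param preset Preset name.
#' @return A [kinetic_scheme()].
#' @examples
#' stationary_po(scheme_preset("wt"), 140)
#' @export
scheme_preset <- function(preset = c("wt", "n999s", "e656a", "two_state")) {
  preset <- match.arg(preset)
  if (preset == "two_state") {
    return(kinetic_scheme(
      states = c("C", "O"), classes = c("closed", "open"),
      transitions = tibble::tribble(
        ~from, ~to, ~base_rate, ~voltage_efold,
        "C", "O", 100, Inf,
        "O", "C", 100, Inf),
      name = "two_state"))
  }
  # linear C2 <-> C1 <-> O; voltage dependence on the C1<->O step
  p <- switch(preset,
    wt    = list(k21 = 31,  k12 = 3900, ko0 = 130, ve_o = 25,
                 kc0 = 3000, ve_c = -80),
    n999s = list(k21 = 93,  k12 = 3900, ko0 = 650, ve_o = 25,
                 kc0 = 3000, ve_c = -80),
    e656a = list(k21 = 31,  k12 = 3900, ko0 = 260, ve_o = 25,
                 kc0 = 900,  ve_c = -80))
  kinetic_scheme(
    states = c("C2", "C1", "O"),
    classes = c("closed", "closed", "open"),
    transitions = tibble::tribble(
      ~from, ~to, ~base_rate, ~voltage_efold,
      "C2", "C1", p$k21, Inf,
      "C1", "C2", p$k12, Inf,
      "C1", "O",  p$ko0, p$ve_o,
      "O",  "C1", p$kc0, p$ve_c),
    name = preset)
}
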