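# shared fixtures: tiny schemes, fast acquisition settings, hand-built paths

two_state <- function(k_co = 100, k_oc = 100) {
  kinetic_scheme(
    states = c("C", "O"), classes = c("closed", "open"),
    transitions = tibble::tribble(
      ~from, ~to, ~base_rate, ~voltage_efold,
      "C", "O", k_co, Inf,
      "O", "C", k_oc, Inf),
    name = "two_state_test")
}

c2c1o <- function(k21 = 500, k12 = 1500, ko = 500, kc = 800) {
  kinetic_scheme(
    states = c("C2", "C1", "O"),
    classes = c("closed", "closed", "open"),
    transitions = tibble::tribble(
      ~from, ~to, ~base_rate, ~voltage_efold,
      "C2", "C1", k21, Inf,
      "C1", "C2", k12, Inf,
      "C1", "O",  ko,  Inf,
      "O",  "C1", kc,  Inf),
    name = "c2c1o_test")
}

# small/fast acquisition settings for unit tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(sampling_rate = 20000, filter_cutoff = 4000, sweep_duration = 0.5,
         protocol_voltages = seq(-40, 160, by = 40), noise_sd = 0.8,
         seed = 42L),
    list(...))
  do.call(acquisition_config, args)
}

# a state_path built by hand from (state, class, duration) vectors
manual_path <- function(states, classes, durations, voltage = 120) {
  p <- tibble::tibble(
    state = states, class = classes,
    start = cumsum(c(0, durations[-length(durations)])),
    duration = durations)
  structure(p, total_duration = sum(durations), voltage = voltage,
            class = c("state_path", class(p)))
}

# open-time fraction of a path: single-channel ground-truth NPo
path_open_fraction <- function(p) {
  sum(p$duration[p$class == "open"]) / attr(p, "total_duration")
}

# an event_list built by hand from (level, duration)
manual_events <- function(levels, durations, dead_time = 0) {
  ev <- tibble::tibble(
    level = as.integer(levels),
    start = cumsum(c(0, durations[-length(durations)])),
    duration = durations)
  structure(ev, sweep_duration = sum(durations), dead_time = dead_time,
            class = c("event_list", class(ev)))
}
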