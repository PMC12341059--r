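test_that("mean sojourn time is the reciprocal of the summed outgoing rates", {
  expect_equal(mean_dwell(two_state(100, 100), "O", 0), 0.010)
  expect_equal(mean_dwell(c2c1o(k12 = 500, ko = 1500), "C1", 0), 1 / 2000)
  # voltage-dependent rates: mean open dwell shrinks with depolarisation for
  # the WT preset (its O->C1 rate falls with V, so dwell lengthens instead)
  wt <- scheme_preset("wt")
  expect_gt(mean_dwell(wt, "O", 140), mean_dwell(wt, "O", 60))
})

test_that("absorbing states are rejected as invalid schemes", {
  bad <- structure(
    list(states = c("C", "O"),
         classes = c(C = "closed", O = "open"),
         transitions = tibble::tibble(from = "C", to = "O",
                                      base_rate = 10, voltage_efold = Inf),
         name = "absorbing"),
    class = "kinetic_scheme")
  expect_error(mean_dwell(bad, "O", 0), "absorbing")
  expect_error(sample_path(bad, 0, 1), "absorbing")
})

test_that("analytic mean dwell matches Monte-Carlo sojourn means", {
  wt <- scheme_preset("wt")
  p <- sample_path(wt, 120, 60, seed = 101)
  open <- p$duration[p$state == "O"][-1]            # drop possible edge
  expect_gt(length(open), 1000)
  mc <- mean(open)
  se <- stats::sd(open) / sqrt(length(open))
  truth <- mean_dwell(wt, "O", 120)
  expect_lt(abs(mc - truth), 3 * se + 0.02 * truth)
})

test_that("stationary open probability solves the generator", {
  expect_equal(stationary_po(two_state(100, 100), 50), 0.5)
  expect_equal(stationary_po(two_state(300, 100), -20), 0.75)
  # detailed-balance closed form for the linear C2-C1-O chain
  s <- c2c1o(k21 = 500, k12 = 1500, ko = 500, kc = 800)
  pi_c1 <- 500 / 1500
  pi_o <- pi_c1 * 500 / 800
  expect_equal(stationary_po(s, 0), pi_o / (1 + pi_c1 + pi_o))
})

test_that("long-run simulated open fraction agrees with stationary_po", {
  wt <- scheme_preset("wt")
  fr <- vapply(1:6, function(s)
    path_open_fraction(sample_path(wt, 140, 40, seed = 200 + s)), numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - stationary_po(wt, 140)), 3 * se)
})

test_that("sojourn-time law holds across states of a branching scheme", {
  s <- c2c1o()
  p <- sample_path(s, 0, 30, seed = 7)
  for (st in c("C1", "O")) {
    d <- p$duration[p$state == st]
    d <- d[-length(d)]
    expect_gt(length(d), 1000)
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - mean_dwell(s, st, 0)), 3 * se)
  }
})

test_that("sample_path is reproducible per seed and respects duration", {
  s <- two_state()
  p1 <- sample_path(s, 0, 2, seed = 9)
  p2 <- sample_path(s, 0, 2, seed = 9)
  expect_identical(p1, p2)
  expect_equal(sum(p1$duration), 2, tolerance = 1e-12)
  expect_true(all(p1$duration > 0))
  expect_true(all(p1$state[-1] != p1$state[-nrow(p1)]))
})

test_that("vanishing opening rate leaves a single closed segment", {
  s <- two_state(k_co = 1e-9, k_oc = 100)
  p <- sample_path(s, 0, 15, seed = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$class, "closed")
  expect_equal(p$duration, 15)
})

test_that("rendered unitary amplitude follows gamma * (V - Vrev)", {
  expect_equal(unitary_current_pa(165, 120, 0), 19.8)
  expect_equal(unitary_current_pa(165, -40, 0), -6.6)
  cfg <- acquisition_config(sampling_rate = 20000, filter_cutoff = Inf,
                            sweep_duration = 0.05, noise_sd = 0,
                            unitary_conductance = 165)
  open_path <- manual_path("O", "open", 0.05)
  sw <- render_sweep(open_path, 120, cfg)
  expect_true(all(sw$current == 19.8))
  closed_path <- manual_path("C", "closed", 0.05)
  expect_true(all(render_sweep(closed_path, 120, cfg)$current == 0))
})

test_that("render_sweep rejects paths whose duration mismatches the config", {
  cfg <- acquisition_config(sampling_rate = 20000, filter_cutoff = Inf,
                            sweep_duration = 0.05, noise_sd = 0)
  expect_error(render_sweep(manual_path("O", "open", 0.2), 120, cfg),
               "duration")
})

test_that("default protocol produces 11 sweeps from -40 to +160 mV", {
  cfg <- acquisition_config(sweep_duration = 0.01, noise_sd = 0,
                            filter_cutoff = Inf)
  rec <- simulate_recording(two_state(), cfg)
  expect_length(rec$sweeps, 11)
  expect_equal(vapply(rec$sweeps, `[[`, numeric(1), "voltage"),
               seq(-40, 160, by = 20), ignore_attr = TRUE)
})

test_that("recordings are bit-identical for identical scheme/config/seed", {
  cfg <- quick_config(sweep_duration = 0.2)
  r1 <- simulate_recording(scheme_preset("wt"), cfg)
  r2 <- simulate_recording(scheme_preset("wt"), cfg)
  expect_identical(r1, r2)
})

test_that("paxilline block pins every channel closed at every voltage", {
  cfg <- quick_config(paxilline_block = TRUE, n_channels = 3)
  rec <- simulate_recording(scheme_preset("wt"), cfg)
  for (sw in rec$sweeps) {
    expect_true(all(vapply(sw$truth, function(p) all(p$class == "closed"),
                           logical(1))))
  }
})

test_that("WT-like preset activates only above +80 mV", {
  wt <- scheme_preset("wt")
  expect_lt(stationary_po(wt, 60), 0.01)
  expect_gt(stationary_po(wt, 140), 0.1)
  # NPo-V from ground-truth paths, averaged over seeds, is ~0 at <= +60 mV
  # and clearly positive above +80 mV
  volts <- seq(-40, 160, by = 20)
  mean_npo <- vapply(volts, function(v) {
    mean(vapply(1:20, function(s)
      path_open_fraction(sample_path(wt, v, 3, seed = 1000 + 31 * s + v)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(mean_npo[volts <= 60] < 0.02))
  expect_true(all(mean_npo[volts >= 100] > 0.05))
  # monotone non-decreasing activation within Monte-Carlo slack
  expect_true(all(diff(mean_npo) > -0.01))
})

test_that("gain-of-function presets shift gating the expected way", {
  wt <- scheme_preset("wt"); gof <- scheme_preset("n999s")
  e656a <- scheme_preset("e656a")
  for (v in c(60, 100, 140)) {
    expect_gt(stationary_po(gof, v), stationary_po(wt, v))
    expect_gt(stationary_po(e656a, v), stationary_po(wt, v))
  }
  # N999S-like acts through shortened closed sojourns, E656A-like through
  # lengthened open sojourns
  expect_lt(mean_dwell(gof, "C1", 120), mean_dwell(wt, "C1", 120))
  expect_gt(mean_dwell(e656a, "O", 120), mean_dwell(wt, "O", 120))
})
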