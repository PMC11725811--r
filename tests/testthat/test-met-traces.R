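test_that("cycle averaging folds periodic traces and suppresses noise", {
  drv <- manual_driver(n_pre = 500, cycles = 10, period = 1000)
  # constant current: flat averaged cycle at that value
  tr <- manual_trace(rep(-42, length(drv)), drv, stim_on = 501)
  cyc <- cycle_average(tr)
  expect_equal(cyc$period, 1000)
  expect_equal(cyc$n_cycles, 10)
  expect_true(all(cyc$current == -42))

  # identical cycles + zero-mean noise: residual SD shrinks by ~sqrt(10)
  set.seed(7)
  clean <- -100 + 50 * sin(2 * pi * seq_len(10000) / 1000)
  noisy <- c(rep(-100, 500), clean) +
    c(rep(0, 500), rnorm(10000, 0, 5))
  tr2 <- manual_trace(noisy, drv, stim_on = 501)
  cyc2 <- cycle_average(tr2)
  resid_sd <- sd(cyc2$current - clean[1:1000])
  expect_equal(resid_sd, 5 / sqrt(10), tolerance = 0.15)

  # noise-free generator trace with instantaneous mechanics (no onset
  # transient): averaged cycle equals any single cycle
  st <- simulate_met_traces(fix_channel(noise_sd = 0),
                            fix_jet(c_drag = 0, tau_jet = 0),
                            fix_protocol_hold(), seed = 1)
  tr3 <- st$traces[[1]]
  cyc3 <- cycle_average(tr3)
  one <- tr3$samples[tr3$stim_on + cyc3$period + seq_len(cyc3$period) - 1]
  expect_equal(cyc3$current, one, tolerance = 1e-10)
})

test_that("aperiodic drivers are rejected with a pointer to step mode", {
  drv <- c(rep(0, 100), rep(1, 2000))
  tr <- manual_trace(rnorm(2100), drv, stim_on = 101)
  expect_error(cycle_average(tr), "step-mode")
})

test_that("peak-to-peak current recovers the generator ground truth", {
  ch <- fix_channel(noise_sd = 0)
  st <- simulate_met_traces(ch, fix_jet(), fix_protocol_hold(v = -124),
                            seed = 1)
  pp <- peak_to_peak_current(st$traces[[1]])
  expect_equal(pp$i_max, st$truth$i_max_pp[1], tolerance = 1 / 1000)
  expect_lt(pp$i_max, 0)  # inward at -124 mV

  # no channels: i_max indistinguishable from noise
  st0 <- simulate_met_traces(fix_channel(n_channels = 0, noise_sd = 5),
                             fix_jet(), fix_protocol_hold(), seed = 2)
  pp0 <- peak_to_peak_current(st0$traces[[1]])
  expect_lt(abs(pp0$i_max), 3 * 5 / sqrt(pp0$n_cycles) * 3)

  # at the reversal potential the peak-to-peak current vanishes
  ste <- simulate_met_traces(fix_channel(noise_sd = 0), fix_jet(),
                             fix_protocol_hold(v = 0), seed = 3)
  expect_lt(abs(peak_to_peak_current(ste$traces[[1]])$i_max), 1e-9)
})

test_that("i_max is invariant to a constant leak offset", {
  st <- simulate_met_traces(fix_channel(), fix_jet(), fix_protocol_hold(),
                            seed = 4)
  tr <- st$traces[[1]]
  shifted <- tr
  shifted$samples <- tr$samples + 500
  expect_equal(peak_to_peak_current(shifted)$i_max,
               peak_to_peak_current(tr)$i_max, tolerance = 1e-12)
})

test_that("resting open probability spans its trivial anchors", {
  # channels fully shut at rest: p_rest tiny -> ~0
  st0 <- simulate_met_traces(fix_channel(p_rest = 1e-4, adapt_gain = 0,
                                         noise_sd = 0),
                             fix_jet(), fix_protocol_hold(), seed = 1)
  expect_equal(resting_open_probability(st0$traces[[1]])$p_open, 0,
               tolerance = 1e-3)
  # channels fully open at rest
  st1 <- simulate_met_traces(fix_channel(p_rest = 1 - 1e-4, adapt_gain = 0,
                                         noise_sd = 0),
                             fix_jet(), fix_protocol_hold(), seed = 1)
  expect_equal(resting_open_probability(st1$traces[[1]])$p_open, 1,
               tolerance = 1e-3)
  # intermediate value, noise-free
  st5 <- simulate_met_traces(fix_channel(p_rest = 0.5, adapt_gain = 0,
                                         noise_sd = 0),
                             fix_jet(), fix_protocol_hold(), seed = 1)
  expect_equal(resting_open_probability(st5$traces[[1]])$p_open, 0.5,
               tolerance = 0.01)
})

test_that("P_open recovery holds across p_rest and buffers at default noise", {
  for (p in c(0.05, 0.3)) for (buf in c("EGTA_1mM", "BAPTA_5mM")) {
    errs <- vapply(1:5, function(s) {
      st <- simulate_met_traces(fix_channel(p_rest = p), fix_jet(),
                                fix_protocol_hold(buffer = buf), seed = s)
      est <- resting_open_probability(st$traces[[1]])
      expect_true(est$reliable)
      abs(est$p_open - st$truth$p_open_rest[1])
    }, numeric(1))
    expect_lt(median(errs), 0.02)
    expect_lt(max(errs), 0.05)
  }
})

test_that("P_open without a MET current is flagged unreliable", {
  st <- simulate_met_traces(fix_channel(n_channels = 0, noise_sd = 5),
                            fix_jet(), fix_protocol_hold(), seed = 6)
  expect_false(resting_open_probability(st$traces[[1]])$reliable)
})

test_that("an ohmic trace set gives a linear I-V with exact reversal", {
  e_rev <- 10
  drv <- manual_driver(n_pre = 200, cycles = 4, period = 500)
  p_t <- 0.5 + 0.4 * ifelse(drv > 0, 1, ifelse(drv < 0, -1, 0))
  traces <- lapply(c(-44, -24, -4, 16, 36), function(v)
    manual_trace(8 * (v - e_rev) * p_t * 1e-1, drv, v_m = v, stim_on = 201))
  iv <- build_iv_and_reversal(traces)
  expect_equal(iv$reversal_mV, e_rev, tolerance = 1e-9)
  # linearity: second differences of the I-V points vanish
  expect_lt(max(abs(diff(iv$points$i_max_pp_pA, differences = 2))), 1e-9)
})

test_that("a single-voltage series reports the reversal absent", {
  st <- simulate_met_traces(fix_channel(), fix_jet(), fix_protocol_hold(),
                            seed = 7)
  expect_warning(iv <- build_iv_and_reversal(st), "absent")
  expect_true(is.na(iv$reversal_mV))
})

test_that("reversal interpolation matches a dense-grid zero search", {
  st <- simulate_met_traces(fix_channel(), fix_jet(), trace_protocol(),
                            seed = 8)
  iv <- build_iv_and_reversal(st)
  grid <- seq(min(iv$points$v_mV), max(iv$points$v_mV), by = 0.01)
  ig <- approx(iv$points$v_mV, iv$points$i_max_pp_pA, xout = grid)$y
  brute <- grid[which.min(abs(ig))]
  expect_equal(iv$reversal_mV, brute, tolerance = 0.011)
})

test_that("saturation detection follows the 5% increment rule", {
  ch <- fix_channel(p_rest = 0.1, noise_sd = 0)
  jet <- fix_jet()
  mk <- function(amp) simulate_met_traces(
    ch, jet, fix_protocol_hold(
      waveform = list(type = "sinusoid", frequency = 50, amplitude = amp,
                      cycles = 10)), seed = 1)$traces[[1]]
  # amplitudes far past x_half + 5 lambda: saturated
  big <- detect_saturation(list(mk(0.02), mk(0.03)), c(0.02, 0.03))
  expect_true(big$saturated)
  # small amplitudes on the rising phase: not saturated
  small <- detect_saturation(list(mk(0.001), mk(0.002)), c(0.001, 0.002))
  expect_false(small$saturated)
  # identical repeated amplitude: saturated by the rule
  same <- detect_saturation(list(mk(0.004), mk(0.004)), c(0.004, 0.004))
  expect_true(same$saturated)
  expect_error(detect_saturation(list(mk(0.004), mk(0.003)),
                                 c(0.004, 0.003)), "non-decreasing")
})

test_that("trace-set summaries carry one row per voltage", {
  st <- simulate_met_traces(fix_channel(), fix_jet(),
                            fix_protocol_hold(v = c(-124, -84, 96)),
                            seed = 9)
  s <- summarize_met_traces(st)
  expect_equal(nrow(s), 3)
  expect_equal(s$v_mV, c(-124, -84, 96))
  expect_true(all(s$reliable))
})
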