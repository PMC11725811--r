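# Shared fixtures: small, fast model configurations used across tests.

fix_channel <- function(...) channel_model(...)

fix_jet <- function(...) fluid_jet_model(...)

# Single-voltage protocol at the holding potential (fast).
fix_protocol_hold <- function(v = -84, buffer = "EGTA_1mM", ...) {
  trace_protocol(voltage_steps = v, buffer_label = buffer, ...)
}

# Noise-free Gaussian line profile sampled on a pixel grid.
gauss_profile <- function(center_nm, sigma_nm = 150, n_px = 96, px = 50,
                          amplitude = 1, background = 0.1) {
  xpos <- (seq_len(n_px) - 0.5) * px
  list(positions = xpos,
       values = background + amplitude *
         exp(-(xpos - center_nm)^2 / (2 * sigma_nm^2)))
}

# A small movie with one force step (20%-70% of the duration), for
# tracking tests.
fix_movie <- function(k_true = 3, force_nN = 0.3, n_frames = 200,
                      photon_scale = 2000, seed = 1) {
  t_ms <- n_frames / 5000 * 1e3
  simulate_bundle_movie(
    movie_spec(n_frames = n_frames, photon_scale = photon_scale),
    fluid_jet_model(k_true = k_true),
    list(list(amplitude = force_nN, onset = 0.2 * t_ms,
              duration = 0.5 * t_ms)),
    seed = seed)
}

# Build a CurrentTrace by hand (for analysis-only tests).
manual_trace <- function(samples, driver, sample_rate = 50000, v_m = -84,
                         stim_on = NULL, buffer = "EGTA_1mM") {
  structure(list(samples = samples, driver = driver,
                 sample_rate = sample_rate, v_m = v_m,
                 buffer_label = buffer, stim_on = stim_on, meta = list()),
            class = "CurrentTrace")
}

# Sinusoidal driver with a stimulus-off baseline.
manual_driver <- function(n_pre = 500, cycles = 10, period = 1000,
                          amplitude = 1) {
  n <- cycles * period
  c(rep(0, n_pre), amplitude * sin(2 * pi * seq_len(n) / period))
}
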