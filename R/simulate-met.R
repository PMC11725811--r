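# First-order low-pass via the exact discrete update
# y[i] = y[i-1] + (1 - exp(-dt/tau)) * (x[i] - y[i-1]).
lowpass1 <- function(x, dt, tau_s) {
  if (tau_s <= 0) return(x)
  a <- 1 - exp(-dt / tau_s)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive"))
}

# Overdamped spring c dx/dt = F - k x driven by force_nN, returns nm.
# k in mN/m (= pN/nm), c_drag in uN s/m, dt in s.
spring_response <- function(force_nN, dt, k, c_drag) {
  x_ss <- 1000 * force_nN / k        # nm
  tau_s <- 1e-3 * c_drag / k
  if (tau_s <= 0) return(x_ss)
  lowpass1(x_ss, dt, tau_s)
}

# Driver-voltage waveform with stimulus-off padding; returns list(driver,
# stim_on) with stim_on the first in-stimulus sample index.
build_driver <- function(protocol) {
  sr <- protocol$sample_rate
  n_pre <- round(protocol$pre_ms * 1e-3 * sr)
  n_post <- round(protocol$post_ms * 1e-3 * sr)
  wf <- protocol$waveform
  if (wf$type == "sinusoid") {
    n_stim <- round(wf$cycles / wf$frequency * sr)
    t_stim <- (seq_len(n_stim) - 1) / sr
    stim <- wf$amplitude * sin(2 * pi * wf$frequency * t_stim)
  } else {
    n_stim <- round(wf$duration_ms * 1e-3 * sr)
    stim <- rep(wf$amplitude, n_stim)
  }
  list(driver = c(rep(0, n_pre), stim, rep(0, n_post)), stim_on = n_pre + 1)
}

# Adaptation set-point shift (nm) at membrane potential v_mV.
adapt_shift <- function(channel, v_mV, buffer_label) {
  if (identical(buffer_label, "BAPTA_5mM")) return(0)
  channel$adapt_gain * max(0, channel$e_rev_ca - v_mV)
}

#' Simulate MET current traces across a membrane-potential series
#'
#' Generates one stimulus-annotated current trace per voltage step. The
#' driver voltage is low-passed through the fluid jet, converted to force,
#' and applied to the overdamped bundle spring; the resulting displacement
#' gates the Boltzmann channel population, giving
#' `I(t) = n_channels * g_single * (V - e_rev) * P_open(x(t)) / 1000 +
#' i_leak + noise` in pA (pS times mV gives fA, hence the factor). Inward
#' current at hyperpolarized potentials is negative; positive driver voltage
#' (excitatory deflection, toward the tallest stereocilia row) is positive
#' displacement.
#'
#' @param channel A [channel_model()].
#' @param jet A [fluid_jet_model()].
#' @param protocol A [trace_protocol()].
#' @param seed Integer seed; all randomness is local to this call.
#'
#' @return A `CurrentTraceSet`: list with `traces` (one `CurrentTrace` per
#'   voltage: `samples` pA, `driver` V, `sample_rate`, `v_m`, `buffer_label`,
#'   `stim_on`) and `truth`, a data frame of the per-voltage ground truth
#'   (`p_open_rest`, peak-to-peak transduction current `i_max_pp`, signed).
#' @export
simulate_met_traces <- function(channel, jet, protocol, seed = 1) {
  stopifnot(inherits(channel, "ChannelModel"), inherits(jet, "FluidJetModel"),
            inherits(protocol, "TraceProtocol"))
  dv <- build_driver(protocol)
  dt <- 1 / protocol$sample_rate
  force <- jet$dv_gain * lowpass1(dv$driver, dt, jet$tau_jet * 1e-3)  # nN
  x <- spring_response(force, dt, jet$k_true, jet$c_drag)             # nm
  gmax_nS <- channel$n_channels * channel$g_single * 1e-3             # nS

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  traces <- list()
  truth <- data.frame(v_mV = protocol$voltage_steps, p_open_rest = NA_real_,
                      i_max_pp = NA_real_)
  for (i in seq_along(protocol$voltage_steps)) {
    v <- protocol$voltage_steps[i]
    shift <- adapt_shift(channel, v, protocol$buffer_label)
    p <- stats::plogis((x - channel$x_half - shift) / channel$lambda_slope)
    i_clean <- gmax_nS * (v - channel$e_rev) * p + channel$i_leak
    noise <- if (channel$noise_sd > 0)
      stats::rnorm(length(i_clean), 0, channel$noise_sd) else 0
    truth$p_open_rest[i] <-
      stats::plogis(-(channel$x_half + shift) / channel$lambda_slope)
    truth$i_max_pp[i] <- gmax_nS * (v - channel$e_rev) * (max(p) - min(p))
    traces[[i]] <- structure(
      list(samples = i_clean + noise, driver = dv$driver,
           sample_rate = protocol$sample_rate, v_m = v,
           buffer_label = protocol$buffer_label, stim_on = dv$stim_on,
           meta = list()),
      class = "CurrentTrace")
  }
  structure(list(traces = traces, truth = truth, protocol = protocol,
                 displacement_nm = x),
            class = "CurrentTraceSet")
}

# Save/restore the global RNG state so simulators with an explicit seed do
# not perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
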