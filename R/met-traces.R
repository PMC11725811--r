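# Index range of the stimulus-off baseline at the start of a trace.
# Uses the annotated pre-stimulus interval when present, else the first
# 10 ms.
baseline_window <- function(trace) {
  n <- length(trace$samples)
  if (!is.null(trace$stim_on) && trace$stim_on > 1)
    return(seq_len(min(trace$stim_on - 1, n)))
  seq_len(max(1, min(n, round(0.01 * trace$sample_rate))))
}

# Stimulus-on portion of the driver: from the annotated onset (or the first
# sample above 1% of the driver maximum) to the last sample above threshold.
stimulus_window <- function(trace) {
  thr <- 0.01 * max(abs(trace$driver))
  idx <- which(abs(trace$driver) > thr)
  if (!length(idx)) return(integer(0))
  start <- if (!is.null(trace$stim_on) && trace$stim_on <= idx[length(idx)])
    trace$stim_on else idx[1]
  seq(start, idx[length(idx)])
}

#' Average a periodic trace over stimulus cycles
#'
#' Detects the driver period from its autocorrelation over the stimulus-on
#' window and folds the current into one mean cycle, reducing independent
#' noise by about the square root of the number of cycles.
#'
#' @param trace A `CurrentTrace`.
#' @return List with `current` and `driver` (one averaged cycle each),
#'   `period` (samples), `n_cycles`, and `sample_rate`.
#' @export
cycle_average <- function(trace) {
  win <- stimulus_window(trace)
  if (length(win) < 8)
    stop("driver carries no stimulus; nothing to cycle-average")
  drv <- trace$driver[win]
  cur <- trace$samples[win]
  n <- length(drv)
  ac <- stats::acf(drv, lag.max = floor(n / 2), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  ac[!is.finite(ac)] <- 0   # constant driver yields NaN autocorrelations
  # first local maximum of the autocorrelation after lag 0, refined to the
  # best lag in its neighbourhood
  lag <- NA_integer_
  for (k in 3:(length(ac) - 1)) {
    if (ac[k] >= ac[k - 1] && ac[k] > ac[k + 1] && ac[k] > 0.5) {
      nb <- max(2, k - 5):min(length(ac), k + 5)
      lag <- nb[which.max(ac[nb])] - 1
      break
    }
  }
  if (is.na(lag) || n < 2 * lag)
    stop("aperiodic driver: fewer than 2 cycles detected; ",
         "use step-mode analysis instead")
  p <- lag
  # threshold trimming can shave a few end samples off the last cycle, so
  # round (not floor) the cycle count when the full trace can supply it
  n_cycles <- round(n / p)
  if (win[1] + n_cycles * p - 1 > length(trace$samples) || n_cycles < 1)
    n_cycles <- floor(n / p)
  m <- n_cycles * p
  full <- seq(win[1], win[1] + m - 1)
  list(current = rowMeans(matrix(trace$samples[full], nrow = p)),
       driver = rowMeans(matrix(trace$driver[full], nrow = p)),
       period = p, n_cycles = n_cycles, sample_rate = trace$sample_rate)
}

#' Peak-to-peak MET current of a trace
#'
#' For sinusoidal stimuli the trace is cycle-averaged first; the excitatory
#' and inhibitory half-phases are defined by the sign of the driver voltage
#' (positive DV is excitatory; samples at DV = 0 belong to neither phase).
#' `i_exc` and `i_inhib` are the extrema of the averaged cycle in their
#' respective phases, paired in the orientation that maximizes the
#' peak-to-peak magnitude, and `i_max = i_exc - i_inhib` (signed: negative
#' below the reversal potential, where transduction current is inward). For
#' step stimuli the plateau means of the positive/negative driver phases are
#' used.
#'
#' @param trace A `CurrentTrace`.
#' @param mode `"auto"` (sinusoid if cycle detection succeeds), `"sinusoid"`
#'   or `"step"`.
#' @return List with `i_exc`, `i_inhib`, `i_max` (signed, pA),
#'   `i_max_magnitude`, and `n_cycles` (NA in step mode).
#' @export
peak_to_peak_current <- function(trace, mode = c("auto", "sinusoid", "step")) {
  mode <- match.arg(mode)
  if (mode != "step") {
    cyc <- if (mode == "sinusoid") cycle_average(trace)
           else tryCatch(cycle_average(trace), error = function(e) NULL)
    if (!is.null(cyc)) {
      exc <- cyc$driver > 0
      inh <- cyc$driver < 0
      if (!any(exc) || !any(inh))
        stop("driver lacks an excitatory or inhibitory phase")
      # orientation that maximizes |i_exc - i_inhib|
      d1 <- max(cyc$current[exc]) - min(cyc$current[inh])
      d2 <- min(cyc$current[exc]) - max(cyc$current[inh])
      if (abs(d1) >= abs(d2)) {
        i_exc <- max(cyc$current[exc]); i_inhib <- min(cyc$current[inh])
      } else {
        i_exc <- min(cyc$current[exc]); i_inhib <- max(cyc$current[inh])
      }
      return(list(i_exc = i_exc, i_inhib = i_inhib, i_max = i_exc - i_inhib,
                  i_max_magnitude = abs(i_exc - i_inhib),
                  n_cycles = cyc$n_cycles))
    }
    mode <- "step"
  }
  win <- stimulus_window(trace)
  if (!length(win)) stop("driver carries no stimulus")
  drv <- trace$driver[win]; cur <- trace$samples[win]
  plateau_mean <- function(sel) {
    idx <- which(sel)
    if (!length(idx)) return(NA_real_)
    tail_idx <- idx[idx >= idx[1] + floor(0.8 * length(idx))]
    mean(cur[if (length(tail_idx)) tail_idx else idx])
  }
  i_exc <- plateau_mean(drv > 0.5 * max(drv, 0))
  i_inhib <- plateau_mean(drv < 0.5 * min(drv, 0))
  if (is.na(i_inhib)) i_inhib <- mean(trace$samples[baseline_window(trace)])
  list(i_exc = i_exc, i_inhib = i_inhib, i_max = i_exc - i_inhib,
       i_max_magnitude = abs(i_exc - i_inhib), n_cycles = NA_integer_)
}

#' Resting open probability of the MET current
#'
#' The fraction of the maximal MET current flowing with the bundle at rest:
#' the holding current (mean over the stimulus-off baseline) minus the
#' current during maximal inhibitory deflection, divided by the maximal
#' (peak-to-peak) MET current. The raw value is returned unclamped; a
#' quality flag marks values outside `[-0.05, 1.05]`, and the estimate is
#' flagged unreliable when the peak-to-peak current is smaller than
#' `reliability_factor` times the baseline noise SD (no MET current, no
#' meaningful open probability).
#'
#' @param trace A `CurrentTrace`.
#' @param mode Passed to [peak_to_peak_current()].
#' @param reliability_factor Multiple of the baseline noise SD below which
#'   `|i_max|` renders the estimate unreliable (default 5).
#' @return List with `p_open` (fraction), `i_hold`, `i_exc`, `i_inhib`,
#'   `i_max` (pA), `reliable` and `in_range` flags.
#' @export
resting_open_probability <- function(trace, mode = "auto",
                                     reliability_factor = 5) {
  base <- baseline_window(trace)
  i_hold <- mean(trace$samples[base])
  noise_sd <- stats::sd(trace$samples[base])
  pp <- peak_to_peak_current(trace, mode = mode)
  p <- (i_hold - pp$i_inhib) / pp$i_max
  reliable <- is.na(noise_sd) || noise_sd == 0 ||
    abs(pp$i_max) >= reliability_factor * noise_sd
  list(p_open = p, i_hold = i_hold, i_exc = pp$i_exc, i_inhib = pp$i_inhib,
       i_max = pp$i_max, reliable = reliable,
       in_range = is.finite(p) && p >= -0.05 && p <= 1.05)
}

#' Peak-to-peak current-voltage curve and reversal potential
#'
#' Computes the signed peak-to-peak MET current at each membrane potential
#' and interpolates the reversal potential linearly between the two voltages
#' bracketing the zero crossing. With no sign change across the series the
#' reversal is reported absent (never extrapolated).
#'
#' @param set A `CurrentTraceSet` (or plain list of `CurrentTrace`).
#' @param mode Passed to [peak_to_peak_current()].
#' @return An `IVCurve`: list with `points` (data frame `v_mV`,
#'   `i_max_pp_pA`) ordered by voltage, and `reversal_mV` (NA if absent).
#' @export
build_iv_and_reversal <- function(set, mode = "auto") {
  traces <- if (inherits(set, "CurrentTraceSet")) set$traces else set
  stopifnot(length(traces) >= 1)
  v <- vapply(traces, function(tr) tr$v_m, numeric(1))
  i <- vapply(traces, function(tr) peak_to_peak_current(tr, mode)$i_max,
              numeric(1))
  o <- order(v)
  v <- v[o]; i <- i[o]
  if (anyDuplicated(v)) stop("duplicate membrane potentials in the series")
  rev_mV <- NA_real_
  if (length(v) >= 2) {
    sgn <- sign(i)
    cross <- which(sgn[-length(sgn)] * sgn[-1] <= 0 &
                     !(sgn[-length(sgn)] == 0 & sgn[-1] == 0))
    if (length(cross)) {
      j <- cross[1]
      rev_mV <- if (i[j + 1] == i[j]) mean(v[c(j, j + 1)]) else
        v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
    }
  }
  if (is.na(rev_mV))
    warning("no sign change in the I-V curve: reversal potential absent")
  structure(list(points = data.frame(v_mV = v, i_max_pp_pA = i),
                 reversal_mV = rev_mV),
            class = "IVCurve")
}

#' Detect saturation of the MET current across a stimulus-amplitude series
#'
#' For recordings in which the stimulus is gradually increased until the
#' maximal current is achieved: the series is saturated when the final
#' amplitude increment raises the peak-to-peak current magnitude by less
#' than `tol` (default 5%).
#'
#' @param traces List of `CurrentTrace` at increasing stimulus amplitude.
#' @param amplitudes Stimulus amplitudes matching `traces`
#'   (non-decreasing, else an error).
#' @param tol Relative increment below which the response is saturated.
#' @param mode Passed to [peak_to_peak_current()].
#' @return List with `saturated` flag, `i_max_final` (signed peak-to-peak
#'   of the largest amplitude, pA), and `i_max_series`.
#' @export
detect_saturation <- function(traces, amplitudes, tol = 0.05, mode = "auto") {
  stopifnot(length(traces) >= 2, length(amplitudes) == length(traces))
  if (any(diff(amplitudes) < 0))
    stop("stimulus amplitudes must be non-decreasing")
  i_mag <- vapply(traces, function(tr)
    peak_to_peak_current(tr, mode)$i_max_magnitude, numeric(1))
  n <- length(i_mag)
  rel <- (i_mag[n] - i_mag[n - 1]) / abs(i_mag[n - 1])
  list(saturated = is.finite(rel) && rel < tol,
       i_max_final = peak_to_peak_current(traces[[n]], mode)$i_max,
       i_max_series = i_mag)
}

#' Summarize a trace set into per-voltage MET statistics
#'
#' Convenience wrapper: peak-to-peak current and resting open probability
#' per trace, as one row per membrane potential.
#'
#' @param set A `CurrentTraceSet`.
#' @param mode Passed to the per-trace operations.
#' @return Data frame with columns `v_mV`, `i_hold_pA`, `i_exc_pA`,
#'   `i_inhib_pA`, `i_max_pA`, `p_open`, `reliable`, `in_range`, `buffer`.
#' @export
summarize_met_traces <- function(set, mode = "auto") {
  traces <- if (inherits(set, "CurrentTraceSet")) set$traces else set
  rows <- lapply(traces, function(tr) {
    r <- resting_open_probability(tr, mode = mode)
    data.frame(v_mV = tr$v_m, i_hold_pA = r$i_hold, i_exc_pA = r$i_exc,
               i_inhib_pA = r$i_inhib, i_max_pA = r$i_max, p_open = r$p_open,
               reliable = r$reliable, in_range = r$in_range,
               buffer = tr$buffer_label %||% NA_character_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
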