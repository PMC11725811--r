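#' Reslice a bundle movie into a space-time kymograph
#'
#' Row \eqn{f} of the kymograph is frame \eqn{f}'s intensity profile along
#' the measurement line (a frame row, optionally averaged over a band of
#' rows), oriented orthogonal to the bundle edge.
#'
#' @param movie A `BundleMovie`.
#' @param line Row index (1-based) of the measurement line, or an integer
#'   vector of rows to average.
#' @return A `Kymograph`: list with `image` (time x position matrix),
#'   `pixel_size` nm, `frame_rate` Hz, `stimulus` (per-frame force record).
#' @export
reslice_kymograph <- function(movie, line = NULL) {
  stopifnot(inherits(movie, "BundleMovie"))
  n_rows <- dim(movie$frames)[2]
  if (is.null(line)) line <- seq_len(n_rows)
  if (any(line < 1) || any(line > n_rows))
    stop("measurement line outside frame bounds")
  img <- if (length(line) == 1) movie$frames[, line, , drop = TRUE]
         else apply(movie$frames[, line, , drop = FALSE], c(1, 3), mean)
  if (is.null(dim(img))) img <- matrix(img, nrow = 1)  # one-frame movie
  structure(list(image = img, pixel_size = movie$pixel_size,
                 frame_rate = movie$frame_rate, stimulus = movie$stimulus),
            class = "Kymograph")
}

#' Min-max normalize an intensity profile
#'
#' Maps gray values affinely onto `[0, 1]`; invariant to camera gain and
#' offset. A constant profile has no contrast and is an error.
#'
#' @param values Raw gray values.
#' @param positions Sample positions (nm); defaults to the sample index.
#' @return An `IntensityProfile`: list with `positions` (nm) and `values`
#'   in `[0, 1]`.
#' @export
normalize_profile <- function(values, positions = seq_along(values)) {
  stopifnot(length(values) == length(positions))
  rng <- range(values)
  if (diff(rng) == 0) stop("no contrast: profile is constant")
  structure(list(positions = as.numeric(positions),
                 values = (values - rng[1]) / diff(rng)),
            class = "IntensityProfile")
}

#' Fit a Gaussian amplitude function to an intensity profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(p - center)^2 /
#' (2 sigma^2))` to the (normalized) profile, the standard sub-pixel bundle
#' localization step. Initialization: intensity-weighted centroid for the
#' centre, 2 pixels for sigma. The fit is flagged (not an error) when the
#' solver fails, the centre leaves the profile support, or sigma collapses
#' below half a pixel.
#'
#' @param profile An `IntensityProfile`, or raw numeric values (then
#'   normalized internally with positions from `positions`).
#' @param positions Positions (nm) when `profile` is a raw vector.
#' @param init Optional named list overriding starting values
#'   (`center`, `sigma`, `amplitude`, `offset`).
#' @return List with `center` nm, `sigma` nm, `amplitude`, `offset` (in
#'   normalized intensity units), and `fit_ok`.
#' @export
fit_gaussian_position <- function(profile, positions = NULL, init = NULL) {
  if (!inherits(profile, "IntensityProfile")) {
    if (is.null(positions)) positions <- seq_along(profile)
    profile <- normalize_profile(profile, positions)
  }
  p <- profile$positions
  v <- profile$values
  if (length(p) < 5) stop("profile too short to fit (need >= 5 samples)")
  px <- if (length(p) > 1) min(diff(sort(p))) else 1
  w <- v - min(v)
  start <- list(center = sum(p * w) / sum(w), sigma = 2 * px,
                amplitude = max(v) - min(v), offset = min(v))
  if (!is.null(init)) start[names(init)] <- init
  fail <- list(center = NA_real_, sigma = NA_real_, amplitude = NA_real_,
               offset = NA_real_, fit_ok = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ offset + amplitude * exp(-(p - center)^2 / (2 * sigma^2)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- as.list(stats::coef(fit))
  cf$sigma <- abs(cf$sigma)
  ok <- is.finite(cf$center) && cf$center >= min(p) && cf$center <= max(p) &&
    is.finite(cf$sigma) && cf$sigma >= 0.5 * px
  c(cf[c("center", "sigma", "amplitude", "offset")], list(fit_ok = ok))
}

#' Track bundle displacement across a kymograph
#'
#' Fits each kymograph row with [fit_gaussian_position()] (warm-started from
#' the previous frame) and reports positions relative to the mean
#' pre-stimulus centre, positive toward the excitatory direction. Frames
#' whose fit fails are flagged and excluded from the baseline; a trace with
#' more than 20% failed rows is flagged unusable.
#'
#' @param kymo A `Kymograph`.
#' @param max_fail_frac Failed-row fraction above which the trace is
#'   unusable.
#' @return A `DisplacementTrace`: data frame with `frame`, `t_s`, `x_nm`
#'   (relative to the pre-stimulus mean), `center_nm` (absolute),
#'   `fit_sigma_nm`, `amplitude`, `offset`, `fit_ok`; attributes `usable`
#'   (logical) and `baseline_nm`.
#' @export
track_displacement <- function(kymo, max_fail_frac = 0.2) {
  stopifnot(inherits(kymo, "Kymograph"))
  n <- nrow(kymo$image)
  pos <- (seq_len(ncol(kymo$image)) - 0.5) * kymo$pixel_size
  fits <- vector("list", n)
  prev <- NULL
  for (f in seq_len(n)) {
    row <- kymo$image[f, ]
    fits[[f]] <- if (diff(range(row)) == 0)
      list(center = NA_real_, sigma = NA_real_, amplitude = NA_real_,
           offset = NA_real_, fit_ok = FALSE)
    else fit_gaussian_position(row, positions = pos, init = prev)
    if (isTRUE(fits[[f]]$fit_ok))
      prev <- fits[[f]][c("center", "sigma", "amplitude", "offset")]
  }
  center <- vapply(fits, `[[`, numeric(1), "center")
  ok <- vapply(fits, `[[`, logical(1), "fit_ok")
  pre <- if (!is.null(kymo$stimulus) && any(kymo$stimulus != 0)) {
    seq_len(max(1, which(kymo$stimulus != 0)[1] - 1))
  } else seq_len(min(n, 10))
  baseline <- mean(center[pre][ok[pre]], na.rm = TRUE)
  out <- data.frame(frame = seq_len(n),
                    t_s = (seq_len(n) - 1) / kymo$frame_rate,
                    x_nm = center - baseline, center_nm = center,
                    fit_sigma_nm = vapply(fits, `[[`, numeric(1), "sigma"),
                    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
                    offset = vapply(fits, `[[`, numeric(1), "offset"),
                    fit_ok = ok)
  structure(out, usable = mean(!ok) <= max_fail_frac, baseline_nm = baseline,
            class = c("DisplacementTrace", "data.frame"))
}

#' Estimate steady-state bundle stiffness from a force step
#'
#' Apparent overall steady-state stiffness `k = F / x_steady`, with
#' `x_steady` the mean displacement over the final 20% of the step (the
#' settled plateau). With force in nN and displacement in nm the stiffness
#' comes out in mN/m via `k = 1000 * F / x`. The estimate is flagged when
#' the plateau displacement is indistinguishable from zero (below 3x the
#' pre-stimulus displacement SD).
#'
#' @param trace A `DisplacementTrace`.
#' @param stimulus Per-frame force record (nN) aligned to the trace, or a
#'   single step `list(amplitude = nN, onset = ms, duration = ms)`.
#' @param steady_frac Final fraction of the step used as the plateau.
#' @return A `StiffnessEstimate`: list with `force_nN`, `x_steady_nm`,
#'   `k_mN_per_m`, `window` (frames used), `quality` (plateau residual SD,
#'   nm) and `valid` flag.
#' @export
estimate_stiffness <- function(trace, stimulus, steady_frac = 0.2) {
  stopifnot(inherits(trace, "DisplacementTrace"))
  n <- nrow(trace)
  if (is.list(stimulus) && !is.null(stimulus$amplitude)) {
    fr <- attr(trace, "frame_rate")
    force <- steps_to_force(list(stimulus), n,
                            if (is.null(fr)) 1000 / (trace$t_s[2] * 1e3) else fr)
  } else {
    stopifnot(length(stimulus) == n)
    force <- as.numeric(stimulus)
  }
  f_step <- max(abs(force))
  if (f_step == 0) stop("zero-force stimulus: stiffness undefined")
  on <- which(abs(force) == f_step)
  # contiguous block of the (largest) step
  brk <- which(diff(on) > 1)
  if (length(brk)) on <- on[seq_len(brk[1])]
  window <- on[on >= on[1] + floor((1 - steady_frac) * length(on))]
  sel <- window[trace$fit_ok[window]]
  if (!length(sel)) stop("no usable frames in the steady-state window")
  x_steady <- mean(trace$x_nm[sel])
  pre <- which(force == 0 & seq_len(n) < on[1] & trace$fit_ok)
  pre_sd <- if (length(pre) >= 2) stats::sd(trace$x_nm[pre]) else NA_real_
  valid <- !is.finite(pre_sd) || pre_sd == 0 || abs(x_steady) >= 3 * pre_sd
  f_signed <- force[on[1]]
  structure(list(force_nN = f_signed, x_steady_nm = x_steady,
                 k_mN_per_m = if (valid) 1000 * f_signed / x_steady else NA_real_,
                 window = window, quality = stats::sd(trace$x_nm[sel]),
                 valid = valid),
            class = "StiffnessEstimate")
}

#' Track a movie and estimate bundle stiffness in one call
#'
#' Convenience wrapper: reslice along `line`, track, estimate stiffness from
#' the movie's stimulus record.
#'
#' @param movie A `BundleMovie`.
#' @param line Passed to [reslice_kymograph()].
#' @return List with `trace` and `stiffness`.
#' @export
bundle_stiffness_pipeline <- function(movie, line = 1) {
  kymo <- reslice_kymograph(movie, line)
  trace <- track_displacement(kymo)
  list(trace = trace, stiffness = estimate_stiffness(trace, kymo$stimulus))
}
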