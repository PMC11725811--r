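# Per-frame force (nN) from a list of rectangular steps.
steps_to_force <- function(force_steps, n_frames, frame_rate) {
  f <- rep(0, n_frames)
  t_ms <- (seq_len(n_frames) - 1) / frame_rate * 1e3
  for (s in force_steps) {
    stopifnot(all(c("amplitude", "onset", "duration") %in% names(s)))
    if (s$onset < 0 || s$onset + s$duration > t_ms[n_frames])
      stop("force step outside movie duration")
    on <- t_ms >= s$onset & t_ms < s$onset + s$duration
    f[on] <- f[on] + s$amplitude
  }
  f
}

#' Simulate a hair-bundle movie under fluid-jet force steps
#'
#' Each frame images the bundle edge as a Gaussian line profile,
#' `background + amplitude * exp(-(x - x_c(t))^2 / (2 edge_sigma^2))`,
#' replicated over the frame's rows with independent shot noise. The edge
#' centre `x_c(t)` follows the overdamped bundle spring driven by the
#' low-passed jet force, so the steady-state displacement of a step of force
#' `F` is `F / k_true` (100 nm for 0.3 nN at 3 mN/m).
#'
#' @param spec A [movie_spec()].
#' @param jet A [fluid_jet_model()]; `dv_gain` is unused here because steps
#'   are specified directly in force units.
#' @param force_steps List of steps `list(amplitude = nN, onset = ms,
#'   duration = ms)`; steps must lie inside the movie.
#' @param seed Integer seed.
#'
#' @return A `BundleMovie`: list with `frames` (array
#'   `[frame, row, column]`), `pixel_size` nm, `frame_rate` Hz, `stimulus`
#'   (per-frame force, nN) and `truth` (data frame `frame`, `t_s`, `x_nm`
#'   edge position, `displacement_nm` relative to rest).
#' @export
simulate_bundle_movie <- function(spec, jet, force_steps, seed = 1) {
  stopifnot(inherits(spec, "MovieSpec"), inherits(jet, "FluidJetModel"))
  force <- steps_to_force(force_steps, spec$n_frames, spec$frame_rate)
  dt <- 1 / spec$frame_rate
  force_lp <- lowpass1(force, dt, jet$tau_jet * 1e-3)
  disp <- spring_response(force_lp, dt, jet$k_true, jet$c_drag)
  xc <- spec$x_rest + disp
  fov <- spec$width_px * spec$pixel_size
  bad <- which(xc < 0 | xc > fov)
  if (length(bad))
    stop("bundle displaced beyond the field of view at frame ", bad[1])

  xpos <- (seq_len(spec$width_px) - 0.5) * spec$pixel_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- array(0, dim = c(spec$n_frames, spec$height_px, spec$width_px))
  for (f in seq_len(spec$n_frames)) {
    clean <- spec$background +
      spec$amplitude * exp(-(xpos - xc[f])^2 / (2 * spec$edge_sigma^2))
    if (is.finite(spec$photon_scale)) {
      counts <- stats::rpois(spec$height_px * spec$width_px,
                             rep(spec$photon_scale * clean,
                                 each = spec$height_px))
      frames[f, , ] <- matrix(counts / spec$photon_scale,
                              nrow = spec$height_px)
    } else {
      frames[f, , ] <- matrix(rep(clean, each = spec$height_px),
                              nrow = spec$height_px)
    }
  }
  truth <- data.frame(frame = seq_len(spec$n_frames),
                      t_s = (seq_len(spec$n_frames) - 1) * dt,
                      x_nm = xc, displacement_nm = disp)
  structure(list(frames = frames, pixel_size = spec$pixel_size,
                 frame_rate = spec$frame_rate, stimulus = force,
                 truth = truth, spec = spec),
            class = "BundleMovie")
}
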