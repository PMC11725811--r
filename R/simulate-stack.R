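#' Simulate a two-channel confocal z-stack with known intensity ratios
#'
#' Builds a voxel grid in which every voxel belongs to the compartment of its
#' nearest landmark. The F-actin channel is the compartment's `actin_level`
#' plus Gaussian noise; the MYO7A channel is the compartment's `true_ratio`
#' times the clean actin field plus independent noise. Axes follow the
#' acquisition convention: x-y in-plane, z along the optical axis with slice
#' 1 the most apical plane.
#'
#' @param spec A [stack_spec()].
#' @param seed Integer seed.
#'
#' @return A `ConfocalStack`: list with `myo7a` and `actin` (arrays
#'   `[x, y, z]`), `voxel_size` nm, `landmarks`, and `truth` (data frame
#'   `landmark`, `true_ratio`, `actin_level`).
#' @export
simulate_confocal_stack <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "StackSpec"))
  d <- spec$dims; vs <- spec$voxel_size
  extent <- d * vs
  for (l in spec$landmarks)
    if (any(l$position < 0) || any(l$position > extent))
      stop("landmark outside stack bounds: ", l$name)

  # Nearest-landmark compartment label per voxel (squared distance, nm).
  cx <- (seq_len(d[1]) - 0.5) * vs[1]
  cy <- (seq_len(d[2]) - 0.5) * vs[2]
  cz <- (seq_len(d[3]) - 0.5) * vs[3]
  nms <- names(spec$landmarks)
  dist2 <- array(Inf, dim = d)
  label <- array(1L, dim = d)
  for (k in seq_along(nms)) {
    p <- spec$landmarks[[k]]$position
    dd <- outer(outer((cx - p["x"])^2, (cy - p["y"])^2, `+`),
                (cz - p["z"])^2, `+`)
    closer <- dd < dist2
    label[closer] <- k
    dist2[closer] <- dd[closer]
  }
  actin_clean <- array(spec$actin_level[nms][label], dim = d)
  myo_clean <- array(spec$true_ratio[nms][label], dim = d) * actin_clean

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nvox <- prod(d)
  actin <- actin_clean +
    if (spec$noise_sd > 0) stats::rnorm(nvox, 0, spec$noise_sd) else 0
  myo <- myo_clean +
    if (spec$noise_sd > 0) stats::rnorm(nvox, 0, spec$noise_sd) else 0

  structure(list(myo7a = myo, actin = actin, voxel_size = vs,
                 landmarks = spec$landmarks,
                 truth = data.frame(landmark = nms,
                                    true_ratio = as.numeric(spec$true_ratio[nms]),
                                    actin_level = as.numeric(spec$actin_level[nms]))),
            class = "ConfocalStack")
}
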