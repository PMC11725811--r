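#' Model of the mechanoelectrical transducer (MET) channel population
#'
#' Describes the MET channel complement of a single hair bundle as a
#' population of identical two-state channels gated by bundle displacement.
#' The open probability follows a single Boltzmann,
#' \deqn{P_{open}(x) = \frac{1}{1 + \exp(-(x - x_{set})/\lambda)},}
#' where the set point \eqn{x_{set}} equals `x_half` plus a Ca2+-dependent
#' adaptation shift `adapt_gain * max(0, e_rev_ca - V)`. Calcium entering
#' through resting MET channels drives adaptive channel closure, so at
#' hyperpolarized potentials (large inward Ca2+ driving force) the set point
#' moves in the excitatory direction and the resting open probability falls;
#' near or above the Ca2+ reversal potential the shift vanishes and the
#' resting open probability rises. Fast intracellular Ca2+ buffering (5 mM
#' BAPTA) suppresses the adaptation machinery, which the simulator emulates
#' by zeroing the shift under the `BAPTA_5mM` buffer label.
#'
#' `p_rest` is the resting open probability in the absence of any adaptation
#' shift (equivalently, under strong BAPTA buffering, or at membrane
#' potentials at or above `e_rev_ca`). When `x_half` is `NULL` it is derived
#' from `p_rest` via the Boltzmann inverse
#' `x_half = lambda_slope * log(1/p_rest - 1)` with the bundle resting
#' position at 0 nm.
#'
#' @param n_channels Number of MET channels in the bundle (count, >= 0).
#' @param g_single Single-channel conductance (pS, >= 0).
#' @param e_rev Reversal potential of the MET current (mV); the MET channel
#'   is a nonselective cation channel reversing near 0 mV.
#' @param p_rest Target resting open probability with no adaptation shift
#'   (fraction in `[0, 1]`).
#' @param lambda_slope Gating slope of the Boltzmann (nm, > 0).
#' @param x_half Displacement at half activation (nm). Derived from `p_rest`
#'   when `NULL`; if supplied it takes precedence and `p_rest` is recomputed.
#' @param adapt_gain Set-point shift per mV of inward Ca2+ driving force
#'   (nm/mV, >= 0). 0 emulates full suppression of adaptation.
#' @param e_rev_ca Reversal potential for Ca2+ (mV) used in the adaptation
#'   shift; the shift is `adapt_gain * max(0, e_rev_ca - V)`.
#' @param i_leak Leak current at the holding potential (pA).
#' @param noise_sd Gaussian current noise SD (pA, >= 0).
#'
#' @return An object of class `ChannelModel`.
#' @examples
#' ch <- channel_model(p_rest = 0.1, adapt_gain = 0)
#' ch$x_half / ch$lambda_slope  # log(9)
#' @export
channel_model <- function(n_channels = 800, g_single = 10, e_rev = 0,
                          p_rest = 0.5, lambda_slope = 20, x_half = NULL,
                          adapt_gain = 0.3, e_rev_ca = 40,
                          i_leak = -20, noise_sd = 5) {
  stopifnot(is.finite(n_channels), n_channels >= 0,
            is.finite(g_single), g_single >= 0,
            is.finite(e_rev),
            is.finite(lambda_slope), lambda_slope > 0,
            is.finite(adapt_gain), adapt_gain >= 0,
            is.finite(e_rev_ca), is.finite(i_leak),
            is.finite(noise_sd), noise_sd >= 0)
  if (is.null(x_half)) {
    stopifnot(is.finite(p_rest), p_rest > 0, p_rest < 1)
    x_half <- lambda_slope * log(1 / p_rest - 1)
  } else {
    stopifnot(is.finite(x_half))
    p_rest <- stats::plogis(-x_half / lambda_slope)
  }
  structure(list(n_channels = n_channels, g_single = g_single, e_rev = e_rev,
                 p_rest = p_rest, lambda_slope = lambda_slope,
                 x_half = x_half, adapt_gain = adapt_gain,
                 e_rev_ca = e_rev_ca, i_leak = i_leak, noise_sd = noise_sd),
            class = "ChannelModel")
}

#' Model of the piezo-driven fluid-jet stimulator and hair-bundle mechanics
#'
#' The fluid jet converts a driver-voltage (DV) command into force on the
#' bundle through a linear gain after first-order low-pass filtering
#' (`tau_jet`), a lumped stand-in for the jet's hydrodynamics. The bundle is
#' treated as an overdamped Hookean spring: `c_drag * dx/dt = F - k_true * x`,
#' so a force step `F` settles at `x = F / k_true`. With `k_true` in mN/m and
#' force in pN, displacement comes out in nm (1 mN/m = 1 pN/nm).
#'
#' @param dv_gain Force per driver-voltage unit (nN/V).
#' @param tau_jet First-order low-pass time constant of the jet (ms, >= 0).
#' @param k_true Bundle stiffness (mN/m, > 0).
#' @param c_drag Bundle viscous damping (uN s/m, >= 0). The mechanical time
#'   constant is `c_drag / k_true` in ms.
#'
#' @return An object of class `FluidJetModel`.
#' @export
fluid_jet_model <- function(dv_gain = 100, tau_jet = 0.5, k_true = 3,
                            c_drag = 0.6) {
  stopifnot(is.finite(dv_gain), is.finite(tau_jet), tau_jet >= 0,
            is.finite(k_true), k_true > 0, is.finite(c_drag), c_drag >= 0)
  structure(list(dv_gain = dv_gain, tau_jet = tau_jet, k_true = k_true,
                 c_drag = c_drag),
            class = "FluidJetModel")
}

#' Stimulus and voltage protocol for MET current recordings
#'
#' Describes the driver-voltage waveform and the membrane-potential series of
#' a recording. The default emulates the standard saturating protocol: a
#' 50 Hz sinusoidal force stimulus delivered at membrane potentials from
#' -124 mV to +96 mV (20 mV increments from -84 mV), with 1 mM intracellular
#' EGTA. A stimulus-off baseline of `pre_ms` precedes the waveform and is the
#' holding-current window used downstream.
#'
#' @param sample_rate Sampling rate (Hz, > 0).
#' @param waveform A list, either
#'   `list(type = "sinusoid", frequency, amplitude, cycles)` (frequency Hz,
#'   amplitude V, whole cycles) or
#'   `list(type = "step", amplitude, duration_ms)` (amplitude V).
#' @param voltage_steps Membrane potentials of the series (mV, nonempty).
#' @param holding_potential Holding potential (mV).
#' @param buffer_label Intracellular Ca2+ buffer condition, `"EGTA_1mM"`
#'   (adaptation intact) or `"BAPTA_5mM"` (adaptation suppressed).
#' @param pre_ms,post_ms Stimulus-off padding before/after the waveform (ms).
#'
#' @return An object of class `TraceProtocol`.
#' @export
trace_protocol <- function(sample_rate = 50000,
                           waveform = list(type = "sinusoid", frequency = 50,
                                           amplitude = 0.008, cycles = 10),
                           voltage_steps = c(-124, seq(-84, 96, by = 20)),
                           holding_potential = -84,
                           buffer_label = c("EGTA_1mM", "BAPTA_5mM"),
                           pre_ms = 20, post_ms = 10) {
  buffer_label <- match.arg(buffer_label)
  stopifnot(is.finite(sample_rate), sample_rate > 0,
            length(voltage_steps) >= 1, all(is.finite(voltage_steps)),
            is.list(waveform), !is.null(waveform$type),
            pre_ms >= 0, post_ms >= 0)
  if (!waveform$type %in% c("sinusoid", "step"))
    stop("waveform$type must be 'sinusoid' or 'step'")
  structure(list(sample_rate = sample_rate, waveform = waveform,
                 voltage_steps = voltage_steps,
                 holding_potential = holding_potential,
                 buffer_label = buffer_label,
                 pre_ms = pre_ms, post_ms = post_ms),
            class = "TraceProtocol")
}

#' Specification of a synthetic hair-bundle movie
#'
#' The bundle edge is imaged as a Gaussian intensity profile along the
#' measurement axis, riding on a uniform background; every row of a frame
#' carries the same profile with independent shot noise. Shot noise follows a
#' scaled Poisson model: a gray value `g` is observed as
#' `rpois(photon_scale * g) / photon_scale` (`photon_scale = Inf` is
#' noise-free).
#'
#' @param pixel_size Pixel pitch (nm, > 0).
#' @param frame_rate Frame rate (Hz, > 0).
#' @param n_frames Number of frames (>= 1).
#' @param width_px,height_px Frame size in pixels; the measurement axis runs
#'   along the width.
#' @param edge_sigma Gaussian width of the bundle profile (nm, > 0).
#' @param amplitude Peak gray value of the profile above background.
#' @param background Background gray value.
#' @param photon_scale Photon counts per gray unit (shot-noise scale); `Inf`
#'   disables noise.
#' @param x_rest Resting edge position (nm); defaults to the field centre.
#'
#' @return An object of class `MovieSpec`.
#' @export
movie_spec <- function(pixel_size = 50, frame_rate = 5000, n_frames = 900,
                       width_px = 96, height_px = 8,
                       edge_sigma = 150, amplitude = 1, background = 0.1,
                       photon_scale = 2000, x_rest = NULL) {
  stopifnot(pixel_size > 0, frame_rate > 0, n_frames >= 1,
            width_px >= 8, height_px >= 1, edge_sigma > 0,
            amplitude > 0, background >= 0, photon_scale > 0)
  if (is.null(x_rest)) x_rest <- width_px * pixel_size / 2
  structure(list(pixel_size = pixel_size, frame_rate = frame_rate,
                 n_frames = n_frames, width_px = width_px,
                 height_px = height_px, edge_sigma = edge_sigma,
                 amplitude = amplitude, background = background,
                 photon_scale = photon_scale, x_rest = x_rest),
            class = "MovieSpec")
}

#' Canonical anatomical landmark names along the hair cell
#'
#' Five positions along the confocal z-stack used for ratiometric
#' quantification, ordered from the stereocilia down into the cell body.
#' @return Character vector of the five landmark names.
#' @export
landmark_names <- function() {
  c("stereocilia_tips", "stereocilia_bases", "cuticular_plate",
    "cytoplasm_apex", "cytoplasm_base")
}

#' Default Gaussian kernel widths per landmark
#'
#' Standard deviations of the sampling volume along x-y and z: 250 nm and
#' 500 nm for the two stereocilia positions; 1 um and 500 nm for the
#' cuticular plate; 1 um and 1 um for the two cytoplasmic positions.
#'
#' @param name Landmark name, one of [landmark_names()].
#' @return Named numeric vector `c(sigma_xy =, sigma_z =)` in nm.
#' @export
landmark_default_sigmas <- function(name) {
  name <- match.arg(name, landmark_names())
  switch(name,
         stereocilia_tips  = c(sigma_xy = 250,  sigma_z = 500),
         stereocilia_bases = c(sigma_xy = 250,  sigma_z = 500),
         cuticular_plate   = c(sigma_xy = 1000, sigma_z = 500),
         cytoplasm_apex    = c(sigma_xy = 1000, sigma_z = 1000),
         cytoplasm_base    = c(sigma_xy = 1000, sigma_z = 1000))
}

#' Anatomical sampling landmark
#'
#' @param name Landmark name, one of [landmark_names()].
#' @param position Numeric length-3 position `(x, y, z)` in nm.
#' @param sigma_xy,sigma_z Gaussian SDs of the sampling volume (nm, > 0);
#'   defaults per landmark from [landmark_default_sigmas()].
#' @return An object of class `Landmark`.
#' @export
landmark <- function(name, position, sigma_xy = NULL, sigma_z = NULL) {
  name <- match.arg(name, landmark_names())
  stopifnot(length(position) == 3, all(is.finite(position)))
  def <- landmark_default_sigmas(name)
  if (is.null(sigma_xy)) sigma_xy <- def[["sigma_xy"]]
  if (is.null(sigma_z)) sigma_z <- def[["sigma_z"]]
  stopifnot(sigma_xy > 0, sigma_z > 0)
  structure(list(name = name,
                 position = stats::setNames(as.numeric(position),
                                            c("x", "y", "z")),
                 sigma_xy = sigma_xy, sigma_z = sigma_z),
            class = "Landmark")
}

#' Specification of a synthetic two-channel confocal stack
#'
#' Channel 2 (F-actin / phalloidin) is a piecewise-constant intensity field:
#' each voxel takes the `actin_level` of its nearest landmark, plus Gaussian
#' noise. Channel 1 (MYO7A immunostain) equals the per-compartment
#' `true_ratio` times the clean actin field, plus its own noise. Default
#' landmark depths place the five positions 4 um apart along a 22-um cell so
#' the sampling volumes of adjacent compartments barely overlap.
#'
#' @param voxel_size Numeric length-3 `(x, y, z)` voxel pitch in nm.
#' @param dims Integer length-3 stack size in voxels `(nx, ny, nz)`.
#' @param landmarks List of five [landmark()] objects (one per canonical
#'   name); `NULL` builds the default centred column of landmarks.
#' @param true_ratio Named numeric vector of MYO7A/F-actin intensity ratios
#'   per landmark (>= 0); a scalar is recycled to all five.
#' @param actin_level Named numeric vector of F-actin intensity per landmark
#'   compartment; scalar recycled.
#' @param noise_sd Additive Gaussian noise SD per channel (same units as
#'   intensities).
#'
#' @return An object of class `StackSpec`.
#' @export
stack_spec <- function(voxel_size = c(50, 50, 250),
                       dims = c(96, 96, 88),
                       landmarks = NULL,
                       true_ratio = c(stereocilia_tips = 0.8,
                                      stereocilia_bases = 1.0,
                                      cuticular_plate = 1.2,
                                      cytoplasm_apex = 0.6,
                                      cytoplasm_base = 0.5),
                       actin_level = c(stereocilia_tips = 100,
                                       stereocilia_bases = 120,
                                       cuticular_plate = 150,
                                       cytoplasm_apex = 60,
                                       cytoplasm_base = 60),
                       noise_sd = 2) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(dims) == 3, all(dims >= 4), noise_sd >= 0)
  nms <- landmark_names()
  if (length(true_ratio) == 1) true_ratio <- stats::setNames(rep(true_ratio, 5), nms)
  if (length(actin_level) == 1) actin_level <- stats::setNames(rep(actin_level, 5), nms)
  stopifnot(all(nms %in% names(true_ratio)), all(true_ratio >= 0),
            all(nms %in% names(actin_level)), all(actin_level > 0))
  if (is.null(landmarks)) {
    cx <- dims[1] * voxel_size[1] / 2
    cy <- dims[2] * voxel_size[2] / 2
    # evenly staggered depths (2, 6, 10, 14, 18 um on the default 22-um
    # stack), scaled to the actual z extent
    zs <- c(2, 6, 10, 14, 18) / 22 * dims[3] * voxel_size[3]
    landmarks <- Map(function(nm, z) landmark(nm, c(cx, cy, z)), nms, zs)
  }
  stopifnot(length(landmarks) == 5)
  got <- vapply(landmarks, function(l) l$name, character(1))
  if (!setequal(got, nms) || anyDuplicated(got))
    stop("landmarks must contain exactly the five canonical positions")
  names(landmarks) <- got
  structure(list(voxel_size = as.numeric(voxel_size), dims = as.integer(dims),
                 landmarks = landmarks[nms],
                 true_ratio = true_ratio[nms],
                 actin_level = actin_level[nms], noise_sd = noise_sd),
            class = "StackSpec")
}

#' Specification of a synthetic gene universe with known set structure
#'
#' Defines named gene sets (sizes), pairwise overlaps, and optional direction
#' counts, from which differential-expression tables with an exactly known
#' pass/fail structure are generated. Overlapping genes are allocated to one
#' pair at a time (no triple intersections), so each set's size must be at
#' least the sum of its specified overlaps.
#'
#' @param universe_size Total number of genes in the universe.
#' @param set_sizes Named integer vector of set sizes.
#' @param overlaps List of overlap specifications
#'   `list(a =, b =, n =, n_down_a =, n_down_b =)`; `n_down_*` (optional)
#'   fixes how many of the shared genes are downregulated in the table of
#'   set `a`/`b`.
#' @param tables Character vector naming which sets correspond to
#'   differential-expression contrasts (a full table is emitted for each);
#'   the remaining sets are plain gene panels.
#' @param down_frac Default fraction of unconstrained in-set genes that are
#'   downregulated.
#'
#' @return An object of class `GeneUniverseSpec`.
#' @seealso [fig_overlap_spec()] for the default maturation/knockout layout.
#' @export
gene_universe_spec <- function(universe_size, set_sizes, overlaps = list(),
                               tables = names(set_sizes), down_frac = 0.5) {
  stopifnot(universe_size >= 1, length(set_sizes) >= 1,
            !is.null(names(set_sizes)), all(set_sizes >= 0),
            all(set_sizes <= universe_size),
            all(tables %in% names(set_sizes)),
            down_frac >= 0, down_frac <= 1)
  used <- stats::setNames(rep(0, length(set_sizes)), names(set_sizes))
  for (ov in overlaps) {
    stopifnot(all(c("a", "b", "n") %in% names(ov)),
              ov$a %in% names(set_sizes), ov$b %in% names(set_sizes),
              ov$n >= 0, ov$n <= min(set_sizes[[ov$a]], set_sizes[[ov$b]]))
    used[ov$a] <- used[ov$a] + ov$n
    used[ov$b] <- used[ov$b] + ov$n
  }
  if (any(used > set_sizes))
    stop("infeasible overlap specification: overlaps exceed set size for ",
         paste(names(set_sizes)[used > set_sizes], collapse = ", "))
  if (sum(set_sizes) > universe_size)
    stopifnot(sum(set_sizes) - sum(vapply(overlaps, `[[`, numeric(1), "n")) <=
                universe_size)
  structure(list(universe_size = as.integer(universe_size),
                 set_sizes = set_sizes, overlaps = overlaps,
                 tables = tables, down_frac = down_frac),
            class = "GeneUniverseSpec")
}

#' Default gene-universe layout: cochlear maturation vs Myo7a knockout
#'
#' Encodes the published set structure: 3,266 genes differentially expressed
#' during posthearing maturation (P15 to P30 in control cochleae); 1,739
#' differentially expressed in the knockout at P30, of which 1,007 overlap
#' the maturation set (all 1,007 down in the knockout, 713 of them up during
#' maturation); and a literature panel of 64 hair-bundle genes of which 16
#' overlap the knockout DEGs (14 down).
#'
#' @param universe_size Total genes in the universe.
#' @return A [gene_universe_spec()] object.
#' @export
fig_overlap_spec <- function(universe_size = 20000) {
  gene_universe_spec(
    universe_size = universe_size,
    set_sizes = c(maturation = 3266, ko_p30 = 1739, bundle_panel = 64),
    overlaps = list(
      list(a = "maturation", b = "ko_p30", n = 1007,
           n_down_a = 1007 - 713, n_down_b = 1007),
      list(a = "bundle_panel", b = "ko_p30", n = 16, n_down_b = 14)),
    tables = c("maturation", "ko_p30"))
}
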