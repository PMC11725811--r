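#' Normalized anisotropic Gaussian weight field for a landmark
#'
#' Separable Gaussian with SDs (`sigma_xy`, `sigma_xy`, `sigma_z`) centred on
#' the landmark, truncated at 4 SD per axis (and at the stack boundary) and
#' renormalized to sum exactly 1, so the weighted average of a constant field
#' is that constant regardless of truncation.
#'
#' @param dims Stack size in voxels `(nx, ny, nz)`.
#' @param lm A [landmark()].
#' @param voxel_size Numeric length-3 voxel pitch `(x, y, z)` in nm.
#' @param truncate Truncation radius in SD units (default 4).
#' @return 3-D array of weights summing to 1 (zero outside the truncation
#'   box).
#' @export
gaussian_weights <- function(dims, lm, voxel_size, truncate = 4) {
  stopifnot(inherits(lm, "Landmark"), length(dims) == 3,
            length(voxel_size) == 3, all(voxel_size > 0), truncate > 0)
  extent <- dims * voxel_size
  if (any(lm$position < 0) || any(lm$position > extent))
    stop("landmark outside stack bounds: ", lm$name)
  sig <- c(lm$sigma_xy, lm$sigma_xy, lm$sigma_z)
  if (any(sig < voxel_size))
    warning("landmark ", lm$name, ": sigma below one voxel on some axis; ",
            "the sampling volume is under-resolved")
  ax <- vector("list", 3)
  for (a in 1:3) {
    centers <- (seq_len(dims[a]) - 0.5) * voxel_size[a]
    w <- exp(-(centers - lm$position[a])^2 / (2 * sig[a]^2))
    w[abs(centers - lm$position[a]) > truncate * sig[a]] <- 0
    ax[[a]] <- w
  }
  w3 <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  s <- sum(w3)
  if (s == 0) stop("empty weight field for landmark ", lm$name)
  w3 / s
}

#' MYO7A/F-actin intensity ratio in a Gaussian volume at a landmark
#'
#' Averages each channel with the identical normalized Gaussian weight field
#' and returns the ratio of the two weighted averages. The measurement is
#' flagged invalid when the weighted F-actin average falls below
#' `actin_floor_frac` of the channel maximum (a near-zero denominator would
#' make the ratio noise-dominated).
#'
#' @param stack A `ConfocalStack` (channels `myo7a`, `actin`, `voxel_size`).
#' @param lm A [landmark()].
#' @param actin_floor_frac Denominator floor as a fraction of the actin
#'   channel maximum (default 0.01).
#' @param truncate Passed to [gaussian_weights()].
#' @return A `RatioMeasurement`: list with `landmark`, `myo7a_avg`,
#'   `actin_avg`, `ratio`, `valid`.
#' @export
local_ratio <- function(stack, lm, actin_floor_frac = 0.01, truncate = 4) {
  stopifnot(inherits(stack, "ConfocalStack") ||
              (is.list(stack) && !is.null(stack$myo7a) && !is.null(stack$actin)))
  stopifnot(identical(dim(stack$myo7a), dim(stack$actin)))
  w <- gaussian_weights(dim(stack$myo7a), lm, stack$voxel_size,
                        truncate = truncate)
  m <- sum(w * stack$myo7a)
  a <- sum(w * stack$actin)
  valid <- a > actin_floor_frac * max(stack$actin)
  structure(list(landmark = lm$name, myo7a_avg = m, actin_avg = a,
                 ratio = if (valid) m / a else NA_real_, valid = valid),
            class = "RatioMeasurement")
}

#' Percent reduction of a group mean relative to control
#'
#' `100 * (1 - mean_test / mean_control)`; undefined (NA, flagged) when the
#' control mean is not positive.
#'
#' @param mean_test Mean of the test (e.g. knockout) group.
#' @param mean_control Mean of the control group.
#' @return List with `percent` and `valid`.
#' @export
percent_reduction <- function(mean_test, mean_control) {
  if (!is.finite(mean_control) || mean_control <= 0)
    return(list(percent = NA_real_, valid = FALSE))
  list(percent = 100 * (1 - mean_test / mean_control), valid = TRUE)
}

#' Group summary of ratiometric measurements across cells
#'
#' Aggregates per-cell [local_ratio()] measurements into mean, SD and n per
#' (genotype, age, landmark) group, excluding (and counting) invalid
#' measurements, and appends the percent reduction of each group relative to
#' the control genotype at the same age and landmark.
#'
#' @param measurements Data frame with columns `cell_id`, `genotype`, `age`,
#'   `landmark`, `ratio`, `valid`.
#' @param control Genotype label of the control group.
#' @return A `GroupSummary` data frame: `genotype`, `age`, `landmark`,
#'   `mean`, `sd`, `n`, `n_invalid`, `percent_reduction` (NA for the control
#'   rows).
#' @export
profile_cells <- function(measurements, control = "control") {
  req <- c("genotype", "age", "landmark", "ratio", "valid")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keys <- unique(measurements[c("genotype", "age", "landmark")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- measurements[measurements$genotype == k$genotype &
                          measurements$age == k$age &
                          measurements$landmark == k$landmark, ]
    ok <- sub$valid & is.finite(sub$ratio)
    if (!any(ok)) {
      warning("group with no valid measurements omitted: ",
              paste(k$genotype, k$age, k$landmark))
      return(NULL)
    }
    data.frame(genotype = k$genotype, age = k$age, landmark = k$landmark,
               mean = mean(sub$ratio[ok]),
               sd = if (sum(ok) > 1) stats::sd(sub$ratio[ok]) else 0,
               n = sum(ok), n_invalid = sum(!ok))
  })
  out <- do.call(rbind, rows)
  out$percent_reduction <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$genotype[i] == control) next
    ctrl <- out[out$genotype == control & out$age == out$age[i] &
                  out$landmark == out$landmark[i], ]
    if (nrow(ctrl) == 1)
      out$percent_reduction[i] <-
        percent_reduction(out$mean[i], ctrl$mean)$percent
  }
  class(out) <- c("GroupSummary", "data.frame")
  out
}
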