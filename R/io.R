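# Readers and writers for the interchange formats: long-format CSV for
# current traces, multi-page TIFF (+ JSON sidecar) for movies and stacks,
# TSV for differential-expression tables, JSON for landmark annotations.

#' Write a current trace set as long-format CSV
#'
#' Columns: `time_s`, `current_pA`, `driver_V`, `v_mV`, `buffer`,
#' `stim_on` (index of the first in-stimulus sample).
#' @param set A `CurrentTraceSet` or list of `CurrentTrace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_set_csv <- function(set, path) {
  traces <- if (inherits(set, "CurrentTraceSet")) set$traces else set
  rows <- lapply(traces, function(tr) {
    n <- length(tr$samples)
    data.frame(time_s = (seq_len(n) - 1) / tr$sample_rate,
               current_pA = tr$samples, driver_V = tr$driver,
               v_mV = tr$v_m, buffer = tr$buffer_label,
               stim_on = tr$stim_on)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a current trace set from long-format CSV
#'
#' @param path CSV file written by [write_trace_set_csv()].
#' @return A `CurrentTraceSet` (without ground truth).
#' @export
read_trace_set_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_s", "current_pA", "driver_V", "v_mV")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  traces <- lapply(split(df, df$v_mV), function(sub) {
    sub <- sub[order(sub$time_s), ]
    sr <- 1 / stats::median(diff(sub$time_s))
    structure(list(samples = sub$current_pA, driver = sub$driver_V,
                   sample_rate = sr, v_m = sub$v_mV[1],
                   buffer_label = if ("buffer" %in% names(sub))
                     sub$buffer[1] else NA_character_,
                   stim_on = if ("stim_on" %in% names(sub))
                     sub$stim_on[1] else NULL,
                   meta = list()),
              class = "CurrentTrace")
  })
  traces <- traces[order(vapply(traces, `[[`, numeric(1), "v_m"))]
  structure(list(traces = unname(traces), truth = NULL),
            class = "CurrentTraceSet")
}

# Scale an array into [0, 1] for float TIFF storage; returns list(data,
# offset, scale) with original = data * scale + offset.
.tiff_scale <- function(x) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  list(data = (x - lo) / scale, offset = lo, scale = scale)
}

#' Write a bundle movie as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per frame; pixel size, frame rate, the stimulus
#' record and the intensity scaling live in `<path>.json`.
#' @param movie A `BundleMovie`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  sc <- .tiff_scale(movie$frames)
  pages <- lapply(seq_len(dim(movie$frames)[1]),
                  function(f) sc$data[f, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "BundleMovie", pixel_size_nm = movie$pixel_size,
               frame_rate_hz = movie$frame_rate, stimulus_nN = movie$stimulus,
               intensity_offset = sc$offset, intensity_scale = sc$scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a bundle movie written by [write_movie_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist unless
#'   `pixel_size` and `frame_rate` are supplied).
#' @param pixel_size,frame_rate Overrides when no sidecar is present.
#' @return A `BundleMovie` (without ground truth).
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_rate = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(intensity_offset = 0, intensity_scale = 1, stimulus_nN = NULL)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_nm
  if (is.null(frame_rate)) frame_rate <- meta$frame_rate_hz
  if (is.null(pixel_size) || is.null(frame_rate))
    stop("pixel size / frame rate unavailable: supply them or the sidecar")
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                             ncol(pages[[1]])))
  for (f in seq_along(pages))
    frames[f, , ] <- pages[[f]] * meta$intensity_scale + meta$intensity_offset
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate, stimulus = meta$stimulus_nN,
                 truth = NULL),
            class = "BundleMovie")
}

#' Write a two-channel confocal stack as multi-page TIFF with sidecar
#'
#' Pages are ordered all MYO7A z-slices first, then all F-actin slices;
#' voxel size, slice counts and intensity scaling live in `<path>.json`.
#' @param stack A `ConfocalStack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$myo7a)
  both <- c(stack$myo7a, stack$actin)
  sc <- .tiff_scale(both)
  arr <- array(sc$data, dim = c(d[1], d[2], 2 * d[3]))
  pages <- lapply(seq_len(2 * d[3]), function(k) t(arr[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "ConfocalStack", voxel_size_nm = stack$voxel_size,
               n_z = d[3], channels = c("myo7a", "actin"),
               intensity_offset = sc$offset, intensity_scale = sc$scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a confocal stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with sidecar `<path>.json`.
#' @return A `ConfocalStack` (without ground truth or landmarks).
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z
  stopifnot(length(pages) == 2 * nz)
  restore <- function(idx) {
    a <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), nz))
    for (k in seq_len(nz))
      a[, , k] <- t(pages[[idx[k]]]) * meta$intensity_scale +
        meta$intensity_offset
    a
  }
  structure(list(myo7a = restore(seq_len(nz)),
                 actin = restore(nz + seq_len(nz)),
                 voxel_size = meta$voxel_size_nm,
                 landmarks = NULL, truth = NULL),
            class = "ConfocalStack")
}

#' Write or read differential-expression tables as TSV
#'
#' Columns `gene_id`, `log2FC`, `lfcSE`, `padj`.
#' @param table Data frame to write.
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_deg_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_tsv
#' @export
read_deg_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read landmark annotations from JSON
#'
#' Expected shape: `{"cell_id": ..., "landmarks": [{"name": ...,
#' "x_nm": ..., "y_nm": ..., "z_nm": ...}, ...]}`; per-landmark sigmas
#' default by name.
#' @param path JSON file.
#' @return List with `cell_id` and a named list of [landmark()] objects.
#' @export
read_landmarks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lms <- lapply(seq_len(nrow(doc$landmarks)), function(i) {
    r <- doc$landmarks[i, ]
    landmark(r$name, c(r$x_nm, r$y_nm, r$z_nm),
             sigma_xy = if ("sigma_xy_nm" %in% names(r)) r$sigma_xy_nm,
             sigma_z = if ("sigma_z_nm" %in% names(r)) r$sigma_z_nm)
  })
  names(lms) <- vapply(lms, `[[`, character(1), "name")
  list(cell_id = doc$cell_id, landmarks = lms)
}
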