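# Core data containers and their file formats.
#
# Array convention: 3D stacks are arrays with dim = (ny, nx, nz), R
# column-major. Voxel sizes are carried as a named vector c(x=, y=, z=) in
# micrometres. The physical position of voxel (i, j, k) (1-based) is
# ((j - 0.5) * vx, (i - 0.5) * vy, (k - 0.5) * vz) in (x, y, z).

#' Create a 3D image stack
#'
#' Container for a single-channel 3D fluorescence stack with physical voxel
#' calibration. Default voxel size matches confocal acquisition at
#' 80 x 80 nm pixels and 200 nm z-steps.
#'
#' @param intensity 3D numeric array, dims (ny, nx, nz), non-negative a.u.
#'   A matrix is promoted to a single-plane stack.
#' @param voxel_size_um named numeric `c(x=, y=, z=)` in micrometres.
#' @param channel channel label.
#' @return An object of class `rq_stack`.
#' @export
image_stack <- function(intensity,
                        voxel_size_um = c(x = 0.08, y = 0.08, z = 0.2),
                        channel = "") {
  if (is.matrix(intensity)) intensity <- array(intensity, c(dim(intensity), 1L))
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L,
            all(dim(intensity) >= 1L))
  vs <- .check_voxel_size(voxel_size_um)
  structure(list(intensity = intensity, voxel_size_um = vs,
                 channel = as.character(channel)),
            class = "rq_stack")
}

.check_voxel_size <- function(vs) {
  stopifnot(is.numeric(vs), length(vs) == 3L)
  if (is.null(names(vs)) || !all(c("x", "y", "z") %in% names(vs)))
    names(vs) <- c("x", "y", "z")
  vs <- vs[c("x", "y", "z")]
  if (any(!is.finite(vs)) || any(vs <= 0)) stop("voxel sizes must be > 0")
  vs
}

# spacing in array-dimension order (y, x, z)
.spacing <- function(stack) unname(stack$voxel_size_um[c("y", "x", "z")])

#' @export
print.rq_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<rq_stack '%s'> %d x %d x %d voxels @ %.3f x %.3f x %.3f um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size_um["x"], x$voxel_size_um["y"],
              x$voxel_size_um["z"]))
  invisible(x)
}

#' Create a 2D STED frame
#'
#' @param intensity numeric matrix, non-negative a.u.
#' @param pixel_size_um pixel edge in micrometres (default 0.015, i.e. the
#'   15 nm 2D-STED pixel size).
#' @param channel channel label.
#' @return An object of class `rq_frame`.
#' @export
sted_frame <- function(intensity, pixel_size_um = 0.015, channel = "") {
  stopifnot(is.matrix(intensity), is.numeric(intensity),
            length(pixel_size_um) == 1L, pixel_size_um > 0)
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um,
                 channel = as.character(channel)),
            class = "rq_frame")
}

#' @export
print.rq_frame <- function(x, ...) {
  cat(sprintf("<rq_frame '%s'> %d x %d px @ %.0f nm\n", x$channel,
              nrow(x$intensity), ncol(x$intensity), 1000 * x$pixel_size_um))
  invisible(x)
}

#' Create a sampled trace
#'
#' Uniformly sampled time series (fluorescence in a.u. or membrane voltage
#' in mV). `duration_s` defaults to `n * dt`, but generators may set the
#' nominal session duration so that rates are computed over the intended
#' recording window.
#'
#' @param time_s sample times, strictly increasing and uniform.
#' @param value sample values.
#' @param kind one of "fluorescence", "voltage" or "generic".
#' @param duration_s nominal duration in seconds.
#' @return data.frame of class `rq_trace` with columns `time_s`, `value`.
#' @export
rq_trace <- function(time_s, value,
                     kind = c("generic", "fluorescence", "voltage"),
                     duration_s = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(time_s) == length(value), length(time_s) >= 1L)
  if (length(time_s) > 1L) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(dt)) stop("sampling must be uniform")
    dt <- mean(dt)
  } else {
    dt <- NA_real_
  }
  if (is.null(duration_s)) {
    duration_s <- if (is.na(dt)) NA_real_ else length(time_s) * dt
  }
  structure(data.frame(time_s = time_s, value = value),
            class = c("rq_trace", "data.frame"),
            kind = kind, dt = dt, duration_s = duration_s)
}

.trace_dt <- function(trace) {
  dt <- attr(trace, "dt")
  if (is.null(dt) || is.na(dt)) dt <- mean(diff(trace$time_s))
  dt
}

.trace_duration <- function(trace) {
  d <- attr(trace, "duration_s")
  if (is.null(d) || is.na(d)) d <- nrow(trace) * .trace_dt(trace)
  d
}

# ---------------------------------------------------------------------------
# File formats: 32-bit float TIFF for images (one file per channel, planes
# in z order), two-column CSV for traces, JSON for manifests.

#' Write a stack as a multi-page 32-bit float TIFF
#'
#' Pages are z-planes in order. The TIFF writer stores floats in `[0, 1]`,
#' so intensities are divided by their maximum and the scale factor is
#' recorded, together with the voxel calibration and channel label, in a
#' JSON sidecar at `<path>.json`. [read_stack_tiff()] restores the
#' original values (to 32-bit float precision).
#'
#' @param stack an `rq_stack`.
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  scale <- max(stack$intensity, 1e-12)
  planes <- lapply(seq_len(dim(stack$intensity)[3]),
                   function(k) stack$intensity[, , k] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(scale = scale,
                            voxel_size_um = as.list(stack$voxel_size_um),
                            channel = stack$channel,
                            axis_order = "z-y-x"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a stack
#'
#' Reads the JSON sidecar written by [write_stack_tiff()] when present
#' (restoring scale, calibration and channel); arguments provide the
#' calibration for plain TIFFs.
#'
#' @param path TIFF file, pages interpreted as z-planes.
#' @inheritParams image_stack
#' @export
read_stack_tiff <- function(path,
                            voxel_size_um = c(x = 0.08, y = 0.08, z = 0.2),
                            channel = "") {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  arr <- array(0, c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) arr[, , k] <- planes[[k]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    arr <- arr * meta$scale
    voxel_size_um <- unlist(meta$voxel_size_um)
    if (nzchar(meta$channel)) channel <- meta$channel
  }
  image_stack(arr, voxel_size_um, channel)
}

#' Write a trace as a two-column CSV (time_s, value)
#' @param trace an `rq_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, value = trace$value),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column CSV trace
#' @param path CSV with columns time_s, value.
#' @inheritParams rq_trace
#' @export
read_trace_csv <- function(path, kind = "generic", duration_s = NULL) {
  d <- read.csv(path)
  rq_trace(d$time_s, d$value, kind = kind, duration_s = duration_s)
}
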