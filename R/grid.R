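#' Saturation offset-frequency schedule
#'
#' A `cest_grid` records the offset frequencies (Hz) at which CEST images are
#' acquired, which slot holds the unsaturated reference acquisition
#' \eqn{\omega_0}, the water resonance \eqn{\omega_1} (0 Hz in all presets),
#' and the centre frequencies \eqn{\omega_i} of the CEST pools of interest.
#'
#' @param offsets_hz numeric vector of unique offset frequencies in Hz.
#' @param ref_index index (1-based) of the unsaturated reference offset
#'   \eqn{\omega_0} within `offsets_hz`.
#' @param water_offset_hz water resonance \eqn{\omega_1} in Hz.
#' @param pool_offsets_hz numeric vector of CEST pool centres \eqn{\omega_i}
#'   in Hz (may be empty for a water-only schedule).
#' @return An object of class `cest_grid`.
#' @export
freq_grid <- function(offsets_hz, ref_index, water_offset_hz = 0,
                      pool_offsets_hz = numeric(0)) {
  offsets_hz <- as.numeric(offsets_hz)
  if (anyDuplicated(offsets_hz)) stop("offset frequencies must be unique")
  if (length(offsets_hz) < 2L) stop("grid needs at least two offsets")
  ref_index <- as.integer(ref_index)
  if (ref_index < 1L || ref_index > length(offsets_hz))
    stop("ref_index out of range")
  pool_offsets_hz <- as.numeric(pool_offsets_hz)
  g <- structure(list(
    offsets_hz = offsets_hz,
    ref_index = ref_index,
    water_offset_hz = as.numeric(water_offset_hz),
    pool_offsets_hz = pool_offsets_hz
  ), class = "cest_grid")
  # flag (don't forbid) pool/water frequencies that are not grid points;
  # asymmetry analysis additionally needs the mirrored -omega_i
  g$off_grid <- setdiff(c(water_offset_hz, pool_offsets_hz, -pool_offsets_hz),
                        offsets_hz)
  g
}

#' @export
print.cest_grid <- function(x, ...) {
  cat(sprintf(
    "<cest_grid> %d offsets [%g, %g] Hz; ref omega0 = %g Hz; water = %g Hz\n",
    length(x$offsets_hz), min(x$offsets_hz), max(x$offsets_hz),
    x$offsets_hz[x$ref_index], x$water_offset_hz))
  if (length(x$pool_offsets_hz))
    cat("  pools at", paste(x$pool_offsets_hz, collapse = ", "), "Hz\n")
  if (length(x$off_grid))
    cat("  off-grid frequencies:", paste(x$off_grid, collapse = ", "), "Hz\n")
  invisible(x)
}

n_offsets <- function(grid) length(grid$offsets_hz)

grid_step <- function(grid) stats::median(diff(sort(grid$offsets_hz)))

grid_span <- function(grid) diff(range(grid$offsets_hz))

#' Index of an offset frequency on the grid
#'
#' @param grid a [freq_grid()].
#' @param omega_hz frequency in Hz.
#' @param tol matching tolerance in Hz.
#' @return integer index into `grid$offsets_hz`.
#' @export
offset_index <- function(grid, omega_hz, tol = 1e-6) {
  d <- abs(grid$offsets_hz - omega_hz)
  i <- which.min(d)
  if (d[i] > tol) {
    near <- grid$offsets_hz[order(d)[1:min(3L, length(d))]]
    stop(sprintf("offset %g Hz is not on the grid; nearest available: %s",
                 omega_hz, paste(near, collapse = ", ")))
  }
  i
}

#' Offsets that a reduced acquisition must retain
#'
#' The reference \eqn{\omega_0}, the water frequency \eqn{\omega_1}, every
#' pool centre \eqn{\omega_i} and its negation \eqn{-\omega_i} (needed for
#' MTR-asymmetry analysis).
#'
#' @param grid a [freq_grid()].
#' @return numeric vector of required offsets in Hz (those present on grid).
#' @export
required_offsets <- function(grid) {
  req <- c(grid$offsets_hz[grid$ref_index], grid$water_offset_hz,
           grid$pool_offsets_hz, -grid$pool_offsets_hz)
  unique(req[req %in% grid$offsets_hz])
}

#' Choose a reduced offset schedule
#'
#' Keeps all required offsets (see [required_offsets()]) and fills the
#' remaining budget with approximately evenly spaced offsets from the rest of
#' the schedule.
#'
#' @param grid a [freq_grid()].
#' @param n_keep total number of offsets to retain.
#' @return numeric vector of offsets (Hz), sorted in grid order.
#' @export
select_reduced_offsets <- function(grid, n_keep) {
  req <- required_offsets(grid)
  if (n_keep < length(req))
    stop(sprintf("n_keep = %d cannot retain the %d required offsets",
                 n_keep, length(req)))
  if (n_keep > n_offsets(grid)) stop("n_keep exceeds the grid size")
  rest <- setdiff(grid$offsets_hz, req)
  n_extra <- n_keep - length(req)
  extra <- if (n_extra > 0L && length(rest) > 0L) {
    rest[unique(round(seq(1L, length(rest), length.out = n_extra)))]
  } else numeric(0)
  keep <- c(req, extra)
  grid$offsets_hz[grid$offsets_hz %in% keep]
}
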