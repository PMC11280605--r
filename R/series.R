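#' Amplitude image series
#'
#' Real, non-negative amplitude images \eqn{f(x,\omega)}, one 2D slice per
#' offset frequency, stored as an `ny x nx x n_offsets` array. Pixel indices
#' are row-major 2D array indices; the first array dimension is image rows.
#'
#' @param data numeric array `ny x nx x n_offsets`.
#' @param grid the [freq_grid()] the third dimension is indexed by.
#' @return object of class `cest_images`.
#' @export
image_series <- function(data, grid) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image series must be a 3D array")
  if (dim(data)[3] != n_offsets(grid))
    stop("third dimension must match the number of grid offsets")
  if (any(!is.finite(data))) stop("image series must be finite")
  structure(list(data = data, grid = grid), class = "cest_images")
}

#' @export
print.cest_images <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_images> %d x %d pixels, %d offsets\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Phase factor series
#'
#' Unit-modulus complex phase factors \eqn{A(x,\omega) = e^{i\phi(x,\omega)}}
#' matching an amplitude [image_series()].
#'
#' @param phi real phase angles in radians: an `ny x nx` matrix (shared by
#'   all offsets) or an `ny x nx x n_offsets` array.
#' @param grid the [freq_grid()].
#' @return object of class `cest_phase` whose `$data` is the complex
#'   unit-modulus array `ny x nx x n_offsets`.
#' @export
phase_series <- function(phi, grid) {
  if (is.matrix(phi))
    phi <- array(phi, c(dim(phi), n_offsets(grid)))
  if (length(dim(phi)) != 3L || dim(phi)[3] != n_offsets(grid))
    stop("phase must be ny x nx (x n_offsets)")
  if (any(!is.finite(phi))) stop("phase angles must be finite")
  structure(list(data = exp(1i * phi), grid = grid), class = "cest_phase")
}

#' @export
print.cest_phase <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_phase> %d x %d pixels, %d offsets\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Complex k-space series
#'
#' One complex 2D k-space array per retained offset, with the applied noise
#' level (fraction of the mean reference k-space magnitude) and RNG seed
#' recorded exactly as used.
#'
#' @param data complex array `ny x nx x n_offsets`.
#' @param grid the [freq_grid()].
#' @param noise_level fraction p of `mean(|g(omega0)|)` used as the Gaussian
#'   noise standard deviation, or 0.
#' @param rng_seed integer seed used for the noise draw, or `NA`.
#' @return object of class `cest_kspace`.
#' @export
kspace_series <- function(data, grid, noise_level = 0, rng_seed = NA_integer_) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("k-space series must be a 3D array")
  if (dim(data)[3] != n_offsets(grid))
    stop("third dimension must match the number of grid offsets")
  if (noise_level < 0) stop("noise level must be >= 0")
  structure(list(data = data, grid = grid,
                 noise_level = as.numeric(noise_level),
                 rng_seed = rng_seed),
            class = "cest_kspace")
}

#' @export
print.cest_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_kspace> %d x %d samples, %d offsets, noise %.3g%s\n",
              d[1], d[2], d[3], x$noise_level,
              if (!is.na(x$rng_seed)) sprintf(" (seed %d)", x$rng_seed)
              else ""))
  invisible(x)
}
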