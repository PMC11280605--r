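#' Add complex Gaussian noise to a k-space series
#'
#' Adds independent zero-mean Gaussian noise to the real and imaginary parts
#' of every offset's k-space data, with standard deviation
#' \eqn{\sigma = p \cdot \mathrm{mean}(|g(\omega_0)|)} — the noise level `p`
#' is expressed relative to the mean magnitude of the reference-offset
#' k-space signal. Deterministic given `seed`; the level and seed are
#' recorded on the returned series. The caller's RNG state is restored on
#' exit.
#'
#' @param ks a [kspace_series()].
#' @param level noise fraction p, >= 0.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return a [kspace_series()] with noisy data.
#' @export
add_noise <- function(ks, level, seed = NULL) {
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0)
    return(kspace_series(ks$data, ks$grid, noise_level = 0,
                         rng_seed = if (is.null(seed)) NA_integer_
                                    else as.integer(seed)))
  sigma <- level * mean(Mod(ks$data[, , ks$grid$ref_index]))
  n <- length(ks$data)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  noise <- complex(real = stats::rnorm(n, sd = sigma),
                   imaginary = stats::rnorm(n, sd = sigma))
  kspace_series(ks$data + array(noise, dim(ks$data)), ks$grid,
                noise_level = level,
                rng_seed = if (is.null(seed)) NA_integer_
                           else as.integer(seed))
}

#' Restrict a k-space series to a subset of offsets
#'
#' Emulates an acquisition with fewer saturation offsets. The kept set must
#' retain the reference \eqn{\omega_0}, the water frequency, every pool
#' centre \eqn{\omega_i} and its negation (required for asymmetry analysis).
#' Retained arrays are passed through bit-exactly; the achieved reduction
#' fraction is attached as attribute `"reduction_fraction"`.
#'
#' @param ks a [kspace_series()].
#' @param keep numeric vector of offsets (Hz) to retain.
#' @return a [kspace_series()] on the reduced [freq_grid()].
#' @export
subsample_offsets <- function(ks, keep) {
  grid <- ks$grid
  keep <- sort(unique(as.numeric(keep)))
  if (!all(keep %in% grid$offsets_hz))
    stop("keep contains offsets not on the grid")
  req <- required_offsets(grid)
  missing <- setdiff(req, keep)
  if (length(missing))
    stop(sprintf("keep drops required offset(s): %s Hz",
                 paste(missing, collapse = ", ")))
  sel <- which(grid$offsets_hz %in% keep)
  new_grid <- freq_grid(grid$offsets_hz[sel],
                        ref_index = match(grid$offsets_hz[grid$ref_index],
                                          grid$offsets_hz[sel]),
                        water_offset_hz = grid$water_offset_hz,
                        pool_offsets_hz = grid$pool_offsets_hz)
  out <- kspace_series(ks$data[, , sel, drop = FALSE], new_grid,
                       noise_level = ks$noise_level, rng_seed = ks$rng_seed)
  attr(out, "reduction_fraction") <-
    (n_offsets(grid) - length(sel)) / n_offsets(grid)
  out
}
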