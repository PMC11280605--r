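# Plug-and-play denoiser registry. The contract is a pure, deterministic
# two-argument function (2D image, noise-variance parameter lambda) -> image
# of the same shape; lambda <= 0 must be the identity. Any denoiser honouring
# the contract can be plugged into the reconstruction via its registry name.

.denoisers <- new.env(parent = emptyenv())

#' Register a plug-and-play denoiser
#'
#' @param name registry key.
#' @param fn function `(image, lambda) -> image`; `lambda` is the estimated
#'   noise variance of the image. Must be pure and deterministic and act as
#'   the identity for `lambda <= 0`.
#' @export
register_denoiser <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .denoisers)
  invisible(name)
}

#' Look up a registered denoiser
#' @param name registry key.
#' @return the denoiser function.
#' @export
get_denoiser <- function(name) {
  if (!exists(name, envir = .denoisers))
    stop(sprintf("unknown denoiser '%s'; registered: %s", name,
                 paste(ls(.denoisers), collapse = ", ")))
  get(name, envir = .denoisers)
}

#' Non-local-means denoising
#'
#' Patch-based non-local means: each pixel is replaced by a weighted average
#' of pixels in a search window, weighted by the similarity of their
#' surrounding patches, `w = exp(-max(d2 - 2 lambda, 0) / h2)` with `d2` the
#' mean squared patch difference and `h2 = lambda` (the noise variance). The
#' default spatial prior of the joint reconstruction.
#'
#' @param image numeric matrix.
#' @param lambda noise variance; `<= 0` returns the image unchanged.
#' @param patch_radius half-width of the comparison patch (patch size
#'   `2*patch_radius+1`).
#' @param search_radius half-width of the search window.
#' @return denoised matrix.
#' @export
denoise_nlm <- function(image, lambda, patch_radius = 1L,
                        search_radius = 4L) {
  if (lambda <= 0) return(image)
  nlm_denoise_cpp(image, lambda, as.integer(patch_radius),
                  as.integer(search_radius))
}

#' Gaussian-blur denoiser (simple reference denoiser)
#'
#' Separable Gaussian smoothing with a fixed 1-pixel spatial sigma whenever
#' `lambda > 0`; identity otherwise. Mainly useful as a cheap pluggable
#' alternative and for exercising the plug-and-play contract.
#'
#' @param image numeric matrix.
#' @param lambda noise variance; only its sign is used.
#' @param sigma_px spatial standard deviation in pixels.
#' @return smoothed matrix.
#' @export
denoise_gaussian <- function(image, lambda, sigma_px = 1) {
  if (lambda <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    # replicate-pad rows, convolve columns of m with kern
    n <- nrow(m); rr <- (length(kern) - 1L) / 2L
    pad <- m[c(rep(1L, rr), seq_len(n), rep(n, rr)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern))
      out <- out + kern[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(image, k)), k))
}

register_default_denoisers <- function() {
  register_denoiser("nlm", denoise_nlm)
  register_denoiser("gaussian", denoise_gaussian)
  register_denoiser("identity", function(image, lambda) image)
}
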