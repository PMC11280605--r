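# Centered orthonormal 2D discrete Fourier transform.
#
# Convention (fixed for the whole package, shared by simulation and
# reconstruction): the image origin sits at the array centre
# (floor(n/2) + 1), moved to index 1 by ifftshift before the DFT; the DFT is
# scaled by 1/sqrt(N) so the transform is unitary and its adjoint equals its
# inverse. decode(encode(x)) == x to machine precision.

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  h1 <- floor(n1 / 2); h2 <- floor(n2 / 2)
  x[c((h1 + 1):n1, seq_len(h1)), c((h2 + 1):n2, seq_len(h2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  h1 <- ceiling(n1 / 2); h2 <- ceiling(n2 / 2)
  x[c((h1 + 1):n1, seq_len(h1)), c((h2 + 1):n2, seq_len(h2)), drop = FALSE]
}

#' Centered orthonormal 2D DFT and its inverse
#'
#' `fft2c` maps an image (origin at the array centre) to centred k-space;
#' `ifft2c` is its inverse and adjoint (the transform is unitary, so
#' Parseval's identity holds exactly).
#'
#' @param x complex or numeric matrix.
#' @return complex matrix of the same dimensions.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Fourier-encode an image series into k-space
#'
#' Per offset, applies the phase factor and the centred orthonormal 2D DFT:
#' \eqn{g(\omega) = F[A(x,\omega) f(x,\omega)]}. The returned series carries
#' `noise_level = 0`; use [add_noise()] to emulate acquisition noise.
#'
#' @param images an [image_series()].
#' @param phase a [phase_series()] with the same shape and grid.
#' @return a [kspace_series()].
#' @export
encode_kspace <- function(images, phase) {
  if (!identical(dim(images$data), dim(phase$data)))
    stop("images and phase must share the same shape")
  if (!isTRUE(all.equal(images$grid$offsets_hz, phase$grid$offsets_hz)))
    stop("images and phase must share the same grid")
  k <- array(complex(real = 0), dim(images$data))
  for (w in seq_len(dim(k)[3]))
    k[, , w] <- fft2c(phase$data[, , w] * images$data[, , w])
  kspace_series(k, images$grid, noise_level = 0)
}

#' Conventional per-offset FFT reconstruction
#'
#' Inverse-transforms each offset's k-space independently; the magnitude goes
#' to the amplitude series and the argument to the phase series. This is the
#' first step of the conventional two-step (FFT + pixel-wise fit) baseline.
#'
#' @param ks a [kspace_series()].
#' @return list with `images` ([image_series()]) and `phase`
#'   ([phase_series()]).
#' @export
fft_recon <- function(ks) {
  d <- dim(ks$data)
  mag <- array(0, d)
  phi <- array(0, d)
  for (w in seq_len(d[3])) {
    c_img <- ifft2c(ks$data[, , w])
    mag[, , w] <- Mod(c_img)
    phi[, , w] <- Arg(c_img)
  }
  list(images = image_series(mag, ks$grid),
       phase = phase_series(phi, ks$grid))
}
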