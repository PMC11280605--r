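#' Multi-pool Z-spectrum model parameters
#'
#' Parameters of the pixel-wise Z-spectrum model. The water pool is a
#' Lorentzian centred at \eqn{\omega_1}; CEST pools are Gaussians (model
#' `"LG"`) or Lorentzians (model `"LL"`) centred at the known pool
#' frequencies \eqn{\omega_i}:
#' \deqn{Z(\omega) = 1 - \frac{a}{(\omega-\omega_1)^2 + \Gamma}
#'       \mp \sum_i b_i \exp\!\left[-\frac{(\omega-\omega_i)^2}{\sigma_i^2}\right]}
#' for `"LG"`, with each pool term replaced by
#' \eqn{b_i/((\omega-\omega_i)^2+\sigma_i)} for `"LL"` (mirroring the water
#' term, so the LL width parameter has units Hz^2). Pool amplitudes are stored
#' as dip depths and subtracted by default (`pool_sign = "dip"`), matching the
#' saturation-transfer dips seen in measured Z-spectra; `pool_sign =
#' "literal"` adds the pool terms instead.
#'
#' @param a water amplitude, the Lorentzian numerator (units Hz^2); the dip
#'   depth at the water centre is `a / gamma`.
#' @param gamma water Lorentzian width parameter \eqn{\Gamma} (Hz^2), > 0.
#' @param pools data frame with columns `center_hz`, `b`, `sigma` (one row per
#'   CEST pool; may have zero rows). For `"LG"`, `b` is the dimensionless dip
#'   depth and `sigma` the Gaussian width in Hz; for `"LL"`, `b` is the
#'   Lorentzian numerator (Hz^2-scaled) and `sigma` the width in Hz^2.
#' @param model `"LG"` (Lorentzian water + Gaussian pools) or `"LL"`
#'   (all-Lorentzian).
#' @param water_center_hz water resonance \eqn{\omega_1} in Hz.
#' @param pool_sign `"dip"` (subtract pool terms) or `"literal"` (add them).
#' @return An object of class `zspec_params`.
#' @export
zspec_params <- function(a, gamma, pools = NULL, model = c("LG", "LL"),
                         water_center_hz = 0, pool_sign = c("dip", "literal")) {
  model <- match.arg(model)
  pool_sign <- match.arg(pool_sign)
  if (is.null(pools))
    pools <- data.frame(center_hz = numeric(0), b = numeric(0),
                        sigma = numeric(0))
  pools <- as.data.frame(pools)
  stopifnot(all(c("center_hz", "b", "sigma") %in% names(pools)))
  if (!is.finite(a) || a < 0) stop("water amplitude a must be finite and >= 0")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be finite and > 0")
  if (nrow(pools) && any(pools$sigma <= 0)) stop("pool widths must be > 0")
  if (nrow(pools) && any(!is.finite(pools$center_hz)))
    stop("pool centers must be finite")
  structure(list(a = as.numeric(a), gamma = as.numeric(gamma),
                 pools = pools, model = model,
                 water_center_hz = as.numeric(water_center_hz),
                 pool_sign = pool_sign),
            class = "zspec_params")
}

#' @export
print.zspec_params <- function(x, ...) {
  cat(sprintf("<zspec_params> %s model: a = %g, gamma = %g (depth %.4g)\n",
              x$model, x$a, x$gamma, x$a / x$gamma))
  if (nrow(x$pools))
    for (i in seq_len(nrow(x$pools)))
      cat(sprintf("  pool %d: center %g Hz, b = %g, sigma = %g\n",
                  i, x$pools$center_hz[i], x$pools$b[i], x$pools$sigma[i]))
  invisible(x)
}

#' Evaluate the multi-pool Z-spectrum model
#'
#' @param params a [zspec_params()].
#' @param omega_hz numeric vector of offset frequencies in Hz.
#' @return numeric vector of dimensionless Z values.
#' @export
eval_zmodel <- function(params, omega_hz) {
  if (any(!is.finite(omega_hz))) stop("omega must be finite")
  dw <- omega_hz - params$water_center_hz
  z <- 1 - params$a / (dw^2 + params$gamma)
  sgn <- if (params$pool_sign == "dip") -1 else 1
  if (nrow(params$pools)) {
    for (i in seq_len(nrow(params$pools))) {
      dp <- omega_hz - params$pools$center_hz[i]
      term <- if (params$model == "LG") {
        params$pools$b[i] * exp(-dp^2 / params$pools$sigma[i]^2)
      } else {
        params$pools$b[i] / (dp^2 + params$pools$sigma[i])
      }
      z <- z + sgn * term
    }
  }
  z
}

# ---- internal batched parameterisation ------------------------------------
#
# The fitter works on a depth parameterisation so that simple box bounds are
# dimensionless: theta = (d, Gamma, e_1, s_1, ..., e_K, s_K) with
#   water term  = d * Gamma / ((w - w1)^2 + Gamma)        (d = a / Gamma)
#   LG pool     = e_i * exp(-(w - wi)^2 / s_i^2)          (e = b)
#   LL pool     = e_i * s_i / ((w - wi)^2 + s_i)          (e = b / sigma)
# Rows of theta are pixels.

theta_from_params <- function(params) {
  th <- c(params$a / params$gamma, params$gamma)
  if (nrow(params$pools)) {
    for (i in seq_len(nrow(params$pools))) {
      b <- params$pools$b[i]; s <- params$pools$sigma[i]
      e <- if (params$model == "LG") b else b / s
      th <- c(th, e, s)
    }
  }
  th
}

params_from_theta <- function(theta, centers, model, water_center_hz,
                              pool_sign) {
  k <- length(centers)
  pools <- if (k) {
    e <- theta[2 * seq_len(k) + 1]
    s <- theta[2 * seq_len(k) + 2]
    b <- if (model == "LG") e else e * s
    data.frame(center_hz = centers, b = b, sigma = s)
  } else NULL
  zspec_params(a = theta[1] * theta[2], gamma = theta[2], pools = pools,
               model = model, water_center_hz = water_center_hz,
               pool_sign = pool_sign)
}

# Z values for a theta matrix (npix x p) at offsets omega (length m).
# Returns npix x m. sgn = -1 for dips.
zmodel_batch <- function(theta, omega, centers, model, sgn) {
  npix <- nrow(theta); m <- length(omega)
  dw2 <- (omega)^2  # omega passed already water-centred
  d <- theta[, 1]; g <- theta[, 2]
  D <- outer(g, dw2, "+")              # npix x m
  Z <- 1 - (d * g) / D
  k <- length(centers)
  if (k) for (i in seq_len(k)) {
    e <- theta[, 2 * i + 1]; s <- theta[, 2 * i + 2]
    dp2 <- (omega + 0 - (centers[i]))^2  # centers already water-centred shift
    if (model == "LG") {
      Z <- Z + sgn * e * exp(-outer(1 / s^2, dp2))
    } else {
      Dp <- outer(s, dp2, "+")
      Z <- Z + sgn * (e * s) / Dp
    }
  }
  Z
}

# Jacobian blocks for zmodel_batch: list of npix x m matrices, one per theta
# column, in theta order.
zmodel_jacobian_batch <- function(theta, omega, centers, model, sgn) {
  npix <- nrow(theta); m <- length(omega)
  d <- theta[, 1]; g <- theta[, 2]
  dw2 <- omega^2
  D <- outer(g, dw2, "+")
  J <- vector("list", ncol(theta))
  J[[1]] <- -g / D                                  # dZ/dd
  J[[2]] <- -d * sweep(1 / D^2, 2, dw2, "*")        # dZ/dGamma = -d*dw2/D^2
  k <- length(centers)
  if (k) for (i in seq_len(k)) {
    e <- theta[, 2 * i + 1]; s <- theta[, 2 * i + 2]
    dp2 <- (omega - centers[i])^2
    if (model == "LG") {
      E <- exp(-outer(1 / s^2, dp2))
      J[[2 * i + 1]] <- sgn * E
      J[[2 * i + 2]] <- sgn * (e * E) * outer(2 / s^3, dp2)
    } else {
      Dp <- outer(s, dp2, "+")
      J[[2 * i + 1]] <- sgn * s / Dp
      J[[2 * i + 2]] <- sgn * e * sweep(1 / Dp^2, 2, dp2, "*")
    }
  }
  J
}
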