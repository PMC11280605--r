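#' Reconstruction configuration
#'
#' Parameters of the joint k-omega ADMM reconstruction.
#'
#' @param rho ADMM penalty parameter (affects convergence rate, not the
#'   converged solution); default 0.5.
#' @param epsilon stopping threshold on the mean relative change of the
#'   amplitude images and of the Z-spectrum samples between successive outer
#'   iterations; default 0.001.
#' @param max_outer_iters cap on outer ADMM iterations.
#' @param cgls_max_iters,cgls_tol inner CGLS iteration cap and relative
#'   residual tolerance for the quadratic image updates.
#' @param patch_size odd patch width (pixels) for the local-variance estimate
#'   of the denoiser strength lambda; default 5.
#' @param lambda_scale fraction of the patch-variance mode used as lambda
#'   (0.5 gives the conservative half-mode choice, avoiding over-smoothing).
#' @param denoiser registered denoiser name (see [register_denoiser()]).
#' @param dual_y_uses `"Z"` (dual ascent on `f - f0*Z`, the printed form) or
#'   `"T"` (on the split constraint `f - f0*T`).
#' @param phase_update `"outer"` re-estimates the phase factor from each
#'   complex image solve once per outer iteration; `"never"` keeps the
#'   initial phase.
#' @param mask_frac background threshold for Z-fitting, as a fraction of the
#'   maximum reference amplitude.
#' @param verbose print per-iteration diagnostics.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(rho = 0.5, epsilon = 0.001, max_outer_iters = 100L,
                         cgls_max_iters = 50L, cgls_tol = 1e-6,
                         patch_size = 5L, lambda_scale = 0.5,
                         denoiser = "nlm", dual_y_uses = c("Z", "T"),
                         phase_update = c("outer", "never"),
                         mask_frac = 0.05, verbose = FALSE) {
  dual_y_uses <- match.arg(dual_y_uses)
  phase_update <- match.arg(phase_update)
  if (rho <= 0) stop("rho must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 3")
  if (lambda_scale <= 0 || lambda_scale > 1)
    stop("lambda_scale must be in (0, 1]")
  structure(list(rho = rho, epsilon = epsilon,
                 max_outer_iters = as.integer(max_outer_iters),
                 cgls_max_iters = as.integer(cgls_max_iters),
                 cgls_tol = cgls_tol, patch_size = patch_size,
                 lambda_scale = lambda_scale, denoiser = denoiser,
                 dual_y_uses = dual_y_uses, phase_update = phase_update,
                 mask_frac = mask_frac, verbose = verbose),
            class = "recon_config")
}

cdot <- function(u, v) sum(Re(Conj(u) * v))

#' Conjugate gradient for least squares
#'
#' Minimises \eqn{\|M x - b\|^2} given the forward operator and its adjoint,
#' without forming normal equations. Operators act on (complex) vectors.
#'
#' @param forward function mapping a solution vector to data space.
#' @param adjoint its adjoint (validated by inner-product tests in the
#'   package's test suite).
#' @param rhs data vector b.
#' @param init starting iterate.
#' @param tol relative tolerance on the normal-equation residual
#'   \eqn{\|M^H(b - Mx)\|}.
#' @param max_iters iteration cap.
#' @return list with `x`, `iters`, `relres`, `converged`.
#' @export
cgls_solve <- function(forward, adjoint, rhs, init, tol = 1e-6,
                       max_iters = 50L) {
  x <- init
  r <- rhs - forward(x)
  s <- adjoint(r)
  p <- s
  gamma <- cdot(s, s)
  g0 <- sqrt(gamma)
  if (g0 == 0)
    return(list(x = x, iters = 0L, relres = 0, converged = TRUE))
  iters <- 0L
  while (iters < max_iters) {
    q <- forward(p)
    qq <- cdot(q, q)
    if (qq == 0) break
    alpha <- gamma / qq
    x <- x + alpha * p
    r <- r - alpha * q
    s <- adjoint(r)
    gamma_new <- cdot(s, s)
    iters <- iters + 1L
    if (sqrt(gamma_new) <= tol * g0) {
      gamma <- gamma_new
      break
    }
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  list(x = x, iters = iters, relres = sqrt(gamma) / g0,
       converged = sqrt(gamma) <= tol * g0)
}

#' Local-noise-variance estimate of the denoiser strength
#'
#' Computes the population variance of every dense `patch_size x patch_size`
#' patch fully inside the image, takes the mode of the variance histogram
#' (64 equal-width bins over the observed range, mode = centre of the tallest
#' bin), and returns `lambda_scale` times the mode — a conservative noise
#' estimate that avoids over-smoothing structured regions.
#'
#' @param image numeric matrix, larger than the patch.
#' @param patch_size odd patch width in pixels.
#' @param lambda_scale fraction of the mode returned.
#' @param nbins number of histogram bins.
#' @return non-negative scalar lambda (variance units).
#' @export
estimate_lambda <- function(image, patch_size = 5L, lambda_scale = 0.5,
                            nbins = 64L) {
  k <- as.integer(patch_size)
  if (nrow(image) < k || ncol(image) < k)
    stop("image must be larger than the patch")
  box <- function(m) {
    cs <- apply(m, 2, cumsum)
    rs <- rbind(cs[k, , drop = FALSE],
                cs[(k + 1):nrow(m), , drop = FALSE] -
                  cs[1:(nrow(m) - k), , drop = FALSE])
    cs2 <- t(apply(rs, 1, cumsum))
    cbind(cs2[, k, drop = FALSE],
          cs2[, (k + 1):ncol(m), drop = FALSE] -
            cs2[, 1:(ncol(m) - k), drop = FALSE])
  }
  n <- k * k
  s1 <- box(image)
  s2 <- box(image^2)
  v <- pmax(s2 / n - (s1 / n)^2, 0)
  vmax <- max(v)
  if (vmax <= 0) return(0)
  h <- tabulate(pmin(floor(as.vector(v) / vmax * nbins) + 1L, nbins),
                nbins = nbins)
  mode_center <- (which.max(h) - 0.5) * vmax / nbins
  lambda_scale * mode_center
}

# ---- ADMM building blocks --------------------------------------------------
# State arrays are ny x nx x m (m offsets). The reference slice of Z and T is
# identically 1 (the unsaturated acquisition: Z(omega0) = 1 trivially) and
# carries zero y/t duals; the Eq-coupling constraints act at omega != omega0.

# Quadratic update of f at one offset w != ref: minimise
# 1/2 |F A f - g|^2 + rho/2 |f - (f0 T - y/rho)|^2 + rho/2 |f - (v + z/rho)|^2
# as a stacked least-squares problem solved by CGLS.
update_f_slice <- function(g_w, A_w, c1, c2, rho, init, cfg) {
  n <- length(g_w)
  sr <- sqrt(rho)
  fwd <- function(u) {
    um <- matrix(u, nrow(A_w))
    c(as.vector(fft2c(A_w * um)), sr * u, sr * u)
  }
  adj <- function(w) {
    w1 <- matrix(w[seq_len(n)], nrow(A_w))
    as.vector(Conj(A_w) * ifft2c(w1)) + sr * w[n + seq_len(n)] +
      sr * w[2 * n + seq_len(n)]
  }
  rhs <- c(as.vector(g_w), sr * as.vector(c1), sr * as.vector(c2))
  sol <- cgls_solve(fwd, adj, rhs, as.vector(init) + 0i,
                    tol = cfg$cgls_tol, max_iters = cfg$cgls_max_iters)
  matrix(sol$x, nrow(A_w))
}

# Quadratic update of the reference image f0: its data fidelity plus the
# penalties of every w != ref through T (the step where information from all
# offsets flows into f0), plus the denoising penalty at ref.
update_f0_slice <- function(g0, A0, Tm, c_t, c2, rho, init, cfg) {
  # Tm: n x nw matrix of T slices (columns); c_t: n x nw targets f_w + y_w/rho
  n <- length(g0)
  sr <- sqrt(rho)
  fwd <- function(u) {
    um <- matrix(u, nrow(A0))
    c(as.vector(fft2c(A0 * um)), sr * as.vector(Tm * u), sr * u)
  }
  adj <- function(w) {
    w1 <- matrix(w[seq_len(n)], nrow(A0))
    wt <- matrix(w[n + seq_len(n * ncol(Tm))], n)
    as.vector(Conj(A0) * ifft2c(w1)) + sr * rowSums(Tm * wt) +
      sr * w[n + n * ncol(Tm) + seq_len(n)]
  }
  rhs <- c(as.vector(g0), sr * as.vector(c_t), sr * as.vector(c2))
  sol <- cgls_solve(fwd, adj, rhs, as.vector(init) + 0i,
                    tol = cfg$cgls_tol, max_iters = cfg$cgls_max_iters)
  matrix(sol$x, nrow(A0))
}

# Closed-form update of the auxiliary spectrum T (per pixel, per offset):
# T = (rho Z - t + f0 y + rho f f0) / (rho f0^2 + rho).
update_T <- function(f, f0, Z, y, t, rho) {
  m <- dim(f)[3]
  f0b <- array(f0, dim(f))
  (rho * Z - t + f0b * y + rho * f * f0b) / (rho * f0b^2 + rho)
}

# Dual ascent (as printed; y can optionally ascend on the T-form constraint).
update_duals <- function(state, rho, dual_y_uses) {
  f0b <- array(state$f0, dim(state$f))
  yc <- if (dual_y_uses == "Z") state$Zs else state$T
  state$y <- state$y + rho * (state$f - f0b * yc)
  state$z <- state$z + rho * (state$v - state$f)
  state$t <- state$t + rho * (state$T - state$Zs)
  state$y[, , state$ref] <- 0
  state$t[, , state$ref] <- 0
  state
}

# Z update: per non-background pixel, least-squares projection of the
# unconstrained minimiser T + t/rho onto the multi-pool model family,
# evaluated back onto the grid. Returns samples + fitted theta.
update_Z <- function(state, grid, centers, model, pool_sign, theta_warm) {
  m <- dim(state$f)[3]
  sel <- setdiff(seq_len(m), state$ref)
  target <- state$T + state$t / state$rho
  tm <- matrix(target, ncol = m)[state$mask_idx, sel, drop = FALSE]
  fit <- fit_zspectrum_map(tm, grid$offsets_hz[sel], centers, model = model,
                           init = theta_warm,
                           water_center_hz = grid$water_offset_hz,
                           pool_sign = pool_sign,
                           maxit = 30L, xtol = 1e-9)
  sgn <- if (pool_sign == "dip") -1 else 1
  zfit <- zmodel_batch(fit$theta, grid$offsets_hz - grid$water_offset_hz,
                       centers - grid$water_offset_hz, model, sgn)
  Zs <- array(1, dim(state$f))
  zm <- matrix(Zs, ncol = m)
  zm[state$mask_idx, ] <- zfit
  zm[, state$ref] <- 1
  Zs <- array(zm, dim(state$f))
  list(Zs = Zs, theta = fit$theta)
}

# PnP denoising of v = D(f - z/rho) per offset with per-offset lambda.
denoise_v <- function(state, cfg) {
  den <- get_denoiser(cfg$denoiser)
  m <- dim(state$f)[3]
  v <- state$f
  for (w in seq_len(m)) {
    x <- state$f[, , w] - state$z[, , w] / state$rho
    lam <- estimate_lambda(x, cfg$patch_size, cfg$lambda_scale)
    v[, , w] <- den(x, lam)
  }
  v
}

fidelity_residual <- function(f, A, ks) {
  m <- dim(f)[3]
  tot <- 0
  for (w in seq_len(m))
    tot <- tot + sum(Mod(fft2c(A[, , w] * f[, , w]) - ks$data[, , w])^2)
  sqrt(tot)
}

recon_result <- function(images, phase, zfit, history, converged, method) {
  structure(list(images = images, phase = phase, zfit = zfit,
                 history = history, converged = converged, method = method),
            class = "cest_recon")
}

#' @export
print.cest_recon <- function(x, ...) {
  cat(sprintf("<cest_recon> method '%s', %d iterations, converged: %s\n",
              x$method, nrow(x$history), x$converged))
  invisible(x)
}

#' Parameter maps of a reconstruction's Z-spectrum fit
#'
#' @param result a `cest_recon` from [conventional_reconstruct()] or
#'   [joint_reconstruct()].
#' @return named list of matrices (`a`, `gamma`, `pool<i>_b`,
#'   `pool<i>_sigma`) with `NA` at masked background pixels.
#' @export
zparam_maps <- function(result) {
  zf <- result$zfit
  sh <- dim(result$images$data)[1:2]
  k <- length(zf$centers)
  blank <- matrix(NA_real_, sh[1], sh[2])
  to_map <- function(vals) { m <- blank; m[zf$mask_idx] <- vals; m }
  d <- zf$theta[, 1]; g <- zf$theta[, 2]
  out <- list(a = to_map(d * g), gamma = to_map(g))
  if (k) for (i in seq_len(k)) {
    e <- zf$theta[, 2 * i + 1]; s <- zf$theta[, 2 * i + 2]
    b <- if (zf$model == "LG") e else e * s
    out[[sprintf("pool%d_b", i)]] <- to_map(b)
    out[[sprintf("pool%d_sigma", i)]] <- to_map(s)
  }
  out
}

#' Conventional two-step reconstruction (FFT + pixel-wise fit)
#'
#' The baseline: each offset's image is reconstructed independently by
#' inverse FFT, then the normalised spectra \eqn{f(x,\omega)/f(x,\omega_0)}
#' of non-background pixels are fitted pixel-by-pixel to the multi-pool
#' model. The returned images are the per-offset FFT magnitudes.
#'
#' @param ks a [kspace_series()].
#' @param centers_hz fixed pool centre frequencies in Hz.
#' @param model `"LG"` or `"LL"`.
#' @param cfg a [recon_config()] (only `mask_frac` and model options used).
#' @param pool_sign `"dip"` or `"literal"`.
#' @return a `cest_recon` result.
#' @export
conventional_reconstruct <- function(ks, centers_hz = ks$grid$pool_offsets_hz,
                                     model = c("LG", "LL"),
                                     cfg = recon_config(),
                                     pool_sign = "dip") {
  model <- match.arg(model)
  grid <- ks$grid
  fr <- fft_recon(ks)
  f <- fr$images$data
  m <- dim(f)[3]
  f0 <- f[, , grid$ref_index]
  mask <- f0 >= cfg$mask_frac * max(f0)
  mask_idx <- which(mask)
  sel <- setdiff(seq_len(m), grid$ref_index)
  fm <- matrix(f, ncol = m)
  Y <- fm[mask_idx, sel, drop = FALSE] / fm[mask_idx, grid$ref_index]
  fit <- fit_zspectrum_map(Y, grid$offsets_hz[sel], centers_hz, model = model,
                           water_center_hz = grid$water_offset_hz,
                           pool_sign = pool_sign)
  zfit <- list(theta = fit$theta, mask_idx = mask_idx, centers = centers_hz,
               model = model, water_center_hz = grid$water_offset_hz,
               pool_sign = pool_sign, mae = fit$mae,
               converged = fit$converged)
  recon_result(fr$images, fr$phase, zfit,
               history = data.frame(), converged = NA, method = "conventional")
}

#' Joint k-omega ADMM reconstruction
#'
#' Reconstructs amplitude images at all offsets simultaneously by solving
#' the penalised data-fidelity problem subject to the pixel-wise Z-spectrum
#' self-consistency constraint \eqn{f(x,\omega) = f(x,\omega_0) Z(x,\omega)},
#' using ADMM: CGLS solves of the quadratic image subproblems (the reference
#' image update couples information from all offsets), pixel-wise model
#' fitting for Z, plug-and-play spatial denoising for the regularisation
#' proximal step, a closed-form auxiliary-spectrum update, and dual ascent.
#' Initialised from the conventional reconstruction; updates use the freshest
#' available peers (Gauss-Seidel ordering following the update listing).
#' Iterations stop when the mean relative change of both the images and the
#' Z-spectrum samples falls below `cfg$epsilon`, or at
#' `cfg$max_outer_iters`. A divergence guard aborts (with `converged =
#' FALSE` and a diagnostic attribute) if the data-fidelity residual grows
#' 10-fold over 5 iterations.
#'
#' @inheritParams conventional_reconstruct
#' @return a `cest_recon` result whose `history` holds per-iteration relative
#'   changes, fidelity residuals and constraint violations.
#' @export
joint_reconstruct <- function(ks, centers_hz = ks$grid$pool_offsets_hz,
                              model = c("LG", "LL"), cfg = recon_config(),
                              pool_sign = "dip") {
  model <- match.arg(model)
  grid <- ks$grid
  rho <- cfg$rho
  m <- n_offsets(grid)
  ref <- grid$ref_index
  conv0 <- conventional_reconstruct(ks, centers_hz, model, cfg, pool_sign)
  dims <- dim(conv0$images$data)
  sgn <- if (pool_sign == "dip") -1 else 1
  omega_c <- grid$offsets_hz - grid$water_offset_hz
  centers_c <- centers_hz - grid$water_offset_hz

  state <- list(
    f = conv0$images$data,
    A = conv0$phase$data,
    f0 = conv0$images$data[, , ref],
    rho = rho, ref = ref,
    mask_idx = conv0$zfit$mask_idx,
    y = array(0, dims), z = array(0, dims), t = array(0, dims))
  theta <- conv0$zfit$theta
  zfit0 <- zmodel_batch(theta, omega_c, centers_c, model, sgn)
  Zs <- array(1, dims)
  zm <- matrix(Zs, ncol = m)
  zm[state$mask_idx, ] <- zfit0
  zm[, ref] <- 1
  state$Zs <- array(zm, dims)
  state$v <- state$f
  state$T <- state$Zs

  hist_rows <- list()
  converged <- FALSE
  guard_tripped <- FALSE
  for (k in seq_len(cfg$max_outer_iters)) {
    f_old <- state$f
    Z_old <- state$Zs
    f0b <- array(state$f0, dims)
    # --- image updates (CGLS), phase factored out of the complex solve
    for (w in setdiff(seq_len(m), ref)) {
      c1 <- f0b[, , w] * state$T[, , w] - state$y[, , w] / rho
      c2 <- state$v[, , w] + state$z[, , w] / rho
      sol <- update_f_slice(ks$data[, , w], state$A[, , w], c1, c2, rho,
                            state$f[, , w], cfg)
      state$f[, , w] <- Mod(sol)
      if (cfg$phase_update == "outer") {
        ph <- Arg(sol)
        keep <- Mod(sol) < 1e-12 * max(Mod(sol))
        ph[keep] <- 0
        state$A[, , w] <- state$A[, , w] * exp(1i * ph)
      }
    }
    sel <- setdiff(seq_len(m), ref)
    Tm <- matrix(state$T[, , sel], ncol = length(sel))
    c_t <- matrix(state$f[, , sel] + state$y[, , sel] / rho,
                  ncol = length(sel))
    c2 <- state$v[, , ref] + state$z[, , ref] / rho
    sol0 <- update_f0_slice(ks$data[, , ref], state$A[, , ref], Tm, c_t, c2,
                            rho, state$f0, cfg)
    state$f[, , ref] <- Mod(sol0)
    state$f0 <- state$f[, , ref]
    if (cfg$phase_update == "outer") {
      ph <- Arg(sol0)
      ph[Mod(sol0) < 1e-12 * max(Mod(sol0))] <- 0
      state$A[, , ref] <- state$A[, , ref] * exp(1i * ph)
    }
    # --- Z update (model projection of T + t/rho)
    zu <- update_Z(state, grid, centers_hz, model, pool_sign, theta)
    state$Zs <- zu$Zs
    theta <- zu$theta
    # --- PnP denoising
    state$v <- denoise_v(state, cfg)
    # --- closed-form T update, then dual ascent
    state$T <- update_T(state$f, state$f0, state$Zs, state$y, state$t, rho)
    state$T[, , ref] <- 1
    state <- update_duals(state, rho, cfg$dual_y_uses)

    f0b <- array(state$f0, dims)
    rel_f <- mean(abs(state$f - f_old)) / max(mean(abs(f_old)), 1e-300)
    rel_z <- mean(abs(state$Zs - Z_old)[, , sel]) /
      max(mean(abs(Z_old)[, , sel]), 1e-300)
    fid <- fidelity_residual(state$f, state$A, ks)
    cons_fz <- mean(abs(state$f - f0b * state$Zs)[, , sel])
    cons_vf <- mean(abs(state$v - state$f))
    cons_tz <- mean(abs(state$T - state$Zs)[, , sel])
    hist_rows[[k]] <- data.frame(iter = k, rel_change_f = rel_f,
                                 rel_change_z = rel_z, fidelity = fid,
                                 constraint_fz = cons_fz,
                                 constraint_vf = cons_vf,
                                 constraint_tz = cons_tz)
    if (cfg$verbose)
      message(sprintf(
        "iter %3d  rel_f %.3e  rel_z %.3e  fid %.4e  |f-f0Z| %.3e",
        k, rel_f, rel_z, fid, cons_fz))
    if (rel_f < cfg$epsilon && rel_z < cfg$epsilon) {
      converged <- TRUE
      break
    }
    if (k >= 5) {
      fids <- vapply(hist_rows[(k - 4):k], function(r) r$fidelity, 0)
      if (fids[5] > 10 * min(fids)) {
        guard_tripped <- TRUE
        warning("joint_reconstruct: data-fidelity residual grew 10x over 5 ",
                "iterations; aborting")
        break
      }
    }
  }
  history <- do.call(rbind, hist_rows)
  zfit <- list(theta = theta, mask_idx = state$mask_idx, centers = centers_hz,
               model = model, water_center_hz = grid$water_offset_hz,
               pool_sign = pool_sign)
  phase <- structure(list(data = state$A, grid = grid), class = "cest_phase")
  res <- recon_result(image_series(state$f, grid), phase, zfit, history,
                      converged, method = "joint")
  attr(res, "diverged") <- guard_tripped
  res
}
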