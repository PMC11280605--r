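# CGLS, ADMM building blocks, and the two reconstructions.

test_that("CGLS solves trivial and dense-oracle systems", {
  # identity operator: solution = rhs in one iteration
  id <- function(x) x
  r <- complex(real = stats::rnorm(16), imaginary = stats::rnorm(16))
  sol <- cgls_solve(id, id, r, init = rep(0 + 0i, 16))
  expect_lt(max(Mod(sol$x - r)), 1e-12)
  expect_lte(sol$iters, 2L)
  # dense 8x8 least squares vs normal-equations solve
  set.seed(5)
  M <- matrix(stats::rnorm(12 * 8), 12, 8)
  b <- stats::rnorm(12)
  fwd <- function(x) as.vector(M %*% x)
  adj <- function(y) as.vector(t(M) %*% y)
  sol2 <- cgls_solve(fwd, adj, b, init = rep(0, 8), tol = 1e-12,
                     max_iters = 100L)
  direct <- solve(t(M) %*% M, t(M) %*% b)
  expect_lt(max(abs(sol2$x - direct)), 1e-8)
  # starting at the exact solution returns immediately
  sol3 <- cgls_solve(fwd, adj, as.vector(M %*% direct), init = direct)
  expect_equal(sol3$iters, 0L)
  expect_equal(sol3$relres, 0)
})

test_that("Fourier operators pass the adjoint inner-product test", {
  set.seed(31)
  for (rep in 1:10) {
    u <- matrix(complex(real = stats::rnorm(64), imaginary = stats::rnorm(64)),
                8, 8)
    w <- matrix(complex(real = stats::rnorm(64), imaginary = stats::rnorm(64)),
                8, 8)
    lhs <- sum(Re(Conj(fft2c(u)) * w))
    rhs <- sum(Re(Conj(u) * ifft2c(w)))
    expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
  }
})

test_that("closed-form T update equals the numeric minimiser", {
  upd <- function(f, f0, Z, y, t, rho)
    (rho * Z - t + f0 * y + rho * f * f0) / (rho * f0^2 + rho)
  set.seed(7)
  for (rep in 1:10) {
    f <- stats::runif(1); f0 <- stats::runif(1, 0.1, 1)
    Z <- stats::runif(1); y <- stats::rnorm(1); t <- stats::rnorm(1)
    rho <- stats::runif(1, 0.1, 2)
    obj <- function(T_) y * (f - f0 * T_) + rho / 2 * (f - f0 * T_)^2 +
      t * (T_ - Z) + rho / 2 * (T_ - Z)^2
    num <- stats::optimize(obj, c(-10, 10), tol = 1e-12)$minimum
    h <- 1e-4   # FD Newton polish: exact for a quadratic objective
    g1 <- (obj(num + h) - obj(num - h)) / (2 * h)
    g2 <- (obj(num + h) - 2 * obj(num) + obj(num - h)) / h^2
    num <- num - g1 / g2
    expect_lt(abs(upd(f, f0, Z, y, t, rho) - num), 1e-8)
  }
  # consistent point is a fixed point: y = t = 0 and f = f0 * Z -> T = Z
  expect_equal(upd(0.5 * 0.8, 0.5, 0.8, 0, 0, 0.5), 0.8)
  # y = t = 0, f0 = 1 -> equal-weight average of Z and f
  expect_equal(upd(0.6, 1, 0.9, 0, 0, 0.5), (0.9 + 0.6) / 2)
  # array version agrees
  arr <- cestrecon:::update_T(array(0.4, c(2, 2, 3)), matrix(0.5, 2, 2),
                              array(0.8, c(2, 2, 3)),
                              array(0.1, c(2, 2, 3)),
                              array(-0.2, c(2, 2, 3)), 0.5)
  expect_equal(arr[1, 1, 1], upd(0.4, 0.5, 0.8, 0.1, -0.2, 0.5))
})

test_that("Z-update target is the calculus solution T + t/rho", {
  set.seed(11)
  for (rep in 1:5) {
    T_ <- stats::runif(1); t <- stats::rnorm(1); rho <- stats::runif(1, 0.1, 2)
    obj <- function(Z) t * (T_ - Z) + rho / 2 * (T_ - Z)^2
    span <- abs(t) / rho + 2
    num <- stats::optimize(obj, c(T_ - span, T_ + span), tol = 1e-12)$minimum
    expect_lt(abs(num - (T_ + t / rho)), 1e-6)
  }
})

test_that("dual updates are linear and additive", {
  dims <- c(2, 2, 3)
  state <- list(f = array(0.4, dims), f0 = matrix(0.5, 2, 2),
                Zs = array(0.8, dims), v = array(0.4, dims),
                T = array(0.8, dims),
                y = array(0, dims), z = array(0, dims), t = array(0, dims),
                ref = 1L)
  rho <- 0.5
  # exact constraints -> duals unchanged
  s0 <- state; s0$f <- array(0.5 * 0.8, dims); s0$v <- s0$f
  s0 <- cestrecon:::update_duals(s0, rho, "Z")
  expect_equal(max(abs(s0$y)), 0)
  expect_equal(max(abs(s0$z)), 0)
  expect_equal(max(abs(s0$t)), 0)
  # residual r increments y by rho * r, twice by 2 rho r
  s1 <- cestrecon:::update_duals(state, rho, "Z")
  r <- 0.4 - 0.5 * 0.8
  expect_equal(s1$y[1, 1, 2], rho * r)
  s2 <- cestrecon:::update_duals(s1, rho, "Z")
  expect_equal(s2$y[1, 1, 2], 2 * rho * r)
  # the reference slice carries no spectrum-constraint duals
  expect_equal(max(abs(s1$y[, , 1])), 0)
  expect_equal(max(abs(s1$t[, , 1])), 0)
})

test_that("lambda estimation calibrates to the noise variance", {
  expect_equal(estimate_lambda(matrix(7, 32, 32)), 0)
  set.seed(2)
  img <- matrix(stats::rnorm(128 * 128, sd = 0.1), 128, 128)
  lam <- estimate_lambda(img, 5L, 0.5)
  expect_lt(abs(lam - 0.5 * 0.01) / (0.5 * 0.01), 0.25)
  # adding noise to a structured image cannot lower the estimate much
  scene <- brain_scene(64L)
  clean <- synthesize_series(scene)$data[, , 10]
  noisy <- clean + matrix(stats::rnorm(64 * 64, sd = 0.05), 64, 64)
  expect_gte(estimate_lambda(noisy), estimate_lambda(clean))
})

test_that("denoiser registry enforces the plug-and-play contract", {
  expect_error(get_denoiser("no_such"), "unknown denoiser")
  img <- matrix(stats::rnorm(64), 8, 8)
  # lambda <= 0 is the identity for all bundled denoisers
  for (nm in c("nlm", "gaussian", "identity"))
    expect_identical(get_denoiser(nm)(img, 0), img)
  # a user-registered denoiser is picked up by name
  register_denoiser("blur_test", function(image, lambda)
    denoise_gaussian(image, lambda, sigma_px = 2))
  expect_equal(get_denoiser("blur_test")(img, 1),
               denoise_gaussian(img, 1, sigma_px = 2))
  # denoising a noisy piecewise-constant image reduces MSE to the truth
  scene <- brain_scene(32L)
  clean <- synthesize_series(scene)$data[, , 10]
  set.seed(4)
  noisy <- clean + matrix(stats::rnorm(32 * 32, sd = 0.05), 32, 32)
  den <- denoise_nlm(noisy, 0.05^2)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("conventional reconstruction recovers scene parameters noiselessly", {
  scene <- brain_scene(32L)
  sim <- simulate_acquisition(scene)
  res <- conventional_reconstruct(sim$kspace)
  maps <- zparam_maps(res)
  # air is masked, no fit attempted there
  expect_true(all(is.na(maps$a[scene$label_map == "air"])))
  # per-compartment parameter recovery <= 1e-4 relative
  for (nm in c("tissue", "cest_roi")) {
    px <- scene$label_map == nm
    truth <- scene$compartment_params[[nm]]
    expect_lt(max(abs(maps$a[px] - truth$a)) / truth$a, 1e-4)
    expect_lt(max(abs(maps$gamma[px] - truth$gamma)) / truth$gamma, 1e-4)
  }
  px <- scene$label_map == "cest_roi"
  expect_lt(max(abs(zparam_maps(res)$pool1_b[px] - 0.10)) / 0.10, 1e-4)
  # reconstructed magnitudes equal the truth
  expect_lt(max(abs(res$images$data - sim$truth$data)), 1e-12)
})

test_that("joint reconstruction honours the stopping rule edge cases", {
  scene <- brain_scene(16L)
  sim <- simulate_acquisition(scene, noise_level = 0.1, seed = 9)
  # epsilon = Inf returns after one outer iteration, converged
  res <- joint_reconstruct(sim$kspace,
                           cfg = recon_config(epsilon = Inf,
                                              max_outer_iters = 50))
  expect_true(res$converged)
  expect_equal(nrow(res$history), 1L)
  # history schema
  expect_true(all(c("rel_change_f", "rel_change_z", "fidelity",
                    "constraint_fz") %in% names(res$history)))
  # phase factors remain unit-modulus after re-estimation
  expect_lt(max(abs(Mod(res$phase$data) - 1)), 1e-12)
  # a swapped-in denoiser runs the identical pipeline
  res2 <- joint_reconstruct(sim$kspace,
                            cfg = recon_config(epsilon = Inf,
                                               max_outer_iters = 50,
                                               denoiser = "identity"))
  expect_equal(nrow(res2$history), 1L)
})

test_that("joint reconstruction is deterministic given the seed", {
  scene <- brain_scene(16L)
  sim1 <- simulate_acquisition(scene, noise_level = 0.15, seed = 21)
  sim2 <- simulate_acquisition(scene, noise_level = 0.15, seed = 21)
  expect_identical(sim1$kspace$data, sim2$kspace$data)
  cfg <- recon_config(max_outer_iters = 2)
  r1 <- joint_reconstruct(sim1$kspace, cfg = cfg)
  r2 <- joint_reconstruct(sim2$kspace, cfg = cfg)
  expect_identical(r1$images$data, r2$images$data)
  expect_identical(r1$history, r2$history)
})
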