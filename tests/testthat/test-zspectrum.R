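# Multi-pool Z-spectrum model, fitting, and MTR asymmetry.

test_that("model evaluation matches closed forms", {
  # empty model
  p0 <- zspec_params(a = 0, gamma = 100)
  expect_equal(eval_zmodel(p0, seq(-500, 500, 100)), rep(1, 11))
  # water-only at the centre: Z = 1 - a/Gamma; even symmetry
  pw <- zspec_params(a = 3000, gamma = 10000)
  expect_equal(eval_zmodel(pw, 0), 1 - 3000 / 10000)
  d <- seq(50, 500, 50)
  expect_equal(eval_zmodel(pw, d), eval_zmodel(pw, -d))
  # pool sign conventions: dip subtracts, literal adds
  pd <- ref_lg_params()
  pl <- pd; pl$pool_sign <- "literal"
  w <- 450
  water_part <- 1 - pd$a / (w^2 + pd$gamma)
  expect_equal(eval_zmodel(pd, w), water_part - 0.10)
  expect_equal(eval_zmodel(pl, w), water_part + 0.10)
  # LL pools mirror the water term's form
  pll <- zspec_params(a = 3000, gamma = 10000,
                      pools = data.frame(center_hz = 450, b = 500,
                                         sigma = 10000),
                      model = "LL")
  expect_equal(eval_zmodel(pll, 450),
               1 - 3000 / (450^2 + 10000) - 500 / 10000)
  expect_error(eval_zmodel(pd, NaN), "finite")
})

test_that("parameter constructor enforces invariants", {
  expect_error(zspec_params(a = -1, gamma = 10), ">= 0")
  expect_error(zspec_params(a = 1, gamma = 0), "> 0")
  expect_error(zspec_params(a = 1, gamma = 10,
                            pools = data.frame(center_hz = 1, b = 1,
                                               sigma = -5)),
               "> 0")
})

test_that("noiseless fits recover parameters from perturbed inits", {
  p <- ref_lg_params()
  om <- grid51()$offsets_hz
  z <- eval_zmodel(p, om)
  init <- p
  init$a <- p$a * 0.9; init$gamma <- p$gamma * 1.1
  init$pools$b <- p$pools$b * 1.1; init$pools$sigma <- p$pools$sigma * 0.9
  fit <- fit_zspectrum(z, om, centers_hz = 450, model = "LG", init = init)
  expect_lt(abs(fit$params$a - p$a) / p$a, 1e-6)
  expect_lt(abs(fit$params$gamma - p$gamma) / p$gamma, 1e-6)
  expect_lt(abs(fit$params$pools$b - p$pools$b) / p$pools$b, 1e-6)
  expect_lt(abs(fit$params$pools$sigma - p$pools$sigma) / p$pools$sigma,
            1e-6)
  expect_lt(fit$mae, 1e-10)
  # data-driven default initialisation reaches the same solution
  fit2 <- fit_zspectrum(z, om, centers_hz = 450, model = "LG")
  expect_lt(fit2$mae, 1e-10)
})

test_that("flat and degenerate spectra return the zero-amplitude model", {
  om <- grid51()$offsets_hz
  fit <- fit_zspectrum(rep(1, length(om)), om, centers_hz = 450)
  expect_equal(fit$params$a, 0)
  expect_equal(fit$params$pools$b, 0)
  expect_equal(fit$mae, 0)
  expect_true(fit$degenerate)
  expect_error(fit_zspectrum(c(1, 1, 1), c(-50, 0, 50), centers_hz = 450),
               "at least")
})

test_that("batched map fit agrees with an independent LM implementation", {
  skip_if_not_installed("minpack.lm")
  p <- ref_lg_params()
  om <- grid51()$offsets_hz
  set.seed(99)
  z <- eval_zmodel(p, om) + rnorm(length(om), sd = 0.01)
  fit <- fit_zspectrum(z, om, centers_hz = 450, model = "LG")
  # oracle: minpack.lm on the same depth parameterisation and bounds
  model_fn <- function(th) {
    1 - th[1] * th[2] / (om^2 + th[2]) - th[3] * exp(-(om - 450)^2 / th[4]^2)
  }
  span <- diff(range(om))
  nls_fit <- minpack.lm::nls.lm(
    par = c(0.85, 150^2, 0.08, 150),
    lower = c(0, 1e-8 * span^2, 0, 1e-3 * span),
    upper = c(1.5, span^2, 1.5, span),
    fn = function(th) model_fn(th) - z,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  th <- nls_fit$par
  expect_equal(fit$params$a, th[1] * th[2], tolerance = 1e-4)
  expect_equal(fit$params$gamma, th[2], tolerance = 1e-4)
  expect_equal(fit$params$pools$b, th[3], tolerance = 1e-4)
  expect_equal(fit$params$pools$sigma, th[4], tolerance = 1e-4)
})

test_that("model comparison prefers the matching lineshape family", {
  om <- grid51()$offsets_hz
  # LG truth
  zg <- eval_zmodel(ref_lg_params(), om)
  cg <- compare_fits(zg, om, centers_hz = 450, reference = zg)
  expect_lte(cg$mae_lg, cg$mae_ll)
  expect_gte(cg$reduction_pct, 0)
  # LL truth
  pll <- zspec_params(a = 0.9 * 200^2, gamma = 200^2,
                      pools = data.frame(center_hz = 450, b = 0.10 * 120^2,
                                         sigma = 120^2),
                      model = "LL")
  zl <- eval_zmodel(pll, om)
  cl <- compare_fits(zl, om, centers_hz = 450, reference = zl)
  expect_lte(cl$mae_ll, cl$mae_lg)
  # reference equal to the LG fit's own prediction -> zero MAE
  fitg <- fit_zspectrum(zg, om, centers_hz = 450, model = "LG")
  pred <- eval_zmodel(fitg$params, om)
  cself <- compare_fits(zg, om, centers_hz = 450, reference = pred)
  expect_lt(cself$mae_lg, 1e-12)
  expect_error(compare_fits(zg, om, centers_hz = 450, reference = zg[-1]),
               "same grid")
})

test_that("MTR asymmetry follows its definition and invariances", {
  expect_equal(mtr_asymmetry(0.9, 0.7, 1), 0.2)
  expect_equal(mtr_asymmetry(0.5, 0.5, 2), 0)
  expect_equal(mtr_asymmetry(0.9, 0.7, 1),
               mtr_asymmetry(0.9 * 7, 0.7 * 7, 7))
  expect_true(is.na(mtr_asymmetry(0.9, 0.7, 0)))
  expect_true(is.na(mtr_asymmetry(0.9, 0.7, -1)))
})

test_that("MTR asymmetry maps vanish for symmetric spectra and mask air", {
  # water-only scene: symmetric Z -> zero asymmetry on unmasked pixels
  scene <- water_scene(8L)
  f <- synthesize_series(scene)
  m <- mtr_asymmetry_map(f, 450)
  expect_lt(max(abs(m), na.rm = TRUE), 1e-14)
  # brain phantom: insert pixels equal the analytic pool dip difference
  scene2 <- brain_scene(32L)
  f2 <- synthesize_series(scene2)
  m2 <- mtr_asymmetry_map(f2, 450)
  p <- scene2$compartment_params$cest_roi
  expected <- eval_zmodel(p, -450) - eval_zmodel(p, 450)
  insert <- scene2$label_map == "cest_roi"
  expect_equal(unique(round(m2[insert], 12)), round(expected, 12))
  # air masked
  expect_true(all(is.na(m2[scene2$label_map == "air"])))
  # fully-zero reference -> fully masked map
  f3 <- f2; f3$data[, , f3$grid$ref_index] <- 0
  expect_true(all(is.na(mtr_asymmetry_map(f3, 450))))
  # requesting a frequency whose mirror is absent errors with alternatives
  expect_error(mtr_asymmetry_map(f2, 475), "nearest")
})
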