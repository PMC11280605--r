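# Frequency grid, phantom construction and forward simulation.

test_that("frequency grid validates its invariants", {
  expect_error(freq_grid(c(0, 0, 50), 1), "unique")
  expect_error(freq_grid(c(-50, 0, 50), 7), "out of range")
  g <- freq_grid(seq(-100, 100, 50), ref_index = 1, pool_offsets_hz = 60)
  expect_true(60 %in% g$off_grid)   # off-grid pools are flagged, not fatal
  expect_equal(offset_index(g, -100), 1L)
  expect_error(offset_index(g, 30), "nearest available")
})

test_that("brain preset reproduces the 51-offset schedule with a 450 Hz pool", {
  scene <- brain_scene(128L)
  expect_equal(length(scene$grid$offsets_hz), 51L)
  expect_equal(range(scene$grid$offsets_hz), c(-1250, 1250))
  expect_equal(unique(diff(scene$grid$offsets_hz)), 50)
  expect_equal(scene$grid$pool_offsets_hz, 450)
  expect_equal(scene$grid$offsets_hz[scene$grid$ref_index], -1250)
  expect_true(all(scene$s0_map >= 0))
  expect_setequal(unique(as.vector(scene$label_map)),
                  names(scene$compartment_params))
  # ROI masks disjoint from designated background
  bg <- scene$roi_masks[[scene$background]]
  for (nm in setdiff(names(scene$roi_masks), scene$background))
    expect_false(any(scene$roi_masks[[nm]] & bg))
})

test_that("phantom spec validation catches bad inputs", {
  spec <- phantom_preset("simulated_brain", c(16L, 16L))
  bad <- spec
  bad$shape <- c(-4L, 16L)
  expect_error(build_phantom(bad), "positive")
  bad2 <- spec
  bad2$compartments[[1]]$geometry$type <- "blob"
  expect_error(build_phantom(bad2), "unknown geometry")
})

test_that("synthesized series obeys the Z-spectrum forward model", {
  scene <- water_scene(8L)
  f <- synthesize_series(scene)
  g <- scene$grid
  # reference slice equals s0 exactly
  expect_identical(f$data[, , g$ref_index], scene$s0_map)
  # water-only: symmetric about omega1 = 0 for grid-symmetric offsets
  ip <- offset_index(g, 450); im <- offset_index(g, -450)
  expect_equal(f$data[, , ip], f$data[, , im], tolerance = 1e-14)
  # zero-amplitude compartment: f identical to s0 at every offset
  flat <- build_phantom(list(
    shape = c(4L, 4L),
    grid = list(offsets_hz = seq(-200, 200, 100), ref_index = 1),
    compartments = list(list(name = "x",
                             geometry = list(type = "background"),
                             s0 = 2, zspec = list(a = 0, gamma = 100)))))
  ff <- synthesize_series(flat)
  for (w in seq_len(5)) expect_equal(ff$data[, , w], flat$s0_map)
  # bounded by the reference whenever 0 <= Z <= 1
  scene2 <- brain_scene(16L)
  f2 <- synthesize_series(scene2)
  s0 <- array(scene2$s0_map, dim(f2$data))
  expect_true(all(f2$data <= s0 + 1e-12) && all(f2$data >= 0))
})

test_that("Fourier encoding round-trips and is unitary", {
  scene <- brain_scene(16L)
  sim <- simulate_acquisition(scene)
  af <- sim$phase$data * sim$truth$data
  for (w in c(1, 10, 51)) {
    k <- sim$kspace$data[, , w]
    back <- ifft2c(k)
    expect_lt(max(abs(back - af[, , w])), 1e-12 * max(abs(af[, , w])))
    # Parseval under the orthonormal convention
    expect_equal(sum(Mod(k)^2), sum(Mod(af[, , w])^2), tolerance = 1e-12)
  }
  # constant image with unit phase -> single DC coefficient at the centre
  cimg <- image_series(array(3, c(8, 8, 2)),
                       freq_grid(c(-50, 50), 1))
  cph <- phase_series(matrix(0, 8, 8), cimg$grid)
  kc <- encode_kspace(cimg, cph)$data[, , 1]
  dc <- c(5, 5)  # floor(n/2)+1
  expect_equal(Mod(kc[dc[1], dc[2]]), 3 * 8, tolerance = 1e-12)
  kc[dc[1], dc[2]] <- 0
  expect_lt(max(Mod(kc)), 1e-12)
})

test_that("k-space noise has the prescribed scale and is reproducible", {
  scene <- brain_scene(32L)
  sim <- simulate_acquisition(scene)
  expect_identical(add_noise(sim$kspace, 0)$data, sim$kspace$data)
  ks1 <- add_noise(sim$kspace, 0.105, seed = 123)
  ks2 <- add_noise(sim$kspace, 0.105, seed = 123)
  expect_identical(ks1$data, ks2$data)
  expect_equal(ks1$noise_level, 0.105)
  expect_equal(ks1$rng_seed, 123L)
  sig <- 0.105 * mean(Mod(sim$kspace$data[, , sim$kspace$grid$ref_index]))
  emp_re <- stats::sd(Re(ks1$data - sim$kspace$data))
  emp_im <- stats::sd(Im(ks1$data - sim$kspace$data))
  expect_lt(abs(emp_re - sig) / sig, 0.02)
  expect_lt(abs(emp_im - sig) / sig, 0.02)
  expect_error(add_noise(sim$kspace, -0.1), ">= 0")
})

test_that("offset subsampling keeps required offsets and is bit-exact", {
  scene <- brain_scene(8L)
  sim <- simulate_acquisition(scene)
  g <- scene$grid
  # identity subsample
  all_keep <- subsample_offsets(sim$kspace, g$offsets_hz)
  expect_identical(all_keep$data, sim$kspace$data)
  expect_equal(attr(all_keep, "reduction_fraction"), 0)
  # 51 -> 37 and 51 -> 44 reductions report computed fractions
  k37 <- select_reduced_offsets(g, 37)
  r37 <- subsample_offsets(sim$kspace, k37)
  expect_equal(attr(r37, "reduction_fraction"), (51 - 37) / 51)
  expect_equal(attr(subsample_offsets(sim$kspace,
                                      select_reduced_offsets(g, 44)),
                    "reduction_fraction"),
               (51 - 44) / 51)
  # retained arrays bit-exact; required offsets present
  sel <- which(g$offsets_hz %in% k37)
  expect_identical(r37$data, sim$kspace$data[, , sel])
  expect_true(all(c(-1250, 0, 450, -450) %in% r37$grid$offsets_hz))
  # dropping the reference errors
  expect_error(subsample_offsets(sim$kspace,
                                 setdiff(g$offsets_hz, -1250)),
               "required offset")
  expect_error(subsample_offsets(sim$kspace, setdiff(g$offsets_hz, -450)),
               "required offset")
})

test_that("scene phase is smooth, finite, and optionally offset-dependent", {
  scene <- brain_scene(16L)
  ph <- scene_phase_series(scene)
  expect_true(all(abs(Mod(ph$data) - 1) < 1e-12))
  expect_identical(ph$data[, , 1], ph$data[, , 20])
  ph2 <- scene_phase_series(scene, per_offset_scale = 0.1)
  expect_false(identical(ph2$data[, , 1], ph2$data[, , 20]))
  # zero coefficients give the identity phase factor
  spec <- phantom_preset("simulated_brain", c(8L, 8L))
  spec$phase_coef <- rep(0, 6)
  ph0 <- scene_phase_series(build_phantom(spec))
  expect_true(all(ph0$data == 1 + 0i))
})
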