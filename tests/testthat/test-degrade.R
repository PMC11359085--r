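test_that("temporal downsampling follows the nearest-index rule", {
  cube <- thermal_cube(array(rep(1:90 / 10 + 20, each = 4), c(2, 2, 90)),
                       fps = 60)
  down <- temporal_downsample(cube, 15)
  expect_equal(n_frames(down), 23)
  expect_equal(down$data[1, 1, ], seq(1, 89, by = 4) / 10 + 20)  # 0,4,...,88
  expect_equal(down$fps, 15)

  same <- temporal_downsample(cube, 60)
  expect_identical(same$data, cube$data)
  expect_error(temporal_downsample(cube, 120), "unsupported direction")

  # 50 -> 8.7 fps: every output time maps to a source frame within half a
  # source period
  cube2 <- thermal_cube(array(20, c(1, 1, 450)), fps = 50)
  down2 <- temporal_downsample(cube2, 8.7)
  idx <- irmimic:::downsample_indices(450, 50, 8.7)
  kprime <- seq_along(idx) - 1
  expect_lt(max(abs((idx - 1) / 50 - kprime / 8.7)), 1 / (2 * 50) + 1e-12)
})

test_that("PSF blurring is a normalized reflective convolution", {
  cube <- thermal_cube(array(rnorm(4 * 4 * 3) + 30, c(4, 4, 3)), 10)
  expect_identical(apply_psf(cube, matrix(1, 1, 1))$data, cube$data)

  const <- thermal_cube(array(30, c(6, 6, 2)), 10)
  k <- gaussian_kernel(1)
  expect_equal(apply_psf(const, k)$data, const$data, tolerance = 1e-12)

  # a delta frame reproduces the kernel away from borders
  a <- array(0, c(11, 11, 2)); a[6, 6, ] <- 1
  blurred <- suppressWarnings(apply_psf(suppressWarnings(thermal_cube(a, 10)), k))
  h <- (nrow(k) - 1) / 2
  expect_equal(blurred$data[(6 - h):(6 + h), (6 - h):(6 + h), 1], unname(k),
               tolerance = 1e-12)
  expect_error(apply_psf(cube, matrix(0.25, 2, 2)), "odd")
})

test_that("spatial noise addition picks the nearest setpoint and keeps means", {
  beta25 <- matrix(rnorm(16), 4, 4); beta25 <- beta25 - mean(beta25)
  beta30 <- matrix(rnorm(16), 4, 4); beta30 <- beta30 - mean(beta30)
  prof <- camera_profile("c", 10, c(4, 4), 50, psf_sigma = 0,
                         spatial_noise = list(
                           spatial_noise_map(beta25, 25, 10),
                           spatial_noise_map(beta30, 30, 10)))
  cube <- thermal_cube(array(29, c(4, 4, 5)), 10)
  out <- add_spatial_noise(cube, prof)
  expect_equal(attr(out, "setpoint_used"), 30)
  expect_equal(out$data[, , 2], 29 + beta30, tolerance = 1e-12)
  for (kk in 1:5)
    expect_equal(mean(out$data[, , kk]), 29, tolerance = 1e-12)

  zero <- camera_profile("z", 10, c(4, 4), 50, psf_sigma = 0,
                         spatial_noise = list(
                           spatial_noise_map(matrix(0, 4, 4), 25, 10)))
  expect_equal(add_spatial_noise(cube, zero)$data, cube$data)
  expect_error(add_spatial_noise(cube, ideal_profile(10, c(4, 4))),
               "no characterized spatial noise")
})

test_that("temporal-noise synthesis matches its model statistics", {
  shape <- c(3, 3)
  zero <- uniform_temporal_model(shape, fs = 10, sigma_hf = 0, seed = 1)
  expect_equal(max(abs(synthesize_temporal_noise(zero, 100, 10, seed = 2))), 0)

  hf <- uniform_temporal_model(shape, fs = 10, sigma_hf = 0.07, seed = 1)
  n1 <- synthesize_temporal_noise(hf, 1000, 10, seed = 3)
  sds <- apply(n1, c(1, 2), sd)
  expect_true(all(abs(sds - 0.07) / 0.07 < 0.10))
  expect_identical(synthesize_temporal_noise(hf, 50, 10, seed = 4),
                   synthesize_temporal_noise(hf, 50, 10, seed = 4))

  # paired-video mode reproduces the fitted drift exactly (no phase offset)
  lf <- uniform_temporal_model(shape, fs = 10, sigma_hf = 0,
                               lf_amplitude = 0.3, lf_period_s = 20, seed = 5)
  syn <- synthesize_temporal_noise(lf, 200, 10, seed = 6, phase_offset = FALSE)
  t <- (0:199) / 10
  manual <- lf$a[1, 1, 2] * cos(lf$omega[1, 1] * t) +
    lf$b[1, 1, 2] * sin(lf$omega[1, 1] * t)
  expect_equal(syn[1, 1, ], manual, tolerance = 1e-12)
})

test_that("degrade_cube composes stages in the fixed order", {
  scene <- tiny_scene(shape = c(8, 8), fps = 10, duration = 10, seed = 7)
  rec <- generate_acquisition(scene, "benign")

  # all stages disabled, and the all-identity profile, are both identities
  idp <- ideal_profile(10, c(8, 8))
  off <- degradation_config(idp, apply_stages = c(temporal = FALSE, psf = FALSE,
                                                  spatial_noise = FALSE,
                                                  temporal_noise = FALSE))
  expect_identical(degrade_cube(rec, off)$cube$data, rec$cube$data)
  expect_identical(degrade_cube(rec, degradation_config(idp))$cube$data,
                   rec$cube$data)

  # noise-before-PSF differs from the pipeline's PSF-before-noise
  beta <- matrix(rnorm(64), 8, 8); beta <- beta - mean(beta)
  prof <- camera_profile("lq", fps = 5, fpa = c(8, 8), netd_mK = 70,
                         psf_sigma = 1,
                         spatial_noise = list(spatial_noise_map(beta, 30, 10)),
                         temporal_noise = uniform_temporal_model(
                           c(8, 8), fs = 5, sigma_hf = 0.07, seed = 2))
  deg <- degrade_cube(rec, degradation_config(prof, seed = 11))
  expect_equal(deg$cube$fps, 5)
  manual <- temporal_downsample(rec$cube, 5)
  manual <- add_spatial_noise(manual, prof)          # noise first (wrong order)
  manual <- apply_psf(manual, prof$psf)
  manual$data <- manual$data + synthesize_temporal_noise(
    prof$temporal_noise, n_frames(manual), 5, seed = 11)
  expect_gt(max(abs(manual$data - deg$cube$data)), 1e-6)

  # mask carried through unchanged; corners subsampled
  rec$marker_corners <- replicate(n_frames(rec$cube),
                                  cbind(c(1, 1, 8, 8), c(1, 8, 1, 8)),
                                  simplify = FALSE)
  deg2 <- degrade_cube(rec, degradation_config(prof, seed = 1))
  expect_identical(deg2$lesion_mask, rec$lesion_mask)
  expect_length(deg2$marker_corners, n_frames(deg2$cube))
})

test_that("degradation adds a predictable amount of temporal variance", {
  scene <- tiny_scene(shape = c(6, 6), fps = 10, duration = 40, seed = 9)
  rec <- generate_acquisition(scene, "benign")
  tn <- uniform_temporal_model(c(6, 6), fs = 10, sigma_hf = 0.10, seed = 4)
  prof <- camera_profile("n", fps = 10, fpa = c(6, 6), netd_mK = 100,
                         psf_sigma = 0, temporal_noise = tn)
  deg <- degrade_cube(rec, degradation_config(prof, seed = 5))
  # detrended variance: residual around the noiseless input is pure model noise
  resid <- deg$cube$data - rec$cube$data
  v <- mean(apply(resid, c(1, 2), var))
  expect_lt(abs(v - 0.01) / 0.01, 0.30)
})

test_that("block-average spatial downsampling crops the remainder", {
  x <- matrix(1:25, 5, 5)
  b <- irmimic:::block_average(x, 2)
  expect_equal(dim(b), c(2, 2))
  expect_equal(b[1, 1], mean(x[1:2, 1:2]))
})
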