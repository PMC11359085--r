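test_that("generate_trc evaluates the double-exponential recovery", {
  expect_equal(generate_trc(c(30, 0, -1, 0, -2), 50, 10), rep(30, 50))
  y <- generate_trc(c(30, -3, -0.1, 0, -1), 100, 1)
  expect_equal(y[1], 27)                       # f(0) = th1 + th2 + th4
  expect_equal(generate_trc(c(30, -3, -0.1, 0, -1), 2000, 1)[2000], 30,
               tolerance = 1e-6)               # plateau
  # closed form at one sample, computed through an independent power-based path
  th <- c(32, -2, -0.05, -1, -0.5); fps <- 50; k <- 100
  t <- k / fps
  expected <- th[1] + th[2] * exp(th[3])^t + th[4] * exp(th[5])^t
  expect_equal(generate_trc(th, 101, fps)[101], expected, tolerance = 1e-12)
  expect_error(generate_trc(c(30, NA, -1, 0, -1), 10, 1))
})

test_that("scene configuration enforces geometry and rate signs", {
  expect_error(skin_scene_config(shape = c(10, 10),
                                 lesion = list(center = c(2, 2), radius = 5)),
               "fit inside")
  bad <- list(mean = c(33, -2, 0.1, -1, -0.3), sd = rep(0.1, 5))
  expect_error(skin_scene_config(theta_benign = bad), "negative")
})

test_that("generated acquisitions are deterministic and class-structured", {
  scene <- tiny_scene(seed = 11)
  r1 <- generate_acquisition(scene, "MM")
  r2 <- generate_acquisition(scene, "MM")
  expect_identical(r1$cube$data, r2$cube$data)   # same seed, same cube

  # planted class offset shows up in the generator's own parameter fields
  f0 <- apply(r1$truth$theta[, , c(1, 2, 4)], c(1, 2), sum)
  plateau <- r1$truth$theta[, , 1]
  cfg_off <- scene$theta_lesion_malignant$mean[1] - scene$theta_benign$mean[1]
  expect_equal(mean(plateau[r1$lesion_mask]) - mean(plateau[!r1$lesion_mask]),
               cfg_off, tolerance = 0.2)
  expect_lt(abs(mean(f0[r1$lesion_mask]) - mean(f0[!r1$lesion_mask])), 0.3)

  # zero spread collapses the lesion to one curve
  z <- lapply(scene$theta_lesion_benign["mean"], identity)
  scene0 <- tiny_scene(seed = 11,
                       theta_lesion_benign = list(mean = z$mean, sd = rep(0, 5)))
  r0 <- generate_acquisition(scene0, "benign")
  Y <- irmimic:::cube_to_matrix(r0$cube$data)[, as.vector(r0$lesion_mask)]
  expect_lt(max(apply(Y, 1, function(v) diff(range(v)))), 1e-12)
})

test_that("nearby TRCs are highly correlated by construction", {
  r <- generate_acquisition(tiny_scene(shape = c(12, 12), seed = 4), "benign")
  a <- r$cube$data
  rho <- cor(a[6, 6, ], a[6, 7, ])
  expect_gt(rho, 0.99)
})

test_that("blackbody stacks expose a recoverable fixed pattern", {
  quiet <- camera_profile("quiet", fps = 10, fpa = c(8, 8), netd_mK = 0,
                          psf_sigma = 0)
  st0 <- generate_blackbody_stack(quiet, 20, n_frames = 5, seed = 1,
                                  beta_sd = c(low = 0, mid = 0, high = 0,
                                              band = 0))
  expect_equal(max(abs(st0$data - 20)), 0)     # zero-noise profile

  prof <- camera_profile("hf", fps = 10, fpa = c(8, 8), netd_mK = 70,
                         psf_sigma = 0)
  st <- generate_blackbody_stack(prof, 20, n_frames = 180, seed = 2)
  bt <- attr(st, "beta_true")
  expect_lt(abs(mean(bt)), 1e-12)
  m <- extract_spatial_noise(st, 20)
  expect_lt(sqrt(mean((m$beta - bt)^2)), 3 * 0.07 / sqrt(180))

  # characterization grid of six setpoints
  sp <- seq(15, 40, by = 5)
  stacks <- lapply(sp, function(s)
    generate_blackbody_stack(prof, s, n_frames = 20, seed = s))
  expect_length(stacks, 6)
  expect_identical(generate_blackbody_stack(prof, 20, 20, seed = 9)$data,
                   generate_blackbody_stack(prof, 20, 20, seed = 9)$data)
})

test_that("paired acquisitions share physiology and respect rate ordering", {
  scene <- tiny_scene(shape = c(8, 8), fps = 10, duration = 10, seed = 5)
  hq <- ideal_profile(10, c(8, 8))
  lq <- ideal_profile(2, c(8, 8))
  pair <- generate_paired_acquisition(scene, hq, lq)
  expect_identical(pair$hq$truth$theta, pair$lq$truth$theta)
  # noiseless profiles: LQ equals HQ subsampled by the nearest-index rule
  sub <- temporal_downsample(pair$hq$cube, 2)
  expect_equal(pair$lq$cube$data, sub$data, tolerance = 1e-12)
  expect_error(generate_paired_acquisition(scene, lq, hq),
               "unsupported direction")
})

test_that("simulated NUC jumps step the frame-mean series by the set magnitude", {
  shape <- c(6, 6)
  prof <- camera_profile("nuc", fps = 4, fpa = shape, netd_mK = 10,
                         psf_sigma = 0,
                         nuc_sim = list(interval_s = 10, magnitude_C = 1))
  scene <- tiny_scene(shape = shape, fps = 4, duration = 35, seed = 6)
  rec <- irmimic:::with_seed(1, {
    tf <- irmimic:::draw_theta_fields(scene, "benign")
    irmimic:::render_through_profile(tf$theta, tf$mask, scene, prof,
                                     "benign", "x", noise_seed = 3)
  })
  m <- colMeans(matrix(rec$cube$data, ncol = n_frames(rec$cube)))
  dm <- diff(m)
  jumps <- which(abs(dm) > 0.5)
  expect_true(all(c(40, 80, 120) %in% jumps))
  expect_equal(abs(dm[jumps]), rep(1, length(jumps)), tolerance = 0.1)
})
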