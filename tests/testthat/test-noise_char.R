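test_that("spatial noise extraction removes the mean and recovers patterns", {
  const <- thermal_cube(array(25, c(5, 5, 10)), 10)
  expect_equal(extract_spatial_noise(const, 25)$beta, matrix(0, 5, 5))

  P <- matrix(rnorm(30), 5, 6)
  cube <- thermal_cube(25 + aperm(array(P, c(5, 6, 8)), c(1, 2, 3)), 10)
  m <- extract_spatial_noise(cube, 25)
  expect_equal(m$beta, P - mean(P), tolerance = 1e-12)
  expect_lt(abs(mean(m$beta)), 1e-12)          # zero-mean invariant
  expect_identical(m$n_frames_used, 8L)
})

smooth_series_cube <- function(m, shape = c(4, 4), fps = 10) {
  thermal_cube(aperm(array(m, c(length(m), shape)), c(2, 3, 1)), fps)
}

test_that("NUC correction detects, removes and does not invent jumps", {
  base <- 25 + 2 * (1 - exp(-0.05 * (0:299) / 10))
  # clean series: no jumps, identity
  clean <- smooth_series_cube(base)
  r0 <- correct_nuc_jumps(clean)
  expect_identical(nrow(r0$jumps), 0L)
  expect_identical(r0$cube$data, clean$data)

  # single +2 degC step at frame 100
  y <- base; y[100:300] <- y[100:300] + 2
  r1 <- correct_nuc_jumps(smooth_series_cube(y))
  expect_equal(r1$jumps$frame, 100)
  expect_equal(r1$jumps$magnitude, 2, tolerance = 0.05)
  m_corr <- colMeans(matrix(r1$cube$data, ncol = 300))
  expect_lt(max(abs(diff(m_corr))), 0.05)

  # idempotence
  r2 <- correct_nuc_jumps(r1$cube)
  expect_identical(nrow(r2$jumps), 0L)
  expect_identical(r2$cube$data, r1$cube$data)

  # two opposite steps cancel back to the baseline up to a constant
  y2 <- base; y2[80:300] <- y2[80:300] + 1; y2[200:300] <- y2[200:300] - 1
  r3 <- correct_nuc_jumps(smooth_series_cube(y2))
  resid <- colMeans(matrix(r3$cube$data, ncol = 300)) - base
  expect_lt(diff(range(resid)), 0.05)

  # translation equivariance
  r4 <- correct_nuc_jumps(smooth_series_cube(y + 5))
  expect_equal(r4$cube$data, r1$cube$data + 5, tolerance = 1e-12)
})

test_that("Fourier fits recover a known drift and degenerate gracefully", {
  fs <- 1; n <- 300
  s <- 2 * cos(2 * pi * (0:(n - 1)) / (fs * 60))
  fit <- fit_temporal_noise_series(s, fs, Z = 1, period_range = c(30, 300),
                                   n_grid = 400)
  amp <- sqrt(fit$a[2]^2 + fit$b[2]^2)
  expect_equal(amp, 2, tolerance = 0.01)
  expect_lt(abs(fit$omega - 2 * pi / 60), 0.002)  # within one grid step

  # residual orthogonal to the fitted basis at the selected frequency
  X <- irmimic:::fourier_design(n, fs, fit$omega, 1L)
  lf <- X %*% c(fit$a, fit$b[2])[c(1, 2, 3)]
  expect_lt(max(abs(crossprod(X, s - lf))), 1e-8)

  cst <- fit_temporal_noise_series(rep(25, 60), fs = 1, Z = 1)
  expect_equal(cst$a[1], 25)
  expect_equal(cst$sigma_hf, 0)
  expect_equal(cst$a[-1], 0)
})

test_that("sigma_hf is estimated within 20% at n = 1000", {
  fs <- 2; n <- 1000
  lf <- 0.3 * sin(2 * pi * (0:(n - 1)) / (fs * 60))
  ests <- vapply(1:50, function(s) {
    set.seed(s)
    fit_temporal_noise_series(lf + rnorm(n, 0, 0.05), fs, Z = 1,
                              period_range = c(30, 120), n_grid = 50)$sigma_hf
  }, 0)
  expect_lt(abs(median(ests) - 0.05) / 0.05, 0.20)
})

test_that("characterize_camera stores six maps and recovers detector sigma", {
  shape <- c(8, 8)
  tn <- uniform_temporal_model(shape, fs = 10, sigma_hf = 0.07,
                               lf_amplitude = 0.3, lf_period_s = 60, seed = 3)
  prof <- camera_profile("cam", fps = 10, fpa = shape, netd_mK = 70,
                         psf_sigma = 0, temporal_noise = tn)
  sp <- seq(15, 40, by = 5)
  stacks <- lapply(seq_along(sp), function(i)
    generate_blackbody_stack(prof, sp[i], n_frames = if (i == 1) 900 else 30,
                             seed = i))
  ch <- characterize_camera(stacks, sp, prof, Z = 1, n_grid = 60,
                            period_range = c(30, 90))
  expect_length(ch$spatial_noise, 6)
  expect_equal(vapply(ch$spatial_noise, function(m) m$setpoint, 0), sp)
  relerr <- abs(ch$temporal_noise$sigma_hf - 0.07) / 0.07
  expect_lt(median(relerr), 0.25)
  expect_error(characterize_camera(stacks[c(1, 1)], c(20, 20), prof),
               "duplicate")

  # noiseless single stack: all-zero beta, zero sigma
  quiet <- camera_profile("q", fps = 10, fpa = c(4, 4), netd_mK = 0,
                          psf_sigma = 0)
  st0 <- generate_blackbody_stack(quiet, 20, n_frames = 40, seed = 1,
                                  beta_sd = c(low = 0, mid = 0, high = 0,
                                              band = 0))
  ch0 <- characterize_camera(list(st0), 20, quiet, Z = 1, n_grid = 20)
  expect_equal(max(abs(ch0$spatial_noise[[1]]$beta)), 0)
  expect_equal(max(ch0$temporal_noise$sigma_hf), 0)
})

test_that("video temporal-noise characterization isolates the drift", {
  # model-exact cube: residual noise is numerically zero
  cube <- exact_cube(K = 200, fps = 10)
  tn0 <- extract_video_temporal_noise(cube, Z = 1, n_grid = 30)
  expect_lt(max(abs(tn0$a)), 1e-6)
  expect_lt(max(abs(tn0$b)), 1e-6)

  # recovery signal + known sinusoid: LF amplitude recovered within 5%
  # (several drift cycles must be visible or the recovery fit absorbs some)
  fps <- 2; K <- 480
  y <- generate_trc(c(33, -2.5, -0.05, -1.2, -0.4), K, fps)
  drift <- 0.3 * cos(2 * pi * (0:(K - 1)) / (fps * 30) + 0.7)
  a <- aperm(array(y + drift, c(K, 4, 4)), c(2, 3, 1))
  tn <- extract_video_temporal_noise(thermal_cube(a, fps), Z = 1,
                                     period_range = c(15, 45), n_grid = 120)
  amp <- sqrt(tn$a[, , 2]^2 + tn$b[, , 2]^2)
  expect_equal(mean(amp), 0.3, tolerance = 0.05)

  # a broken pixel is flagged, the rest are fitted (plain-array input)
  a_bad <- a; a_bad[2, 2, ] <- NaN
  tn_bad <- extract_video_temporal_noise(a_bad, Z = 1, fps = fps,
                                         period_range = c(15, 45), n_grid = 30)
  expect_false(tn_bad$valid[2, 2])
  expect_true(all(tn_bad$valid[-(2 + 4)]))
})

test_that("a characterized profile re-synthesizes the right noise level", {
  shape <- c(6, 6)
  tn_true <- uniform_temporal_model(shape, fs = 10, sigma_hf = 0.06,
                                    lf_amplitude = 0.25, lf_period_s = 40,
                                    seed = 8)
  prof <- camera_profile("cam", fps = 10, fpa = shape, netd_mK = 60,
                         psf_sigma = 0, temporal_noise = tn_true)
  ratios <- vapply(1:10, function(s) {
    st <- generate_blackbody_stack(prof, 20, n_frames = 600, seed = s)
    ch <- characterize_camera(list(st), 20, prof, Z = 1, n_grid = 40,
                              period_range = c(20, 60))
    syn <- synthesize_temporal_noise(ch$temporal_noise, K_IR = 600, fps = 10,
                                     seed = s + 100)
    v_true <- var(as.vector(st$data[3, 3, ]))
    v_syn <- var(as.vector(syn[3, 3, ] + 20))
    v_syn / v_true
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.30)
})
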