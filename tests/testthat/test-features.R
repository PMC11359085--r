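test_that("distance and energy features match brute-force oracles", {
  expect_equal(euclidean_distance(1:5, 1:5), 0)
  expect_equal(euclidean_distance(c(4, 1, 1, 1), c(1, 1, 1, 1)), 3 / 4)
  expect_equal(energy_difference(1:5, 1:5), 0)
  expect_equal(energy_difference(c(1, 2), c(5, 6)), 0)  # offset-invariant

  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(37, 30, 2); b <- rnorm(37, 30, 2)
    expect_equal(euclidean_distance(a, b), brute_distance(a, b),
                 tolerance = 1e-12)
    expect_equal(energy_difference(a, b), brute_energy_difference(a, b),
                 tolerance = 1e-10)
  }
  expect_error(euclidean_distance(1:4, 1:5), "lengths differ")
  expect_error(energy_difference(1:4, 1:5), "lengths differ")
})

test_that("the normalized distance is a metric", {
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    dxy <- euclidean_distance(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, euclidean_distance(y, x))
    expect_lte(euclidean_distance(x, z),
               dxy + euclidean_distance(y, z) + 1e-12)
  }
})

test_that("descriptive models average parameters, not curves", {
  thA <- c(33, -2, -0.05, -1, -0.4)
  thB <- c(34, -3, -0.15, -1.5, -0.9)
  m1 <- build_descriptive_model(cbind(thA), cbind(thB), K_IR = 100, fps = 10)
  expect_equal(sum(m1$fM^2), 1, tolerance = 1e-9)
  expect_equal(sum(m1$fB^2), 1, tolerance = 1e-9)
  ref <- generate_trc(thA, 100, 10)
  expect_equal(m1$fM, ref / sqrt(sum(ref^2)), tolerance = 1e-12)

  # parameter average differs from curve average for distinct rates
  m2 <- build_descriptive_model(cbind(thA, thB), cbind(thA), 100, 10)
  curve_param_avg <- generate_trc((thA + thB) / 2, 100, 10)
  curve_curve_avg <- (generate_trc(thA, 100, 10) + generate_trc(thB, 100, 10)) / 2
  expect_equal(m2$fM, curve_param_avg / sqrt(sum(curve_param_avg^2)),
               tolerance = 1e-12)
  expect_gt(max(abs(curve_param_avg - curve_curve_avg)), 1e-3)
  expect_error(build_descriptive_model(matrix(0, 5, 0), cbind(thA), 100, 10),
               "empty class")
})

test_that("similitude features behave at fixed points and match brute force", {
  model <- generate_trc(c(30, -2, -0.05, -1, -0.5), 50, 5)
  model <- model / sqrt(sum(model^2))
  same <- matrix(model, 50, 10)
  s <- similitude_features(same, model)
  expect_equal(unname(s[c("proj_mean", "proj_sd", "rho_mean", "dist_mean")]),
               c(1, 0, 1, 0), tolerance = 1e-12)
  opp <- similitude_features(-same, model)
  expect_equal(unname(opp[c("proj_mean", "rho_mean")]), c(-1, -1),
               tolerance = 1e-12)

  set.seed(9)
  rnd <- matrix(rnorm(50 * 12, 30, 1), 50, 12)
  rnd <- sweep(rnd, 2, sqrt(colSums(rnd^2)), "/")
  expect_equal(similitude_features(rnd, model), brute_similitude(rnd, model),
               tolerance = 1e-10)
  expect_true(all(abs(similitude_features(rnd, model)[c("proj_mean", "rho_mean")]) <= 1))

  expect_warning(similitude_features(rnd[, 1:5], model), "only 5")
  withz <- cbind(rnd, 30)  # constant member: undefined correlation
  expect_warning(sz <- similitude_features(withz, model), "zero-variance")
  expect_equal(sz, similitude_features(rnd, model), tolerance = 1e-12)
  expect_error(similitude_features(rnd[1:10, ], model), "length differs")
})

test_that("feature extraction separates identical from contrasting tissue", {
  # lesion identical to surrounding skin: d and Ed collapse
  flat <- tiny_scene(shape = c(10, 10), fps = 5, duration = 20, seed = 13,
                     theta_lesion_benign = list(
                       mean = c(33.5, -2.7, -0.045, -1.3, -0.28),
                       sd = c(0, 0, 0, 0, 0)),
                     theta_benign = list(
                       mean = c(33.5, -2.7, -0.045, -1.3, -0.28),
                       sd = c(0, 0, 0, 0, 0)))
  rec_flat <- generate_acquisition(flat, "benign")
  fits_flat <- fit_cube_trcs(rec_flat$cube, keep_fitted = FALSE)
  sel_flat <- select_trcs(fits_flat, rec_flat$lesion_mask)
  mdl <- build_descriptive_model(cbind(c(34.2, -3.1, -0.09, -1.5, -0.45)),
                                 cbind(c(33.5, -2.7, -0.045, -1.3, -0.28)),
                                 n_frames(rec_flat$cube), rec_flat$cube$fps)
  fv_flat <- extract_features(rec_flat, sel_flat, mdl, fits_flat)
  expect_lt(fv_flat$d, 1e-8)
  expect_lt(abs(fv_flat$Ed), 1e-6)
  expect_length(fv_flat$similitude, 24)
  expect_named(fv_flat$selected,
               c("Ed_abs", "rho_sd_BL", "proj_sd_BN", "dist_sd_MN"))

  # malignant scene: the planted contrast appears in d
  rec_mm <- generate_acquisition(tiny_scene(shape = c(10, 10), fps = 5,
                                            duration = 20, seed = 13), "MM")
  fits_mm <- fit_cube_trcs(rec_mm$cube, keep_fitted = FALSE)
  sel_mm <- select_trcs(fits_mm, rec_mm$lesion_mask)
  fv_mm <- extract_features(rec_mm, sel_mm, mdl, fits_mm)
  expect_gt(fv_mm$d, fv_flat$d + 0.01)

  # determinism: rerunning the whole extraction reproduces the vector
  fv_mm2 <- extract_features(rec_mm, sel_mm, mdl, fits_mm)
  expect_identical(fv_mm$similitude, fv_mm2$similitude)
})
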