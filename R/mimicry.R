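# End-to-end mimicry validation: generate a paired two-camera acquisition,
# characterize the low-quality camera's temporal noise from its own video,
# degrade the high-quality member with that profile, and compare.

#' Demonstration camera profiles
#'
#' Ready-made profiles for validation experiments, sized to a given frame
#' shape so their spatial noise maps match the synthetic scene.
#'
#' \itemize{
#'   \item \code{"hq"}: a fast, sensitive reference imager (50 fps, 20 mK
#'     NETD, no optical blur modeled, no drift).
#'   \item \code{"lq_noisy"}: a consumer-grade microbolometer (15 fps,
#'     70 mK high-frequency noise, 0.3 degC ambient drift with a 60 s
#'     period, 1.2 px Gaussian PSF, NUC jumps of 0.5 degC every 60 s).
#'   \item \code{"lq_quiet"}: a lower-noise target (8.7 fps, 35 mK
#'     high-frequency noise, same drift and PSF, no NUC jumps).
#' }
#'
#' @param which Profile name.
#' @param shape \code{c(I, J)} of the scenes the profile will image.
#' @param seed Seed for the generated spatial pattern and drift phases.
#' @return A \code{\link{camera_profile}} whose \code{temporal_noise} slot
#'   holds the *generative* model (what the simulated camera actually does);
#'   characterization re-estimates it from data.
#' @export
demo_camera_profile <- function(which = c("hq", "lq_noisy", "lq_quiet"),
                                shape = c(64, 64), seed = 1L) {
  which <- match.arg(which)
  shape <- as.integer(shape)
  beta_map <- function(sd_scale, seed) {
    b <- with_seed(seed, {
      raw <- sd_scale * (0.6 * smooth_field(matrix(stats::rnorm(prod(shape)),
                                                   shape[1L], shape[2L]),
                                            min(shape) / 8) +
                         0.4 * matrix(stats::rnorm(prod(shape)),
                                      shape[1L], shape[2L]))
      raw - mean(raw)
    })
    spatial_noise_map(b - mean(b), setpoint = 30, n_frames_used = 180L)
  }
  switch(which,
    hq = camera_profile("demo-hq", fps = 50, fpa = shape, netd_mK = 20,
                        psf_sigma = 0),
    lq_noisy = camera_profile(
      "demo-lq-noisy", fps = 15, fpa = shape, netd_mK = 70, psf_sigma = 1.2,
      spatial_noise = list(beta_map(0.08, seed + 11L)),
      temporal_noise = uniform_temporal_model(shape, fs = 15, sigma_hf = 0.07,
                                              lf_amplitude = 0.3,
                                              lf_period_s = 60, seed = seed + 13L),
      nuc = nuc_params(),
      nuc_sim = list(interval_s = 60, magnitude_C = 0.5)),
    lq_quiet = camera_profile(
      "demo-lq-quiet", fps = 8.7, fpa = shape, netd_mK = 35, psf_sigma = 1.2,
      spatial_noise = list(beta_map(0.08, seed + 11L)),
      temporal_noise = uniform_temporal_model(shape, fs = 8.7, sigma_hf = 0.035,
                                              lf_amplitude = 0.3,
                                              lf_period_s = 60, seed = seed + 13L)))
}

#' Paired-acquisition mimicry experiment
#'
#' Reproduces the degradation-model validation protocol on synthetic data:
#' one skin scene is acquired simultaneously by a high-quality camera and a
#' low-quality camera; the low-quality video is NUC-corrected and its
#' temporal noise characterized in paired-video mode (per-pixel recovery fit
#' subtracted, Fourier-series drift plus Gaussian residual fitted); the
#' high-quality video is then degraded with the characterized profile and
#' compared with the actual low-quality video by per-pixel Pearson
#' correlation.
#'
#' @param lq Which low-quality demonstration profile to mimic
#'   (\code{"lq_noisy"} or \code{"lq_quiet"}), or a ready
#'   \code{\link{camera_profile}}.
#' @param shape Scene size in pixels.
#' @param duration_s Scene duration (seconds).
#' @param fps_hq High-quality frame rate.
#' @param seed Integer seed driving scene and noise generation.
#' @param Z Fourier order for the temporal-noise characterization.
#' @param n_grid Period-grid size of the Fourier fit.
#' @param shared_omega Use the shared-frequency fast mode of the fit.
#' @param label Lesion class of the scene.
#' @return List with \code{report} (a \code{\link{validate_mimicry}}
#'   result), \code{pair} (the generated records), \code{degraded} (the
#'   mimicked record) and \code{profile} (the characterized profile).
#' @export
mimicry_experiment <- function(lq = "lq_noisy", shape = c(64, 64),
                               duration_s = 90, fps_hq = 50, seed = 7L,
                               Z = 3L, n_grid = 200L, shared_omega = FALSE,
                               label = "benign") {
  profile_lq <- if (inherits(lq, "camera_profile")) lq
                else demo_camera_profile(lq, shape = shape, seed = seed)
  profile_hq <- demo_camera_profile("hq", shape = shape, seed = seed)
  profile_hq$fps <- fps_hq
  scene <- skin_scene_config(shape = shape, fps_truth = fps_hq,
                             duration_s = duration_s, seed = seed)
  pair <- generate_paired_acquisition(scene, profile_hq, profile_lq,
                                      label = label)
  lq_corr <- correct_nuc_jumps(pair$lq$cube,
                               profile_lq$nuc %||% nuc_params())$cube
  tn <- extract_video_temporal_noise(lq_corr, Z = Z,
                                     period_range = c(30, duration_s),
                                     n_grid = n_grid,
                                     shared_omega = shared_omega)
  prof_fit <- profile_lq
  prof_fit$temporal_noise <- tn
  degraded <- degrade_cube(pair$hq,
                           degradation_config(prof_fit, mode = "paired_video",
                                              seed = seed + 1L))
  actual <- lq_corr
  mim <- degraded$cube
  Kc <- min(n_frames(actual), n_frames(mim))
  if (n_frames(actual) != n_frames(mim)) {  # guard off-by-one frame counts
    actual <- thermal_cube(actual$data[, , seq_len(Kc), drop = FALSE],
                           fps = actual$fps)
    mim <- thermal_cube(mim$data[, , seq_len(Kc), drop = FALSE], fps = mim$fps)
  }
  list(report = validate_mimicry(actual, mim), pair = pair,
       degraded = degraded, profile = prof_fit)
}
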