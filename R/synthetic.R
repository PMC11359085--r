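# Synthetic-scene generation: ground-truth skin acquisitions, paired
# two-camera captures of one scene, and blackbody calibration stacks.

# Evaluate code with a temporarily-seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic skin-scene configuration
#'
#' Describes the ground truth of a simulated active-thermography acquisition:
#' after a 30 s cooling stimulus the skin re-warms toward its plateau, so each
#' pixel's thermoregulation curve (TRC) follows the double-exponential
#' recovery \code{f(t) = th1 + th2 exp(th3 t) + th4 exp(th5 t)} with negative
#' amplitudes \code{th2, th4} and negative rates \code{th3, th5}. Parameter
#' fields are drawn per pixel around class means and spatially low-pass
#' filtered, so nearby TRCs are highly correlated, as on real skin.
#'
#' The default parameter distributions place the healthy-skin and lesion
#' initial temperatures \code{f(0) = th1 + th2 + th4} within about 0.1 degC
#' of each other (cooling equalizes the start of the recovery) while the
#' malignant class recovers faster toward a slightly warmer plateau --- the
#' vascularization contrast the screening features are designed to detect.
#'
#' @param shape \code{c(I, J)} frame size in pixels.
#' @param fps_truth Frame rate of the noiseless ground truth (frames/s).
#' @param duration_s Acquisition length in seconds (default 90, i.e. a 1.5
#'   minute recovery sequence).
#' @param lesion List \code{list(center = c(i, j), radius = r)} in pixels;
#'   defaults to a centered disk of radius \code{min(shape) / 5}. The disk
#'   must fit inside the frame.
#' @param theta_benign,theta_lesion_benign,theta_lesion_malignant Lists
#'   \code{list(mean = <5-vector>, sd = <5-vector>)} over the recovery
#'   parameters for healthy surrounding skin, benign lesion tissue and
#'   malignant lesion tissue. Means of the rates (3rd, 5th entries) must be
#'   negative.
#' @param ambient_C Room temperature in degC (acquisition-protocol range
#'   20--22).
#' @param theta_smooth_sigma Gaussian width (pixels) of the spatial low-pass
#'   applied to parameter jitter.
#' @param seed Integer seed; every generator consuming the scene is
#'   deterministic given it.
#' @return An object of class \code{skin_scene_config}.
#' @export
skin_scene_config <- function(shape = c(64, 64), fps_truth = 50,
                              duration_s = 90, lesion = NULL,
                              theta_benign = list(
                                mean = c(33.5, -2.7, -0.045, -1.3, -0.28),
                                sd   = c(0.25, 0.15, 0.004, 0.10, 0.03)),
                              theta_lesion_benign = list(
                                mean = c(33.6, -2.8, -0.05, -1.3, -0.30),
                                sd   = c(0.25, 0.15, 0.004, 0.10, 0.03)),
                              theta_lesion_malignant = list(
                                mean = c(34.2, -3.1, -0.09, -1.5, -0.45),
                                sd   = c(0.25, 0.15, 0.008, 0.10, 0.05)),
                              ambient_C = 21, theta_smooth_sigma = 2,
                              seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L), fps_truth > 0,
            duration_s > 0, ambient_C >= 20 - 1e-9, ambient_C <= 22 + 1e-9)
  if (is.null(lesion))
    lesion <- list(center = (shape + 1) / 2, radius = max(2, min(shape) / 5))
  for (th in list(theta_benign, theta_lesion_benign, theta_lesion_malignant)) {
    stopifnot(length(th$mean) == 5L, length(th$sd) == 5L, all(th$sd >= 0))
    if (th$mean[3L] >= 0 || th$mean[5L] >= 0)
      stop("mean recovery rates (theta 3 and 5) must be negative")
  }
  ctr <- lesion$center; r <- lesion$radius
  if (ctr[1L] - r < 1 || ctr[1L] + r > shape[1L] ||
      ctr[2L] - r < 1 || ctr[2L] + r > shape[2L])
    stop("lesion disk does not fit inside the frame")
  structure(list(shape = shape, fps_truth = fps_truth, duration_s = duration_s,
                 lesion = lesion, theta_benign = theta_benign,
                 theta_lesion_benign = theta_lesion_benign,
                 theta_lesion_malignant = theta_lesion_malignant,
                 ambient_C = ambient_C, theta_smooth_sigma = theta_smooth_sigma,
                 seed = as.integer(seed)),
            class = "skin_scene_config")
}

#' Double-exponential thermal recovery curve
#'
#' Evaluates \code{f(k Ts) = th1 + th2 exp(th3 k Ts) + th4 exp(th5 k Ts)} for
#' \code{k = 0 .. K_IR - 1}, \code{Ts = 1 / fps}.
#'
#' @param theta Numeric 5-vector (plateau degC, two amplitudes degC, two
#'   rates 1/s).
#' @param K_IR Number of samples (>= 2).
#' @param fps Sample rate in frames/s (> 0).
#' @return Numeric temperature series of length \code{K_IR}.
#' @examples
#' generate_trc(c(30, -3, -0.1, 0, -1), K_IR = 3, fps = 1)
#' @export
generate_trc <- function(theta, K_IR, fps) {
  stopifnot(length(theta) == 5L, all(is.finite(theta)), K_IR >= 2, fps > 0)
  t <- (seq_len(K_IR) - 1L) / fps
  theta[1L] + theta[2L] * exp(theta[3L] * t) + theta[4L] * exp(theta[5L] * t)
}

# Draw the five per-pixel parameter fields for a scene. Jitter is white noise
# low-pass filtered to theta_smooth_sigma, rescaled to unit variance, so the
# per-pixel spread equals the configured sd while neighbors stay correlated.
draw_theta_fields <- function(scene, label) {
  I <- scene$shape[1L]; J <- scene$shape[2L]
  mask <- lesion_disk_mask(scene)
  th_bg <- scene$theta_benign
  th_les <- if (is_malignant_label(label)) scene$theta_lesion_malignant
            else scene$theta_lesion_benign
  fields <- array(0, c(I, J, 5L))
  for (p in 1:5) {
    jit <- smooth_field(matrix(stats::rnorm(I * J), I, J),
                        scene$theta_smooth_sigma)
    f <- th_bg$mean[p] + th_bg$sd[p] * jit
    f[mask] <- th_les$mean[p] + th_les$sd[p] * jit[mask]
    fields[, , p] <- f
  }
  list(theta = fields, mask = mask)
}

lesion_disk_mask <- function(scene) {
  I <- scene$shape[1L]; J <- scene$shape[2L]
  ctr <- scene$lesion$center
  outer(seq_len(I), seq_len(J),
        function(i, j) (i - ctr[1L])^2 + (j - ctr[2L])^2 <= scene$lesion$radius^2)
}

# Evaluate the double-exponential fields on a time grid, one frame at a time.
evaluate_theta_cube <- function(theta, times) {
  I <- dim(theta)[1L]; J <- dim(theta)[2L]
  a <- array(0, c(I, J, length(times)))
  th1 <- theta[, , 1L]; th2 <- theta[, , 2L]; th3 <- theta[, , 3L]
  th4 <- theta[, , 4L]; th5 <- theta[, , 5L]
  for (k in seq_along(times)) {
    t <- times[k]
    a[, , k] <- th1 + th2 * exp(th3 * t) + th4 * exp(th5 * t)
  }
  a
}

#' Generate a noiseless ground-truth acquisition
#'
#' Draws spatially smooth recovery-parameter fields for one scene (lesion
#' parameters inside the mask per \code{label}, healthy-skin parameters
#' outside) and evaluates the noiseless TRC cube at the scene's ground-truth
#' frame rate. The drawn fields are kept in the record's \code{truth} slot
#' for oracle comparisons.
#'
#' @param scene A \code{\link{skin_scene_config}}.
#' @param label Lesion class: \code{"benign"}, \code{"BCC"}, \code{"SCC"} or
#'   \code{"MM"}.
#' @param subject_id Identifier stored in the record.
#' @return An \code{\link{acquisition_record}} with a flat rendering of the
#'   mask as visible image and \code{truth = list(theta = <I x J x 5 array>)}.
#' @export
generate_acquisition <- function(scene, label, subject_id = "synthetic") {
  stopifnot(inherits(scene, "skin_scene_config"))
  label <- match.arg(label, c("benign", "BCC", "SCC", "MM"))
  with_seed(scene$seed, {
    tf <- draw_theta_fields(scene, label)
    K <- max(2L, round(scene$duration_s * scene$fps_truth))
    a <- evaluate_theta_cube(tf$theta, (seq_len(K) - 1L) / scene$fps_truth)
    acquisition_record(thermal_cube(a, fps = scene$fps_truth),
                       lesion_mask = tf$mask,
                       visible = tf$mask * 0.5 + 0.25,
                       label = label, subject_id = subject_id,
                       truth = list(theta = tf$theta))
  })
}

#' Spatially uniform temporal-noise model
#'
#' Convenience constructor for a generative \code{\link{temporal_noise_model}}
#' in which every detector shares one high-frequency standard deviation and
#' one low-frequency sinusoidal drift (amplitude and period), with an
#' optional per-detector random phase and amplitude jitter. The drift mimics
#' the on--off cycling of an air-conditioning unit as seen by the camera.
#'
#' @param shape \code{c(I, J)} detector grid.
#' @param fs Frame rate the model applies at (frames/s).
#' @param sigma_hf High-frequency (white Gaussian) standard deviation, degC.
#' @param lf_amplitude Drift amplitude in degC (0 disables the drift).
#' @param lf_period_s Drift fundamental period in seconds.
#' @param phase_jitter Standard deviation (radians) of the per-detector phase
#'   around a common random phase.
#' @param amp_jitter Relative per-detector amplitude jitter (e.g. 0.1).
#' @param seed Integer seed for the phase/amplitude draws.
#' @return A \code{\link{temporal_noise_model}} with \code{Z = 1}.
#' @export
uniform_temporal_model <- function(shape, fs, sigma_hf, lf_amplitude = 0,
                                   lf_period_s = 60, phase_jitter = 0.2,
                                   amp_jitter = 0.1, seed = 1L) {
  I <- shape[1L]; J <- shape[2L]
  with_seed(seed, {
    phi <- stats::runif(1, 0, 2 * pi) +
      matrix(stats::rnorm(I * J, 0, phase_jitter), I, J)
    amp <- lf_amplitude * (1 + matrix(stats::rnorm(I * J, 0, amp_jitter), I, J))
    a <- array(0, c(I, J, 2L)); b <- array(0, c(I, J, 2L))
    a[, , 2L] <- amp * cos(phi)
    b[, , 2L] <- amp * sin(phi)
    temporal_noise_model(a, b,
                         omega = matrix(2 * pi / lf_period_s, I, J),
                         sigma_hf = matrix(sigma_hf, I, J), fs = fs)
  })
}

#' Generate a blackbody calibration stack
#'
#' Simulates a sequence of frames of a blackbody radiator held at
#' \code{setpoint}: a fixed spatial pattern \code{beta_true} (low-, mid- and
#' high-spatial-frequency components plus row/column banding, zero spatial
#' mean) on top of the setpoint, plus per-frame temporal noise from the
#' profile's temporal model (or plain Gaussian noise at the profile's NETD if
#' no model is attached), plus injected NUC jumps if the profile carries a
#' \code{nuc_sim} spec. The generated pattern is attached as attribute
#' \code{"beta_true"} for oracle comparisons.
#'
#' @param profile A \code{\link{camera_profile}}; its \code{fpa} sets the
#'   frame shape.
#' @param setpoint Blackbody temperature in degC.
#' @param n_frames Number of frames (>= 2; 180 is typical for a
#'   characterization sequence).
#' @param seed Integer seed.
#' @param beta_sd Named numeric vector of component amplitudes in degC:
#'   \code{low}, \code{mid}, \code{high} spatial frequency and \code{band}
#'   (row/column stripes).
#' @return A \code{\link{thermal_cube}} at the profile's frame rate.
#' @export
generate_blackbody_stack <- function(profile, setpoint, n_frames = 180L,
                                     seed = 1L,
                                     beta_sd = c(low = 0.06, mid = 0.03,
                                                 high = 0.03, band = 0.02)) {
  stopifnot(inherits(profile, "camera_profile"), n_frames >= 2)
  I <- profile$fpa[1L]; J <- profile$fpa[2L]
  with_seed(seed, {
    beta <- beta_sd[["low"]] * smooth_field(matrix(stats::rnorm(I * J), I, J), min(I, J) / 8) +
            beta_sd[["mid"]] * smooth_field(matrix(stats::rnorm(I * J), I, J), 2) +
            beta_sd[["high"]] * matrix(stats::rnorm(I * J), I, J) +
            beta_sd[["band"]] * (matrix(stats::rnorm(I), I, J) +
                                 matrix(stats::rnorm(J), I, J, byrow = TRUE))
    beta <- beta - mean(beta)
    a <- array(setpoint + beta, dim = c(I, J, n_frames))
    tn <- profile$temporal_noise
    if (!is.null(tn)) {
      noise <- synthesize_temporal_noise(tn, K_IR = n_frames, fps = profile$fps,
                                         seed = stats::runif(1, 1, 2^30),
                                         phase_offset = FALSE)
      a <- a + noise
    } else if (profile$netd_mK > 0) {
      a <- a + array(stats::rnorm(length(a), 0, profile$netd_mK / 1000), dim = dim(a))
    }
    if (!is.null(profile$nuc_sim))
      a <- inject_nuc_jumps(a, profile$fps, profile$nuc_sim)
    cube <- thermal_cube(a, fps = profile$fps)
    attr(cube, "beta_true") <- beta
    cube
  })
}

# Add frame-global step offsets every interval_s seconds with alternating
# random sign, mimicking shutter-based NUC recalibration events.
inject_nuc_jumps <- function(a, fps, nuc_sim) {
  K <- dim(a)[3L]
  interval <- nuc_sim$interval_s %||% 60
  mag <- nuc_sim$magnitude_C %||% 0.5
  step <- max(1L, round(interval * fps))
  if (step > K - 1L) return(a)
  at <- seq(step, K - 1L, by = step)
  offset <- 0
  for (k0 in at) {
    offset <- mag * sample(c(-1, 1), 1L)
    idx <- (k0 + 1L):K
    a[, , idx] <- a[, , idx] + offset
  }
  a
}

# Render a ground-truth scene through a camera profile: sample at the
# profile's frame rate, blur each frame with its PSF, add its spatial noise
# map (if any of matching shape), its temporal noise and its simulated NUC
# jumps. Noise draws use `noise_seed`.
render_through_profile <- function(theta, mask, scene, profile, label,
                                   subject_id, noise_seed) {
  K <- max(2L, round(scene$duration_s * profile$fps))
  a <- evaluate_theta_cube(theta, (seq_len(K) - 1L) / profile$fps)
  if (nrow(profile$psf) > 1L || ncol(profile$psf) > 1L)
    a <- conv_cube_reflect(a, profile$psf)
  with_seed(noise_seed, {
    if (length(profile$spatial_noise)) {
      m <- nearest_setpoint_map(profile, mean(a))
      if (all(dim(m$beta) >= dim(a)[1:2])) {
        beta <- m$beta[seq_len(dim(a)[1L]), seq_len(dim(a)[2L]), drop = FALSE]
        a <- a + array(beta, dim = dim(a))
      }
    }
    tn <- profile$temporal_noise
    if (!is.null(tn))
      a <- a + synthesize_temporal_noise(tn, K_IR = K, fps = profile$fps,
                                         seed = stats::runif(1, 1, 2^30),
                                         phase_offset = FALSE)
    else if (profile$netd_mK > 0)
      a <- a + array(stats::rnorm(length(a), 0, profile$netd_mK / 1000),
                     dim = dim(a))
    if (!is.null(profile$nuc_sim))
      a <- inject_nuc_jumps(a, profile$fps, profile$nuc_sim)
  })
  acquisition_record(thermal_cube(a, fps = profile$fps), lesion_mask = mask,
                     visible = mask * 0.5 + 0.25, label = label,
                     subject_id = subject_id,
                     truth = list(theta = theta))
}

#' Generate a paired two-camera acquisition
#'
#' Renders one ground-truth scene twice: through a high-quality profile and
#' through a lower-quality profile (its own frame rate, PSF, spatial noise,
#' temporal noise and simulated NUC jumps). Both records share the scene seed,
#' so the underlying physiology is identical; only the cameras differ. This
#' emulates a simultaneous acquisition of the same lesion with two imagers,
#' the setting used to validate the degradation model.
#'
#' @param scene A \code{\link{skin_scene_config}}.
#' @param profile_hq,profile_lq \code{\link{camera_profile}}s with
#'   \code{profile_hq$fps >= profile_lq$fps}.
#' @param label Lesion class.
#' @return List with elements \code{hq} and \code{lq}, both
#'   \code{\link{acquisition_record}}s.
#' @export
generate_paired_acquisition <- function(scene, profile_hq, profile_lq,
                                        label = "benign") {
  stopifnot(inherits(scene, "skin_scene_config"),
            inherits(profile_hq, "camera_profile"),
            inherits(profile_lq, "camera_profile"))
  if (profile_lq$fps > profile_hq$fps)
    stop("unsupported direction: the low-quality camera must not be faster than the high-quality one")
  label <- match.arg(label, c("benign", "BCC", "SCC", "MM"))
  tf <- with_seed(scene$seed, draw_theta_fields(scene, label))
  hq <- render_through_profile(tf$theta, tf$mask, scene, profile_hq, label,
                               "synthetic-hq", noise_seed = scene$seed * 2L + 1L)
  lq <- render_through_profile(tf$theta, tf$mask, scene, profile_lq, label,
                               "synthetic-lq", noise_seed = scene$seed * 2L + 2L)
  list(hq = hq, lq = lq)
}
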