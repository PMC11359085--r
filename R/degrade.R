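# The degradation pipeline: temporal downsampling, PSF blur, spatial-noise
# addition and temporal-noise synthesis, applied in that fixed order.

#' Temporal downsampling by the nearest-index rule
#'
#' Output frame k' (0-based) takes source frame \code{round(k' * fps_src /
#' fps_target)}, for k' = 0, 1, ... while the index stays inside the cube.
#' No interpolation is performed: every output frame is an unmodified source
#' frame, frame 0 is preserved, and the maximum timing error is half a source
#' sampling period.
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param fps_target Target frame rate, \code{0 < fps_target <= cube$fps}.
#' @return A \code{\link{thermal_cube}} at \code{fps_target}.
#' @export
temporal_downsample <- function(cube, fps_target) {
  stopifnot(inherits(cube, "thermal_cube"), fps_target > 0)
  if (fps_target > cube$fps)
    stop("unsupported direction: fps_target exceeds the source frame rate")
  idx <- downsample_indices(n_frames(cube), cube$fps, fps_target)
  thermal_cube(cube$data[, , idx, drop = FALSE], fps = fps_target, t0 = cube$t0)
}

# 1-based source indices selected by the nearest-index rule.
downsample_indices <- function(K, fps_src, fps_target) {
  r <- fps_src / fps_target
  kprime <- 0:ceiling(K / r + 1)
  src <- round(kprime * r)
  src[src < K] + 1L
}

#' Blur every frame with a PSF kernel
#'
#' Spatial convolution of each frame with a normalized point-spread-function
#' kernel, using reflective boundary handling. Constant frames are unchanged
#' (the kernel sums to one).
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param psf Normalized kernel matrix with odd side lengths.
#' @return The blurred \code{\link{thermal_cube}}.
#' @export
apply_psf <- function(cube, psf) {
  stopifnot(inherits(cube, "thermal_cube"), is.matrix(psf))
  if (nrow(psf) %% 2L == 0L || ncol(psf) %% 2L == 0L)
    stop("PSF kernel must have odd side lengths")
  if (abs(sum(psf) - 1) > 1e-9) stop("PSF kernel must sum to 1")
  if (nrow(psf) == 1L && ncol(psf) == 1L) return(cube)
  thermal_cube(conv_cube_reflect(cube$data, psf), fps = cube$fps, t0 = cube$t0)
}

# Spatial-noise map whose setpoint is nearest to a scene temperature.
nearest_setpoint_map <- function(profile, temperature) {
  if (!length(profile$spatial_noise))
    stop("profile has no characterized spatial noise")
  sp <- vapply(profile$spatial_noise, function(m) m$setpoint, 0)
  profile$spatial_noise[[which.min(abs(sp - temperature))]]
}

#' Add a camera's spatial fixed-pattern noise
#'
#' Selects the profile's spatial noise map whose setpoint is nearest to the
#' cube's overall mean temperature and adds it to every frame. Maps larger
#' than the frame are cropped top-left anchored. Because beta has zero
#' spatial mean, per-frame spatial means are unchanged (exactly so when the
#' map is used uncropped). The chosen setpoint is attached as attribute
#' \code{"setpoint_used"}.
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param profile A \code{\link{camera_profile}} with at least one
#'   \code{\link{spatial_noise_map}}.
#' @return The \code{\link{thermal_cube}} with pattern noise added.
#' @export
add_spatial_noise <- function(cube, profile) {
  stopifnot(inherits(cube, "thermal_cube"), inherits(profile, "camera_profile"))
  m <- nearest_setpoint_map(profile, mean(cube$data))
  shp <- frame_shape(cube)
  if (any(dim(m$beta) < shp))
    stop("spatial noise map is smaller than the cube frame")
  beta <- m$beta[seq_len(shp[1L]), seq_len(shp[2L]), drop = FALSE]
  out <- thermal_cube(cube$data + array(beta, dim = dim(cube$data)),
                      fps = cube$fps, t0 = cube$t0)
  attr(out, "setpoint_used") <- m$setpoint
  out
}

#' Synthesize temporal noise from a fitted model
#'
#' Evaluates each detector's low-frequency Fourier reconstruction at sample
#' times \code{k / fps} and adds white Gaussian high-frequency noise of the
#' detector's sigma. With \code{phase_offset = TRUE} (the mimicry default) a
#' per-detector random phase, uniform on [0, 2 pi), time-shifts the drift so
#' synthesized videos do not replay the characterization record verbatim;
#' validation against a paired video uses \code{phase_offset = FALSE} to
#' reproduce the fitted drift exactly. Invalid detectors produce zeros.
#'
#' @param model A \code{\link{temporal_noise_model}}.
#' @param K_IR Number of frames to synthesize (>= 1).
#' @param fps Frame rate of the target cube.
#' @param seed Integer seed (reproducible draws).
#' @param phase_offset Randomize the drift phase per detector?
#' @return An \code{I x J x K_IR} noise array in degC.
#' @export
synthesize_temporal_noise <- function(model, K_IR, fps, seed = 1L,
                                      phase_offset = TRUE) {
  stopifnot(inherits(model, "temporal_noise_model"), K_IR >= 1, fps > 0)
  I <- nrow(model$omega); J <- ncol(model$omega); P <- I * J
  Z <- model$Z
  t <- (seq_len(K_IR) - 1L) / fps
  with_seed(seed, {
    phi <- if (phase_offset) stats::runif(P, 0, 2 * pi) else numeric(P)
    lf <- matrix(0, K_IR, P)
    om <- as.vector(model$omega)
    am <- matrix(aperm(model$a, c(3L, 1L, 2L)), nrow = Z + 1L)
    bm <- matrix(aperm(model$b, c(3L, 1L, 2L)), nrow = Z + 1L)
    lf <- lf + matrix(am[1L, ], K_IR, P, byrow = TRUE)
    for (z in seq_len(Z)) {
      ang <- outer(t, z * om) + matrix(z * phi, K_IR, P, byrow = TRUE)
      lf <- lf + cos(ang) * matrix(am[z + 1L, ], K_IR, P, byrow = TRUE) +
                 sin(ang) * matrix(bm[z + 1L, ], K_IR, P, byrow = TRUE)
    }
    hf <- matrix(stats::rnorm(K_IR * P), K_IR, P) *
      matrix(as.vector(model$sigma_hf), K_IR, P, byrow = TRUE)
    noise <- lf + hf
    noise[, !as.vector(model$valid)] <- 0
    matrix_to_cube(noise, I, J)
  })
}

#' Degradation configuration
#'
#' @param target_profile The \code{\link{camera_profile}} to mimic.
#' @param mode \code{"blackbody_profile"} (noise characterized on blackbody
#'   stacks; synthesized drift gets a random per-detector phase) or
#'   \code{"paired_video"} (noise characterized from a paired acquisition;
#'   fitted phases are reused).
#' @param seed Integer seed for the noise draws.
#' @param apply_stages Named logical flags enabling the stages
#'   \code{temporal}, \code{psf}, \code{spatial_noise}, \code{temporal_noise}
#'   (all \code{TRUE} by default).
#' @param spatial_downsample Optional integer block size for block-average
#'   spatial downsampling (default off; frame dimensions are normally left
#'   unmodified, since resampling would introduce noise that is not
#'   characteristic of the target camera).
#' @return An object of class \code{degradation_config}.
#' @export
degradation_config <- function(target_profile,
                               mode = c("blackbody_profile", "paired_video"),
                               seed = 1L,
                               apply_stages = c(temporal = TRUE, psf = TRUE,
                                                spatial_noise = TRUE,
                                                temporal_noise = TRUE),
                               spatial_downsample = NULL) {
  stopifnot(inherits(target_profile, "camera_profile"))
  mode <- match.arg(mode)
  stages <- c(temporal = TRUE, psf = TRUE, spatial_noise = TRUE,
              temporal_noise = TRUE)
  stages[names(apply_stages)] <- apply_stages
  structure(list(target_profile = target_profile, mode = mode,
                 seed = as.integer(seed), apply_stages = stages,
                 spatial_downsample = spatial_downsample),
            class = "degradation_config")
}

# Integer block-average downsampling; non-divisible margins are cropped.
block_average <- function(x, b) {
  I <- (nrow(x) %/% b) * b; J <- (ncol(x) %/% b) * b
  x <- x[seq_len(I), seq_len(J), drop = FALSE]
  xr <- rowsum(x, rep(seq_len(I %/% b), each = b))
  t(rowsum(t(xr), rep(seq_len(J %/% b), each = b))) / b^2
}

#' Degrade an acquisition to mimic a lower-quality camera
#'
#' Applies, in order: temporal downsampling to the target frame rate, PSF
#' blurring, spatial fixed-pattern noise addition, and temporal noise
#' synthesis --- the full degradation model. The lesion mask is carried
#' through unchanged (spatially) and marker-corner lists are subsampled in
#' time; the result's frame rate is the target camera's. Disabling all
#' stages returns the record unchanged.
#'
#' @param record An \code{\link{acquisition_record}} (registered).
#' @param config A \code{\link{degradation_config}}.
#' @return The degraded \code{\link{acquisition_record}}.
#' @export
degrade_cube <- function(record, config) {
  stopifnot(inherits(record, "acquisition_record"),
            inherits(config, "degradation_config"))
  prof <- config$target_profile
  st <- config$apply_stages
  cube <- record$cube
  corners <- record$marker_corners
  mask <- record$lesion_mask
  if (st[["temporal"]] && prof$fps != cube$fps) {
    idx <- downsample_indices(n_frames(cube), cube$fps, prof$fps)
    if (!is.null(corners)) corners <- corners[idx]
    cube <- temporal_downsample(cube, prof$fps)
  }
  if (st[["psf"]]) cube <- apply_psf(cube, prof$psf)
  if (!is.null(config$spatial_downsample)) {
    b <- as.integer(config$spatial_downsample)
    a <- cube$data
    out <- NULL
    for (k in seq_len(dim(a)[3L])) {
      fr <- block_average(a[, , k], b)
      if (is.null(out)) out <- array(0, c(dim(fr), dim(a)[3L]))
      out[, , k] <- fr
    }
    cube <- thermal_cube(out, fps = cube$fps, t0 = cube$t0)
    mask <- block_average(mask * 1, b) >= 0.5
    corners <- NULL
  }
  if (st[["spatial_noise"]] && length(prof$spatial_noise))
    cube <- add_spatial_noise(cube, prof)
  if (st[["temporal_noise"]] && !is.null(prof$temporal_noise)) {
    noise <- synthesize_temporal_noise(
      prof$temporal_noise, K_IR = n_frames(cube), fps = cube$fps,
      seed = config$seed,
      phase_offset = (config$mode == "blackbody_profile"))
    shp <- frame_shape(cube)
    if (any(dim(noise)[1:2] < shp))
      stop("temporal noise model grid is smaller than the cube frame")
    noise <- noise[seq_len(shp[1L]), seq_len(shp[2L]), , drop = FALSE]
    cube <- thermal_cube(cube$data + noise, fps = cube$fps, t0 = cube$t0)
  }
  acquisition_record(cube, lesion_mask = mask, visible = record$visible,
                     marker_corners = corners, label = record$label,
                     subject_id = record$subject_id, truth = record$truth)
}
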