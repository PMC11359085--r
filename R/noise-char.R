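# Camera noise characterization: spatial fixed-pattern extraction from
# blackbody stacks, NUC jump correction, and per-detector Fourier-series +
# Gaussian temporal-noise fitting.

#' Extract spatial noise from a blackbody stack
#'
#' Averages all frames of a blackbody sequence (removing temporal noise) and
#' subtracts the scalar two-dimensional mean of the average image, leaving
#' the camera's fixed spatial pattern beta.
#'
#' @param stack A \code{\link{thermal_cube}} of a stabilized blackbody
#'   (>= 2 frames; 180 recommended).
#' @param setpoint Blackbody setpoint in degC, recorded in the map.
#' @return A \code{\link{spatial_noise_map}}.
#' @export
extract_spatial_noise <- function(stack, setpoint) {
  stopifnot(inherits(stack, "thermal_cube"))
  ubar <- apply(stack$data, c(1L, 2L), mean)
  beta <- ubar - mean(ubar)
  beta <- beta - mean(beta)  # second pass guards rounding at large offsets
  spatial_noise_map(beta, setpoint, n_frames(stack))
}

#' Detect and remove NUC step discontinuities
#'
#' Shutter-based non-uniformity correction (NUC) events appear as
#' frame-global steps in the temperature series. Steps are detected on the
#' frame spatial-mean series: frame-to-frame differences whose magnitude
#' exceeds \code{jump_threshold_k} times the MAD scale of all differences are
#' declared jumps (at least \code{min_gap_frames} apart), and the cumulative
#' step offsets are subtracted from all subsequent frames so the series is
#' continuous. The operation is idempotent and translation-equivariant.
#'
#' @param cube A \code{\link{thermal_cube}} with >= 3 frames.
#' @param params A \code{\link{nuc_params}}.
#' @return List with \code{cube} (corrected) and \code{jumps}, a data frame
#'   with columns \code{frame} (first affected frame, 1-based) and
#'   \code{magnitude} (degC). With no detected jumps the cube is returned
#'   unchanged and \code{jumps} has zero rows.
#' @export
correct_nuc_jumps <- function(cube, params = nuc_params()) {
  stopifnot(inherits(cube, "thermal_cube"), inherits(params, "nuc_params"))
  K <- n_frames(cube)
  if (K < 3L) stop("NUC correction needs at least 3 frames")
  m <- colMeans(matrix(cube$data, ncol = K))
  dm <- diff(m)
  base <- stats::median(dm)
  dev <- dm - base  # smooth drift contributes a near-constant difference
  scale <- stats::mad(dev, center = 0)
  if (scale == 0) scale <- .Machine$double.eps^0.5
  cand <- which(abs(dev) > params$jump_threshold_k * scale)
  keep <- integer(0)
  for (k in cand) {
    if (!length(keep) || k - keep[length(keep)] >= params$min_gap_frames)
      keep <- c(keep, k)
  }
  if (!length(keep))
    return(list(cube = cube, jumps = data.frame(frame = integer(0),
                                                magnitude = numeric(0))))
  mags <- dev[keep]
  a <- cube$data
  for (i in seq_along(keep)) {
    idx <- (keep[i] + 1L):K
    a[, , idx] <- a[, , idx] - mags[i]
  }
  list(cube = thermal_cube(a, fps = cube$fps, t0 = cube$t0),
       jumps = data.frame(frame = keep + 1L, magnitude = mags))
}

# Fourier design matrix at angular frequency omega for samples k = 0..n-1 at
# rate fs: columns cos(z w k/fs) for z = 0..Z then sin(z w k/fs) for z = 1..Z.
fourier_design <- function(n, fs, omega, Z) {
  t <- (seq_len(n) - 1L) / fs
  X <- matrix(0, n, 2L * Z + 1L)
  X[, 1L] <- 1
  for (z in seq_len(Z)) {
    X[, 1L + z] <- cos(z * omega * t)
    X[, 1L + Z + z] <- sin(z * omega * t)
  }
  X
}

omega_grid <- function(n, fs, period_range, n_grid) {
  if (is.null(period_range)) period_range <- c(30, n / fs)
  period_range[2L] <- max(period_range[2L], period_range[1L] * 1.0001)
  periods <- seq(period_range[1L], period_range[2L], length.out = n_grid)
  sort(unique(2 * pi / periods))
}

# Vectorized per-detector Fourier fit on the columns of Y (n x P).
# Returns coefficient arrays plus per-column omega, sigma and rss.
fit_temporal_noise_matrix <- function(Y, fs, Z, period_range = NULL,
                                      n_grid = 200L, shared_omega = FALSE) {
  n <- nrow(Y); P <- ncol(Y)
  if (n < 2L * (2L * Z + 2L))
    stop(sprintf("series length %d too short for Fourier order %d", n, Z))
  omegas <- omega_grid(n, fs, period_range, n_grid)
  ss_tot <- colSums(Y^2)
  best_rss <- rep(Inf, P)
  best_om <- rep(omegas[1L], P)
  for (om in omegas) {
    Q <- qr.Q(qr(fourier_design(n, fs, om, Z)))
    B <- crossprod(Q, Y)
    rss <- pmax(ss_tot - colSums(B^2), 0)
    if (shared_omega) {
      if (sum(rss) < sum(best_rss)) { best_rss <- rss; best_om[] <- om }
    } else {
      upd <- rss < best_rss
      if (any(upd)) { best_rss[upd] <- rss[upd]; best_om[upd] <- om }
    }
  }
  a <- matrix(0, Z + 1L, P); b <- matrix(0, Z + 1L, P)
  sigma <- numeric(P)
  for (om in unique(best_om)) {
    cols <- which(best_om == om)
    X <- fourier_design(n, fs, om, Z)
    qx <- qr(X)
    cf <- qr.coef(qx, Y[, cols, drop = FALSE])
    cf[is.na(cf)] <- 0
    res <- Y[, cols, drop = FALSE] - X %*% cf
    a[, cols] <- cf[1:(Z + 1L), , drop = FALSE]
    b[2:(Z + 1L), cols] <- cf[(Z + 2L):(2L * Z + 1L), , drop = FALSE]
    sigma[cols] <- apply(res, 2L, stats::sd)
  }
  # rank-deficient / constant columns: keep the mean, zero the rest
  const <- apply(Y, 2L, function(y) stats::sd(y) == 0)
  if (any(const)) {
    a[, const] <- 0; b[, const] <- 0
    a[1L, const] <- colMeans(Y[, const, drop = FALSE])
    sigma[const] <- 0
    best_om[const] <- min(omegas)
  }
  list(a = a, b = b, omega = best_om, sigma_hf = sigma, rss = best_rss)
}

#' Fit a Fourier-series + Gaussian temporal-noise model to one series
#'
#' The fundamental angular frequency omega is chosen by grid search over a
#' range of candidate periods (default 30 s up to the record length, 200 grid
#' points); at each candidate the harmonic coefficients solve a linear least
#' squares problem, and the candidate minimizing the residual sum of squares
#' wins. The high-frequency standard deviation is the standard deviation of
#' the residual (series minus low-frequency reconstruction).
#'
#' @param series Numeric temperature (or noise) series, length >=
#'   \code{2 * (2 * Z + 2)}.
#' @param fs Sample rate in frames/s.
#' @param Z Fourier order (harmonics 0..Z).
#' @param period_range Numeric \code{c(min, max)} candidate fundamental
#'   periods in seconds, or \code{NULL} for the default.
#' @param n_grid Number of period grid points.
#' @return List with \code{a}, \code{b} (length \code{Z + 1}, \code{b[1]} is
#'   0), \code{omega} (rad/s), \code{sigma_hf} (degC) and \code{rss}. A
#'   constant series returns \code{a[1] = mean}, all other coefficients 0 and
#'   \code{sigma_hf = 0}.
#' @export
fit_temporal_noise_series <- function(series, fs, Z = 3L, period_range = NULL,
                                      n_grid = 200L) {
  stopifnot(is.numeric(series), fs > 0, Z >= 0)
  fit <- fit_temporal_noise_matrix(matrix(series, ncol = 1L), fs, Z,
                                   period_range, n_grid)
  list(a = as.vector(fit$a), b = as.vector(fit$b), omega = fit$omega[1L],
       sigma_hf = fit$sigma_hf[1L], rss = fit$rss[1L])
}

#' Characterize a camera from blackbody stacks
#'
#' NUC-corrects each stack, extracts one spatial noise map per setpoint, and
#' fits the per-detector temporal noise model from the longest stack (after
#' removing each detector's temporal mean, so the model describes noise
#' around zero). The result is the input profile with its
#' \code{spatial_noise} and \code{temporal_noise} slots populated.
#'
#' @param stacks List of blackbody \code{\link{thermal_cube}}s.
#' @param setpoints Numeric vector of setpoints (degC), one per stack; must
#'   be distinct.
#' @param profile The \code{\link{camera_profile}} being characterized.
#' @param Z Fourier order for the temporal model (default 3).
#' @param shared_omega If \code{TRUE}, fit one fundamental frequency for the
#'   whole frame (fast mode) instead of one per detector.
#' @param period_range,n_grid Passed to the Fourier fit.
#' @return The updated \code{\link{camera_profile}}.
#' @export
characterize_camera <- function(stacks, setpoints, profile, Z = 3L,
                                shared_omega = FALSE, period_range = NULL,
                                n_grid = 200L) {
  stopifnot(length(stacks) >= 1L, length(setpoints) == length(stacks))
  if (anyDuplicated(setpoints)) stop("duplicate blackbody setpoints")
  nucp <- profile$nuc %||% nuc_params()
  stacks <- lapply(stacks, function(s) correct_nuc_jumps(s, nucp)$cube)
  maps <- lapply(seq_along(stacks), function(i)
    extract_spatial_noise(stacks[[i]], setpoints[i]))
  longest <- which.max(vapply(stacks, n_frames, 0L))
  cube <- stacks[[longest]]
  I <- frame_shape(cube)[1L]; J <- frame_shape(cube)[2L]
  Y <- cube_to_matrix(cube$data)
  Y <- sweep(Y, 2L, colMeans(Y))
  fit <- fit_temporal_noise_matrix(Y, cube$fps, Z, period_range, n_grid,
                                   shared_omega)
  tn <- temporal_noise_model(
    a = aperm(array(fit$a, c(Z + 1L, I, J)), c(2L, 3L, 1L)),
    b = aperm(array(fit$b, c(Z + 1L, I, J)), c(2L, 3L, 1L)),
    omega = matrix(fit$omega, I, J),
    sigma_hf = matrix(fit$sigma_hf, I, J),
    fs = cube$fps)
  profile$spatial_noise <- maps
  profile$temporal_noise <- tn
  profile
}

#' Characterize temporal noise from a registered video
#'
#' The paired-video characterization mode: for each pixel the temporal noise
#' is the series minus its double-exponential recovery fit, and that noise is
#' then modeled as a Fourier series plus Gaussian residual. Pixels whose
#' recovery fit fails (or whose series is not finite) are flagged invalid and
#' excluded; their model entries are zero.
#'
#' @param cube A registered \code{\link{thermal_cube}}, or a plain 3-D array
#'   (in which case \code{fps} must be given; non-finite pixels are then
#'   tolerated and flagged rather than rejected).
#' @param Z Fourier order.
#' @param fps Frame rate, required when \code{cube} is a plain array.
#' @param shared_omega,period_range,n_grid Passed to the Fourier fit.
#' @param fits Optional precomputed \code{\link{fit_cube_trcs}} result for
#'   the cube, to avoid refitting.
#' @return A \code{\link{temporal_noise_model}} whose \code{valid} slot marks
#'   usable detectors.
#' @export
extract_video_temporal_noise <- function(cube, Z = 3L, fps = NULL,
                                         shared_omega = FALSE,
                                         period_range = NULL, n_grid = 200L,
                                         fits = NULL) {
  if (inherits(cube, "thermal_cube")) {
    a <- cube$data; fps <- cube$fps
  } else {
    stopifnot(is.array(cube), length(dim(cube)) == 3L, !is.null(fps))
    a <- cube
  }
  I <- dim(a)[1L]; J <- dim(a)[2L]; K <- dim(a)[3L]
  Y <- cube_to_matrix(a)
  if (is.null(fits)) fits <- fit_cube_trcs_matrix(Y, fps)
  valid <- fits$converged & apply(is.finite(Y), 2L, all)
  NT <- Y - fits$fitted
  am <- matrix(0, Z + 1L, I * J); bm <- matrix(0, Z + 1L, I * J)
  om <- rep(NA_real_, I * J); sg <- numeric(I * J)
  if (any(valid)) {
    fit <- fit_temporal_noise_matrix(NT[, valid, drop = FALSE], fps, Z,
                                     period_range, n_grid, shared_omega)
    am[, valid] <- fit$a; bm[, valid] <- fit$b
    om[valid] <- fit$omega; sg[valid] <- fit$sigma_hf
  }
  om[!is.finite(om)] <- 2 * pi / max(K / fps, 1)
  temporal_noise_model(
    a = aperm(array(am, c(Z + 1L, I, J)), c(2L, 3L, 1L)),
    b = aperm(array(bm, c(Z + 1L, I, J)), c(2L, 3L, 1L)),
    omega = matrix(om, I, J), sigma_hf = matrix(sg, I, J),
    fs = fps, valid = matrix(valid, I, J))
}
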