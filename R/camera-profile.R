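#' Spatial fixed-pattern noise map
#'
#' The zero-mean fixed-pattern image beta of a camera at one blackbody
#' setpoint, extracted by time-averaging a calibration stack and removing the
#' scalar spatial mean. It bundles horizontal/vertical banding, low-, mid- and
#' high-frequency pattern and residual non-uniformity.
#'
#' @param beta Numeric I x J matrix in degrees C with (machine-precision)
#'   zero spatial mean.
#' @param setpoint Blackbody setpoint in degrees C the map was measured at.
#' @param n_frames_used Number of frames averaged.
#' @return An object of class \code{spatial_noise_map}.
#' @export
spatial_noise_map <- function(beta, setpoint, n_frames_used) {
  stopifnot(is.matrix(beta), is.numeric(beta), all(is.finite(beta)))
  if (abs(mean(beta)) > 1e-9)
    stop(sprintf("spatial noise map must have zero 2-D mean (got %.3g degC)", mean(beta)))
  structure(list(beta = beta, setpoint = as.numeric(setpoint),
                 n_frames_used = as.integer(n_frames_used)),
            class = "spatial_noise_map")
}

#' Per-detector temporal noise model
#'
#' Fourier-series low-frequency drift plus white Gaussian high-frequency
#' noise, fitted independently for each detector (i, j):
#' \deqn{N^{LF}_{i,j,k} = \sum_{z=0}^{Z} a_{i,j,z} \cos(z \omega_{i,j} k / f_s)
#'       + b_{i,j,z} \sin(z \omega_{i,j} k / f_s),}
#' with residual \eqn{N^{HF} \sim N(0, \sigma_{i,j}^2)}. \code{b[, , 1]}
#' (the z = 0 sine term) is identically zero.
#'
#' @param a,b Numeric arrays \code{I x J x (Z + 1)} of cosine/sine
#'   coefficients in degrees C; slice \code{z + 1} holds harmonic z.
#' @param omega Numeric I x J matrix of fundamental angular frequencies in
#'   rad/s (> 0).
#' @param sigma_hf Numeric I x J matrix of high-frequency standard deviations
#'   in degrees C (>= 0).
#' @param fs Frame rate (frames/s) the model was fitted at.
#' @param valid Logical I x J matrix; \code{FALSE} marks detectors whose fit
#'   failed (their coefficients are zero).
#' @return An object of class \code{temporal_noise_model}.
#' @export
temporal_noise_model <- function(a, b, omega, sigma_hf, fs, valid = NULL) {
  stopifnot(is.array(a), is.array(b), length(dim(a)) == 3L,
            identical(dim(a), dim(b)))
  I <- dim(a)[1L]; J <- dim(a)[2L]; Z <- dim(a)[3L] - 1L
  stopifnot(identical(dim(omega), c(I, J)), identical(dim(sigma_hf), c(I, J)))
  if (any(sigma_hf < 0)) stop("sigma_hf must be non-negative everywhere")
  if (any(omega <= 0)) stop("omega must be positive everywhere")
  if (any(b[, , 1L] != 0)) stop("b[, , 1] (the z = 0 sine term) must be zero")
  if (is.null(valid)) valid <- matrix(TRUE, I, J)
  structure(list(a = a, b = b, omega = omega, sigma_hf = sigma_hf,
                 Z = Z, fs = as.numeric(fs), valid = valid),
            class = "temporal_noise_model")
}

#' @export
print.temporal_noise_model <- function(x, ...) {
  cat(sprintf("<temporal_noise_model> %d x %d detectors, Z=%d, fs=%.4g fps, median sigma_hf=%.4g degC\n",
              nrow(x$omega), ncol(x$omega), x$Z, x$fs,
              stats::median(x$sigma_hf[x$valid])))
  invisible(x)
}

#' NUC jump-detection parameters
#'
#' Controls detection of the step discontinuities that a camera's shutter
#' based non-uniformity correction (NUC) introduces in temperature series.
#'
#' @param jump_threshold_k Multiplier on the robust (MAD) scale of the
#'   frame-to-frame mean differences above which a difference is declared a
#'   jump (default 6).
#' @param min_gap_frames Minimum number of frames between two detected jumps
#'   (default 5).
#' @return An object of class \code{nuc_params}.
#' @export
nuc_params <- function(jump_threshold_k = 6, min_gap_frames = 5) {
  stopifnot(jump_threshold_k > 0, min_gap_frames >= 1)
  structure(list(jump_threshold_k = jump_threshold_k,
                 min_gap_frames = as.integer(min_gap_frames)),
            class = "nuc_params")
}

#' Camera profile
#'
#' Static specifications of an infrared imager (frame rate, focal-plane-array
#' size, nominal NETD) plus its characterized degradation ingredients: a
#' normalized PSF kernel, per-setpoint spatial noise maps, an optional
#' per-detector temporal noise model, and optional NUC handling parameters.
#'
#' The PSF may be given either as an explicit kernel (odd sides, non-negative,
#' summing to 1) or as a parametric Gaussian width \code{psf_sigma} in pixels,
#' which is expanded to a kernel of side \code{2 * ceiling(3 * sigma) + 1}.
#'
#' @param name Camera name.
#' @param fps Frame rate in frames/s (> 0).
#' @param fpa Integer vector \code{c(rows, cols)} of the focal plane array.
#' @param netd_mK Nominal noise-equivalent temperature difference in mK.
#' @param psf Optional explicit kernel matrix; mutually exclusive with
#'   \code{psf_sigma}.
#' @param psf_sigma Optional Gaussian PSF width in pixels (0 = identity).
#' @param spatial_noise List of \code{\link{spatial_noise_map}} objects.
#' @param temporal_noise Optional \code{\link{temporal_noise_model}}.
#' @param nuc Optional \code{\link{nuc_params}}.
#' @param nuc_sim Optional list \code{list(interval_s=, magnitude_C=)}
#'   describing NUC jumps to inject when this profile is used to *generate*
#'   synthetic acquisitions (simulation-side only; ignored by degradation).
#' @return An object of class \code{camera_profile}.
#' @examples
#' p <- camera_profile("lowcost", fps = 8.7, fpa = c(288, 384), netd_mK = 70,
#'                     psf_sigma = 1.2)
#' sum(p$psf)
#' @export
camera_profile <- function(name, fps, fpa, netd_mK, psf = NULL,
                           psf_sigma = NULL, spatial_noise = list(),
                           temporal_noise = NULL, nuc = NULL, nuc_sim = NULL) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  if (!is.null(psf) && !is.null(psf_sigma))
    stop("give either `psf` or `psf_sigma`, not both")
  if (is.null(psf)) psf <- gaussian_kernel(psf_sigma %||% 0)
  if (nrow(psf) %% 2L == 0L || ncol(psf) %% 2L == 0L)
    stop("PSF kernel must have odd side lengths")
  if (any(psf < 0)) stop("PSF kernel entries must be non-negative")
  s <- sum(psf)
  if (!is.finite(s) || s <= 0) stop("PSF kernel is not normalizable")
  if (abs(s - 1) > 1e-9) psf <- psf / s
  for (m in spatial_noise) stopifnot(inherits(m, "spatial_noise_map"))
  if (!is.null(temporal_noise)) stopifnot(inherits(temporal_noise, "temporal_noise_model"))
  if (!is.null(nuc)) stopifnot(inherits(nuc, "nuc_params"))
  structure(list(name = as.character(name), fps = as.numeric(fps),
                 fpa = as.integer(fpa), netd_mK = as.numeric(netd_mK),
                 psf = psf, spatial_noise = spatial_noise,
                 temporal_noise = temporal_noise, nuc = nuc,
                 nuc_sim = nuc_sim),
            class = "camera_profile")
}

#' @export
print.camera_profile <- function(x, ...) {
  cat(sprintf("<camera_profile> %s: %.4g fps, FPA %d x %d, NETD %g mK, PSF %d x %d\n",
              x$name, x$fps, x$fpa[1L], x$fpa[2L], x$netd_mK,
              nrow(x$psf), ncol(x$psf)))
  if (length(x$spatial_noise))
    cat("  spatial noise setpoints:",
        paste(vapply(x$spatial_noise, function(m) m$setpoint, 0), collapse = ", "),
        "degC\n")
  if (!is.null(x$temporal_noise)) { cat("  "); print(x$temporal_noise) }
  invisible(x)
}

#' Save / load a camera profile
#'
#' Profiles are serialized as a YAML file holding the nominal specifications
#' plus relative paths to plain-text CSV companions for the characterized
#' arrays (PSF kernel, beta maps, temporal-noise coefficient planes).
#' Loading is deterministic: reading the same file twice yields equal objects.
#'
#' @param profile A \code{\link{camera_profile}}.
#' @param path Path of the YAML file; companions are written next to it,
#'   prefixed with the file's base name.
#' @return \code{load_camera_profile} returns a validated
#'   \code{camera_profile}; \code{save_camera_profile} returns \code{path}
#'   invisibly.
#' @export
save_camera_profile <- function(profile, path) {
  stopifnot(inherits(profile, "camera_profile"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  base <- sub("\\.ya?ml$", "", basename(path))
  dirn <- dirname(path)
  wcsv <- function(m, tag) {
    fn <- sprintf("%s_%s.csv", base, tag)
    utils::write.table(m, file.path(dirn, fn), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    fn
  }
  doc <- list(name = profile$name, fps = profile$fps,
              fpa = as.integer(profile$fpa), netd_mK = profile$netd_mK,
              psf = list(kernel_file = wcsv(profile$psf, "psf")))
  if (length(profile$spatial_noise))
    doc$spatial_noise <- lapply(seq_along(profile$spatial_noise), function(i) {
      m <- profile$spatial_noise[[i]]
      list(setpoint = m$setpoint, n_frames_used = m$n_frames_used,
           beta_file = wcsv(m$beta, sprintf("beta_%02d", i)))
    })
  tn <- profile$temporal_noise
  if (!is.null(tn)) {
    zt <- lapply(0:tn$Z, function(z)
      list(z = z, a_file = wcsv(tn$a[, , z + 1L], sprintf("tn_a%d", z)),
           b_file = wcsv(tn$b[, , z + 1L], sprintf("tn_b%d", z))))
    doc$temporal_noise <- list(Z = tn$Z, fs = tn$fs, harmonics = zt,
                               omega_file = wcsv(tn$omega, "tn_omega"),
                               sigma_hf_file = wcsv(tn$sigma_hf, "tn_sigma"),
                               valid_file = wcsv(tn$valid * 1L, "tn_valid"))
  }
  if (!is.null(profile$nuc))
    doc$nuc <- list(jump_threshold_k = profile$nuc$jump_threshold_k,
                    min_gap_frames = profile$nuc$min_gap_frames)
  if (!is.null(profile$nuc_sim)) doc$nuc_sim <- profile$nuc_sim
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname save_camera_profile
#' @export
load_camera_profile <- function(path) {
  if (!file.exists(path)) stop("camera profile file not found: ", path)
  doc <- yaml::read_yaml(path)
  dirn <- dirname(path)
  rcsv <- function(fn) as.matrix(utils::read.table(file.path(dirn, fn),
                                                   sep = ",", header = FALSE))
  psf <- NULL; psf_sigma <- NULL
  if (!is.null(doc$psf)) {
    if (!is.null(doc$psf$kernel_file)) psf <- unname(rcsv(doc$psf$kernel_file))
    else if (!is.null(doc$psf$kernel)) psf <- do.call(rbind, doc$psf$kernel)
    else if (!is.null(doc$psf$sigma)) psf_sigma <- doc$psf$sigma
  }
  sn <- lapply(doc$spatial_noise %||% list(), function(e)
    spatial_noise_map(unname(rcsv(e$beta_file)), e$setpoint, e$n_frames_used %||% 1L))
  tn <- NULL
  if (!is.null(doc$temporal_noise)) {
    e <- doc$temporal_noise
    om <- unname(rcsv(e$omega_file)); I <- nrow(om); J <- ncol(om)
    a <- array(0, c(I, J, e$Z + 1L)); b <- array(0, c(I, J, e$Z + 1L))
    for (h in e$harmonics) {
      a[, , h$z + 1L] <- unname(rcsv(h$a_file))
      b[, , h$z + 1L] <- unname(rcsv(h$b_file))
    }
    tn <- temporal_noise_model(a, b, om, unname(rcsv(e$sigma_hf_file)),
                               fs = e$fs,
                               valid = unname(rcsv(e$valid_file)) > 0)
  }
  nuc <- if (!is.null(doc$nuc))
    nuc_params(doc$nuc$jump_threshold_k %||% 6, doc$nuc$min_gap_frames %||% 5)
  camera_profile(doc$name, doc$fps, unlist(doc$fpa), doc$netd_mK,
                 psf = psf, psf_sigma = psf_sigma, spatial_noise = sn,
                 temporal_noise = tn, nuc = nuc, nuc_sim = doc$nuc_sim)
}
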