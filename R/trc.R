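# Per-pixel thermoregulation-curve modeling: double-exponential fits,
# reference temperature, curve selection and representative curves.

dexp_curve <- function(theta, t) {
  theta[1L] + theta[2L] * exp(theta[3L] * t) + theta[4L] * exp(theta[5L] * t)
}

# Variable-projection fit: for fixed rates (th3, th5) the plateau and the
# two amplitudes solve a linear least-squares problem, so the nonlinear
# search runs over the two rates only. This removes the near-collinearity
# of a rate approaching zero with the plateau term, which stalls a naive
# 5-parameter Levenberg-Marquardt on noisy recovery curves.
dexp_amp_solve <- function(r, t, y) {
  X <- cbind(1, exp(r[1L] * t), exp(r[2L] * t))
  cf <- qr.coef(qr(X), y)
  cf[is.na(cf)] <- 0
  list(cf = cf, res = as.vector(X %*% cf) - y)
}

# Deterministic rate initializer tied to the record length: a slow component
# spanning ~20% of the record and a fast one spanning ~5%.
dexp_init_rates <- function(t) {
  Ttot <- max(t[length(t)], 1e-6)
  c(-1 / (0.2 * Ttot), -1 / (0.05 * Ttot))
}

dexp_fit_core <- function(y, t) {
  init <- dexp_init_rates(t)
  restarts <- list(c(1, 1), c(3, 0.3), c(0.2, 3), c(10, 1))
  best <- NULL
  for (r in restarts) {
    start <- init * r
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = c(-Inf, -Inf), upper = c(0, 0),
        fn = function(p) dexp_amp_solve(p, t, y)$res,
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rates <- unname(coef(fit))
    sol <- dexp_amp_solve(rates, t, y)
    th <- c(sol$cf[1L], sol$cf[2L], rates[1L], sol$cf[3L], rates[2L])
    ok <- fit$info %in% 1:3 && all(is.finite(th))
    if (ok) { best <- list(theta = th, rms = sqrt(mean(sol$res^2))); break }
  }
  if (is.null(best)) {
    Ttot <- max(t[length(t)], 1e-6)
    th <- c(mean(y), 0, -1 / Ttot, 0, -1 / Ttot)
    list(theta = th, rms = sqrt(mean((mean(y) - y)^2)), converged = FALSE)
  } else c(best, converged = TRUE)
}

#' Fit a double-exponential recovery model to one TRC
#'
#' Models a thermoregulation curve as \code{f(t) = th1 + th2 exp(th3 t) +
#' th4 exp(th5 t)} by nonlinear least squares with the rates constrained
#' non-positive. The fit uses variable projection: for fixed rates the
#' plateau and amplitudes solve a linear least-squares problem, and a
#' Levenberg--Marquardt search runs over the two rates only, from a
#' deterministic initializer (time constants at 20\% and 5\% of the record
#' length); up to three restarts with perturbed rates are attempted on
#' non-convergence. Fitting never throws on a well-formed series: if every
#' attempt fails, \code{converged = FALSE} is returned with the fallback
#' parameters \code{(mean, 0, -1/T, 0, -1/T)}.
#'
#' The initial temperature \code{f0 = th1 + th2 + th4} is the fit evaluated
#' at t = 0, not the first sample.
#'
#' @param series Numeric temperature series of length >= 8.
#' @param fps Sample rate in frames/s.
#' @return An object of class \code{double_exp_fit}: \code{theta} (5-vector),
#'   \code{f0} (degC), \code{rms_residual} (degC), \code{converged}.
#' @examples
#' y <- generate_trc(c(32, -2, -0.05, -1, -0.5), K_IR = 900, fps = 10)
#' fit <- fit_double_exponential(y, fps = 10)
#' fit$f0  # close to 32 - 2 - 1 = 29
#' @export
fit_double_exponential <- function(series, fps) {
  if (length(series) < 8L)
    stop("series must have at least 8 samples to identify 5 parameters")
  stopifnot(fps > 0, all(is.finite(series)))
  t <- (seq_along(series) - 1L) / fps
  res <- dexp_fit_core(series, t)
  structure(list(theta = res$theta,
                 f0 = sum(res$theta[c(1L, 2L, 4L)]),
                 rms_residual = res$rms, converged = res$converged),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf("<double_exp_fit> f0=%.3f degC, plateau=%.3f, rates=(%.4g, %.4g), rms=%.3g%s\n",
              x$f0, x$theta[1L], x$theta[3L], x$theta[5L], x$rms_residual,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Fit every column of a K x P series matrix; returns 5 x P theta, fitted
# curves, f0, rms and convergence flags. Non-finite columns get the fallback.
fit_cube_trcs_matrix <- function(Y, fps) {
  K <- nrow(Y); P <- ncol(Y)
  t <- (seq_len(K) - 1L) / fps
  theta <- matrix(0, 5L, P)
  fitted <- matrix(0, K, P)
  rms <- numeric(P); conv <- logical(P)
  for (p in seq_len(P)) {
    y <- Y[, p]
    if (!all(is.finite(y))) {
      mu <- mean(y[is.finite(y)])
      if (!is.finite(mu)) mu <- 0
      theta[, p] <- c(mu, 0, -1 / max(t[K], 1e-6), 0, -1 / max(t[K], 1e-6))
      fitted[, p] <- mu; rms[p] <- Inf; conv[p] <- FALSE
      next
    }
    res <- dexp_fit_core(y, t)
    theta[, p] <- res$theta
    fitted[, p] <- dexp_curve(res$theta, t)
    rms[p] <- res$rms; conv[p] <- res$converged
  }
  list(theta = theta, fitted = fitted,
       f0 = colSums(theta[c(1L, 2L, 4L), , drop = FALSE]),
       rms = rms, converged = conv)
}

#' Fit recovery models for every pixel of a cube
#'
#' Applies \code{\link{fit_double_exponential}} to each pixel's TRC.
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param keep_fitted Keep the fitted curves (needed for video temporal-noise
#'   characterization); default \code{TRUE}.
#' @return An object of class \code{trc_fit_grid}: \code{theta}
#'   (\code{I x J x 5}), \code{f0}, \code{rms_residual} and \code{converged}
#'   (\code{I x J} matrices), \code{fps}, and optionally \code{fitted}
#'   (\code{K x (I*J)} matrix, pixels in column-major order).
#' @export
fit_cube_trcs <- function(cube, keep_fitted = TRUE) {
  stopifnot(inherits(cube, "thermal_cube"))
  I <- frame_shape(cube)[1L]; J <- frame_shape(cube)[2L]
  res <- fit_cube_trcs_matrix(cube_to_matrix(cube$data), cube$fps)
  structure(list(theta = aperm(array(res$theta, c(5L, I, J)), c(2L, 3L, 1L)),
                 f0 = matrix(res$f0, I, J),
                 rms_residual = matrix(res$rms, I, J),
                 converged = matrix(res$converged, I, J),
                 fitted = if (keep_fitted) res$fitted,
                 fps = cube$fps),
            class = "trc_fit_grid")
}

#' Reference temperature of the lesion area
#'
#' The expectation of the fitted initial temperature f(0) over the
#' (converged) lesion-area fits.
#'
#' @param fits A \code{trc_fit_grid} (from \code{\link{fit_cube_trcs}}), or a
#'   list of \code{double_exp_fit} objects.
#' @param lesion_mask Logical matrix selecting the lesion set L; required
#'   when \code{fits} is a grid.
#' @return Tref in degC.
#' @export
compute_reference_temperature <- function(fits, lesion_mask = NULL) {
  if (inherits(fits, "trc_fit_grid")) {
    stopifnot(!is.null(lesion_mask))
    sel <- lesion_mask & fits$converged
    if (!any(sel)) stop("no converged fits in the lesion area")
    return(mean(fits$f0[sel]))
  }
  f0 <- vapply(fits, function(f) f$f0, 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop("no converged fits in the lesion area")
  mean(f0[conv])
}

#' Select TRCs with initial temperature near the reference
#'
#' Applies the relative-margin selection rule: a pixel enters the selection
#' set S when its fitted initial temperature satisfies
#' \code{|f0 - Tref| <= p * Tref}. The working sets are then
#' \code{L* = L intersect S} (lesion) and \code{N* = N intersect S}
#' (non-lesion). Pixels whose fit did not converge are excluded from S.
#'
#' @param fits A \code{trc_fit_grid}.
#' @param lesion_mask Logical lesion matrix (the set L).
#' @param Tref Reference temperature in degC (> 0); defaults to
#'   \code{\link{compute_reference_temperature}} on the lesion area.
#' @param p Relative margin (0 < p < 1; default 0.01, i.e. a 1\% band).
#' @return An object of class \code{selection_result}: logical matrices
#'   \code{S}, \code{L_star}, \code{N_star}, plus \code{Tref} and \code{p}.
#' @export
select_trcs <- function(fits, lesion_mask, Tref = NULL, p = 0.01) {
  stopifnot(inherits(fits, "trc_fit_grid"), is.matrix(lesion_mask))
  if (is.null(Tref)) Tref <- compute_reference_temperature(fits, lesion_mask)
  stopifnot(Tref > 0, p > 0, p < 1)
  S <- fits$converged & (abs(fits$f0 - Tref) <= p * Tref)
  L_star <- S & lesion_mask
  N_star <- S & !lesion_mask
  if (!any(L_star) || !any(N_star))
    stop("selection failure: empty L* or N*; consider a larger margin p")
  structure(list(Tref = Tref, p = p, S = S, L_star = L_star, N_star = N_star),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> Tref=%.3f degC, p=%.3g, |S|=%d, |L*|=%d, |N*|=%d\n",
              x$Tref, x$p, sum(x$S), sum(x$L_star), sum(x$N_star)))
  invisible(x)
}

#' Representative TRC of a pixel set
#'
#' Pointwise mean of the raw (not fitted) TRCs over a set of pixels.
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param pixel_set Logical \code{I x J} matrix or an n x 2 matrix of
#'   (row, col) indices; must select at least one pixel.
#' @return Numeric series of length \code{K_IR}.
#' @export
representative_trc <- function(cube, pixel_set) {
  stopifnot(inherits(cube, "thermal_cube"))
  Y <- cube_to_matrix(cube$data)
  I <- frame_shape(cube)[1L]
  if (is.logical(pixel_set)) {
    stopifnot(identical(dim(pixel_set), frame_shape(cube)))
    cols <- which(as.vector(pixel_set))
  } else {
    pixel_set <- as.matrix(pixel_set)
    cols <- (pixel_set[, 2L] - 1L) * I + pixel_set[, 1L]
  }
  if (!length(cols)) stop("empty pixel set")
  rowMeans(Y[, cols, drop = FALSE])
}
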