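# Screening features: distance and energy of the representative TRCs, and
# statistical-similitude features against class-descriptive curves.

#' Normalized Euclidean distance between two TRCs
#'
#' The L2 norm of the difference divided by the number of samples, so that
#' records of different lengths are comparable.
#'
#' @param trc_a,trc_b Numeric series of equal length (>= 1).
#' @return Non-negative distance (degC per sample count).
#' @export
euclidean_distance <- function(trc_a, trc_b) {
  if (length(trc_a) != length(trc_b)) stop("series lengths differ")
  sqrt(sum((trc_a - trc_b)^2)) / length(trc_a)
}

#' Energy difference between two TRCs
#'
#' Each series is first unbiased by subtracting its own minimum; the feature
#' is the squared norm of the first unbiased series minus that of the
#' second. The signed value is returned (the classifier consumes its
#' absolute value); offsetting either series leaves it unchanged.
#'
#' @param trc_a,trc_b Numeric series of equal length.
#' @return Signed energy difference (degC^2 scale).
#' @export
energy_difference <- function(trc_a, trc_b) {
  if (length(trc_a) != length(trc_b)) stop("series lengths differ")
  ua <- trc_a - min(trc_a)
  ub <- trc_b - min(trc_b)
  sum(ua^2) - sum(ub^2)
}

# Evaluate double-exponential curves for a 5 x n matrix of parameters on a
# common time grid; columns are curves.
theta_curves <- function(theta, K_IR, fps) {
  t <- (seq_len(K_IR) - 1L) / fps
  exp(outer(t, theta[3L, ])) * rep(theta[2L, ], each = K_IR) +
    exp(outer(t, theta[5L, ])) * rep(theta[4L, ], each = K_IR) +
    rep(theta[1L, ], each = K_IR)
}

unit_normalize_cols <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2L, nrm, "/")
}

#' Build the class-descriptive TRC model
#'
#' Averages the five recovery parameters over the training records of each
#' class, evaluates the average-parameter curve on the analysis grid, and
#' scales each curve to unit norm. Averaging parameters (not curves) keeps
#' the descriptive curve inside the model family.
#'
#' @param theta_malignant,theta_benign 5-row matrices (or lists of
#'   5-vectors) of fitted parameters from the training records of each
#'   class; at least one column each.
#' @param K_IR Number of samples of the analysis grid.
#' @param fps Sample rate of the grid.
#' @return An object of class \code{descriptive_model} with unit-norm curves
#'   \code{fM}, \code{fB} and the averaged parameter vectors.
#' @export
build_descriptive_model <- function(theta_malignant, theta_benign, K_IR, fps) {
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(cbind, x)
    x <- as.matrix(x)
    if (nrow(x) != 5L) stop("parameters must be 5-vectors")
    if (ncol(x) < 1L) stop("empty class: no training parameters")
    x
  }
  thM <- rowMeans(as_mat(theta_malignant))
  thB <- rowMeans(as_mat(theta_benign))
  fM <- generate_trc(thM, K_IR, fps)
  fB <- generate_trc(thB, K_IR, fps)
  structure(list(fM = fM / sqrt(sum(fM^2)), fB = fB / sqrt(sum(fB^2)),
                 theta_M_mean = thM, theta_B_mean = thB,
                 K_IR = as.integer(K_IR), fps = fps),
            class = "descriptive_model")
}

#' Statistical-similitude features of a TRC set against a model curve
#'
#' For each member curve fn of the set (already modeled and unit-normalized,
#' mirroring the model's treatment) three quantities are computed against
#' the unit-norm model fm: the projection \code{<fn, fm>}, the Pearson
#' correlation, and the sample-normalized Euclidean distance. The feature
#' set is the mean and standard deviation of each over the members.
#'
#' @param trc_set Numeric matrix, one member curve per column (intended for
#'   at least 10 members; smaller sets proceed with a warning).
#' @param model Unit-norm numeric series of matching length.
#' @param min_set Floor on the member count before warning (default 10).
#' @return Named numeric vector \code{proj_mean, proj_sd, rho_mean, rho_sd,
#'   dist_mean, dist_sd}. Members with zero variance (undefined correlation)
#'   are skipped.
#' @export
similitude_features <- function(trc_set, model, min_set = 10L) {
  trc_set <- as.matrix(trc_set)
  if (ncol(trc_set) == 0L) stop("empty TRC set")
  if (nrow(trc_set) != length(model)) stop("member length differs from model")
  if (ncol(trc_set) < min_set)
    warning(sprintf("similitude set has only %d members (< %d)",
                    ncol(trc_set), min_set))
  sds <- apply(trc_set, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("skipping %d zero-variance member(s)", sum(sds == 0)))
    trc_set <- trc_set[, sds > 0, drop = FALSE]
    if (ncol(trc_set) == 0L) stop("all members have zero variance")
  }
  proj <- as.vector(crossprod(trc_set, model))
  rho <- as.vector(stats::cor(trc_set, model))
  dist <- sqrt(colSums((trc_set - model)^2)) / length(model)
  c(proj_mean = mean(proj), proj_sd = stats::sd(proj),
    rho_mean = mean(rho), rho_sd = stats::sd(rho),
    dist_mean = mean(dist), dist_sd = stats::sd(dist))
}

# Modeled + unit-normalized member curves for the pixels of a logical set.
member_curves <- function(fits, set_mask, K_IR) {
  cols <- which(as.vector(set_mask))
  th <- matrix(aperm(fits$theta, c(3L, 1L, 2L)), nrow = 5L)[, cols, drop = FALSE]
  unit_normalize_cols(theta_curves(th, K_IR, fits$fps))
}

#' Extract the screening feature vector of one record
#'
#' Computes the distance d and energy difference Ed between the
#' representative TRCs of the selected lesion (L*) and non-lesion (N*) sets,
#' plus the 24 statistical-similitude features: the six statistics of
#' \code{\link{similitude_features}} for each combination of model curve
#' (malignant fM / benign fB) and area (L* / N*), suffixed \code{_ML},
#' \code{_MN}, \code{_BL}, \code{_BN} (model class first, area second). The
#' classifier's selected 4-vector is \code{[|Ed|, rho_sd_BL, proj_sd_BN,
#' dist_sd_MN]}.
#'
#' @param record An \code{\link{acquisition_record}}.
#' @param selection A \code{\link{select_trcs}} result for the record.
#' @param model A \code{\link{descriptive_model}} built from training
#'   records (excluding this one during evaluation).
#' @param fits Optional precomputed \code{\link{fit_cube_trcs}} grid; fitted
#'   per call otherwise.
#' @return An object of class \code{feature_vector}: \code{d}, \code{Ed}
#'   (signed), \code{similitude} (named 24-vector) and \code{selected}
#'   (named 4-vector).
#' @export
extract_features <- function(record, selection, model, fits = NULL) {
  stopifnot(inherits(record, "acquisition_record"),
            inherits(selection, "selection_result"),
            inherits(model, "descriptive_model"))
  cube <- record$cube
  if (is.null(fits)) fits <- fit_cube_trcs(cube, keep_fitted = FALSE)
  K <- n_frames(cube)
  rep_L <- representative_trc(cube, selection$L_star)
  rep_N <- representative_trc(cube, selection$N_star)
  d <- euclidean_distance(rep_L, rep_N)
  Ed <- energy_difference(rep_L, rep_N)
  mem_L <- member_curves(fits, selection$L_star, K)
  mem_N <- member_curves(fits, selection$N_star, K)
  curves <- list(M = model$fM, B = model$fB)
  areas <- list(L = mem_L, N = mem_N)
  sim <- c()
  for (mc in names(curves)) for (ar in names(areas)) {
    s <- suppressWarnings(similitude_features(areas[[ar]], curves[[mc]]))
    names(s) <- paste0(names(s), "_", mc, ar)
    sim <- c(sim, s)
  }
  selected <- c(Ed_abs = abs(Ed),
                rho_sd_BL = unname(sim["rho_sd_BL"]),
                proj_sd_BN = unname(sim["proj_sd_BN"]),
                dist_sd_MN = unname(sim["dist_sd_MN"]))
  structure(list(d = d, Ed = Ed, similitude = sim, selected = selected),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> d=%.4g, Ed=%.4g; selected: %s\n", x$d, x$Ed,
              paste(sprintf("%s=%.4g", names(x$selected), x$selected),
                    collapse = ", ")))
  invisible(x)
}
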