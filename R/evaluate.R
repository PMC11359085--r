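# Bootstrap classifier evaluation and degradation-mimicry validation.

#' Classification metrics
#'
#' Accuracy, true positive rate, true negative rate and positive predictive
#' value (malignant = positive), in percent, plus per-subclass TPRs over the
#' members of each malignant subclass. Metrics with a zero denominator are
#' reported as \code{NA} (absent), never as 0.
#'
#' @param truth Character vector of true labels: \code{"benign"} or a
#'   malignant subclass (\code{"BCC"}, \code{"SCC"}, \code{"MM"}) or plain
#'   \code{"malignant"}.
#' @param predicted Character vector of predicted binary labels
#'   (\code{"benign"} / \code{"malignant"}), same length.
#' @return Named list \code{accuracy, TPR, TPR_MM, TPR_BCC, TPR_SCC, TNR,
#'   PPV} in percent.
#' @examples
#' compute_metrics(c("MM", "BCC", "benign", "benign"),
#'                 c("malignant", "benign", "benign", "benign"))
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  if (!length(truth)) stop("empty label vectors")
  pos_t <- is_malignant_label(truth) | truth == "malignant"
  pos_p <- is_malignant_label(predicted) | predicted == "malignant"
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(
    accuracy = pct(sum(pos_t == pos_p), length(truth)),
    TPR = pct(sum(pos_t & pos_p), sum(pos_t)),
    TPR_MM = pct(sum(truth == "MM" & pos_p), sum(truth == "MM")),
    TPR_BCC = pct(sum(truth == "BCC" & pos_p), sum(truth == "BCC")),
    TPR_SCC = pct(sum(truth == "SCC" & pos_p), sum(truth == "SCC")),
    TNR = pct(sum(!pos_t & !pos_p), sum(!pos_t)),
    PPV = pct(sum(pos_t & pos_p), sum(pos_p)))
  out
}

#' Bootstrap evaluation configuration
#'
#' @param n_reps Number of bootstrap repetitions (default 2000).
#' @param train_frac Fraction of each resample used for training (default
#'   0.8).
#' @param classifier One of \code{"random_forest"} (default; it achieves the
#'   best screening performance), \code{"knn"}, \code{"svm_rbf"},
#'   \code{"xgboost"}.
#' @param classifier_params Free-form list passed to the classifier (e.g.
#'   \code{list(ntree = 100)}, \code{list(k = 5)}).
#' @param seed Integer seed; evaluation is reproducible given it.
#' @param resample Resample records with replacement before splitting
#'   (the bootstrap protocol). \code{FALSE} gives plain random 80/20 splits,
#'   used for permutation-null checks where bootstrap duplicates would leak
#'   record identity between train and test.
#' @param permute_labels Permute the labels independently in every
#'   repetition (null-distribution mode).
#' @param use_full_features With feature-precursor input, classify on the
#'   full 24 + 2 feature vector instead of the selected 4-vector.
#' @return An object of class \code{bootstrap_config}.
#' @export
bootstrap_config <- function(n_reps = 2000L, train_frac = 0.8,
                             classifier = c("random_forest", "knn",
                                            "svm_rbf", "xgboost"),
                             classifier_params = list(), seed = 1L,
                             resample = TRUE, permute_labels = FALSE,
                             use_full_features = FALSE) {
  stopifnot(n_reps >= 1, train_frac > 0, train_frac < 1)
  structure(list(n_reps = as.integer(n_reps), train_frac = train_frac,
                 classifier = match.arg(classifier),
                 classifier_params = classifier_params,
                 seed = as.integer(seed), resample = isTRUE(resample),
                 permute_labels = isTRUE(permute_labels),
                 use_full_features = isTRUE(use_full_features)),
            class = "bootstrap_config")
}

fit_predict <- function(classifier, params, Xtr, ytr, Xte) {
  ytr <- factor(ytr, levels = c("benign", "malignant"))
  switch(classifier,
    random_forest = {
      ntree <- params$ntree %||% 100L
      rf <- randomForest::randomForest(x = Xtr, y = ytr, ntree = ntree)
      as.character(stats::predict(rf, Xte))
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE))
        stop("package 'class' is required for the knn classifier")
      k <- params$k %||% 5L
      as.character(class::knn(Xtr, Xte, ytr, k = min(k, nrow(Xtr))))
    },
    svm_rbf = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("package 'e1071' is required for the svm_rbf classifier")
      m <- e1071::svm(x = Xtr, y = ytr, kernel = "radial")
      as.character(stats::predict(m, Xte))
    },
    xgboost = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("package 'xgboost' is required for the xgboost classifier")
      m <- xgboost::xgboost(as.matrix(Xtr), ytr,
                            nrounds = params$nrounds %||% 50L,
                            verbosity = 0)
      p <- stats::predict(m, as.matrix(Xte))  # P(second level) = P(malignant)
      ifelse(p > 0.5, "malignant", "benign")
    })
}

#' Bootstrap classifier evaluation
#'
#' Repeats \code{n_reps} times: resample the records with replacement to a
#' dataset of the original size, split it into training (\code{train_frac})
#' and test portions, fit the classifier on the training portion only, score
#' the test portion, and accumulate the metrics. Per-subclass TPRs are
#' accumulated only over repetitions whose test portion contains that
#' subclass; a repetition whose test portion lacks one of the two top-level
#' classes is redrawn (up to 100 attempts, counted in the report).
#'
#' With feature-precursor input (a list of \code{\link{prepare_record_features}}
#' results) the class-descriptive model is rebuilt inside every training
#' fold before features are assembled, so no label information leaks from
#' test records into fM/fB. With a plain feature matrix the features are
#' taken as fixed.
#'
#' @param x Numeric feature matrix / data frame (one row per record), or a
#'   list of \code{trc_feature_precursor} objects.
#' @param labels Character vector of record labels (\code{"benign"},
#'   \code{"BCC"}, \code{"SCC"}, \code{"MM"} or \code{"malignant"}).
#' @param config A \code{\link{bootstrap_config}}.
#' @return An object of class \code{eval_report}: a data frame with one row
#'   per metric (\code{min}, \code{max}, \code{avg}, \code{sd}, in percent)
#'   plus attributes \code{n_reps_completed} and \code{n_redraws}.
#' @export
bootstrap_evaluate <- function(x, labels, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  precursor_mode <- is.list(x) && !is.data.frame(x) &&
    all(vapply(x, inherits, TRUE, "trc_feature_precursor"))
  n <- if (precursor_mode) length(x) else nrow(x)
  stopifnot(length(labels) == n)
  bin <- ifelse(is_malignant_label(labels) | labels == "malignant",
                "malignant", "benign")
  if (min(table(factor(bin, levels = c("benign", "malignant")))) < 2L)
    stop("need at least 2 records per top-level class")
  if (!precursor_mode) x <- as.data.frame(x)
  metric_names <- c("accuracy", "TPR", "TPR_MM", "TPR_BCC", "TPR_SCC",
                    "TNR", "PPV")
  acc <- matrix(NA_real_, config$n_reps, length(metric_names),
                dimnames = list(NULL, metric_names))
  n_redraws <- 0L
  ntr <- round(config$train_frac * n)
  ntr <- min(max(ntr, 1L), n - 1L)
  with_seed(config$seed, {
    for (rep in seq_len(config$n_reps)) {
      lab <- if (config$permute_labels) sample(labels) else labels
      lab_bin <- ifelse(is_malignant_label(lab) | lab == "malignant",
                        "malignant", "benign")
      ok <- FALSE
      for (try in 1:100) {
        idx <- if (config$resample) sample.int(n, n, replace = TRUE)
               else sample.int(n, n)
        tr <- idx[seq_len(ntr)]; te <- idx[(ntr + 1L):n]
        if (length(unique(lab_bin[tr])) == 2L &&
            length(unique(lab_bin[te])) == 2L) { ok <- TRUE; break }
        n_redraws <- n_redraws + 1L
      }
      if (!ok) next
      if (precursor_mode) {
        feats <- fold_features(x, tr, te, config$use_full_features, lab_bin)
        Xtr <- feats$Xtr
        Xte <- feats$Xte
      } else {
        Xtr <- x[tr, , drop = FALSE]; Xte <- x[te, , drop = FALSE]
      }
      pred <- fit_predict(config$classifier, config$classifier_params,
                          Xtr, lab_bin[tr], Xte)
      m <- compute_metrics(lab[te], pred)
      acc[rep, ] <- unlist(m)[metric_names]
    }
  })
  done <- !apply(acc, 1L, function(r) all(is.na(r)))
  summ <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(min = NA, max = NA, avg = NA, sd = NA))
    c(min = min(v), max = max(v), avg = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0)
  }
  rep_df <- as.data.frame(t(apply(acc, 2L, summ)))
  structure(rep_df, class = c("eval_report", "data.frame"),
            n_reps_completed = sum(done), n_redraws = n_redraws)
}

# Assemble the per-record feature rows for one bootstrap fold: build the
# descriptive model from the training records' representative-curve
# parameters only, then compute the model-dependent similitude features for
# every record that the fold touches. `idx_tr`/`idx_te` index records with
# multiplicity (bootstrap duplicates share one feature row).
fold_features <- function(precursors, idx_tr, idx_te, full, lab_bin) {
  thetas <- vapply(precursors, function(p) p$theta_rep, numeric(5L))
  trM <- idx_tr[lab_bin[idx_tr] == "malignant"]
  trB <- idx_tr[lab_bin[idx_tr] == "benign"]
  p1 <- precursors[[1L]]
  model <- build_descriptive_model(thetas[, trM, drop = FALSE],
                                   thetas[, trB, drop = FALSE],
                                   K_IR = p1$K_IR, fps = p1$fps)
  used <- sort(unique(c(idx_tr, idx_te)))
  rows <- matrix(NA_real_, length(precursors),
                 length(precursor_features(precursors[[used[1L]]], model, full)))
  for (i in used)
    rows[i, ] <- precursor_features(precursors[[i]], model, full)
  colnames(rows) <- names(precursor_features(precursors[[used[1L]]], model, full))
  list(Xtr = rows[idx_tr, , drop = FALSE], Xte = rows[idx_te, , drop = FALSE])
}

#' Model-dependent features of one precursor
#'
#' @param precursor A \code{trc_feature_precursor}.
#' @param model A \code{\link{descriptive_model}}.
#' @param full Return the full 26-feature row instead of the selected four.
#' @return Named numeric vector (one classifier input row).
#' @export
precursor_features <- function(precursor, model, full = FALSE) {
  sim <- c()
  curves <- list(M = model$fM, B = model$fB)
  areas <- list(L = precursor$members_L, N = precursor$members_N)
  for (mc in names(curves)) for (ar in names(areas)) {
    s <- suppressWarnings(similitude_features(areas[[ar]], curves[[mc]]))
    names(s) <- paste0(names(s), "_", mc, ar)
    sim <- c(sim, s)
  }
  if (full) c(d = precursor$d, Ed = precursor$Ed, sim)
  else c(Ed_abs = abs(precursor$Ed),
         rho_sd_BL = unname(sim["rho_sd_BL"]),
         proj_sd_BN = unname(sim["proj_sd_BN"]),
         dist_sd_MN = unname(sim["dist_sd_MN"]))
}

#' Precompute the model-independent feature ingredients of a record
#'
#' Runs the per-record pipeline once (per-pixel fits, curve selection,
#' representative TRCs, member-curve modeling) so that bootstrap folds only
#' have to rebuild the class-descriptive model and the model-dependent
#' similitude statistics.
#'
#' @param record An \code{\link{acquisition_record}}.
#' @param p Selection margin (default 0.01).
#' @param fits Optional precomputed \code{\link{fit_cube_trcs}} grid.
#' @return An object of class \code{trc_feature_precursor}.
#' @export
prepare_record_features <- function(record, p = 0.01, fits = NULL) {
  stopifnot(inherits(record, "acquisition_record"))
  cube <- record$cube
  if (is.null(fits)) fits <- fit_cube_trcs(cube, keep_fitted = FALSE)
  sel <- select_trcs(fits, record$lesion_mask, p = p)
  K <- n_frames(cube)
  rep_L <- representative_trc(cube, sel$L_star)
  rep_N <- representative_trc(cube, sel$N_star)
  rep_fit <- fit_double_exponential(rep_L, cube$fps)
  structure(list(label = record$label,
                 d = euclidean_distance(rep_L, rep_N),
                 Ed = energy_difference(rep_L, rep_N),
                 theta_rep = rep_fit$theta,
                 members_L = member_curves(fits, sel$L_star, K),
                 members_N = member_curves(fits, sel$N_star, K),
                 K_IR = K, fps = cube$fps),
            class = "trc_feature_precursor")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d repetitions completed (%d redraws)\n",
              attr(x, "n_reps_completed"), attr(x, "n_redraws")))
  print.data.frame(round(as.data.frame(x), 2))
  invisible(x)
}

#' Validate degradation mimicry by per-pixel Pearson correlation
#'
#' Computes the Pearson correlation between the TRC of every pixel of an
#' actually acquired cube and the corresponding TRC of a cube degraded to
#' mimic that camera. Pixels with zero temporal variance in either cube are
#' excluded and counted. The comparison is symmetric in its arguments.
#'
#' @param actual,mimicked \code{\link{thermal_cube}}s of equal shape and
#'   frame rate.
#' @return An object of class \code{mimicry_report}: \code{coefficients}
#'   (I x J matrix, NA where excluded), \code{mean}, \code{sd},
#'   \code{n_trcs} (number of compared pixels) and \code{n_excluded}.
#' @export
validate_mimicry <- function(actual, mimicked) {
  stopifnot(inherits(actual, "thermal_cube"), inherits(mimicked, "thermal_cube"))
  if (!identical(dim(actual$data), dim(mimicked$data)))
    stop("cube shapes differ")
  if (abs(actual$fps - mimicked$fps) > 1e-9)
    stop("frame rates differ")
  rho <- colwise_pearson(cube_to_matrix(actual$data),
                         cube_to_matrix(mimicked$data))
  I <- frame_shape(actual)[1L]
  structure(list(coefficients = matrix(rho, I),
                 mean = mean(rho, na.rm = TRUE),
                 sd = stats::sd(rho, na.rm = TRUE),
                 n_trcs = sum(!is.na(rho)),
                 n_excluded = sum(is.na(rho))),
            class = "mimicry_report")
}

#' @export
print.mimicry_report <- function(x, ...) {
  cat(sprintf("<mimicry_report> mean rho = %.4f +/- %.4f over %d TRCs (%d excluded)\n",
              x$mean, x$sd, x$n_trcs, x$n_excluded))
  invisible(x)
}
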