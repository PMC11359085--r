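# Marker-based affine registration of an IR sequence to its first frame.

#' Track marker corners through a sequence
#'
#' Starting from supplied first-frame corner coordinates (standing in for a
#' manual selection), each corner is located in every subsequent frame by
#' normalized cross-correlation template matching: the template is the patch
#' around the corner's position in the previous frame, searched in a
#' \code{search_w x search_w} window around that position.
#'
#' @param cube A \code{\link{thermal_cube}}.
#' @param initial_corners 4 x 2 matrix of (row, col) corner positions in
#'   frame 1.
#' @param search_w Search window side in pixels (odd; default 11).
#' @param patch_w Template patch side in pixels (odd; default 7).
#' @param score_floor Minimum acceptable correlation score (default 0.5);
#'   a worse match raises a tracking-lost error naming frame and corner.
#' @return List with \code{corners} (per-frame list of 4 x 2 matrices) and
#'   \code{scores} (K x 4 matrix; frame 1 scores are 1).
#' @export
track_corners <- function(cube, initial_corners, search_w = 11L,
                          patch_w = 7L, score_floor = 0.5) {
  stopifnot(inherits(cube, "thermal_cube"))
  initial_corners <- as.matrix(initial_corners)
  stopifnot(nrow(initial_corners) == 4L, ncol(initial_corners) == 2L)
  K <- n_frames(cube)
  hp <- (patch_w - 1L) %/% 2L
  hs <- (search_w - 1L) %/% 2L
  corners <- vector("list", K)
  scores <- matrix(1, K, 4L)
  corners[[1L]] <- initial_corners
  get_patch <- function(fr, r, c) {
    if (r - hp < 1L || r + hp > nrow(fr) || c - hp < 1L || c + hp > ncol(fr))
      return(NULL)
    fr[(r - hp):(r + hp), (c - hp):(c + hp)]
  }
  for (k in 2:K) {
    prev <- cube$data[, , k - 1L]
    cur <- cube$data[, , k]
    pos <- matrix(0, 4L, 2L)
    for (cn in 1:4) {
      r0 <- round(corners[[k - 1L]][cn, 1L]); c0 <- round(corners[[k - 1L]][cn, 2L])
      tmpl <- get_patch(prev, r0, c0)
      if (is.null(tmpl))
        stop(sprintf("tracking lost: corner %d leaves the frame at frame %d", cn, k))
      tv <- as.vector(tmpl)
      best <- -Inf; br <- r0; bc <- c0
      for (dr in -hs:hs) for (dc in -hs:hs) {
        cand <- get_patch(cur, r0 + dr, c0 + dc)
        if (is.null(cand)) next
        cv <- as.vector(cand)
        s <- if (stats::sd(tv) == 0 || stats::sd(cv) == 0) 0
             else stats::cor(tv, cv)
        if (s > best) { best <- s; br <- r0 + dr; bc <- c0 + dc }
      }
      if (best < score_floor)
        stop(sprintf("tracking lost: corner %d match score %.2f below %.2f at frame %d",
                     cn, best, score_floor, k))
      pos[cn, ] <- c(br, bc)
      scores[k, cn] <- best
    }
    corners[[k]] <- pos
  }
  list(corners = corners, scores = scores)
}

#' Estimate an affine transform from point correspondences
#'
#' Least-squares fit of the 2 x 3 affine matrix mapping homogeneous
#' \code{(row, col)} source points to destination points; exact when the
#' motion is truly affine.
#'
#' @param src,dst n x 2 matrices (n >= 3) of corresponding points; the
#'   source points must not be collinear.
#' @return A 2 x 3 matrix of class \code{affine_transform}.
#' @export
estimate_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) >= 3L, identical(dim(src), dim(dst)))
  X <- cbind(src, 1)
  qx <- qr(X)
  if (qx$rank < 3L) stop("degenerate geometry: correspondence points are collinear")
  A <- t(qr.coef(qx, dst))  # 2 x 3, rows = (row', col') coefficients
  if (abs(det(A[, 1:2])) < 1e-12)
    stop("degenerate geometry: singular affine transform")
  structure(A, class = "affine_transform")
}

affine_apply <- function(A, pts) {
  pts <- as.matrix(pts)
  t(A[, 1:2] %*% t(pts) + A[, 3L])
}

affine_compose <- function(A2, A1) {  # A2 after A1
  L <- A2[, 1:2] %*% A1[, 1:2]
  t3 <- A2[, 1:2] %*% A1[, 3L] + A2[, 3L]
  structure(cbind(L, t3), class = "affine_transform")
}

affine_identity <- function() structure(cbind(diag(2), c(0, 0)),
                                        class = "affine_transform")

# Bilinear sampling of img at (possibly fractional) rows r, cols c, with
# edge clamping.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00];        v10 <- img[i00 + 1]
  v01 <- img[i00 + nr];   v11 <- img[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Register a sequence to its first frame and crop the marker border
#'
#' For each consecutive frame pair an affine transform is estimated from the
#' marker corners; the pairwise transforms are composed relative to frame 1
#' and each frame is resampled (bilinear) through its composed transform so
#' the whole sequence is aligned to the first frame. Finally a 3-pixel
#' safety border is removed on every side, discarding pixels that may have
#' imaged the plastic marker during residual motion.
#'
#' @param record An \code{\link{acquisition_record}} whose
#'   \code{marker_corners} are available, or for which \code{corners} is
#'   supplied.
#' @param corners Optional per-frame corner list overriding the record's.
#' @param border Crop width in pixels (default 3).
#' @return The registered \code{\link{acquisition_record}} with frames and
#'   mask cropped to \code{(I - 2 * border) x (J - 2 * border)}.
#' @export
register_cube <- function(record, corners = NULL, border = 3L) {
  stopifnot(inherits(record, "acquisition_record"))
  corners <- corners %||% record$marker_corners
  if (is.null(corners)) stop("per-frame marker corners are required")
  cube <- record$cube
  I <- frame_shape(cube)[1L]; J <- frame_shape(cube)[2L]
  if (I <= 2L * border + 2L || J <= 2L * border + 2L)
    stop(sprintf("frame too small to crop a %d-pixel border", border))
  K <- n_frames(cube)
  a <- cube$data
  out <- array(0, dim(a))
  out[, , 1L] <- a[, , 1L]
  grid_r <- matrix(seq_len(I), I, J)
  grid_c <- matrix(seq_len(J), I, J, byrow = TRUE)
  Ck <- affine_identity()
  for (k in 2:K) {
    Ak <- estimate_affine(corners[[k - 1L]], corners[[k]])
    Ck <- affine_compose(Ak, Ck)  # frame-1 coords -> frame-k coords
    src <- affine_apply(Ck, cbind(as.vector(grid_r), as.vector(grid_c)))
    out[, , k] <- matrix(bilinear_sample(a[, , k], src[, 1L], src[, 2L]), I, J)
  }
  ri <- (border + 1L):(I - border); ci <- (border + 1L):(J - border)
  reg <- thermal_cube(out[ri, ci, , drop = FALSE], fps = cube$fps, t0 = cube$t0)
  acquisition_record(reg, lesion_mask = record$lesion_mask[ri, ci],
                     visible = if (!is.null(record$visible) &&
                                   length(dim(record$visible)) == 2L)
                       record$visible[ri, ci] else NULL,
                     marker_corners = NULL, label = record$label,
                     subject_id = record$subject_id, truth = record$truth)
}
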