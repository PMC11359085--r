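#' Thermal video cube
#'
#' The basic container transformed by every pipeline stage: an
#' \code{I x J x K} array of calibrated temperatures in degrees Celsius,
#' indexed (row, col, frame), together with the acquisition frame rate.
#' Frame \code{k} (1-based in R) corresponds to time \code{t = (k - 1) / fps}
#' seconds after \code{t0}.
#'
#' Values outside the plausible skin-imaging range (0 to 60 degrees C) trigger
#' a warning but are accepted; non-finite values are an error.
#'
#' @param data Numeric 3-D array \code{I x J x K} of temperatures (degrees C),
#'   with \code{I, J >= 1} and \code{K >= 2}.
#' @param fps Frame rate in frames per second (> 0). The sampling period is
#'   \code{Ts = 1 / fps}.
#' @param t0 Acquisition start offset in seconds (default 0).
#' @return An object of class \code{thermal_cube} with fields \code{data},
#'   \code{fps} and \code{t0}.
#' @examples
#' cube <- thermal_cube(array(30, dim = c(4, 4, 10)), fps = 50)
#' dim(cube$data)
#' @export
thermal_cube <- function(data, fps, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x frames)")
  d <- dim(data)
  if (d[1L] < 1L || d[2L] < 1L || d[3L] < 2L)
    stop("cube must have I >= 1, J >= 1 and at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stop(sprintf("non-finite temperature at pixel (%d, %d), frame %d",
                 idx[1L], idx[2L], idx[3L]))
  }
  rng <- range(data)
  if (rng[1L] < 0 || rng[2L] > 60)
    warning(sprintf("temperatures outside the plausible 0-60 degC range: [%.2f, %.2f]",
                    rng[1L], rng[2L]))
  structure(list(data = data, fps = as.numeric(fps), t0 = as.numeric(t0)),
            class = "thermal_cube")
}

#' @export
print.thermal_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<thermal_cube> %d x %d pixels, %d frames @ %.4g fps (%.1f s), range [%.2f, %.2f] degC\n",
              d[1L], d[2L], d[3L], x$fps, d[3L] / x$fps,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Number of frames, frame shape and sample times of a cube
#'
#' @param cube A \code{thermal_cube}.
#' @return \code{cube_times} returns the vector of frame times in seconds
#'   (relative to \code{t0}); \code{n_frames} the frame count; and
#'   \code{frame_shape} the \code{c(I, J)} pixel dimensions.
#' @export
cube_times <- function(cube) {
  (seq_len(dim(cube$data)[3L]) - 1L) / cube$fps
}

#' @rdname cube_times
#' @export
n_frames <- function(cube) dim(cube$data)[3L]

#' @rdname cube_times
#' @export
frame_shape <- function(cube) dim(cube$data)[1:2]

#' Acquisition record
#'
#' Bundles one acquisition: the IR cube, the lesion mask drawn on the aligned
#' visible image, optional visible image and per-frame marker corners, the
#' biopsy label, and a subject identifier. The mask partitions pixels into the
#' lesion TRC set L (\code{TRUE}) and the non-lesion set N (\code{FALSE});
#' both must be non-empty.
#'
#' @param cube A \code{thermal_cube}.
#' @param lesion_mask Logical matrix of the cube's frame shape; \code{TRUE}
#'   marks the pigmented lesion area.
#' @param visible Optional numeric matrix or array (grayscale or RGB) aligned
#'   to the first IR frame.
#' @param marker_corners Optional list, one element per frame, each a 4 x 2
#'   matrix of (row, col) marker-corner positions.
#' @param label One of \code{"unknown"}, \code{"benign"}, \code{"BCC"},
#'   \code{"SCC"}, \code{"MM"}.
#' @param subject_id Opaque identifier string.
#' @param truth Optional list of generator ground truth (synthetic scenes
#'   only); carried for oracle comparisons, never used by the pipeline.
#' @return An object of class \code{acquisition_record}.
#' @export
acquisition_record <- function(cube, lesion_mask, visible = NULL,
                               marker_corners = NULL,
                               label = "unknown", subject_id = "",
                               truth = NULL) {
  stopifnot(inherits(cube, "thermal_cube"))
  label <- match.arg(label, c("unknown", "benign", "BCC", "SCC", "MM"))
  if (!is.logical(lesion_mask) || !is.matrix(lesion_mask))
    stop("`lesion_mask` must be a logical matrix")
  if (!identical(dim(lesion_mask), dim(cube$data)[1:2]))
    stop("lesion mask shape must equal the cube frame shape")
  if (!any(lesion_mask) || all(lesion_mask))
    stop("lesion mask must contain at least one TRUE and one FALSE pixel")
  if (!is.null(marker_corners)) {
    if (!is.list(marker_corners) || length(marker_corners) != n_frames(cube))
      stop("`marker_corners` must be a list with one 4 x 2 matrix per frame")
  }
  structure(list(cube = cube, lesion_mask = lesion_mask, visible = visible,
                 marker_corners = marker_corners, label = label,
                 subject_id = as.character(subject_id), truth = truth),
            class = "acquisition_record")
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf("<acquisition_record> label=%s subject=%s lesion px=%d\n",
              x$label, if (nzchar(x$subject_id)) x$subject_id else "?",
              sum(x$lesion_mask)))
  print(x$cube)
  invisible(x)
}

#' Malignancy of a lesion label
#'
#' @param label Character vector of lesion labels.
#' @return Logical: \code{TRUE} for the malignant subclasses BCC, SCC and MM.
#' @export
is_malignant_label <- function(label) label %in% c("BCC", "SCC", "MM")
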