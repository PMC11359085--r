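#' Write / read an acquisition record
#'
#' An acquisition is stored as a multi-page 32-bit TIFF for the IR stack
#' plus a JSON sidecar carrying the frame rate, label, subject id and
#' marker corners, a PNG for the lesion mask, and (optionally) a PNG for the
#' visible image. \code{path} is a basename prefix: \code{write_cube(rec,
#' "dir/acq1")} produces \code{acq1.tif}, \code{acq1.json},
#' \code{acq1_mask.png} and, if present, \code{acq1_visible.png}.
#'
#' Temperatures are scaled into the TIFF's 32-bit sample range (the fixed
#' affine map \code{(T + 32) / 128}), giving a storage resolution of about
#' 3e-8 degC --- far below any camera's NETD. Writing is aligned to the read
#' quantization grid, so write-then-read is idempotent and data already at
#' storage precision round-trips identically. The storable range is -32 to
#' 96 degC.
#'
#' @param record An \code{\link{acquisition_record}}.
#' @param path Basename prefix (with or without a \code{.json}/\code{.tif}
#'   extension, which is stripped).
#' @return \code{write_cube} returns \code{path} invisibly;
#'   \code{read_cube} returns the reconstructed
#'   \code{\link{acquisition_record}}.
#' @examples
#' rec <- generate_acquisition(skin_scene_config(shape = c(8, 8), fps_truth = 5,
#'                                               duration_s = 4, seed = 1), "benign")
#' p <- file.path(tempdir(), "acq1")
#' write_cube(rec, p)
#' rec2 <- read_cube(p)
#' identical(rec2$cube$fps, rec$cube$fps)
#' @export
write_cube <- function(record, path) {
  stopifnot(inherits(record, "acquisition_record"))
  path <- sub("\\.(json|tiff?)$", "", path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cube <- record$cube
  rng <- range(cube$data)
  if (rng[1L] < -32 || rng[2L] >= 96)
    stop("temperatures outside the storable range [-32, 96) degC")
  K <- n_frames(cube)
  # The TIFF writer truncates v * (2^32 - 1) to an integer sample while the
  # reader returns sample / 2^32; the half-step rescale below makes the
  # stored sample round(v * 2^32), i.e. round-to-nearest on the read grid,
  # which is idempotent under repeated write/read cycles.
  M <- 2^32
  pages <- lapply(seq_len(K), function(k)
    (((cube$data[, , k] + 32) / 128) * M + 0.5) / (M - 1))
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  png::writePNG(record$lesion_mask * 1, paste0(path, "_mask.png"))
  if (!is.null(record$visible))
    png::writePNG(pmin(pmax(record$visible, 0), 1), paste0(path, "_visible.png"))
  side <- list(format = "irmimic-acquisition-v1",
               fps = cube$fps, t0 = cube$t0,
               shape = dim(cube$data)[1:2], n_frames = K,
               label = record$label, subject_id = record$subject_id,
               corners = if (!is.null(record$marker_corners))
                 lapply(record$marker_corners, function(m) unname(as.matrix(m))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  path <- sub("\\.(json|tiff?)$", "", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing JSON sidecar ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(side$format, "irmimic-acquisition-v1"))
    stop("format error: ", sidecar, " is not an acquisition sidecar")
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  if (length(pages) != side$n_frames)
    stop(sprintf("integrity error: TIFF has %d frames but sidecar declares %d",
                 length(pages), side$n_frames))
  shp <- as.integer(side$shape)
  for (k in seq_along(pages))
    if (!identical(dim(pages[[k]])[1:2], shp))
      stop(sprintf("integrity error: frame %d shape differs from sidecar", k))
  a <- array(0, dim = c(shp, length(pages)))
  for (k in seq_along(pages)) a[, , k] <- pages[[k]] * 128 - 32
  cube <- thermal_cube(a, fps = side$fps, t0 = side$t0 %||% 0)
  mask <- png::readPNG(paste0(path, "_mask.png"))
  if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
  vis_file <- paste0(path, "_visible.png")
  visible <- if (file.exists(vis_file)) png::readPNG(vis_file)
  corners <- NULL
  if (!is.null(side$corners) && length(side$corners))
    corners <- lapply(seq_len(side$n_frames), function(k) {
      m <- side$corners
      if (is.array(m) && length(dim(m)) == 3L) matrix(m[k, , ], 4L, 2L)
      else as.matrix(m[[k]])
    })
  acquisition_record(cube, mask > 0.5, visible = visible,
                     marker_corners = corners,
                     label = side$label %||% "unknown",
                     subject_id = side$subject_id %||% "")
}

# Quantize temperatures to what the TIFF container stores (32-bit samples
# of the scaled value); write_cube(read_cube(.)) is exact on such data.
storage_quantize <- function(x) round(((x + 32) / 128) * 2^32) / 2^32 * 128 - 32
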