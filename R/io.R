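#' Write a thermal video to disk
#'
#' Frames are stored as a 32-bit float multi-page TIFF (one page per frame,
#' row-major, origin top-left).  Because float TIFF pages are normalized,
#' temperatures are mapped to `[0, 1]` with an affine radiometric
#' calibration (`offset_K`, `scale_K`) recorded in a JSON sidecar next to
#' the TIFF, together with timestamps, pixel pitch (mm), laser interval,
#' seed and phantom id.  Existing outputs are never silently overwritten.
#'
#' @param video a [thermal_video()].
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param overwrite allow replacing existing files.
#' @return `path`, invisibly.
#' @export
write_thermal_video <- function(video, path, overwrite = FALSE) {
  stopifnot(inherits(video, "thermal_video"))
  sidecar <- paste0(path, ".json")
  if (!overwrite && (file.exists(path) || file.exists(sidecar)))
    stop("output exists; pass overwrite = TRUE to replace: ", path)
  rng <- range(video$frames)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], 1e-12)
  pages <- lapply(seq_len(dim(video$frames)[3]), function(i)
    (video$frames[, , i] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- video$meta
  jsonlite::write_json(
    list(timestamps_s = video$timestamps,
         pixel_pitch_mm = video$pixel_pitch * 1e3,
         laser_on_s = video$laser_on,
         offset_K = offset, scale_K = scale,
         n_frames = dim(video$frames)[3],
         frame_dim = dim(video$frames)[1:2],
         meta = meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thermal video written by [write_thermal_video()]
#'
#' @param path TIFF path with its `<path>.json` sidecar.
#' @return a [thermal_video()]; frames carry float32 precision.
#' @export
read_thermal_video <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar (required keys: timestamps_s, ",
         "pixel_pitch_mm, offset_K, scale_K): ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("timestamps_s", "pixel_pitch_mm", "offset_K", "scale_K")
  miss <- setdiff(req, names(sc))
  if (length(miss))
    stop("sidecar missing required keys: ", paste(miss, collapse = ", "))
  if (length(sc$timestamps_s) > 1 && any(diff(sc$timestamps_s) <= 0))
    stop("sidecar timestamps are not strictly increasing")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(sc$timestamps_s))
    stop("TIFF page count does not match sidecar timestamps (truncated file?)")
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages))
    frames[, , i] <- pages[[i]] * sc$scale_K + sc$offset_K
  thermal_video(frames, sc$timestamps_s, sc$pixel_pitch_mm / 1e3,
                laser_on = sc$laser_on_s,
                meta = if (!is.null(sc$meta)) as.list(sc$meta) else list())
}

#' Export/import a thermal video as per-frame CSV matrices
#'
#' One CSV per frame (`frame_0001.csv`, ...) plus the same JSON sidecar as
#' the TIFF encoding, under a directory.  The CSV path is lossless in
#' double precision, so it also serves as the import route for radiometric
#' exports.
#'
#' @param video a [thermal_video()].
#' @param dir output directory (created if needed).
#' @param overwrite allow replacing an existing directory's contents.
#' @return `dir`, invisibly.
#' @export
write_thermal_video_csv <- function(video, dir, overwrite = FALSE) {
  stopifnot(inherits(video, "thermal_video"))
  sidecar <- file.path(dir, "video.json")
  if (!overwrite && file.exists(sidecar))
    stop("output exists; pass overwrite = TRUE to replace: ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(video$frames)[3]
  for (i in seq_len(nt)) {
    write.table(video$frames[, , i],
                file.path(dir, sprintf("frame_%04d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(timestamps_s = video$timestamps,
         pixel_pitch_mm = video$pixel_pitch * 1e3,
         laser_on_s = video$laser_on,
         n_frames = nt, frame_dim = dim(video$frames)[1:2],
         meta = video$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_thermal_video_csv
#' @export
read_thermal_video_csv <- function(dir) {
  sidecar <- file.path(dir, "video.json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar (video.json) in ", dir)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  files <- file.path(dir, sprintf("frame_%04d.csv", seq_len(sc$n_frames)))
  if (!all(file.exists(files)))
    stop("frame CSVs missing (truncated export?) in ", dir)
  frames <- array(0, dim = c(sc$frame_dim, sc$n_frames))
  for (i in seq_along(files)) {
    m <- as.matrix(read.csv(files[i], header = FALSE))
    frames[, , i] <- m
  }
  thermal_video(frames, sc$timestamps_s, sc$pixel_pitch_mm / 1e3,
                laser_on = sc$laser_on_s,
                meta = if (!is.null(sc$meta)) as.list(sc$meta) else list())
}
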