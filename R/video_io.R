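#' Video container
#'
#' An `ego_video` is an ordered list of decoded frames plus the frame rate.
#' Frames are numeric arrays `H x W x 3` on \[0, 1\], row = image y. Frame
#' `i` (1-based in R) has 0-based index `i - 1` and timestamp
#' `(i - 1) / fps` seconds.
#'
#' @param frames List of `H x W x 3` arrays.
#' @param fps Frames per second (nominal 30).
#' @return An `ego_video` object.
#' @export
ego_video <- function(frames, fps = 30) {
  stopifnot(length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  stopifnot(length(d) == 3, d[3] == 3)
  structure(list(frames = frames, fps = fps), class = "ego_video")
}

#' @export
print.ego_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<ego_video %d frames %dx%d @ %g fps (%.2f s)>\n",
              length(x$frames), d[1], d[2], x$fps,
              (length(x$frames) - 1) / x$fps))
  invisible(x)
}

#' Number of frames in a video
#' @param video An `ego_video`.
#' @return Integer frame count.
#' @export
n_frames <- function(video) length(video$frames)

#' Frame timestamps
#' @param video An `ego_video`.
#' @return Numeric vector of timestamps in seconds, `index / fps`.
#' @export
frame_times <- function(video) (seq_along(video$frames) - 1) / video$fps

standardize_video <- function(video, target_height = 480) {
  stopifnot(target_height >= 16)
  d <- dim(video$frames[[1]])
  if (d[1] == target_height) return(video)
  w <- round(d[2] * target_height / d[1] / 2) * 2  # nearest even width
  video$frames <- lapply(video$frames, resize_frame, h = target_height, w = w)
  video
}

#' Read a video at analysis resolution
#'
#' Decodes a clip and standardizes it to the analysis height (default 480
#' pixels, preserving aspect ratio with the width rounded to the nearest even
#' integer). Two on-disk layouts are supported: a directory of numbered
#' PNG/TIFF frames with an optional `manifest.json` carrying `fps`, or a
#' single multi-page TIFF. Container videos (MP4/AVI) must be exploded to
#' frames first; when `ffmpeg` happens to be on the PATH it is used to do so
#' automatically. When no frame rate is recorded, 30 fps is assumed.
#'
#' @param path Directory of frames, a multi-page TIFF, or an MP4/AVI (the
#'   latter only when `ffmpeg` is available).
#' @param target_height Analysis height in pixels (>= 16), default 480.
#' @return An [ego_video].
#' @export
read_video <- function(path, target_height = 480) {
  stopifnot(target_height >= 16)
  if (!file.exists(path)) stop("video path does not exist: ", path)
  fps <- 30
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.json")
    if (file.exists(mf)) {
      man <- jsonlite::read_json(mf)
      if (!is.null(man$fps)) fps <- as.numeric(man$fps)
    }
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frames found in directory: ", path)
    frames <- lapply(files, read_frame_file)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, as_rgb_array)
  } else if (grepl("\\.(mp4|avi|mov)$", path, ignore.case = TRUE)) {
    ff <- Sys.which("ffmpeg")
    if (!nzchar(ff)) {
      stop("cannot decode container video '", path,
           "': no ffmpeg available; explode the video to a directory of ",
           "PNG frames (with a manifest.json recording fps) and pass that")
    }
    tmp <- tempfile("frames")
    dir.create(tmp)
    status <- system2(ff, c("-i", shQuote(path), "-loglevel", "error",
                            file.path(tmp, "frame_%06d.png")))
    if (status != 0) stop("ffmpeg failed to decode: ", path)
    return(read_video(tmp, target_height))
  } else {
    stop("unrecognized video path (expected directory, TIFF or MP4/AVI): ", path)
  }
  if (length(frames) == 0) stop("video decoded to zero frames: ", path)
  standardize_video(ego_video(frames, fps), target_height)
}

read_frame_file <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    as_rgb_array(png::readPNG(f))
  } else {
    as_rgb_array(tiff::readTIFF(f))
  }
}

as_rgb_array <- function(a) {
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write a video as a directory of PNG frames
#'
#' The inverse of the directory layout [read_video] accepts: numbered PNG
#' frames plus a `manifest.json` holding the frame rate and frame count.
#'
#' @param video An [ego_video].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(video$frames)) {
    png::writePNG(pmin(pmax(video$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i - 1)))
  }
  jsonlite::write_json(list(fps = video$fps, n_frames = n_frames(video)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

# ---- label files -----------------------------------------------------------

.hand_levels <- c("left", "right", "other")
.state_levels <- c("interaction", "no_interaction", "hand_absent")

#' Read per-frame manual interaction labels
#'
#' CSV with mandatory header `frame,hand,state`; `hand` is one of
#' `left/right/other`, `state` one of
#' `interaction/no_interaction/hand_absent`, frame indices 0-based. At most
#' one record per (frame, hand) pair.
#'
#' @param path CSV file path.
#' @return `data.frame` with columns `frame`, `hand`, `state` in file order.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("frame", "hand", "state"))) {
    stop("label file must have header frame,hand,state: ", path)
  }
  bad <- which(!df$hand %in% .hand_levels)
  if (length(bad)) stop("unknown hand token '", df$hand[bad[1]],
                        "' at line ", bad[1] + 1)
  bad <- which(!df$state %in% .state_levels)
  if (length(bad)) stop("unknown state token '", df$state[bad[1]],
                        "' at line ", bad[1] + 1)
  if (any(df$frame < 0) || any(df$frame != floor(df$frame))) {
    stop("frame indices must be non-negative integers")
  }
  dup <- which(duplicated(df[, c("frame", "hand")]))
  if (length(dup)) stop("duplicate (frame, hand) record at line ", dup[1] + 1)
  df
}

#' Write labels to CSV
#' @param labels `data.frame` with columns `frame`, `hand`, `state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels[, c("frame", "hand", "state")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# ---- metrics files ---------------------------------------------------------

#' Write hand-use metrics to JSON
#'
#' One object per hand with keys `pct_interaction`, `mean_duration_s`,
#' `interactions_per_hour`; undefined metrics (no interactions observed)
#' serialize as JSON `null` and read back as `NA`.
#'
#' @param metrics Named list (per hand) of [hand_use_metrics] results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  out <- lapply(metrics, function(m) {
    list(pct_interaction = null_if_na(m$pct_interaction),
         mean_duration_s = null_if_na(m$mean_duration_s),
         interactions_per_hour = null_if_na(m$interactions_per_hour))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

null_if_na <- function(x) if (is.null(x) || is.na(x)) NULL else x

#' Read hand-use metrics from JSON
#' @param path JSON path written by [write_metrics].
#' @return Named list per hand; missing metrics are `NA`.
#' @export
read_metrics <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m) {
    list(pct_interaction = na_if_null(m$pct_interaction),
         mean_duration_s = na_if_null(m$mean_duration_s),
         interactions_per_hour = na_if_null(m$interactions_per_hour))
  })
}

na_if_null <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
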