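# Candidate hand boxes per frame. The detector contract is pluggable: any
# per-frame source of (box, score) pairs can drive the pipeline, including
# boxes exported by an external CNN. The self-contained baseline detects
# connected skin-coloured blobs.

#' Baseline skin-blob hand detector
#'
#' Thresholds the skin-probability map, labels connected components, and
#' returns the tight bounding box of every component whose pixel area reaches
#' `min_area_frac` of the frame. The score of a box is the mean skin
#' probability inside it. Boxes are sorted by score (descending), ties broken
#' by larger area, and at most `max_detections` are returned. Deterministic
#' for a fixed frame and skin model.
#'
#' @param frame `H x W x 3` array on \[0,1\].
#' @param skin_model A `skin_model`, see [skin_model_default].
#' @param min_area_frac Minimum component area as a fraction of frame area
#'   (default 0.001).
#' @param max_detections Maximum number of boxes returned (default 4).
#' @param skin_threshold Mask threshold as fraction of map maximum
#'   (default 0.75).
#' @return List of detections, each a list with `box` ([bbox]), `score` and
#'   `area`; empty list when nothing passes.
#' @export
detect_hands <- function(frame, skin_model, min_area_frac = 0.001,
                         max_detections = 4, skin_threshold = 0.75) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  sp <- skin_probability(frame, skin_model, skin_threshold)
  if (!any(sp$mask)) return(list())
  lab <- label_mat(sp$mask)
  n <- max(lab)
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area_frac * H * W) next
    y0 <- min(idx[, 1]) - 1; y1 <- max(idx[, 1]) - 1
    x0 <- min(idx[, 2]) - 1; x1 <- max(idx[, 2]) - 1
    box <- bbox(x0, y0, x1 - x0 + 1, y1 - y0 + 1)
    score <- mean(sp$prob[bbox_rows(box, H), bbox_cols(box, W)])
    out[[length(out) + 1]] <- list(box = box, score = score, area = area)
  }
  if (length(out) == 0) return(list())
  ord <- order(-vapply(out, `[[`, numeric(1), "score"),
               -vapply(out, `[[`, numeric(1), "area"))
  out[ord][seq_len(min(max_detections, length(out)))]
}

#' Load externally produced detections
#'
#' Reads per-frame hand boxes exported by any detector (e.g. a CNN) from a
#' CSV with header `frame,x,y,w,h,score`. Verification and handedness are
#' assigned downstream by the arm-angle stage, so records load with
#' `verified = FALSE` and `handedness = "unknown"`.
#'
#' @param path CSV file path.
#' @param frame_width,frame_height Dimensions of the analysed frames, used to
#'   validate box bounds.
#' @return `data.frame` with columns `frame`, `x`, `y`, `w`, `h`, `score`,
#'   `verified`, `handedness`.
#' @export
load_external_detections <- function(path, frame_width, frame_height) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("frame", "x", "y", "w", "h", "score"))) {
    stop("detections file must have header frame,x,y,w,h,score: ", path)
  }
  if (nrow(df) > 0) {
    bad <- which(df$x < 0 | df$y < 0 | df$w < 1 | df$h < 1 |
                   df$x + df$w > frame_width | df$y + df$h > frame_height)
    if (length(bad)) {
      stop("detection box outside frame bounds at line ", bad[1] + 1)
    }
  }
  df$verified <- rep(FALSE, nrow(df))
  df$handedness <- rep("unknown", nrow(df))
  df
}
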