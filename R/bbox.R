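#' Bounding box
#'
#' Axis-aligned box in pixel coordinates, 0-based with the origin at the
#' top-left of the image and y pointing down. The box is half-open on the
#' right and bottom: it covers pixels `x .. x+w-1` and `y .. y+h-1`.
#'
#' @param x,y Top-left corner (pixels, 0-based).
#' @param w,h Width and height in pixels (>= 1).
#' @return An object of class `bbox`.
#' @export
bbox <- function(x, y, w, h) {
  stopifnot(is.finite(c(x, y, w, h)), w >= 1, h >= 1, x >= 0, y >= 0)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

bbox_valid <- function(box, W, H) {
  box$x >= 0 && box$y >= 0 && box$w >= 1 && box$h >= 1 &&
    box$x + box$w <= W && box$y + box$h <= H
}

# clip a box to frame bounds; returns NULL when nothing remains
bbox_clip <- function(box, W, H) {
  x0 <- max(0, box$x); y0 <- max(0, box$y)
  x1 <- min(W, box$x + box$w); y1 <- min(H, box$y + box$h)
  if (x1 - x0 < 1 || y1 - y0 < 1) return(NULL)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

bbox_centroid <- function(box) {
  c(x = box$x + (box$w - 1) / 2, y = box$y + (box$h - 1) / 2)
}

# logical H x W membership mask
bbox_mask <- function(box, H, W) {
  m <- matrix(FALSE, H, W)
  ys <- seq.int(floor(box$y) + 1, min(H, ceiling(box$y + box$h)))
  xs <- seq.int(floor(box$x) + 1, min(W, ceiling(box$x + box$w)))
  m[ys, xs] <- TRUE
  m
}

# 1-based row/col index ranges covered by a box
bbox_rows <- function(box, H) seq.int(max(1, floor(box$y) + 1), min(H, floor(box$y + box$h)))
bbox_cols <- function(box, W) seq.int(max(1, floor(box$x) + 1), min(W, floor(box$x + box$w)))

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b `bbox` objects.
#' @return IoU in \[0, 1\].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}
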