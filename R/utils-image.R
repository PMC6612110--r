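# Internal image helpers. Frames are numeric arrays dim c(H, W, 3) on [0,1],
# row = image y (downwards), column = image x. EBImage stores images
# transposed (first dimension = x), so every EBImage call goes through the
# wrappers below and coordinates are swapped exactly once.

# grayscale luma view of a frame
frame_gray <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# bilinear resize of an H x W matrix to h x w
resize_mat <- function(m, h, w) {
  img <- EBImage::Image(t(m))
  t(EBImage::imageData(EBImage::resize(img, w = w, h = h)))
}

resize_frame <- function(frame, h, w) {
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- resize_mat(frame[, , ch], h, w)
  out
}

# morphology on H x W logical/0-1 matrices; square brushes are symmetric so
# no transposition is needed
dilate_mat <- function(m, size = 3) {
  EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), EBImage::makeBrush(size, "box"))) > 0.5
}

erode_mat <- function(m, size = 3) {
  EBImage::imageData(EBImage::erode(EBImage::Image(m * 1), EBImage::makeBrush(size, "box"))) > 0.5
}

# connected-component labels of a binary H x W matrix
label_mat <- function(m) {
  EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
}

fill_holes <- function(m) {
  EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0.5
}

# per-component shape stats on a label matrix; returns data.frame with
# label, area (filled), perimeter (arc length), cx, cy (0-based image coords),
# top_y, top_x (topmost filled pixel, mean x over ties)
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0) {
    return(data.frame(label = integer(), area = numeric(), perimeter = numeric(),
                      cx = numeric(), cy = numeric(), top_y = numeric(), top_x = numeric()))
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(lab)))
  # EBImage shape features operate on its own (x = first dim) convention; our
  # first dim is y, so returned "x" moments are image-y. Swap on the way out.
  sh <- EBImage::computeFeatures.shape(filled)
  mo <- EBImage::computeFeatures.moment(filled)
  sh <- matrix(sh, ncol = ncol(sh), dimnames = dimnames(sh))
  out <- data.frame(label = seq_len(n),
                    area = sh[, "s.area"],
                    perimeter = sh[, "s.perimeter"],
                    cx = mo[, "m.cy"] - 1,
                    cy = mo[, "m.cx"] - 1,
                    top_y = NA_real_, top_x = NA_real_)
  for (k in seq_len(n)) {
    idx <- which(filled == k, arr.ind = TRUE)
    ymin <- min(idx[, 1])
    out$top_y[k] <- ymin - 1
    out$top_x[k] <- mean(idx[idx[, 1] == ymin, 2]) - 1
  }
  out
}

# mask (logical H x W) of one filled component
component_mask <- function(lab, k) {
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(lab)))
  filled == k
}

# 8-connected component count (bwlabel is 4-connected, which fragments thin
# diagonal curves); label propagation until fixpoint
count_components8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  lab[m] <- seq_len(sum(m))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    old <- lab
    for (s in shifts) {
      sh <- matrix(.Machine$integer.max, H, W)
      ys <- seq_len(H) + s[1]; xs <- seq_len(W) + s[2]
      ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
      sh[ok_y, ok_x] <- lab[ys[ok_y], xs[ok_x]]
      sh[sh == 0L] <- .Machine$integer.max
      upd <- m & sh < lab
      lab[upd] <- sh[upd]
    }
    if (identical(lab, old)) break
  }
  length(unique(lab[m]))
}
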