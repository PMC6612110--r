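# Hand segmentation: combine skin-colour back-projection with an edge map,
# filter candidate contours on area and perimeter, select the contour that
# best overlaps the (dilated) edge image, and re-centre the bounding box at
# the midpoint of the winning contour's centroid and topmost pixel. The
# upward re-centring promotes coverage of the hand rather than the arm, which
# sits below the hand in an egocentric view.

#' Gradient-magnitude edge operator
#'
#' Baseline pluggable edge operator: central-difference gradient magnitude of
#' the grayscale image. Any function mapping an `H x W` intensity matrix to a
#' non-negative strength matrix of the same size can be substituted (e.g. a
#' learned hand-tuned edge model).
#'
#' @param gray `H x W` intensity matrix on \[0,1\].
#' @return `H x W` edge-strength matrix.
#' @export
edge_gradient <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (gray[, 3:W] - gray[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (gray[3:H, ] - gray[1:(H - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

#' Smoothed-gradient edge operator with non-maximum suppression
#'
#' Default edge operator for segmentation: gradient magnitude of the
#' Gaussian-smoothed image, thinned by non-maximum suppression along the
#' quantized gradient direction. Produces thin, contour-like edges (the
#' behaviour a hand-tuned edge model has on real footage), so subtracting
#' the dilated edge map from the skin mask removes only a narrow boundary
#' ring rather than eroding whole regions on textured scenes.
#'
#' @param gray `H x W` intensity matrix on \[0,1\].
#' @param sigma Gaussian smoothing scale in pixels (default 1.5).
#' @param min_strength Absolute minimum-contrast floor: responses below this
#'   gradient magnitude (intensity units per pixel, default 0.01) are
#'   suppressed as sensor/texture noise, so a frame with only weak contours
#'   does not promote its noise floor through the later max-relative
#'   threshold.
#' @return `H x W` edge-strength matrix (non-maxima zeroed).
#' @export
edge_gradient_nms <- function(gray, sigma = 1.5, min_strength = 0.01) {
  g <- EBImage::imageData(EBImage::gblur(EBImage::Image(gray), sigma))
  H <- nrow(g); W <- ncol(g)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  # suppress non-maxima along the true gradient direction, comparing against
  # bilinearly interpolated neighbours one pixel away on either side
  nz <- mag > 0
  ux <- matrix(0, H, W); uy <- matrix(0, H, W)
  ux[nz] <- gx[nz] / mag[nz]
  uy[nz] <- gy[nz] / mag[nz]
  sample_mag <- function(sy, sx) {
    sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
    fy <- sy - y0; fx <- sx - x0
    (1 - fy) * ((1 - fx) * mag[cbind(y0, x0)] + fx * mag[cbind(y0, x1)]) +
      fy * ((1 - fx) * mag[cbind(y1, x0)] + fx * mag[cbind(y1, x1)])
  }
  ys <- as.vector(row(mag)); xs <- as.vector(col(mag))
  n1 <- sample_mag(ys + as.vector(uy), xs + as.vector(ux))
  n2 <- sample_mag(ys - as.vector(uy), xs - as.vector(ux))
  keep <- as.vector(mag) >= n1 & as.vector(mag) >= n2 &
    as.vector(mag) >= min_strength
  mag * matrix(keep, H, W)
}

#' Binary hand-edge map
#'
#' Edge strength from the configured operator, binarized at a fraction of its
#' maximum, then morphologically closed (dilation followed by erosion) to
#' bridge small gaps in contours.
#'
#' @param frame `H x W x 3` array, or an `H x W` grayscale matrix.
#' @param edge_operator Function of a grayscale matrix returning edge
#'   strength; default [edge_gradient_nms].
#' @param edge_thresh Binarization threshold as a fraction of the maximum
#'   strength (default 0.05).
#' @param brush_size Side of the square structuring element (default 3).
#' @return Logical `H x W` edge map.
#' @export
hand_edge_map <- function(frame, edge_operator = edge_gradient_nms,
                          edge_thresh = 0.05, brush_size = 3) {
  gray <- if (length(dim(frame)) == 3) frame_gray(frame) else frame
  strength <- edge_operator(gray)
  mx <- max(strength)
  if (mx <= 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  bin <- strength >= edge_thresh * mx
  erode_mat(dilate_mat(bin, brush_size), brush_size)
}

#' Segment the hand inside a detected bounding box
#'
#' Candidate contours are the connected components of the skin mask refined
#' by the edge map (dilated edge pixels are subtracted to split merged
#' regions) within the box. Contours with filled area below
#' `area_min_frac` or above `area_max_frac` of the box area are eliminated,
#' as are contours whose perimeter falls within
#' `[perim_lo, perim_hi] x box perimeter` (box-hugging artefacts). The winner
#' maximizes the fraction of its filled area covered by the dilated edge map
#' (ties broken by larger area). The box is then re-centred at the midpoint
#' of the winner's centroid and topmost pixel, size preserved, clamped to the
#' frame.
#'
#' @param frame `H x W x 3` array.
#' @param box Source [bbox] (within the frame).
#' @param skin_model A `skin_model` (see [skin_model_default]).
#' @param edge_operator Pluggable edge operator, default [edge_gradient_nms].
#' @param config Named list of thresholds, see [default_config]
#'   (`seg.*` keys).
#' @return A `hand_segment`: list with `mask` (logical `H x W`, hand pixels
#'   inside the re-centred box), `contour` (ordered boundary pixels, columns
#'   `x`, `y`, 0-based), `recentred_box`, `source_box`, `area`, `overlap`;
#'   or `NULL` when no candidate contour survives the filters.
#' @export
segment_hand <- function(frame, box, skin_model,
                         edge_operator = edge_gradient_nms,
                         config = default_config()) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  stopifnot(bbox_valid(box, W, H))
  sp <- skin_probability(frame, skin_model, config$seg.skin_thresh)
  edges <- hand_edge_map(frame, edge_operator, config$seg.edge_thresh)
  edge_dil <- dilate_mat(edges, 3)
  refined <- sp$mask & !edge_dil

  rows <- bbox_rows(box, H); cols <- bbox_cols(box, W)
  crop <- refined[rows, cols, drop = FALSE]
  if (!any(crop)) return(NULL)
  lab <- label_mat(crop)
  stats <- component_stats(lab)
  if (nrow(stats) == 0) return(NULL)

  box_area <- box$w * box$h
  box_perim <- 2 * (box$w + box$h)
  keep <- stats$area >= config$seg.area_min_frac * box_area &
    stats$area <= config$seg.area_max_frac * box_area &
    !(stats$perimeter >= config$seg.perim_lo * box_perim &
        stats$perimeter <= config$seg.perim_hi * box_perim)
  stats <- stats[keep, , drop = FALSE]
  if (nrow(stats) == 0) return(NULL)

  edge_crop <- edge_dil[rows, cols, drop = FALSE]
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(lab)))
  stats$overlap <- vapply(stats$label, function(k) {
    comp <- filled == k
    sum(comp & edge_crop) / sum(comp)
  }, numeric(1))
  ord <- order(-stats$overlap, -stats$area)
  win <- stats[ord[1], ]

  # component back in frame coordinates (0-based)
  comp_crop <- filled == win$label
  cx <- win$cx + cols[1] - 1
  cy <- win$cy + rows[1] - 1
  top_x <- win$top_x + cols[1] - 1
  top_y <- win$top_y + rows[1] - 1

  ctr_x <- (cx + top_x) / 2
  ctr_y <- (cy + top_y) / 2
  nx <- min(max(0, ctr_x - (box$w - 1) / 2), W - box$w)
  ny <- min(max(0, ctr_y - (box$h - 1) / 2), H - box$h)
  newbox <- bbox(nx, ny, box$w, box$h)

  # the edge-map subtraction eroded every candidate by a one-element
  # boundary ring; restore it on the winner before clipping to the box
  mask <- matrix(FALSE, H, W)
  mask[rows, cols] <- comp_crop
  mask <- dilate_mat(mask, 3) & bbox_mask(newbox, H, W)

  oc <- EBImage::ocontour(EBImage::Image(comp_crop * 1))
  contour <- NULL
  if (length(oc) > 0) {
    # our first dim is y, so ocontour's first column is y
    contour <- cbind(x = oc[[1]][, 2] + cols[1] - 1,
                     y = oc[[1]][, 1] + rows[1] - 1)
  }

  structure(list(mask = mask, contour = contour, recentred_box = newbox,
                 source_box = box, area = win$area, overlap = win$overlap,
                 centroid = c(x = cx, y = cy), top = c(x = top_x, y = top_y)),
            class = "hand_segment")
}
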