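# The 122-value hand-object interaction feature: 60 motion values (two
# 30-value histogram differences from dense optical flow), 60 shape values
# (PCA-reduced HOG of the re-centred box crop) and 2 colour values
# (Bhattacharyya distances between HSV histograms of the box vs the hand and
# the box vs the background). Motion features rest on the assumption that a
# held object moves with the hand while an untouched object moves with the
# background.

#' Dense optical flow between consecutive frames
#'
#' Pyramidal iterative Lucas-Kanade estimation: coarse-to-fine over a
#' Gaussian image pyramid, warping the second frame by the current estimate
#' and solving the locally averaged normal equations per pixel at each
#' iteration. Parameters are fixed and documented: `levels` pyramid levels
#' (halving resolution, default 3), `iters` iterations per level (default 3),
#' Gaussian window sigma 2 px, Tikhonov regularization 1e-4 so textureless
#' pixels return near-zero flow.
#'
#' @param prev,curr Consecutive frames (`H x W x 3` arrays or grayscale
#'   matrices) of identical size.
#' @param levels,iters,sigma,lambda Estimator parameters, see above.
#' @return A `flow_field`: list with `dx`, `dy` (`H x W` matrices, pixels per
#'   frame; x positive rightward, y positive downward).
#' @export
dense_flow <- function(prev, curr, levels = 3, iters = 3, sigma = 2,
                       lambda = 1e-4) {
  g1 <- if (length(dim(prev)) == 3) frame_gray(prev) else prev
  g2 <- if (length(dim(curr)) == 3) frame_gray(curr) else curr
  if (!identical(dim(g1), dim(g2))) stop("frame shape mismatch in dense_flow")
  out <- .lk_flow_cpp(g1, g2, as.integer(levels), as.integer(iters),
                      sigma, lambda)
  structure(list(dx = out$dx, dy = out$dy), class = "flow_field")
}

#' Region partition for interaction features
#'
#' The three regions over which flow and colour histograms are compared: the
#' segmented hand, the re-centred bounding box around it, and the background
#' (the frame minus the box). The hand is always a subset of the box; box and
#' background partition the frame.
#'
#' @param hand_mask Logical `H x W` matrix of hand pixels (e.g.
#'   `segment$mask`); may be all-`FALSE`.
#' @param box Re-centred [bbox].
#' @param H,W Frame dimensions.
#' @return A `region_set`: list of logical matrices `hand`, `box`,
#'   `background`.
#' @export
region_set <- function(hand_mask, box, H, W) {
  bm <- bbox_mask(box, H, W)
  structure(list(hand = hand_mask & bm, box = bm, background = !bm),
            class = "region_set")
}

# L1-normalized histogram over fixed edges; all-zero for an empty region
norm_hist <- function(values, edges) {
  if (length(values) == 0) return(numeric(length(edges) - 1))
  nb <- length(edges) - 1
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1), nb)
  h <- tabulate(idx, nbins = nb)
  h / sum(h)
}

flow_region_hist <- function(flow, mask, n_bins = 15, mag_cap = 20) {
  dx <- flow$dx[mask]; dy <- flow$dy[mask]
  mag <- sqrt(dx^2 + dy^2)
  mag <- pmin(mag, mag_cap)  # overflow folds into the top bin
  dir <- (atan2(dy, dx) * 180 / pi) %% 360
  c(norm_hist(mag, seq(0, mag_cap, length.out = n_bins + 1)),
    norm_hist(dir, seq(0, 360, length.out = n_bins + 1)))
}

#' Motion-cue feature (60 values)
#'
#' Per region, a 15-bin L1-normalized histogram of flow magnitude (on
#' `[0, mag_cap]` pixels, overflow in the top bin) and a 15-bin histogram of
#' flow direction (degrees, full circle). The feature is the concatenation of
#' two difference vectors: hand histograms minus box histograms, and
#' background histograms minus box histograms, magnitudes before directions
#' within each pair.
#'
#' @param flow A `flow_field` from [dense_flow].
#' @param regions A `region_set`.
#' @param n_bins Bins per histogram (default 15).
#' @param mag_cap Magnitude range cap in pixels (default 20).
#' @return Numeric vector of length `4 * n_bins` (60 with defaults).
#' @export
motion_feature <- function(flow, regions, n_bins = 15, mag_cap = 20) {
  h_hand <- flow_region_hist(flow, regions$hand, n_bins, mag_cap)
  h_box <- flow_region_hist(flow, regions$box, n_bins, mag_cap)
  h_bg <- flow_region_hist(flow, regions$background, n_bins, mag_cap)
  c(h_hand - h_box, h_bg - h_box)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Unsigned gradient orientations (0-180 degrees) in `orientations` bins,
#' magnitude-weighted votes accumulated over non-overlapping square cells,
#' L2-normalized over sliding blocks of `block x block` cells (stride one
#' cell). When the image holds fewer cells than a block in either direction
#' the block size degrades gracefully to the available cells.
#'
#' @param gray `H x W` intensity matrix.
#' @param orientations Orientation bins (default 9).
#' @param cell Cell side in pixels (default 8).
#' @param block Block side in cells (default 2).
#' @return Numeric descriptor vector.
#' @export
hog_descriptor <- function(gray, orientations = 9, cell = 8, block = 2) {
  H <- nrow(gray); W <- ncol(gray)
  ncy <- max(1, floor(H / cell)); ncx <- max(1, floor(W / cell))
  gray <- gray[seq_len(min(H, ncy * cell)), seq_len(min(W, ncx * cell)), drop = FALSE]
  H <- nrow(gray); W <- ncol(gray)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3) gx[, 2:(W - 1)] <- (gray[, 3:W] - gray[, 1:(W - 2)]) / 2
  if (H >= 3) gy[2:(H - 1), ] <- (gray[3:H, ] - gray[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  obin <- pmin(floor(ang / (180 / orientations)) + 1, orientations)

  cy <- pmin((row(gray) - 1) %/% cell + 1, ncy)
  cx <- pmin((col(gray) - 1) %/% cell + 1, ncx)
  idx <- cy + (cx - 1) * ncy + (obin - 1) * ncy * ncx
  hist3 <- numeric(ncy * ncx * orientations)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  hist3[as.integer(rownames(acc))] <- acc
  ch <- array(hist3, dim = c(ncy, ncx, orientations))

  by <- min(block, ncy); bx <- min(block, ncx)
  out <- numeric(0)
  for (j in seq_len(ncx - bx + 1)) {
    for (i in seq_len(ncy - by + 1)) {
      v <- as.vector(ch[i:(i + by - 1), j:(j + bx - 1), ])
      out <- c(out, v / sqrt(sum(v^2) + 1e-12))
    }
  }
  out
}

#' Fit the shape-feature PCA
#'
#' Learns the mean and leading principal components of raw HOG descriptors;
#' [shape_feature] projects new descriptors onto them. Within
#' cross-validation the PCA must be fitted on training-fold data only (the
#' leave-one-subject-out harness does this per fold).
#'
#' @param hog_matrix `n x d` matrix of raw HOG descriptors (`n` must exceed
#'   `n_components`).
#' @param n_components Components to keep (default 60).
#' @return A `shape_pca` model.
#' @export
fit_shape_pca <- function(hog_matrix, n_components = 60) {
  hog_matrix <- as.matrix(hog_matrix)
  if (nrow(hog_matrix) <= n_components) {
    stop("need more than ", n_components, " training vectors to fit the PCA")
  }
  if (ncol(hog_matrix) < n_components) {
    stop("raw HOG dimension below the requested number of components")
  }
  p <- prcomp(hog_matrix, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(center = p$center, rotation = p$rotation,
                 sdev = p$sdev[seq_len(n_components)],
                 n_components = n_components, d = ncol(hog_matrix)),
            class = "shape_pca")
}

#' Project HOG descriptors through a fitted PCA
#' @param pca A `shape_pca` from [fit_shape_pca].
#' @param x Descriptor vector or `n x d` matrix.
#' @return Matrix of projected rows (`n x n_components`).
#' @export
shape_pca_transform <- function(pca, x) {
  if (!inherits(pca, "shape_pca")) stop("pca model is not fitted")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != pca$d) stop("HOG dimension mismatch with fitted PCA")
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' Shape feature (60 values)
#'
#' Crops the re-centred box from the frame, resizes the crop to 10% of the
#' frame height by 15% of the frame width (guaranteeing identical dimensions
#' regardless of box size), computes the HOG descriptor and projects it
#' through the fitted PCA.
#'
#' @param frame `H x W x 3` array.
#' @param box Re-centred [bbox].
#' @param pca A fitted `shape_pca`.
#' @param ... Passed to [hog_descriptor].
#' @return Numeric vector of length `pca$n_components` (default 60).
#' @export
shape_feature <- function(frame, box, pca, ...) {
  if (!inherits(pca, "shape_pca")) stop("pca model is not fitted")
  H <- dim(frame)[1]; W <- dim(frame)[2]
  gray <- frame_gray(frame)
  crop <- gray[bbox_rows(box, H), bbox_cols(box, W), drop = FALSE]
  rs <- resize_mat(crop, max(8, round(0.10 * H)), max(8, round(0.15 * W)))
  as.vector(shape_pca_transform(pca, hog_descriptor(rs, ...)))
}

#' Bhattacharyya distance between two normalized histograms
#'
#' `sqrt(1 - sum(sqrt(p * q)))`: 0 for identical histograms, 1 for disjoint
#' support.
#'
#' @param p,q Non-negative vectors of equal length summing to 1 (an all-zero
#'   vector is treated as disjoint from everything).
#' @return Distance in \[0, 1\].
#' @export
bhattacharyya_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

region_hsv_hist <- function(frame, mask, bins = 15) {
  if (!any(mask)) return(numeric(3 * bins))
  rgb <- rbind(frame[, , 1][mask], frame[, , 2][mask], frame[, , 3][mask])
  hsv <- rgb2hsv(rgb, maxColorValue = 1)
  edges <- seq(0, 1, length.out = bins + 1)
  h <- c(norm_hist(hsv[1, ], edges), norm_hist(hsv[2, ], edges),
         norm_hist(hsv[3, ], edges))
  h / sum(h)
}

#' Colour feature (2 values)
#'
#' HSV histograms (15 bins per channel, concatenated and L1-normalized) are
#' extracted from the hand, box and background regions; the feature is the
#' Bhattacharyya distance between box and hand, and between box and
#' background.
#'
#' @param frame `H x W x 3` array.
#' @param regions A `region_set`.
#' @param bins Bins per HSV channel (default 15).
#' @return Numeric vector `c(d_box_hand, d_box_background)`, each in
#'   \[0, 1\].
#' @export
colour_feature <- function(frame, regions, bins = 15) {
  h_hand <- region_hsv_hist(frame, regions$hand, bins)
  h_box <- region_hsv_hist(frame, regions$box, bins)
  h_bg <- region_hsv_hist(frame, regions$background, bins)
  c(bhattacharyya_distance(h_box, h_hand),
    bhattacharyya_distance(h_box, h_bg))
}

#' Assemble the combined interaction feature
#'
#' Concatenates motion, shape and colour blocks in that order; with the
#' default sizes the combined feature has 122 values (60 + 60 + 2).
#'
#' @param motion Motion block (length 60).
#' @param shape Shape block (length 60).
#' @param colour Colour block (length 2).
#' @return Numeric vector of length 122 with a `blocks` attribute giving the
#'   index ranges of the three families.
#' @export
assemble_feature <- function(motion, shape, colour) {
  if (length(motion) != 60) stop("motion block must have 60 values")
  if (length(shape) != 60) stop("shape block must have 60 values")
  if (length(colour) != 2) stop("colour block must have 2 values")
  structure(c(motion, shape, colour),
            blocks = list(motion = 1:60, shape = 61:120, colour = 121:122))
}
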