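# Rotating three-rectangle Haar-like arm-angle feature. A centre rectangle
# extends from the box centroid to the image border along a ray; two side
# rectangles of the same width sit adjacent and parallel on either side. The
# response at each angle is the average of (CV_side - CV_centre) over the two
# sides, where CV is the coefficient of variation of pixel intensities: a
# uniform arm in the centre rectangle against cluttered surroundings gives a
# large positive response, so the response peaks when the ray is aligned with
# the arm.
#
# Angle convention: 0 deg points image-left (west) and angles increase
# clockwise on screen (90 = up, 180 = right, 270 = down). This is the unique
# convention under which the quadrant rule reads naturally: 0-180 spans the
# top half of the image (another person's hand reaching in from the top),
# 180-270 the bottom-right (the user's right arm), 270-360 the bottom-left
# (the user's left arm).

#' Rotating Haar-like arm-angle feature
#'
#' Sweeps the three-rectangle Haar-like response through 360 degrees around
#' the centroid of a hand bounding box in `step_deg` increments, then sums
#' consecutive `bin_deg` bins; with the defaults (1 degree steps, 5 degree
#' bins) the binned vector has 72 values. Binning is a partition, so the
#' binned vector sums to the raw profile's total.
#'
#' @param frame `H x W x 3` array or `H x W` grayscale matrix.
#' @param box [bbox] around the detected hand; its centroid must lie inside
#'   the frame.
#' @param rect_width_frac Centre-rectangle width as a fraction of the shorter
#'   box side (default 0.5).
#' @param step_deg Angular step in degrees (default 1).
#' @param bin_deg Bin width in degrees (default 5; must be a multiple of
#'   `step_deg`).
#' @return An `arm_feature`: list with `raw_profile` (length
#'   `360 / step_deg`), `binned` (length `360 / bin_deg`) and `centroid`.
#' @export
arm_angle_feature <- function(frame, box, rect_width_frac = 0.5,
                              step_deg = 1, bin_deg = 5) {
  gray <- if (length(dim(frame)) == 3) frame_gray(frame) else frame
  H <- nrow(gray); W <- ncol(gray)
  ctr <- bbox_centroid(box)
  if (ctr["x"] < 0 || ctr["x"] > W - 1 || ctr["y"] < 0 || ctr["y"] > H - 1) {
    stop("box centroid lies outside the frame")
  }
  stopifnot(360 %% step_deg == 0, bin_deg %% step_deg == 0)
  w_rect <- rect_width_frac * min(box$w, box$h)
  raw <- .arm_sweep_cpp(gray, ctr["x"], ctr["y"], w_rect, as.integer(step_deg))
  per_bin <- bin_deg / step_deg
  groups <- rep(seq_len(360 / bin_deg), each = per_bin)
  binned <- as.vector(rowsum(raw, groups))
  structure(list(raw_profile = raw, binned = binned, centroid = ctr),
            class = "arm_feature")
}

as_binned <- function(feature) {
  if (inherits(feature, "arm_feature")) feature$binned else as.numeric(feature)
}

#' Train the hand-verification forest
#'
#' Fits a binary random-forest classifier on binned arm-angle features to
#' confirm whether a candidate bounding box truly contains a hand. Because
#' the binned profile rotates with the arm angle — hand presence is
#' angle-agnostic — the training set is augmented by circular shifts of the
#' bin vector by default, which densifies angle coverage and lets the
#' per-bin tree splits generalize from far fewer labelled boxes.
#'
#' @param features Matrix (`n x 72`) of binned arm-angle features.
#' @param labels Logical vector, `TRUE` = hand present.
#' @param ntree Number of trees (default 150).
#' @param seed RNG seed for the forest (default 42).
#' @param augment_rotations Augment training rows with circular bin shifts
#'   (every 3 bins, i.e. 15-degree steps; default `TRUE`).
#' @return A `hand_verifier` model.
#' @export
train_hand_verifier <- function(features, labels, ntree = 150, seed = 42,
                                augment_rotations = TRUE) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("need both classes to train verifier")
  if (augment_rotations) {
    nb <- ncol(features)
    shifted <- lapply(seq(0, nb - 3, by = 3), function(sh) {
      features[, ((seq_len(nb) - 1 + sh) %% nb) + 1, drop = FALSE]
    })
    features <- do.call(rbind, shifted)
    labels <- rep(labels, length(shifted))
  }
  colnames(features) <- paste0("b", seq_len(ncol(features)))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = features, y = factor(labels, levels = c(FALSE, TRUE)), ntree = ntree)
  structure(list(forest = forest, ntree = ntree, seed = seed,
                 n_features = ncol(features)),
            class = "hand_verifier")
}

#' Verify a candidate box with the trained forest
#'
#' @param feature An `arm_feature` or a numeric vector of binned values.
#' @param model A `hand_verifier` from [train_hand_verifier].
#' @return `TRUE` iff the positive-class vote fraction is at least 0.5.
#' @export
verify_box <- function(feature, model) {
  if (!inherits(model, "hand_verifier")) stop("model is not a trained hand_verifier")
  x <- matrix(as_binned(feature), nrow = 1)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  votes <- predict(model$forest, x, type = "prob")
  unname(votes[1, "TRUE"] >= 0.5)
}

#' Handedness from arm-angle quadrant sums
#'
#' Sums the binned arm-angle feature over the top half (0-180 degrees,
#' quadrants I+II), the bottom-right quadrant (180-270, III) and the
#' bottom-left quadrant (270-360, IV). The hand is the user's left hand when
#' quadrant IV has the strictly highest sum, the user's right hand for III,
#' and another person's hand for I+II; ties resolve right, then left, then
#' other. The decision is invariant to positive scaling of the feature.
#'
#' @param feature An `arm_feature` or numeric vector of 72 binned values.
#' @return One of `"left"`, `"right"`, `"other"`.
#' @export
classify_handedness <- function(feature) {
  b <- as_binned(feature)
  stopifnot(length(b) == 72)
  sums <- c(other = sum(b[1:36]),     # 0-180 deg, top half
            right = sum(b[37:54]),    # 180-270 deg, bottom-right
            left = sum(b[55:72]))     # 270-360 deg, bottom-left
  best <- names(sums)[sums == max(sums)]
  if ("right" %in% best) "right" else if ("left" %in% best) "left" else "other"
}
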