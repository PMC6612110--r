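# Synthetic egocentric scenes with full ground truth. A skin-coloured
# elliptical hand with an arm strip extending to a frame border moves over a
# static noise-textured background; an object of distinct colour either
# translates rigidly with the hand (interaction), moves independently, or is
# absent. Geometry parameters and labels are recorded per frame so every
# pipeline stage can be scored without manual annotation. Skin pixels share
# one chroma (luminance-only shading), so they sit at the mode of the
# baseline skin model by construction.

#' Scene specification
#'
#' @param n_frames Number of frames (default 90, i.e. 3 s at 30 fps).
#' @param fps Frames per second (default 30).
#' @param height,width Frame size in pixels (defaults 480 x 854, the
#'   analysis resolution of a 16:9 camera).
#' @param entry Border the arm enters from: `"bottom-left"` (user's left
#'   hand), `"bottom-right"` (right hand) or `"top"` (another person's
#'   hand).
#' @param coupling Object behaviour: `"moves_with_hand"` (interaction),
#'   `"independent"`, or `"absent"` (both no interaction).
#' @param seed RNG seed; a fixed seed gives bit-identical scenes.
#' @param hand_scale Hand ellipse semi-axes as a fraction of frame height
#'   (default `c(0.11, 0.08)`, x then y).
#' @param speed Hand drift amplitude in pixels per frame (default 3).
#' @param trajectory Optional explicit per-frame hand-centre path: a
#'   two-column matrix or data.frame (`cx`, `cy` in pixels, `n_frames`
#'   rows). When `NULL` (default) a smooth seeded path is generated that
#'   stays inside the frame; an explicit path whose hand leaves the frame
#'   is an error.
#' @param skin_rgb Base skin colour; the default's normalized-rg chroma sits
#'   at the skin-model mode.
#' @param object_rgb Object colour (default blue, far from skin chroma).
#' @param bg_rgb,bg_noise Background base colour and per-pixel noise SD.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_frames = 90, fps = 30, height = 480, width = 854,
                       entry = c("bottom-left", "bottom-right", "top"),
                       coupling = c("moves_with_hand", "independent", "absent"),
                       seed = 1,
                       hand_scale = c(0.11, 0.08),
                       speed = 3,
                       trajectory = NULL,
                       skin_rgb = c(0.798, 0.589, 0.513),
                       object_rgb = c(0.15, 0.25, 0.85),
                       bg_rgb = c(0.49, 0.64, 0.53),
                       bg_noise = 0.08) {
  entry <- match.arg(entry)
  coupling <- match.arg(coupling)
  stopifnot(n_frames >= 1, fps > 0, height >= 60, width >= 60)
  if (!is.null(trajectory)) {
    trajectory <- as.matrix(trajectory)
    stopifnot(ncol(trajectory) == 2, nrow(trajectory) == n_frames)
  }
  structure(list(n_frames = n_frames, fps = fps, height = height,
                 width = width, entry = entry, coupling = coupling,
                 seed = seed, hand_scale = hand_scale, speed = speed,
                 trajectory = trajectory,
                 skin_rgb = skin_rgb, object_rgb = object_rgb,
                 bg_rgb = bg_rgb, bg_noise = bg_noise),
            class = "scene_spec")
}

# arm anchor point on the frame border for an entry side
entry_anchor <- function(entry, H, W) {
  switch(entry,
         "bottom-left" = c(x = 0.03 * W, y = H - 1),
         "bottom-right" = c(x = 0.97 * W, y = H - 1),
         "top" = c(x = 0.5 * W, y = 0))
}

# arm-angle (degrees) of the ray from the hand centre towards the border
# anchor under the package convention (0 = west, clockwise through top)
ray_angle_deg <- function(ctr, anchor) {
  ux <- anchor["x"] - ctr["x"]; uy <- anchor["y"] - ctr["y"]
  (atan2(-uy, -ux) * 180 / pi) %% 360
}

#' Generate a synthetic scene
#'
#' Renders the scene described by a [scene_spec] and returns the video with
#' per-frame ground truth: hand centre and axes, arm anchor and true arm
#' angle, handedness, interaction label, the padded hand box (the analogue
#' of a detector's output box) and the tight box around all skin pixels.
#' Masks are re-derivable on demand via [truth_hand_mask] /
#' [truth_skin_mask] so scenes stay light in memory.
#'
#' @param spec A `scene_spec`.
#' @return An `ego_scene`: list with `video` ([ego_video]), `truth`
#'   (per-frame `data.frame`), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  set.seed(spec$seed)
  ax <- spec$hand_scale[1] * H
  ay <- spec$hand_scale[2] * H
  obj_r <- 0.55 * ay
  # the arm must be a little wider than the Haar centre rectangle (half the
  # shorter padded-box side ~ 1.18*ay) so an aligned rectangle sees pure arm
  arm_w <- 1.5 * ay
  anchor <- entry_anchor(spec$entry, H, W)

  # smooth pseudo-random hand trajectory around a home position on the
  # anchor's side of the frame
  home_x <- unname(0.25 * W + 0.5 * W * (anchor["x"] / W))
  home_y <- if (spec$entry == "top") 0.40 * H else 0.55 * H
  ph <- runif(4, 0, 2 * pi)
  t <- seq_len(spec$n_frames)
  margin <- max(ax, ay) + obj_r + 3
  if (!is.null(spec$trajectory)) {
    cx <- spec$trajectory[, 1]
    cy <- spec$trajectory[, 2]
    if (any(cx < margin) || any(cx > W - 1 - margin) ||
        any(cy < margin) || any(cy > H - 1 - margin)) {
      stop("hand trajectory leaves the frame")
    }
  } else {
    # drift amplitude: requested, but clamped so the hand stays inside the
    # frame for any phase draw
    amp <- spec$speed * 12
    amp_x <- min(amp, home_x - margin, W - 1 - margin - home_x)
    amp_y <- min(0.85 * amp, home_y - margin, H - 1 - margin - home_y)
    cx <- home_x + amp_x * 0.7 * sin(2 * pi * t / 75 + ph[1]) +
      amp_x * 0.3 * sin(2 * pi * t / 31 + ph[2])
    cy <- home_y + amp_y * 0.7 * sin(2 * pi * t / 63 + ph[3]) +
      amp_y * 0.3 * sin(2 * pi * t / 27 + ph[4])
  }
  if (any(cx < margin) || any(cx > W - 1 - margin) ||
      any(cy < margin) || any(cy > H - 1 - margin)) {
    stop("hand trajectory leaves the frame; reduce speed or enlarge the frame")
  }

  # object path
  if (spec$coupling == "moves_with_hand") {
    off <- c(0.8 * ax, -0.9 * ay)  # at the fingertips, above the hand
    ox <- cx + off[1] * (if (spec$entry == "bottom-right") -1 else 1)
    oy <- cy + off[2]
  } else if (spec$coupling == "independent") {
    ox <- unname((0.8 - 0.6 * (anchor["x"] / W)) * W) +
      0.08 * W * sin(2 * pi * t / 41 + ph[2])
    oy <- 0.25 * H + 0.05 * H * sin(2 * pi * t / 29 + ph[3])
  } else {
    ox <- rep(NA_real_, spec$n_frames); oy <- rep(NA_real_, spec$n_frames)
  }

  background <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    background[, , ch] <- pmin(pmax(
      spec$bg_rgb[ch] + matrix(rnorm(H * W, 0, spec$bg_noise), H, W), 0), 1)
  }
  lum_seed <- sample.int(.Machine$integer.max, 1)

  handed <- switch(spec$entry, "bottom-left" = "left",
                   "bottom-right" = "right", "top" = "other")
  label <- if (spec$coupling == "moves_with_hand") "interaction" else "no_interaction"

  frames <- vector("list", spec$n_frames)
  truth <- data.frame(frame = t - 1, cx = cx, cy = cy, ax = ax, ay = ay,
                      arm_w = arm_w, anchor_x = unname(anchor["x"]),
                      anchor_y = unname(anchor["y"]),
                      angle_deg = NA_real_, obj_x = ox, obj_y = oy,
                      obj_r = obj_r, handedness = handed, label = label,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, scene_geometry(truth, H, W))
  truth$skin_box_x <- truth$skin_box_y <- NA_real_
  truth$skin_box_w <- truth$skin_box_h <- NA_real_
  for (i in t) {
    skin_m <- ellipse_mask(H, W, cx[i], cy[i], ax, ay) |
      strip_mask(H, W, cx[i], cy[i], anchor["x"], anchor["y"], arm_w / 2)
    obj_m <- if (!is.na(ox[i])) ellipse_mask(H, W, ox[i], oy[i], obj_r, obj_r)
      else matrix(FALSE, H, W)
    frames[[i]] <- render_frame(background, skin_m, obj_m, spec, lum_seed + i)
    vis <- skin_m & !obj_m
    idx <- which(vis, arr.ind = TRUE)
    truth$skin_box_x[i] <- min(idx[, 2]) - 1
    truth$skin_box_y[i] <- min(idx[, 1]) - 1
    truth$skin_box_w[i] <- max(idx[, 2]) - min(idx[, 2]) + 1
    truth$skin_box_h[i] <- max(idx[, 1]) - min(idx[, 1]) + 1
    truth$angle_deg[i] <- ray_angle_deg(c(x = cx[i], y = cy[i]), anchor)
  }
  structure(list(video = ego_video(frames, spec$fps), truth = truth,
                 spec = spec),
            class = "ego_scene")
}

# per-frame padded hand box (the analogue of a detector's hand box; a tight
# ellipse box would fill > 75% of itself and trip the contour area filter)
scene_geometry <- function(truth, H, W) {
  pad <- 0.18
  hx0 <- pmax(0, truth$cx - truth$ax * (1 + pad))
  hx1 <- pmin(W - 1, truth$cx + truth$ax * (1 + pad))
  hy0 <- pmax(0, truth$cy - truth$ay * (1 + pad))
  hy1 <- pmin(H - 1, truth$cy + truth$ay * (1 + pad))
  data.frame(hand_box_x = hx0, hand_box_y = hy0,
             hand_box_w = hx1 - hx0 + 1, hand_box_h = hy1 - hy0 + 1)
}

# geometric masks -------------------------------------------------------------

ellipse_mask <- function(H, W, cx, cy, ax, ay) {
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), W), H, W)
  ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
}

strip_mask <- function(H, W, x0, y0, x1, y1, halfw) {
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), W), H, W)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- max(vx^2 + vy^2, 1e-9)
  u <- ((X - x0) * vx + (Y - y0) * vy) / len2
  u <- pmin(pmax(u, 0), 1)
  px <- x0 + u * vx; py <- y0 + u * vy
  (X - px)^2 + (Y - py)^2 <= halfw^2
}

#' Ground-truth masks for one frame of a scene
#'
#' `truth_hand_mask` is the visible hand (ellipse minus any occluding
#' object); `truth_skin_mask` additionally includes the arm strip — the full
#' skin-coloured blob a colour-based detector sees; `truth_object_mask` is
#' the object (empty when absent).
#'
#' @param scene An `ego_scene`.
#' @param i Frame number (1-based).
#' @return Logical `H x W` matrix.
#' @export
truth_hand_mask <- function(scene, i) {
  r <- scene$truth[i, ]
  H <- scene$spec$height; W <- scene$spec$width
  m <- ellipse_mask(H, W, r$cx, r$cy, r$ax, r$ay)
  m & !truth_object_mask(scene, i)
}

#' @rdname truth_hand_mask
#' @export
truth_skin_mask <- function(scene, i) {
  r <- scene$truth[i, ]
  H <- scene$spec$height; W <- scene$spec$width
  m <- ellipse_mask(H, W, r$cx, r$cy, r$ax, r$ay) |
    strip_mask(H, W, r$cx, r$cy, r$anchor_x, r$anchor_y, r$arm_w / 2)
  m & !truth_object_mask(scene, i)
}

#' @rdname truth_hand_mask
#' @export
truth_object_mask <- function(scene, i) {
  r <- scene$truth[i, ]
  H <- scene$spec$height; W <- scene$spec$width
  if (is.na(r$obj_x)) return(matrix(FALSE, H, W))
  ellipse_mask(H, W, r$obj_x, r$obj_y, r$obj_r, r$obj_r)
}

#' Ground-truth boxes for one frame
#' @param scene An `ego_scene`.
#' @param i Frame number (1-based).
#' @param which `"hand"` for the padded hand box, `"skin"` for the tight box
#'   around all skin pixels.
#' @return A [bbox].
#' @export
truth_box <- function(scene, i, which = c("hand", "skin")) {
  which <- match.arg(which)
  r <- scene$truth[i, ]
  if (which == "hand") bbox(r$hand_box_x, r$hand_box_y, r$hand_box_w, r$hand_box_h)
  else bbox(r$skin_box_x, r$skin_box_y, r$skin_box_w, r$skin_box_h)
}

render_frame <- function(background, skin, obj, spec, lum_seed) {
  H <- spec$height; W <- spec$width
  frame <- background
  set.seed(lum_seed)
  # luminance-only shading keeps chroma exactly at the skin-model mode;
  # mild amplitude: hands are smoothly shaded, unlike the noise background
  lum <- matrix(runif(H * W, 0.97, 1.03), H, W)
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[skin] <- pmin(spec$skin_rgb[ch] * lum[skin], 1)
    plane[obj] <- pmin(pmax(spec$object_rgb[ch] * lum[obj], 0), 1)
    frame[, , ch] <- plane
  }
  frame
}

#' Generate a LOSO-ready synthetic dataset
#'
#' Builds `n_subjects` synthetic subjects, each a concatenation of
#' fixed-length scene segments whose object coupling is allocated so that
#' close to `positive_rate` of frames are interactions (the class balance of
#' a typical ADL recording session). Subjects differ in seed-driven
#' trajectories, segment order, hand sides and object colours. Each
#' subject's frames are featurized against ground-truth boxes and masks
#' (isolating classifier evaluation from detector errors), yielding the raw
#' blocks [evaluate_loso] expects.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_frames Frames per subject (default 600).
#' @param height,width Frame size used for the synthetic evaluation
#'   (defaults 160 x 284).
#' @param positive_rate Target fraction of interaction frames
#'   (default 0.48).
#' @param segment_len Frames per scene segment (default 60).
#' @param seed Master seed.
#' @return Named list of subjects, each with `motion`, `hog`, `colour`,
#'   `labels`, `hand` — see [evaluate_loso].
#' @export
generate_subjects <- function(n_subjects, n_frames = 600, height = 160,
                              width = 284, positive_rate = 0.48,
                              segment_len = 60, seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects for LOSO")
  out <- list()
  for (s in seq_len(n_subjects)) {
    sseed <- seed * 1000 + s
    set.seed(sseed)
    n_seg <- max(2, round(n_frames / segment_len))
    # balanced left/right segments, with interaction segments split across
    # the sides, so both hands see both classes in every subject and the
    # overall positive rate matches the target as closely as segments allow
    sides <- rep(c("bottom-left", "bottom-right"), length.out = n_seg)
    total_pos <- round(positive_rate * n_seg)
    extra_to_left <- sample(c(0L, 1L), 1)
    coup <- character(n_seg)
    for (side in unique(sides)) {
      idx <- which(sides == side)
      n_pos <- total_pos %/% 2 +
        if (side == "bottom-left") extra_to_left * (total_pos %% 2) else
          (1L - extra_to_left) * (total_pos %% 2)
      n_pos <- min(length(idx), n_pos)
      coup[idx] <- sample(c(rep("moves_with_hand", n_pos),
                            sample(c("independent", "absent"),
                                   length(idx) - n_pos, replace = TRUE)))
    }
    # tiny subjects: make sure both classes occur at all
    if (!any(coup == "moves_with_hand")) coup[1] <- "moves_with_hand"
    if (all(coup == "moves_with_hand")) coup[n_seg] <- "independent"
    ord <- sample(n_seg)
    sides <- sides[ord]; coup <- coup[ord]
    seg_seeds <- sample.int(1e6, n_seg)
    obj_col <- c(runif(1, 0, 0.3), runif(1, 0.1, 0.4), runif(1, 0.6, 1))
    speed <- runif(1, 2, 3.5)
    feats <- list()
    for (g in seq_len(n_seg)) {
      sc <- generate_scene(scene_spec(
        n_frames = segment_len, height = height, width = width,
        entry = sides[g], coupling = coup[g], seed = seg_seeds[g],
        object_rgb = obj_col, speed = speed))
      feats[[g]] <- featurize_scene(sc)
    }
    out[[sprintf("subject%02d", s)]] <- list(
      motion = do.call(rbind, lapply(feats, `[[`, "motion")),
      hog = do.call(rbind, lapply(feats, `[[`, "hog")),
      colour = do.call(rbind, lapply(feats, `[[`, "colour")),
      labels = unlist(lapply(feats, `[[`, "labels"), use.names = FALSE),
      hand = unlist(lapply(feats, `[[`, "hand"), use.names = FALSE))
  }
  out
}

#' Featurize a scene against its ground truth
#'
#' Computes the raw interaction-feature blocks for every frame pair of a
#' scene using the ground-truth hand mask and hand box as the segmentation
#' (oracle preprocessing). Frame 1 of the scene has no predecessor and is
#' skipped.
#'
#' @param scene An `ego_scene`.
#' @return List with `motion` (`n x 60`), `hog` (`n x d` raw descriptors),
#'   `colour` (`n x 2`), `labels` (logical), `hand` (character).
#' @export
featurize_scene <- function(scene) {
  H <- scene$spec$height; W <- scene$spec$width
  nf <- n_frames(scene$video)
  motion <- NULL; hog <- NULL; colour <- NULL
  labels <- logical(0); hand <- character(0)
  for (i in 2:nf) {
    fl <- dense_flow(scene$video$frames[[i - 1]], scene$video$frames[[i]])
    box <- truth_box(scene, i, "hand")
    regions <- region_set(truth_hand_mask(scene, i), box, H, W)
    mo <- motion_feature(fl, regions)
    gray <- frame_gray(scene$video$frames[[i]])
    crop <- gray[bbox_rows(box, H), bbox_cols(box, W), drop = FALSE]
    hg <- hog_descriptor(resize_mat(crop, max(8, round(0.10 * H)),
                                    max(8, round(0.15 * W))))
    co <- colour_feature(scene$video$frames[[i]], regions)
    motion <- rbind(motion, mo)
    hog <- rbind(hog, hg)
    colour <- rbind(colour, co)
    labels <- c(labels, scene$truth$label[i] == "interaction")
    hand <- c(hand, scene$truth$handedness[i])
  }
  rownames(motion) <- rownames(hog) <- rownames(colour) <- NULL
  list(motion = motion, hog = hog, colour = colour, labels = labels,
       hand = hand)
}

#' Construct a binary timeline with prescribed metrics
#'
#' Analytically inverts [extract_metrics]: builds a 0/1 sequence whose
#' percentage of interaction time, mean interaction duration and
#' interactions per hour equal the targets exactly. Targets must be mutually
#' consistent (`pct = n * mean / total * 100` with integer run counts and
#' frame totals); inconsistent or unfittable targets raise an error.
#'
#' @param pct_interaction Target percentage in \[0, 100\].
#' @param mean_duration_s Target mean duration (seconds); `NA` iff
#'   `pct_interaction` is 0.
#' @param interactions_per_hour Target rate; `NA` iff `pct_interaction` is
#'   0.
#' @param n_frames Sequence length.
#' @param fps Frames per second.
#' @return Integer 0/1 vector of length `n_frames`.
#' @export
generate_timeline <- function(pct_interaction, mean_duration_s,
                              interactions_per_hour, n_frames, fps = 30) {
  stopifnot(n_frames >= 1)
  if (pct_interaction == 0) {
    if (!is.na(mean_duration_s) || !is.na(interactions_per_hour)) {
      stop("zero interaction time is inconsistent with defined duration/rate")
    }
    return(integer(n_frames))
  }
  total_s <- n_frames / fps
  k <- interactions_per_hour * total_s / 3600
  total_ones <- pct_interaction / 100 * n_frames
  if (abs(k - round(k)) > 1e-6 || round(k) < 1) {
    stop("interactions_per_hour does not yield an integer run count")
  }
  k <- round(k)
  if (abs(total_ones - round(total_ones)) > 1e-6) {
    stop("pct_interaction does not yield an integer frame count")
  }
  total_ones <- round(total_ones)
  if (abs(mean_duration_s - total_ones / k / fps) > 1e-9) {
    stop("mean_duration_s inconsistent with pct_interaction and rate")
  }
  if (total_ones + (k - 1) > n_frames) stop("runs do not fit in n_frames")
  base <- total_ones %/% k
  lens <- rep(base, k)
  extra <- total_ones - base * k
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1
  gap_total <- n_frames - total_ones
  gaps <- rep(gap_total %/% (k + 1), k + 1)
  rem <- gap_total - sum(gaps)
  if (rem > 0) gaps[seq_len(rem)] <- gaps[seq_len(rem)] + 1
  # interior gaps must be >= 1 to keep runs distinct
  if (k > 1 && any(gaps[2:k] < 1)) {
    take <- which(gaps[2:k] < 1) + 1
    for (g in take) {
      donor <- which.max(gaps)
      gaps[donor] <- gaps[donor] - 1
      gaps[g] <- gaps[g] + 1
    }
  }
  out <- integer(0)
  for (j in seq_len(k)) {
    out <- c(out, integer(gaps[j]), rep(1L, lens[j]))
  }
  c(out, integer(n_frames - length(out)))
}
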