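# End-to-end orchestration: video -> detections -> arm-angle verification and
# handedness -> segmentation -> interaction features -> per-frame decisions ->
# per-hand timelines -> functional metrics. Any stage failure for a frame
# degrades that frame to hand_absent (the timeline layer owns missing-frame
# semantics); a frame is never allowed to abort the video.

# Run detection, verification, handedness and segmentation on one frame and
# extract the raw feature blocks for every accepted hand. Returns a list of
# candidates: list(hand, motion, hog, colour). Shared by run_pipeline and by
# model fitting, so training features flow through the same preprocessing as
# prediction-time features.
frame_candidates <- function(frame, prev_frame, models, config) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  dets <- detect_hands(frame, models$skin,
                       min_area_frac = config$detector.min_area_frac,
                       max_detections = config$detector.max_detections,
                       skin_threshold = config$detector.skin_threshold)
  out <- list()
  if (length(dets) == 0 || is.null(prev_frame)) return(out)
  flow <- NULL
  seen <- character(0)
  for (d in dets) {
    feat <- try(arm_angle_feature(frame, d$box,
                                  rect_width_frac = config$arm.rect_width_frac,
                                  step_deg = config$arm.step_deg,
                                  bin_deg = config$arm.bin_deg), silent = TRUE)
    if (inherits(feat, "try-error")) next
    if (!is.null(models$verifier) && !verify_box(feat, models$verifier)) next
    hand <- classify_handedness(feat)
    if (hand %in% seen) next  # keep the highest-scored box per hand
    seg <- segment_hand(frame, d$box, models$skin, config = config)
    if (is.null(seg)) next
    if (is.null(flow)) flow <- dense_flow(prev_frame, frame)
    regions <- region_set(seg$mask, seg$recentred_box, H, W)
    mo <- motion_feature(flow, regions, config$feat.n_bins, config$feat.mag_cap)
    gray <- frame_gray(frame)
    crop <- gray[bbox_rows(seg$recentred_box, H),
                 bbox_cols(seg$recentred_box, W), drop = FALSE]
    hg <- hog_descriptor(resize_mat(crop, max(8, round(0.10 * H)),
                                    max(8, round(0.15 * W))),
                         orientations = config$feat.hog_orientations,
                         cell = config$feat.hog_cell,
                         block = config$feat.hog_block)
    co <- colour_feature(frame, regions, config$feat.hsv_bins)
    out[[length(out) + 1]] <- list(hand = hand, motion = mo, hog = hg,
                                   colour = co)
    seen <- c(seen, hand)
  }
  out
}

#' Fit the pipeline's learned models on synthetic data
#'
#' Trains the two learned components the pipeline needs when no externally
#' trained models are supplied. The arm-angle hand verifier is trained on
#' binned arm features from detector-produced boxes (arm present) versus
#' background boxes of the same size (arm absent). The interaction
#' classifier and its shape PCA are then trained on features extracted
#' through the pipeline's own preprocessing (detection, verification,
#' segmentation) on labelled synthetic scenes, so training and prediction
#' features share one path.
#'
#' @param seed Master RNG seed.
#' @param height,width Frame size of the training scenes (defaults
#'   160 x 284).
#' @param n_verifier_scenes Scenes used for verifier training (default 30).
#' @param n_train_scenes Labelled scenes for the interaction model (default
#'   10), alternating coupling and entry side.
#' @param scene_frames Frames per training scene (default 40).
#' @param config Configuration list, see [default_config].
#' @return A `pipeline_models` list: `skin`, `verifier`, `pca`,
#'   `interaction`.
#' @export
fit_pipeline_models <- function(seed = 42, height = 160, width = 284,
                                n_verifier_scenes = 30, n_train_scenes = 10,
                                scene_frames = 40,
                                config = default_config()) {
  skin <- skin_model_default()
  entries <- c("bottom-left", "bottom-right", "top")
  feats <- NULL
  labs <- logical(0)
  for (k in seq_len(n_verifier_scenes)) {
    sc <- generate_scene(scene_spec(n_frames = 1, height = height,
                                    width = width,
                                    entry = entries[(k %% 3) + 1],
                                    coupling = "absent", seed = seed + k))
    frame <- sc$video$frames[[1]]
    dets <- detect_hands(frame, skin,
                         min_area_frac = config$detector.min_area_frac,
                         skin_threshold = config$detector.skin_threshold)
    if (length(dets) == 0) next
    pos_box <- dets[[1]]$box
    f_pos <- arm_angle_feature(frame, pos_box)
    # arm-absent sample: a capped-size box in the frame corner diagonally
    # opposite the arm's border anchor, clear of hand and arm
    r <- sc$truth[1, ]
    nw <- min(pos_box$w, width / 4); nh <- min(pos_box$h, height / 4)
    nx <- if (r$anchor_x > width / 2) 2 else width - nw - 2
    ny <- if (r$anchor_y > height / 2) 2 else height - nh - 2
    f_neg <- arm_angle_feature(frame, bbox(nx, ny, nw, nh))
    feats <- rbind(feats, f_pos$binned, f_neg$binned)
    labs <- c(labs, TRUE, FALSE)
  }
  verifier <- train_hand_verifier(feats, labs, ntree = config$rf.ntree,
                                  seed = seed)

  models0 <- list(skin = skin, verifier = verifier)
  couplings <- c("moves_with_hand", "independent", "absent")
  sides <- c("bottom-left", "bottom-right")
  motion <- NULL; hog <- NULL; colour <- NULL; y <- logical(0)
  for (k in seq_len(n_train_scenes)) {
    coup <- couplings[(k %% 3) + 1]
    sc <- generate_scene(scene_spec(n_frames = scene_frames, height = height,
                                    width = width,
                                    entry = sides[(k %% 2) + 1],
                                    coupling = coup, seed = seed + 100 + k))
    for (i in 2:scene_frames) {
      cands <- frame_candidates(sc$video$frames[[i]],
                                sc$video$frames[[i - 1]], models0, config)
      for (cd in cands) {
        if (cd$hand != sc$truth$handedness[i]) next
        motion <- rbind(motion, cd$motion)
        hog <- rbind(hog, cd$hog)
        colour <- rbind(colour, cd$colour)
        y <- c(y, sc$truth$label[i] == "interaction")
      }
    }
  }
  pca <- fit_shape_pca(hog, config$feat.pca_components)
  x <- cbind(motion, shape_pca_transform(pca, hog), colour)
  interaction <- train_interaction_model(x, y, ntree = config$rf.ntree,
                                         seed = seed)
  structure(list(skin = skin, verifier = verifier, pca = pca,
                 interaction = interaction, seed = seed),
            class = "pipeline_models")
}

#' Run the full hand-use pipeline on a video
#'
#' Executes the sequential stages frame by frame: baseline skin-blob
#' detection, arm-angle verification and handedness assignment, hand
#' segmentation with box re-centring, interaction-feature extraction against
#' the previous frame, forest classification, then per-hand timeline
#' construction with gap bridging, moving-average smoothing and metric
#' extraction. Frames where any stage fails contribute `hand_absent` and are
#' handled by the timeline gap rule. Deterministic for fixed inputs and
#' models.
#'
#' @param video An [ego_video].
#' @param models A `pipeline_models` list from [fit_pipeline_models] (or
#'   assembled from externally trained components).
#' @param config Configuration list, see [default_config].
#' @return A `pipeline_result`: list with `predictions` (frame decisions),
#'   `timeline` (`hand_timeline`), `smoothed` (per-hand 0/1 vectors) and
#'   `metrics` (per-hand `hand_use_metrics` for left and right).
#' @export
run_pipeline <- function(video, models, config = default_config()) {
  stopifnot(inherits(video, "ego_video"))
  nf <- n_frames(video)
  rows <- list()
  for (i in seq_len(nf)) {
    prev <- if (i > 1) video$frames[[i - 1]] else NULL
    cands <- frame_candidates(video$frames[[i]], prev, models, config)
    for (cd in cands) {
      x <- assemble_feature(cd$motion,
                            as.vector(shape_pca_transform(models$pca, cd$hog)),
                            cd$colour)
      state <- if (predict_interaction(models$interaction, x))
        "interaction" else "no_interaction"
      rows[[length(rows) + 1]] <- data.frame(frame = i - 1, hand = cd$hand,
                                             state = state,
                                             stringsAsFactors = FALSE)
    }
  }
  pred <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), hand = character(), state = character(),
               stringsAsFactors = FALSE)
  timeline <- build_timeline(pred, nf, video$fps,
                             bridge_frames = config$timeline.bridge_frames)
  smoothed <- lapply(timeline$states, smooth_threshold,
                     window = config$timeline.window)
  metrics <- lapply(smoothed[c("left", "right")], extract_metrics,
                    fps = video$fps)
  structure(list(predictions = pred, timeline = timeline,
                 smoothed = smoothed, metrics = metrics, config = config),
            class = "pipeline_result")
}

#' Save / load fitted pipeline models
#'
#' Serializes a `pipeline_models` object to a single file with a JSON
#' metadata sidecar (`<path>.json`) recording the seed and forest settings.
#'
#' @param models A `pipeline_models` list.
#' @param path Output file path (RDS format).
#' @return `path` (save) or a `pipeline_models` (load).
#' @export
save_pipeline_models <- function(models, path) {
  saveRDS(models, path)
  jsonlite::write_json(
    list(seed = models$seed,
         verifier_trees = models$verifier$ntree,
         interaction_trees = models$interaction$ntree,
         pca_components = models$pca$n_components,
         feature_dim = models$interaction$d),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pipeline_models
#' @export
load_pipeline_models <- function(path) {
  readRDS(path)
}
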