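test_that("binned feature has 72 values and partitions the raw profile", {
  sc <- fix_scene_small()
  f <- arm_angle_feature(sc$video$frames[[1]], truth_box(sc, 1, "hand"))
  expect_length(f$raw_profile, 360)
  expect_length(f$binned, 72)
  expect_equal(sum(f$binned), sum(f$raw_profile), tolerance = 1e-9)

  # partition property holds for arbitrary images too
  set.seed(11)
  for (k in 1:5) {
    g <- matrix(runif(80 * 120), 80, 120)
    f2 <- arm_angle_feature(g, bbox(40, 30, 30, 20))
    expect_equal(sum(f2$binned), sum(f2$raw_profile), tolerance = 1e-9)
  }
})

test_that("a uniform frame gives an all-zero response", {
  g <- matrix(0.5, 100, 150)
  f <- arm_angle_feature(g, bbox(60, 40, 30, 20))
  expect_equal(max(abs(f$raw_profile)), 0)
  expect_equal(max(abs(f$binned)), 0)
})

test_that("response peaks at the arm direction on generated scenes", {
  for (s in 1:6) {
    sc <- generate_scene(scene_spec(
      n_frames = 1, height = 160, width = 284, seed = 400 + s,
      entry = c("bottom-left", "bottom-right", "top")[(s %% 3) + 1],
      coupling = "absent"))
    f <- arm_angle_feature(sc$video$frames[[1]], truth_box(sc, 1, "hand"))
    am <- which.max(f$raw_profile) - 1
    tr <- sc$truth$angle_deg[1]
    expect_lte(min(abs(am - tr), 360 - abs(am - tr)), 5)
  }
})

test_that("rotating the arm by a quadrant shifts the response peak with it", {
  # entry sides differ by construction; peak must follow the true angle, so
  # the angular distance between peaks matches the distance between truths
  sc_a <- generate_scene(scene_spec(n_frames = 1, height = 160, width = 284,
                                    entry = "bottom-left", seed = 77,
                                    coupling = "absent"))
  sc_b <- generate_scene(scene_spec(n_frames = 1, height = 160, width = 284,
                                    entry = "top", seed = 77,
                                    coupling = "absent"))
  pk <- function(sc) which.max(arm_angle_feature(
    sc$video$frames[[1]], truth_box(sc, 1, "hand"))$raw_profile) - 1
  d_true <- (sc_a$truth$angle_deg[1] - sc_b$truth$angle_deg[1]) %% 360
  d_peak <- (pk(sc_a) - pk(sc_b)) %% 360
  diff <- abs(d_peak - d_true)
  expect_lte(min(diff, 360 - diff), 10)
})

test_that("handedness follows the quadrant rule", {
  b <- numeric(72)
  b[55:72] <- 1  # 270-360 deg: bottom-left quadrant
  expect_equal(classify_handedness(b), "left")
  b <- numeric(72)
  b[37:54] <- 1  # 180-270 deg: bottom-right quadrant
  expect_equal(classify_handedness(b), "right")
  # equal binned values: the top half spans 36 bins vs 18 per bottom quadrant
  expect_equal(classify_handedness(rep(1, 72)), "other")
  # ties break right > left > other
  b <- numeric(72)
  b[37:72] <- 1  # III and IV tie
  expect_equal(classify_handedness(b), "right")
})

test_that("handedness is invariant to positive scaling", {
  set.seed(21)
  for (k in 1:20) {
    b <- rnorm(72)
    expect_equal(classify_handedness(b * runif(1, 0.01, 100)),
                 classify_handedness(b))
  }
})

test_that("the verifier separates arm-present from arm-absent boxes", {
  entries <- c("bottom-left", "bottom-right", "top")
  feats <- NULL; labs <- logical(0)
  for (s in 1:60) {
    sc <- generate_scene(scene_spec(n_frames = 1, height = 120, width = 214,
                                    entry = entries[(s %% 3) + 1],
                                    seed = 500 + s, coupling = "absent"))
    frame <- sc$video$frames[[1]]
    f_pos <- arm_angle_feature(frame, truth_box(sc, 1, "hand"))
    # arm-absent box: capped size, in the corner diagonally opposite the
    # arm's border anchor so it never brushes hand or arm
    r <- sc$truth[1, ]
    nw <- min(r$hand_box_w, 214 / 4); nh <- min(r$hand_box_h, 120 / 4)
    nx <- if (r$anchor_x > 214 / 2) 2 else 214 - nw - 2
    ny <- if (r$anchor_y > 120 / 2) 2 else 120 - nh - 2
    f_neg <- arm_angle_feature(frame, bbox(nx, ny, nw, nh))
    feats <- rbind(feats, f_pos$binned, f_neg$binned)
    labs <- c(labs, TRUE, FALSE)
  }
  train <- seq_len(nrow(feats)) <= 70
  model <- train_hand_verifier(feats[train, ], labs[train], seed = 9)
  pred <- vapply(which(!train), function(i) verify_box(feats[i, ], model),
                 logical(1))
  expect_gte(mean(pred == labs[!train]), 0.9)
  # memorized positive
  expect_true(verify_box(feats[which(labs)[1], ],
                         train_hand_verifier(feats, labs, seed = 9)))
  # the all-zero feature resembles the arm-absent class (flat response)
  centro_pos <- colMeans(feats[labs, ])
  centro_neg <- colMeans(feats[!labs, ])
  expect_lt(sum(centro_neg^2), sum(centro_pos^2))
  expect_false(verify_box(numeric(72), model))
})

test_that("untrained verifier input is rejected", {
  expect_error(verify_box(numeric(72), list()), "not a trained")
  expect_error(train_hand_verifier(matrix(rnorm(72 * 4), 4), rep(TRUE, 4)),
               "both classes")
})
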