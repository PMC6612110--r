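test_that("the skin histogram is a proper distribution", {
  sm <- fix_skin_model()
  expect_true(all(sm$hist >= 0))
  expect_equal(sum(sm$hist), 1, tolerance = 1e-12)
})

test_that("skin model round-trips through JSON", {
  sm <- fix_skin_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_skin_model(sm, path)
  back <- read_skin_model(path)
  expect_equal(back$hist, sm$hist, tolerance = 1e-12)
  expect_equal(back$edges, sm$edges, tolerance = 1e-12)
})

test_that("back-projection masks behave at the extremes", {
  sm <- fix_skin_model()
  # whole frame at the model mode: probability is maximal everywhere
  sp <- skin_probability(solid_frame(c(0.798, 0.589, 0.513)), sm)
  expect_true(all(sp$mask))
  # no support anywhere: empty mask
  sp0 <- skin_probability(solid_frame(c(0.05, 0.05, 0.9)), sm)
  expect_false(any(sp0$mask))
})

test_that("skin ellipse on green recovers with IoU >= 0.9", {
  ef <- ellipse_frame()
  sp <- skin_probability(ef$frame, fix_skin_model())
  expect_gte(mask_iou(sp$mask, ef$mask), 0.9)
})

test_that("edge maps: uniform empty, disc ring closed, gaps bridged", {
  expect_false(any(hand_edge_map(solid_frame(c(0.4, 0.4, 0.4)))))

  # white disc on black: after closing, the edge ring is a single component
  # enclosing a hole
  g <- matrix(0, 100, 100)
  g[egohanduse:::ellipse_mask(100, 100, 50, 50, 25, 25)] <- 1
  em <- hand_edge_map(g)
  expect_equal(egohanduse:::count_components8(em), 1)
  filled <- egohanduse:::fill_holes(em)
  expect_gt(sum(filled), sum(em))  # there was an interior hole

  # a ring with a one-pixel gap is reconnected by dilation + erosion
  ring <- egohanduse:::ellipse_mask(100, 100, 50, 50, 25, 25) &
    !egohanduse:::ellipse_mask(100, 100, 50, 50, 23, 23)
  ring_gap <- ring
  ring_gap[50, ] <- FALSE  # cut one row: two arcs
  expect_gt(egohanduse:::count_components8(ring_gap), 1)
  closed <- egohanduse:::erode_mat(egohanduse:::dilate_mat(ring_gap, 3), 3)
  expect_equal(egohanduse:::count_components8(closed), 1)
})

test_that("segment_hand recovers the hand and re-centres upward", {
  sc <- fix_scene_small()
  seg <- segment_hand(sc$video$frames[[1]], truth_box(sc, 1, "hand"),
                      fix_skin_model())
  expect_s3_class(seg, "hand_segment")
  tm <- truth_hand_mask(sc, 1)
  expect_gte(mask_iou(seg$mask, tm), 0.75)
  # new centre is the midpoint of the contour centroid and its top pixel
  expect_equal(seg$recentred_box$x + (seg$recentred_box$w - 1) / 2,
               (seg$centroid["x"] + seg$top["x"]) / 2,
               ignore_attr = TRUE, tolerance = 1e-9)
  # top pixel above centroid implies the box never moves down
  expect_lte(seg$top["y"], seg$centroid["y"])
  expect_lte(seg$recentred_box$y + (seg$recentred_box$h - 1) / 2,
             seg$centroid["y"])
  # mask pixels all inside the re-centred box
  outside <- seg$mask & !egohanduse:::bbox_mask(seg$recentred_box, 160, 284)
  expect_false(any(outside))
})

test_that("segment_hand is deterministic", {
  sc <- fix_scene_small()
  s1 <- segment_hand(sc$video$frames[[2]], truth_box(sc, 2, "hand"),
                     fix_skin_model())
  s2 <- segment_hand(sc$video$frames[[2]], truth_box(sc, 2, "hand"),
                     fix_skin_model())
  expect_identical(s1, s2)
})

test_that("area and perimeter filters eliminate distractors", {
  # frame: a box-hugging skin ring along the box border plus a small interior
  # blob; the ring is removed by the perimeter rule, the blob wins
  H <- 120; W <- 200
  f <- solid_frame(c(0.2, 0.6, 0.2), H, W)
  skin <- c(0.798, 0.589, 0.513)
  box <- bbox(50, 30, 80, 60)
  ring <- matrix(FALSE, H, W)
  ring[31:90, 51:130] <- TRUE
  ring[34:87, 54:127] <- FALSE  # 3-px thick frame hugging the box border
  blob <- egohanduse:::ellipse_mask(H, W, 90, 60, 14, 10)
  for (ch in 1:3) {
    plane <- f[, , ch]
    plane[ring | blob] <- skin[ch]
    f[, , ch] <- plane
  }
  seg <- segment_hand(f, box, fix_skin_model())
  expect_s3_class(seg, "hand_segment")
  # the winner is the interior blob, not the ring
  expect_lt(seg$area, 0.3 * box$w * box$h)
  expect_gte(mask_iou(seg$mask, blob), 0.6)

  # a speck below 2% of the box area yields no segmentation at all
  f2 <- solid_frame(c(0.2, 0.6, 0.2), H, W)
  speck <- egohanduse:::ellipse_mask(H, W, 90, 60, 3, 3)  # ~29 px < 2% of 4800
  for (ch in 1:3) {
    plane <- f2[, , ch]
    plane[speck] <- skin[ch]
    f2[, , ch] <- plane
  }
  expect_null(segment_hand(f2, box, fix_skin_model()))
})

test_that("mean segmentation IoU reaches 0.8 on synthetic scenes", {
  ious <- numeric(0)
  for (s in 1:10) {
    sc <- generate_scene(scene_spec(n_frames = 2, height = 160, width = 284,
                                    seed = 600 + s,
                                    entry = c("bottom-left", "bottom-right")[(s %% 2) + 1]))
    for (i in 1:2) {
      seg <- segment_hand(sc$video$frames[[i]], truth_box(sc, i, "hand"),
                          fix_skin_model())
      tm <- truth_hand_mask(sc, i)
      ious <- c(ious, if (is.null(seg)) 0 else mask_iou(seg$mask, tm))
    }
  }
  expect_gte(mean(ious), 0.8)
})
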