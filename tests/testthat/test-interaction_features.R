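test_that("dense flow recovers known translations", {
  # smooth random texture
  set.seed(31)
  tex <- matrix(runif(40 * 70), 40, 70)
  tex <- egohanduse:::resize_mat(tex, 160, 280)
  f1 <- array(rep(tex, 3), dim = c(160, 280, 3))
  shifted <- cbind(tex[, 1:3], tex[, 1:(280 - 3)])
  f2 <- array(rep(shifted, 3), dim = c(160, 280, 3))
  fl <- dense_flow(f1, f2)
  expect_gte(median(fl$dx), 2.5)
  expect_lte(median(fl$dx), 3.5)
  expect_lte(abs(median(fl$dy)), 0.5)

  # identical frames: essentially no motion
  fl0 <- dense_flow(f1, f1)
  expect_lt(median(sqrt(fl0$dx^2 + fl0$dy^2)), 0.1)

  # uncorrelated noise frames: finite output, no error
  set.seed(32)
  n1 <- array(runif(60 * 80 * 3), dim = c(60, 80, 3))
  n2 <- array(runif(60 * 80 * 3), dim = c(60, 80, 3))
  fln <- dense_flow(n1, n2)
  expect_true(all(is.finite(fln$dx)) && all(is.finite(fln$dy)))

  expect_error(dense_flow(n1, array(0, dim = c(30, 80, 3))), "mismatch")
})

test_that("region set partitions the frame with hand inside box", {
  sc <- fix_scene_small()
  box <- truth_box(sc, 2, "hand")
  rs <- region_set(truth_hand_mask(sc, 2), box, 160, 284)
  expect_false(any(rs$hand & !rs$box))
  expect_false(any(rs$box & rs$background))
  expect_true(all(rs$box | rs$background))
})

test_that("motion feature is 60 values of histogram differences", {
  flow <- structure(list(dx = matrix(2, 50, 60), dy = matrix(0, 50, 60)),
                    class = "flow_field")
  hand <- matrix(FALSE, 50, 60); hand[20:30, 20:30] <- TRUE
  rs <- region_set(hand, bbox(10, 10, 40, 30), 50, 60)
  mf <- motion_feature(flow, rs)
  expect_length(mf, 60)
  # identical uniform flow in hand and box: the first difference vector is 0
  expect_equal(max(abs(mf[1:30])), 0)

  # hand+box moving 5 px right, background static: background-minus-box has
  # positive mass at zero magnitude and negative mass in the 5-px bin
  dx <- matrix(0, 50, 60); dx[rs$box] <- 5
  flow2 <- structure(list(dx = dx, dy = matrix(0, 50, 60)),
                     class = "flow_field")
  mf2 <- motion_feature(flow2, rs)
  expect_equal(max(abs(mf2[1:30])), 0)        # hand matches box
  bg_minus_box_mag <- mf2[31:45]
  bin5 <- findInterval(5, seq(0, 20, length.out = 16), rightmost.closed = TRUE)
  expect_gt(bg_minus_box_mag[1], 0)           # zero-magnitude bin
  expect_lt(bg_minus_box_mag[bin5], 0)        # 5-px bin
})

test_that("region histograms normalize and difference vectors sum to zero", {
  sc <- fix_scene_small()
  fl <- dense_flow(sc$video$frames[[1]], sc$video$frames[[2]])
  box <- truth_box(sc, 2, "hand")
  rs <- region_set(truth_hand_mask(sc, 2), box, 160, 284)
  for (m in rs) {
    h <- egohanduse:::flow_region_hist(fl, m)
    expect_equal(sum(h[1:15]), 1, tolerance = 1e-9)
    expect_equal(sum(h[16:30]), 1, tolerance = 1e-9)
  }
  mf <- motion_feature(fl, rs)
  expect_equal(sum(mf[1:15]), 0, tolerance = 1e-9)
  expect_equal(sum(mf[16:30]), 0, tolerance = 1e-9)
  expect_equal(sum(mf[31:45]), 0, tolerance = 1e-9)
  expect_equal(sum(mf[46:60]), 0, tolerance = 1e-9)
  # an empty region yields all-zero histograms
  h0 <- egohanduse:::flow_region_hist(fl, matrix(FALSE, 160, 284))
  expect_equal(h0, numeric(30))
})

test_that("shape PCA honours its contract", {
  set.seed(41)
  X <- matrix(rnorm(200 * 144), 200, 144)
  pca <- fit_shape_pca(X, 60)
  expect_equal(ncol(shape_pca_transform(pca, X)), 60)
  # projecting the training mean gives the zero vector
  expect_equal(max(abs(shape_pca_transform(pca, pca$center))), 0,
               tolerance = 1e-9)
  # data of true rank 5: components beyond 5 carry ~no variance
  B <- matrix(rnorm(5 * 144), 5, 144)
  Xr <- matrix(rnorm(200 * 5), 200, 5) %*% B
  pr <- fit_shape_pca(Xr, 60)
  expect_lt(sum(pr$sdev[6:60]^2), 1e-16 * sum(pr$sdev^2))
  expect_error(fit_shape_pca(X[1:50, ], 60), "training vectors")
})

test_that("shape feature is a 60-value deterministic descriptor", {
  sc <- fix_scene_small()
  set.seed(42)
  hogs <- matrix(abs(rnorm(70 * length(egohanduse:::hog_descriptor(
    matrix(runif(16 * 43), 16, 43))))), nrow = 70)
  pca <- fit_shape_pca(hogs, 60)
  box <- truth_box(sc, 2, "hand")
  s1 <- shape_feature(sc$video$frames[[2]], box, pca)
  s2 <- shape_feature(sc$video$frames[[2]], box, pca)
  expect_length(s1, 60)
  expect_identical(s1, s2)
  # a uniform crop has an all-zero raw HOG, so the feature equals the
  # projection of the zero vector
  su <- shape_feature(solid_frame(c(0.5, 0.5, 0.5), 160, 284), box, pca)
  expect_equal(su, as.vector(shape_pca_transform(pca, numeric(pca$d))),
               tolerance = 1e-6)
  expect_error(shape_feature(sc$video$frames[[2]], box, list()), "not fitted")
})

test_that("Bhattacharyya distance matches closed forms", {
  p <- c(0.5, 0.5, 0, 0); q <- c(1, 0, 0, 0)
  expect_equal(bhattacharyya_distance(p, p), 0)
  expect_equal(bhattacharyya_distance(p, c(0, 0, 0.5, 0.5)), 1)
  expect_equal(bhattacharyya_distance(p, q), sqrt(1 - sqrt(0.5)),
               tolerance = 1e-12)
})

test_that("colour feature returns two distances in [0, 1]", {
  sc <- fix_scene_small()
  box <- truth_box(sc, 2, "hand")
  rs <- region_set(truth_hand_mask(sc, 2), box, 160, 284)
  cf <- colour_feature(sc$video$frames[[2]], rs)
  expect_length(cf, 2)
  expect_true(all(cf >= 0 & cf <= 1))
  # identical regions give distance zero
  rs_same <- list(hand = rs$box, box = rs$box, background = rs$box)
  cf0 <- colour_feature(sc$video$frames[[2]], rs_same)
  expect_equal(cf0[1], 0, tolerance = 1e-12)
})

test_that("assemble_feature enforces block sizes", {
  x <- assemble_feature(numeric(60), numeric(60), numeric(2))
  expect_length(x, 122)
  expect_error(assemble_feature(numeric(59), numeric(60), numeric(2)),
               "motion")
  expect_error(assemble_feature(numeric(60), numeric(60), numeric(3)),
               "colour")
})

test_that("motion features separate co-moving from independent objects", {
  norms <- list(pos = numeric(0), neg = numeric(0))
  for (s in 1:2) {
    for (coup in c("moves_with_hand", "independent")) {
      sc <- generate_scene(scene_spec(n_frames = 26, height = 160, width = 284,
                                      coupling = coup, seed = 700 + s))
      ft <- featurize_scene(sc)
      key <- if (coup == "moves_with_hand") "pos" else "neg"
      norms[[key]] <- c(norms[[key]], sqrt(rowSums(ft$motion^2)))
    }
  }
  expect_gte(length(norms$pos) + length(norms$neg), 100)
  expect_gt(mean(norms$pos), mean(norms$neg))
})
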