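pred_df <- function(frames, hand, state) {
  data.frame(frame = frames, hand = hand, state = state,
             stringsAsFactors = FALSE)
}

test_that("absence after an interaction bridges up to 90 frames, never more", {
  # interaction at frame 0, 60 absent frames, interaction at frame 61
  p <- pred_df(c(0, 61), "left", "interaction")
  tl <- build_timeline(p, 62, fps = 30)
  expect_true(all(tl$states$left == "interaction"))

  # exactly 90 absent frames bridge
  p <- pred_df(c(0, 91), "left", "interaction")
  tl <- build_timeline(p, 92, fps = 30)
  expect_true(all(tl$states$left == "interaction"))

  # 91 absent frames do not
  p <- pred_df(c(0, 92), "left", "interaction")
  tl <- build_timeline(p, 93, fps = 30)
  expect_equal(sum(tl$states$left == "interaction"), 2)
  expect_equal(sum(tl$states$left == "no_interaction"), 91)
})

test_that("absence is only bridged after interactions", {
  # absence after a no-interaction frame stays no_interaction
  p <- pred_df(c(0, 20), "right", c("no_interaction", "interaction"))
  tl <- build_timeline(p, 30, fps = 30)
  expect_equal(sum(tl$states$right == "interaction"), 10)
  # a video with no detections is all no_interaction
  tl0 <- build_timeline(pred_df(integer(), character(), character()), 50)
  expect_true(all(tl0$states$left == "no_interaction"))
  expect_true(all(tl0$states$right == "no_interaction"))
})

test_that("bridging never converts a classifier no_interaction", {
  set.seed(51)
  for (k in 1:10) {
    n <- 300
    frames <- sort(sample(0:(n - 1), 80))
    states <- sample(c("interaction", "no_interaction"), 80, replace = TRUE)
    p <- pred_df(frames, "left", states)
    tl <- build_timeline(p, n, fps = 30)
    keep <- states == "no_interaction"
    expect_true(all(tl$states$left[frames[keep] + 1] == "no_interaction"))
    expect_true(all(tl$states$left[frames[!keep] + 1] == "interaction"))
  }
})

test_that("smoothing handles constant and impulse inputs", {
  expect_true(all(smooth_threshold(rep(1, 500)) == 1))
  expect_true(all(smooth_threshold(rep(0, 500)) == 0))
  # a single 1 among 3000 zeros: after min-max normalization the plateau of
  # windows containing the impulse reaches 1 and is thresholded on
  x <- integer(3000); x[1500] <- 1L
  out <- smooth_threshold(x)
  expect_gte(sum(out), 1)
  expect_lte(sum(out), 120)
  expect_true(all(which(out == 1) >= 1500 - 120 & which(out == 1) <= 1500 + 120))
})

test_that("a square wave survives smoothing with bounded edge shifts", {
  x <- rep(rep(c(1L, 0L), each = 600), 3)
  out <- smooth_threshold(x)
  expect_lte(sum(out != x), 6 * 60)  # each of ~6 transitions shifts <= 60
  r <- rle(out)
  expect_equal(sum(r$values == 1), 3)  # still three interaction periods
})

test_that("re-smoothing its own output changes little (idempotence)", {
  x <- rep(rep(c(1L, 0L), each = 600), 2)
  once <- smooth_threshold(x)
  twice <- smooth_threshold(once)
  n_trans <- sum(diff(once) != 0) + 1
  expect_lte(sum(twice != once), n_trans * 120)
})

test_that("metrics match hand-computed values and the identity holds", {
  # 3600 frames at 30 fps with two 300-frame runs
  x <- integer(3600)
  x[101:400] <- 1L; x[2001:2300] <- 1L
  m <- extract_metrics(x, fps = 30)
  expect_equal(m$pct_interaction, 100 * 600 / 3600, tolerance = 1e-12)
  expect_equal(m$mean_duration_s, 10)
  expect_equal(m$interactions_per_hour, 60)
  # identity: pct == n * mean / total * 100, exactly
  expect_equal(m$pct_interaction,
               m$n_interactions * m$mean_duration_s / m$total_s * 100,
               tolerance = 1e-9)

  m0 <- extract_metrics(integer(100), fps = 30)
  expect_equal(m0$pct_interaction, 0)
  expect_true(is.na(m0$mean_duration_s))
  expect_true(is.na(m0$interactions_per_hour))

  m1 <- extract_metrics(rep(1L, 450), fps = 30)
  expect_equal(m1$pct_interaction, 100)
  expect_equal(m1$mean_duration_s, 15)
  expect_equal(m1$interactions_per_hour, 1 / (15 / 3600))
  expect_error(extract_metrics(integer(0)), "empty")
})

test_that("the metrics identity holds for random sequences", {
  set.seed(52)
  for (k in 1:50) {
    x <- as.integer(runif(500) < runif(1))
    m <- extract_metrics(x, fps = 30)
    if (m$n_interactions > 0) {
      expect_equal(m$pct_interaction,
                   m$n_interactions * m$mean_duration_s / m$total_s * 100,
                   tolerance = 1e-9)
    } else {
      expect_equal(m$pct_interaction, 0)
    }
  }
})

test_that("identical treatment of manual and predicted timelines", {
  set.seed(53)
  x <- as.integer(runif(2000) < 0.4)
  m_pred <- extract_metrics(smooth_threshold(x), fps = 30)
  m_manual <- extract_metrics(smooth_threshold(x), fps = 30)
  expect_identical(m_pred, m_manual)
})

test_that("correlation validation picks the test by normality", {
  set.seed(54)
  a <- rnorm(20); b <- a + rnorm(20, sd = 0.01)
  v <- validate_metrics(b, a)
  expect_equal(v$method, "pearson")
  expect_gt(v$rho, 0.99)
  expect_lt(v$p_value, 0.05)

  # grossly non-normal data (extreme outlier) routes to Spearman
  h <- c(rnorm(19), 100); h2 <- h + rnorm(20, sd = 0.01)
  v2 <- validate_metrics(h2, h)
  expect_equal(v2$method, "spearman")

  # perfect anti-monotone pair: rho -1, one-sided (right) p near 1
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  v3 <- validate_metrics(-x, x)
  expect_equal(v3$rho, -1, tolerance = 1e-9)
  expect_gt(v3$p_value, 0.95)

  expect_error(validate_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("timelines round-trip through CSV", {
  p <- pred_df(c(0, 5, 9), c("left", "right", "left"),
               c("interaction", "no_interaction", "interaction"))
  tl <- build_timeline(p, 12, fps = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeline(tl, path)
  back <- read_timeline(path, fps = 30)
  expect_equal(back$states$left, tl$states$left)
  expect_equal(back$states$right, tl$states$right)
  expect_equal(back$n_frames, 12)
})
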