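# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_skin_model <- function() fixture("skin_model", skin_model_default)

# a small coupled scene reused across feature tests
fix_scene_small <- function() fixture("scene_small", function() {
  generate_scene(scene_spec(n_frames = 6, height = 160, width = 284,
                            entry = "bottom-left",
                            coupling = "moves_with_hand", seed = 301))
})

# a plain frame: solid colour everywhere
solid_frame <- function(rgb, H = 60, W = 80) {
  f <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) f[, , ch] <- rgb[ch]
  f
}

# frame with a skin-coloured ellipse on a green background (no noise)
ellipse_frame <- function(H = 120, W = 200, cx = 100, cy = 60, ax = 30,
                          ay = 20, skin = c(0.798, 0.589, 0.513),
                          bg = c(0.2, 0.6, 0.2)) {
  f <- solid_frame(bg, H, W)
  m <- egohanduse:::ellipse_mask(H, W, cx, cy, ax, ay)
  for (ch in 1:3) {
    plane <- f[, , ch]
    plane[m] <- skin[ch]
    f[, , ch] <- plane
  }
  list(frame = f, mask = m)
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)
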