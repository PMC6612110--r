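# Per-hand binary interaction timelines and the three functional hand-use
# measures. Frames where the hand was lost (detection or segmentation
# failure) are bridged for up to 90 frames (3 s at 30 fps) when they
# immediately follow an interaction; a 120-frame (4 s) equally weighted
# moving average with min-max normalization and a 0.5 threshold then smooths
# short-term fluctuations before metric extraction.

.bridge_default <- 90L
.window_default <- 120L

#' Build per-hand timelines from frame decisions
#'
#' Frames with a verified detection of a hand carry the classifier's binary
#' decision for that hand; all other frames start as `hand_absent`. A run of
#' at most `bridge_frames` consecutive absent frames immediately following
#' an interaction frame is filled with `interaction` (a suddenly lost hand
#' is assumed to continue its interaction for up to 3 s); every other absent
#' frame becomes `no_interaction`. Absence after a `no_interaction` frame is
#' never bridged, so the rule can only prolong interactions.
#'
#' @param predictions `data.frame` with columns `frame` (0-based), `hand`
#'   (`left`/`right`/`other`) and `state` (`interaction`/`no_interaction`).
#' @param n_frames Total frame count of the video.
#' @param fps Frames per second (default 30).
#' @param bridge_frames Maximum bridged absence length (default 90).
#' @return A `hand_timeline`: list with `states` (named list of per-frame
#'   character vectors for left/right/other), `fps`, `n_frames`.
#' @export
build_timeline <- function(predictions, n_frames, fps = 30,
                           bridge_frames = .bridge_default) {
  stopifnot(n_frames >= 1)
  if (nrow(predictions) > 0 && any(predictions$frame >= n_frames)) {
    stop("prediction frame index beyond n_frames")
  }
  states <- lapply(c(left = "left", right = "right", other = "other"), function(h) {
    s <- rep("hand_absent", n_frames)
    sel <- predictions$hand == h
    s[predictions$frame[sel] + 1] <- predictions$state[sel]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (r$values[k] != "hand_absent") next
      prev_inter <- k > 1 && r$values[k - 1] == "interaction"
      r$values[k] <- if (prev_inter && r$lengths[k] <= bridge_frames)
        "interaction" else "no_interaction"
    }
    inverse.rle(r)
  })
  structure(list(states = states, fps = fps, n_frames = n_frames),
            class = "hand_timeline")
}

#' Moving-average smoothing and threshold
#'
#' Binarizes a timeline (`interaction` = 1), applies a centred equally
#' weighted moving average of `window` frames (edge windows shrink to the
#' available frames), min-max normalizes the result over the whole video and
#' thresholds at 0.5. A constant input bypasses normalization: all zeros
#' stay zeros, all ones stay ones.
#'
#' @param x Per-frame character states, logical, or 0/1 numeric vector for
#'   one hand.
#' @param window Moving-average length in frames (default 120, i.e. 4 s at
#'   30 fps).
#' @return Integer 0/1 vector of the same length.
#' @export
smooth_threshold <- function(x, window = .window_default) {
  if (is.character(x)) x <- as.numeric(x == "interaction")
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 1)
  before <- ceiling(window / 2) - 1
  after <- window - 1 - before
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1, i - before)
  hi <- pmin(n, i + after)
  avg <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  mn <- min(avg); mx <- max(avg)
  if (mx - mn < 1e-12) return(as.integer(avg >= 0.5))
  as.integer((avg - mn) / (mx - mn) >= 0.5)
}

#' Functional hand-use metrics from a binary sequence
#'
#' Maximal runs of 1 are individual interactions. The three measures are the
#' percentage of frames spent in interaction, the mean interaction duration
#' in seconds, and the number of interactions normalized to recording
#' duration (per hour). With at least one interaction the identity
#' `pct == n_interactions * mean_duration_s / total_s * 100` holds exactly;
#' with none, duration and rate are undefined (`NA`).
#'
#' @param binary Integer/logical 0-1 vector (non-empty).
#' @param fps Frames per second.
#' @return A `hand_use_metrics`: list with `pct_interaction`,
#'   `mean_duration_s`, `interactions_per_hour`, `n_interactions`,
#'   `total_s`.
#' @export
extract_metrics <- function(binary, fps = 30) {
  binary <- as.integer(as.numeric(binary) > 0.5)
  n <- length(binary)
  if (n == 0) stop("cannot extract metrics from an empty sequence")
  r <- rle(binary)
  runs <- r$lengths[r$values == 1]
  total_s <- n / fps
  if (length(runs) == 0) {
    m <- list(pct_interaction = 0, mean_duration_s = NA_real_,
              interactions_per_hour = NA_real_, n_interactions = 0L,
              total_s = total_s)
  } else {
    m <- list(pct_interaction = 100 * sum(runs) / n,
              mean_duration_s = mean(runs) / fps,
              interactions_per_hour = length(runs) / (total_s / 3600),
              n_interactions = length(runs), total_s = total_s)
  }
  structure(m, class = "hand_use_metrics")
}

#' @export
print.hand_use_metrics <- function(x, ...) {
  cat(sprintf("<hand_use_metrics %.2f%% interaction, mean %.2f s, %.1f/h (%d interactions over %.1f s)>\n",
              x$pct_interaction,
              if (is.na(x$mean_duration_s)) NA else x$mean_duration_s,
              if (is.na(x$interactions_per_hour)) NA else x$interactions_per_hour,
              x$n_interactions, x$total_s))
  invisible(x)
}

#' Correlate predicted and observed metrics across subjects
#'
#' Normality of each vector is assessed with a Shapiro-Wilk test at
#' alpha = 0.05; when both pass, a Pearson correlation is used, otherwise
#' Spearman. The correlation is tested one-tailed (right) against the null
#' of no correlation.
#'
#' @param predicted,actual Paired metric vectors across subjects (length
#'   >= 3, non-constant).
#' @param alpha Normality-test level (default 0.05).
#' @return A `metric_validation`: list with `rho`, `p_value`, `method`.
#' @export
validate_metrics <- function(predicted, actual, alpha = 0.05) {
  stopifnot(length(predicted) == length(actual), length(predicted) >= 3)
  if (sd(predicted) == 0 || sd(actual) == 0) {
    stop("correlation undefined for a constant metric vector")
  }
  normal <- shapiro.test(predicted)$p.value > alpha &&
    shapiro.test(actual)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(actual, predicted, method = method,
                                  alternative = "greater", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 method = method),
            class = "metric_validation")
}

#' Write / read a timeline as CSV
#'
#' Columns `frame,left_state,right_state,other_state`, frame indices
#' 0-based.
#'
#' @param timeline A `hand_timeline`.
#' @param path CSV path.
#' @param fps Frame rate to attach on read (default 30).
#' @return `path` (write) or a `hand_timeline` (read).
#' @export
write_timeline <- function(timeline, path) {
  df <- data.frame(frame = seq_len(timeline$n_frames) - 1,
                   left_state = timeline$states$left,
                   right_state = timeline$states$right,
                   other_state = timeline$states$other)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path, fps = 30) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(states = list(left = df$left_state, right = df$right_state,
                               other = df$other_state),
                 fps = fps, n_frames = nrow(df)),
            class = "hand_timeline")
}
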