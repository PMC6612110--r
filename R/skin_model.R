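# Skin-colour model: a 2-D histogram over normalized-rg chroma derived from a
# mixture-of-Gaussians skin model, used for back-projection. Chroma is
# r = R/(R+G+B), g = G/(R+G+B), which discounts illumination level; skin from
# different people forms a compact cluster in this plane.

#' Baseline skin-colour model
#'
#' Builds the back-projection histogram by evaluating a two-component
#' mixture of Gaussians over normalized-rg chroma on a regular grid. The
#' component means/SDs place the skin cluster at the canonical location
#' (r around 0.42, g around 0.31) with a secondary, slightly redder mode.
#'
#' @param nbins Bins per chroma axis (default 64).
#' @return A `skin_model`: list with `edges` (shared bin edges on \[0,1\])
#'   and `hist` (`nbins x nbins` matrix, non-negative, summing to 1).
#' @export
skin_model_default <- function(nbins = 64) {
  edges <- seq(0, 1, length.out = nbins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  comps <- list(
    list(w = 0.65, mr = 0.42, sr = 0.040, mg = 0.31, sg = 0.030),
    list(w = 0.35, mr = 0.46, sr = 0.050, mg = 0.30, sg = 0.035)
  )
  h <- matrix(0, nbins, nbins)
  for (cp in comps) {
    h <- h + cp$w * outer(stats::dnorm(mid, cp$mr, cp$sr),
                          stats::dnorm(mid, cp$mg, cp$sg))
  }
  h <- h / sum(h)
  structure(list(edges = edges, hist = h), class = "skin_model")
}

#' Save / load a skin model as JSON
#'
#' @param model A `skin_model`.
#' @param path JSON file path.
#' @return `path` (write) or a `skin_model` (read).
#' @export
write_skin_model <- function(model, path) {
  jsonlite::write_json(list(edges = model$edges, hist = as.vector(model$hist),
                            nbins = length(model$edges) - 1),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_skin_model
#' @export
read_skin_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(edges = raw$edges,
                 hist = matrix(raw$hist, raw$nbins, raw$nbins)),
            class = "skin_model")
}

# chroma coordinates of a frame; near-black pixels map to the achromatic point
frame_chroma <- function(frame) {
  s <- frame[, , 1] + frame[, , 2] + frame[, , 3]
  safe <- pmax(s, 1e-8)
  r <- frame[, , 1] / safe
  g <- frame[, , 2] / safe
  r[s < 1e-6] <- 1 / 3
  g[s < 1e-6] <- 1 / 3
  list(r = r, g = g)
}

#' Skin probability map by histogram back-projection
#'
#' Replaces every pixel with the histogram value of its chroma bin, then
#' thresholds at a fraction of the maximum over the frame to obtain a binary
#' skin mask. A frame with zero support everywhere yields an empty mask.
#'
#' @param frame `H x W x 3` array on \[0,1\].
#' @param model A `skin_model`.
#' @param threshold Mask threshold as a fraction of the map maximum
#'   (default 0.75).
#' @return List with `prob` (`H x W` matrix) and `mask` (logical `H x W`).
#' @export
skin_probability <- function(frame, model, threshold = 0.75) {
  stopifnot(inherits(model, "skin_model"))
  ch <- frame_chroma(frame)
  nb <- length(model$edges) - 1
  ri <- pmin(pmax(findInterval(as.vector(ch$r), model$edges,
                               rightmost.closed = TRUE), 1), nb)
  gi <- pmin(pmax(findInterval(as.vector(ch$g), model$edges,
                               rightmost.closed = TRUE), 1), nb)
  prob <- matrix(model$hist[cbind(ri, gi)], nrow(ch$r), ncol(ch$r))
  # chroma bins in the model's far tail carry no real support; zero them so
  # a skin-free frame yields an empty mask rather than a max-relative one
  prob[prob < 1e-6 * max(model$hist)] <- 0
  mx <- max(prob)
  mask <- if (mx > 0) prob >= threshold * mx else matrix(FALSE, nrow(prob), ncol(prob))
  list(prob = prob, mask = mask)
}
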