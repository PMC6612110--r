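# The hand-object interaction classifier: a 150-tree random forest over the
# 122-value combined feature, with leave-one-subject-out (LOSO) evaluation
# and single-family ablations. Features from left and right hands are pooled
# into one classifier; timelines are split by handedness downstream.

.family_cols <- function(family) {
  switch(family,
         all = 1:122, motion = 1:60, shape = 61:120, colour = 121:122,
         stop("unknown feature family: ", family))
}

#' Train the interaction forest
#'
#' @param features `n x d` feature matrix (122 columns for the combined
#'   feature; 60 or 2 for single-family ablations).
#' @param labels Logical vector, `TRUE` = interaction.
#' @param ntree Number of trees (default 150).
#' @param seed RNG seed (default 42); fixing it makes training
#'   deterministic.
#' @param family Feature family the matrix holds (`"all"`, `"motion"`,
#'   `"shape"`, `"colour"`), recorded for dimension checks.
#' @return An `interaction_model`.
#' @export
train_interaction_model <- function(features, labels, ntree = 150, seed = 42,
                                    family = "all") {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("training set must contain both interaction and no-interaction frames")
  }
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = features, y = factor(labels, levels = c(FALSE, TRUE)), ntree = ntree)
  structure(list(forest = forest, ntree = ntree, seed = seed,
                 family = family, d = ncol(features)),
            class = "interaction_model")
}

#' Per-frame interaction decisions
#'
#' Majority vote of the trees at the 0.5 vote threshold.
#'
#' @param model An `interaction_model`.
#' @param features Feature vector or `n x d` matrix matching the model's
#'   input dimension.
#' @return Logical vector, `TRUE` = interaction.
#' @export
predict_interaction <- function(model, features) {
  if (!inherits(model, "interaction_model")) stop("model is not trained")
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(x) != model$d) {
    stop("feature dimension ", ncol(x), " does not match model (", model$d, ")")
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  votes <- predict(model$forest, x, type = "prob")
  unname(votes[, "TRUE"] >= 0.5)
}

#' F1-score and accuracy of binary decisions
#'
#' F1 is the harmonic mean of precision and recall,
#' `2TP / (2TP + FP + FN)`; an all-negative truth/prediction pair yields
#' `NA` F1.
#'
#' @param truth,pred Logical vectors.
#' @return List with `f1`, `accuracy`, `tp`, `fp`, `fn`, `tn`.
#' @export
classification_scores <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, accuracy = (tp + tn) / length(truth),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

# assemble the design matrix for one family from a subject's raw blocks;
# shape features go through the fold's PCA
subject_design <- function(subj, family, pca) {
  blocks <- list()
  if (family %in% c("all", "motion")) blocks$motion <- subj$motion
  if (family %in% c("all", "shape")) {
    blocks$shape <- shape_pca_transform(pca, subj$hog)
  }
  if (family %in% c("all", "colour")) blocks$colour <- subj$colour
  do.call(cbind, blocks)
}

#' Leave-one-subject-out evaluation
#'
#' Each subject in turn is held out for testing while the remainder train
#' both the shape PCA and the forest, so no test-subject information leaks
#' into either fit. Scores are reported per subject and hand (F1 and
#' accuracy) with means and standard deviations across subjects; a held-out
#' subject with no frames of one hand skips that hand with a warning.
#'
#' @param subjects Named list; each element a list with matrices `motion`
#'   (`n x 60`), `hog` (`n x d` raw HOG), `colour` (`n x 2`), logical
#'   `labels` and character `hand` (`"left"`/`"right"`) of length `n`. See
#'   [generate_subjects] for a synthetic source.
#' @param family Feature family to use (default `"all"`); single families
#'   give the ablation protocol.
#' @param ntree,seed Forest settings (defaults 150 trees, seed 42).
#' @param n_components Shape-PCA components (default 60).
#' @return A `loso_result`: list with `per_subject` (data.frame subject,
#'   hand, f1, accuracy, n), `summary` (per hand mean/sd), `mean_f1`,
#'   `mean_accuracy`, and fold bookkeeping in `folds`.
#' @export
evaluate_loso <- function(subjects, family = "all", ntree = 150, seed = 42,
                          n_components = 60) {
  stopifnot(length(subjects) >= 2)
  if (is.null(names(subjects)) || any(names(subjects) == "")) {
    names(subjects) <- paste0("subject", seq_along(subjects))
  }
  rows <- list()
  folds <- list()
  for (s in names(subjects)) {
    train_ids <- setdiff(names(subjects), s)
    folds[[s]] <- train_ids
    pca <- NULL
    if (family %in% c("all", "shape")) {
      hog_train <- do.call(rbind, lapply(subjects[train_ids], `[[`, "hog"))
      pca <- fit_shape_pca(hog_train, n_components)
    }
    x_train <- do.call(rbind, lapply(subjects[train_ids], subject_design,
                                     family = family, pca = pca))
    y_train <- unlist(lapply(subjects[train_ids], `[[`, "labels"),
                      use.names = FALSE)
    model <- train_interaction_model(x_train, y_train, ntree = ntree,
                                     seed = seed, family = family)
    test <- subjects[[s]]
    x_test <- subject_design(test, family, pca)
    pred <- predict_interaction(model, x_test)
    for (h in c("left", "right")) {
      sel <- test$hand == h
      if (!any(sel)) {
        warning("subject ", s, " has no frames for hand '", h, "'; skipped")
        next
      }
      sc <- classification_scores(test$labels[sel], pred[sel])
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, hand = h, f1 = sc$f1, accuracy = sc$accuracy,
        n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_subject, per_subject$hand), function(d) {
    data.frame(hand = d$hand[1],
               mean_f1 = mean(d$f1, na.rm = TRUE),
               sd_f1 = sd(d$f1, na.rm = TRUE),
               mean_accuracy = mean(d$accuracy),
               sd_accuracy = sd(d$accuracy),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_subject = per_subject, summary = summ,
                 mean_f1 = mean(per_subject$f1, na.rm = TRUE),
                 mean_accuracy = mean(per_subject$accuracy),
                 family = family, folds = folds),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result family=%s subjects=%d mean F1=%.3f mean acc=%.3f>\n",
              x$family, length(x$folds), x$mean_f1, x$mean_accuracy))
  print(x$summary)
  invisible(x)
}

#' Single-family ablation
#'
#' Re-runs the leave-one-subject-out protocol restricted to one feature
#' family (optical-flow motion cues, HOG shape, or colour histogram scores).
#'
#' @param subjects As in [evaluate_loso].
#' @param family One of `"motion"`, `"shape"`, `"colour"`.
#' @param ... Passed to [evaluate_loso].
#' @return A `loso_result`.
#' @export
ablate_family <- function(subjects, family, ...) {
  stopifnot(family %in% c("motion", "shape", "colour"))
  evaluate_loso(subjects, family = family, ...)
}

#' Export a LOSO evaluation as CSV
#'
#' Writes one row per subject with per-hand F1 and accuracy columns
#' (`subject, f1_left, f1_right, acc_left, acc_right`).
#'
#' @param result A `loso_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  ps <- result$per_subject
  subjects <- unique(ps$subject)
  get <- function(s, h, col) {
    v <- ps[ps$subject == s & ps$hand == h, col]
    if (length(v) == 0) NA_real_ else v
  }
  df <- data.frame(
    subject = subjects,
    f1_left = vapply(subjects, get, numeric(1), h = "left", col = "f1"),
    f1_right = vapply(subjects, get, numeric(1), h = "right", col = "f1"),
    acc_left = vapply(subjects, get, numeric(1), h = "left", col = "accuracy"),
    acc_right = vapply(subjects, get, numeric(1), h = "right", col = "accuracy"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
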