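# Stage classification: CART (Gini) feature ranking, top-k subset selection,
# one-vs-rest RBF SVMs with Platt probability calibration, and
# subject-grouped cross-validation.

#' Rank features by decision-tree Gini importance
#'
#' Fits a CART classification tree (Gini impurity) to the labelled feature
#' matrix and ranks features by the total impurity decrease of the *primary*
#' splits they own (surrogate splits are not credited, so duplicated columns
#' share rather than double their importance). Features never chosen get
#' importance 0 and are ordered after all chosen ones.
#'
#' @param x Numeric feature matrix or data.frame (epochs x features).
#' @param labels Stage label per row (>= 2 distinct classes).
#' @param minsplit,cp `rpart` growth controls; the defaults (20, 0.001) grow
#'   a deep deterministic tree with no cross-validated pruning.
#' @return A data.frame `feature`, `importance`, sorted descending.
#' @export
rank_features_gini <- function(x, labels, minsplit = 20, cp = 0.001) {
  x <- as.data.frame(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("feature ranking needs at least 2 classes", call. = FALSE)
  dat <- cbind(x, .stage = factor(labels))
  fit <- rpart::rpart(.stage ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = minsplit, cp = cp, xval = 0,
                        maxsurrogate = 0))
  imp <- setNames(numeric(ncol(x)), colnames(x))
  frame <- fit$frame
  splits <- fit$splits
  if (!is.null(splits) && nrow(splits)) {
    i <- 1L
    for (node in seq_len(nrow(frame))) {
      if (frame$var[node] == "<leaf>") next
      v <- rownames(splits)[i]
      imp[v] <- imp[v] + splits[i, "improve"]
      i <- i + 1L + frame$ncompete[node] + frame$nsurrogate[node]
    }
  }
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out[order(-out$importance), ]
}

#' Select the top-k feature subset
#'
#' @param ranking Ranking data.frame from [rank_features_gini()].
#' @param k Subset size (default 8).
#' @return Character vector of the top-k feature names, in rank order.
#' @export
select_subset <- function(ranking, k = 8) {
  if (k < 1 || k > nrow(ranking))
    stop("`k` must be between 1 and the number of ranked features",
         call. = FALSE)
  as.character(ranking$feature[seq_len(k)])
}

#' Train the one-vs-rest SVM staging model
#'
#' Standardizes the selected features (z-score; parameters stored for reuse
#' at prediction) and trains one RBF-kernel binary SVM per stage
#' (stage-vs-rest) with Platt-calibrated probabilities and, by default,
#' inverse-frequency class weights to counter the dominance of N2. A stage
#' absent from the training labels gets a constant low-probability scorer
#' (with a warning).
#'
#' @param x Feature matrix or data.frame (epochs x features).
#' @param labels Stage label per row.
#' @param subset Feature names to use (default: all columns of `x`).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF width; default `1 / length(subset)` (features are
#'   standardized, so per-feature variance is 1).
#' @param class_weights Use inverse-frequency class weights (default TRUE).
#' @param seed Seed for the Platt calibration's internal cross-validation.
#' @return A `staging_model` list.
#' @export
train_ovr_svm <- function(x, labels, subset = NULL, cost = 1, gamma = NULL,
                          class_weights = TRUE, seed = 1) {
  x <- as.data.frame(x)
  labels <- as.character(labels)
  if (is.null(subset)) subset <- colnames(x)
  stopifnot(all(subset %in% colnames(x)))
  if (length(unique(labels)) < 2)
    stop("training needs at least 2 classes", call. = FALSE)
  xm <- as.matrix(x[, subset, drop = FALSE])
  if (!all(is.finite(xm))) stop("non-finite feature values", call. = FALSE)
  center <- colMeans(xm)
  scale_ <- apply(xm, 2, sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(xm, 2, center), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / length(subset)
  scorers <- setNames(vector("list", 5), STAGE_LEVELS)
  for (s in STAGE_LEVELS) {
    y <- factor(ifelse(labels == s, "pos", "rest"),
                levels = c("pos", "rest"))
    if (sum(y == "pos") < 2) {
      warning("stage ", s, " (near-)absent from training data; ",
              "constant low-probability scorer used")
      scorers[[s]] <- NULL
      next
    }
    cw <- if (class_weights)
      setNames(length(y) / (2 * table(y)[c("pos", "rest")]),
               c("pos", "rest"))
    else NULL
    set.seed(seed + match(s, STAGE_LEVELS))
    scorers[[s]] <- e1071::svm(x = z, y = y, kernel = "radial",
                               cost = cost, gamma = gamma,
                               probability = TRUE, class.weights = cw)
  }
  structure(list(subset = subset, center = center, scale = scale_,
                 scorers = scorers, stage_levels = STAGE_LEVELS,
                 cost = cost, gamma = gamma, seed = seed),
            class = "staging_model")
}

#' Predict sleep stages from feature vectors
#'
#' Scores each epoch with the five calibrated stage-vs-rest probabilities
#' and returns the argmax stage; exact ties break to the earlier stage in
#' the fixed `N0, N1, N2, N3, REM` order.
#'
#' @param model A `staging_model` from [train_ovr_svm()].
#' @param newdata Feature matrix/data.frame with the model's feature columns
#'   (one row per epoch), or a single named feature vector.
#' @return List with `stage` (character vector) and `prob` (epochs x 5
#'   matrix of per-stage probabilities).
#' @export
predict_stage <- function(model, newdata) {
  stopifnot(inherits(model, "staging_model"))
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  xm <- as.matrix(newdata[, model$subset, drop = FALSE])
  if (!all(is.finite(xm)))
    stop("non-finite feature values in prediction input", call. = FALSE)
  z <- sweep(sweep(xm, 2, model$center), 2, model$scale, "/")
  prob <- matrix(1e-6, nrow(z), 5,
                 dimnames = list(NULL, model$stage_levels))
  for (s in model$stage_levels) {
    sc <- model$scorers[[s]]
    if (is.null(sc)) next
    pr <- predict(sc, z, probability = TRUE)
    prob[, s] <- attr(pr, "probabilities")[, "pos"]
  }
  idx <- apply(prob, 1, which.max)     # ties -> earliest stage index
  list(stage = model$stage_levels[idx], prob = prob)
}

#' Subject-grouped cross-validation of the staging pipeline
#'
#' Splits *subjects* (never epochs) into `folds` groups; inside each
#' training fold the Gini ranking, the top-`k` subset and the
#' standardization are re-fit from scratch, so no information leaks from
#' the held-out subjects.
#'
#' @param features Feature data.frame with the 20 feature columns plus
#'   `stage` and `subject_id` (e.g. rows bound from [extract_features()]).
#' @param folds Number of folds (default 10; must not exceed the number of
#'   subjects).
#' @param k Feature-subset size (default 8).
#' @param seed Seed for the fold shuffle and SVM calibration.
#' @param feature_cols Feature columns (default [feature_names()]).
#' @param ... Passed to [train_ovr_svm()].
#' @return List with `fold_accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `recall` (per stage), `confusion` (truth x predicted), `predictions`
#'   (per-epoch held-out predictions with fold and subject), and
#'   `fold_subjects`.
#' @export
cross_validate <- function(features, folds = 10, k = 8, seed = 1,
                           feature_cols = feature_names(), ...) {
  stopifnot(all(c("stage", "subject_id") %in% names(features)))
  subjects <- unique(features$subject_id)
  if (folds > length(subjects))
    stop("more folds than subjects", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(subjects)
  fold_of <- setNames(rep(seq_len(folds), length.out = length(subjects)),
                      shuffled)
  conf <- matrix(0L, 5, 5, dimnames = list(truth = STAGE_LEVELS,
                                           predicted = STAGE_LEVELS))
  acc <- numeric(folds)
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_sub <- names(fold_of)[fold_of == f]
    is_test <- features$subject_id %in% test_sub
    tr <- features[!is_test, , drop = FALSE]
    te <- features[is_test, , drop = FALSE]
    ranking <- rank_features_gini(tr[, feature_cols], tr$stage)
    subset <- select_subset(ranking, k)
    model <- train_ovr_svm(tr[, feature_cols], tr$stage, subset = subset,
                           seed = seed + f, ...)
    pred <- predict_stage(model, te[, feature_cols])$stage
    acc[f] <- mean(pred == te$stage)
    preds[[f]] <- data.frame(fold = f, subject_id = te$subject_id,
                             truth = te$stage, predicted = pred)
    conf <- conf + table(factor(te$stage, STAGE_LEVELS),
                         factor(pred, STAGE_LEVELS))
  }
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       sd_accuracy = sd(acc), recall = recall, confusion = conf,
       predictions = do.call(rbind, preds),
       fold_subjects = split(names(fold_of), fold_of))
}

#' Stage a whole recording
#'
#' Extracts the 20-feature vector of every 30-s epoch of `channel` and
#' predicts its stage with a trained model.
#'
#' @param model A `staging_model`.
#' @param rec A preprocessed [eeg_recording()].
#' @param channel Channel label (e.g. `"Pz-Oz"`).
#' @param cfg A [feature_config()].
#' @return A [hypnogram()] with one label per epoch.
#' @export
stage_recording <- function(model, rec, channel, cfg = feature_config()) {
  fm <- extract_features(rec, channel, cfg)
  pred <- predict_stage(model, fm[, feature_names()])
  hypnogram(pred$stage)
}
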