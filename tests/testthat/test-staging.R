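# small synthetic feature matrices with known class structure
make_sep_features <- function(n_per_class = 40, n_noise = 19, seed = 1,
                              sd_signal = 0.01) {
  set.seed(seed)
  classes <- rep(stage_levels(), each = n_per_class)
  n <- length(classes)
  x <- as.data.frame(matrix(rnorm(n * n_noise), n))
  names(x) <- paste0("noise", seq_len(n_noise))
  x <- cbind(sig = as.numeric(factor(classes, stage_levels())) +
               rnorm(n, sd = sd_signal), x)
  list(x = x, labels = classes)
}

test_that("an injected separating feature ranks first", {
  d <- make_sep_features(seed = 61)
  rk <- rank_features_gini(d$x, d$labels)
  expect_equal(as.character(rk$feature[1]), "sig")
  expect_gt(rk$importance[1], max(rk$importance[-1]) * 5)
  expect_error(rank_features_gini(d$x, rep("N2", nrow(d$x))), "2 classes")
})

test_that("duplicated columns share importance instead of doubling it", {
  d <- make_sep_features(seed = 62, sd_signal = 0.3)
  rk1 <- rank_features_gini(d$x, d$labels)
  orig <- rk1$importance[rk1$feature == "sig"]
  x2 <- cbind(d$x, sig_dup = d$x$sig)
  rk2 <- rank_features_gini(x2, d$labels)
  combined <- sum(rk2$importance[rk2$feature %in% c("sig", "sig_dup")])
  expect_lt(abs(combined - orig) / orig, 0.2)
})

test_that("subset selection takes the top k in rank order", {
  d <- make_sep_features(seed = 63)
  rk <- rank_features_gini(d$x, d$labels)
  expect_equal(select_subset(rk, 20), as.character(rk$feature))
  expect_equal(select_subset(rk, 1), "sig")
  expect_length(select_subset(rk, 8), 8)
  expect_error(select_subset(rk, 0), "between")
})

test_that("the OvR SVM separates separable stages and is deterministic", {
  d <- make_sep_features(n_per_class = 30, n_noise = 2, seed = 64)
  # a hard margin (high C) recovers the separable structure exactly
  model <- train_ovr_svm(d$x, d$labels, cost = 10, seed = 3)
  pred <- predict_stage(model, d$x)
  expect_equal(mean(pred$stage == d$labels), 1)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  model2 <- train_ovr_svm(d$x, d$labels, cost = 10, seed = 3)
  expect_identical(predict_stage(model2, d$x)$stage, pred$stage)
})

test_that("duplicating every training epoch barely moves the decision rule", {
  set.seed(80)
  classes <- rep(stage_levels(), each = 30)
  n <- length(classes)
  x <- data.frame(f1 = as.numeric(factor(classes, stage_levels())) +
                    rnorm(n, sd = 0.3),
                  f2 = rnorm(n))
  m1 <- train_ovr_svm(x, classes, seed = 2)
  m2 <- train_ovr_svm(rbind(x, x), c(classes, classes), seed = 2)
  grid <- data.frame(f1 = seq(0.5, 5.5, by = 0.05), f2 = 0)
  expect_gte(mean(predict_stage(m1, grid)$stage ==
                    predict_stage(m2, grid)$stage), 0.95)
})

test_that("argmax prediction breaks exact ties toward the earlier stage", {
  d <- make_sep_features(n_per_class = 20, n_noise = 2, seed = 65)
  model <- train_ovr_svm(d$x, d$labels, seed = 1)
  # force a tie by zeroing all scorers: every stage at the 1e-6 floor
  model$scorers <- setNames(vector("list", 5), stage_levels())
  pred <- suppressWarnings(predict_stage(model, d$x[1:3, ]))
  expect_equal(pred$stage, rep("N0", 3))
})

test_that("a stage missing from training yields a constant low scorer", {
  d <- make_sep_features(n_per_class = 25, n_noise = 2, seed = 66)
  keep <- d$labels != "REM"
  expect_warning(
    model <- train_ovr_svm(d$x[keep, ], d$labels[keep], seed = 1),
    "REM")
  pred <- predict_stage(model, d$x)
  expect_true(all(pred$prob[, "REM"] == 1e-6))
  expect_false("REM" %in% pred$stage)
})

test_that("cross-validation partitions subjects exactly once", {
  d <- make_sep_features(n_per_class = 40, n_noise = 5, seed = 67)
  feats <- cbind(d$x, stage = d$labels,
                 subject_id = rep(sprintf("s%02d", 1:10), 20))
  cv <- cross_validate(feats, folds = 5, k = 3,
                       feature_cols = setdiff(names(d$x), NULL), seed = 2)
  all_subj <- sort(unname(unlist(cv$fold_subjects)))
  expect_equal(all_subj, sort(unique(feats$subject_id)))
  expect_length(cv$fold_accuracy, 5)
  expect_equal(sum(cv$confusion), nrow(feats))
  expect_equal(rowSums(cv$confusion),
               table(factor(feats$stage, stage_levels())),
               ignore_attr = TRUE)
  expect_error(cross_validate(feats, folds = 11), "folds")
})

test_that("held-out subjects cannot influence their fold's model", {
  d <- make_sep_features(n_per_class = 40, n_noise = 5, seed = 68,
                         sd_signal = 0.4)
  feats <- cbind(d$x, stage = d$labels,
                 subject_id = rep(sprintf("s%02d", 1:10), 20))
  cv_clean <- cross_validate(feats, folds = 5, k = 3, seed = 9,
                             feature_cols = names(d$x))
  # corrupt one held-out subject's features wildly; since its fold's
  # ranking, standardization and SVM are fit on the training subjects only,
  # predictions for the OTHER subjects in the same test fold must not move
  fold1 <- cv_clean$fold_subjects[[1]]
  expect_gte(length(fold1), 2)
  victim <- fold1[1]
  corrupted <- feats
  rows <- corrupted$subject_id == victim
  corrupted[rows, names(d$x)] <- corrupted[rows, names(d$x)] * 1000 + 500
  cv_corr <- cross_validate(corrupted, folds = 5, k = 3, seed = 9,
                            feature_cols = names(d$x))
  others <- setdiff(fold1, victim)
  pc <- cv_clean$predictions
  pd <- cv_corr$predictions
  expect_equal(pd$predicted[pd$subject_id %in% others],
               pc$predicted[pc$subject_id %in% others])
})

test_that("staging a synthetic night recovers its dominant stage", {
  # train on a tiny labelled synthetic cohort, stage an unseen all-N3 night
  set.seed(71)
  stages_tr <- rep(stage_levels(), times = 12)[sample(60)]
  h_tr <- hypnogram(stages_tr)
  rec_tr <- synthesize_eeg(h_tr, seed = 72)
  rec_tr <- preprocess_recording(rec_tr)
  fm <- extract_features(rec_tr, "Pz-Oz", stages = h_tr)
  ranking <- rank_features_gini(fm[, feature_names()], fm$stage)
  model <- train_ovr_svm(fm[, feature_names()], fm$stage,
                         subset = select_subset(ranking, 8), seed = 4)
  h_n3 <- hypnogram(rep("N3", 20))
  rec_n3 <- preprocess_recording(synthesize_eeg(h_n3, seed = 73))
  staged <- stage_recording(model, rec_n3, "Pz-Oz")
  expect_length(staged, 20)
  expect_gte(mean(unclass(staged) == "N3"), 0.9)
  staged2 <- stage_recording(model, rec_n3, "Pz-Oz")
  expect_identical(unclass(staged), unclass(staged2))
})
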