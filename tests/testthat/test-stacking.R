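test_that("binarize_labels maps the positive class to 1", {
  expect_equal(binarize_labels(c("normal", "tumor", "normal"), "normal"),
               c(1L, 0L, 1L))
  y <- rep("pos", 4)
  expect_equal(binarize_labels(y, "pos"), rep(1L, 4))
  # 1s and 0s partition the samples
  yy <- sample(c("a", "b", "c"), 30, replace = TRUE)
  b <- binarize_labels(yy, "b")
  expect_equal(sum(b == 1) + sum(b == 0), 30)
  expect_error(binarize_labels(yy, "zz"), "not among")
})

test_that("augment appends one integer-coded prediction column per base", {
  d <- perfect_feature_dataset(n_per_class = 5, n_noise = 4)
  specs <- list(classifier_spec(3, 1), classifier_spec(4), classifier_spec(3, 8))
  masks <- list(c(TRUE, rep(FALSE, 4)), rep(TRUE, 5),
                c(TRUE, TRUE, rep(FALSE, 3)))
  trained <- lapply(1:3, function(j) {
    list(model = fit_classifier(specs[[j]], d$X[, masks[[j]], drop = FALSE],
                                d$y, seed = j),
         mask = masks[[j]])
  })
  aug <- augment(d, trained)
  expect_equal(n_features(aug), 5 + 3)
  expect_identical(aug$feature_names[6:8], c("P_1", "P_2", "P_3"))
  # original columns unchanged
  expect_identical(aug$X[, 1:5], d$X)
  # appended column j equals an independently recomputed predict() of base j
  for (j in 1:3) {
    pj <- predict(trained[[j]]$model, d$X[, masks[[j]], drop = FALSE])
    expect_equal(unname(aug$X[, 5 + j]),
                 as.numeric(match(pj, d$class_names) - 1))
  }
  # memorizing bases on their training rows reproduce the label codes
  expect_equal(unname(aug$X[, 6]), as.numeric(d$y) - 1)

  # width mismatch is caught
  trained_bad <- list(list(model = trained[[1]]$model, mask = c(TRUE, FALSE)))
  expect_error(augment(d, trained_bad), "mask width")
})

test_that("a single perfect base yields stacked accuracy 1.0", {
  d <- perfect_feature_dataset(n_per_class = 10, n_noise = 4, seed = 3)
  sp <- stratified_split(d, 0.6, seed = 5)
  front <- make_front(list(front_member(classifier_spec(3, 1),
                                        c(TRUE, rep(FALSE, 4)), 1, 1)),
                      5, d$feature_names, d$class_names)
  fit <- fit_stack(front, sp, seed = 2)
  expect_equal(fit$test_accuracy, 1.0)
  expect_equal(fit$base_test_accuracies, 1.0)
  expect_length(fit$model$base_solutions, 1)
  expect_equal(fit$model$augmented_feature_names,
               c(d$feature_names, "P_1"))
})

test_that("meta-learner is the highest-F rank-1 solution and sees P columns", {
  d <- perfect_feature_dataset(n_per_class = 8, n_noise = 3, seed = 11)
  sp <- stratified_split(d, 0.6, seed = 7)
  # two bases: a weak LR on noise (low F) and a strong SVM on the signal
  weak <- front_member(classifier_spec(4), c(FALSE, TRUE, TRUE, FALSE),
                       0.55, 0.5)
  strong <- front_member(classifier_spec(3, 3), c(TRUE, FALSE, FALSE, FALSE),
                         1, 1)
  front <- make_front(list(weak, strong), 4, d$feature_names, d$class_names)
  fit <- fit_stack(front, sp, seed = 4)
  expect_equal(fit$model$meta_spec$code, 3)   # the strong solution leads
  expect_equal(length(fit$base_test_accuracies), 2)
  expect_equal(fit$test_accuracy, 1.0)

  # meta_features variants keep the prediction columns
  for (mf in c("mask+preds", "preds_only")) {
    f2 <- fit_stack(front, sp, seed = 4, meta_features = mf)
    expect_equal(f2$test_accuracy, 1.0)
  }
})

test_that("multiclass stacking builds one one-vs-rest meta-model per class", {
  d <- synth_dataset(n_per_class = 10, n_features = 6, n_informative = 2,
                     effect_size = 6, n_classes = 3, seed = 19)
  sp <- stratified_split(d, 0.6, seed = 3)
  front <- make_front(list(front_member(classifier_spec(1, c(10, 0)),
                                        c(TRUE, TRUE, rep(FALSE, 4)), 1, 1)),
                      6, d$feature_names, d$class_names)
  fit <- fit_stack(front, sp, seed = 6)
  expect_length(fit$model$meta_models, 3)
  expect_gte(fit$test_accuracy, 0.9)
  # predictions carry the full class set
  expect_identical(levels(fit$predictions), d$class_names)
})

test_that("one-vs-rest with 2 classes agrees with the single binary meta", {
  d <- synth_dataset(n_per_class = 12, n_features = 5, n_informative = 2,
                     effect_size = 6, seed = 23)
  sp <- stratified_split(d, 0.6, seed = 9)
  front <- make_front(list(front_member(classifier_spec(4),
                                        c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                        1, 1)),
                      5, d$feature_names, d$class_names)
  direct <- fit_stack(front, sp, seed = 12)
  ovr <- fit_stack(front, sp, seed = 12, force_ovr = TRUE)
  expect_identical(as.character(direct$predictions),
                   as.character(ovr$predictions))
})

test_that("stacked model predicts on fresh data through the same pipeline", {
  d <- perfect_feature_dataset(n_per_class = 10, n_noise = 3, seed = 31)
  sp <- stratified_split(d, 0.6, seed = 2)
  front <- make_front(list(front_member(classifier_spec(3, 1),
                                        c(TRUE, rep(FALSE, 3)), 1, 1)),
                      4, d$feature_names, d$class_names)
  fit <- fit_stack(front, sp, seed = 8)
  pred <- predict(fit$model, sp$test)
  expect_identical(as.character(pred), as.character(fit$predictions))
})
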