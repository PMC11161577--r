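test_that("motion keyframes match the hand-enumerated run-scan oracle", {
  bits <- c(0, 0, 1, 1, 1, 0, 0, 1, 1)
  kf <- suppressWarnings(motion_keyframes(bitpattern_clip(bits), n = 4))
  # 0-based run centers {0, 3, 5, 7} -> 1-based frame indices
  expect_equal(kf$indices, c(1, 4, 6, 8))
  expect_equal(kf$durations, c(3, 2, 2))

  alt <- rep(c(0, 1), 100)
  kf2 <- motion_keyframes(bitpattern_clip(alt), n = 96)
  expect_equal(kf2$indices, 1:96)              # every run has length 1
  expect_true(all(kf2$durations == 1))
  expect_true(all(diff(kf2$indices) >= 1))     # strictly increasing
})

test_that("keyframe selection is scale invariant and rejects constant video", {
  bits <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  clip <- bitpattern_clip(bits)
  clip2 <- video_clip(clip$frames * 0.37, clip$fps, clip$pixel_size)
  k1 <- suppressWarnings(motion_keyframes(clip, n = 6))
  k2 <- suppressWarnings(motion_keyframes(clip2, n = 6))
  expect_equal(k1$indices, k2$indices)

  const <- video_clip(array(0.5, c(2, 2, 10)), 50, 1)
  expect_error(motion_keyframes(const), "zero range|constant")
  expect_error(motion_keyframes(video_clip(array(0.5, c(2, 2, 1)), 50, 1)),
               "degenerate")
})

test_that("short videos repeat-pad to the requested count with a warning", {
  bits <- c(0, 0, 1, 1, 0, 0)
  expect_warning(kf <- motion_keyframes(bitpattern_clip(bits), n = 8),
                 "padding")
  expect_length(kf$indices, 8)
  expect_length(kf$durations, 7)
  expect_true(all(utils::tail(kf$durations, 5) == 0))
})

test_that("stratified CV partitions the data and is seeded", {
  toy <- toy_features(25)
  res <- fit_logistic_cv(toy$features, toy$labels, k = 5, seed = 3)
  fold <- res$cv$fold_assignment
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 50)
  expect_true(all(table(fold, toy$labels) == 5))     # stratified
  expect_equal(sum(res$cv$confusion), 50)            # every sample tested once
  res2 <- fit_logistic_cv(toy$features, toy$labels, k = 5, seed = 3)
  expect_identical(res$cv$fold_assignment, res2$cv$fold_assignment)
  expect_true(res$cv$mean_auroc >= 0 && res$cv$mean_auroc <= 1)
})

test_that("separable features classify well; permuted labels sit at chance", {
  toy <- toy_features(100)
  res <- fit_logistic_cv(toy$features, toy$labels, k = 5, seed = 1)
  expect_gte(res$cv$mean_accuracy, 0.9)
  perm <- withr::with_seed(8, sample(toy$labels))
  resp <- fit_logistic_cv(toy$features, perm, k = 5, seed = 1)
  expect_lt(abs(resp$cv$mean_accuracy - 0.5), 0.15)
})

test_that("degenerate label sets raise label errors", {
  toy <- toy_features(10)
  expect_error(fit_logistic_cv(toy$features, factor(rep("young", 20))),
               "label")
  expect_error(fit_logistic_cv(toy$features[, 1:5], toy$labels), "schema")
  expect_error(fit_logistic_cv(toy$features[1:6, ], toy$labels[c(1:3, 11:13)],
                               k = 5), "label")
})

test_that("linear SHAP matches exhaustive coalition enumeration", {
  toy <- toy_features(30)
  res <- fit_logistic_cv(toy$features, toy$labels, k = 5, seed = 2)
  for (i in c(1, 17, 42)) {
    ex <- explain_shap(res$model, toy$features, toy$features[i, ])
    oracle <- brute_force_shap(res$model, toy$features, toy$features[i, ])
    expect_lt(max(abs(ex$attributions - oracle)), 1e-9)
    # efficiency identity
    expect_equal(sum(ex$attributions) + ex$base_value, ex$link_output,
                 tolerance = 1e-12)
  }
  # explaining the background mean attributes nothing
  ex0 <- explain_shap(res$model, toy$features,
                      colMeans(toy$features))
  expect_lt(max(abs(ex0$attributions)), 1e-9)
  expect_error(explain_shap(res$model, toy$features, c(dd = 1)), "schema")
})

test_that("predict_age reports calibrated probability, label and log-likelihood", {
  toy <- toy_features(20)
  res <- fit_logistic_cv(toy$features, toy$labels, k = 5, seed = 4)
  pr <- predict_age(res$model, toy$features[1, ])       # a young heart
  expect_true(pr$probability >= 0 && pr$probability <= 1)
  expect_lte(pr$log_likelihood, 0)
  expect_equal(pr$label, "young")
  pr_old <- predict_age(res$model, toy$features[40, ])
  expect_equal(pr_old$label, "old")
  # tie at 0.5 breaks to the positive (old) class
  m <- res$model
  m$intercept <- 0; m$weights[] <- 0
  tie <- predict_age(m, toy$features[1, ])
  expect_equal(tie$probability, 0.5)
  expect_equal(tie$label, "old")
  expect_error(predict_age(list(), toy$features[1, ]), "state")
})

test_that("the keyframe CNN separates cohorts and respects its contracts", {
  # two tiny cohorts differing in heart rate and fractional shortening
  ys <- tiny_spec(dd = 36, sd = 20, hp_mean = 0.4, fps = 40, duration = 12,
                  width = 32, wall_thickness = 3)
  os <- tiny_spec(dd = 33, sd = 25, hp_mean = 0.7, hp_cv = 0.15, fps = 40,
                  duration = 12, width = 32, wall_thickness = 3, seed = 2L)
  coh <- make_cohort(ys, os, n_each = 8, seed = 19)
  kfs <- suppressWarnings(lapply(coh$hearts,
                                 function(h) motion_keyframes(h$clip)))
  cfg <- video_classifier_config(filters = c(2L, 3L, 4L), dense = c(8L, 4L),
                                 frame_size = c(16L, 16L), epochs = 4,
                                 seed = 6)
  res <- train_video_classifier(kfs, coh$labels, cfg, k = 4, seed = 9)
  expect_equal(sort(unique(res$cv$fold_assignment)), 1:4)
  expect_equal(sum(res$cv$confusion), 16)
  expect_true(all(res$cv$per_fold$accuracy >= 0 & res$cv$per_fold$accuracy <= 1))
  res2 <- train_video_classifier(kfs, coh$labels, cfg, k = 4, seed = 9)
  expect_identical(res$cv$fold_assignment, res2$cv$fold_assignment)

  pr <- predict_age(res$model, kfs[[1]])
  expect_true(pr$probability >= 0 && pr$probability <= 1)
  expect_lte(pr$log_likelihood, 0)

  bad <- kfs
  bad[[2]]$frames <- bad[[2]]$frames[1:10, , ]
  expect_error(train_video_classifier(bad, coh$labels, cfg, k = 4),
               "schema")
})
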