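test_that("temporal stacks clamp at the clip boundaries", {
  clip <- video_clip(array(runif(8 * 8 * 100), c(8, 8, 100)), fps = 100,
                     pixel_size = 1)
  st <- build_temporal_stack(clip, 10)
  expect_equal(attr(st, "channel_indices"), c(6, 10, 14))
  expect_equal(dim(st), c(8, 8, 3))
  expect_equal(attr(build_temporal_stack(clip, 1), "channel_indices"),
               c(1, 1, 5))
  expect_equal(attr(build_temporal_stack(clip, 100), "channel_indices"),
               c(96, 100, 100))
  expect_identical(st[, , 2], clip$frames[, , 10])
  expect_error(build_temporal_stack(clip, 0), "index")
  expect_error(build_temporal_stack(clip, 101), "index")
})

test_that("diameter-balanced sampling caps each bin without duplicates", {
  expect_length(sample_training_frames(rep(12, 200), per_bin = 75, seed = 1),
                75)
  expect_equal(sample_training_frames(rep(9, 40), per_bin = 75, seed = 1),
               1:40)
  d <- c(rep(10, 200), rep(15, 80), rep(20, 75))
  idx <- sample_training_frames(d, per_bin = 75, seed = 2)
  expect_length(idx, 225)
  expect_false(any(duplicated(idx)))
  per_bin_counts <- table(round(d[idx]))
  expect_true(all(per_bin_counts <= 75))
  expect_length(sample_training_frames(numeric(0)), 0)
  # seeded determinism
  expect_identical(sample_training_frames(d, seed = 9),
                   sample_training_frames(d, seed = 9))
})

test_that("Dice loss matches its closed form and is symmetric and bounded", {
  a <- matrix(c(1, 1, 0, 0), 2)
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(dice_loss(a, a), 0, tolerance = 1e-6)
  expect_equal(dice_loss(a, 1 - a), 1, tolerance = 1e-6)
  expect_equal(dice_loss(a, b), 0.5, tolerance = 1e-6)   # 1 - 2*1/(2+2)
  expect_error(dice_loss(a, matrix(0, 3, 3)), "dimension")

  set.seed(5)
  for (i in 1:20) {
    p <- matrix(runif(64), 8)
    t <- matrix(rbinom(64, 1, 0.4), 8)
    expect_gte(dice_loss(p, t), 0)
    expect_lte(dice_loss(p, t), 1)
    tb <- matrix(rbinom(64, 1, 0.4), 8)
    expect_equal(dice_loss(t, tb), dice_loss(tb, t), tolerance = 1e-9)
  }
})

test_that("conv/dense backward gradients agree with finite differences", {
  # spot-check of the hand-coded backprop on a tiny random problem
  set.seed(11)
  l <- flyheart:::nn_conv(2, 3, 3, 3)
  x <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  target <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  loss_of <- function(W) {
    l$W <- W
    f <- flyheart:::conv_fwd(l, x)
    sum((f$out - target)^2) / 2
  }
  f <- flyheart:::conv_fwd(l, x)
  flyheart:::conv_bwd(l, f$cache, f$out - target)
  eps <- 1e-6
  for (k in sample(length(l$W), 5)) {
    Wp <- l$W; Wp[k] <- Wp[k] + eps
    Wm <- l$W; Wm[k] <- Wm[k] - eps
    num <- (loss_of(Wp) - loss_of(Wm)) / (2 * eps)
    expect_equal(num, l$gW[k], tolerance = 1e-4)
  }
})

unet_fixture <- function(epochs = 2, seed = 5) {
  s <- tiny_spec(duration = 1.2, seed = 31)
  h <- simulate_heart(s)
  idx <- seq(1, n_frames(h$clip), by = 2)
  stacks <- lapply(idx, function(t) build_temporal_stack(h$clip, t))
  masks <- lapply(idx, function(t) h$masks[, , t])
  cfg <- unet_config(filters_per_level = c(2L, 4L), epochs = epochs,
                     seed = seed, batch_size = 16L)
  list(model = train_segmenter(stacks, masks, cfg), heart = h, spec = s)
}

test_that("training selects the best validation epoch deterministically", {
  fx1 <- unet_fixture()
  fx2 <- unet_fixture()
  expect_equal(nrow(fx1$model$history), 2)
  expect_identical(fx1$model$best_epoch, fx2$model$best_epoch)
  expect_identical(fx1$model$net$enc[[1]]$W, fx2$model$net$enc[[1]]$W)
  expect_equal(fx1$model$history$val_loss[fx1$model$best_epoch],
               min(fx1$model$history$val_loss))
})

test_that("probabilities are proper and thresholded masks nest monotonically", {
  fx <- unet_fixture()
  sub <- video_clip(fx$heart$clip$frames[, , 1:6], fps = fx$spec$fps,
                    pixel_size = fx$spec$pixel_size)
  p <- predict_probabilities(fx$model, sub)
  expect_true(all(p >= 0 & p <= 1))
  m_lo <- segment_frames(fx$model, sub, threshold = 0.3)
  m_hi <- segment_frames(fx$model, sub, threshold = 0.7)
  expect_true(all(m_lo[m_hi]))                 # mask(hi) subset of mask(lo)
  expect_true(all(segment_frames(fx$model, sub, threshold = 0)))
  expect_error(segment_frames(fx$model, sub, threshold = 1.5), "parameter")
})

test_that("checkpoints round-trip through disk", {
  fx <- unet_fixture()
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(fx$model, tmp)
  back <- load_segmenter(tmp)
  sub <- video_clip(fx$heart$clip$frames[, , 1:4], fps = fx$spec$fps,
                    pixel_size = fx$spec$pixel_size)
  expect_identical(predict_probabilities(back, sub),
                   predict_probabilities(fx$model, sub))
})

test_that("training rejects degenerate inputs", {
  s <- tiny_spec(duration = 0.3)
  h <- simulate_heart(s)
  st <- lapply(1:4, function(t) build_temporal_stack(h$clip, t))
  mk <- lapply(1:4, function(t) h$masks[, , t])
  expect_error(train_segmenter(st[1], mk[1], unet_config(c(2L, 4L))), "data")
  expect_error(train_segmenter(st, mk[1:3], unet_config(c(2L, 4L))), "data")
  expect_error(unet_config(filters_per_level = c(8, 8, 16)), "increasing")
})
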