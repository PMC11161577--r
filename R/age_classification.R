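CARDIAC_FEATURES <- c("dd", "sd", "fs", "di", "si", "hp", "ai")

#' Cardiac feature table from analyzed hearts
#'
#' Convenience helper: computes the seven classifier features (DD, SD, FS,
#' DI, SI, HP, AI) for each heart of a simulated cohort from its waveform
#' via beat detection.
#'
#' @param cohort result of [make_cohort()].
#' @return data.frame with columns `dd, sd, fs, di, si, hp, ai, label`.
#' @export
cohort_features <- function(cohort) {
  rows <- lapply(cohort$hearts, function(h) {
    trace <- diameter_trace(h$waveform, fps = h$spec$fps,
                            pixel_size = h$spec$pixel_size)
    bt <- detect_beats(trace)
    st <- aggregate_stats(bt, roi_length_um = h$spec$width * h$spec$pixel_size)
    data.frame(dd = st$dd, sd = st$sd, fs = st$fs, di = st$di, si = st$si,
               hp = st$hp, ai = st$ai, label = h$label)
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = levels(cohort$labels))
  out
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      ix <- sample(which(labels == cl))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, sc) {
  sweep(sweep(as.matrix(x), 2, sc$center), 2, sc$scale, "/")
}

safe_auc <- function(truth, prob, pos) {
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob,
    levels = setdiff(levels(truth), pos) |> c(pos),
    direction = "<", quiet = TRUE)))
}

cv_report <- function(per_fold, confusion, fold_assignment) {
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_auroc = mean(per_fold$auroc, na.rm = TRUE),
                 confusion = confusion,
                 fold_assignment = fold_assignment),
            class = "cv_report")
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds: mean accuracy %.3f, mean AUROC %.3f\n",
              nrow(x$per_fold), x$mean_accuracy, x$mean_auroc))
  print(x$confusion)
  invisible(x)
}

#' Logistic age classification with stratified k-fold cross-validation
#'
#' Ridge-penalized (unit-strength L2) logistic regression on the seven
#' cardiac statistics, standardized per training fold; per-fold accuracy,
#' AUROC and a pooled confusion matrix are reported, and a final model is
#' refit on the full data for downstream prediction and SHAP attribution.
#'
#' @param features data.frame with columns `dd, sd, fs, di, si, hp, ai`.
#' @param labels two-level factor; the last level is the positive ("old")
#'   class.
#' @param k number of stratified folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `model` (class `stats_classifier`: coefficients on the
#'   standardized scale, the scaler, feature names, positive class) and
#'   `cv` (a `cv_report`).
#' @export
fit_logistic_cv <- function(features, labels, k = 5L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("label error: need exactly 2 classes, got ", nlevels(labels),
         call. = FALSE)
  miss <- setdiff(CARDIAC_FEATURES, names(features))
  if (length(miss)) stop("schema error: missing features: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(features[, CARDIAC_FEATURES])
  if (any(!is.finite(x))) stop("schema error: non-finite feature values",
                               call. = FALSE)
  if (min(table(labels)) < k)
    stop("label error: need at least k = ", k, " samples per class",
         call. = FALSE)
  pos <- levels(labels)[2]
  fold <- stratified_folds(labels, k, seed)
  y <- as.integer(labels == pos)

  per_fold <- data.frame(fold = integer(0), accuracy = numeric(0),
                         auroc = numeric(0))
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(predicted = levels(labels),
                                      truth = levels(labels)))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    sc <- standardizer(x[tr, , drop = FALSE])
    fit <- ridge_logistic(apply_standardizer(x[tr, , drop = FALSE], sc), y[tr])
    prob <- logistic_prob(fit, apply_standardizer(x[te, , drop = FALSE], sc))
    pred <- factor(ifelse(prob >= 0.5, pos, levels(labels)[1]),
                   levels = levels(labels))
    per_fold <- rbind(per_fold, data.frame(
      fold = f,
      accuracy = mean(pred == labels[te]),
      auroc = safe_auc(labels[te], prob, pos)))
    confusion <- confusion + table(predicted = pred, truth = labels[te])
  }

  sc <- standardizer(x)
  fit <- ridge_logistic(apply_standardizer(x, sc), y)
  model <- structure(list(intercept = fit$intercept, weights = fit$weights,
                          scaler = sc, features = CARDIAC_FEATURES,
                          classes = levels(labels), positive = pos),
                     class = "stats_classifier")
  list(model = model, cv = cv_report(per_fold, confusion, fold))
}

# unit-strength L2 logistic fit on (already standardized) features:
# glmnet ridge with lambda = 1/n gives total penalty ||w||^2 / 2
ridge_logistic <- function(z, y) {
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(z), standardize = FALSE,
                        thresh = 1e-12)
  list(intercept = as.numeric(fit$a0),
       weights = stats::setNames(as.numeric(fit$beta), colnames(z)))
}

logistic_prob <- function(fit, z) {
  as.numeric(1 / (1 + exp(-(fit$intercept + z %*% fit$weights))))
}

#' Exact Shapley attributions for the linear age model
#'
#' For a model linear on standardized features, the Shapley value of
#' feature j with a mean-imputation value function is exactly
#' `w_j * (z_j - mean(z_background_j))` on the link (log-odds) scale, and
#' the attributions plus the base value reproduce the model output exactly
#' (efficiency).
#'
#' @param model a `stats_classifier` from [fit_logistic_cv()].
#' @param background_features data.frame of background samples (the
#'   expectation reference).
#' @param x one sample to explain: named numeric vector or 1-row data.frame
#'   carrying the model's features.
#' @return object of class `shap_explanation`: `attributions` (named, link
#'   scale), `base_value`, and `link_output` for `x`.
#' @export
explain_shap <- function(model, background_features, x) {
  stopifnot(inherits(model, "stats_classifier"))
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  if (!all(model$features %in% names(x)))
    stop("schema error: x lacks features: ",
         paste(setdiff(model$features, names(x)), collapse = ", "),
         call. = FALSE)
  miss <- setdiff(model$features, names(background_features))
  if (length(miss)) stop("schema error: background lacks features: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  zb <- apply_standardizer(background_features[, model$features], model$scaler)
  zx <- apply_standardizer(rbind(x[model$features]), model$scaler)[1, ]
  mu <- colMeans(zb)
  attributions <- model$weights * (zx - mu)
  base <- model$intercept + sum(model$weights * mu)
  structure(list(attributions = attributions, base_value = base,
                 link_output = model$intercept + sum(model$weights * zx)),
            class = "shap_explanation")
}

#' Motion keyframe selection by frame differencing
#'
#' The per-frame sum of squared pixel differences against a reference frame
#' `t0` is min-max normalized to \[0, 1\] and binarized at
#' `binarize_threshold`; the resulting series decomposes into maximal runs
#' of equal value, and the center frame of each run (in temporal order) is
#' collected until `n` keyframes are gathered. The inter-keyframe durations
#' (frames) accompany the frames as classifier input. Runs short of `n`
#' repeat-pad the last keyframe with duration 0 (with a warning).
#'
#' @param clip a [video_clip()] with T >= 2 frames.
#' @param n number of keyframes (default 96).
#' @param binarize_threshold threshold on the normalized SSD series.
#' @param t0 reference frame index (default 1, the first frame).
#' @return object of class `keyframe_set`: `indices` (1-based, strictly
#'   increasing before padding), `durations` (n - 1 inter-keyframe
#'   intervals, frames), `frames` (H x W x n array), `fps`.
#' @export
motion_keyframes <- function(clip, n = 96L, binarize_threshold = 0.5,
                             t0 = 1L) {
  Tn <- n_frames(clip)
  if (Tn < 2) stop("degenerate input: need at least 2 frames", call. = FALSE)
  ref <- clip$frames[, , t0]
  ssd <- vapply(seq_len(Tn), function(t)
    sum((clip$frames[, , t] - ref)^2), numeric(1))
  rng <- max(ssd) - min(ssd)
  if (rng == 0)
    stop("degenerate input: constant video, SSD motion series has zero range",
         call. = FALSE)
  s <- (ssd - min(ssd)) / rng
  centers <- run_centers(as.integer(s >= binarize_threshold))
  idx <- centers[seq_len(min(n, length(centers)))]
  if (length(idx) < n) {
    warning("only ", length(idx), " motion runs found; repeat-padding the ",
            "last keyframe to ", n)
    idx <- c(idx, rep(idx[length(idx)], n - length(idx)))
  }
  structure(list(indices = idx,
                 durations = diff(idx),
                 frames = clip$frames[, , idx, drop = FALSE],
                 fps = clip$fps),
            class = "keyframe_set")
}

# centers of maximal runs of equal value; center = floor((start + end) / 2)
# in 0-based frame arithmetic, returned 1-based
run_centers <- function(b) {
  r <- rle(b)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  ((start - 1L) + (end - 1L)) %/% 2L + 1L
}

#' Configuration of the keyframe video classifier
#'
#' Three convolution blocks (two 3x3 conv + relu each, then 2x2 max pool),
#' flatten, concatenation of the 95 inter-keyframe durations, three dense
#' layers, sigmoid output. Keyframes are downsampled to `frame_size` before
#' entering the network.
#'
#' @param filters per-block filter counts (3 blocks).
#' @param dense widths of the two hidden dense layers (the third dense
#'   layer is the single output unit).
#' @param frame_size `c(rows, cols)` after downsampling; divisible by 8.
#' @param epochs,batch_size,lr training parameters.
#' @param seed seed for init, shuffling and fold assignment.
#' @return object of class `vc_config`.
#' @export
video_classifier_config <- function(filters = c(8L, 16L, 32L),
                                    dense = c(32L, 16L),
                                    frame_size = c(96L, 128L),
                                    epochs = 12L, batch_size = 16L,
                                    lr = 1e-3, seed = 1L) {
  stopifnot(length(filters) == 3, length(dense) == 2,
            all(frame_size %% 8 == 0))
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 frame_size = as.integer(frame_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "vc_config")
}

# nearest-neighbour resize of an H x W x K array to rows x cols
resize_frames <- function(frames, rows, cols) {
  d <- dim(frames)
  ri <- pmax(1L, round(seq(1, d[1], length.out = rows)))
  ci <- pmax(1L, round(seq(1, d[2], length.out = cols)))
  frames[ri, ci, , drop = FALSE]
}

build_vc_net <- function(n_keyframes, n_durations, config) {
  f <- config$filters
  h <- config$frame_size[1]; w <- config$frame_size[2]
  net <- list(f = f)
  net$conv <- list(
    nn_conv(n_keyframes, f[1], 3L, 3L), nn_conv(f[1], f[1], 3L, 3L),
    nn_conv(f[1], f[2], 3L, 3L), nn_conv(f[2], f[2], 3L, 3L),
    nn_conv(f[2], f[3], 3L, 3L), nn_conv(f[3], f[3], 3L, 3L))
  flat <- f[3] * (h %/% 8L) * (w %/% 8L)
  net$dense <- list(nn_dense(flat + n_durations, config$dense[1]),
                    nn_dense(config$dense[1], config$dense[2]),
                    nn_dense(config$dense[2], 1L))
  net$flat <- flat
  net$layers <- c(net$conv, net$dense)
  net
}

vc_fwd <- function(net, x, dur) {        # x: (K,h,w,N); dur: (n_dur, N)
  cc <- list(); h <- x
  for (b in 1:3) {
    c1 <- conv_fwd(net$conv[[2 * b - 1]], h); r1 <- relu_fwd(c1$out)
    c2 <- conv_fwd(net$conv[[2 * b]], r1$out); r2 <- relu_fwd(c2$out)
    pl <- maxpool2_fwd(r2$out)
    cc[[b]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    r2 = r2$cache, pool = pl$cache)
    h <- pl$out
  }
  N <- dim(h)[4]
  flat <- matrix(h, nrow = net$flat, ncol = N)
  z <- rbind(flat, dur)
  d1 <- dense_fwd(net$dense[[1]], z); a1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(net$dense[[2]], a1$out); a2 <- relu_fwd(d2$out)
  d3 <- dense_fwd(net$dense[[3]], a2$out)
  p <- sigmoid(d3$out)
  list(p = as.numeric(p),
       cache = list(blocks = cc, shape = dim(h), d1 = d1$cache, a1 = a1$cache,
                    d2 = d2$cache, a2 = a2$cache, d3 = d3$cache))
}

vc_bwd <- function(net, cache, dz) {     # dz: 1 x N grad wrt logit
  da2 <- dense_bwd(net$dense[[3]], cache$d3, dz)
  dd2 <- relu_bwd(cache$a2, da2)
  da1 <- dense_bwd(net$dense[[2]], cache$d2, dd2)
  dd1 <- relu_bwd(cache$a1, da1)
  dzin <- dense_bwd(net$dense[[1]], cache$d1, dd1)
  dflat <- dzin[seq_len(net$flat), , drop = FALSE]   # duration grads unused
  dh <- array(dflat, dim = cache$shape)
  for (b in 3:1) {
    cb <- cache$blocks[[b]]
    dr2 <- maxpool2_bwd(cb$pool, dh)
    dc2 <- relu_bwd(cb$r2, dr2)
    dr1 <- conv_bwd(net$conv[[2 * b]], cb$c2, dc2)
    dc1 <- relu_bwd(cb$r1, dr1)
    dh <- conv_bwd(net$conv[[2 * b - 1]], cb$c1, dc1)
  }
  invisible(NULL)
}

keyframes_to_tensors <- function(keyframe_sets, config) {
  geom <- vapply(keyframe_sets, function(ks) dim(ks$frames), numeric(3))
  if (any(geom[1, ] != geom[1, 1]) || any(geom[2, ] != geom[2, 1]) ||
      any(geom[3, ] != geom[3, 1]))
    stop("schema error: keyframe sets have mismatched geometry",
         call. = FALSE)
  rows <- config$frame_size[1]; cols <- config$frame_size[2]
  K <- geom[3, 1]
  n <- length(keyframe_sets)
  x <- array(0, c(K, rows, cols, n))
  for (i in seq_len(n)) {
    fr <- resize_frames(keyframe_sets[[i]]$frames, rows, cols)
    x[, , , i] <- aperm(fr, c(3, 1, 2))
  }
  dur <- vapply(keyframe_sets, function(ks) as.numeric(ks$durations),
                numeric(length(keyframe_sets[[1]]$durations)))
  list(x = x, dur = matrix(dur, ncol = n))
}

train_vc_once <- function(x, dur, y, config) {
  net <- build_vc_net(dim(x)[1], nrow(dur), config)
  n <- dim(x)[4]
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    for (b0 in seq(1, n, by = config$batch_size)) {
      ix <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      fw <- vc_fwd(net, x[, , , ix, drop = FALSE], dur[, ix, drop = FALSE])
      dz <- matrix((fw$p - y[ix]) / length(ix), nrow = 1)  # BCE grad
      vc_bwd(net, fw$cache, dz)
      adam_step(net$layers, lr = config$lr)
    }
  }
  net
}

vc_predict <- function(net, x, dur, chunk = 16L) {
  n <- dim(x)[4]
  p <- numeric(n)
  for (b0 in seq(1, n, by = chunk)) {
    ix <- b0:min(b0 + chunk - 1L, n)
    p[ix] <- vc_fwd(net, x[, , , ix, drop = FALSE],
                    dur[, ix, drop = FALSE])$p
  }
  p
}

#' Train the keyframe video age classifier with k-fold cross-validation
#'
#' Keyframe clips pass through three convolution blocks (two 2-D conv
#' layers + max pooling each); the flattened features are concatenated with
#' the inter-keyframe durations and passed through three dense layers to a
#' sigmoid output. Binary cross-entropy, Adam, stratified folds; a final
#' model is refit on all data.
#'
#' @param keyframe_sets list of [motion_keyframes()] results, identical
#'   geometry.
#' @param labels two-level factor (last level = positive class).
#' @param config a [video_classifier_config()].
#' @param k folds (default 5).
#' @param seed fold/init seed.
#' @return list with `model` (class `video_classifier`) and `cv`
#'   (a `cv_report`).
#' @export
train_video_classifier <- function(keyframe_sets, labels,
                                   config = video_classifier_config(),
                                   k = 5L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("label error: need exactly 2 classes", call. = FALSE)
  if (min(table(labels)) < k)
    stop("label error: need at least k = ", k, " samples per class",
         call. = FALSE)
  tens <- keyframes_to_tensors(keyframe_sets, config)
  pos <- levels(labels)[2]
  y <- as.integer(labels == pos)
  fold <- stratified_folds(labels, k, seed)

  per_fold <- data.frame(fold = integer(0), accuracy = numeric(0),
                         auroc = numeric(0))
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(predicted = levels(labels),
                                      truth = levels(labels)))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    dsc <- standardizer(t(tens$dur[, tr, drop = FALSE]))
    dur_tr <- t(apply_standardizer(t(tens$dur[, tr, drop = FALSE]), dsc))
    dur_te <- t(apply_standardizer(t(tens$dur[, te, drop = FALSE]), dsc))
    net <- withr::with_seed(
      derive_seed(seed, paste0("vcfold", f)),
      train_vc_once(tens$x[, , , tr, drop = FALSE], dur_tr, y[tr], config))
    prob <- vc_predict(net, tens$x[, , , te, drop = FALSE], dur_te)
    pred <- factor(ifelse(prob >= 0.5, pos, levels(labels)[1]),
                   levels = levels(labels))
    per_fold <- rbind(per_fold, data.frame(
      fold = f, accuracy = mean(pred == labels[te]),
      auroc = safe_auc(labels[te], prob, pos)))
    confusion <- confusion + table(predicted = pred, truth = labels[te])
  }

  dsc <- standardizer(t(tens$dur))
  dur_all <- t(apply_standardizer(t(tens$dur), dsc))
  net <- withr::with_seed(derive_seed(seed, "vcfinal"),
                          train_vc_once(tens$x, dur_all, y, config))
  model <- structure(list(net = net, config = config, dur_scaler = dsc,
                          classes = levels(labels), positive = pos),
                     class = "video_classifier")
  list(model = model, cv = cv_report(per_fold, confusion, fold))
}

#' Predict age class from a trained classifier
#'
#' Works for both pipelines: a `stats_classifier` with a cardiac feature
#' vector, or a `video_classifier` with a `keyframe_set`. Probability 0.5
#' ties break to the positive ("old") class.
#'
#' @param model a `stats_classifier` or `video_classifier`.
#' @param input named feature vector / 1-row data.frame, or a
#'   [motion_keyframes()] result matching the trained geometry.
#' @return list with `probability` (of the positive class), `label`, and
#'   `log_likelihood` (log probability of the predicted class, always
#'   <= 0).
#' @export
predict_age <- function(model, input) {
  if (inherits(model, "stats_classifier")) {
    if (is.data.frame(input)) input <- unlist(input[1, , drop = TRUE])
    if (!all(model$features %in% names(input)))
      stop("schema error: input lacks model features", call. = FALSE)
    z <- apply_standardizer(rbind(input[model$features]), model$scaler)
    prob <- as.numeric(1 / (1 + exp(-(model$intercept + z %*% model$weights))))
  } else if (inherits(model, "video_classifier")) {
    tens <- keyframes_to_tensors(list(input), model$config)
    dur <- t(apply_standardizer(t(tens$dur), model$dur_scaler))
    prob <- vc_predict(model$net, tens$x, dur)
  } else {
    stop("state error: not a trained classifier", call. = FALSE)
  }
  label <- if (prob >= 0.5) model$positive else
    setdiff(model$classes, model$positive)
  list(probability = prob, label = label,
       log_likelihood = log(if (prob >= 0.5) prob else 1 - prob))
}
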