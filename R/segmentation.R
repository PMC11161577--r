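#' Configuration of the attention U-Net segmenter
#'
#' Symmetric encoder/decoder with one 2-D convolution per resolution level
#' (filter counts strictly increasing down the encoder), rectangular
#' convolution kernels, additive attention gates on the skip connections,
#' a single-channel sigmoid head, Dice loss, and Adam. The default filter
#' ladder is 8, 16, 32, 64, 128; the default kernel is 3 x 7 — wider along
#' the horizontal heart-tube axis.
#'
#' @param filters_per_level integer vector, strictly increasing.
#' @param kernel_shape `c(rows, cols)`, odd entries; rectangular allowed.
#' @param attention_gates gate the skip connections (default `TRUE`).
#' @param batch_size images per optimizer step.
#' @param epochs training epochs.
#' @param lr Adam step size.
#' @param augment random horizontal flips + small intensity jitter.
#' @param val_frac held-out validation fraction (default 0.15, i.e. an
#'   85/15 train/validation split).
#' @param seed integer seed covering init, shuffling and augmentation.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(filters_per_level = c(8L, 16L, 32L, 64L, 128L),
                        kernel_shape = c(3L, 7L), attention_gates = TRUE,
                        batch_size = 16L, epochs = 30L, lr = 1e-3,
                        augment = TRUE, val_frac = 0.15, seed = 1L) {
  if (any(diff(filters_per_level) <= 0))
    stop("unet_config: filters_per_level must be strictly increasing",
         call. = FALSE)
  stopifnot(length(kernel_shape) == 2, all(kernel_shape %% 2 == 1),
            batch_size >= 1, epochs >= 1, val_frac > 0, val_frac < 1)
  structure(list(filters_per_level = as.integer(filters_per_level),
                 kernel_shape = as.integer(kernel_shape),
                 attention_gates = isTRUE(attention_gates),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 augment = isTRUE(augment), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Temporal three-frame stack for one frame
#'
#' The network input for frame `t` appends the frames at `t - offset` and
#' `t + offset` (clamped to the clip bounds) as extra channels, encoding
#' local wall motion.
#'
#' @param clip a [video_clip()].
#' @param t frame index, 1-based, in `[1, T]`.
#' @param offset temporal offset in frames (default 4).
#' @return H x W x 3 array, channels ordered (t - offset, t, t + offset);
#'   attribute `center_index` records `t`.
#' @export
build_temporal_stack <- function(clip, t, offset = 4L) {
  Tn <- n_frames(clip)
  if (t < 1 || t > Tn)
    stop("index error: frame ", t, " outside [1, ", Tn, "]", call. = FALSE)
  idx <- pmin(pmax(c(t - offset, t, t + offset), 1L), Tn)
  out <- clip$frames[, , idx, drop = FALSE]
  attr(out, "center_index") <- as.integer(t)
  attr(out, "channel_indices") <- as.integer(idx)
  out
}

#' Diameter-balanced training-frame sampling
#'
#' Frames are binned by their measured diameter rounded to the nearest
#' integer pixel; up to `per_bin` frames per bin are sampled without
#' replacement (all frames when a bin is smaller), counteracting the class
#' imbalance between the long diastolic plateaus and the brief systoles.
#'
#' @param mask_diameters per-frame diameter in px (non-negative).
#' @param per_bin frames sampled per diameter bin (default 75).
#' @param seed sampling seed.
#' @return sorted integer frame indices (union over bins).
#' @export
sample_training_frames <- function(mask_diameters, per_bin = 75L, seed = 1L) {
  if (length(mask_diameters) == 0) return(integer(0))
  bins <- round(mask_diameters)
  withr::with_seed(seed, {
    picked <- lapply(split(seq_along(bins), bins), function(ix) {
      if (length(ix) <= per_bin) ix else sample(ix, per_bin)
    })
    sort(unlist(picked, use.names = FALSE))
  })
}

#' Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' the soft complement of the Dice overlap coefficient; bounded in
#' \[0, 1\] and symmetric in its arguments for binary inputs.
#'
#' @param pred probability map (any shape).
#' @param target reference mask, same shape.
#' @param eps smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim2(pred), dim2(target)))
    stop("dimension error: pred ", paste(dim2(pred), collapse = "x"),
         " vs target ", paste(dim2(target), collapse = "x"), call. = FALSE)
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Dice overlap coefficient of two binary masks
#' @param a,b logical/0-1 arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum((a > 0) & (b > 0)) / (sa + sb)
}

# ---- attention U-Net graph -------------------------------------------------

build_unet <- function(in_ch, config) {
  f <- config$filters_per_level
  kh <- config$kernel_shape[1]; kw <- config$kernel_shape[2]
  L <- length(f)
  net <- list(L = L, f = f, attention = config$attention_gates)
  net$enc <- vector("list", L)
  net$enc[[1]] <- nn_conv(in_ch, f[1], kh, kw)
  for (i in 2:L) net$enc[[i]] <- nn_conv(f[i - 1], f[i], kh, kw)
  net$up <- net$att_g <- net$att_x <- net$att_psi <- net$merge <-
    vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    fi <- f[i]; fint <- max(1L, fi %/% 2L)
    net$up[[i]] <- nn_conv(f[i + 1], fi, kh, kw)
    if (config$attention_gates) {
      net$att_g[[i]] <- nn_conv(fi, fint, 1L, 1L)
      net$att_x[[i]] <- nn_conv(fi, fint, 1L, 1L)
      net$att_psi[[i]] <- nn_conv(fint, 1L, 1L, 1L)
    }
    net$merge[[i]] <- nn_conv(2L * fi, fi, kh, kw)
  }
  net$head <- nn_conv(f[1], 1L, 1L, 1L)
  net$layers <- c(net$enc, net$up,
                  if (config$attention_gates)
                    c(net$att_g, net$att_x, net$att_psi),
                  net$merge, list(net$head))
  net
}

unet_fwd <- function(net, x) {                      # x: (C,H,W,N)
  L <- net$L
  cache <- list(enc = vector("list", L), pool = vector("list", L - 1),
                dec = vector("list", L - 1))
  e <- vector("list", L)
  cf <- conv_fwd(net$enc[[1]], x)
  rf <- relu_fwd(cf$out)
  e[[1]] <- rf$out
  cache$enc[[1]] <- list(conv = cf$cache, relu = rf$cache)
  for (i in 2:L) {
    pf <- maxpool2_fwd(e[[i - 1]])
    cache$pool[[i - 1]] <- pf$cache
    cf <- conv_fwd(net$enc[[i]], pf$out)
    rf <- relu_fwd(cf$out)
    e[[i]] <- rf$out
    cache$enc[[i]] <- list(conv = cf$cache, relu = rf$cache)
  }
  d <- e[[L]]
  for (i in rev(seq_len(L - 1))) {
    upx <- upsample2_fwd(d)
    cu <- conv_fwd(net$up[[i]], upx)
    ru <- relu_fwd(cu$out)
    u <- ru$out
    C <- net$f[i]
    if (net$attention) {
      cg <- conv_fwd(net$att_g[[i]], u)
      cx <- conv_fwd(net$att_x[[i]], e[[i]])
      ra <- relu_fwd(cg$out + cx$out)
      cp <- conv_fwd(net$att_psi[[i]], ra$out)
      psi <- sigmoid(cp$out)                        # (1,Hi,Wi,N)
      psi_b <- psi[rep(1L, C), , , , drop = FALSE]
      xs <- e[[i]] * psi_b
    } else {
      cg <- cx <- ra <- cp <- psi <- psi_b <- NULL
      xs <- e[[i]]
    }
    dcat <- dim(u)
    cat_ <- array(0, c(2L * C, dcat[2], dcat[3], dcat[4]))
    cat_[seq_len(C), , , ] <- xs
    cat_[C + seq_len(C), , , ] <- u
    cm <- conv_fwd(net$merge[[i]], cat_)
    rm_ <- relu_fwd(cm$out)
    d <- rm_$out
    cache$dec[[i]] <- list(up_conv = cu$cache, up_relu = ru$cache,
                           att_g = if (net$attention) cg$cache,
                           att_x = if (net$attention) cx$cache,
                           att_relu = if (net$attention) ra$cache,
                           att_psi = if (net$attention) cp$cache,
                           psi = psi, e = e[[i]],
                           merge = cm$cache, merge_relu = rm_$cache)
  }
  ch <- conv_fwd(net$head, d)
  p <- sigmoid(ch$out)
  list(p = p, z = ch$out, cache = c(cache, list(head = ch$cache)))
}

unet_bwd <- function(net, cache, dz) {              # dz: grad wrt pre-sigmoid
  L <- net$L
  dd <- conv_bwd(net$head, cache$head, dz)
  de <- vector("list", L)
  for (i in seq_len(L - 1)) {
    cc <- cache$dec[[i]]
    C <- net$f[i]
    dcat <- conv_bwd(net$merge[[i]], cc$merge, relu_bwd(cc$merge_relu, dd))
    dxs <- dcat[seq_len(C), , , , drop = FALSE]
    du <- dcat[C + seq_len(C), , , , drop = FALSE]
    if (net$attention) {
      psi_b <- cc$psi[rep(1L, C), , , , drop = FALSE]
      de_i <- dxs * psi_b
      dpsi <- array(colSums(matrix(dxs * cc$e, nrow = C)),
                    dim = dim(cc$psi))
      dpz <- dpsi * cc$psi * (1 - cc$psi)
      da <- conv_bwd(net$att_psi[[i]], cc$att_psi, dpz)
      da <- relu_bwd(cc$att_relu, da)
      du <- du + conv_bwd(net$att_g[[i]], cc$att_g, da)
      de_i <- de_i + conv_bwd(net$att_x[[i]], cc$att_x, da)
    } else {
      de_i <- dxs
    }
    de[[i]] <- de_i
    dup <- conv_bwd(net$up[[i]], cc$up_conv, relu_bwd(cc$up_relu, du))
    dd <- upsample2_bwd(dup)
  }
  de[[L]] <- dd                                      # bottleneck grad
  for (i in rev(seq_len(L))) {
    g <- de[[i]]
    g <- relu_bwd(cache$enc[[i]]$relu, g)
    dx <- conv_bwd(net$enc[[i]], cache$enc[[i]]$conv, g)
    if (i > 1) {
      dpool <- maxpool2_bwd(cache$pool[[i - 1]], dx)
      de[[i - 1]] <- de[[i - 1]] + dpool
    }
  }
  invisible(NULL)
}

# Dice loss gradient wrt pre-sigmoid activations, batch-global
dice_grad_z <- function(p, target, eps = 1e-7) {
  num <- 2 * sum(p * target) + eps
  den <- sum(p) + sum(target) + eps
  dp <- (num / den - 2 * target) / den
  dp * p * (1 - p)
}

# stacks: (H,W,3) list/array -> (3,H,W,N) tensor
stacks_to_tensor <- function(stacks) {
  if (is.array(stacks) && length(dim(stacks)) == 4) {
    stacks <- lapply(seq_len(dim(stacks)[4]), function(i) stacks[, , , i])
  }
  d <- dim(stacks[[1]])
  out <- array(0, c(d[3], d[1], d[2], length(stacks)))
  for (i in seq_along(stacks)) out[, , , i] <- aperm(stacks[[i]], c(3, 1, 2))
  out
}

masks_to_tensor <- function(masks) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  }
  d <- dim(masks[[1]])
  out <- array(0, c(1L, d[1], d[2], length(masks)))
  for (i in seq_along(masks)) out[1, , , i] <- masks[[i]] * 1.0
  out
}

#' Train the attention U-Net heart-wall segmenter
#'
#' Seeded 85/15 train/validation split, Dice-loss optimization with Adam in
#' 16-image batches (defaults), optional horizontal-flip and intensity-jitter
#' augmentation, and selection of the epoch checkpoint with the lowest
#' validation loss.
#'
#' @param stacks temporal stacks: list of H x W x 3 arrays (or an
#'   H x W x 3 x N array). H and W must be divisible by
#'   2^(levels - 1).
#' @param masks reference wall masks: list of H x W arrays (or H x W x N).
#' @param config a [unet_config()].
#' @return object of class `seg_model`: the network plus `config`,
#'   `history` (data.frame epoch/train_loss/val_loss) and `best_epoch`.
#' @export
train_segmenter <- function(stacks, masks, config = unet_config()) {
  x_all <- stacks_to_tensor(stacks)
  y_all <- masks_to_tensor(masks)
  n <- dim(x_all)[4]
  if (n < 2) stop("data error: need at least 2 samples (one for validation)",
                  call. = FALSE)
  if (dim(y_all)[4] != n)
    stop("data error: ", n, " stacks but ", dim(y_all)[4], " masks",
         call. = FALSE)
  lv <- length(config$filters_per_level)
  if (any(c(dim(x_all)[2], dim(x_all)[3]) %% 2^(lv - 1) != 0))
    stop("data error: frame geometry must be divisible by 2^(levels-1) = ",
         2^(lv - 1), call. = FALSE)

  withr::with_seed(config$seed, {
    net <- build_unet(in_ch = dim(x_all)[1], config)
    n_val <- max(1L, round(config$val_frac * n))
    perm <- sample(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    xv <- x_all[, , , val_idx, drop = FALSE]
    yv <- y_all[, , , val_idx, drop = FALSE]

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, epoch = NA_integer_, params = NULL)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      tr_losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        ix <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        xb <- x_all[, , , ix, drop = FALSE]
        yb <- y_all[, , , ix, drop = FALSE]
        if (config$augment) {
          if (stats::runif(1) < 0.5) {               # horizontal flip
            wrev <- rev(seq_len(dim(xb)[3]))
            xb <- xb[, , wrev, , drop = FALSE]
            yb <- yb[, , wrev, , drop = FALSE]
          }
          xb <- xb + stats::rnorm(1, 0, 0.03)        # intensity jitter
        }
        fw <- unet_fwd(net, xb)
        tr_losses <- c(tr_losses, dice_loss(fw$p, yb))
        unet_bwd(net, fw$cache, dice_grad_z(fw$p, yb))
        adam_step(net$layers, lr = config$lr)
      }
      vl <- dice_loss(predict_unet(net, xv), yv)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = mean(tr_losses),
                                           val_loss = vl))
      if (vl < best$loss) {
        best <- list(loss = vl, epoch = ep, params = snapshot_params(net$layers))
      }
    }
    restore_params(net$layers, best$params)
    structure(list(net = net, config = config, history = history,
                   best_epoch = best$epoch, in_ch = dim(x_all)[1]),
              class = "seg_model")
  })
}

# inference forward in batches (no gradient caches kept beyond each chunk)
predict_unet <- function(net, x, chunk = 16L) {
  n <- dim(x)[4]
  out <- array(0, c(1L, dim(x)[2], dim(x)[3], n))
  for (b0 in seq(1, n, by = chunk)) {
    ix <- b0:min(b0 + chunk - 1L, n)
    out[, , , ix] <- unet_fwd(net, x[, , , ix, drop = FALSE])$p
  }
  out
}

#' Per-pixel wall probability maps for a clip
#'
#' Runs the trained segmenter over every frame's temporal stack.
#'
#' @param model a `seg_model` from [train_segmenter()].
#' @param clip a [video_clip()].
#' @param offset temporal stack offset (default 4).
#' @return H x W x T numeric array of probabilities in \[0, 1\].
#' @export
predict_probabilities <- function(model, clip, offset = 4L) {
  Tn <- n_frames(clip)
  stacks <- lapply(seq_len(Tn), function(t)
    build_temporal_stack(clip, t, offset))
  x <- stacks_to_tensor(stacks)
  p <- predict_unet(model$net, x)
  array(p[1, , , ], dim = c(dim(p)[2], dim(p)[3], Tn))
}

#' Threshold the segmenter into per-frame binary wall masks
#'
#' @param model a `seg_model`.
#' @param clip a [video_clip()].
#' @param threshold probability threshold in \[0, 1\]; a pixel is wall when
#'   its probability is >= threshold.
#' @param offset temporal stack offset.
#' @return H x W x T logical array.
#' @export
segment_frames <- function(model, clip, threshold = 0.5, offset = 4L) {
  if (threshold < 0 || threshold > 1)
    stop("parameter error: threshold must be in [0, 1], got ", threshold,
         call. = FALSE)
  predict_probabilities(model, clip, offset) >= threshold
}

#' Save / load a segmenter checkpoint (weights + config + seed embedded)
#' @param model a `seg_model`.
#' @param path checkpoint file path.
#' @export
save_segmenter <- function(model, path) {
  saveRDS(list(params = snapshot_params(model$net$layers),
               config = model$config, history = model$history,
               best_epoch = model$best_epoch, in_ch = model$in_ch), path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  ck <- readRDS(path)
  net <- withr::with_seed(ck$config$seed, build_unet(ck$in_ch, ck$config))
  restore_params(net$layers, ck$params)
  structure(list(net = net, config = ck$config, history = ck$history,
                 best_epoch = ck$best_epoch, in_ch = ck$in_ch),
            class = "seg_model")
}
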