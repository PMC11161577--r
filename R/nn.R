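# Minimal CPU neural-network core used by the attention U-Net segmenter and
# the keyframe video classifier. Feature maps are arrays in (C, H, W, N)
# layout so convolution outputs reshape without transposes; convolutions are
# evaluated by kernel-offset block gathers feeding a single BLAS matmul, and
# gradients scatter back by the mirrored block adds. All layers are
# environments so optimizer state mutates in place.

nn_conv <- function(cin, cout, kh, kw) {
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)  # same-padding requires odd kernels
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$cin <- cin; l$cout <- cout; l$kh <- kh; l$kw <- kw
  fan_in <- cin * kh * kw
  l$W <- matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
  l$b <- numeric(cout)
  # patch-element table, c fastest then di then dj — matches W column order
  pe <- expand.grid(c = seq_len(cin), di = seq_len(kh), dj = seq_len(kw))
  l$pe <- as.matrix(pe)
  l
}

nn_dense <- function(nin, nout) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"; l$nin <- nin; l$nout <- nout
  l$W <- matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  l$b <- numeric(nout)
  l
}

# x: (C,H,W,N) -> list(out (cout,H,W,N), cache)
conv_fwd <- function(l, x) {
  d <- dim(x); H <- d[2]; W <- d[3]; N <- d[4]
  ph <- (l$kh - 1L) %/% 2L; pw <- (l$kw - 1L) %/% 2L
  xp <- array(0, c(l$cin, H + 2L * ph, W + 2L * pw, N))
  xp[, ph + seq_len(H), pw + seq_len(W), ] <- x
  K <- nrow(l$pe)
  cols <- matrix(0, K, H * W * N)
  for (r in seq_len(K)) {
    c0 <- l$pe[r, 1]; di <- l$pe[r, 2]; dj <- l$pe[r, 3]
    cols[r, ] <- xp[c0, di:(di + H - 1L), dj:(dj + W - 1L), ]
  }
  out <- l$W %*% cols + l$b
  list(out = array(out, c(l$cout, H, W, N)),
       cache = list(cols = cols, H = H, W = W, N = N, ph = ph, pw = pw))
}

conv_bwd <- function(l, cache, dout) {
  H <- cache$H; W <- cache$W; N <- cache$N
  dmat <- matrix(dout, nrow = l$cout)
  l$gW <- dmat %*% t(cache$cols)
  l$gb <- rowSums(dmat)
  dcols <- crossprod(l$W, dmat)                      # K x HWN
  K <- nrow(l$pe)
  dc <- array(dcols, c(K, H, W, N))
  dxp <- array(0, c(l$cin, H + 2L * cache$ph, W + 2L * cache$pw, N))
  for (r in seq_len(K)) {
    c0 <- l$pe[r, 1]; di <- l$pe[r, 2]; dj <- l$pe[r, 3]
    dxp[c0, di:(di + H - 1L), dj:(dj + W - 1L), ] <-
      dxp[c0, di:(di + H - 1L), dj:(dj + W - 1L), ] + dc[r, , , ]
  }
  dxp[, cache$ph + seq_len(H), cache$pw + seq_len(W), , drop = FALSE]
}

dense_fwd <- function(l, x) {                        # x: (nin, N)
  list(out = l$W %*% x + l$b, cache = x)
}

dense_bwd <- function(l, cache, dout) {
  l$gW <- dout %*% t(cache)
  l$gb <- rowSums(dout)
  crossprod(l$W, dout)
}

relu_fwd <- function(x) { m <- x > 0; list(out = x * m, cache = m) }
relu_bwd <- function(cache, d) d * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling with argmax routing; H and W must be even
maxpool2_fwd <- function(x) {
  d <- dim(x); H <- d[2]; W <- d[3]
  oi <- seq(1L, H, 2L); ei <- oi + 1L
  oj <- seq(1L, W, 2L); ej <- oj + 1L
  four <- list(x[, oi, oj, , drop = FALSE], x[, ei, oj, , drop = FALSE],
               x[, oi, ej, , drop = FALSE], x[, ei, ej, , drop = FALSE])
  m <- four[[1]]; arg <- array(1L, dim(m))
  for (k in 2:4) {
    sel <- four[[k]] > m
    m[sel] <- four[[k]][sel]
    arg[sel] <- k
  }
  list(out = m, cache = list(arg = arg, H = H, W = W))
}

maxpool2_bwd <- function(cache, d) {
  arg <- cache$arg
  dims <- dim(arg)
  C <- dims[1]; h <- dims[2]; w <- dims[3]; N <- dims[4]
  dx <- array(0, c(C, cache$H, cache$W, N))
  oi <- seq(1L, cache$H, 2L); ei <- oi + 1L
  oj <- seq(1L, cache$W, 2L); ej <- oj + 1L
  slots <- list(list(oi, oj), list(ei, oj), list(oi, ej), list(ei, ej))
  for (k in 1:4) {
    dk <- array(0, dims)
    sel <- arg == k
    dk[sel] <- d[sel]
    dx[, slots[[k]][[1]], slots[[k]][[2]], ] <- dk
  }
  dx
}

# nearest-neighbour 2x upsampling
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(d) {
  dims <- dim(d); H <- dims[2]; W <- dims[3]
  oi <- seq(1L, H, 2L); ei <- oi + 1L
  oj <- seq(1L, W, 2L); ej <- oj + 1L
  d[, oi, oj, , drop = FALSE] + d[, ei, oj, , drop = FALSE] +
    d[, oi, ej, , drop = FALSE] + d[, ei, ej, , drop = FALSE]
}

# Adam with in-place moment state on each layer environment
adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$mW)) {
      l$mW <- 0 * l$W; l$vW <- 0 * l$W
      l$mb <- 0 * l$b; l$vb <- 0 * l$b
      l$t <- 0L
    }
    l$t <- l$t + 1L
    l$mW <- beta1 * l$mW + (1 - beta1) * l$gW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$gW^2
    l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
    l$vb <- beta2 * l$vb + (1 - beta2) * l$gb^2
    c1 <- 1 - beta1^l$t; c2 <- 1 - beta2^l$t
    l$W <- l$W - lr * (l$mW / c1) / (sqrt(l$vW / c2) + eps)
    l$b <- l$b - lr * (l$mb / c1) / (sqrt(l$vb / c2) + eps)
  }
  invisible(NULL)
}

snapshot_params <- function(layers)
  lapply(layers, function(l) list(W = l$W, b = l$b))

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$W <- snap[[i]]$W
    layers[[i]]$b <- snap[[i]]$b
  }
  invisible(NULL)
}
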