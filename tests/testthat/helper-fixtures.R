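# Small fixture builders shared by the test files. Everything is generated
# in code at test time; no binary fixtures are stored.

# tiny heart whose geometry fits a 32 x 48 frame (segmenter-friendly dims)
tiny_spec <- function(...) {
  args <- utils::modifyList(list(
    dd = 36, sd = 20, hp_mean = 0.5, hp_cv = 0.05, fps = 100, duration = 2,
    height = 32, width = 48, pixel_size = 2, wall_thickness = 4,
    noise_sigma = 0.05, seed = 42L), list(...))
  do.call(heart_spec, args)
}

# piecewise-linear trapezoid trace with exactly known interval boundaries.
# Returns the trace plus the constructed per-beat onset / relaxation-end
# frames (1-based) — the construction is the oracle for detect_beats.
trapezoid_trace <- function(n_beats, dd = 60, sd = 40, fps = 100,
                            contr = 8L, hold = 12L, relax = 8L, plateau = 40L,
                            lead = 25L) {
  beat_len <- contr + hold + relax + plateau
  x <- rep(dd, lead)
  onsets <- integer(n_beats); rel_ends <- integer(n_beats)
  for (b in seq_len(n_beats)) {
    onsets[b] <- length(x) + 1L
    x <- c(x,
           seq(dd, sd, length.out = contr + 1L)[-1],
           rep(sd, hold),
           seq(sd, dd, length.out = relax + 1L)[-1])
    rel_ends[b] <- length(x)
    x <- c(x, rep(dd, plateau))
  }
  x <- c(x, rep(dd, 10L))
  list(trace = diameter_trace(x, fps = fps, pixel_size = 1),
       onsets = onsets, rel_ends = rel_ends,
       beat_len = beat_len, fps = fps)
}

# clip whose per-frame SSD-vs-frame-1 binarizes to exactly `bits`
bitpattern_clip <- function(bits, fps = 50) {
  frames <- array(0.2, dim = c(2, 2, length(bits)))
  for (t in seq_along(bits)) frames[, , t] <- 0.2 + 0.6 * bits[t]
  video_clip(frames, fps = fps, pixel_size = 1)
}

# synthetic cardiac feature table with a known separable structure
toy_features <- function(n_per_class = 30, seed = 1) {
  withr::with_seed(seed, {
    young <- data.frame(dd = rnorm(n_per_class, 60, 2),
                        sd = rnorm(n_per_class, 40, 2),
                        fs = rnorm(n_per_class, 33, 2),
                        di = rnorm(n_per_class, 0.25, 0.02),
                        si = rnorm(n_per_class, 0.16, 0.02),
                        hp = rnorm(n_per_class, 0.41, 0.03),
                        ai = rnorm(n_per_class, 0.05, 0.01))
    old <- data.frame(dd = rnorm(n_per_class, 55, 2),
                      sd = rnorm(n_per_class, 44, 2),
                      fs = rnorm(n_per_class, 20, 2),
                      di = rnorm(n_per_class, 0.45, 0.04),
                      si = rnorm(n_per_class, 0.30, 0.03),
                      hp = rnorm(n_per_class, 0.72, 0.05),
                      ai = rnorm(n_per_class, 0.12, 0.02))
    list(features = rbind(young, old),
         labels = factor(rep(c("young", "old"), each = n_per_class),
                         levels = c("young", "old")))
  })
}

# brute-force Shapley values over all feature coalitions with a
# mean-imputation value function on the link scale (independent oracle)
brute_force_shap <- function(model, background, x) {
  feats <- model$features
  p <- length(feats)
  zb <- sweep(sweep(as.matrix(background[, feats]), 2,
                    model$scaler$center), 2, model$scaler$scale, "/")
  zx <- (unlist(x[feats]) - model$scaler$center) / model$scaler$scale
  mu <- colMeans(zb)
  vfun <- function(S) {                 # link output, features in S set to x
    z <- mu; z[S] <- zx[S]
    model$intercept + sum(model$weights * z)
  }
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    rows <- subsets[!subsets[[j]], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      S <- others[unlist(rows[r, others])]
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
    }
  }
  stats::setNames(phi, feats)
}
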