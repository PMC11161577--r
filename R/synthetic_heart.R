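#' Specification of a synthetic beating heart
#'
#' Parameters describing a tubular heart imaged side-on as two horizontal wall
#' bands whose separation (the lumen diameter) oscillates between a diastolic
#' and a systolic value. The waveform is a smoothed trapezoid per beat:
#' a cosine-ramped contraction, a systolic hold, a cosine-ramped relaxation,
#' and a diastolic plateau. Per-beat heart periods are jittered with a
#' truncated normal so arrhythmic rhythms can be emulated.
#'
#' @param dd diastolic (maximal) lumen diameter, um. Must exceed `sd`.
#' @param sd systolic (minimal) lumen diameter, um. Must be positive.
#' @param hp_mean mean heart period, s.
#' @param hp_cv coefficient of variation of the per-beat heart period
#'   (dimensionless, >= 0). 0 gives a perfectly regular rhythm.
#' @param si_frac fraction of each heart period spent in the systolic
#'   interval (contraction onset to end of relaxation), in (0, 1).
#' @param wall_thickness rendered wall band thickness, px.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise on rendered frames (intensity units; frames live in \[0, 1\]).
#' @param fps frame rate, frames/s.
#' @param duration recording length, s.
#' @param height,width frame geometry, px.
#' @param pixel_size calibration, um/px.
#' @param seed integer seed; all randomness of the generator flows from it.
#'
#' @return An object of class `heart_spec`.
#' @export
heart_spec <- function(dd = 60, sd = 40, hp_mean = 0.5, hp_cv = 0.05,
                       si_frac = 0.4, wall_thickness = 6, noise_sigma = 0.05,
                       fps = 200, duration = 10, height = 96, width = 64,
                       pixel_size = 1.0, seed = 1L) {
  spec <- structure(list(
    dd = dd, sd = sd, hp_mean = hp_mean, hp_cv = hp_cv, si_frac = si_frac,
    wall_thickness = as.integer(wall_thickness), noise_sigma = noise_sigma,
    fps = fps, duration = duration, height = as.integer(height),
    width = as.integer(width), pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "heart_spec")
  validate_heart_spec(spec)
  spec
}

validate_heart_spec <- function(spec) {
  stopifnot(inherits(spec, "heart_spec"))
  with(spec, {
    if (!(dd > sd)) stop("invalid heart_spec: requires dd > sd, got dd = ",
                         dd, ", sd = ", sd, call. = FALSE)
    if (!(sd > 0)) stop("invalid heart_spec: requires sd > 0, got ", sd,
                        call. = FALSE)
    if (!(si_frac > 0 && si_frac < 1))
      stop("invalid heart_spec: requires 0 < si_frac < 1, got ", si_frac,
           call. = FALSE)
    if (hp_cv < 0) stop("invalid heart_spec: requires hp_cv >= 0, got ",
                        hp_cv, call. = FALSE)
    if (fps <= 0) stop("invalid heart_spec: requires fps > 0", call. = FALSE)
    if (duration <= 0) stop("invalid heart_spec: requires duration > 0",
                            call. = FALSE)
    if (hp_mean <= 0) stop("invalid heart_spec: requires hp_mean > 0",
                           call. = FALSE)
    if (pixel_size <= 0) stop("invalid heart_spec: requires pixel_size > 0",
                              call. = FALSE)
  })
  invisible(spec)
}

# Deterministic sub-seed so each stochastic stage of the generator draws from
# its own stream while everything still flows from the one user seed.
derive_seed <- function(seed, tag) {
  offs <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483629)
}

# Truncated-normal heart periods: HP ~ N(hp_mean, (hp_cv*hp_mean)^2) with
# HP > 2 frame intervals, so no beat degenerates to fewer than two frames.
draw_heart_periods <- function(spec, n) {
  lo <- 2 / spec$fps
  if (spec$hp_cv == 0) return(rep(spec$hp_mean, n))
  sdev <- spec$hp_cv * spec$hp_mean
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, spec$hp_mean, sdev)
    out <- c(out, x[x > lo])
  }
  out[seq_len(n)]
}

# Diameter at time u since beat onset for a beat of period hp.
# SI = contraction ramp + systolic hold + relaxation ramp; DI = plateau at dd.
beat_diameter <- function(u, hp, spec) {
  si <- spec$si_frac * hp
  ramp <- min(0.1 * hp, si / 2)
  amp <- spec$dd - spec$sd
  d <- numeric(length(u))
  contr <- u < ramp
  hold <- u >= ramp & u < si - ramp
  relax <- u >= si - ramp & u < si
  plateau <- u >= si
  d[contr] <- spec$dd - amp * (1 - cos(pi * u[contr] / ramp)) / 2
  d[hold] <- spec$sd
  d[relax] <- spec$sd +
    amp * (1 - cos(pi * (u[relax] - (si - ramp)) / ramp)) / 2
  d[plateau] <- spec$dd
  d
}

#' Generate a ground-truth diameter waveform and beat table
#'
#' Lays down beats back-to-back from t = 0 with seeded per-beat heart-period
#' jitter and evaluates the smoothed-trapezoid diameter at every frame time.
#'
#' @param spec a [heart_spec()].
#' @return A list with `waveform` (per-frame diameter, um), `time`
#'   (per-frame time, s), and `beats` — the ground-truth beat table, a
#'   data.frame with one row per complete beat inside the recording:
#'   `onset_t`, `rel_end_t` (s), `si`, `di`, `hp` (s), `dd`, `sd` (um).
#' @export
generate_waveform <- function(spec) {
  validate_heart_spec(spec)
  n_frames <- round(spec$fps * spec$duration)
  time <- (seq_len(n_frames) - 1) / spec$fps

  hp <- withr::with_seed(derive_seed(spec$seed, "waveform"), {
    n_guess <- ceiling(spec$duration / spec$hp_mean * 2) + 4
    draw_heart_periods(spec, n_guess)
  })
  while (sum(hp) < spec$duration + 2 * spec$hp_mean) {
    hp <- c(hp, spec$hp_mean)  # deterministic top-up; practically unreachable
  }
  onset <- cumsum(c(0, hp))
  k <- findInterval(time, onset)          # beat index per frame, 1-based
  u <- time - onset[k]
  waveform <- beat_diameter_vec(u, hp[k], spec)

  complete <- which(onset[-1] <= spec$duration + 1e-9)
  beats <- data.frame(
    onset_t = onset[complete],
    rel_end_t = onset[complete] + spec$si_frac * hp[complete],
    si = spec$si_frac * hp[complete],
    di = (1 - spec$si_frac) * hp[complete],
    hp = hp[complete],
    dd = rep(spec$dd, length(complete)),
    sd = rep(spec$sd, length(complete))
  )
  list(waveform = waveform, time = time, beats = beats)
}

# vectorised over per-frame (u, hp) pairs
beat_diameter_vec <- function(u, hp, spec) {
  si <- spec$si_frac * hp
  ramp <- pmin(0.1 * hp, si / 2)
  amp <- spec$dd - spec$sd
  d <- rep(spec$dd, length(u))
  contr <- u < ramp
  hold <- u >= ramp & u < si - ramp
  relax <- u >= si - ramp & u < si
  d[contr] <- spec$dd - amp * (1 - cos(pi * u[contr] / ramp[contr])) / 2
  d[hold] <- spec$sd
  d[relax] <- spec$sd +
    amp * (1 - cos(pi * (u[relax] - (si[relax] - ramp[relax])) /
                     ramp[relax])) / 2
  d
}

#' Render a waveform into video frames and ground-truth wall masks
#'
#' Each frame shows two horizontal wall bands of `wall_thickness` px whose
#' inner-edge gap equals `round(waveform[t] / pixel_size)` px, centred
#' vertically, over a darker background, plus seeded Gaussian intensity
#' noise. Masks mark wall pixels only (not the lumen).
#'
#' @param waveform per-frame diameter, um (finite, positive).
#' @param spec a [heart_spec()] supplying geometry, noise and seed.
#' @return A list with `clip` (a [video_clip()]) and `masks` (logical
#'   H x W x T array of wall pixels).
#' @export
render_frames <- function(waveform, spec) {
  validate_heart_spec(spec)
  stopifnot(all(is.finite(waveform)), all(waveform > 0))
  H <- spec$height; W <- spec$width; Tn <- length(waveform)
  gap <- as.integer(round(waveform / spec$pixel_size))
  wt <- spec$wall_thickness
  if (max(gap) + 2L * wt > H)
    stop("geometry error: lumen gap ", max(gap), " px + 2 x wall_thickness ",
         wt, " px exceeds frame height ", H, " px", call. = FALSE)

  lumen_start <- (H - gap) %/% 2L + 1L           # first lumen row, 1-based
  frames <- array(0.15, dim = c(H, W, Tn))
  masks <- array(FALSE, dim = c(H, W, Tn))
  rows <- seq_len(H)
  for (t in seq_len(Tn)) {
    top <- (lumen_start[t] - wt):(lumen_start[t] - 1L)
    bot <- (lumen_start[t] + gap[t]):(lumen_start[t] + gap[t] + wt - 1L)
    wall <- rows %in% c(top, bot)
    frames[wall, , t] <- 0.85
    masks[wall, , t] <- TRUE
  }
  if (spec$noise_sigma > 0) {
    noise <- withr::with_seed(
      derive_seed(spec$seed, "noise"),
      array(stats::rnorm(length(frames), 0, spec$noise_sigma), dim = dim(frames))
    )
    frames <- frames + noise
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  list(clip = video_clip(frames, fps = spec$fps, pixel_size = spec$pixel_size),
       masks = masks)
}

#' Simulate one complete synthetic heart
#'
#' Convenience wrapper: waveform + ground-truth beats, rendered clip and
#' masks, all from the single seed carried by `spec`.
#'
#' @param spec a [heart_spec()].
#' @param render if `FALSE`, skip frame rendering (waveform and beat table
#'   only) — useful for large cohorts where only cardiac statistics are
#'   needed.
#' @return list with `spec`, `waveform`, `time`, `beats`, and (when
#'   rendered) `clip`, `masks`.
#' @export
simulate_heart <- function(spec, render = TRUE) {
  wf <- generate_waveform(spec)
  out <- list(spec = spec, waveform = wf$waveform, time = wf$time,
              beats = wf$beats)
  if (render) {
    r <- render_frames(wf$waveform, spec)
    out$clip <- r$clip
    out$masks <- r$masks
  }
  out
}

#' Default cohort specs emulating young and aged hearts
#'
#' The aged cohort has reduced fractional shortening (smaller DD-SD gap) and
#' a longer, more variable heart period — the directional aging phenotypes of
#' the fly heart. Effect sizes are arguments, not constants.
#'
#' @param dd,sd,hp_mean,hp_cv see [heart_spec()].
#' @param ... passed to [heart_spec()].
#' @return a [heart_spec()].
#' @export
young_heart_spec <- function(dd = 60, sd = 40, hp_mean = 0.4, hp_cv = 0.05, ...) {
  heart_spec(dd = dd, sd = sd, hp_mean = hp_mean, hp_cv = hp_cv, ...)
}

#' @rdname young_heart_spec
#' @export
old_heart_spec <- function(dd = 55, sd = 44, hp_mean = 0.7, hp_cv = 0.15, ...) {
  heart_spec(dd = dd, sd = sd, hp_mean = hp_mean, hp_cv = hp_cv, ...)
}

#' Generate a labeled two-class cohort of synthetic hearts
#'
#' Each heart's spec is perturbed multiplicatively around its cohort spec
#' (diameters and mean heart period jittered with CV `perturb_cv`) so
#' within-cohort variance is nonzero; every heart gets its own derived seed.
#'
#' @param young_spec,old_spec cohort-level [heart_spec()]s.
#' @param n_each hearts per class (>= 1).
#' @param seed master seed for the whole cohort.
#' @param perturb_cv coefficient of variation of the per-heart perturbation.
#' @param render render clips/masks per heart (memory heavy for large
#'   cohorts); if `FALSE` only waveforms and beat tables are produced.
#' @return list with `hearts` (list of [simulate_heart()] results) and
#'   `labels` (factor, levels `young`, `old`, one per heart).
#' @export
make_cohort <- function(young_spec, old_spec, n_each, seed = 1L,
                        perturb_cv = 0.05, render = TRUE) {
  stopifnot(n_each >= 1)
  validate_heart_spec(young_spec)
  validate_heart_spec(old_spec)
  specs <- c(rep(list(young_spec), n_each), rep(list(old_spec), n_each))
  labels <- factor(rep(c("young", "old"), each = n_each),
                   levels = c("young", "old"))
  n <- length(specs)
  pert <- withr::with_seed(derive_seed(seed, "cohort"),
                           matrix(stats::rnorm(3 * n, 1, perturb_cv), ncol = 3))
  pert <- pmax(pert, 0.5)
  hearts <- vector("list", n)
  for (i in seq_len(n)) {
    s <- specs[[i]]
    s$dd <- s$dd * pert[i, 1]
    s$sd <- min(s$sd * pert[i, 2], 0.95 * s$dd)  # keep dd > sd
    s$hp_mean <- s$hp_mean * pert[i, 3]
    s$seed <- derive_seed(seed, paste0("heart", i))
    hearts[[i]] <- simulate_heart(s, render = render)
    hearts[[i]]$label <- as.character(labels[i])
  }
  list(hearts = hearts, labels = labels)
}
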