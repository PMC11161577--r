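#' Heart-wall velocity from a diameter trace
#'
#' Central differences of the (optionally moving-average smoothed) diameter,
#' scaled by the frame rate; endpoints use one-sided differences.
#'
#' @param trace a [diameter_trace()] (>= 3 valid frames).
#' @param smooth_window moving-average window in frames (1 = no smoothing);
#'   must be shorter than the trace.
#' @return numeric velocity series, um/s, same length as the trace.
#' @export
compute_velocity <- function(trace, smooth_window = 1L) {
  x <- trace$values
  n <- length(x)
  if (sum(trace$valid) < 3)
    stop("compute_velocity: need at least 3 valid frames", call. = FALSE)
  if (smooth_window >= n)
    stop("parameter error: smooth_window (", smooth_window,
         ") must be smaller than the trace length (", n, ")", call. = FALSE)
  s <- moving_average(x, smooth_window)
  v <- numeric(n)
  v[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
  v[1] <- s[2] - s[1]
  v[n] <- s[n] - s[n - 1]
  v * trace$fps
}

# centered moving average; edges use the shrunken window that fits
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect beats from a diameter trace
#'
#' Velocity-threshold state machine. The trace is smoothed with a centred
#' moving average, differentiated, and scanned: a contraction onset is a
#' downward crossing of -v_thr; the end of relaxation is the first return of
#' the velocity into the band \[-v_thr, +v_thr\] after the subsequent
#' positive excursion (> +v_thr). The quiescent diastolic interval runs from
#' each relaxation end to the next onset; heart period is onset-to-next-onset.
#' Beats truncated by the trace edges are dropped. `v_thr` defaults to
#' `v_thr_frac` times the 95th percentile of the absolute velocity.
#'
#' @param trace a [diameter_trace()].
#' @param smooth_window smoothing window in frames.
#' @param v_thr_frac fraction of the 95th-percentile |velocity| used as the
#'   crossing threshold.
#' @param min_amplitude_um minimum peak-to-peak diameter excursion for the
#'   trace to count as oscillating; below it no beats are reported.
#' @return object of class `beat_table`: list with `beats` (data.frame:
#'   `onset_t`, `rel_end_t`, `si`, `di`, `hp` \[s\], `dd`, `sd` \[um\],
#'   `fs`, `ef` \[%\]), `fps`, and the detection parameters.
#' @export
detect_beats <- function(trace, smooth_window = 5L, v_thr_frac = 0.2,
                         min_amplitude_um = 1.0) {
  stopifnot(inherits(trace, "diameter_trace"))
  seg <- longest_valid_run(trace$valid)
  empty <- beat_table(data.frame(), trace$fps, smooth_window, v_thr_frac)
  if (length(seg) < 5) return(empty)
  x <- trace$values[seg]
  fps <- trace$fps
  s <- moving_average(x, smooth_window)
  if (diff(range(s)) < min_amplitude_um) return(empty)
  n <- length(s)
  v <- numeric(n)
  v[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2 * fps
  v[1] <- (s[2] - s[1]) * fps
  v[n] <- (s[n] - s[n - 1]) * fps
  thr <- v_thr_frac * stats::quantile(abs(v), 0.95, names = FALSE)
  if (thr <= 0) return(empty)

  # downward crossings of -thr; a virtual zero velocity precedes frame 1 so
  # a contraction starting exactly at the trace start is still an onset
  onsets <- which(v < -thr & c(0, v[-n]) >= -thr)
  if (length(onsets) < 2) return(empty)

  rel_ends <- rep(NA_integer_, length(onsets))
  bound <- c(onsets[-1], n + 1L)
  for (k in seq_along(onsets)) {
    i <- onsets[k]
    lim <- bound[k] - 1L
    pos <- i + which(v[(i + 1):lim] > thr)          # positive excursion
    if (i >= lim || length(pos) == 0) next
    j <- pos[1]
    back <- j + which(abs(v[(j + 1):lim]) <= thr)   # re-entry into band
    if (j >= lim || length(back) == 0) next
    rel_ends[k] <- back[1]
  }

  keep <- which(!is.na(rel_ends))
  keep <- keep[keep < length(onsets)]               # need the next onset for HP
  if (length(keep) == 0) return(empty)
  t0 <- seg[1] - 1L                                 # offset into full trace
  rows <- lapply(keep, function(k) {
    i <- onsets[k]; r <- rel_ends[k]; nxt <- onsets[k + 1L]
    si <- (r - i) / fps
    hp <- (nxt - i) / fps
    sd_ <- min(x[i:r])                              # SD: min over the SI
    dd_ <- max(x[r:nxt])                            # DD: max over the DI
    data.frame(onset_t = (t0 + i - 1L) / fps,
               rel_end_t = (t0 + r - 1L) / fps,
               si = si, di = hp - si, hp = hp, dd = dd_, sd = sd_)
  })
  beats <- do.call(rbind, rows)
  beats$fs <- fractional_shortening(beats$dd, beats$sd)
  beats$ef <- ejection_fraction(beats$dd, beats$sd)
  beat_table(beats, fps, smooth_window, v_thr_frac)
}

beat_table <- function(beats, fps, smooth_window = NA, v_thr_frac = NA) {
  structure(list(beats = beats, fps = fps, smooth_window = smooth_window,
                 v_thr_frac = v_thr_frac),
            class = "beat_table")
}

longest_valid_run <- function(valid) {
  r <- rle(valid)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  starts[i]:ends[i]
}

#' Diastolic and systolic diameter of one beat
#'
#' DD is the largest diameter attained during the beat's diastolic interval;
#' SD is the smallest attained over its systolic interval.
#'
#' @param beat one-row data.frame with `onset_t`, `rel_end_t`, `hp` (s).
#' @param trace the [diameter_trace()] the beat was detected in.
#' @return named numeric `c(dd, sd)` in um.
#' @export
beat_morphology <- function(beat, trace) {
  fps <- trace$fps
  i <- round(beat$onset_t * fps) + 1L
  r <- round(beat$rel_end_t * fps) + 1L
  e <- round((beat$onset_t + beat$hp) * fps) + 1L
  n <- length(trace$values)
  if (i < 1 || e > n || r <= i || e <= r)
    stop("interval error: beat interval outside trace or empty", call. = FALSE)
  c(dd = max(trace$values[r:e]), sd = min(trace$values[i:r]))
}

#' Fractional shortening, percent
#'
#' `100 * (dd - sd) / dd` — the percent reduction of lumen diameter from
#' diastole to systole.
#'
#' @param dd,sd diastolic and systolic diameters (same units; `dd > 0`).
#' @return FS in percent.
#' @export
fractional_shortening <- function(dd, sd) {
  if (any(dd <= 0)) stop("domain error: fractional_shortening requires dd > 0",
                         call. = FALSE)
  100 * (dd - sd) / dd
}

#' Ejection fraction, percent (cross-sectional area model)
#'
#' `100 * (dd^2 - sd^2) / dd^2`: the fractional area change of a circular
#' cross-section, used as the tube-heart proxy for ejected volume fraction.
#'
#' @inheritParams fractional_shortening
#' @return EF in percent.
#' @export
ejection_fraction <- function(dd, sd) {
  if (any(dd <= 0)) stop("domain error: ejection_fraction requires dd > 0",
                         call. = FALSE)
  100 * (dd^2 - sd^2) / dd^2
}

#' Arrhythmia index
#'
#' Sample standard deviation of the per-beat heart periods normalized by
#' their median; 0 for a perfectly regular rhythm.
#'
#' @param hp numeric vector of heart periods, s (>= 2 beats).
#' @return dimensionless AI.
#' @export
arrhythmia_index <- function(hp) {
  if (length(hp) < 2)
    stop("insufficient data: arrhythmia_index needs >= 2 beats", call. = FALSE)
  stats::sd(hp) / stats::median(hp)
}

#' Stroke volume, pL (cylindrical tube model)
#'
#' `SV = pi * L * ((dd/2)^2 - (sd/2)^2)` in um^3, converted at
#' 1 pL = 1000 um^3, with L the heart segment length in um.
#'
#' @param dd,sd diameters in um (`dd >= sd >= 0`).
#' @param roi_length_um segment length L, um (> 0).
#' @return stroke volume in pL.
#' @export
stroke_volume <- function(dd, sd, roi_length_um) {
  if (any(sd < 0) || any(dd < sd) || roi_length_um <= 0)
    stop("domain error: stroke_volume requires dd >= sd >= 0 and L > 0",
         call. = FALSE)
  pi * roi_length_um * ((dd / 2)^2 - (sd / 2)^2) / 1000
}

#' Cardiac output, pL/s
#'
#' Sum of per-beat stroke volumes divided by the summed beat times.
#'
#' @param beat_table a `beat_table` with >= 1 beat.
#' @param roi_length_um segment length L, um.
#' @return cardiac output in pL/s.
#' @export
cardiac_output <- function(beat_table, roi_length_um) {
  b <- beat_table$beats
  if (nrow(b) < 1)
    stop("insufficient data: cardiac_output needs >= 1 beat", call. = FALSE)
  sv <- stroke_volume(b$dd, b$sd, roi_length_um)
  sum(sv) / sum(b$hp)
}

#' Contractile latencies per beat
#'
#' For each beat: the time from contraction onset to the most-negative
#' wall-velocity sample, and the time from that sample to the most-positive
#' velocity sample later in the same beat.
#'
#' @param trace a [diameter_trace()].
#' @param beat_table a `beat_table` from [detect_beats()].
#' @param smooth_window velocity smoothing window, frames.
#' @return data.frame with one row per usable beat: `t_peak_contraction`,
#'   `t_contraction_to_relaxation` (s); beats shorter than 3 frames are
#'   skipped with a warning.
#' @export
contractile_latency <- function(trace, beat_table, smooth_window = 5L) {
  v <- compute_velocity(trace, smooth_window)
  fps <- trace$fps
  b <- beat_table$beats
  out <- vector("list", nrow(b))
  skipped <- 0L
  for (k in seq_len(nrow(b))) {
    i <- round(b$onset_t[k] * fps) + 1L
    e <- min(round((b$onset_t[k] + b$hp[k]) * fps) + 1L, length(v))
    if (e - i < 2L) { skipped <- skipped + 1L; next }
    vb <- v[i:e]
    j_min <- which.min(vb)
    j_max <- j_min - 1L + which.max(vb[j_min:length(vb)])
    out[[k]] <- data.frame(
      beat = k,
      t_peak_contraction = (j_min - 1L) / fps,
      t_contraction_to_relaxation = (j_max - j_min) / fps
    )
  }
  if (skipped > 0)
    warning(skipped, " beat(s) shorter than 3 frames skipped in latency ",
            "computation")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(beat = integer(0),
                                      t_peak_contraction = numeric(0),
                                      t_contraction_to_relaxation = numeric(0))
  res
}

#' Tachycardic and bradycardic arrhythmia events
#'
#' Tachycardic events are beats whose systolic interval strictly exceeds
#' `tachy_thr`; bradycardic events are beats whose diastolic interval
#' strictly exceeds `brady_thr` (defaults 0.5 s and 1.0 s).
#'
#' @param beat_table a `beat_table`.
#' @param tachy_thr,brady_thr thresholds in seconds.
#' @return object of class `arrhythmia_events`: list with `tachy_beats`,
#'   `brady_beats` (row indices into the beat table), `n_tachy`, `n_brady`,
#'   `mean_tachy_si`, `mean_brady_di`, and the thresholds.
#' @export
flag_arrhythmia_events <- function(beat_table, tachy_thr = 0.5,
                                   brady_thr = 1.0) {
  b <- beat_table$beats
  tachy <- if (nrow(b)) which(b$si > tachy_thr) else integer(0)
  brady <- if (nrow(b)) which(b$di > brady_thr) else integer(0)
  structure(list(
    tachy_beats = tachy, brady_beats = brady,
    n_tachy = length(tachy), n_brady = length(brady),
    mean_tachy_si = if (length(tachy)) mean(b$si[tachy]) else NA_real_,
    mean_brady_di = if (length(brady)) mean(b$di[brady]) else NA_real_,
    tachy_thr = tachy_thr, brady_thr = brady_thr
  ), class = "arrhythmia_events")
}

arrhythmia_events_df <- function(ev) {
  data.frame(
    type = c(rep("tachy", ev$n_tachy), rep("brady", ev$n_brady)),
    beat = c(ev$tachy_beats, ev$brady_beats)
  )
}

#' Per-heart aggregate cardiac statistics
#'
#' Means of the per-beat quantities plus derived rates: `hr = 1/mean(hp)`,
#' arrhythmia index over the HP list (reported only with >= 2 beats),
#' stroke volume and cardiac output under the cylindrical model, and mean
#' contractile latencies when a trace is supplied.
#'
#' @param beat_table a `beat_table` (>= 1 beat; >= 2 for AI).
#' @param roi_length_um segment length L for the volume model, um.
#' @param trace optional [diameter_trace()] for latency statistics.
#' @param smooth_window latency velocity smoothing window.
#' @return object of class `cardiac_stats` (named list): `n_beats`, `dd`,
#'   `sd` (um), `fs`, `ef` (%), `hp`, `di`, `si` (s), `hr` (Hz), `ai`,
#'   `sv` (pL), `co` (pL/s), `t_peak_contraction`,
#'   `t_contraction_to_relaxation` (s).
#' @export
aggregate_stats <- function(beat_table, roi_length_um, trace = NULL,
                            smooth_window = 5L) {
  b <- beat_table$beats
  if (nrow(b) < 1)
    stop("insufficient data: aggregate_stats needs >= 1 beat", call. = FALSE)
  lat <- if (!is.null(trace))
    contractile_latency(trace, beat_table, smooth_window) else NULL
  structure(list(
    n_beats = nrow(b),
    dd = mean(b$dd), sd = mean(b$sd),
    fs = mean(b$fs), ef = mean(b$ef),
    hp = mean(b$hp), di = mean(b$di), si = mean(b$si),
    hr = 1 / mean(b$hp),
    ai = if (nrow(b) >= 2) arrhythmia_index(b$hp) else NA_real_,
    sv = mean(stroke_volume(b$dd, b$sd, roi_length_um)),
    co = cardiac_output(beat_table, roi_length_um),
    t_peak_contraction = if (is.null(lat)) NA_real_ else
      mean(lat$t_peak_contraction),
    t_contraction_to_relaxation = if (is.null(lat)) NA_real_ else
      mean(lat$t_contraction_to_relaxation)
  ), class = "cardiac_stats")
}

#' @exportS3Method base::print
print.cardiac_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<cardiac_stats> %d beats\n",
           "  DD %.2f um   SD %.2f um   FS %.1f %%   EF %.1f %%\n",
           "  HP %.3f s    HR %.3f Hz   DI %.3f s    SI %.3f s    AI %.3f\n",
           "  SV %.2f pL   CO %.2f pL/s\n"),
    x$n_beats, x$dd, x$sd, x$fs, x$ef, x$hp, x$hr, x$di, x$si,
    ifelse(is.na(x$ai), NA_real_, x$ai), x$sv, x$co))
  invisible(x)
}
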