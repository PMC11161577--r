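#' Grayscale video clip container
#'
#' @param frames numeric array H x W x T with intensities in \[0, 1\].
#' @param fps frame rate, frames/s.
#' @param pixel_size calibration, um/px.
#' @return object of class `video_clip`.
#' @export
video_clip <- function(frames, fps, pixel_size) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, fps > 0,
            pixel_size > 0)
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size),
            class = "video_clip")
}

#' @exportS3Method base::print
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d frames, %d x %d px, %.6g fps, %.6g um/px\n",
              d[3], d[1], d[2], x$fps, x$pixel_size))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip a [video_clip()].
#' @export
n_frames <- function(clip) dim(clip$frames)[3]

#' Read a grayscale video from a multi-page TIFF
#'
#' Multi-channel pages are converted to grayscale by luminance average.
#' Intensities are returned in \[0, 1\] (the TIFF reader scales 8/16-bit
#' data on read).
#'
#' @param path file path to a multi-page TIFF.
#' @param fps,pixel_size acquisition metadata (not stored in the TIFF).
#' @return a [video_clip()].
#' @export
read_video <- function(path, fps, pixel_size) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path,
                               call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("format error: cannot decode TIFF container at ",
                           path, ": ", conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  gray <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)  # luminance average
    p
  })
  frames <- array(unlist(gray), dim = c(dim(gray[[1]]), length(gray)))
  video_clip(frames, fps = fps, pixel_size = pixel_size)
}

#' Write a clip (or mask stack) as a multi-page TIFF
#'
#' Masks (logical arrays) are written as 0/255 8-bit pages.
#'
#' @param x a [video_clip()] or a logical/numeric H x W x T array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_video <- function(x, path) {
  frames <- if (inherits(x, "video_clip")) x$frames else x
  if (is.logical(frames)) frames <- frames * 1.0
  pages <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a beat table or cardiac statistics to CSV
#'
#' Comma-separated, header row, '.' decimal, UTF-8.
#'
#' @param x data.frame (beat table) or `cardiac_stats`.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  if (inherits(x, "cardiac_stats")) x <- as.data.frame(unclass(x))
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a diameter trace as CSV (frame, time_s, diameter_um, valid)
#' @param trace a [diameter_trace()].
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$values)
  utils::write.csv(data.frame(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1) / trace$fps,
    diameter_um = trace$values,
    valid = trace$valid
  ), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a heart_spec or run configuration to YAML
#' @param x list-like object.
#' @param path output path.
#' @export
write_config_yaml <- function(x, path) {
  yaml::write_yaml(lapply(unclass(x), function(v)
    if (is.function(v)) NULL else v), path)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' @param pixel_size um/px calibration (> 0).
#' @param fps frames/s (> 0).
#' @param roi a [roi()] or `NULL` for full width.
#' @param threshold segmentation probability threshold in \[0, 1\].
#' @param tachy_thr,brady_thr arrhythmia event thresholds, s.
#' @param smooth_window beat-detection smoothing window, frames.
#' @param roi_length_um heart segment length used in the cylindrical
#'   stroke-volume model; defaults to ROI width x `pixel_size`.
#' @param seed integer seed for stochastic stages.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size, fps, roi = NULL, threshold = 0.5,
                       tachy_thr = 0.5, brady_thr = 1.0, smooth_window = 5L,
                       roi_length_um = NULL, seed = 1L, out_dir = ".") {
  stopifnot(pixel_size > 0, fps > 0, threshold >= 0, threshold <= 1,
            tachy_thr > 0, brady_thr > 0, smooth_window >= 1)
  structure(list(pixel_size = pixel_size, fps = fps, roi = roi,
                 threshold = threshold, tachy_thr = tachy_thr,
                 brady_thr = brady_thr, smooth_window = as.integer(smooth_window),
                 roi_length_um = roi_length_um, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the segment-and-analyze pipeline on one clip
#'
#' Segmentation (or supplied oracle masks) -> diameter trace -> beat table ->
#' cardiac statistics + arrhythmia events -> annotated M-mode; all artifacts
#' written to the output directory along with the configuration snapshot.
#'
#' @param clip a [video_clip()].
#' @param model a trained segmenter from [train_segmenter()], or `NULL` if
#'   `masks` are supplied directly (e.g. ground-truth masks).
#' @param config a [run_config()].
#' @param masks optional precomputed H x W x T logical mask stack,
#'   bypassing segmentation.
#' @return list with `trace`, `beats`, `stats`, `events`, `mmode`,
#'   and `out_dir`.
#' @export
run_pipeline <- function(clip, model = NULL, config, masks = NULL) {
  stopifnot(inherits(clip, "video_clip"), inherits(config, "run_config"))
  if (is.null(masks)) {
    if (is.null(model)) stop("run_pipeline: need a trained segmenter or masks",
                             call. = FALSE)
    masks <- segment_frames(model, clip, threshold = config$threshold)
  }
  W <- dim(masks)[2]
  use_roi <- if (is.null(config$roi)) roi(1L, W) else config$roi
  trace <- extract_trace(masks, roi = use_roi, pixel_size = config$pixel_size,
                         fps = config$fps)
  beats <- detect_beats(trace, smooth_window = config$smooth_window)
  L <- if (is.null(config$roi_length_um))
    (use_roi$c1 - use_roi$c0 + 1) * config$pixel_size else config$roi_length_um
  stats <- aggregate_stats(beats, roi_length_um = L)
  events <- flag_arrhythmia_events(beats, tachy_thr = config$tachy_thr,
                                   brady_thr = config$brady_thr)
  mid_col <- (use_roi$c0 + use_roi$c1) %/% 2L
  mmode <- make_mmode(clip, masks, column = mid_col, beat_table = beats)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_trace_csv(trace, out("trace.csv"))
  write_table_csv(beats$beats, out("beats.csv"))
  write_table_csv(stats, out("stats.csv"))
  write_table_csv(arrhythmia_events_df(events), out("events.csv"))
  write_mmode_png(mmode, out("mmode.png"))
  write_config_yaml(config, out("config.yaml"))
  list(trace = trace, beats = beats, stats = stats, events = events,
       mmode = mmode, out_dir = config$out_dir)
}
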