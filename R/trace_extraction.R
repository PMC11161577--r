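#' Rectangular region of interest over pixel columns
#'
#' Columns are 1-based and inclusive; the diameter of a frame is averaged
#' over the columns `c0..c1`. An optional row range restricts the wall
#' search vertically.
#'
#' @param c0,c1 first and last column (1 <= c0 <= c1).
#' @param r0,r1 optional first/last row.
#' @return object of class `roi`.
#' @export
roi <- function(c0, c1, r0 = NULL, r1 = NULL) {
  stopifnot(c0 >= 1, c1 >= c0)
  if (!is.null(r0)) stopifnot(r0 >= 1, r1 >= r0)
  structure(list(c0 = as.integer(c0), c1 = as.integer(c1),
                 r0 = if (is.null(r0)) NULL else as.integer(r0),
                 r1 = if (is.null(r1)) NULL else as.integer(r1)),
            class = "roi")
}

#' Lumen diameter of one mask column
#'
#' Finds maximal vertical runs of wall pixels. With two or more runs the
#' diameter is the count of non-wall rows strictly between the last row of
#' the uppermost run and the first row of the lowermost run (so speckle
#' runs in between are excluded from the lumen). Fewer than two runs means
#' no lumen is defined and `NA` is returned.
#'
#' @param column logical or 0/1 vector (one mask column, row 1 at top).
#' @return diameter in px, or `NA_real_` if invalid.
#' @export
column_lumen_diameter <- function(column) {
  w <- which(column > 0)
  if (length(w) < 2) return(NA_real_)
  gaps <- which(diff(w) > 1L)
  if (length(gaps) == 0) return(NA_real_)          # single run
  top_last <- w[gaps[1]]
  bottom_first <- w[gaps[length(gaps)] + 1L]
  span <- bottom_first - top_last - 1L
  wall_between <- sum(w > top_last & w < bottom_first)
  as.numeric(span - wall_between)
}

#' Mean lumen diameter of one frame within an ROI
#'
#' Averages valid column diameters across the ROI and calibrates to um.
#' A frame is invalid (`NA`) when fewer than 25% of ROI columns have a
#' defined lumen.
#'
#' @param mask H x W logical/0-1 wall mask.
#' @param roi a [roi()].
#' @param pixel_size um/px.
#' @param min_valid_frac minimum fraction of valid columns (default 0.25).
#' @return diameter in um, or `NA_real_`.
#' @export
frame_diameter <- function(mask, roi, pixel_size, min_valid_frac = 0.25) {
  H <- nrow(mask); W <- ncol(mask)
  if (roi$c1 > W || roi$c0 < 1)
    stop("ROI bounds error: columns [", roi$c0, ", ", roi$c1,
         "] outside image width ", W, call. = FALSE)
  rows <- if (is.null(roi$r0)) seq_len(H) else {
    if (roi$r1 > H) stop("ROI bounds error: rows outside image height ", H,
                         call. = FALSE)
    roi$r0:roi$r1
  }
  sub <- mask[rows, roi$c0:roi$c1, drop = FALSE]
  d <- apply(sub, 2, column_lumen_diameter)
  valid <- !is.na(d)
  if (mean(valid) < min_valid_frac) return(NA_real_)
  mean(d[valid]) * pixel_size
}

#' Per-frame calibrated diameter trace
#'
#' @param values per-frame mean lumen diameter, um (`NA` where invalid).
#' @param valid logical per-frame validity flags.
#' @param fps frames/s.
#' @param pixel_size um/px.
#' @return object of class `diameter_trace`.
#' @export
diameter_trace <- function(values, valid = !is.na(values), fps, pixel_size) {
  stopifnot(length(values) == length(valid), fps > 0, pixel_size > 0)
  structure(list(values = as.numeric(values), valid = valid, fps = fps,
                 pixel_size = pixel_size),
            class = "diameter_trace")
}

#' Extract a diameter trace from a mask stack
#'
#' Per-frame mean ROI diameter; interior gaps of invalid frames up to
#' `max_gap` frames long are filled by linear interpolation between the
#' nearest valid neighbours (never extrapolated); longer gaps and
#' leading/trailing invalid frames stay flagged invalid and are excluded
#' from beat analysis.
#'
#' @param masks H x W x T logical/0-1 array.
#' @param roi a [roi()]; defaults to the full width.
#' @param pixel_size um/px.
#' @param fps frames/s.
#' @param max_gap longest interior invalid gap filled by interpolation.
#' @return a [diameter_trace()].
#' @export
extract_trace <- function(masks, roi = NULL, pixel_size, fps, max_gap = 5L) {
  stopifnot(length(dim(masks)) == 3)
  W <- dim(masks)[2]; Tn <- dim(masks)[3]
  if (is.null(roi)) roi <- roi(1L, W)
  vals <- vapply(seq_len(Tn), function(t)
    frame_diameter(masks[, , t], roi, pixel_size), numeric(1))
  if (all(is.na(vals)))
    stop("extraction error: no frame has a measurable lumen in the ROI",
         call. = FALSE)
  valid <- !is.na(vals)
  filled <- vals
  idx_valid <- which(valid)
  first_v <- idx_valid[1]; last_v <- idx_valid[length(idx_valid)]
  gaps <- rle(!valid)
  pos <- cumsum(c(1, gaps$lengths))
  for (g in seq_along(gaps$lengths)) {
    if (!gaps$values[g]) next
    s <- pos[g]; e <- pos[g] + gaps$lengths[g] - 1L
    if (s <= first_v || e >= last_v) next            # never extrapolate
    if (gaps$lengths[g] > max_gap) next              # long gaps stay invalid
    filled[s:e] <- stats::approx(x = c(s - 1L, e + 1L),
                                 y = vals[c(s - 1L, e + 1L)],
                                 xout = s:e)$y
    valid[s:e] <- TRUE
  }
  diameter_trace(filled, valid, fps = fps, pixel_size = pixel_size)
}

#' Annotated M-mode image
#'
#' Traces one pixel column of the clip over time (width = T frames), tints
#' wall pixels red, and draws a green vertical line at each DI start (end
#' of relaxation) and a red line at each DI end (next contraction onset).
#'
#' @param clip a [video_clip()].
#' @param masks H x W x T wall masks aligned with `clip`.
#' @param column pixel column to trace (1-based, inside the image).
#' @param beat_table a `beat_table` from [detect_beats()], or `NULL` for an
#'   unannotated M-mode.
#' @return object of class `mmode_image`: list with `image`
#'   (H x T x 3 RGB array in \[0,1\]), `di_start_frames`, `di_end_frames`.
#' @export
make_mmode <- function(clip, masks, column, beat_table = NULL) {
  H <- dim(clip$frames)[1]; W <- dim(clip$frames)[2]; Tn <- dim(clip$frames)[3]
  if (column < 1 || column > W)
    stop("bounds error: column ", column, " outside image width ", W,
         call. = FALSE)
  slab <- clip$frames[, column, ]                   # H x T
  wall <- masks[, column, ] > 0
  img <- array(rep(slab, 3), dim = c(H, Tn, 3))
  # red tint on wall pixels
  img[, , 1][wall] <- pmin(1, slab[wall] + 0.4)
  img[, , 2][wall] <- slab[wall] * 0.5
  img[, , 3][wall] <- slab[wall] * 0.5
  di_start <- integer(0); di_end <- integer(0)
  if (!is.null(beat_table) && nrow(beat_table$beats) > 0) {
    b <- beat_table$beats
    fps <- beat_table$fps
    di_start <- pmin(Tn, pmax(1L, round(b$rel_end_t * fps) + 1L))
    di_end <- pmin(Tn, pmax(1L, round((b$onset_t + b$hp) * fps) + 1L))
    for (f in di_start) { img[, f, 1] <- 0; img[, f, 2] <- 1; img[, f, 3] <- 0 }
    for (f in di_end) { img[, f, 1] <- 1; img[, f, 2] <- 0; img[, f, 3] <- 0 }
  }
  structure(list(image = img, di_start_frames = di_start,
                 di_end_frames = di_end, column = column),
            class = "mmode_image")
}

#' Write an M-mode image as PNG
#' @param mmode an `mmode_image` from [make_mmode()].
#' @param path output path.
#' @export
write_mmode_png <- function(mmode, path) {
  png::writePNG(mmode$image, path)
  invisible(path)
}
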